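# Matching between predictions and the validated set is pair-level
# (mirna_id, target_id): the curated interaction lists carry no site
# coordinates, so a predictor is credited for a pair regardless of the
# exact site it reports.

.unique_keys <- function(df) unique(.pair_key(df$mirna_id, df$target_id))

# best score per (mirna, target) pair, orientation-aware
.pair_level <- function(predictions, orientation) {
  key <- .pair_key(predictions$mirna_id, predictions$target_id)
  o <- if (orientation == "lower_better") order(key, predictions$score)
       else order(key, -predictions$score)
  p <- predictions[o, , drop = FALSE]
  p <- p[!duplicated(.pair_key(p$mirna_id, p$target_id)), , drop = FALSE]
  rownames(p) <- NULL
  p
}

.orientation_of <- function(predictions, orientation = NULL) {
  if (!is.null(orientation)) return(match.arg(orientation,
                                              c("lower_better", "higher_better")))
  o <- attr(predictions, "orientation")
  if (is.null(o)) "lower_better" else o
}

#' Confusion counts of a prediction set against a validated set
#'
#' True positives are validated pairs that are predicted; false positives
#' are predicted pairs that are not validated; false negatives are
#' validated pairs that are not predicted. When a negative (known
#' non-interacting) set is supplied, true negatives are the negatives not
#' predicted.
#'
#' @param predictions,validated,negatives data.frames with `mirna_id` and
#'   `target_id` columns; `negatives` optional.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`
#'   (`tn` is `NA` without negatives).
#' @export
confusion_from_predictions <- function(predictions, validated,
                                       negatives = NULL) {
  pk <- .unique_keys(predictions)
  vk <- .unique_keys(validated)
  tn <- NA_integer_
  if (!is.null(negatives)) {
    nk <- .unique_keys(negatives)
    if (length(intersect(vk, nk)))
      stop("validated and negative sets overlap")
    tn <- length(setdiff(nk, pk))
  }
  structure(list(tp = length(intersect(pk, vk)),
                 fp = length(setdiff(pk, vk)),
                 fn = length(setdiff(vk, pk)),
                 tn = tn),
            class = "confusion_counts")
}

#' Precision and recall from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN). An empty call set has
#' vacuous precision 1.0; recall is likewise 1.0 when there is nothing to
#' recall.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/fn).
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(counts) {
  precision <- if (counts$tp + counts$fp == 0L) 1.0
               else counts$tp / (counts$tp + counts$fp)
  recall <- if (counts$tp + counts$fn == 0L) 1.0
            else counts$tp / (counts$tp + counts$fn)
  c(precision = precision, recall = recall)
}

#' Specificity and sensitivity from confusion counts
#'
#' Specificity = TN/(TN+FP), sensitivity = TP/(TP+FN); requires counts
#' built with a negative set.
#'
#' @inheritParams precision_recall
#' @return named numeric vector `c(specificity =, sensitivity =)`.
#' @export
specificity_sensitivity <- function(counts) {
  if (is.na(counts$tn)) stop("counts carry no true-negative information")
  c(specificity = counts$tn / (counts$tn + counts$fp),
    sensitivity = counts$tp / (counts$tp + counts$fn))
}

#' Precision/recall threshold sweep over all observed scores
#'
#' At every unique prediction score t, the call set is the set of
#' predictions scoring at or better than t (<= t for penalty-like scores,
#' >= t for expectation-like scores), and precision and recall are
#' computed against the validated set. Predictions are first collapsed to
#' pair level (best score per pair).
#'
#' @param predictions prediction data.frame.
#' @param validated validated-interaction data.frame.
#' @param negatives optional negative-pair data.frame (adds a `tn` column).
#' @param orientation `"lower_better"` or `"higher_better"`; defaults to
#'   the `orientation` attribute of `predictions`.
#' @return data.frame of class `threshold_curve` with columns `threshold`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#' @export
threshold_sweep <- function(predictions, validated, negatives = NULL,
                            orientation = NULL) {
  if (!nrow(predictions)) stop("no predictions to sweep")
  orientation <- .orientation_of(predictions, orientation)
  p <- .pair_level(predictions, orientation)
  vk <- .unique_keys(validated)
  nk <- if (is.null(negatives)) NULL else .unique_keys(negatives)
  if (!is.null(nk) && length(intersect(vk, nk)))
    stop("validated and negative sets overlap")
  keys <- .pair_key(p$mirna_id, p$target_id)
  grid <- sort(unique(p$score))
  rows <- lapply(grid, function(t) {
    called <- if (orientation == "lower_better") keys[p$score <= t]
              else keys[p$score >= t]
    tp <- length(intersect(called, vk))
    fp <- length(setdiff(called, vk))
    fn <- length(setdiff(vk, called))
    tn <- if (is.null(nk)) NA_integer_ else length(setdiff(nk, called))
    pr <- precision_recall(list(tp = tp, fp = fp, fn = fn))
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = pr[["precision"]], recall = pr[["recall"]])
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("threshold_curve", "data.frame")
  attr(curve, "orientation") <- orientation
  curve
}

#' Optimal score of a threshold curve
#'
#' The score cutoff at which precision and recall intersect: the grid
#' threshold minimizing |precision - recall|, ties broken toward larger
#' precision + recall, then toward the smaller threshold.
#'
#' @param curve a `threshold_curve` from [threshold_sweep()] (or any
#'   data.frame with `threshold`, `precision`, `recall`).
#' @return a single threshold value.
#' @export
optimal_score <- function(curve) {
  if (!nrow(curve)) stop("empty curve")
  gap <- abs(curve$precision - curve$recall)
  tot <- curve$precision + curve$recall
  o <- order(gap, -tot, curve$threshold)
  curve$threshold[o[1L]]
}

#' ROC curve and AUC for scored positives and negatives
#'
#' Sweeps all observed scores, computing the true- and false-positive
#' rates of the call set at each threshold; the area under the curve is
#' the trapezoid rule, which equals the probability that a random positive
#' scores better than a random negative (ties counted 1/2).
#'
#' @param positive_scores,negative_scores numeric vectors (non-empty).
#' @param orientation `"lower_better"` or `"higher_better"`.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(positive_scores, negative_scores,
                    orientation = c("lower_better", "higher_better")) {
  orientation <- match.arg(orientation)
  if (!length(positive_scores) || !length(negative_scores))
    stop("both score sets must be non-empty")
  pos <- if (orientation == "lower_better") -positive_scores else positive_scores
  neg <- if (orientation == "lower_better") -negative_scores else negative_scores
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Combine two prediction sets by union or intersection
#'
#' Set algebra on (mirna_id, target_id) keys after collapsing each input
#' to pair level. The retained score is the better of the two for a union
#' and the worse of the two for an intersection (orientation-aware), so a
#' union is exactly as permissive, and an intersection exactly as
#' conservative, as its inputs.
#'
#' @param set_a,set_b prediction data.frames.
#' @param mode `"union"` or `"intersection"`.
#' @param orientation score orientation shared by both sets; defaults to
#'   the `orientation` attribute of `set_a`.
#' @return combined prediction data.frame.
#' @export
combine_predictions <- function(set_a, set_b,
                                mode = c("union", "intersection"),
                                orientation = NULL) {
  mode <- match.arg(mode)
  orientation <- .orientation_of(set_a, orientation)
  a <- .pair_level(set_a, orientation)
  b <- .pair_level(set_b, orientation)
  ka <- .pair_key(a$mirna_id, a$target_id)
  kb <- .pair_key(b$mirna_id, b$target_id)
  better <- if (orientation == "lower_better") pmin else pmax
  worse <- if (orientation == "lower_better") pmax else pmin
  if (mode == "union") {
    only_a <- a[!(ka %in% kb), , drop = FALSE]
    only_b <- b[!(kb %in% ka), , drop = FALSE]
    shared <- a[ka %in% kb, , drop = FALSE]
    if (nrow(shared)) {
      m <- match(.pair_key(shared$mirna_id, shared$target_id), kb)
      shared$score <- better(shared$score, b$score[m])
    }
    out <- rbind(shared, only_a, only_b)
  } else {
    out <- a[ka %in% kb, , drop = FALSE]
    if (nrow(out)) {
      m <- match(.pair_key(out$mirna_id, out$target_id), kb)
      out$score <- worse(out$score, b$score[m])
    }
  }
  if (nrow(out))
    out$tool <- paste0(mode, "(",
                       paste(sort(unique(c(set_a$tool, set_b$tool))),
                             collapse = ","), ")")
  rownames(out) <- NULL
  attr(out, "orientation") <- orientation
  out
}

#' Free energy versus transcript length trend
#'
#' Locally weighted (lowess) smoothing of duplex free energy against
#' transcript length, with the Spearman rank correlation. A negative rho
#' and a decreasing smoothed curve indicate that longer transcripts tend
#' to reach lower (more favorable) free energies.
#'
#' @param records data.frame with columns `transcript_length` and
#'   `delta_g` (kcal/mol); at least 10 rows.
#' @param span lowess smoother span (fraction of points).
#' @return list with `curve` (data.frame `transcript_length`,
#'   `delta_g_smooth`), `rho` and `p_value`.
#' @export
energy_length_trend <- function(records, span = 2 / 3) {
  stopifnot(all(c("transcript_length", "delta_g") %in% names(records)))
  if (nrow(records) < 10L) stop("need at least 10 energy records")
  lw <- lowess(records$transcript_length, records$delta_g, f = span)
  rho <- suppressWarnings(
    cor(records$transcript_length, records$delta_g, method = "spearman"))
  if (is.na(rho)) rho <- 0  # zero-variance input: no rank trend
  pv <- suppressWarnings(
    cor.test(records$transcript_length, records$delta_g,
             method = "spearman", exact = FALSE)$p.value)
  list(curve = data.frame(transcript_length = lw$x, delta_g_smooth = lw$y),
       rho = rho, p_value = pv)
}
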