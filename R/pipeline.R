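.default_run_config <- function() {
  list(
    study = list(n_tp = 40L, n_fn = 40L, n_decoys = 12L,
                 mirna_length = 21L, gc_target = NULL,
                 transcript_length_range = c(300L, 600L),
                 energy_slope = -0.05, energy_intercept = -10,
                 energy_sd = 5, guard_penalty = 6),
    predictors = list(
      stringent = list(cutoff = 2.5),
      tolerant = list(cutoff = 4.5, wobble = 0.25)),
    roc_cutoff = 8,
    seed = 42L)
}

.merge_config <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

.predictor_config <- function(p) {
  duplex_config(wobble = if (is.null(p$wobble)) 0.5 else p$wobble,
                mismatch = if (is.null(p$mismatch)) 1 else p$mismatch,
                gap = if (is.null(p$gap)) 1 else p$gap)
}

# per-pair best score (censored for pairs with no hit) for ROC scoring
.pair_scores <- function(predictions, pairs, censor) {
  key <- .pair_key(pairs$mirna_id, pairs$target_id)
  if (!nrow(predictions)) return(rep(censor, length(key)))
  p <- .pair_level(predictions, "lower_better")
  m <- match(key, .pair_key(p$mirna_id, p$target_id))
  ifelse(is.na(m), censor, p$score[m])
}

#' Run the full synthetic evaluation-and-characterization study
#'
#' Generates a synthetic benchmark ([generate_study()]), runs the
#' reference scanner as two predictors of different stringency, evaluates
#' each against the implanted validated set (confusion counts at the
#' default and at the optimal cutoff, precision/recall threshold sweep,
#' ROC/AUC with decoy pairs as negatives), combines the predictors by
#' union and intersection, characterizes the TP-like versus FN-like
#' groups (duplex features with Wilcoxon rank tests, positional entropy
#' profiles, alignment-vector clustering), and fits the free energy
#' versus transcript length trend. The whole run is deterministic given
#' the seed.
#'
#' For ROC scoring, every validated and negative pair is scanned at
#' `roc_cutoff` and pairs with no reported site are censored at
#' `roc_cutoff + 1` (a score worse than any reported one).
#'
#' @param config named list overriding the defaults (see
#'   `mirduplex:::.default_run_config()`), or a path to a JSON file with
#'   the same structure.
#' @param seed integer; overrides `config$seed`.
#' @return a nested report list of class `mirduplex_report`.
#' @export
run_study <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- .merge_config(.default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  study <- do.call(generate_study, c(cfg$study, list(seed = cfg$seed)))
  all_tx <- c(study$transcripts, study$decoys)
  validated <- study$interactions
  negatives <- study$negatives
  censor <- cfg$roc_cutoff + 1

  predictors <- list()
  predictions <- list()
  for (nm in names(cfg$predictors)) {
    p <- cfg$predictors[[nm]]
    pcfg <- .predictor_config(p)
    preds <- predict_transcriptome(study$mirnas, all_tx, cutoff = p$cutoff,
                                   config = pcfg, tool = nm)
    predictions[[nm]] <- preds
    entry <- list(cutoff = p$cutoff,
                  n_predictions = nrow(preds),
                  mean_per_mirna = attr(preds, "mean_per_mirna"))
    if (nrow(preds)) {
      counts <- confusion_from_predictions(preds, validated, negatives)
      entry$default_counts <- unclass(counts)
      entry$default_pr <- as.list(precision_recall(counts))
      curve <- threshold_sweep(preds, validated, negatives)
      entry$curve <- as.data.frame(curve)
      opt <- optimal_score(curve)
      entry$optimal_score <- opt
      at_opt <- preds[preds$score <= opt, , drop = FALSE]
      opt_counts <- confusion_from_predictions(at_opt, validated, negatives)
      entry$optimal_counts <- unclass(opt_counts)
      entry$optimal_pr <- as.list(precision_recall(opt_counts))
    }
    deep <- predict_transcriptome(study$mirnas, all_tx,
                                  cutoff = cfg$roc_cutoff, config = pcfg,
                                  tool = nm)
    pos <- .pair_scores(deep, validated, censor)
    neg <- .pair_scores(deep, negatives, censor)
    roc <- roc_auc(pos, neg, orientation = "lower_better")
    entry$auc <- roc$auc
    predictors[[nm]] <- entry
  }

  combinations <- list()
  if (length(predictions) >= 2L) {
    nms <- names(predictions)[1:2]
    for (mode in c("union", "intersection")) {
      comb <- combine_predictions(predictions[[nms[1]]],
                                  predictions[[nms[2]]], mode = mode)
      counts <- confusion_from_predictions(comb, validated, negatives)
      combinations[[mode]] <- list(
        of = nms, counts = unclass(counts),
        pr = as.list(precision_recall(counts)))
    }
  }

  # TP-like vs FN-like characterization from the ground-truth duplexes
  keys <- .pair_key(validated$mirna_id, validated$target_id)
  alns <- study$alignments[keys]
  feats <- do.call(rbind, lapply(alns, interaction_features))
  feats$group <- validated$group
  rownames(feats) <- NULL
  tests <- list()
  for (f in c("gc_fraction", "max_match_stretch", "first_stretch",
              "match_mismatch_ratio")) {
    a <- feats[[f]][feats$group == "tp_like"]
    b <- feats[[f]][feats$group == "fn_like"]
    a[!is.finite(a)] <- max(feats[[f]][is.finite(feats[[f]])], 21) + 1
    b[!is.finite(b)] <- max(feats[[f]][is.finite(feats[[f]])], 21) + 1
    tests[[f]] <- compare_feature_distributions(a, b)
  }
  ent <- list(
    tp_like = entropy_profile(alns[validated$group == "tp_like"]),
    fn_like = entropy_profile(alns[validated$group == "fn_like"]))
  vecs <- t(vapply(alns, alignment_vector, numeric(20L)))
  hc <- cluster_alignment_vectors(vecs)
  trend <- energy_length_trend(study$energy)

  structure(list(
    seed = cfg$seed,
    sizes = list(n_tp = cfg$study$n_tp, n_fn = cfg$study$n_fn,
                 n_decoys = cfg$study$n_decoys),
    predictors = predictors,
    combinations = combinations,
    features = list(table = feats, tests = tests),
    entropy = ent,
    clustering = list(n = nrow(vecs), leaf_order = hc$order,
                      max_merge_height = max(hc$height)),
    energy_trend = list(rho = trend$rho, p_value = trend$p_value,
                        curve = trend$curve)),
    class = "mirduplex_report")
}

#' Write a study report as JSON
#'
#' @param report a `mirduplex_report` from [run_study()].
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(path)
}

#' @export
print.mirduplex_report <- function(x, ...) {
  cat("mirduplex study report (seed ", x$seed, ")\n", sep = "")
  cat("  interactions: ", x$sizes$n_tp, " TP-like + ", x$sizes$n_fn,
      " FN-like; ", x$sizes$n_decoys, " decoys\n", sep = "")
  for (nm in names(x$predictors)) {
    p <- x$predictors[[nm]]
    cat(sprintf("  %-10s cutoff %.2f: %d predictions", nm, p$cutoff,
                p$n_predictions))
    if (!is.null(p$optimal_pr))
      cat(sprintf("; optimal score %.2f (P %.2f / R %.2f); AUC %.3f",
                  p$optimal_score, p$optimal_pr$precision,
                  p$optimal_pr$recall, p$auc))
    cat("\n")
  }
  for (m in names(x$combinations)) {
    cm <- x$combinations[[m]]
    cat(sprintf("  %-12s of %s: TP %d, FP %d\n", m,
                paste(cm$of, collapse = "+"), cm$counts$tp, cm$counts$fp))
  }
  for (f in names(x$features$tests))
    cat(sprintf("  %-22s Wilcoxon p = %.3g\n", f,
                x$features$tests[[f]]$p_value))
  cat(sprintf("  energy~length Spearman rho = %.3f\n", x$energy_trend$rho))
  invisible(x)
}
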