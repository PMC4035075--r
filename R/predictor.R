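# Candidate site windows end at transcript position e, where e is fixed by
# the anchor: miRNA position i pairs transcript position e - i + 1, so the
# reverse complement of miRNA positions 2..8 must occur (allowing one
# substitution) at transcript [e - 7, e - 1]. Window lengths between
# nchar(mirna) - max_gaps and nchar(mirna) + max_gaps are aligned and the
# best-scoring window per end is kept.

.seed_anchor_ends <- function(mirna, transcript, max_mismatch = 1L) {
  seed <- substr(mirna, 2L, 8L)
  if (nchar(seed) < 7L) return(integer(0))
  pat <- Biostrings::RNAString(reverse_complement_rna(seed))
  m <- Biostrings::matchPattern(pat, Biostrings::RNAString(transcript),
                                max.mismatch = max_mismatch)
  Biostrings::start(m) + 7L
}

.align_best_window <- function(mirna, transcript, e, config) {
  n <- nchar(mirna)
  len <- nchar(transcript)
  best <- NULL
  for (L in (n - config$max_gaps):(n + config$max_gaps)) {
    if (L < 1L) next
    s <- e - L + 1L
    if (s < 1L || e > len) next
    site <- substr(transcript, s, e)
    aln <- align_duplex(mirna, site, config, site_start = s, site_end = e)
    if (is.null(aln)) next
    if (is.null(best) || aln$penalty < best$penalty - 1e-9 ||
        (abs(aln$penalty - best$penalty) < 1e-9 && aln$n_gaps < best$n_gaps))
      best <- aln
  }
  best
}

# keep the lowest-penalty site per cluster of overlapping hits, leftmost on ties
.collapse_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$site_start, hits$site_end), , drop = FALSE]
  keep <- logical(nrow(hits))
  i <- 1L
  while (i <= nrow(hits)) {
    j <- i
    hi <- hits$site_end[i]
    while (j < nrow(hits) && hits$site_start[j + 1L] <= hi) {
      j <- j + 1L
      hi <- max(hi, hits$site_end[j])
    }
    block <- i:j
    best <- block[which.min(hits$score[block])]  # which.min: leftmost tie
    keep[best] <- TRUE
    i <- j + 1L
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_predictions <- function() {
  data.frame(mirna_id = character(0), target_id = character(0),
              score = numeric(0), site_start = integer(0),
              site_end = integer(0), tool = character(0),
              stringsAsFactors = FALSE)
}

#' Scan one transcript for target sites of one miRNA
#'
#' Slides the miRNA over the transcript, aligns candidate site windows with
#' [align_duplex()], and reports non-overlapping sites whose penalty is at
#' or below `cutoff` (lowest-penalty site per overlapping cluster, leftmost
#' on ties). By default candidate windows are pre-filtered by a seed
#' anchor: the reverse complement of miRNA positions 2-8 must match the
#' transcript with at most one substitution. `exhaustive = TRUE` aligns
#' every window instead.
#'
#' @param mirna,transcript RNA sequences (single strings, 5'->3').
#' @param cutoff maximum reported penalty (>= 0).
#' @param config a [duplex_config()].
#' @param mirna_id,target_id identifiers for the output rows.
#' @param tool tool label for the output rows.
#' @param exhaustive align every window instead of seed-anchored ones.
#' @return prediction data.frame (columns `mirna_id, target_id, score,
#'   site_start, site_end, tool`); empty when the transcript is shorter
#'   than the miRNA or nothing scores below the cutoff.
#' @export
scan_transcript <- function(mirna, transcript, cutoff, config = duplex_config(),
                            mirna_id = "mirna", target_id = "target",
                            tool = "mirduplex", exhaustive = FALSE) {
  stopifnot(cutoff >= 0)
  n <- nchar(mirna)
  if (nchar(transcript) < n) return(.empty_predictions())
  ends <- if (exhaustive || n < 9L) seq_len(nchar(transcript))
          else .seed_anchor_ends(mirna, transcript)
  ends <- ends[ends >= n - config$max_gaps & ends <= nchar(transcript)]
  hits <- .empty_predictions()
  for (e in ends) {
    aln <- .align_best_window(mirna, transcript, e, config)
    if (is.null(aln) || aln$penalty > cutoff) next
    hits <- rbind(hits, data.frame(
      mirna_id = mirna_id, target_id = target_id, score = aln$penalty,
      site_start = aln$site_start, site_end = aln$site_end, tool = tool,
      stringsAsFactors = FALSE))
  }
  out <- .collapse_overlaps(hits)
  attr(out, "orientation") <- "lower_better"
  out
}

#' Predict targets for a set of miRNAs over a set of transcripts
#'
#' Runs [scan_transcript()] for every miRNA x transcript pair and
#' concatenates the hits. The mean number of predictions per miRNA is
#' attached as attribute `mean_per_mirna`.
#'
#' @param mirnas,transcripts named character vectors of RNA sequences.
#' @inheritParams scan_transcript
#' @return prediction data.frame with attributes `orientation` and
#'   `mean_per_mirna`.
#' @export
predict_transcriptome <- function(mirnas, transcripts, cutoff,
                                  config = duplex_config(),
                                  tool = "mirduplex", exhaustive = FALSE) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  subject <- Biostrings::RNAStringSet(transcripts)
  out <- list()
  for (mid in names(mirnas)) {
    mirna <- mirnas[[mid]]
    if (exhaustive || nchar(mirna) < 9L) {
      tids <- names(transcripts)
    } else {
      seed <- substr(mirna, 2L, 8L)
      pat <- reverse_complement_rna(seed)
      hitcount <- Biostrings::vcountPattern(pat, subject, max.mismatch = 1L)
      tids <- names(transcripts)[hitcount > 0L]
    }
    for (tid in tids) {
      h <- scan_transcript(mirna, transcripts[[tid]], cutoff, config,
                           mirna_id = mid, target_id = tid, tool = tool,
                           exhaustive = exhaustive)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_predictions()
  rownames(res) <- NULL
  attr(res, "orientation") <- "lower_better"
  attr(res, "mean_per_mirna") <- nrow(res) / length(mirnas)
  res
}
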