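#' Read RNA sequences from a FASTA file
#'
#' DNA input is accepted and normalized (T -> U); sequences are upper-cased
#' and must contain only A/C/G/U after normalization. The identifier is the
#' first whitespace-delimited token of the header line.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences (5'->3'), in file order.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("Tt", "Uu", toupper(as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record: ", ids[!nzchar(seqs)][1L])
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier: ", dup[1L])
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-RNA characters in record ", ids[bad][1L])
  setNames(seqs, ids)
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs named character vector of RNA sequences.
#' @param path output file.
#' @export
write_rna_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(seqs), path)
  invisible(path)
}

.INTERACTION_COLS <- c("mirna_id", "target_id", "species", "dataset", "source")

#' Read a validated-interaction table
#'
#' Tab-separated with header `mirna_id, target_id, species, dataset,
#' source`. Exact duplicate (mirna_id, target_id) pairs are collapsed
#' (first occurrence kept); the number of raw rows is recorded in the
#' `n_raw` attribute and unique-pair counts per dataset label are available
#' via `table(x$dataset)`.
#'
#' @param path TSV file.
#' @return data.frame of unique interactions.
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.INTERACTION_COLS, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "),
         "; expected header: ", paste(.INTERACTION_COLS, collapse = ", "))
  df <- df[, .INTERACTION_COLS]
  n_raw <- nrow(df)
  df <- df[!duplicated(.pair_key(df$mirna_id, df$target_id)), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_raw") <- n_raw
  df
}

#' @rdname read_interaction_table
#' @param records interaction data.frame.
#' @export
write_interaction_table <- function(records, path) {
  write.table(records[, .INTERACTION_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored-prediction table
#'
#' Tab-separated with header containing at least `mirna_id, target_id,
#' score`; optional columns `site_start`, `site_end`, `tool`. The score
#' orientation (whether lower or higher scores are better) is recorded in
#' the `orientation` attribute so threshold sweeps stay orientation-aware.
#'
#' @param path TSV file.
#' @param score_orientation `"lower_better"` (penalty-like, the default) or
#'   `"higher_better"` (expectation/score-like).
#' @return data.frame of predictions with attribute `orientation`.
#' @export
read_prediction_table <- function(path,
                                  score_orientation = c("lower_better",
                                                        "higher_better")) {
  score_orientation <- match.arg(score_orientation)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "score")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "))
  sc <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(sc) | !is.finite(sc))
  if (length(bad))
    stop("non-numeric or non-finite score at row ", bad[1L])
  df$score <- sc
  if (!"tool" %in% names(df)) df$tool <- "unknown"
  for (col in c("site_start", "site_end"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  ok <- is.na(df$site_start) | is.na(df$site_end) |
    df$site_start <= df$site_end
  if (!all(ok))
    stop("site_start > site_end at row ", which(!ok)[1L])
  df <- df[, c("mirna_id", "target_id", "score",
               "site_start", "site_end", "tool")]
  attr(df, "orientation") <- score_orientation
  df
}

#' @rdname read_prediction_table
#' @param predictions prediction data.frame.
#' @export
write_prediction_table <- function(predictions, path) {
  write.table(predictions[, c("mirna_id", "target_id", "score",
                              "site_start", "site_end", "tool")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' miRNA family name of a mature-miRNA identifier
#'
#' Strips a species prefix ("ath-", "osa-", ...) and a mature-arm suffix
#' ("-5p"/"-3p"). Lettered variants (miR414a vs miR414) are distinct
#' families and are NOT merged.
#'
#' @param ids character vector of miRNA identifiers.
#' @return character vector of family names.
#' @examples
#' mirna_family(c("osa-miR414", "ath-miR167a-5p"))  # "miR414" "miR167a"
#' @export
mirna_family <- function(ids) {
  out <- sub("^[A-Za-z]{2,4}-", "", ids)
  sub("-[35]p$", "", out)
}

#' Remove interactions whose miRNA belongs to a blacklisted family
#'
#' Families flagged as ambiguous (the miR414 and miR413 annotations) are
#' removed wholesale, matching by [mirna_family()]. The number of removed
#' records is stored in the `n_removed` attribute.
#'
#' @param records interaction data.frame.
#' @param blacklist character vector of family names, e.g.
#'   `c("miR414", "miR413")`.
#' @return filtered data.frame.
#' @export
filter_ambiguous_mirnas <- function(records,
                                    blacklist = c("miR414", "miR413")) {
  if (!length(blacklist)) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  drop <- mirna_family(records$mirna_id) %in% blacklist
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}
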