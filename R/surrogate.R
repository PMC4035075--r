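#' Synthetic surrogate of the curated interaction lists
#'
#' The published curated lists of experimentally validated miRNA-mRNA
#' interactions (330 unique Arabidopsis pairs; 134 unique pairs from other
#' plant species, 115 after removing the ambiguous miR414 and miR413
#' families) are distributed as a spreadsheet that is not bundled here.
#' This function deterministically constructs a synthetic stand-in table
#' with the same cardinality structure — including raw-row duplicates that
#' the reader must collapse and miR413/miR414 family members under varied
#' species prefixes and mature-arm suffixes — so the deduplication and
#' family-filter bookkeeping can be exercised end-to-end. Identifiers are
#' synthetic; they follow miRBase/AGI naming conventions only in shape.
#'
#' The same table ships as
#' `inst/extdata/synthetic_curated_interactions.tsv`.
#'
#' @return data.frame with columns `mirna_id, target_id, species, dataset,
#'   source`, including duplicate rows (352 Arabidopsis raw rows for 330
#'   unique pairs; 140 non-Arabidopsis raw rows for 134 unique pairs, 19
#'   of which belong to the blacklisted families).
#' @export
curated_surrogate_interactions <- function() {
  src <- "synthetic surrogate"
  # Arabidopsis sheet: 330 unique pairs, 22 raw duplicates
  k <- seq_len(330L)
  ath <- data.frame(
    mirna_id = paste0("ath-miR", 156L + (k - 1L) %% 60L,
                      letters[(k - 1L) %/% 60L + 1L]),
    target_id = sprintf("AT%dG%05d", 1L + (k - 1L) %% 5L, 10000L + k * 10L),
    species = "ath", dataset = "arabidopsis", source = src,
    stringsAsFactors = FALSE)
  ath <- rbind(ath, ath[seq_len(22L), ])

  # non-Arabidopsis sheets: 115 unambiguous pairs ...
  sp <- c("osa", "gma", "vvi")
  j <- seq_len(115L)
  keep <- data.frame(
    mirna_id = paste0(sp[(j - 1L) %% 3L + 1L], "-miR",
                      160L + (j - 1L) %% 13L,
                      letters[(j - 1L) %/% 39L + 1L],
                      ifelse(j %% 7L == 0L, "-5p", "")),
    target_id = sprintf("%s%06d",
                        c("LOC_Os", "Glyma", "VIT_")[(j - 1L) %% 3L + 1L],
                        200000L + j * 7L),
    species = sp[(j - 1L) %% 3L + 1L], dataset = "non_arabidopsis",
    source = src, stringsAsFactors = FALSE)
  # ... plus 19 pairs from the ambiguous miR413/miR414 families
  fam <- rep(c("miR413", "miR414"), length.out = 19L)
  arm <- rep(c("", "-5p", "", "-3p", ""), length.out = 19L)
  i <- seq_len(19L)
  amb <- data.frame(
    mirna_id = paste0(sp[(i - 1L) %% 3L + 1L], "-", fam, arm),
    target_id = sprintf("%s%06d",
                        c("LOC_Os", "Glyma", "VIT_")[(i - 1L) %% 3L + 1L],
                        900000L + i * 3L),
    species = sp[(i - 1L) %% 3L + 1L], dataset = "non_arabidopsis",
    source = src, stringsAsFactors = FALSE)
  non_ath <- rbind(keep, amb)
  non_ath <- rbind(non_ath, non_ath[seq_len(6L), ])  # 6 raw duplicates

  out <- rbind(ath, non_ath)
  rownames(out) <- NULL
  out
}
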