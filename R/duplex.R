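#' Scoring configuration for duplex alignment
#'
#' The penalty scheme of the plant target-prediction family: Watson-Crick
#' matches are free, G:U wobbles cost half a mismatch, mismatches and
#' gaps/bulges cost one unit, and every cost is multiplied inside the seed
#' window (positions counted from the miRNA 5' end). Lower penalties mean
#' better duplexes.
#'
#' @param match,wobble,mismatch,gap per-position costs (non-negative).
#' @param seed_window integer length-2 vector, 1-based inclusive positions
#'   from the miRNA 5' end that receive the seed weighting.
#' @param seed_multiplier factor applied to costs inside `seed_window`.
#' @param max_gaps maximum number of gap columns allowed in one duplex;
#'   beyond this no alignment is reported.
#' @return a list of class `duplex_config`.
#' @export
duplex_config <- function(match = 0, wobble = 0.5, mismatch = 1, gap = 1,
                          seed_window = c(2L, 13L), seed_multiplier = 2,
                          max_gaps = 3L) {
  stopifnot(match >= 0, wobble >= 0, mismatch >= 0, gap >= 0,
            length(seed_window) == 2L, seed_window[1] <= seed_window[2],
            seed_multiplier >= 1, max_gaps >= 0L)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap = gap, seed_window = as.integer(seed_window),
                 seed_multiplier = seed_multiplier,
                 max_gaps = as.integer(max_gaps)),
            class = "duplex_config")
}

#' Classify one miRNA:target base pair
#'
#' Returns `"M"` for a Watson-Crick pair (A:U or G:C), `"W"` for a G:U
#' wobble, `"X"` for any other base combination, and `"G"` when either
#' symbol is the gap character `"-"`.
#'
#' @param mirna_base,target_base character vectors of single bases
#'   (A/C/G/U or "-"); recycled to common length.
#' @return character vector over {M, W, X, G}.
#' @examples
#' classify_pair("G", "C")  # "M"
#' classify_pair("G", "U")  # "W"
#' @export
classify_pair <- function(mirna_base, target_base) {
  n <- max(length(mirna_base), length(target_base))
  a <- rep_len(as.character(mirna_base), n)
  b <- rep_len(as.character(target_base), n)
  ok <- c(.BASES, .GAP)
  bad <- unique(c(a, b)[!(c(a, b) %in% ok)])
  if (length(bad))
    stop("invalid base character(s): ", paste(bad, collapse = ", "))
  out <- rep("X", n)
  out[a == .GAP | b == .GAP] <- "G"
  pair <- ifelse(a <= b, paste0(a, b), paste0(b, a))  # unordered
  out[out != "G" & pair %in% c("AU", "CG")] <- "M"
  out[out != "G" & pair == "GU"] <- "W"
  out
}

#' Penalty of a duplex state string
#'
#' Sums per-position costs (match 0, wobble 0.5, mismatch 1, gap 1 by
#' default), doubling positions that fall inside the seed window.
#'
#' @param states character: either one string such as `"MMWX"` or a vector
#'   of single states.
#' @param seed_window 1-based inclusive position range receiving the seed
#'   multiplier.
#' @param config a [duplex_config()] supplying costs and the multiplier.
#' @return a single non-negative number.
#' @examples
#' penalty_score("MMMM")                       # 0
#' penalty_score(c("M","M","M","M","X"))       # 2: mismatch inside seed
#' @export
penalty_score <- function(states, seed_window = config$seed_window,
                          config = duplex_config()) {
  s <- if (length(states) == 1L) strsplit(states, "", fixed = TRUE)[[1L]]
       else as.character(states)
  if (!length(s)) stop("empty state string")
  if (!all(s %in% c("M", "W", "X", "G")))
    stop("states must be over {M, W, X, G}")
  cost <- c(M = config$match, W = config$wobble,
            X = config$mismatch, G = config$gap)[s]
  pos <- seq_along(s)
  w <- ifelse(pos >= seed_window[1] & pos <= seed_window[2],
              config$seed_multiplier, 1)
  sum(cost * w)
}

.new_duplex_alignment <- function(mirna_id, target_id, site_start, site_end,
                                  aligned_mirna, aligned_target, states,
                                  penalty, n_gaps) {
  structure(list(mirna_id = mirna_id, target_id = target_id,
                 site_start = as.integer(site_start),
                 site_end = as.integer(site_end),
                 aligned_mirna = aligned_mirna,
                 aligned_target = aligned_target,
                 states = states, penalty = penalty,
                 n_gaps = as.integer(n_gaps)),
            class = "duplex_alignment")
}

#' Align a miRNA against a candidate target site
#'
#' Global minimum-penalty alignment of the miRNA (5'->3') against the
#' reversed site, so that under the gap-free convention miRNA position i
#' pairs with site position `nchar(site) - i + 1`. Gapped alignments (up to
#' `config$max_gaps` gap columns) are explored by dynamic programming;
#' penalties follow [penalty_score()] with the seed window indexed by
#' alignment column from the miRNA 5' end. Ties are broken toward fewer
#' gaps, then gaps placed closer to the miRNA 3' end.
#'
#' @param mirna,site RNA sequences (single strings, A/C/G/U, both 5'->3').
#' @param config a [duplex_config()].
#' @param mirna_id,target_id optional identifiers carried into the result.
#' @param site_start,site_end 1-based transcript coordinates of `site`
#'   (defaults treat `site` as its own coordinate system).
#' @return a `duplex_alignment` (fields `aligned_mirna` 5'->3',
#'   `aligned_target` 3'->5' column-aligned to the miRNA, `states`,
#'   `penalty`, `n_gaps`), or `NULL` when no alignment exists within the
#'   gap limit.
#' @examples
#' aln <- align_duplex("AAGG", "CCUU")
#' aln$states   # "MMMM"
#' aln$penalty  # 0
#' @export
align_duplex <- function(mirna, site, config = duplex_config(),
                         mirna_id = NA_character_, target_id = NA_character_,
                         site_start = 1L, site_end = nchar(site)) {
  if (!nzchar(mirna) || !nzchar(site)) stop("empty sequence")
  x <- .encode_rna(.rna_chars(mirna))
  y <- .encode_rna(rev(.rna_chars(site)))  # site 3'->5', columns follow miRNA
  res <- .align_core(x, y, config$wobble, config$mismatch, config$gap,
                     config$seed_window[1], config$seed_window[2],
                     config$seed_multiplier, config$max_gaps)
  if (!res$feasible) return(NULL)
  dec <- function(v) paste(c(.GAP, .BASES)[v + 2L], collapse = "")
  st <- paste(c("M", "W", "X", "G")[res$states + 1L], collapse = "")
  .new_duplex_alignment(mirna_id, target_id, site_start, site_end,
                        dec(res$x_aln), dec(res$y_aln), st,
                        res$penalty, res$n_gaps)
}

#' @export
format.duplex_alignment <- function(x, ...) {
  mid <- chartr("MWXG", "|:  ", x$states)
  paste0("miRNA  5' ", x$aligned_mirna, " 3'\n",
         "          ", mid, "\n",
         "target 3' ", x$aligned_target, " 5'   [",
         x$site_start, "-", x$site_end, "]  penalty ",
         format(x$penalty), "\n")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(format(x, ...))
  invisible(x)
}

# state characters of an alignment (or of a raw state string)
.states_of <- function(x) {
  if (inherits(x, "duplex_alignment")) x <- x$states
  if (length(x) == 1L && nchar(x[1L]) > 1L)
    strsplit(x, "", fixed = TRUE)[[1L]]
  else as.character(x)
}
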