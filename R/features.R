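#' GC content of an RNA sequence
#'
#' @param x character vector of RNA sequences.
#' @return fraction of G+C residues, in \[0, 1\].
#' @export
gc_content <- function(x) {
  stopifnot(all(nzchar(x)))
  gc <- nchar(gsub("[^GC]", "", x))
  gc / nchar(x)
}

#' Longest continuous match stretch of a duplex
#'
#' Length of the longest run of Watson-Crick matches (state M) in the
#' alignment; wobbles, mismatches and gaps all break the run. This is the
#' duplex's "seed region" in the longest-complementary-stretch sense.
#'
#' @param alignment a `duplex_alignment` or a state string/vector.
#' @return integer >= 0.
#' @export
max_match_stretch <- function(alignment) {
  s <- .states_of(alignment)
  r <- rle(s == "M")
  if (!any(r$values)) return(0L)
  as.integer(max(r$lengths[r$values]))
}

#' First match stretch of a duplex
#'
#' Starting at the first matched position (from the miRNA 5' end), the
#' number of consecutive matches until the first non-match state. Leading
#' non-match states are skipped; an alignment with no match returns 0.
#'
#' @inheritParams max_match_stretch
#' @return integer >= 0.
#' @export
first_stretch <- function(alignment) {
  s <- .states_of(alignment)
  first <- match("M", s)
  if (is.na(first)) return(0L)
  r <- rle(s[first:length(s)] == "M")
  as.integer(r$lengths[1L])
}

#' Match/mismatch ratio of a duplex
#'
#' Total matches (M) divided by total mismatches plus gaps (X + G);
#' wobbles are counted in neither term. `Inf` when there is no mismatch.
#'
#' @inheritParams max_match_stretch
#' @return non-negative number, possibly `Inf`.
#' @export
match_mismatch_ratio <- function(alignment) {
  s <- .states_of(alignment)
  nm <- sum(s == "M")
  nx <- sum(s %in% c("X", "G"))
  if (nx == 0L) return(Inf)
  nm / nx
}

#' Duplex feature vector of one interaction
#'
#' The four features used to contrast true-positive and false-negative
#' interactions: miRNA GC content, longest match stretch, first match
#' stretch, and the match/mismatch ratio.
#'
#' @param alignment a `duplex_alignment`.
#' @return one-row data.frame with columns `gc_fraction`,
#'   `max_match_stretch`, `first_stretch`, `match_mismatch_ratio`.
#' @export
interaction_features <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  mirna <- gsub("-", "", alignment$aligned_mirna, fixed = TRUE)
  data.frame(gc_fraction = gc_content(mirna),
             max_match_stretch = max_match_stretch(alignment),
             first_stretch = first_stretch(alignment),
             match_mismatch_ratio = match_mismatch_ratio(alignment))
}

# states of an alignment truncated/padded to `len` positions; absence of
# pairing is treated as non-complementarity (pad state X)
.states_fixed_length <- function(alignment, len = 20L) {
  s <- .states_of(alignment)
  if (length(s) >= len) s[seq_len(len)] else c(s, rep("X", len - length(s)))
}

#' Positional Shannon entropy profile of a set of duplex alignments
#'
#' At each of the first `n_positions` alignment columns (from the miRNA 5'
#' end), the Shannon entropy (bits) of the empirical distribution over the
#' three heatmap states: match, G:U wobble, and mismatch/gap (X and G
#' merged). Alignments shorter than `n_positions` are padded with the
#' mismatch/gap state. Values lie in \[0, log2(3)\].
#'
#' @param alignments list of `duplex_alignment` objects (or state strings).
#' @param n_positions number of positions profiled (default 20).
#' @return data.frame with columns `position` and `entropy`.
#' @export
entropy_profile <- function(alignments, n_positions = 20L) {
  if (!length(alignments)) stop("empty alignment set")
  mat <- vapply(alignments, .states_fixed_length, character(n_positions),
                len = n_positions)
  mat <- matrix(mat, nrow = n_positions)
  mat[mat == "G"] <- "X"  # merge gap into mismatch
  ent <- apply(mat, 1L, function(col) {
    p <- table(factor(col, levels = c("M", "W", "X"))) / length(col)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  data.frame(position = seq_len(n_positions), entropy = as.numeric(ent))
}

#' Heatmap encoding of a duplex alignment
#'
#' The first 20 alignment positions (miRNA 5'->3') encoded as +1 for a
#' match, -1 for a mismatch or gap, and +0.5 for a G:U wobble. Longer
#' alignments are truncated; shorter ones are padded with -1.
#'
#' @param alignment a `duplex_alignment` or state string.
#' @param len vector length (default 20).
#' @return numeric vector of length `len`.
#' @export
alignment_vector <- function(alignment, len = 20L) {
  s <- .states_fixed_length(alignment, len)
  unname(c(M = 1, W = 0.5, X = -1, G = -1)[s])
}

#' Cluster heatmap-encoded alignment vectors
#'
#' Agglomerative hierarchical clustering of alignment vectors using
#' Euclidean distance and complete linkage, as used to group
#' true-positive and false-negative duplex profiles.
#'
#' @param vectors numeric matrix, one row per interaction (e.g. rows of
#'   [alignment_vector()] output), or a list of equal-length vectors.
#' @return an object of class `hclust`; leaf order in `$order`.
#' @export
cluster_alignment_vectors <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 vectors to cluster")
  hclust(dist(vectors, method = "euclidean"), method = "complete")
}

#' Compare a feature between two interaction groups
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation, so tied
#' feature values such as integer stretch lengths are handled).
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return list with `statistic`, `p_value` and `method`.
#' @export
compare_feature_distributions <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
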