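# Independent brute-force oracles used to check the fast implementations.

# enumerate every global alignment of mirna vs the reversed site with at
# most max_gaps gap columns; return the minimum penalty_score
oracle_min_penalty <- function(mirna, site, config = duplex_config()) {
  x <- strsplit(mirna, "")[[1]]
  y <- rev(strsplit(site, "")[[1]])  # site 3'->5'
  n <- length(x); m <- length(y)
  best <- Inf
  rec <- function(i, j, g, states) {
    if (i > n && j > m) {
      p <- penalty_score(states, config = config)
      if (p < best) best <<- p
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1, j + 1, g, c(states, classify_pair(x[i], y[j])))
    if (g < config$max_gaps) {
      if (i <= n) rec(i + 1, j, g + 1, c(states, "G"))
      if (j <= m) rec(i, j + 1, g + 1, c(states, "G"))
    }
  }
  rec(1L, 1L, 0L, character(0))
  best
}

# exhaustive window scan: align every window of every length, keep hits
# below the cutoff, collapse overlapping hits like the scanner does
oracle_scan <- function(mirna, transcript, cutoff, config = duplex_config()) {
  scan_transcript(mirna, transcript, cutoff, config, exhaustive = TRUE)
}

# AUC as the pairwise concordance probability (ties count 1/2);
# lower scores are better
oracle_auc_lower_better <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p < q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# naive agglomerative complete-linkage: returns merge heights in order
oracle_complete_linkage_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < bh) { bh <- h; best <- c(a, b) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                         replace = TRUE), collapse = "")

# a duplex_alignment built directly from a state string, for feature tests
fake_alignment <- function(states) {
  s <- strsplit(states, "")[[1]]
  mirna <- ifelse(s == "G", "-", "A")
  target <- ifelse(s == "M", "U", ifelse(s == "W", "G",
                   ifelse(s == "G", "-", "C")))
  structure(list(mirna_id = "m", target_id = "t", site_start = 1L,
                 site_end = sum(target != "-"),
                 aligned_mirna = paste(mirna, collapse = ""),
                 aligned_target = paste(target, collapse = ""),
                 states = states,
                 penalty = penalty_score(states), n_gaps = sum(s == "G")),
            class = "duplex_alignment")
}

pred_df <- function(mirna_id, target_id, score, tool = "t") {
  data.frame(mirna_id = mirna_id, target_id = target_id, score = score,
             site_start = NA_integer_, site_end = NA_integer_, tool = tool,
             stringsAsFactors = FALSE)
}

pair_df <- function(mirna_id, target_id) {
  data.frame(mirna_id = mirna_id, target_id = target_id,
             stringsAsFactors = FALSE)
}
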