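test_that("pair classification follows the match/wobble/mismatch/gap taxonomy", {
  expect_identical(classify_pair("G", "C"), "M")
  expect_identical(classify_pair("A", "U"), "M")
  expect_identical(classify_pair("U", "A"), "M")
  expect_identical(classify_pair("G", "U"), "W")
  expect_identical(classify_pair("U", "G"), "W")
  expect_identical(classify_pair("A", "G"), "X")
  expect_identical(classify_pair("C", "U"), "X")
  expect_identical(classify_pair("A", "-"), "G")
  expect_identical(classify_pair("-", "C"), "G")
  expect_error(classify_pair("T", "A"), "invalid")
})

test_that("penalty_score applies costs and seed doubling", {
  expect_equal(penalty_score(strrep("M", 21)), 0)
  # one mismatch at position 5, inside the default 2-13 window: 1 x 2
  expect_equal(penalty_score("MMMMXMMMMMMMMMMMMMMMM"), 2)
  # one wobble at position 20, outside the window: 0.5
  expect_equal(penalty_score(paste0(strrep("M", 19), "W", "M")), 0.5)
  # same wobble inside the window doubles
  expect_equal(penalty_score("MWMM"), 1)
  expect_error(penalty_score(""), "empty")
})

test_that("penalty_score is monotone under state degradation", {
  set.seed(11)
  for (k in 1:25) {
    s <- sample(c("M", "W", "X"), 15, replace = TRUE, prob = c(.7, .2, .1))
    base <- penalty_score(s)
    i <- sample(15, 1)
    worse <- s
    if (s[i] == "M") worse[i] <- sample(c("W", "X"), 1)
    else if (s[i] == "W") worse[i] <- "X"
    expect_gte(penalty_score(worse), base)
  }
})

test_that("perfect reverse complement aligns with zero penalty", {
  a <- align_duplex("AAGG", "CCUU")
  expect_identical(a$states, "MMMM")
  expect_equal(a$penalty, 0)
  expect_equal(a$n_gaps, 0L)
})

test_that("a single terminal G:U is recognized and scored by window position", {
  # oracle enumeration over all gapped alignments of these 4-mers gives a
  # minimum of 1.0 under the default config (wobble at column 4, inside
  # the seed window, doubled) and 0.5 without seed weighting
  a <- align_duplex("AAGG", "UCUU")
  expect_identical(a$states, "MMMW")
  expect_equal(a$penalty, 1.0)
  expect_equal(oracle_min_penalty("AAGG", "UCUU"), 1.0)
  flat <- duplex_config(seed_multiplier = 1)
  a2 <- align_duplex("AAGG", "UCUU", flat)
  expect_equal(a2$penalty, 0.5)
  expect_equal(oracle_min_penalty("AAGG", "UCUU", flat), 0.5)
})

test_that("alignment strings satisfy the structural invariants", {
  set.seed(21)
  for (k in 1:20) {
    mirna <- random_rna(sample(6:12, 1))
    site <- random_rna(nchar(mirna) + sample(-2:2, 1))
    a <- align_duplex(mirna, site)
    if (is.null(a)) next
    expect_equal(nchar(a$aligned_mirna), nchar(a$states))
    expect_equal(nchar(a$aligned_target), nchar(a$states))
    expect_identical(gsub("-", "", a$aligned_mirna), mirna)
    # aligned_target is 3'->5'; stripping gaps and reversing gives the site
    stripped <- gsub("-", "", a$aligned_target)
    expect_identical(paste(rev(strsplit(stripped, "")[[1]]), collapse = ""),
                     site)
    # state string consistent with the bases column by column
    xs <- strsplit(a$aligned_mirna, "")[[1]]
    ys <- strsplit(a$aligned_target, "")[[1]]
    expect_identical(paste(classify_pair(xs, ys), collapse = ""), a$states)
    expect_equal(a$penalty, penalty_score(a$states))
  }
})

test_that("dynamic program matches the exhaustive enumeration oracle", {
  set.seed(31)
  cfg <- duplex_config(max_gaps = 2)
  for (k in 1:60) {
    mirna <- random_rna(sample(4:10, 1))
    site <- random_rna(sample(4:10, 1))
    a <- align_duplex(mirna, site, cfg)
    o <- oracle_min_penalty(mirna, site, cfg)
    if (is.null(a)) expect_identical(o, Inf)
    else expect_equal(a$penalty, o)
  }
})

test_that("complementing both strands position-wise preserves the match count", {
  # A:U <-> U:A and G:C <-> C:G swaps keep Watson-Crick pairs Watson-Crick;
  # wobbles are not preserved (G:U -> C:A), so only the M count is asserted.
  set.seed(41)
  comp <- function(s) chartr("ACGU-", "UGCA-", s)
  for (k in 1:15) {
    mirna <- random_rna(9)
    site <- random_rna(9)
    a <- align_duplex(mirna, site)
    xs <- strsplit(comp(a$aligned_mirna), "")[[1]]
    ys <- strsplit(comp(a$aligned_target), "")[[1]]
    relabeled <- classify_pair(xs, ys)
    expect_equal(sum(relabeled == "M"),
                 sum(strsplit(a$states, "")[[1]] == "M"))
  }
})

test_that("alignments beyond the gap limit are not reported", {
  expect_null(align_duplex("ACGUACGUAC", "GU"))  # needs 8 gaps
  expect_error(align_duplex("", "ACGU"), "empty")
})

test_that("the rendered block shows both strands and the midline", {
  a <- align_duplex("AAGG", "UCUU")
  txt <- format(a)
  expect_match(txt, "miRNA  5' AAGG 3'", fixed = TRUE)
  expect_match(txt, "\\|\\|\\|:")
  expect_match(txt, "target 3' UUCU 5'", fixed = TRUE)
})
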