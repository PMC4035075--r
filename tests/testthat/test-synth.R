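test_that("miRNA generation is deterministic and respects length and GC", {
  a <- generate_mirnas(10, length = 21, seed = 7)
  b <- generate_mirnas(10, length = 21, seed = 7)
  expect_identical(a, b)
  expect_true(all(nchar(a) == 21))
  expect_equal(length(a), 10L)
  g <- generate_mirnas(100, gc_target = 0.5, seed = 8)
  expect_gt(mean(gc_content(g)), 0.45)
  expect_lt(mean(gc_content(g)), 0.55)
  expect_error(generate_mirnas(5, gc_target = 1.5), "impossible")
})

test_that("a perfect profile implants the exact reverse complement", {
  set.seed(141)
  mirna <- random_rna(21)
  tx <- random_rna(200)
  imp <- implant_site(tx, mirna, synth_profile(), position = 50, seed = 1)
  expect_identical(substr(imp$transcript, 50, 70), reverse_complement_rna(mirna))
  expect_equal(imp$alignment$penalty, 0)
  expect_identical(imp$alignment$states, strrep("M", 21))
  expect_equal(nchar(imp$transcript), nchar(tx))
})

test_that("seed-window edit categories are realized exactly on re-alignment", {
  set.seed(151)
  count_in_seed <- function(aln, what) {
    s <- strsplit(aln$states, "")[[1]]
    pos <- cumsum(strsplit(aln$aligned_mirna, "")[[1]] != "-")
    sum(s %in% what & pos >= 2 & pos <= 12)
  }
  for (k in 1:10) {
    mirna <- random_rna(21)
    tx <- random_rna(150)
    # category (ii): two mismatches and one G:U wobble in the seed
    if (sum(strsplit(mirna, "")[[1]][2:12] %in% c("G", "U")) >= 1) {
      imp2 <- implant_site(tx, mirna,
                           synth_profile(n_seed_wobbles = 1,
                                         n_seed_mismatches = 2),
                           position = 40, seed = k)
      expect_equal(count_in_seed(imp2$alignment, "W"), 1)
      expect_equal(count_in_seed(imp2$alignment, c("X", "G")), 2)
    }
    # category (iii): three mismatches, no wobble
    imp3 <- implant_site(tx, mirna,
                         synth_profile(n_seed_mismatches = 3),
                         position = 40, seed = k)
    expect_equal(count_in_seed(imp3$alignment, "W"), 0)
    expect_equal(count_in_seed(imp3$alignment, c("X", "G")), 3)
  }
})

test_that("infeasible implant positions error", {
  expect_error(implant_site("ACGU", "ACGUACGUACGUACGUACGUA",
                            synth_profile(), position = 1, seed = 1),
               "no room")
})

test_that("study generation is reproducible and internally consistent", {
  s1 <- generate_study(n_tp = 8, n_fn = 8, n_decoys = 3, seed = 5)
  s2 <- generate_study(n_tp = 8, n_fn = 8, n_decoys = 3, seed = 5)
  expect_identical(s1$mirnas, s2$mirnas)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$energy, s2$energy)
  # labels exhaustive and disjoint
  expect_equal(sort(unique(s1$interactions$group)), c("fn_like", "tp_like"))
  expect_equal(sum(s1$interactions$group == "tp_like"), 8L)
  keys <- paste(s1$interactions$mirna_id, s1$interactions$target_id)
  expect_equal(anyDuplicated(keys), 0L)
  # ground truth: re-aligning every implanted slice reproduces the record
  for (i in seq_len(nrow(s1$interactions))) {
    row <- s1$interactions[i, ]
    site <- substr(s1$transcripts[[row$target_id]], row$site_start, row$site_end)
    aln <- align_duplex(s1$mirnas[[row$mirna_id]], site)
    expect_equal(aln$penalty, row$penalty)
  }
  # FN-like duplexes carry heavier penalties than TP-like ones
  expect_gt(min(s1$interactions$penalty[s1$interactions$group == "fn_like"]),
            max(s1$interactions$penalty[s1$interactions$group == "tp_like"]))
})

test_that("decoys never reach the guard penalty against any miRNA", {
  s <- generate_study(n_tp = 4, n_fn = 4, n_decoys = 3, seed = 13,
                      guard_penalty = 6)
  for (d in s$decoys)
    for (m in s$mirnas)
      expect_equal(nrow(scan_transcript(m, d, cutoff = 6)), 0L)
})

test_that("written studies round-trip through the standard formats", {
  s <- generate_study(n_tp = 4, n_fn = 4, n_decoys = 2, seed = 3)
  dir <- withr::local_tempdir()
  write_study(s, dir)
  mirnas <- read_rna_fasta(file.path(dir, "mirnas.fa"))
  expect_identical(mirnas, s$mirnas)
  tx <- read_rna_fasta(file.path(dir, "transcripts.fa"))
  expect_equal(length(tx), length(s$transcripts) + length(s$decoys))
  rec <- read_interaction_table(file.path(dir, "interactions.tsv"))
  expect_equal(nrow(rec), nrow(s$interactions))
  manifest <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(manifest$n_interactions, 8L)
})
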