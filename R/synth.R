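.sample_rna <- function(len, gc_target = NULL) {
  probs <- if (is.null(gc_target)) rep(0.25, 4)
           else c((1 - gc_target) / 2, gc_target / 2,
                  gc_target / 2, (1 - gc_target) / 2)
  paste(sample(.BASES, len, replace = TRUE, prob = probs), collapse = "")
}

.check_gc_target <- function(gc_target) {
  if (!is.null(gc_target) &&
      (!is.numeric(gc_target) || gc_target < 0 || gc_target > 1))
    stop("impossible gc_target: must lie in [0, 1]")
}

#' Generate random miRNA sequences
#'
#' Bases are drawn independently, uniformly or with P(G) + P(C) equal to
#' `gc_target`; the realized mean GC therefore concentrates around the
#' target (within about +/-0.05 for 50 or more sequences).
#'
#' @param n number of sequences (>= 1).
#' @param length sequence length in nt (default 21, the typical plant
#'   mature miRNA).
#' @param gc_target desired GC fraction in \[0, 1\], or `NULL` for uniform.
#' @param seed integer seed; identical calls are bit-identical.
#' @return named character vector (`syn-miR001`, ...).
#' @export
generate_mirnas <- function(n, length = 21L, gc_target = NULL, seed = NULL) {
  stopifnot(n >= 1L, length >= 1L)
  .check_gc_target(gc_target)
  .with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) .sample_rna(length, gc_target), "")
    setNames(seqs, sprintf("syn-miR%03d", seq_len(n)))
  })
}

#' Generate random transcript sequences
#'
#' @param n number of transcripts.
#' @param length_range integer length-2 vector; lengths drawn uniformly.
#' @param gc_target GC fraction or `NULL` for uniform composition.
#' @param seed integer seed.
#' @param prefix identifier prefix.
#' @return named character vector.
#' @export
generate_transcripts <- function(n, length_range = c(300L, 800L),
                                 gc_target = NULL, seed = NULL,
                                 prefix = "SYNTX") {
  stopifnot(n >= 1L, length_range[1] >= 1L,
            length_range[1] <= length_range[2])
  .check_gc_target(gc_target)
  .with_seed(seed, {
    rng <- length_range[1]:length_range[2]
    lens <- rng[sample.int(length(rng), n, replace = TRUE)]
    seqs <- vapply(lens, .sample_rna, "", gc_target = gc_target)
    setNames(seqs, sprintf("%s%04d", prefix, seq_len(n)))
  })
}

#' Edit profile for an implanted target site
#'
#' Describes how far an implanted site departs from perfect reverse
#' complementarity: the number of G:U wobbles and mismatches placed inside
#' the seed window (miRNA positions 2-12 by default) and the number and
#' kinds of edits in the 3' region beyond it. The three observed seed
#' interaction categories are (i) fewer than two wobbles and no mismatch,
#' (ii) two mismatches plus one wobble, (iii) three mismatches and no
#' wobble.
#'
#' @param seed_window 1-based inclusive miRNA positions of the seed window.
#' @param n_seed_wobbles,n_seed_mismatches edits inside the seed window.
#' @param n_three_prime_edits edits beyond the seed window.
#' @param three_prime_kinds kinds drawn for 3' edits.
#' @return list of class `synth_profile`.
#' @export
synth_profile <- function(seed_window = c(2L, 12L), n_seed_wobbles = 0L,
                          n_seed_mismatches = 0L, n_three_prime_edits = 0L,
                          three_prime_kinds = c("mismatch", "gap", "wobble")) {
  stopifnot(n_seed_wobbles >= 0L, n_seed_mismatches >= 0L,
            n_three_prime_edits >= 0L)
  wlen <- seed_window[2] - seed_window[1] + 1L
  if (n_seed_wobbles + n_seed_mismatches > wlen)
    stop("more seed edits than seed-window positions")
  three_prime_kinds <- match.arg(three_prime_kinds, several.ok = TRUE)
  structure(list(seed_window = as.integer(seed_window),
                 n_seed_wobbles = as.integer(n_seed_wobbles),
                 n_seed_mismatches = as.integer(n_seed_mismatches),
                 n_three_prime_edits = as.integer(n_three_prime_edits),
                 three_prime_kinds = three_prime_kinds),
            class = "synth_profile")
}

# miRNA position of each alignment column (NA for target-bulge columns)
.column_mirna_positions <- function(alignment) {
  ch <- .rna_chars(alignment$aligned_mirna)
  pos <- cumsum(ch != .GAP)
  pos[ch == .GAP] <- NA_integer_
  pos
}

# realized edit counts of an alignment, relative to a profile's windows
.realized_counts <- function(alignment, profile) {
  s <- .states_of(alignment)
  pos <- .column_mirna_positions(alignment)
  in_seed <- !is.na(pos) & pos >= profile$seed_window[1] &
    pos <= profile$seed_window[2]
  three_prime <- is.na(pos) | pos > profile$seed_window[2]
  list(seed_wobbles = sum(s == "W" & in_seed),
       seed_mismatches = sum(s %in% c("X", "G") & in_seed),
       three_prime_edits = sum(s != "M" & three_prime))
}

# one attempt at building an edited site for `mirna` under `profile`;
# returns the site string or NULL if the sampled positions are infeasible
.build_site_once <- function(mchars, profile) {
  n <- length(mchars)
  site <- rev(unname(.WC[mchars]))  # perfect reverse complement, 5'->3'
  lo <- profile$seed_window[1]; hi <- min(profile$seed_window[2], n)
  seed_pos <- lo:hi
  pick <- function(from, k) from[sample.int(length(from), k)]
  eligible_w <- seed_pos[mchars[seed_pos] %in% c("G", "U")]
  if (length(eligible_w) < profile$n_seed_wobbles) return(NULL)
  wob <- pick(eligible_w, profile$n_seed_wobbles)
  rest <- setdiff(seed_pos, wob)
  if (length(rest) < profile$n_seed_mismatches) return(NULL)
  mis <- pick(rest, profile$n_seed_mismatches)
  tp_pos <- if (hi < n) (hi + 1L):n else integer(0)
  if (length(tp_pos) < profile$n_three_prime_edits) return(NULL)
  tpe <- pick(tp_pos, profile$n_three_prime_edits)
  tpk <- sample(profile$three_prime_kinds, length(tpe), replace = TRUE)
  # 3' wobbles need a G or U miRNA base; re-kind infeasible ones
  tpk[tpk == "wobble" & !(mchars[tpe] %in% c("G", "U"))] <- "mismatch"

  drop <- logical(n)  # site positions to delete (miRNA bulges)
  apply_edit <- function(i, kind) {
    j <- n - i + 1L  # site index pairing miRNA position i
    b <- mchars[i]
    if (kind == "wobble") {
      site[j] <<- .WOBBLE[[b]]
    } else if (kind == "mismatch") {
      choices <- setdiff(.BASES, c(.WC[[b]], if (b %in% names(.WOBBLE)) .WOBBLE[[b]]))
      site[j] <<- sample(choices, 1L)
    } else {
      drop[j] <<- TRUE
    }
  }
  for (i in wob) apply_edit(i, "wobble")
  for (i in mis) apply_edit(i, "mismatch")
  for (k in seq_along(tpe)) apply_edit(tpe[k], tpk[k])
  paste(site[!drop], collapse = "")
}

#' Implant a synthetic target site into a transcript
#'
#' Writes a site for `mirna` into `transcript` at `position`, starting
#' from the exact reverse complement and introducing the edits requested
#' by `profile`. The implanted region is re-aligned with [align_duplex()]
#' and must reproduce the requested counts of seed wobbles, seed
#' mismatches and 3' edits exactly; edit positions are resampled on
#' failure, with an error after `max_retries` attempts.
#'
#' @param transcript,mirna RNA sequences (single strings).
#' @param profile a [synth_profile()].
#' @param position 1-based transcript position of the site start.
#' @param seed integer seed.
#' @param config [duplex_config()] used for the verification re-alignment.
#' @param max_retries attempts before giving up.
#' @return list with `transcript` (modified), `alignment` (the verified
#'   `duplex_alignment`, transcript coordinates), `site`, and `profile`.
#' @export
implant_site <- function(transcript, mirna, profile = synth_profile(),
                         position, seed = NULL, config = duplex_config(),
                         max_retries = 25L) {
  mchars <- .rna_chars(mirna)
  .with_seed(seed, {
    for (try in seq_len(max_retries)) {
      site <- .build_site_once(mchars, profile)
      if (is.null(site))
        stop("profile infeasible for this miRNA (not enough eligible positions)")
      e <- position + nchar(site) - 1L
      if (position < 1L || e > nchar(transcript))
        stop("position leaves no room for the site")
      aln <- align_duplex(mirna, site, config,
                          site_start = position, site_end = e)
      if (!is.null(aln)) {
        got <- .realized_counts(aln, profile)
        if (got$seed_wobbles == profile$n_seed_wobbles &&
            got$seed_mismatches == profile$n_seed_mismatches &&
            got$three_prime_edits == profile$n_three_prime_edits) {
          new_tx <- paste0(substr(transcript, 1L, position - 1L), site,
                           substr(transcript, e + 1L, nchar(transcript)))
          return(list(transcript = new_tx, alignment = aln, site = site,
                      profile = profile))
        }
      }
    }
    stop("could not realize the requested edit profile after ",
         max_retries, " attempts")
  })
}

# sample a TP-like profile: seed category (i) (< 2 wobbles, no mismatch),
# at most one 3' edit
.tp_profile <- function(mchars, seed_window = c(2L, 12L)) {
  eligible <- sum(mchars[seed_window[1]:seed_window[2]] %in% c("G", "U"))
  synth_profile(seed_window,
                n_seed_wobbles = if (eligible) sample(0:1, 1L) else 0L,
                n_seed_mismatches = 0L,
                n_three_prime_edits = sample(0:1, 1L),
                three_prime_kinds = c("mismatch", "wobble"))
}

# sample an FN-like profile: seed category (ii) (2 mismatches + 1 wobble)
# or (iii) (3 mismatches), plus 2-3 edits in the 3' region
.fn_profile <- function(mchars, seed_window = c(2L, 12L)) {
  eligible <- sum(mchars[seed_window[1]:seed_window[2]] %in% c("G", "U"))
  cat_ii <- eligible >= 1L && runif(1) < 0.5
  synth_profile(seed_window,
                n_seed_wobbles = if (cat_ii) 1L else 0L,
                n_seed_mismatches = if (cat_ii) 2L else 3L,
                n_three_prime_edits = sample(2:3, 1L),
                three_prime_kinds = c("mismatch", "gap", "wobble"))
}

#' Generate a complete synthetic benchmark study
#'
#' Builds miRNAs, one transcript per interaction with an implanted target
#' site, and decoy transcripts with no implanted site. The validated set
#' splits into a TP-like group (near-perfect sites: fewer than two seed
#' wobbles, at most one 3' edit) and an FN-like group (heavily edited
#' sites: two seed mismatches plus one wobble, or three seed mismatches,
#' plus 2-3 edits in the 3' region), so duplex features separate the
#' groups while miRNA GC content does not. A synthetic free-energy table
#' is drawn as `energy_intercept + energy_slope * length + noise`. Decoys
#' are rejection-sampled so that no seed-anchored window aligns to any
#' miRNA below `guard_penalty`.
#'
#' @param n_tp,n_fn interactions per group.
#' @param n_decoys decoy transcripts.
#' @param mirna_length miRNA length (nt).
#' @param gc_target GC fraction shared by all sequences, or `NULL`.
#' @param transcript_length_range transcript lengths (uniform draw).
#' @param seed_window seed window used by the edit profiles.
#' @param energy_slope,energy_intercept,energy_sd parameters of the
#'   synthetic free-energy model (kcal/mol; slope per nt).
#' @param guard_penalty decoys must not reach this penalty vs any miRNA.
#' @param seed integer seed; regeneration is bit-identical.
#' @param config [duplex_config()] for site verification and the guard.
#' @return list of class `synth_study`: `mirnas`, `transcripts`, `decoys`,
#'   `interactions` (with `group`, site coordinates, realized `penalty`),
#'   `alignments` (ground-truth duplexes, keyed `mirna_id|target_id`),
#'   `negatives` (miRNA x decoy pairs), `energy`, `seed`, `config`.
#' @export
generate_study <- function(n_tp = 100L, n_fn = 100L, n_decoys = 20L,
                           mirna_length = 21L, gc_target = NULL,
                           transcript_length_range = c(300L, 800L),
                           seed_window = c(2L, 12L),
                           energy_slope = -0.05, energy_intercept = -10,
                           energy_sd = 5, guard_penalty = 6,
                           seed = 1L, config = duplex_config()) {
  .check_gc_target(gc_target)
  .with_seed(seed, {
    n_int <- n_tp + n_fn
    mirnas <- generate_mirnas(n_int, mirna_length, gc_target)
    transcripts <- generate_transcripts(n_int, transcript_length_range,
                                        gc_target, prefix = "SYNTX")
    group <- rep(c("tp_like", "fn_like"), c(n_tp, n_fn))
    interactions <- NULL
    alignments <- list()
    for (i in seq_len(n_int)) {
      mid <- names(mirnas)[i]
      tid <- names(transcripts)[i]
      mchars <- .rna_chars(mirnas[[i]])
      prof <- if (group[i] == "tp_like") .tp_profile(mchars, seed_window)
              else .fn_profile(mchars, seed_window)
      pos <- sample.int(nchar(transcripts[[i]]) - mirna_length -
                          config$max_gaps, 1L)
      imp <- implant_site(transcripts[[i]], mirnas[[i]], prof, pos,
                          config = config)
      transcripts[[i]] <- imp$transcript
      aln <- imp$alignment
      aln$mirna_id <- mid
      aln$target_id <- tid
      alignments[[.pair_key(mid, tid)]] <- aln
      interactions <- rbind(interactions, data.frame(
        mirna_id = mid, target_id = tid, species = "synthetic",
        dataset = "synthetic", source = "implanted",
        group = group[i], site_start = aln$site_start,
        site_end = aln$site_end, penalty = aln$penalty,
        stringsAsFactors = FALSE))
    }
    decoys <- character(0)
    tries <- 0L
    while (length(decoys) < n_decoys) {
      tries <- tries + 1L
      if (tries > 50L * n_decoys)
        stop("could not sample enough guarded decoy transcripts")
      lrng <- transcript_length_range[1]:transcript_length_range[2]
      cand <- .sample_rna(lrng[sample.int(length(lrng), 1L)], gc_target)
      clean <- TRUE
      for (m in mirnas) {
        if (nrow(scan_transcript(m, cand, cutoff = guard_penalty,
                                 config = config))) {
          clean <- FALSE
          break
        }
      }
      if (clean) decoys <- c(decoys, cand)
    }
    names(decoys) <- sprintf("SYNDECOY%04d", seq_along(decoys))
    negatives <- expand.grid(mirna_id = names(mirnas),
                             target_id = names(decoys),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
    tx_len <- nchar(transcripts)
    energy <- data.frame(
      mirna_id = interactions$mirna_id,
      target_id = interactions$target_id,
      transcript_length = as.integer(tx_len),
      delta_g = energy_intercept + energy_slope * tx_len +
        rnorm(n_int, sd = energy_sd),
      stringsAsFactors = FALSE)
    structure(list(mirnas = mirnas, transcripts = transcripts,
                   decoys = decoys, interactions = interactions,
                   alignments = alignments, negatives = negatives,
                   energy = energy, seed = seed, config = config),
              class = "synth_study")
  })
}

#' Write a synthetic study to disk
#'
#' FASTA for miRNAs and transcripts (decoys included), TSV tables for
#' interactions, negatives and energies, and a JSON ground-truth manifest.
#'
#' @param study a `synth_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rna_fasta(study$mirnas, file.path(dir, "mirnas.fa"))
  write_rna_fasta(c(study$transcripts, study$decoys),
                  file.path(dir, "transcripts.fa"))
  write_interaction_table(study$interactions,
                          file.path(dir, "interactions.tsv"))
  write.table(study$negatives, file.path(dir, "negatives.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$energy, file.path(dir, "energy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = study$seed,
                   n_interactions = nrow(study$interactions),
                   groups = as.list(table(study$interactions$group)),
                   n_decoys = length(study$decoys),
                   interactions = study$interactions)
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
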