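# mirduplex

Benchmarking machinery for plant miRNA target prediction.

Plant miRNAs silence their mRNA targets through extensive, near-perfect
complementarity along the whole ~21-nt duplex, and the field's target
prediction tools score candidate duplexes with additive penalty schemes:
a Watson–Crick match costs nothing, a G:U wobble costs 0.5, a mismatch
or bulge costs 1, and every cost is doubled in the 5' seed window
(miRNA positions 2–13 by default). Candidates below a score cutoff are
called targets. Choosing that cutoff, comparing and combining
predictors, and understanding which validated interactions predictors
systematically miss is an analysis pipeline of its own. mirduplex
implements it:

* **Duplex alignment** — `align_duplex()` computes the minimum-penalty
  gapped alignment of a miRNA against a site (C++ dynamic program,
  per-column states M/W/X/G, configurable via `duplex_config()`).
* **Reference scanner** — `scan_transcript()` /
  `predict_transcriptome()`: a self-contained, seed-anchored
  penalty-based target scanner, so the pipeline runs end-to-end without
  external tools.
* **Evaluation** — confusion counts against validated interaction sets,
  precision = TP/(TP+FP) and recall = TP/(TP+FN), threshold sweeps over
  all observed scores, the optimal score at the precision–recall
  crossing, ROC/AUC against negative sets, and union/intersection
  combination of predictors.
* **TP/FN characterization** — miRNA GC content, longest continuous
  match stretch, first match stretch, match/mismatch ratio, Wilcoxon
  rank tests between groups, positional Shannon entropy profiles over
  the states {match, wobble, mismatch∪gap}, and complete-linkage
  clustering of ±1/0.5 heatmap-encoded alignment vectors.
* **Synthetic benchmark generator** — `generate_study()` implants
  target sites with controlled seed-window edit profiles (near-perfect
  "TP-like" versus heavily edited "FN-like") plus guarded decoy
  transcripts and a synthetic free-energy table, with full ground
  truth and bit-identical regeneration per seed.
* **Bookkeeping for curated lists** — TSV interaction tables with
  pair-level deduplication and ambiguous miRNA-family filtering
  (miR414/miR413 by default).

## Worked example

Align one miRNA against a site carrying one seed wobble, then find the
site by scanning:

```r
library(mirduplex)

mirna <- "GGAGUGUCAUGAGAACACACA"
tx <- generate_transcripts(1, c(200, 200), seed = 4)
imp <- implant_site(tx[[1]], mirna, synth_profile(n_seed_wobbles = 1),
                    position = 90, seed = 2)
imp$alignment
#> miRNA  5' GGAGUGUCAUGAGAACACACA 3'
#>           ||||||:||||||||||||||
#> target 3' CCUCACGGUACUCUUGUGUGU 5'   [90-110]  penalty 1

scan_transcript(mirna, imp$transcript, cutoff = 3,
                mirna_id = "miR-demo", target_id = "TX1")
#>   mirna_id target_id score site_start site_end      tool
#> 1 miR-demo       TX1     1         90      110 mirduplex
```

The wobble sits in the seed window, so it costs 0.5 × 2 = 1 penalty
unit; the scanner recovers the site at its implanted coordinates.

A complete study — simulate, scan with two predictors, evaluate,
combine, characterize — is one call:

```r
report <- run_study(seed = 42)
report
#> mirduplex study report (seed 42)
#>   interactions: 40 TP-like + 40 FN-like; 12 decoys
#>   stringent  cutoff 2.50: 39 predictions; optimal score 2.00 (P 1.00 / R 0.49); AUC 0.828
#>   tolerant   cutoff 4.50: 40 predictions; optimal score 2.50 (P 1.00 / R 0.50); AUC 0.825
#>   union        of stringent+tolerant: TP 40, FP 0
#>   intersection of stringent+tolerant: TP 39, FP 0
#>   gc_fraction            Wilcoxon p = 0.827
#>   max_match_stretch      Wilcoxon p = 6.37e-14
#>   first_stretch          Wilcoxon p = 1.5e-09
#>   match_mismatch_ratio   Wilcoxon p = 4.14e-15
#>   energy~length Spearman rho = -0.701
```

Reading the report: both predictors recover essentially all TP-like
sites (the near-perfect duplexes) and miss the FN-like ones, so recall
plateaus near 0.5 while precision stays high — the signature of
validated interactions whose duplex geometry diverges from the scoring
model. The three duplex-geometry features separate the two groups at
tiny p-values while miRNA GC content does not, and the synthetic free
energies show the negative length association. `write_report()`
serializes the full report (curves, counts, entropy profiles) to JSON.

A thin command-line wrapper with subcommands
`simulate | scan | evaluate | combine | features | trend | run` is
installed at `system.file("cli", "mirduplex", package = "mirduplex")`.

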