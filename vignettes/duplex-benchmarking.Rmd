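---
title: "Benchmarking plant miRNA target predictors with mirduplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking plant miRNA target predictors with mirduplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirduplex)
```

## The problem

Plant miRNAs guide Argonaute complexes to mRNA targets through extensive,
near-perfect complementarity along the whole ~21-nt duplex. Target
prediction tools in this space therefore score candidate miRNA:mRNA
duplexes with additive penalty schemes — mismatches and bulges cost a
unit, the thermodynamically tolerated G:U wobble pair costs half, and
positions in the 5' seed are weighted more heavily — and call targets
below a score cutoff. Evaluating such predictors against experimentally
validated interactions, picking their operating cutoffs, combining them,
and characterizing the validated interactions they systematically miss
(the false negatives) is a pipeline in its own right. mirduplex
implements that pipeline end-to-end, together with a synthetic benchmark
generator that provides ground truth without any external tool or
download.

## Duplex model and scoring

A duplex alignment pairs the miRNA (5'→3') with a candidate site read in
antiparallel orientation: under the gap-free convention, miRNA position
$i$ pairs with site position $L - i + 1$. Each alignment column is one of
four states:

* **M** — Watson–Crick match (A:U, G:C), cost `match` (default 0);
* **W** — G:U wobble, cost `wobble` (default 0.5);
* **X** — mismatch, cost `mismatch` (default 1);
* **G** — gap/bulge in either strand, cost `gap` (default 1).

Costs are multiplied by `seed_multiplier` (default 2) inside the seed
window, default positions 2–13 counted from the miRNA 5' end — the
conventional weighting of the plant tool family, in which seed
disruptions are the most deleterious. All four costs, the window and the
multiplier are configurable through `duplex_config()`; lower totals mean
better duplexes.

`align_duplex()` finds the minimum-penalty global alignment by dynamic
programming over the miRNA and the reversed site, with at most `max_gaps`
(default 3) gap columns — plant duplexes with more bulges than that are
not credible target sites, and the bound keeps the search small. Because
the seed weight depends on the alignment column, the program tracks the
number of gaps used as a third state dimension, which makes the column
index well defined per state. Ties are resolved deterministically: fewer
gaps first, then gaps placed closer to the miRNA 3' end (bulges in plant
duplexes are biologically 3'-biased). The hot loop is implemented in
C++; the test suite checks it against an exhaustive pure-R enumeration of
all gapped alignments on hundreds of random short duplexes.

One display convention: `aligned_target` is stored 3'→5' so that its
columns line up with the miRNA string, which is how duplexes are drawn
(miRNA on top 5'→3', target below 3'→5').

## The reference scanner

`scan_transcript()` slides a miRNA over a transcript and reports
non-overlapping sites with penalty at or below a cutoff. Candidate site
windows are pre-filtered by a seed anchor: the reverse complement of
miRNA positions 2–8 must occur in the transcript with at most one
substitution. This makes scanning linear-time and reflects the biology —
a site whose seed region is heavily disrupted is exactly the kind of
interaction these penalty schemes are designed to reject — but it is a
heuristic: sites with two or more seed-region edits can be missed even
when their total penalty is below the cutoff. An `exhaustive = TRUE` mode
aligns every window and is used in tests to check the anchored scan.
Overlapping hits collapse to the lowest-penalty site (leftmost on ties,
and gap-free representations are preferred over equal-scoring gapped
ones, so terminal unpaired transcript bases are excluded from the site
rather than scored as bulges).

The scanner is deliberately not a re-implementation of any published
tool; it is a self-contained member of the same scoring family, so the
evaluation machinery can be exercised end-to-end with known ground
truth.

## Evaluation

Matching between predictions and validated interactions is pair-level
(miRNA, target), site-agnostic — curated validated sets carry no site
coordinates. From the confusion counts, precision = TP/(TP+FP) and
recall = TP/(TP+FN); an empty call set has vacuous precision 1, which
keeps threshold curves total without affecting the optimum (recall is 0
there). `threshold_sweep()` walks the native grid of unique prediction
scores, orientation-aware (`lower_better` penalties versus
`higher_better` expectation scores are both common), and
`optimal_score()` selects the cutoff where precision and recall
intersect — operationally, the grid threshold minimizing
$|P - R|$, ties broken toward larger $P + R$, then the smaller
threshold. ROC analysis (`roc_auc()`) sweeps the same scores against a
negative set; the trapezoid AUC equals the pairwise concordance
probability with ties counted one half, which the tests assert to
1e-12 and cross-check against an independent ROC implementation.

`combine_predictions()` implements the union/intersection combination of
two predictors on pair keys: a union keeps the better score of the two
and can only raise TP counts; an intersection keeps the worse score and
can only lower FP counts. These containment relations are asserted on
every synthetic benchmark.

`energy_length_trend()` consumes a table of duplex free energies (ΔG,
kcal/mol — computed upstream by a thermodynamics tool, never here) and
transcript lengths, fits a lowess curve and reports the Spearman rank
correlation; a negative association (longer transcripts reaching lower
ΔG) is a length bias worth knowing about before trusting a universal
energy cutoff.

## TP/FN characterization

Four per-interaction features contrast validated interactions a
predictor finds (TP) with those it misses (FN):

* `gc_content()` — GC fraction of the miRNA;
* `max_match_stretch()` — the longest run of continuous Watson–Crick
  matches (the "seed region" in the longest-complementary-stretch
  sense);
* `first_stretch()` — continuous matches from the first matched base
  until the first non-match;
* `match_mismatch_ratio()` — total matches over total mismatches plus
  gaps, with an infinity sentinel for mismatch-free duplexes.

Wobbles break runs in both stretch metrics ("continuous matches" means
Watson–Crick only) and count in neither ratio term; gaps count as
mismatches for the ratio. This keeps one state taxonomy across all
features. Note that `first_stretch` is not bounded by
`max_match_stretch` ordering in either direction — a duplex can open
with a short run and contain a longer one later.

The positional uncertainty of a set of duplexes is summarized by
`entropy_profile()`: at each of the first 20 alignment columns, the
Shannon entropy (log base 2) of the empirical distribution over three
states {M, W, X∪G}. Three states and base 2 are design choices matching
the heatmap taxonomy below; the profile is bounded by $[0, \log_2 3]$
and both limits are asserted in tests. Alignments shorter than 20
columns are padded with the mismatch/gap state — absence of pairing is
non-complementarity.

For heatmaps and clustering, `alignment_vector()` encodes the first 20
columns as +1 (match), −1 (mismatch/gap) and +0.5 (wobble), truncating
longer duplexes and padding shorter ones with −1;
`cluster_alignment_vectors()` applies complete-linkage agglomerative
clustering on Euclidean distances (via `stats::hclust`, whose merge
heights the tests check against a brute-force linkage oracle).
`compare_feature_distributions()` wraps the two-sided Wilcoxon rank-sum
test with the normal approximation, since stretch lengths are small
integers with heavy ties.

## The synthetic benchmark

`generate_study()` is a first-class module, not a test fixture: it
defines the study conditions under which the pipeline's claims are
checked.

Each interaction gets a random miRNA (21 nt), a random transcript
(uniform base composition, or a shared `gc_target`), and one implanted
site built from the exact reverse complement of the miRNA and then
edited according to a profile (`synth_profile()`, verified by
re-alignment after every implant — the realized edit counts must match
the request exactly, or positions are resampled):

* **TP-like** sites follow the near-perfect seed category — fewer than
  two G:U wobbles and no mismatch in seed positions 2–12 — with at most
  one edit in the 3' region.
* **FN-like** sites follow the divergent seed categories — two
  mismatches plus one wobble, or three mismatches and no wobble — with
  2–3 further 3' edits (mismatch, gap or wobble).

These two profiles are the study's effect size: they guarantee that the
duplex-geometry features separate the groups while the miRNA GC content
(drawn identically for both groups) does not, which is the qualitative
pattern the characterization stage is designed to detect. Decoy
transcripts are rejection-sampled so that no seed-anchored window aligns
to any miRNA below a guard penalty (default 6), giving clean negatives
for TN counts and ROC. The synthetic ΔG table is a linear model,
`intercept + slope × length + Gaussian noise`, with defaults
(−10 kcal/mol, −0.05 kcal/mol/nt, sd 5) chosen so that the trend
analysis faces a realistic signal-to-noise ratio rather than a clean
line.

What the generator does **not** emulate: miRNA family structure and
conservation, multiple sites per target, expression or degradome
evidence, secondary-structure accessibility, and real intergenic
sequence composition. Passing tests therefore demonstrate that the
machinery is correct and sensitive under controlled conditions — not
that any particular tool will reach a particular precision on real
genomes.

Everything is deterministic per seed: regenerating a study with the same
seed is bit-identical, and a full `run_study()` report is `identical()`
across reruns.

## The pipeline

`run_study()` chains the stages: simulate → scan with two predictors of
different stringency (a stringent cutoff at 2.5 penalty units and a
tolerant one at 4.5 with a softer wobble cost) → evaluate each
(confusion at the default and at the optimal cutoff, threshold curve,
AUC) → combine (union and intersection) → characterize TP-like vs
FN-like (features with rank tests, entropy profiles, clustering) → fit
the energy trend → emit one JSON-serializable report. For ROC scoring,
every validated and negative pair is scanned at a deeper cutoff
(default 8) and pairs with no reported site are censored one unit beyond
it — a score worse than any reported one, so censoring only encodes
"not found", never fabricates a ranking among found sites.

The packaged demo configuration uses 40 TP-like + 40 FN-like
interactions and 12 decoys, sized so a full run takes well under two
minutes on one core; the characterization checks in the test suite use
100 interactions per group, the scale at which the rank tests have
comfortable power. Both are choices of this package, made once,
documented here.

```{r, eval = FALSE}
report <- run_study(seed = 42)
print(report)
write_report(report, "report.json")
```

## Numerical and edge-case choices

* Penalties are sums of halves, so all comparisons are exact in floating
  point; DP tie-breaks use a 1e-9 tolerance anyway.
* `precision_recall()` returns 1 for 0/0 ratios (vacuous truth).
* A zero-variance energy table has Spearman rho defined as 0.
* Duplexes needing more gaps than `max_gaps` report no alignment
  (`NULL`) rather than a forced bad one.
* The miRNA is never truncated by the aligner; only transcript-side
  windows vary in length.
* `wilcox.test` is always run with `exact = FALSE`.

## Curated-list bookkeeping

`read_interaction_table()` collapses exact duplicate (miRNA, target)
pairs and reports per-dataset unique-pair counts;
`filter_ambiguous_mirnas()` removes whole miRNA families flagged as
ambiguous (by default miR414 and miR413), matching family names after
stripping species prefixes and mature-arm suffixes but never lettered
variants. Because the published curated spreadsheet is not
redistributable here, the package bundles a *synthetic surrogate* table
(`inst/extdata/synthetic_curated_interactions.tsv`, generated by
`curated_surrogate_interactions()`) that reproduces the published
cardinality structure — 330 unique Arabidopsis pairs, 134
non-Arabidopsis pairs, 115 after the family filter — with synthetic
identifiers, so the bookkeeping path is exercised on realistic input
shapes. Users with the real curated lists can export them to the same
five-column TSV schema and run the identical path.

## Known limitations

* The seed-anchored scanner can miss heavily seed-edited sites below the
  cutoff; use `exhaustive = TRUE` when completeness matters more than
  speed.
* Pair-level TP matching cannot distinguish a correct site from a wrong
  site on the right transcript.
* ΔG values are inputs; no thermodynamic folding is performed.
* The synthetic generator implants exactly one site per validated
  interaction; multi-site biology is out of scope.
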