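---
title: "Methods: proteome-wide association of intrinsic disorder with PTM sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide association of intrinsic disorder with PTM sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrptm)
```

## The problem

Intrinsically disordered regions (IDRs) are protein segments without a
stable tertiary structure. Because they are flexible and solvent-exposed,
they are thought to concentrate post-translational modification (PTM)
sites — phosphorylation on S/T/Y, ubiquitination on K, some forms of
glycosylation — while transmembrane helices, built from buried hydrophobic
residues, should avoid disordered sequence. `idrptm` implements a
proteome-scale analysis of these associations for multi-species protein
sequence sets (the motivating application is algal proteomes spanning green
algae, oomycetes, diatoms, yellow algae and red algae), together with a
synthetic proteome generator that plants every effect the analysis is meant
to detect, so the whole pipeline is testable without external predictors or
genome downloads.

The unit of data is a species-tagged sequence set (`Proteome`, a named
`AAStringSet`) joined with per-residue disorder masks and typed site/segment
annotations (`AnnotatedProteome`). Disorder masks and
phosphorylation/ubiquitination sites are consumed as annotation tables in
the role that dedicated predictors (DISOPRED/RONN, Musite, UbPred, SignalP,
TMHMM) play in a real study; re-implementing those models is out of scope.
Three sequence-defined predictors are implemented here because no reusable
tool fills their role for plant-type proteomes.

## Sequence-defined predictors

**Hydroxyproline O-glycosylation.** `scanOgly()` finds the plant consensus
`[A/S/T/V]-P(1,4)-X(0,10)-[A/S/T/V]-P(1,4)`. Each occurrence counts as one
site and the anchor is the first proline. Two genuinely open choices are
fixed as defaults and exposed as options:

* *Counting unit*: one site per motif occurrence, not per proline. The
  per-protein scale this produces (on the order of one site per protein at
  plant-like composition) matches the magnitudes the analysis works with.
* *Scan policy*: leftmost start, non-overlapping, with the smallest extent
  compatible with the motif (proline runs are consumed inside their run; the
  spacer takes as few residues as possible). This maximizes the number of
  non-overlapping occurrences and makes the scan a deterministic canonical
  form; `extent = "longest"` and `overlap = "all"` give the alternatives.

The ambiguity code `X` never matches a literal class (`[ASTV]`, `P`, `N`,
`S/T`) but can occupy the spacer.

**N-glycosylation sequons.** `scanNglySequons()` reports every `N-X-S/T`
tripeptide with `X != P`, overlaps included. `combineNgly()` then applies
the secretory gate: a sequon is counted only if the protein enters the
secretory pathway (signal peptide present or, under the default
`signal_or_tm` gate, at least one TM helix), its anchor lies outside every
TM helix, and — because the signal peptide is cleaved — the anchor is not
within the signal region (first `signalEnd` residues, default 20; both the
gate variant and the signal exclusion are options). This encodes the
standard biology that N-glycosylation happens on secreted and membrane
proteins, with the least machinery.

**PEST regions.** `scanPest()` re-implements the classic PEST-find
procedure: candidate regions are the stretches between positively charged
flanks (K, R, H) of length >= 12 that contain at least one P, one of D/E and
one of S/T; sequence termini bound terminal candidates but a sequence with
no K/R/H yields none. The score is

`0.55 * DEPST - 0.5 * HI`

where `DEPST` is the mass percent of D/E/P/S/T after removing one
equivalent each of D-or-E, P and S-or-T (average residue masses), and `HI`
is the mean Kyte-Doolittle hydropathy linearly rescaled to 0..90. Regions
scoring above +5 (the conventional threshold, configurable) are reported.
Tool-version details of EMBOSS epestfind (terminal window handling and the
like) are not knowable from the published description; the constants used
here are the published ones and are frozen in the code.

## Redundancy clustering and the species contrast

Proteomes are first length-filtered (50-4000 residues inclusive — the
bounds are kept, since the filter removes strictly shorter/longer
sequences). Redundancy is then removed by identity clustering: every pair
with percent identity `pi >= 90` and percent match `pmatch >= 90` is linked
and clusters are single-linkage connected components; one representative
per cluster is kept (longest member, ties to the lexicographically smallest
id).

The identity quantities come from exact global alignment
(Needleman-Wunsch via `Biostrings`, match +1 / mismatch 0 / gap -1,
configurable). `pmatch` is the number of residue-residue columns over the
shorter sequence's length. `pi` is identities over the *aligned span* — the
columns from the first to the last residue-residue column, counting internal
gap columns in the denominator but not terminal overhangs. The span-based
denominator matters: with a large length difference, a global alignment can
scatter the short sequence's residues across the long one's mandatory gap
columns, so identities divided by residue-residue columns alone would
approach 100% for unrelated pairs. Under the span definition a true
fragment or a substitution-only near-duplicate still scores ~100 while a
scattered match collapses. All-vs-all exact alignment is quadratic; the
implementation screens pairs with a cheap upper bound before computing the
exact span statistics, hashes exact duplicates, and is intended for
desk-scale sets (a few hundred sequences; about half a minute at n = 250).
Full-proteome scalability is explicitly not a goal — externally computed
cluster assignments (e.g. OrthoMCL groups) can be supplied as a TSV and used
everywhere a computed catalog can.

For the evolutionary contrast, clusters are classified against the species
panel: members from exactly one species (including singletons) make a
cluster *specific*, members from every species make it *common*, anything
else is *intermediate* and excluded. `categoryContrast()` compares a
per-protein metric between the two categories: means, their specific/common
ratio, and a one-tailed p for "specific > common" from Welch's
unequal-variance t test (the safe default for unequal group sizes; an exact
or Monte Carlo permutation test is available). Whether the classification
runs on the redundancy-filtered or raw sets is a config switch
(default: filtered, matching the analysis order).

## The statistical core

* **Per-400-residue normalization.** Counts are rescaled to a uniform
  400-residue length. At the proteome level the default is pooled:
  `sum(counts) * 400 / sum(lengths)`; a per-protein-mean mode exists because
  the two differ whenever counts correlate with length.
* **Binned correlation.** Proteins are binned by site count 0, 1, ..., 6,
  >=7 (cap K = 7, configurable); each bin's mean disorder content
  (arithmetic mean of member proteins' disordered fraction) is correlated
  against the numeric bin index (the pooled bin takes the value K). Empty
  bins are dropped; fewer than three non-empty bins flags the correlation
  as not computable. Using the bin index rather than the within-bin mean
  count keeps the x variable well defined for the pooled tail.
* **One-tailed inference.** `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with the
  upper tail of Student's t at `n - 2` degrees of freedom, reported for the
  observed direction. For n = 8 this has the even-df closed form
  `p = (1 - r(1 + (1-r^2)/2 + 3(1-r^2)^2/8)) / 2`, which the test suite
  checks to 1e-12.
* **Multiple testing.** Benjamini-Hochberg step-up per species row (the
  eight parameters of one species) by default; a global family across all
  species x parameters is a config option. Note the step-up adjustment is
  *not* idempotent — re-adjusting adjusted values inflates them — so the
  suite asserts order preservation, pointwise dominance and oracle equality
  instead.
* **Rd/o.** `(Nd/Ld) / (No/Lo)`: sites on disordered residues per
  disordered residue, over the same density in ordered residues, pooled
  across the proteome. Group and total values pool the four counts across
  species — never the mean of per-species ratios, which differs whenever
  denominators differ. Rd/o is computed for site-anchored PTMs only
  (phosphorylation, O-/N-glycosylation, ubiquitination); PEST and TM are
  region counts and enter the binned correlation only.
* **Ubiquitination confidence band.** Only sites with scores in
  `0.69 <= s <= 0.84` (inclusive) are counted — the medium-confidence band
  of the upstream predictor as printed; the band is configurable since the
  printed upper bound excludes high-confidence sites, which may or may not
  have been intended in the original description.

## The synthetic generator

`generateProteomes()` emits multi-species annotated proteomes with planted
ground truth. The defaults are the study conditions of the package's
validation experiments and are not tuned per test:

| quantity | default | why |
|---|---|---|
| species x proteins | 4 x 500 | 2,000 proteins, the parameter-recovery scale |
| length law | log-normal, median 350, sdlog 0.7, truncated [50, 4000] | proteome-like right-skewed lengths inside the filter bounds |
| disorder fraction | Beta(2, 5), segments of mean 30 aa | proteome mean ~0.29, within the 20-35% range typical of these proteomes |
| planted rho (S, T, Y, Ubi) | 18.8, 10.5, 1.3, 12.5 | proteome-scale enrichment estimates for the four site types |
| base densities (S, T, Y, Ubi) | 0.5, 0.2, 0.3, 0.25 per 400 aa | keep per-legal-residue probabilities well below 1 and mean counts in the 0-7 bin range |
| specific-family multipliers | disorder x1.7, PTM rates x2 | the specific/common contrast magnitudes |
| duplicates | 10% at 2% mutation | within the 1-27% redundancy range of real sets |
| secretory | 25% signal peptides; TM count Poisson(0.5), 19-23 aa, ordered regions only | makes the N-gly gate and the negative TM association exercisable |

Disordered segments are composed preferentially of disorder-promoting
residues (A, R, G, Q, S, E, K, P) and ordered segments of order-promoting
ones (I, L, V, C, W, Y, F, N), with all twenty residues possible in both so
every site type has legal residues everywhere. Sites are drawn per legal
residue with probabilities scaled so the expected per-residue density is
`base/400` in ordered and `rho * base/400` in disordered residues — the
planted Rd/o is therefore `rho` in expectation regardless of composition.
Configs whose rates would require more than one site per legal residue are
rejected up front. Decoy ubiquitination sites with out-of-band scores
exercise the confidence filter; the truth table records in-band sites only.

Two deliberate design notes:

* **Pooled Rd/o vs per-family rho.** When specific families carry both a
  higher disorder fraction and a higher PTM rate (the default contrast
  conditions), the disordered residue pool is enriched for high-rate
  proteins and the pooled Rd/o genuinely exceeds the per-family rho (by
  roughly 15% at the defaults). This is a property of the pooled statistic,
  not an estimation error. The rho-recovery experiments therefore use a
  uniform rate multiplier, isolating rho; the contrast experiments keep the
  multipliers.
* **Slope mode.** `siteCountDisorderSlope > 0` switches to a count-first
  construction: per-type counts are drawn Poisson, the protein's disorder
  fraction is `0.15 + slope * total + N(0, 0.05)` (clipped), and sites land
  uniformly on legal residues. This plants a linear disorder-vs-count
  relation for the bin-correlation tests; `rho` is ignored in this mode and
  the two modes are alternatives by construction.

Determinism: one root seed drives everything; each family, member and
duplicate gets its own stream via an integer mixing function, so outputs are
byte-identical across runs of the same config. What the generator does
*not* emulate: real disorder-predictor error structure, evolutionary indels
(family divergence is substitution-only), genuine orthology topologies,
compositional biases beyond the two region classes, or realistic
glycosylation biology — passing tests demonstrate that the pipeline's
arithmetic and recovery behavior are correct under the planted model, not
that any biological conclusion holds for real proteomes.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; converters sit only at
  boundaries.
* Non-standard residues (B, Z, U, O) map to `X` at ingestion with a
  warning; `X` participates in lengths and spacers, never in literal
  matches or identity credit.
* Representative selection ties break by protein id, then species id.
* `rdo` with `No = 0` reports `Inf` (with a warning) and `NA` when either
  residue class is empty; correlations on fewer than three bins or
  zero-variance disorder are signaled rather than computed.
* `categoryContrast` on two identical value multisets returns ratio 1 and
  p = 0.5.
* Validation of annotation tables is strict by default (any bad row aborts
  the load); lenient mode skips bad rows and reports the count, for noisy
  external exports.

## Problem sizes

The bundled experiments run at: 2,000 proteins for parameter recovery
(Rd/o, slope, contrast), ~230 proteins for clustering recovery, and
~100-proteome-scale inputs for the end-to-end pipeline tests. These sizes
give tight recovery (binomial coefficients of variation of a few percent on
site counts) while the full test suite and the acceptance script each finish
in minutes on one CPU.

## Limitations

* The clustering engine is exact alignment + threshold graph + connected
  components — a deliberate, deterministic simplification of a BLAST +
  Markov-clustering workflow. It reproduces the partition-level uses
  (redundancy removal, species-membership classification) but is not an
  orthology method and does not scale to whole real proteomes.
* The O-glycosylation scan policy (occurrence counting, non-overlap,
  shortest extent) is one canonical reading of an unpublished consensus
  scanner; alternatives are provided as options, and absolute site counts
  shift between policies even though enrichment signs do not.
* Printed one-significant-figure p values can only be reproduced where the
  underlying bin count is known; panels with dropped bins (n < 8) are not
  recoverable from the printed correlation alone.
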