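# idrptm

Proteome-wide analysis of how intrinsic protein disorder relates to
post-translational modification (PTM) sites, PEST degradation regions and
transmembrane helices, across multi-species protein sequence sets.

Intrinsically disordered regions (IDRs) are flexible, solvent-exposed
protein segments. The package quantifies whether PTM sites concentrate in
them, for sequence sets such as algal proteomes where disorder content runs
around 20–35%. It is aimed at computational biologists who have per-residue
disorder calls and externally predicted sites (phosphorylation,
ubiquitination, signal peptides, TM helices) as tables, and want the full
downstream analysis: redundancy filtering, motif scanning, normalization,
enrichment statistics and multi-species contrasts — plus a synthetic
proteome generator with planted ground truth to validate every stage.

## What it computes

* **Ingestion and filtering** — FASTA proteomes (`readProteomeFasta`),
  length filter keeping 50–4000 aa (`filterByLength`), summaries.
* **Redundancy clustering** — exact global alignment (match +1 / mismatch 0
  / gap −1); proteins link when percent identity ≥ 90 and percent match
  ≥ 90 (both configurable); single-linkage clusters; longest-member
  representatives (`buildClusters`, `selectRepresentatives`,
  `redundancyContent`).
* **Sequence scanners** — plant hydroxyproline O-glycosylation consensus
  `[A/S/T/V]-P(1,4)-X(0,10)-[A/S/T/V]-P(1,4)` (`scanOgly`); N-glycosylation
  sequons N-X-S/T, X ≠ P, gated by secretory context (`scanNglySequons`,
  `combineNgly`); PEST regions with the classic PEST-find score
  (`scanPest`).
* **Annotations** — per-residue disorder masks, site/segment tables with
  strict residue-type validation, the ubiquitination medium-confidence band
  0.69 ≤ s ≤ 0.84 (`filterUbiquitination`), disorder content.
* **Statistics** — per-400-aa normalization (pooled:
  Σcounts·400/Σlengths); site-count bins 0…≥7 vs mean disorder content;
  one-tailed Pearson inference, t = r√(n−2)/√(1−r²) with the upper t tail
  at n−2 df; Benjamini–Hochberg FDR; the enrichment ratio
  **Rd/o = (Nd/Ld)/(No/Lo)** (site density in disordered over ordered
  residues, pooled; 1 = no structural preference); species-group pooling;
  the species-specific vs common cluster contrast with one-tailed Welch or
  permutation tests (`categoryContrast`).
* **Pipeline** — `runPipeline(runConfig(...))` executes
  ingest → filter → cluster → scan → stats → contrast and writes TSV
  analogues of the study's result tables; `generateProteomes(synthConfig())`
  builds fully annotated synthetic proteome sets with planted enrichment,
  families, duplicates and secretory features.

## Worked example

```r
library(idrptm)

# a small two-species synthetic study, fully annotated, seeded
cfg <- runConfig(
  synth = synthConfig(nSpecies = 2, nProteinsPerSpecies = 40,
                      lengthLaw = list(min = 50, max = 800,
                                       meanlog = log(200), sdlog = 0.5),
                      seed = 9),
  categories = list(source = "truth", piCutoff = 50, pmatchCutoff = 50,
                    externalPath = NULL, onFiltered = TRUE))
rep <- runPipeline(cfg)

subset(rep$table1, parameter == "phospho_S")
#>   species_id parameter         r n_bins p_one_tailed         fdr
#> 1       sp01 phospho_S 0.9501459      7 0.0005187731 0.002593865
#> 9       sp02 phospho_S 0.7158148      8 0.0229217407 0.109246536

subset(rep$table2, parameter == "phospho_S" & group == "Total")
#>   parameter group  Nd   Ld No    Lo     rdo
#> 3 phospho_S Total 276 7189 21 10323 18.8724
```

Reading: in both synthetic species the mean disorder content rises with the
number of S-phosphorylation sites per protein (r = 0.95 and 0.72 over the
site-count bins, one-tailed p of 5·10⁻⁴ and 0.02 — at 40 proteins per
species the bin means are noisy), and pooled over the set, an S-phosphosite
is about 19 times denser in disordered than in ordered residues
(Rd/o = 18.87; the generator planted 18.8) — the pattern the
analysis is designed to detect. `rep$table3` carries the specific/common
cluster contrast and `rep$speciesSummary` the filtering and redundancy
audit trail. The exact numbers above are reproduced by the seeded example;
your values change with the seed and sizes.

Single operations work standalone:

```r
scanOgly("APAPAPAP")      # two non-overlapping consensus sites
scanNglySequons("ANKSA")  # one sequon at the N in position 2
rToOneTailedP(0.976, 8)   # t = 10.98, p = 1.7e-05
bhFdr(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
```

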