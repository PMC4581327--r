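Package: idrptm
Title: Intrinsic Disorder and Post-Translational Modification Analysis for
    Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Proteome-wide analysis of the association between intrinsically
    disordered regions (IDRs) and post-translational modification (PTM)
    sites. Reads multi-species protein sequence sets, removes sequence
    redundancy by identity clustering (90/90 thresholds), scans sequences
    for plant-type hydroxyproline O-glycosylation consensus motifs,
    N-glycosylation sequons gated by secretory context, and PEST
    degradation regions, consumes externally predicted disorder masks and
    phosphorylation/ubiquitination site tables, and computes per-400-residue
    normalized densities, site-count binned disorder correlations with
    one-tailed Pearson inference and Benjamini-Hochberg FDR, the
    disordered/ordered site-density ratio Rd/o, and the species-specific
    versus common protein-cluster contrast. Includes a synthetic proteome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'proteome-io.R'
    'annotations.R'
    'clusters.R'
    'idrptm-package.R'
    'scanners.R'
    'synthetic.R'
    'ptm-stats.R'
    'pipeline.R'
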