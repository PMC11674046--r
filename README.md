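# nucloc

Quantitative image analysis for assays of nuclear export receptor
biology, with a fully ground-truthed synthetic micrograph generator.

Receptors such as CRM1/XPO1 export NES-bearing cargos from the nucleus,
and additionally localize to intranuclear compartments: Cajal bodies in
untreated cells, nucleoli under RNA polymerase I inhibition.  Comparing
receptor variants therefore needs two per-cell quantities from
multi-channel fluorescence micrographs (DNA stain, YFP-tagged receptor,
compartment marker, cargo immunostain):

* a **compartment/nucleoplasm intensity ratio** — mean YFP in one
  selected compartment focus over mean YFP in the nucleoplasm of the
  same cell — plus a binary "compartment positive" call
  (ratio ≥ 1.5 by default); and
* a **cargo export ratio** — nuclear/cytoplasmic (N/C) mean intensity of
  the cargo per cell, or nuclear/total against the whole-micrograph mean
  where cytoplasm cannot be delineated — under an expression-level
  control on the nuclear YFP signal.

Condition-level localization is summarized by a composite score.  With
p̄ the mean percentage of compartment-positive cells across experiments
and r̄ the mean compartment/nucleoplasm ratio across experiments,

    raw score  = p̄ × r̄            (mean of means, experiments weighted equally)
    normalized = 100 × raw / raw(reference)

so the reference condition scores exactly 100.  Conditions are compared
to the reference with two-sided pooled Student's *t* (Welch optional) and
star labels under strict inequalities (`*` p<0.05, `**` p<0.01, `***`
p<0.001, `****` p<0.0001, else `n.s.`).

The package is aimed at cell biologists and image analysts who want this
scoring pipeline as tested, reusable code: every stage — simulation,
segmentation (EBImage-based), per-cell measurement, scoring, export
assay, statistics, report — is an exported function, and the synthetic
generator provides exact per-cell ground truth so the whole chain is
validated without any external data.

## Worked example

Simulate and analyse three conditions — a reference, a
separation-of-function variant (`a541k`: Cajal-body localization lost,
nucleolar relocation kept) and a variant with cargo-selective export
effects (`f572a`) — with three experiments of ~50 cells each:

```r
library(nucloc)
out <- runPipeline(list(conditions = c("wt", "a541k", "f572a"),
                        nExperiments = 3L, nCells = 50L,
                        imageSize = c(340L, 340L)),
                   outDir = "demo_run", masterSeed = 1L)

out$scores$cb[, c("condition", "n_cells", "raw_score", "normalized_score")]
#>   condition n_cells  raw_score normalized_score
#> 1        wt     108 145.850367      100.0000000
#> 2     a541k     108   1.023852        0.7019877
#> 3     f572a      99  10.406534        7.1350759

out$scores$nol[, c("condition", "n_cells", "raw_score", "normalized_score")]
#>   condition n_cells  raw_score normalized_score
#> 1        wt     103 174.413601       100.000000
#> 2     a541k     107 123.688865        70.916984
#> 3     f572a     116   1.799182         1.031561
```

The reference is 100 by construction.  `a541k` has lost Cajal-body
localization (normalized CBscore 0.70) while nucleolar relocation is
largely preserved (normalized NOLscore 70.9); `f572a` shows the converse
nucleolar loss (1.03).  The per-cell export comparisons show `f572a`
abolishing export of cargo A (N/C shifted up versus the reference) while
enhancing export of cargo B (N/C shifted down), both highly significant:

```r
subset(out$comparisons, metric %in% c("cargoA_export", "cargoB_export"))
#>    condition        metric    t_stat      p_value stars
#> 7         wt cargoA_export   0.00000 1.000000e+00  n.s.
#> 8      a541k cargoA_export  19.77904 3.312513e-50  ****
#> 9      f572a cargoA_export  23.42705 7.048783e-60  ****
#> 10        wt cargoB_export   0.00000 1.000000e+00  n.s.
#> 11     a541k cargoB_export  17.86088 7.234158e-44  ****
#> 12     f572a cargoB_export -15.91222 2.687042e-38  ****
```

`demo_run/` now contains the full report: per-cell measurement CSVs,
score tables, export records, expression-control verdicts, the
comparisons table, a config snapshot and a QC log.  Rerunning with the
same `masterSeed` reproduces every table byte for byte.

See the vignette
(`vignettes/quantifying-intranuclear-localization.Rmd`) for the model,
parameter meanings, and design rationale.

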