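---
title: "Quantifying intranuclear receptor localization and nuclear export"
author: "nucloc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intranuclear receptor localization and nuclear export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Nuclear export receptors such as CRM1/XPO1 carry NES-bearing cargos out of
the nucleus, but also localize to intranuclear compartments — Cajal bodies
in untreated cells, nucleoli when RNA polymerase I is inhibited.  Two
questions are asked of fluorescence micrographs of cells expressing a
YFP-tagged receptor variant:

1. **How strongly does the variant localize to a compartment?**
   Quantified per cell as the ratio of the mean YFP intensity in one
   selected compartment focus to the mean YFP intensity in the
   nucleoplasm of the same cell, plus a binary call ("compartment
   positive") per cell.
2. **How well does the variant export an endogenous cargo?**  Quantified
   per cell as the nuclear/cytoplasmic (N/C) ratio of the cargo
   immunostain, or — where cytoplasm cannot be delineated because cells
   grow in clusters — as a nuclear/total ratio against the mean of the
   whole micrograph.

The condition-level summary of question 1 is a composite localization
score.  Writing $p_e$ for the percentage of compartment-positive cells in
experiment $e$ and $\bar r_e$ for the mean compartment/nucleoplasm ratio,
the raw score of a condition over $E$ experiments is

$$ S_\text{raw} = \Big(\tfrac1E \sum_e p_e\Big) \cdot
   \Big(\tfrac1E \sum_e \bar r_e\Big), $$

a mean of means in which every experiment carries equal weight regardless
of its cell count.  Scores are reported normalized to a designated
reference condition,

$$ S_\text{norm} = 100 \cdot S_\text{raw} / S_\text{raw}^\text{(ref)}, $$

so the reference scores exactly 100 by construction (the package asserts
this as an exact fixed point, not a floating-point approximation).
Condition-versus-reference comparisons use the classic two-sided pooled
Student's *t* test with significance called at $p < 0.05$ and
figure-legend star labels under strict inequalities: `****` $p<10^{-4}$,
`***` $p<10^{-3}$, `**` $p<0.01$, `*` $p<0.05$, else `n.s.` ($p = 0.05$
exactly is non-significant).

No public per-cell dataset accompanies this kind of assay, so the package
ships a synthetic scene generator with exact per-cell ground truth; every
analysis stage is validated against it.

## The synthetic scene model

`SceneParams()` describes a field of non-overlapping elliptical cells on a
constant background, rendered into four channels in the canonical order
*dna, yfp, marker, cargo*:

* **dna** — constant level inside every nucleus (DAPI-like);
* **yfp** — the tagged receptor: a log-normal nucleoplasmic level per
  transfected cell, a fixed lower cytoplasmic fraction, and each
  compartment focus multiplied by the cell's true enrichment ratio;
* **marker** — compartment marker (coilin-like for Cajal bodies,
  NMD3-like for nucleoli): enriched in the compartments of *all* cells,
  because marker staining is independent of receptor behaviour;
* **cargo** — the export substrate: constant nuclear and cytoplasmic
  levels per cell whose ratio is the cell's true N/C ratio.

Noise is a mixed Poisson–Gaussian camera model applied per pixel,
`Poisson(v * poissonScale)/poissonScale + N(0, gaussianSD)` clipped at
zero, whose expectation equals the noiseless rendering — so masked means
remain unbiased and noiseless scenes are *exactly* piecewise constant,
which is what makes machine-precision oracle tests possible.

Key generator parameters (all intensities in arbitrary units):

| parameter | default | meaning |
|---|---|---|
| `nCells`, `imageSize` | 120, 640×640 px | field size; a typical micrograph holds ~100+ cells |
| `fractionTransfected` | 0.7 | transfected subpopulation |
| `yfpExpression` | median 200, gsd 1.8 | log-normal nucleoplasmic YFP |
| `fractionPositive` | 0.65 | transfected cells with compartment enrichment |
| `enrichmentRatio` | median 3.0, gsd 1.3 | true compartment/nucleoplasm ratio of positive cells |
| `cargoNCRatio` | median 0.5, gsd 1.35 | true cargo N/C ratio |
| `markerEnrichment` | 4 | marker contrast of foci over nucleoplasm |
| `noise` | poissonScale 1, gaussianSD 2 | camera model |

Negative and untransfected cells have a true ratio of exactly 1.0, so
positivity is a property of enrichment, never geometry.  Cells are placed
by rejection sampling (up to 1000 attempts per cell, then an explicit
"scene overcrowded" error); clustered growth is emulated by shrinking the
cell body to a thin rim around the nucleus and allowing tangency, never
true overlap, which keeps per-pixel ground truth well defined.  Geometry
defaults (nucleus radius 8–11 px, 1–3 Cajal-body foci of 2–3 px, or
nuclei of 9–12 px with 1–2 nucleoli of 3.5–4.4 px) are free choices of
this package: no acquisition metadata (pixel size, bit depth, objective)
constrains them, and validity checking enforces that worst-case
compartment area stays below half of the smallest nucleus.

What the generator deliberately does **not** emulate: optics (PSF,
chromatic aberration), 3-D structure, photobleaching, autofluorescence
texture, overlapping cells, or segmentation-hostile staining artifacts.
Passing tests therefore demonstrate correctness of the *quantification*
given images whose statistical structure matches the assay's assumptions;
they do not certify segmentation robustness on difficult real-world
micrographs.

## From image to per-cell measurements

* **Nuclei** — global Otsu threshold on the DNA channel, hole filling,
  connected components, area filter, and exclusion (with QC tally) of
  border-touching objects.  Otsu was chosen because it is parameter-free
  and adequate for the generator's contrast regime; a blank channel
  yields an empty mask with a warning, not an error.
* **Cell bodies** — in `large_cytoplasm` mode, the cargo channel is
  thresholded into a foreground mask that is partitioned among nuclei by
  seeded propagation (EBImage's watershed-style `propagate`), so every
  foreground pixel belongs to exactly one cell; cytoplasm = cell minus
  nucleus.  In `clustered` mode no cytoplasm is produced and requesting
  N/C ratios is an explicit error — the analysis must use N/total.
* **Compartment foci** — connected regions of marker signal above a
  per-nucleus adaptive threshold (nucleoplasm median × `minContrast`,
  default 2), size-filtered by compartment kind.  The assay quantifies
  *one* compartment per cell; since no selection rule is implied by eye
  scoring, the package selects the focus with the highest mean marker
  intensity — a reproducible proxy for an experimenter picking a clearly
  visible body.  Cells without any detected focus are a QC-tallied data
  outcome.
* **Measurement** — arithmetic means over mask pixels.  The nucleoplasm
  excludes *all* detected foci, each dilated by a 1-px guard ring so
  partial-boundary pixels cannot contaminate the denominator.  The
  whole-nucleus YFP mean (expression control) is measured over the intact
  nucleus.  Divisions are guarded: empty or zero-mean nucleoplasm flags
  the cell invalid with a reason code.  Saturated pixels (≥ `satLevel`)
  are excluded from means and counted.
* **Positivity** — `compartment_ratio >= 1.5` by default.  The visual
  scoring it replaces has no stated criterion, so the threshold is
  configurable and a built-in sweep (`thresholdSweep`, 1.2–2.0) reports
  the sensitivity of every normalized score to it.  At the default,
  simulated positives (ratio median 3.0) separate from negatives (ratio
  1.0) with recall and precision above 0.95.
* **Transfection selection** — cells are kept when their nuclear YFP mean
  falls in a window (absolute a.u. or percentiles), mirroring the
  restriction to low-to-moderate expressors; how "low to moderate" maps
  to numbers is not externally defined, so the window is a config
  parameter (pipeline default 60–5000 a.u. against an untransfected
  level of ~20) with exclusion counts reported on both sides.

Ratios are measured in **all** scored cells with a detectable marker
focus, positive or not.  Marker staining is receptor-independent, and
this choice keeps the percentage factor and the ratio factor of the score
statistically decoupled.  Whether eye-scored assays measured ratios only
in positive cells is unknowable from the outside; both modes exist and
the default is recorded in the output provenance.

## Scores, export assay, and report

`scorePipeline()` computes the mean-of-means score per condition and
*also* a pooled-cells variant (all cells pooled before computing the
percentage and the mean ratio) so the discrepancy between the two
weightings is always visible rather than silently chosen.  Because one
representative experiment may stand in for the ratio factor in published
figures, `ratioMode = "representative"` reproduces that convention
without asserting it as the default.  An optional bootstrap CI
(resampling experiments, then cells; seeded) is available via `nBoot`,
clearly an extension: the composite score is descriptive and carries no
analytic CI.

The export assay (`assayCondition`) attaches per-cell N/C or N/total
ratios and runs the expression control: each condition's nuclear YFP
distribution is compared to the reference by Student's *t*, and
conditions differing at $p<0.05$ are flagged non-comparable, since an
apparent export difference could then be an expression artifact.  The
whole-micrograph "total" includes background pixels by definition; a
cells-only variant would change the scale but not the ordering and is not
the default.

`compareAll()` performs one *t* comparison per condition × metric on
per-cell values (per-experiment percentages for the percentage metrics),
with no multiple-testing correction by default — matching the
single-comparison convention of the assay — and an optional Holm
step-down flag that re-labels stars and is marked as an extension.
Whether the original analyses used equal-variance or Welch *t* is not
stated by the software they used; the pooled variant is the default and
Welch sits behind a flag.

`runPipeline()` ties everything together from a single config (R list or
YAML): for each condition × experiment it simulates a Cajal-body scene
(whose cargo channel carries cargo A, RanBP1-like) and a nucleolus scene
(cargo B, p65-like) — one simulation economy choice instead of separate
export-assay scenes — measures them, scores both compartments, assays
both cargos with the expression control, and writes a report directory
(CSV tables at full float precision, config snapshot, QC and log).
Per-experiment seeds derive deterministically from the master seed via a
documented stable hash (`seedForExperiment`), and reruns are
byte-identical.

## Numerical choices and edge cases

* Intensities are arbitrary-unit doubles end to end; all ratios are
  internal to a cell (or micrograph), so no background subtraction is
  applied by default and every reported ratio is invariant to global
  intensity rescaling (tested to 1e-12).
* TIFF storage: the available writer has no float sample format, so
  scenes are stored as 32-bit samples on a [0, 1] range with the
  intensity scale recorded in a sidecar JSON; round trips are exact to
  better than 1e-9 of the scale.  All analysis functions accept in-memory
  arrays, and the machine-precision oracle guarantees (1e-9 relative on
  noiseless scenes) are properties of the array path.
* Degenerate statistics follow explicit conventions: two zero-variance
  samples give $p=1$ when means agree and $p=0$ (flagged degenerate) when
  they differ; a reference raw score of 0 makes normalization an error
  rather than an Inf.
* Ties in focus selection resolve to the first maximum in label order;
  focus-to-nucleus assignment of a component spanning two touching nuclei
  goes to the majority owner.

## Problem sizes used by the tests

The shipped test-suite and acceptance script exercise deliberately
moderate suites — scenes of 300–640 px with 14–120 cells, 2–5 experiments
per condition, 10 seeded replicate runs for the null-condition
calibration check, and 10,000 null replicates for *t*-test calibration —
sizes this package treats as its standard validation suite.  The same
code runs unchanged on larger fields; nothing in the implementation is
specific to these sizes.

## Known limitations

* Segmentation is threshold-based and tuned to the generator's contrast
  regime; real micrographs with uneven illumination or touching nuclei
  will need the usual preprocessing care (or external masks, which
  `measureCells` accepts directly).
* The composite score inherits the units quirk of multiplying a
  percentage by a ratio; only normalized values are meaningful across
  analyses, and published per-variant score values cannot be reproduced
  without the underlying per-cell data.
* The expression control tests distribution equality of means only; a
  variant could match on mean YFP yet differ in distribution shape.
* 2-D only; no kinetics; no attempt to model the biology of cargo
  retention beyond a generating parameter.
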