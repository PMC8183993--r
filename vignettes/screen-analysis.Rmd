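---
title: "Quantifying translation screens: from pixels to hit lists"
author: "oppscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translation screens: from pixels to hit lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppscreen)
```

## The measurement problem

Global mRNA translation can be read out cell by cell by pulsing cultures
with O-propargyl-puromycin (OPP), a puromycin analog that is incorporated
into nascent polypeptide chains and then click-labeled with a fluorophore.
In a high-content screen, U2OS-like cells in 384-well plates are exposed to
a compound library, pulsed with OPP, fixed, counterstained with a nuclear
dye, and imaged at low magnification (several fields per well). Two
readouts per well drive everything downstream: the **mean cytoplasmic OPP
intensity** (the translation signal) and the **nuclei count** (a viability
proxy). Cycloheximide (CHX), which blocks elongation, serves as the
floor-level control; an mTORC1 inhibitor such as Torin 2 gives an
intermediate reduction — a working assay must order vehicle > Torin-like >
CHX-like.

The analytical crux is that OPP signal lives in the cytoplasm while the
only reliably segmentable landmark is the nucleus. The pipeline therefore
measures translation on a **tertiary object**: each nucleus seeds a
whole-cell ("secondary") region grown outward over the OPP channel, and
the cytoplasm is the secondary object minus the nucleus.

## Segmentation model

`segment_nuclei()` applies light Gaussian smoothing (sigma 1 px by
default), a global Otsu threshold, 8-connected component labeling, and an
area gate (`[min_area, max_area]`, default 40–5000 px at 10x-like
sampling) that removes debris and clumps.

`propagate_cells()` grows each nucleus into a cell region by multi-source
shortest paths. A step between 4-adjacent pixels $p$ and $q$ costs

$$c(p,q) = \sqrt{(I(p)-I(q))^2 + \lambda},$$

where $I$ is the OPP channel and $\lambda \ge 0$ trades intensity guidance
against plain geometric growth: as $\lambda \to 0$ the region hugs
iso-intensity structure, for large $\lambda$ the cost approaches
$\sqrt{\lambda}\times$ path length and the partition tends to a Voronoi
diagram of the seeds. Each pixel takes the label of the seed with minimal
cumulative cost. Three guards keep regions physical:

* expansion stops after `max_distance` steps (default 40 px; the original
  analysis "expands a defined number of pixels" without reporting the
  number, so it is exposed as a parameter rather than guessed);
* pixels at or below a background threshold are never claimed (default:
  Otsu on the OPP channel, clamped below by `bg_floor`), which keeps cells
  off empty plate surface;
* seed pixels always keep their own label.

Determinism matters for reproducibility: the best-first expansion breaks
ties by (cost, label, scan order), so the partition is invariant to seed
renumbering, and an exhaustive shortest-path oracle (independent
`igraph::distances` over the full pixel graph) reproduces it exactly on
randomized small grids in the test suite. $\lambda$ defaults to 0.05,
small enough that intensity structure dominates on 16-bit-scale images.

`subtract_nucleus()` is a pixelwise set difference, and `measure_cells()`
reports per-cell areas and mean OPP intensities over the cell, nucleus and
cytoplasm masks. Two identities are enforced by construction and tested:
`cell_area = nucleus_area + cytoplasm_area`, and the area-weighted mean
identity between the three masks. Cells touching the field border have
truncated cytoplasm; they are flagged and excluded from well summaries,
never silently dropped. Nucleus declumping is out of scope (the synthetic
nuclei are non-overlapping by construction).

## From cells to compounds

`summarize_well()` pools included cells across the fields of a well
(default) rather than averaging per-field means; pooling weights every
cell equally, which is the natural estimator when field cell counts vary.
The alternative (`pool = "fields"`) is provided because the original
description does not say which was used; on balanced synthetic data the
two agree.

`normalize_plate()` divides each well's OPP mean and nuclei count by the
mean over that plate's vehicle (DMSO) wells — percent-of-control
normalization. The DMSO wells are included in their own reference, so per
plate their normalized mean is exactly 1, and any well-independent
multiplicative plate factor cancels identically (a property the test suite
asserts at 1e-9 on paired plates differing by a 2x factor). No spatial
(row/column) correction is applied: the screen design normalizes only to
vehicle.

`aggregate_replicates()` collapses the three replicate plates per compound
into means and coefficients of variation, using the sample SD (n − 1
denominator; the estimator is not stated in the original description, and
with n = 3 the choice is consequential, so it is documented here).
Compounds missing a replicate are flagged and excluded from hit calling
rather than scored on partial data.

## Hit calling

`call_hits()` implements four gates, all strict inequalities:

1. the triplicate-mean normalized OPP deviates from the vehicle mean by
   more than `k_sd` (default 3) vehicle SDs;
2. viability loss is at most `max_toxicity` (default 30%: mean normalized
   nuclei count at least 0.70) — stronger losses are *excluded*, not
   called, because translation collapse secondary to cell death is not a
   translation phenotype;
3. the per-plate deviation exceeds 3 SDs on **all three** plates with a
   consistent sign;
4. the triplicate CV is below `max_cv` (default 20%) for **both** the OPP
   intensity and the nuclei count.

The vehicle SD in gate 3 is each plate's own DMSO SD; gate 1 uses the DMSO
distribution pooled across plates. The source description does not
disambiguate which SD the mean-level test used; the per-plate SD is the
natural scale for per-plate flags, while the pooled SD makes the mean-level
gate robust to a single plate with an unusually tight vehicle spread. Both
are reported per compound in the output.

Classes are `up`/`down` (all four gates), `excluded` (toxicity or
incomplete triplicate, with a reason string), otherwise `null`.

## Dose–response validation

Validation screens re-test hits at 1, 3 and 10 uM on two independent
plates, in both the OPP assay and the orthogonal HPG
(homopropargylglycine) incorporation assay, which labels nascent chains
without arresting elongation. The original criterion —"consistently
decreased translation in a dose-dependent manner"— is qualitative, so
`evaluate_dose_response()` makes it explicit and configurable: a series
passes when the top dose shows at least `min_effect` (default 0.25)
reduction and responses are non-increasing within an additive `mono_tol`
(default 0.05, roughly the vehicle-well noise scale). The strict default
requires every (assay x plate) series to pass; because "either OPP or HPG"
could also be read as either-sufficient, a lenient mode
(`require_both_assays = FALSE`) is provided behind a flag.

## Proteomics stage

The pipeline enters at a quantified protein table (three treated, three
control log2 intensities per protein); raw spectra processing is out of
scope. `differential_proteins()` runs a per-protein two-sample t-test and
flags proteins with raw p < 0.05 and |log2FC| > 0.3 as regulated, with
Benjamini–Hochberg q-values reported alongside (the filter is worded on
raw p; BH estimates the attendant FDR). The default is the pooled-variance
Student test: at n = 3 per group the Welch test is markedly conservative
(empirical size ≈ 0.033 at nominal 0.05 in the package's own null
simulations), whereas the pooled test is exact under the equal-variance
replicate model the generator implements and keeps the null
type-I error at 5%. Welch remains available (`var_equal = FALSE`) and the
choice is recorded in the result's `test` attribute. Moderated-variance
(limma-style) testing is deliberately not the default here; it is noted as
an extension.

`gsea_preranked()` implements the weighted preranked enrichment
statistic: proteins are ranked by log2 ratio (descending, ties broken by
id), and for a set of size $N_s$ in a universe of $N$ the running sum
gains $|r_i|^p / \sum_{j \in S} |r_j|^p$ at members and loses
$1/(N-N_s)$ at non-members ($p$ = 1, "weighted"; $p$ = 0 recovers the
classic Kolmogorov–Smirnov-style statistic). The enrichment score is the
extremum of larger magnitude; an exact positive/negative tie scores 0,
matching reference implementations — on small universes the miss
decrement makes such ties attainable, which is also why the package's
small-universe tests enumerate every membership exhaustively. The null
comes from gene-label permutations (seed mandatory; exhaustive
enumeration replaces sampling when the membership count is small), NES
divides ES by the mean magnitude of same-sign null scores, and FDR q
follows the pooled-null procedure, sign-stratified.

## The synthetic-data generator

Nothing in the analysis can be validated without ground truth, so the
generator is first-class, tested code. It emulates:

* 384-well triplicate plates sharing one layout: vehicle wells (default
  column 1), Torin-like wells (0.5x OPP) and CHX-like wells (0.05x OPP;
  the 0.05/0.5 pair reproduces the qualitative control ordering, not any
  fitted value), and planted compounds with multiplicative OPP effects,
  toxicity factors on the expected cell count, and a replicate-to-replicate
  effect CV;
* per-cell cytoplasmic intensity: baseline x lognormal plate factor
  (sdlog 0.1) x lognormal well factor (CV 5%) x compound effect x
  replicate noise, with Gaussian cell-to-cell spread whose SD scales with
  the well mean (a constant *relative* spread — a strong down-regulator
  well has proportionally dim cells, not negative-going ones). The plate
  and well factors are exactly the level shifts that percent-of-DMSO
  normalization must remove;
* rendering: cells as hard-disk nuclei plus annular cytoplasm over flat
  backgrounds, additive Gaussian pixel noise on both channels, 16-bit
  clipping with the clipped fraction reported. Positions are
  rejection-sampled so cells never overlap and never touch the field
  border; morphology heterogeneity, illumination artifacts and photoreal
  texture are explicit non-goals;
* a 3-vs-3 proteomics table with planted regulated proteins shifted by
  ±`effect_log2fc`, alternating direction.

Every random quantity derives from one user seed through a deterministic
per-plate/per-well/per-purpose splitter, so identical seeds give
bit-identical screens, any subset regenerates in isolation, and fast mode
(well-level tables, no pixels) shares its ground truth with image mode.
At zero pixel noise the image-mode pipeline reproduces fast-mode well
means within 5% (exactly, in practice, because noiseless annuli are
recovered pixel-perfectly); with noise the agreement is bounded by the
standard error terms the tests assert.

What passing these tests does *not* show: robustness to overlapping or
irregular cells, illumination gradients, focus failures, or
plate-position effects beyond a global multiplicative factor. The
generator is a model of the *statistical* structure the analysis assumes,
not of microscopy.

### Default conditions and problem sizes

Defaults follow the screen design where stated (triplicate plates, 16x24
format, 4 fields/well, compounds at 10 uM, Torin 2 at 0.5 uM) and
field-plausible values elsewhere: baseline cytoplasmic intensity
8000 ± 1200 (16-bit-scale units), nucleus radius 7 ± 0.8 px with a 6 px
cytoplasm annulus, pixel noise SD 200, and 120 cells per well as a
rendering-friendly density (the screen itself seeded 750 cells/well, and
the tabular library-scale checks use that value; image-mode tests use
smaller wells and fields, e.g. 2–4 fields of 96–224 px with 5–30 cells,
so the whole suite stays within minutes). Vehicle-well counts per plate
and plate-effect magnitudes are not reported for the original screen;
the defaults (16 vehicle wells, lognormal sdlog 0.1) are configurable
and documented, not inferred. The proteomics reproduction scenario uses
a within-replicate SD of 0.08 log2 units, inside the 0.05–0.1 precision
range typical of TMT-plex triplicates; the type-I-error simulations use
a looser 0.2 to avoid tying the size of the test to that choice.

## Worked example

```{r example}
cfg <- screen_config(
  compounds = rbind(
    planted_compound("downA", effect = 0.4),
    planted_compound("upB", effect = 1.8),
    planted_compound("nullC")),
  seed = 7)
run <- run_screen(cfg)
run
subset(run$hits, class != "null",
       c(compound_id, class, mean_opp_norm, mean_viability_norm, cv_opp))
```

```{r proteomics}
g <- generate_proteomics(500, 43, effect_log2fc = 1, within_group_sd = 0.08,
                         seed = 5)
d <- differential_proteins(g$quant)
sum(d$regulated)
r <- rank_proteins(d)
up_set <- list(planted_up = g$truth$protein_id[g$truth$direction == "up"])
gsea_preranked(r, up_set, n_perm = 500, seed = 9)
```

## Known limitations

* No nucleus declumping: touching nuclei merge (the generator avoids them;
  real confluent wells would need a watershed split).
* The background threshold is global per field; strong illumination
  gradients would bias cytoplasm boundaries.
* CHX-level signal (0.05x) sits at the background floor, so cytoplasm
  segmentation in floor-control wells is intentionally unreliable — the
  well-level readout still separates them cleanly from vehicle.
* The family-wise behavior of the 3-SD/concordance rule is characterized
  by simulation, not analytically; no additional FDR control is applied to
  hit calling, matching the screen's design.
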