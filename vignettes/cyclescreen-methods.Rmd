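---
title: "Methods: cell-cycle RNAi screen analysis in cyclescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle RNAi screen analysis in cyclescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclescreen)
library(dplyr)
```

# The analysis problem

A genome-scale RNAi screen phenotyped by per-cell DNA content asks, for
every gene, whether its knockdown changes the distribution of cells across
the cell cycle. Cells are transfected in 96-well plates (80 sample wells
carrying one siRNA pool each, plus control wells: non-targeting siRNA, GFP
siRNA, transfection-reagent-only mocks, and a CDK1 positive control),
stained for total DNA, and scanned so that every cell contributes one
DNA-content intensity. Each well is then summarized by six parameters:
total cell number and the percentages of cells in sub-G1, G1, S, G2/M and
over-G2. Plates are processed in batches and transfected in triplicate, so
the raw parameters carry plate-, position- and batch-level artifacts that
must be removed before genes can be compared.

`cyclescreen` implements that analysis end to end — gating, two-stage
normalization, control-based z-scoring, the pooled-siRNA library filter,
hit calling, cross-cell-line comparison, profile clustering and set
over-representation — plus a DNA-fiber fork-speed module, and pairs every
stage with a seeded synthetic generator so the whole chain can be validated
against known ground truth without any external data.

# Gating DNA-content histograms

The instrument-era workflow gated each batch's DNA-content histogram by
hand. `estimate_gates()` replaces that with a deterministic procedure, so
that reruns are reproducible:

1. pool the DNA intensities of the batch's negative-control wells
   (non-targeting and GFP siRNA — the unperturbed profile);
2. histogram them (256 bins over `[0, p99.5]`);
3. the G1 peak is the global mode; the G2/M peak is the highest local mode
   within 1.8–2.2 times the G1 position (a physical constraint: G2 cells
   carry twice the G1 DNA content, give or take staining nonlinearity);
4. fit each peak by local Gaussian moments (mean and sd of events within
   ±20% of the peak);
5. place the four boundaries at `mu ± n_sigma · sigma` of the two peaks:
   sub-G1 below `b0 = mu_G1 − n_sigma·sigma_G1`, G1 up to
   `b1 = mu_G1 + n_sigma·sigma_G1`, S between `b1` and
   `b2 = mu_G2 − n_sigma·sigma_G2`, G2/M up to
   `b3 = mu_G2 + n_sigma·sigma_G2`, over-G2 above.

`n_sigma` defaults to 2.5 (dimensionless, in peak standard deviations): wide
enough to capture ≈99% of each Gaussian peak, narrow enough to leave an S
window between typical peaks (at a coefficient of variation of 0.05 the G1
band spans ±12.5% of the peak position). It is configurable because no
recorded boundary convention exists to match. Intervals are half-open on
the right, so an event exactly on a boundary belongs to the higher phase —
an arbitrary but deterministic tie-break. Events with negative intensity
are rejected and counted. If the G1 and G2 bands touch, both boundaries
collapse to their midpoint (a zero-width S gate) rather than crossing.

Gates are estimated per batch from negative controls only and applied to
every well of the batch, mirroring the batch-level structure of the manual
workflow.

## What ±n·sigma gating can and cannot do

Threshold gating on a one-dimensional histogram misassigns the S-phase
cells whose intensity falls inside the G1 or G2/M bands. Under the
generator's S model (uniform between the peaks), the fraction of true-S
events inside the G1 band is ≈ `n_sigma·cv/(g2_ratio−1)` and inside the
G2/M band ≈ `n_sigma·cv·g2_ratio/(g2_ratio−1)` — at `cv = 0.05`,
`n_sigma = 2.5`, `g2_ratio = 2` that is ≈12.5% + 25% of S events, an
overlap that no threshold placement can remove (the distributions
genuinely overlap; even a Bayes-optimal boundary misassigns a similar
share). The gated S fraction is therefore a systematic undercount, and
per-event accuracy is bounded accordingly whenever S occupancy is
substantial. This is a property of all histogram gating, including the
manual original; the validation suite quantifies it on synthetic truth
(`gating_accuracy_study()`), and downstream z-scores are unaffected as a
comparison between wells because every well of a batch is gated
identically. The bivariate EdU module and full mixture deconvolution
(Dean–Jett–Fox-style) are the standard remedies; the latter is out of
scope here.

# Two-stage normalization

Both artifacts the screen design introduces are treated as multiplicative,
and both stages divide by medians:

1. **Plate:** every parameter is divided by its median over the physical
   plate (`plate_id` × replicate). Positive-control wells are excluded from
   the median — their strong phenotype would drag it — but are themselves
   transformed.
2. **Well position:** each value is then divided by the median of its well
   position (e.g. `B07`) across all plates, again excluding positive
   controls from the medians. A position occupied only by positive controls
   falls back to the grand median of all non-positive-control values.

"Normalized using the median" is read as *division* (fold-of-median), not
subtraction: the parameters are counts and percentages, and plate-to-plate
variation in cell number, transfection efficiency and staining acts
proportionally. A subtraction mode would be the matched choice for
additive artifacts; the generator offers an additive noise mode
(`effect_model = "additive"`) precisely so that this misspecification can
be studied, but the analysis itself follows the division reading.

Two exact invariances follow, and are asserted in the tests at 1e-9: a
multiplicative factor applied to one physical plate's raw values cancels in
the plate stage, and a factor applied to one well position (on the
plate-normalized scale that the position stage consumes) cancels in the
position stage. The second invariance is stated at its own stage because a
single-position change can, in principle, reshuffle which well defines a
plate's median and thereby move every value on the plate by one
order-statistic spacing — division by medians is exactly invariant to the
perturbation each stage is built to remove, not to arbitrary upstream
edits.

# Z-scores against pooled negative controls

For gene *g* and parameter *p*:

$$Z_{g,p} = \frac{x_{g,p} - \mu_p}{\sigma_p}$$

where `x` is the **median of the gene's replicate wells** (typically a
triplicate) after both normalization stages, and `mu` and `sigma` are the
**median** and **standard deviation of all pooled negative-control wells**
(non-targeting and GFP siRNA together; mock wells are excluded — they
control for the transfection reagent, not for the siRNA null). Choices the
source description leaves open, fixed here:

* `sigma` is the sample standard deviation (denominator n−1) of individual
  control wells, pooled across plates and replicates — not of triplicate
  medians. Pooling individual wells is the more conservative (larger)
  spread and needs no assumption about the replicate structure of the
  controls.
* By construction a gene sitting exactly at the control median scores 0.
* A degenerate `sigma` (zero spread) flags the parameter; z-scores become
  `NA` with a report rather than infinities.
* Values flagged missing upstream stay missing; genes with fewer than two
  informative replicate wells are reported but still scored from what
  remains.

# The pooled-siRNA library filter

Each well's pool contains four siRNAs. An siRNA *maps* to a transcript when
its reverse complement occurs as an exact, mismatch-free substring of the
transcript (the siRNA antisense strand is what base-pairs with the mRNA);
its gene set is the union of gene tags over matched transcripts. A well is
retained (`pass`) only when every siRNA maps somewhere and the intersection
of the four gene sets is exactly one gene. Failures are classified:
`fail_unmapped` (some siRNA matches nothing), `fail_discordant` (all match,
no common gene), `fail_multi` (the common set holds several genes). The
intersection rule lets an individually ambiguous siRNA pass if the pool
still pins a unique target; a `strict` flag demands individual uniqueness
instead, since the original rule is not recorded. Exact substring search
(Aho–Corasick via `Biostrings::PDict`) is sufficient for 21-nt probes with
a no-mismatch policy; seed-region and gapped-alignment modes are
deliberately out of scope.

# Hits, line comparison, clustering, over-representation

* **Hit calling:** a gene/parameter pair is a hit when `|z| ≥ 5`; the
  boundary is inclusive (the two stated conventions, "±5 cutoff" and
  "\>5", differ exactly on the boundary; inclusive is chosen and
  configurable). Sub-G1 is excluded as non-informative: it mixes debris,
  apoptosis and staining artifacts. A gene is a hit if any retained
  parameter fires.
* **Cross-line comparison:** after intersecting gene universes, each gene
  (and each gene/parameter pair) is `shared`, `line1_only`, `line2_only`
  or `neither` by its hit status in the two lines; the per-parameter table
  doubles as the scatter export for S-phase comparisons across a normal
  and a tumor line.
* **Clustering:** hit genes' z vectors over the concatenated
  parameter × line columns, Euclidean distance, average-linkage
  agglomeration (`stats::hclust`). Rows are sorted by gene id beforehand,
  so leaf order is deterministic with ties broken by id. Average-linkage
  Euclidean replaces the original hybrid partitioning package, which was a
  visualization aid rather than a defined method; the dendrogram exports as
  newick for downstream tools.
* **Over-representation:** one-sided hypergeometric tail
  `P(X ≥ k)` per set with Benjamini–Hochberg adjustment across sets. The
  default universe is the filter-passing gene list — the population the
  screen actually analyzed — not the genome. Specific GO-database p-values
  from the original analysis depend on a dated annotation snapshot and are
  not reproduction targets.

# DNA fiber module

Tracks are dual-labelled (CldU then IdU, 20 min each); measured lengths
convert to kb at 2.59 kb per measured unit and to speed by
`speed = kb / pulse_min`, the per-track speed averaging the available
labels and the IdU/CldU ratio reporting label asymmetry. The published
conversion constant is stated per "mm" although the literature it
originates from calibrates micrometers of immunofluorescent track; the
number, not the unit name, is what the analysis uses, so the factor is a
parameter (`factor = 2.59`) and the unit is whatever the measuring tool
produced. Conditions are compared with a two-sided Mann–Whitney test on
per-track speeds (no distributional assumption; fork-speed distributions
are right-skewed), reporting U, p, medians and the Hodges–Lehmann shift.
Fully tied input has zero rank variance and reports p = 1 with a warning.

# The synthetic generators

The generators define the conditions under which every downstream claim is
tested; their defaults are fixed once and describe a realistic screen.

* **DNA-content model** (`cell_cycle_model()`): G1 and G2/M are Gaussian
  peaks (common CV 0.05, G2/G1 position ratio 2), S is uniform between the
  peaks convolved with the G1 noise (the standard flat S-plateau
  approximation — real S distributions are only approximately flat),
  sub-G1 a truncated Gaussian below G1, over-G2 a Gaussian at twice the
  G2 position. Default occupancy (sub-G1 3%, G1 52%, S 23%, G2/M 17%,
  over-G2 5%) is a typical propidium-iodide profile of a cycling
  near-diploid line.
* **Screen design** (`screen_design()`): 96-well plates, 80 sample wells,
  columns 1 and 12 carrying 4 negative-control, 4 GFP, 4 mock and 4
  positive-control wells, triplicate transfections, batches as contiguous
  plate blocks (16 by default). 4000 cells seeded per well with a single
  scalar growth factor (default 2) — growth kinetics over the ~70 h
  incubation are deliberately not modelled.
* **Artifacts:** per-physical-plate and per-well-position lognormal factors
  on expected cell count (defaults sigma = 0.10 and 0.05; no published
  magnitudes exist, these are typical of plate-based screens), Poisson
  sampling of the cell count, exact multinomial sampling of phases. The
  positive-control wells carry a built-in arrest-and-kill phenotype
  (cell count ×0.2, G2/M occupancy ×3), emulating the CDK1 control.
* **Spikes** (`spike_spec()`): known multiplicative shifts on phase
  occupancy (renormalized) or cell count, per cell line, with a penetrance.
  `spike_multiplier()` converts a target generative z-score into the
  occupancy multiplier under counting noise, so studies can plant effects
  of defined size.
* **Two levels:** `level = "events"` emits per-cell intensities (used
  wherever gating itself is under test); `level = "counts"` emits the
  exact true-phase counts per well — the quantity gating estimates — and
  is used for normalization and hit-recovery studies, where simulating
  millions of per-cell intensities would only add the gating error already
  characterized separately.
* **Library** (`simulate_library()`): one random transcript per gene plus
  decoys; siRNAs are exact antisense 21-mers of their target. Corruption is
  per *well* (probability 0.27 by default, matching the screen's retention
  structure of 73% of wells passing the filter): a corrupted well has 1–4
  siRNAs redirected to another transcript or replaced by a sequence
  verified absent from the transcriptome, so filter outcomes have exact
  truth labels.
* **Fibers** (`simulate_fibers()`): both labels at
  `speed·pulse/2.59` length units with independent lognormal noise of a
  given CV (default 0.3, typical of fiber-length measurements).

What the generators do **not** emulate: instrument optics and object
segmentation, doublets and clumps, apoptosis kinetics, spatial gradients
more structured than a per-position factor, S-phase fine structure,
sequence biology beyond exact matching (no seed-region off-targeting, no
expression levels). Passing tests therefore demonstrate correctness of the
analysis logic under a faithful statistical caricature of the screen — not
robustness to every failure mode of real plates.

# Validation studies and their sizes

The studies in `R/validation.R` are run both by the test suite and by
`scripts/acceptance.R`; sizes were chosen to give stable estimates at
desk scale:

* gating accuracy: one batch of 10^6 events;
* hit recovery: 2000 null + 40 spiked genes (generative z = 8 on S-phase;
  half the spikes shared between two lines, a quarter each line-specific),
  26 plates × 3 replicates × 16 batches per line, 2000 cells per well,
  200 simulation replicates;
* filter retention: 5000 wells at 27% corruption (3 binomial standard
  errors ≈ ±1.9 percentage points);
* fiber power: 500 runs of 100 tracks per arm at a two-fold slowdown,
  CV 0.3;
* hypergeometric correctness: exhaustive enumeration of all draws for
  universes up to N = 12.

# Known limitations

* Threshold gating undercounts S-phase by construction (see above);
  per-event accuracy targets that ignore the S-plateau overlap are not
  attainable by any boundary placement under this generative model.
* The position-median stage assumes every well position is observed on
  several plates (≥3 enforced); tiny screens should skip it.
* The enrichment module treats gene sets as flat lists — no ontology
  hierarchy, no term redundancy handling.
* `sigma` from pooled control wells absorbs residual normalization noise;
  with very few plates the z-scale is accordingly conservative.
* The generators' artifact magnitudes are plausible, not calibrated to any
  deposited dataset.
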