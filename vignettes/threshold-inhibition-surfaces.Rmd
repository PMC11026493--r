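---
title: "Methods: single-cell dose responses, threshold inhibition surfaces, and the titration pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell dose responses and threshold inhibition surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdose)
```

## The per-cell model

Every quantity in scdose is built on the four-parameter sigmoid

$$R(d) = E_{max} + \frac{E_0 - E_{max}}{1 + (d/EC_{50})^{HS}}$$

applied *per cell*: each cell carries its own `E0` (basal response), `Emax`
(plateau at infinite dose), `EC50` (half-maximal concentration, molar) and
`HS` (Hill slope). The model assumes a monotone, memoryless steady-state
response at each dose; kinetics (how fast a cell reaches that steady state)
are deliberately kept out of the model and live only in the synthetic-data
generator. We impose no ordering between `E0` and `Emax`, since resistant
cells can plateau above other cells' basal levels.

Two numerical conventions matter:

* **Concentrations are molar everywhere.** The default simulation grid is
  `dose_grid()`: 50 log-spaced points from 1e-11 to 1e-5 M (the point count
  is a smoothness choice; nothing downstream is sensitive to it).
* **`d = 0` is handled exactly** and returns `E0`, avoiding the `0^HS`
  ambiguity for fractional slopes. The untreated condition always enters
  fits as dose 0.

## Population mixtures

`population_preset()` compiles in five mixtures of per-parameter sampling
distributions (normal on a stated scale; `EC50` on log10, `HS` on log2 — so
back-transformed draws are always positive; `E0`/`Emax` on the linear scale
*without truncation*, so rare negative `Emax` draws are kept). The four
canonical 1000-cell presets share `E0 ~ N(1, 0.1)` and `Emax ~ N(0.16, 0.1)`
and differ in the EC50/HS structure: `low_variance` (sd 0.1 on both log
scales, log10 EC50 mean −7.72, log2 HS mean −1.02), `high_variance` (sd 0.5),
`bimodal` (500/500 cells at log10 EC50 −6.72/−8.72 with log2 HS
−1.42/−0.62), and `resistant` (950 bulk cells plus 50 cells with `Emax` mean
0.46 and log10 EC50 mean −4.72). A fifth preset, `steep_unimodal`, models
switch-like responders: log2 HS ~ N(1.66, 0.5) (mean HS 3.16) with a broad
EC50 spread (sd 0.5); the spreads are our choice, matching the
high-variance preset, since only the mean slope is pinned down externally.

Sampling is deterministic given a seed: subpopulations are visited in listed
order and parameters drawn in the fixed order `e0`, `emax`, `ec50`, `hs`.
Parameters are sampled independently — correlated sampling is out of scope.

`population_average()` is the bulk-assay surrogate: the arithmetic mean of
all per-cell curves at each dose, on the reasoning that a lysate-based
readout sums protein across cells. The package's acceptance suite checks the
motivating phenomenon at this scale: the four canonical presets produce
population averages that agree pairwise within a few percent of the dynamic
range over the default grid (the bimodal mixture's shallow-slope mode makes
it the most separable pair, slightly above 10% at its widest), while their
60%-threshold inhibition curves separate cleanly.

## Threshold inhibition curves and surfaces

A cell is inhibited at dose $d$ and threshold $t \in (0,1)$ when
$R(d) < t\,E_0$ — strictly below a fraction of its *own* basal signal. The
inversion has a closed form (see `?inhibition_dose`), returned as `0`
("already below at any positive dose") or `Inf` ("never reached"; a
resistant cell) in the degenerate regimes. `inhibition_curve()` is then the
per-dose mean of this indicator over cells, and `inhibition_surface()`
stacks curves over thresholds 0.20–0.90 in steps of 0.01 (defaults).

Design choices worth knowing:

* Curves are computed from Hill *parameters* (sampled or fitted), not from
  raw noisy per-dose measurements — the same convention for simulated and
  experimental populations. A raw-measurement mode is a non-goal.
* The threshold-as-fraction-of-basal is undefined for cells with fitted
  `E0 <= 0` (possible on the log2(CNR) scale). Such cells are excluded with
  a warning and removed from the denominator; an all-excluded population is
  an error. This is an interpretation we fixed, not an externally given
  rule.
* `dose_escalation_factor()` reads the dose at which a curve first reaches a
  proportion `p` using *log-linear* interpolation between grid doses
  (rationale: grids are log-spaced), and errors with the plateau value
  attached when `p` is never reached.
* No threshold is privileged; 60% is used throughout as an illustrative
  default.

## Constrained per-cell fitting

`fit_hill()` re-implements bounded nonlinear least squares for the sigmoid
via Levenberg–Marquardt (`minpack.lm::nls.lm`). Defaults mirror the
constraints appropriate for log2(CNR) data: `E0`, `Emax` in [−3, 3], `EC50`
in (0, 40 µM], `HS` in (0, 100] (open lower ends realized as 1e-12 M and
1e-3).

Choices that were genuinely open and how we fixed them:

* **Initialization** (nothing external pins it down): `E0` from the response
  at the lowest dose, `Emax` at the highest, `EC50` from the dose whose
  response is closest to the midpoint, `HS = 1`. Multi-start with
  `n_starts = 5` by default: the extra starts redraw log10(EC50) uniformly
  over the bound range with a fixed seed, making the fit deterministic and
  robust on noisy 11-point curves.
* **EC50 is optimized on the log10 scale** (bounds transformed accordingly)
  for conditioning, and reported linear.
* **Tolerances**: `ftol = ptol = 1e-10`, at most 1000 iterations; a
  parameter is reported `at_bound` within 1e-6 relative distance of a bound.
* **Degenerate data**: exactly flat responses make EC50/HS unidentifiable;
  the fit returns `E0 = Emax = value`, `converged = FALSE`,
  `degenerate = TRUE`. Downstream, `surface_from_fits()` excludes degenerate
  cells by default but keeps them behind `include_degenerate = TRUE`, since
  either convention is defensible.

`fit_cells()` applies this per cell (and channel), excluding cells that lack
any dose level, and `resistant_fraction()` / `param_correlations()` give the
two summary statistics: the count of cells with `EC50` above a cutoff
(default 100 nM) and the Spearman correlations between single-point
parameters (`E0`, `Emax`) and titration-requiring parameters (log2 HS,
log10 EC50), with two-sided p-values from `stats::cor.test`.

## The titration pipeline

`default_titration_schedule()` encodes the reference design: 20 min of
pre-drug imaging, then ten doses at 60-min intervals, each ~4× the last
(0.15 nM → 40 µM), for 11 dose levels including untreated. Extraction
conventions:

* **Complete tracks only**: a trajectory must span the experiment from
  `pre_drug_start` to 60 min after the last dose (each endpoint to within
  one acquisition interval) with no gap longer than 2 intervals. The default
  cadence is 3 min, inferred from the data when not given.
* **Baseline** = mean over the 10 min immediately before the first dose,
  `[t1 − 10, t1)`. (The averaging window convention is ours; the 10-min
  pre-dose span is the anchor.)
* **Per-dose response** = mean over `[start + 50, start + 60)` after each
  dose — the closing window of the hold, closed-open on the right so the
  instant the next dose is added is excluded.

The window convention assumes cells re-equilibrate within a hold. For fast
kinetics (tau ≈ 10 min) the residual drift inside the window is below 1%
of the step size; for slow kinetics (tau ≈ 60 min) window means lag the true
steady states substantially — the test suite demonstrates both regimes, and
slow-relaxing lines should be measured with longer holds rather than
"corrected" here. `compare_distributions()` supports the matched
single-point-vs-titration sanity check with Gaussian KDEs (Silverman
bandwidth) and the mean shift; a KS test is available behind `test = TRUE`
but the comparison is intentionally descriptive by default.

## The imaging pipeline

`process_stack()` chains four primitives per frame, then tracks:

1. `segment_nuclei()`: local-mean adaptive threshold (`EBImage::thresh`,
   window 51 px, offset 0.01) → connected components (`EBImage::bwlabel`) →
   objects under 40 px² removed. These defaults were chosen for
   10×-magnification-scale nuclei on the synthetic fixtures and are all
   configurable; nothing external fixes them.
2. `expand_labels_nearest()`: every background pixel within 5 px (Euclidean)
   of a nucleus receives the label of its *nearest* nucleus — an
   object-preserving dilation, so touching cells never merge and the
   inter-nucleus midline splits by distance. Equal-distance ties go to the
   smaller label (deterministic); the implementation scans offset shells in
   increasing distance order and is tested against a brute-force per-pixel
   search.
3. `measure_cnr()`: mean reporter intensity over nuclear pixels and over the
   ring (expansion minus nucleus; disjoint by construction), reported as
   log2(cytoplasm/nucleus) — scale-invariant by design.
4. `link_tracks()`: frame-to-frame links by maximal pixel overlap, accepted
   greedily in descending overlap with ties to the smaller label, and
   injective per frame pair (no merging). No gap-closing across missed
   detections is attempted.

Autofocus, illumination correction, background subtraction, mitosis handling
and drift registration are acquisition-side concerns and are not modeled.

## The synthetic-data generator

`synth_trajectories()` emulates what the pipeline needs to be tested
against, with exact ground truth: per-cell Hill parameters sampled from a
population spec; per-dose steady-state targets computed by *the same*
`hill_response()` code path; first-order relaxation
$s(t) = \text{target} + (s(t_0) - \text{target})\,e^{-(t - t_0)/\tau}$
between dose steps; samples every 3 min with additive Gaussian noise on
log2(CNR) (default sd 0.05, the simplest model consistent with a
ratio-based readout). The kinetics presets — `fast` (tau = 10 min,
MCF-7-like) and `slow` (tau = 60 min, Vari-068-like) — are declared
assumptions calibrated to qualitative behavior ("steady within an hour"
vs "hours to equilibrate"), not measured constants. Optional dropout
truncates a fraction of tracks at uniform random times.

`synth_image_stack()` renders trajectories as disks-plus-annuli with
intensities constructed so that region means reproduce each cell's
log2(CNR) exactly (cells on a jittered grid, small random walk, optional
Gaussian pixel noise; overlapping placements are refused rather than
rendered). What it does **not** emulate — irregular nuclear shapes, focus
drift, intensity gradients, cell division and death, signaling rebound —
bounds what passing tests show about real data: they validate the
*computational* pipeline (segmentation geometry, ring construction,
tracking, extraction, fitting), not robustness to every imaging artifact.

All generators are bit-reproducible under a fixed seed, and seeded calls
restore the caller's RNG state.

## Problem sizes and determinism in the test suite

The suite exercises the study-scale configurations directly: 1000-cell
populations on the 50-point grid for the population-level claims; 200 cells
through trajectory extraction and fitting for parameter recovery (generating
mean log10 EC50 recovered within 0.1, median per-cell error under 0.15);
and a 30-cell, 63-frame, two-channel rendered stack through the full
segmentation → tracking → extraction → fitting chain (median log10 EC50
error under 0.2). Oracle tests pin the closed forms to independent
computations: threshold inversion vs bisection (1000 random cells, relative
tolerance 1e-9), label expansion vs brute-force nearest-seed search, and
threshold curves vs explicit per-cell indicator means.

## Known limitations

* The model is a steady-state sigmoid; drugs with non-monotone or
  time-dependent pharmacodynamics are out of scope.
* Threshold statistics require a positive fitted basal response; cells
  failing that are dropped, which can bias surfaces for populations with
  near-zero basal signaling.
* Per-cell fits carry no confidence intervals; degenerate (flat) cells are
  flagged rather than resolved.
* The imaging pipeline assumes reasonably separated, roughly convex nuclei;
  it does not segment confluent fields or handle division events.
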