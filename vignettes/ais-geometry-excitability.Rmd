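---
title: "AIS geometry, synthetic cohorts, and the reduced CA1 model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AIS geometry, synthetic cohorts, and the reduced CA1 model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisgeom)
```

`aisgeom` studies how the geometry of a pyramidal neuron's proximal
compartments — soma, proximal apical dendrite, axon-carrying dendrite (AcD)
stem, and axon initial segment (AIS) — shapes its excitability. This
vignette is the package's own account of the methods: the domain model, the
synthetic-cohort generator, the statistics, the reduced compartmental CA1
model and its calibration, and the numerical choices, together with their
limitations.

## The morphology schema and classification

One row describes one neuron, in micrometres: the two longest orthogonal
soma diameters; five apical-dendrite diameters at 5, 10, 15, 20, 25 µm from
the soma base; the AIS distance (path length from the somatodendritic origin
to the AIS start), AIS length, diameters at its start, point of maximum
width, and end, and the position of the maximum; and, for cells whose axon
leaves via a dendrite, the AcD stem length and mean diameter. Anatomical
labels place each cell in a cutting plane (dorsal/medial/ventral) and a
cell-band subregion (hilus, CA3c/b/a, CA2, CA1p/m/d, subiculum).

A cell is classified as an **AcD cell** when its stem is at least 2 µm long
and *strictly* longer than its mean diameter — ties are deliberately not
AcD, the conservative reading of "longer than". Otherwise it has a **distal
axon origin** when the AIS starts more than 5 µm out (the cut applies to the
raw AIS distance for all cells), else a **somatic** origin. The invariant
`acd_stem_length <= ais_distance` encodes the convention that the measured
AIS distance includes the stem; the alternative distance
(`ais_distance_2 = ais_distance - acd_stem_length`) measures from the
somatodendritic compartment including the stem.

Soma size is used in two forms: the ellipse area `pi*(a/2)*(b/2)` for
reporting, and the exact prolate-spheroid surface (polar axis = major
diameter) for the compartmental model.

## The synthetic-cohort generator

The generator exists so every downstream stage is testable without the
measured dataset. It is a **Gaussian copula**: correlated standard normals
with a target Spearman structure (converted entry-wise through
`2*sin(pi*rho/6)`) are pushed through each parameter's inverse CDF. This is
the minimal structure consistent with what a morphometric study reports —
marginal families and pairwise rank correlations — and makes no claim about
higher-order dependence.

Choices that matter:

* **Marginals.** AIS distance, AcD stem length, the stem-to-AIS offset,
  maximum-width position, and the apical level are log-normal,
  parameterized by *median* and log-SD so profile entries read directly as
  medians; bell-shaped parameters (soma axes, AIS length, AIS diameters)
  are normal, truncated at zero by inverse-CDF restriction (monotone, so
  ranks are preserved).
* **AcD construction.** Membership is Bernoulli(regional AcD fraction).
  For AcD cells the AIS distance is built as `stem + offset` with a
  nonnegative log-normal offset, so `stem <= distance` holds by
  construction; non-AcD cells draw the distance from its own marginal and
  have stem length 0. The stem–offset correlation (−0.05) and offset
  dispersion (log-SD 0.7) were fixed once so that the *structural*
  Spearman correlation between log stem length and log AIS distance among
  AcD cells comes out near the reported 0.80.
* **Packaged profiles.** 27 plane × subregion recipes encode the reported
  regional patterns: ~35 µm median AIS length in intermediate (medial)
  CA3a falling to ~25 µm in CA1; AcD fractions of 0.5 in ventral CA1 and
  0.55 in medial CA1 against ~0.15–0.3 dorsally; CA3 stems longer and
  thicker than CA1; dorsal cells smaller with more proximal AIS. Medial
  CA3 distance medians are set so just over 80 % of those cells have
  distal (>5 µm) origins. Per-region dispersions are not printed in the
  source publication; the packaged values are realistic choices fixed once
  (e.g. 6 µm SD for AIS length, log-SD 0.55 for AIS distance, 0.5 for stem
  length) and are part of the study conditions, not free knobs. The shared
  rank-correlation matrix was likewise fixed once, with the soma column
  sized so the soma-size predictability ledger (below) lands near the
  reported ~45 %.
* **Replication.** `generate_multi_hippocampus()` draws per-hippocampus
  multiplicative median jitter (default log-SD 5 % — a documented free
  knob, chosen to produce realistic replicate spread) and
  `generate_study_cohort()` reproduces the sampling design: 20 cells ×
  8 hippocampi per plane for each CA1/CA3/subiculum subregion (~160 each),
  54 hilar and 53 CA2 cells per plane, 3,681 records in total.

What the generator does **not** emulate: measurement error and censoring,
discreteness of traced diameters, within-animal clustering beyond the
median jitter, superficial–deep gradients (layer depth is uniform noise),
and any non-Gaussian tail dependence. Tests passing on synthetic cohorts
therefore validate the *pipeline*, not biological claims about real tissue.

## Statistics

All tests use the sample SD (n−1 denominator) and two-sided p-values with
significance at 0.05. Log-normal parameters (AIS distance, stem length) are
natural-log transformed first; zero stem lengths (non-AcD cells) are
excluded from stem-specific analyses with a recorded count. Variability is
the SD of globally Z-scored values within each (hippocampus, region) group,
flagged `NA` below 3 records.

Partial Spearman correlations rank-transform the two variables (and numeric
covariates), indicator-code categorical covariates, and apply the standard
partial-correlation formula on the rank scale; the p-value uses the t
approximation with `n − k − 2` degrees of freedom. The **predictability
ledger** sums, for each parameter, the squared partial correlations against
every other parameter with location (plane, subregion) partialled out of
each pair; pairs that lose a Bonferroni correction across the tested family
contribute zero. Both r² and a regression R² can be derived from the pair
table attached to the result; the package reports r² sums and does not
conflate the two. Group comparisons are two-way fixed-effects ANOVAs
(type-II sums of squares via `car::Anova`, so factor order is immaterial in
balanced designs) with Tukey HSD contrasts on significant factors, at cell
level by default or on per-hippocampus medians.

## The reduced compartmental model

`build_cell()` maps one record to a section graph:

* **Soma**: a cylinder of length `soma_major` whose lateral surface equals
  the measured spheroid surface (the model uses only that surface value;
  the aspect choice is immaterial at the soma's electrotonic size).
* **Apical trunk** in three parts (150/300/300 µm at 3.5/2.65 µm beyond
  the measurements) ending in two 250 µm tuft branches; the first 25 µm
  carry the five measured diameters as a piecewise-linear profile, then
  taper linearly to the template trunk diameter.
* **Two basal dendrites** of 250 µm at 2.0 µm, each split so that the
  75–100 µm path window from the soma is its own finely segmented section
  (the synaptic zone).
* **Axonal path**: for AcD cells the stem (measured length and diameter)
  leaves the soma base and carries both the AcD basal branch and the axon;
  a hillock tapers to the AIS start diameter over the remaining distance;
  the AIS runs `ais_length` µm with the measured
  start → maximum → end diameter taper and is split in half (template
  fraction, default ½) into proximal and distal sections; a 300 µm axon
  follows. `balance_branches()` inserts a passive stub with the stem's
  geometry ahead of the *other* basal dendrite and shortens that branch by
  the same length, making the two synaptic zones' passive paths to the
  soma electrotonically equivalent (verified to <1 % input-resistance
  difference); for non-AcD cells it is the identity.

Discretization follows two rules: sections containing stimulation sites
(both AIS parts and the synaptic zones) use ≤0.5 µm segments to retain the
input's high-frequency content; all other sections use the d-lambda rule
(segment length ≤0.1 of the AC length constant at 100 Hz). Segment counts
are odd, so every section has a midpoint segment.

### Biophysics and calibration

Channel kinetics are Traub-style Na (m³h) and delayed-rectifier K (n⁴)
rate functions with an adjustable voltage origin `vT`, plus ohmic leak.
The distal AIS carries a −5 mV shift of Na activation (activation-only by
default; a configuration flag extends it to inactivation), implemented as a
voltage offset inside the activation rates. All parameters live in
`inst/extdata/biophys_ca1.yaml`; classes not listed inherit the defaults
block, and each inherited value is logged in the loaded object's
provenance attribute.

The parameter set was calibrated *as a model design step* against canonical
CA1 physiology: resting potential −70 mV, somatic input resistance near
100 MΩ, a 5-ms somatic current-step rheobase of a few hundred pA with
somatic voltage thresholds in the mid −50s mV, distal-AIS spike initiation
(lowest injection threshold at the distal AIS), and a monotone decrease of
the voltage threshold with AIS length across the cohort's 1st–99th
percentile range. Two couplings matter: the AIS Na densities
(0.34/0.51 S cm⁻², proximal/distal) set the absolute threshold level, while
the fixed-size hillock and axon Na reservoirs (0.18/0.16 S cm⁻²) set how
steeply the voltage threshold depends on AIS length — too little makes
short-AIS cells implausibly hard to excite, too much inverts the
relationship at the short end. With the packaged values, a 108-cell
synthetic CA1 sample spans roughly 200–300 pA and −58 to −50 mV; those are
exactly the checks in `tests/testthat/test-acceptance.R` and the quantities
`scripts/acceptance.R` recomputes.

### Numerics

The cable equation is solved implicitly at a fixed 25 µs step (40 kHz):
gating variables advance first by the exponential integrator at the current
voltage, then the linear tree system for the next voltage is assembled with
the updated conductances and solved by one Hines pass (leaf-to-root
elimination, root-to-leaf back-substitution; compartments are stored with
parent index < child index). Backward Euler is unconditionally stable at
the mandated step; a convergence helper (`dt_convergence_check()`) shows
the expected ~2× deviation shrinkage per step halving and <0.1 ms spike-time
shift between 25 and 12.5 µs. The tree solve is tested against a dense
`solve()` reference to 1e−9 mV on random ≤20-compartment trees, against the
analytic finite-cable input resistance to 0.5 %, and for passive charge
conservation to 0.5 %.

Synapses use the double-exponential conductance kernel
(τ_on 0.175 ms, τ_off 5 ms, reversal 0 mV) normalized to unit peak, so the
"total synaptic conductance" of a stimulus is the summed per-synapse peak
(1–100 nS over 1000 synapses). The two kernel states decay exactly per step
and synapse onsets snap to the 25 µs grid. The 1000 synapses are evenly
spaced over the 75–100 µm window (a single synapse sits at the window
midpoint); Gaussian activation times (σ 4 ms, mean 20 ms) are drawn once
per cell and seed and reused across a threshold search, so the search
varies only stimulus strength.

### Threshold definitions and conventions

An AP is a strict crossing of 0 mV at the distal-AIS midpoint, the
initiation site. The voltage threshold is the somatic potential at the
first sample whose centered-difference dV/dt exceeds 25 mV/ms after
stimulus onset (one-sided differences at the trace boundaries); the AP
delay is that crossing time minus the 20 ms onset. For *direct somatic
current injection* the injected charge itself drives the local dV/dt above
25 mV/ms for the first two or three 25 µs samples at a few hundred pA, so
the criterion would otherwise report the resting potential; a 0.2 ms
post-onset blanking window makes it measure the AP upstroke, the quantity
of interest. Synaptic stimulation needs no blanking.

Threshold searches run on the resolution grid (0.5 pA / 0.05 nS by
default): geometric bracketing followed by index bisection returns exactly
the smallest grid amplitude that fires, i.e. the same answer as a linear
scan at that resolution at a fraction of the cost. Cells firing at the
range minimum are flagged `below-range`; cells silent at the range maximum
are flagged `non-converged` with an `NA` threshold.

### Degenerate inputs and tie-breaks

Zero stem length routes the AcD code path to the plain basal case; a
hillock shorter than 0.05 µm is omitted and the AIS attaches directly; the
maximum-width position is clamped to the AIS length and the start/end
diameters to the maximum; a swept `acd_stem_length` drags `ais_distance`
along to keep the path invariant satisfied; soma axes are swapped rather
than rejected when a sweep would invert their order.

## Problem sizes

The test suite and acceptance script use sizes chosen for a single CPU:
108-cell CA1 samples (12 cells × 9 CA1 region profiles) for the
threshold-range checks, the full 3,681-record synthetic study cohort for
the dataset statistics, 2,000–50,000-row draws for copula recovery,
9-point grids for median-reference sweeps, and ~40 ms simulated time per
threshold evaluation (50 ms for synaptic drive). The full suite runs in
about two minutes; the acceptance script in about one.

## Known limitations

* The model is deliberately reduced: two basal dendrites, no oblique
  apical branches, uniform channel kinetics, no HCN/Ca/KCa conductances,
  no temperature protocol beyond a global rate scale. It isolates the
  effect of proximal geometry at fixed channel composition; it does not
  reproduce full CA1 electrophysiology.
* The packaged biophysics is this package's own calibrated parameter set,
  configured entirely through YAML; swapping in another parameter table
  changes absolute thresholds but not the package's machinery.
* The copula generator reproduces reported first- and second-order
  structure only; conclusions about real tissue require the measured
  dataset through `read_morphology_csv()` with a column map.
* Voltage thresholds are quantized by the 25 µs sampling and the search
  resolution; differences below ~0.3 mV between nearby conditions are not
  meaningful.
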