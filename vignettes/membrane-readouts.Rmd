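---
title: "Quantifying membrane dipole potential, fluidity, hydration and peptide uptake with memfluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane dipole potential, fluidity, hydration and peptide uptake with memfluor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfluor)
```

## What this package computes

`memfluor` implements the analysis side of four fluorescence assays of
plasma-membrane biophysics, plus the time-correlated analysis of
cell-penetrating peptide uptake:

1. **Dipole potential by flow cytometry.** Dual-band ESIPT probes
   (3-hydroxyflavone derivatives) emit from a normal (N\*) and a tautomer
   (T\*) excited state. The per-cell ratio of the two band intensities,
   N\*/T\*, *negatively* correlates with the magnitude of the membrane dipole
   potential. `per_cell_emission_ratio()` computes the ratio event-wise
   (never as a ratio of channel means — the assay is defined per cell),
   `summarize_sample()` averages it, and `normalize_to_control()` builds
   vehicle-normalized dose–response tables.
2. **Dipole potential by spectrofluorometry.** For electrochromic styryl
   dyes, the ratio of excitation intensity integrated over the blue edge
   (410–440 nm) to the red edge (490–520 nm) of the excitation spectrum
   *positively* correlates with the dipole potential.
   `integrate_band()`/`excitation_ratio()` implement this with a trapezoidal
   rule.
3. **Membrane fluidity.** Steady-state L-format anisotropy
   $r = (I_{vv} - G I_{vh}) / (I_{vv} + 2 G I_{vh})$ with the instrument
   factor $G = I_{hv}/I_{hh}$ (`anisotropy()`, `g_factor()`).
4. **Membrane hydration.** Generalized polarization
   $GP = (I_{blue} - I_{red}) / (I_{blue} + I_{red})$ of a solvatochromic
   membrane dye, averaged over membrane pixels found by a manually seeded
   watershed (`seeded_watershed_segment()`, `mean_gp()`). Any user-supplied
   region mask (e.g. an organelle mask) can replace the membrane mask.
5. **Uptake and endo-lysosomal escape kinetics.** A peptide carries two
   labels: one pH-insensitive (total uptake) and one quenched in acidic
   compartments. After 10-s binning and first-window normalization, the
   quenchable/pH-insensitive ratio trace reports escape from endo-lysosomes;
   a two-compartment model can be fitted to recover rates.

A synthetic-data module generates every input type with known ground truth,
so each stage of the pipeline is verifiable without experimental data.

## The two-compartment uptake/escape model

Total internalized peptide saturates as
$U(t) = U_{max}\,(1 - e^{-k_u t})$. Escaped (cytosolic) material follows
$\dot C = k_e\,(U - C)$, $C(0) = 0$, with the endo-lysosomal pool
$E = U - C$. The two signals are

$$F_{AF} = E + C + b, \qquad F_{NF} = q\,E + C + b,$$

with quench factor $q \in [0, 1]$ and baseline $b$. The closed-form solution
(`simulate_two_compartment()`) is cross-checked in the tests against a
fourth-order numeric integrator. Defaults are
$U_{max} = 10$, $k_u = 0.02\,\mathrm{s^{-1}}$ (95% of the uptake plateau
between 100 and 300 s), $k_e = 0.002\,\mathrm{s^{-1}}$, $q = 0.05$,
$b = 1$: with strong quenching and slow escape the normalized ratio trace
first dips below 1 (material accumulating in acidic compartments) and then
rises steadily (escape), which is the qualitative signature the assay relies
on. When $q = 1$ the ratio is identically 1 — quenching, not labelling,
drives the signal.

`fit_two_compartment()` fits both normalized traces jointly by multi-start
Levenberg–Marquardt. After first-window normalization only $U_{max}/b$ is
identifiable, so the baseline is fixed at one intensity unit and $U_{max}$
is reported in baseline units. Starts come from a fixed log-spaced grid
jittered with a recorded seed; the lowest residual norm wins. Flat traces
are rejected as unidentifiable rather than fitted.

Two windowing modes are exposed because acquisition practice describes both:
non-overlapping 10-s periods (`mode = "tumbling"`, the default — bins are
independent, which the replicate statistics assume) and a centred moving
average (`mode = "sliding"`). Neither is claimed to be uniquely correct;
endpoint statistics use the tumbling bins.

## Watershed segmentation: relief, ties, and seeding density

The membrane of a rim-labelled cell is a *bright ridge* in both channels, so
the watershed relief is the inverted summed-channel intensity: the ridge
becomes a basin that membrane seeds claim directly. Flooding is Meyer's
marker-based algorithm (compiled in C++): pixels are popped in order of
increasing relief, ties broken by row-major scan order (lowest index wins),
then by insertion order — segmentation is bit-reproducible.

Seeding density matters more than is obvious. A deep basin always pushes its
immediate neighbours into the priority queue before any other front can
reach them, so with a *single* background point per cell the rim label
inevitably annexes a one-to-two-pixel halo around the rim wherever the
surrounding relief is flat. For a 3-px rim that halo is a large fraction of
the labelled area, and because halo pixels carry interior/background GP, an
unweighted membrane mean GP would be biased by far more than the 0.03
recovery tolerance the package tests enforce. The synthetic generator
therefore defaults to `seed_style = "contours"`: the seed set traces each
cell just inside and just outside the membrane, which is what practitioners
actually do when they seed a watershed by hand (drawing a circle inside and
around each cell). `seed_style = "points"` (one interior, one rim, one
background point per cell) remains available; with point seeding the
per-pixel *false-positive rate* over non-membrane pixels stays below 5% on
single-cell images with structured relief, but mask purity does not, and GP
recovery should then use intensity-weighted or refined masks — outside this
package's scope.

Background for `mean_gp()` is estimated per channel as the *median* of the
background-labelled watershed region: robust, reproducible, and insensitive
to the occasional bright speckle. After subtraction a pixel is invalid
(excluded, and counted) when its channel sum is non-positive; this keeps GP
within $[-1, 1]$ wherever it is defined.

## What the generators emulate — and what they do not

All generators are pure functions of a `sim_config()` (seed mandatory; same
configuration, bit-identical output) and encode direction rules through a
single abstract knob, `dp_param` (unitless; 0 = control):

* **Cytometry populations** (`simulate_f66_population()`): lognormal
  per-cell dye load (σ = 0.35), tautomer fraction
  $f_T = \mathrm{plogis}(\log 2 + 0.5\,dp)$ — so $f_T = 2/3$ and a noiseless
  per-cell ratio of exactly 0.5 at control — multiplicative measurement
  noise (CV 5%), scatter clusters separating live cells from debris, and
  viability-marker channels populated from configured live/apoptotic/
  necrotic fractions. Higher `dp_param` means a strictly lower expected
  N\*/T\* ratio.
* **Spectra** (`simulate_excitation_spectrum()`): a single Gaussian peak
  (σ = 40 nm, centre 465 nm at control, blue-shifted 5 nm per unit
  `dp_param`), sampled 380–550 nm at 1 nm with additive noise. Centre 465
  makes the two integration bands mirror-symmetric, so the control ratio is
  exactly 1 and any blue shift raises it.
* **Polarized reads** (`simulate_polarized_reads()`): exact algebraic
  inversion of the anisotropy and G-factor formulas, for round-trip tests.
* **Uptake streams** (`simulate_uptake_events()`): Poisson arrivals at 20
  cells/s (about 24,000 events in a 20-min acquisition, matching the
  ≥ 20,000-cells-per-sample scale of the assay), model curves at arrival
  time × shared per-cell lognormal load × measurement noise, plus a
  DAPI-positive (non-viable) fraction to exercise gating.
* **Membrane images** (`simulate_membrane_image()`): 10–15 disk cells of
  radius 18 px with a 3-px rim at 2,000 expected summed photons per rim
  pixel, gently domed interiors (brightest at the centre, darkest just
  inside the rim, as midplane sections with residual cytosolic dye look),
  dim background, Poisson photon noise, and a per-pixel blue/red split
  encoding the ground-truth GP.

The generators deliberately do **not** model ESIPT photophysics, spectral
overlap beyond a linear spillover, photobleaching, optical point-spread
functions, cell-shape irregularity, or any quantitative mapping from
treatment dose to `dp_param` (only direction and ordering are encoded).
Passing tests therefore demonstrate that the *analysis* is correct and
well-calibrated on data with known truth — not that any particular biological
effect size would be recovered from real samples.

## Numerical and design choices

* **Band integration**: trapezoidal rule with linear interpolation at band
  limits; exact for the piecewise-linear interpolant, and adjacent bands add
  exactly. No smoothing is ever applied implicitly.
* **Emission ratio**: events with non-positive tautomer intensity are
  excluded and counted, never clamped; all summaries report event counts and
  warn below the 20,000-event acquisition target.
* **Gates** are closed regions (boundary events kept) — deterministic and
  consistent with common cytometry practice. Gates are always explicit
  inputs; the package never invents a live gate.
* **Compensation** uses the convention `observed = true · S` with unit
  diagonal, inverted exactly; scatter and time columns are untouched.
* **Statistics**: one-way fixed-effects ANOVA and Tukey's HSD operate on
  replicate means (the experimental unit of the assays), with the
  Tukey–Kramer form for unbalanced designs; the significance threshold is
  0.05 and configurable. Degenerate inputs (all values identical, constant
  response) return flagged F = 0 / p = 1 rather than errors, matching how
  such panels are reported.
* **Anisotropy** values outside the photophysically plausible window
  [−0.2, 0.4] are flagged with a warning but returned; boundary cases
  (r = 1, r = −0.5) are mathematically valid.
* **Problem sizes** used by the test and acceptance suites: 20,000-event
  populations for direction checks (50 seeded repeats), 10,000 null
  simulations for ANOVA calibration, 500 repeats for Tukey power, 200
  repeats of the 2-group × 5-replicate endpoint power simulation at
  event-stream level, and three 320 × 320 images for GP recovery — sizes
  chosen to give the binomial/CLT bounds quoted in the tests while keeping a
  complete run within a few minutes on one core.

## Known limitations

* FCS support is intentionally minimal: list-mode FCS 3.0/3.1 with float
  (or 16/32-bit integer, converted) data; analysis segments, multi-dataset
  files and display transforms (logicle/arcsinh) are out of scope.
* The watershed is 2-D, 4-connected, with no automatic seed placement.
* The kinetic model covers the endocytic route only (uptake → escape); direct
  membrane translocation is not modelled separately, and the ratio readout is
  relative — no absolute peptide quantification.
* Emission ratios are reported as ratios; no calibration to millivolts of
  dipole potential is attempted, because none is defined for these probes.
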