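# memfluor

Quantification of plasma-membrane biophysics from fluorescence data:
**membrane dipole potential** (flow-cytometric dual-band emission ratiometry
and excitation-band ratiometry in spectrofluorometry), **membrane fluidity**
(steady-state anisotropy), **membrane hydration** (generalized polarization
imaging with seeded watershed segmentation), and **cell-penetrating peptide
uptake / endo-lysosomal escape** kinetics — together with seeded
synthetic-data generators that make every stage verifiable against known
ground truth.

## Who it is for

Labs running ratiometric membrane-probe assays (3-hydroxyflavone ESIPT dyes,
electrochromic styryl dyes, solvatochromic GP dyes, TMA-DPH) and
time-correlated flow cytometry of dual-labelled peptides, who need a tested,
scriptable replacement for ad-hoc spreadsheet/FCS-Express analysis.

## The quantities at the core

* Per-cell dual-band emission ratio `N*/T*` (negatively correlated with the
  dipole potential magnitude), averaged per sample and normalized to
  replicate-matched vehicle controls.
* Excitation band ratio `R_exc = ∫410–440 I(λ)dλ / ∫490–520 I(λ)dλ`
  (positively correlated with the dipole potential).
* L-format anisotropy `r = (Ivv − G·Ivh)/(Ivv + 2·G·Ivh)`, `G = Ihv/Ihh`.
* Generalized polarization `GP = (Iblue − Ired)/(Iblue + Ired)` over
  membrane pixels from a manually seeded watershed.
* Two-compartment uptake/escape model: `U(t) = U_max(1 − e^(−k_u t))`,
  `dC/dt = k_e (U − C)`; signals `F_AF = E + C + b`, `F_NF = qE + C + b`
  with acidic-compartment quench factor `q`.
* One-way ANOVA + Tukey's HSD and OLS regression for the group statistics.

Event-level I/O covers per-event CSV (lossless) and FCS 3.0/3.1 (float list
mode), spectral compensation (`observed = true · S`), closed gates and
viability quadrant fractions.

## Worked example

Everything below runs without any experimental data — the generators supply
inputs with known truth:

```r
library(memfluor)

# --- dipole potential, flow cytometry: dose-response vs vehicle -------------
ratio_for <- function(dp, seed) {
  pop  <- simulate_f66_population(sim_config(seed = seed, dp_param = dp))
  live <- apply_gate(pop, attr(pop, "truth")$live_gate)   # FSC/SSC live gate
  mean(per_cell_emission_ratio(live))
}
samples <- do.call(rbind, lapply(1:3, function(rep) data.frame(
  treatment = c("vehicle", "6KC-like"), concentration = c(0, 200),
  replicate = rep,
  mean_ratio = c(ratio_for(0, 100 + rep), ratio_for(1.8, 200 + rep)))))
normalize_to_control(samples, list(treatment = "vehicle"))
#>   treatment concentration normalized_mean       sd n_replicates
#> 1  6KC-like           200           0.407 0.000542            3
#> 2   vehicle             0           1.000 0.000000            3

# --- dipole potential, spectrofluorometry ----------------------------------
excitation_ratio(simulate_excitation_spectrum(sim_config(seed = 1, dp_param = 0)))
#> 1.001
excitation_ratio(simulate_excitation_spectrum(sim_config(seed = 1, dp_param = 1.8)))
#> 1.537

# --- membrane hydration: watershed + GP ------------------------------------
sim <- simulate_membrane_image(sim_config(seed = 2, gp_true = -0.2))
image_mean_gp(sim$pair, sim$seeds)$mean_gp
#> -0.204   (over 4355 membrane pixels; truth -0.2)

# --- uptake / escape kinetics ----------------------------------------------
ev <- simulate_uptake_events(sim_config(seed = 3), duration_s = 950)
ev <- apply_gate(ev, gate_threshold("DAPI", 1000, "below"))  # viable cells
af <- normalize_trace(bin_time_series(ev, "AF532"))
nf <- normalize_trace(bin_time_series(ev, "NF"))
fit <- fit_two_compartment(af, nf)
c(fit$params$k_u, fit$params$k_e, fit$params$q)
#> 0.0214  0.00202  0.034    (truth: 0.02, 0.002, 0.05)
```

The treated population shows the expected *decrease* of the emission ratio
(0.41 of vehicle) together with the *increase* of the excitation ratio
(1.00 → 1.54) — the two assays report the same dipole-potential change in
opposite directions, which is the built-in consistency check of the method
pair. The escape rate `k_e` is recovered within a few percent from a single
simulated 16-minute acquisition.

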