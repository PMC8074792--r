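# fixtures built in code, shared across test files

# small event table with explicit values
tiny_event_table <- function() {
  event_table(
    rbind(c(100, 200, 400, 800),
          c(150, 250, 0, 500),
          c(120, 220, 300, 600)),
    channels(c("FSC", "SSC", "F66_N", "F66_T")),
    sample_meta = list(treatment = "control")
  )
}

# KineticTrace directly from closed-form model curves (no event noise)
model_trace <- function(params, bin_centers, channel, n_per_bin = 100L,
                        normalized = TRUE) {
  m <- simulate_two_compartment(params, bin_centers)
  vals <- m[[channel]]
  if (normalized) vals <- vals / vals[1]
  df <- data.frame(bin_center_s = bin_centers, n = rep(n_per_bin, length(bin_centers)))
  nm <- if (channel == "F_AF") "AF532" else "NF"
  df[[nm]] <- vals
  structure(df, class = c("KineticTrace", "data.frame"),
            window_s = diff(bin_centers[1:2]), mode = "tumbling",
            normalized = normalized, meta = list())
}

# replicate escape-ratio trace from a simulated uptake stream
simulated_ratio_trace <- function(seed, kin, duration_s = 1000,
                                  event_rate_hz = 20) {
  cfg <- sim_config(seed = seed, kinetics = kin, event_rate_hz = event_rate_hz)
  ev <- simulate_uptake_events(cfg, duration_s = duration_s)
  ev <- apply_gate(ev, gate_threshold("DAPI", 1000, "below"))
  af <- normalize_trace(bin_time_series(ev, "AF532"))
  nf <- normalize_trace(bin_time_series(ev, "NF"))
  list(ratio = escape_ratio_trace(nf, af), af = af, nf = nf)
}

# fine-grid trapezoid oracle for band integrals of a function
fine_grid_integral <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  pracma::trapz(x, f(x))
}
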