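#' Two-compartment uptake/escape parameters
#'
#' Parameters of the kinetic model for dual-labelled cell-penetrating peptide
#' uptake read out with a pH-insensitive label (total uptake) and a label
#' quenched in acidic endo-lysosomes (escape): total uptake saturates as
#' `U(t) = U_max * (1 - exp(-k_u * t))`, cytosolic (escaped) material follows
#' `dC/dt = k_e * (U(t) - C)` with `C(0) = 0`, the endo-lysosomal pool is
#' `E = U - C`, and the two fluorescence signals are
#' `F_AF = E + C + baseline` and `F_NF = q * E + C + baseline` where
#' `q` in `[0, 1]` is the acidic-compartment quench factor.
#'
#' @param U_max total-uptake plateau (intensity units, > 0).
#' @param k_u uptake rate (1/s, > 0).
#' @param k_e escape rate (1/s, > 0).
#' @param q quench factor in `[0, 1]`.
#' @param baseline intensity offset (>= 0).
#' @return object of class `TwoCompartmentParams`.
#' @export
two_compartment_params <- function(U_max = 10, k_u = 0.02, k_e = 0.002,
                                   q = 0.05, baseline = 1) {
  if (!is_scalar_number(U_max) || U_max <= 0) stopf("U_max must be > 0")
  if (!is_scalar_number(k_u) || k_u <= 0) stopf("k_u must be > 0")
  if (!is_scalar_number(k_e) || k_e <= 0) stopf("k_e must be > 0")
  if (!is_scalar_number(q) || q < 0 || q > 1) stopf("q must lie in [0, 1]")
  if (!is_scalar_number(baseline) || baseline < 0) stopf("baseline must be >= 0")
  structure(list(U_max = U_max, k_u = k_u, k_e = k_e, q = q,
                 baseline = baseline),
            class = "TwoCompartmentParams")
}

#' Closed-form two-compartment model curves
#'
#' Evaluates the uptake/escape model of [two_compartment_params()] by its
#' closed-form solution. For `k_u != k_e`,
#' `C(t) = U_max * (1 - exp(-k_e t)) - k_e U_max (exp(-k_u t) - exp(-k_e t)) / (k_e - k_u)`;
#' the confluent case `k_u == k_e = k` uses
#' `C(t) = U_max (1 - exp(-k t)) - U_max k t exp(-k t)`.
#'
#' @param params a [two_compartment_params()] (k_e = 0 is additionally
#'   permitted here to represent the no-escape limit).
#' @param t_grid numeric vector of times (s, >= 0).
#' @return data.frame with columns `t`, `U` (total uptake), `E`
#'   (endo-lysosomal), `C` (cytosolic), `F_AF`, `F_NF`.
#' @export
simulate_two_compartment <- function(params, t_grid) {
  p <- params
  t <- as.numeric(t_grid)
  if (any(t < 0)) stopf("times must be >= 0")
  U <- p$U_max * (1 - exp(-p$k_u * t))
  C <- if (p$k_e == 0) {
    rep(0, length(t))
  } else if (abs(p$k_u - p$k_e) < 1e-12 * max(p$k_u, p$k_e)) {
    k <- p$k_u
    p$U_max * (1 - exp(-k * t)) - p$U_max * k * t * exp(-k * t)
  } else {
    p$U_max * (1 - exp(-p$k_e * t)) -
      p$k_e * p$U_max * (exp(-p$k_u * t) - exp(-p$k_e * t)) / (p$k_e - p$k_u)
  }
  E <- U - C
  data.frame(t = t, U = U, E = E, C = C,
             F_AF = E + C + p$baseline,
             F_NF = p$q * E + C + p$baseline)
}

# ---------------------------------------------------------------------------
# traces

kinetic_trace <- function(bin_centers_s, means, counts, window_s,
                          mode = "tumbling", normalized = FALSE,
                          meta = list()) {
  df <- data.frame(bin_center_s = bin_centers_s, n = counts)
  df <- cbind(df, as.data.frame(means))
  structure(df, class = c("KineticTrace", "data.frame"),
            window_s = window_s, mode = mode, normalized = normalized,
            meta = meta)
}

trace_channels <- function(trace) setdiff(names(trace), c("bin_center_s", "n"))

#' Bin a time-stamped event table into a kinetic trace
#'
#' Computes per-bin arithmetic mean intensities of the selected channels over
#' time. Two windowing modes are available: `"tumbling"` (default)
#' partitions time into non-overlapping windows of `window_s` seconds;
#' `"sliding"` computes a centred moving average of width `window_s`
#' advancing in steps of `step_s`. Empty bins carry count 0 and `NA` means;
#' they are excluded by downstream normalization.
#'
#' @param table an [event_table()] with per-event `time_s`, pre-gated (e.g.
#'   to viable, dye-negative events) and compensated as desired.
#' @param channels_used channel names to bin; default all fluorescence
#'   channels.
#' @param window_s window width in seconds (default 10).
#' @param mode `"tumbling"` or `"sliding"`.
#' @param step_s sliding-mode step in seconds (default 1).
#' @return a `KineticTrace` data.frame: `bin_center_s`, `n`, one column per
#'   channel.
#' @export
bin_time_series <- function(table, channels_used = NULL, window_s = 10,
                            mode = c("tumbling", "sliding"), step_s = 1) {
  stopifnot(inherits(table, "EventTable"))
  mode <- match.arg(mode)
  if (is.null(table$time_s)) stopf("event table has no time information")
  if (!is_scalar_number(window_s) || window_s <= 0) stopf("window_s must be > 0")
  if (is.null(channels_used)) channels_used <- fluorescence_channels(table)
  for (ch in channels_used) channel_column(table, ch)
  t <- table$time_s
  ord <- order(t)
  t <- t[ord]
  mat <- table$events[ord, channels_used, drop = FALSE]

  if (mode == "tumbling") {
    n_bins <- max(1L, ceiling((max(t) + 1e-9) / window_s))
    idx <- pmin(floor(t / window_s) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    sums <- rowsum(mat, group = factor(idx, levels = seq_len(n_bins)))
    means <- sweep(sums, 1, pmax(counts, 1L), "/")
    means[counts == 0L, ] <- NA_real_
    centers <- (seq_len(n_bins) - 0.5) * window_s
  } else {
    half <- window_s / 2
    centers <- seq(min(t) + half, max(t), by = step_s)
    if (!length(centers)) centers <- min(t) + half
    cs <- apply(rbind(0, mat), 2, cumsum)
    lo <- findInterval(centers - half - 1e-12, t)  # events with t >= c - w/2
    hi <- findInterval(centers + half + 1e-12, t)  # events with t <= c + w/2
    counts <- hi - lo
    means <- (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) /
      pmax(counts, 1L)
    means[counts == 0L, ] <- NA_real_
  }
  colnames(means) <- channels_used
  kinetic_trace(centers, means, counts, window_s, mode = mode,
                meta = table$sample_meta)
}

#' Normalize a kinetic trace to its first time window
#'
#' Divides every channel by its own mean in the first non-empty bin, so each
#' fluorophore is self-normalized and the first-window value is 1.
#'
#' @param trace a `KineticTrace` from [bin_time_series()].
#' @return the normalized `KineticTrace`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "KineticTrace"))
  first <- which(trace$n > 0)[1]
  if (is.na(first)) stopf("trace has no non-empty bins")
  for (ch in trace_channels(trace)) {
    ref <- trace[[ch]][first]
    if (!is.finite(ref) || ref <= 0)
      stopf("first-window mean of channel '%s' is %g (<= 0); cannot normalize",
            ch, ref)
    trace[[ch]] <- trace[[ch]] / ref
  }
  attr(trace, "normalized") <- TRUE
  trace
}

#' Ratio trace of two normalized single-channel traces
#'
#' Per-bin ratio of the quenchable-label trace to the pH-insensitive-label
#' trace (both already normalized to their first windows); this ratio reports
#' endo-lysosomal escape. Bins empty in either trace are dropped.
#'
#' @param nf_trace,af_trace normalized single-channel `KineticTrace`s on
#'   identical bin grids.
#' @return a `KineticTrace` with channel `ratio`.
#' @export
escape_ratio_trace <- function(nf_trace, af_trace) {
  stopifnot(inherits(nf_trace, "KineticTrace"), inherits(af_trace, "KineticTrace"))
  if (!isTRUE(attr(nf_trace, "normalized")) || !isTRUE(attr(af_trace, "normalized")))
    stopf("both traces must be normalized first (see normalize_trace())")
  if (nrow(nf_trace) != nrow(af_trace) ||
      any(nf_trace$bin_center_s != af_trace$bin_center_s))
    stopf("traces are on different bin grids")
  ch_nf <- trace_channels(nf_trace)[1]
  ch_af <- trace_channels(af_trace)[1]
  keep <- nf_trace$n > 0 & af_trace$n > 0
  kinetic_trace(nf_trace$bin_center_s[keep],
                data.frame(ratio = nf_trace[[ch_nf]][keep] /
                             af_trace[[ch_af]][keep]),
                pmin(nf_trace$n, af_trace$n)[keep],
                attr(nf_trace, "window_s"), mode = attr(nf_trace, "mode"),
                normalized = TRUE, meta = attr(nf_trace, "meta"))
}

# ---------------------------------------------------------------------------
# model fitting

# model prediction in normalized-trace space: baseline fixed at 1 intensity
# unit (only U_max relative to baseline is identifiable after normalization)
normalized_model <- function(theta, t, t_ref) {
  p <- two_compartment_params(U_max = theta[1], k_u = theta[2],
                              k_e = theta[3], q = theta[4], baseline = 1)
  m <- simulate_two_compartment(p, c(t_ref, t))
  ref_af <- m$F_AF[1]; ref_nf <- m$F_NF[1]
  list(af = m$F_AF[-1] / ref_af, nf = m$F_NF[-1] / ref_nf)
}

#' Fit the two-compartment model to normalized traces
#'
#' Joint least-squares fit of the uptake/escape model to the normalized
#' pH-insensitive (AF) and quenchable (NF) traces. The baseline is fixed at
#' one intensity unit (after first-window normalization only the plateau
#' relative to baseline is identifiable). Optimization is multi-start
#' Levenberg-Marquardt: a fixed log-spaced parameter grid jittered with the
#' given seed supplies the starts and the lowest residual norm wins.
#'
#' @param af_trace,nf_trace normalized single-channel `KineticTrace`s on the
#'   same grid, covering at least 600 s.
#' @param n_starts number of starts (>= 8).
#' @param seed seed for the start-grid jitter (recorded in the report).
#' @return list with `params` (a [two_compartment_params()]), `residual_norm`,
#'   `n_obs`, `starts`, `seed`, `converged`.
#' @export
fit_two_compartment <- function(af_trace, nf_trace, n_starts = 10, seed = 101) {
  stopifnot(inherits(af_trace, "KineticTrace"), inherits(nf_trace, "KineticTrace"))
  if (!isTRUE(attr(af_trace, "normalized")) || !isTRUE(attr(nf_trace, "normalized")))
    stopf("fit requires normalized traces")
  if (nrow(af_trace) != nrow(nf_trace) ||
      any(af_trace$bin_center_s != nf_trace$bin_center_s))
    stopf("traces are on different bin grids")
  keep <- af_trace$n > 0 & nf_trace$n > 0
  t <- af_trace$bin_center_s[keep]
  if (length(t) < 8L || diff(range(t)) < 600)
    stopf("traces must cover at least 600 s with enough bins to fit")
  y_af <- af_trace[[trace_channels(af_trace)[1]]][keep]
  y_nf <- nf_trace[[trace_channels(nf_trace)[1]]][keep]
  if (stats::sd(y_af) < 1e-8 && stats::sd(y_nf) < 1e-8)
    stopf("flat input traces: model parameters are unidentifiable")
  t_ref <- t[1]

  resid_fun <- function(theta) {
    m <- normalized_model(theta, t, t_ref)
    c(m$af - y_af, m$nf - y_nf)
  }

  grid <- expand.grid(U_max = c(3, 10, 30), k_u = c(0.005, 0.02, 0.08),
                      k_e = c(5e-4, 2e-3, 8e-3), q = c(0.05, 0.3, 0.7))
  starts <- with_seed(seed, {
    picked <- grid[sample.int(nrow(grid), max(8L, n_starts)), , drop = FALSE]
    jitter <- matrix(exp(stats::rnorm(nrow(picked) * 3, 0, 0.1)),
                     ncol = 3)
    picked$U_max <- picked$U_max * jitter[, 1]
    picked$k_u <- picked$k_u * jitter[, 2]
    picked$k_e <- picked$k_e * jitter[, 3]
    picked
  })

  lower <- c(1e-3, 1e-5, 1e-6, 0)
  upper <- c(1e4, 1, 0.5, 1)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    stopf("two-compartment fit failed to converge from any of %d starts",
          nrow(starts))
  th <- best$fit$par
  list(
    params = two_compartment_params(U_max = th[1], k_u = th[2], k_e = th[3],
                                    q = th[4], baseline = 1),
    residual_norm = best$rn,
    n_obs = 2L * length(t),
    starts = nrow(starts),
    seed = seed,
    converged = best$fit$info %in% 1:4
  )
}

#' Compare groups of ratio traces at an end point
#'
#' Extracts the per-replicate escape-ratio value at the bin containing
#' `t_eval` and delegates the group comparison to [one_way_anova()] and
#' [tukey_hsd()].
#'
#' @param groups named list; each element is a list of ratio `KineticTrace`s
#'   (the replicates of that group, >= 2 each).
#' @param t_eval evaluation time in seconds (default 900); must fall inside a
#'   non-empty bin of every trace.
#' @return list with `values` (data.frame group/replicate/value), `anova` and
#'   `tukey`.
#' @export
endpoint_compare <- function(groups, t_eval = 900) {
  if (length(groups) < 2L || is.null(names(groups)))
    stopf("`groups` must be a named list of >= 2 groups")
  extract <- function(trace) {
    half <- attr(trace, "window_s") / 2
    hit <- which(abs(trace$bin_center_s - t_eval) <= half & trace$n > 0)
    if (!length(hit))
      stopf("t_eval = %g s falls outside the trace", t_eval)
    ch <- trace_channels(trace)[1]
    trace[[ch]][hit[1]]
  }
  values <- do.call(rbind, lapply(names(groups), function(g) {
    reps <- groups[[g]]
    if (length(reps) < 2L) stopf("group '%s' has < 2 replicates", g)
    data.frame(group = g, replicate = seq_along(reps),
               value = vapply(reps, extract, 0), stringsAsFactors = FALSE)
  }))
  gd <- split(values$value, values$group)
  list(values = values, anova = one_way_anova(gd), tukey = tukey_hsd(gd))
}
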