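#' Per-cell dual-band emission ratio
#'
#' Computes, for every event, the ratio of the normal-band (N*) to the
#' tautomer-band (T*) emission intensity of a dual-band ESIPT probe. This
#' ratio negatively correlates with the magnitude of the membrane dipole
#' potential. Events with tautomer intensity `<= 0` have no defined ratio;
#' they are excluded and counted in the attached report rather than clamped.
#'
#' @param table an [event_table()], already compensated and gated as desired.
#' @param channel_N,channel_T names of the N* and T* band channels.
#' @return numeric vector of per-event ratios with attribute `n_excluded`.
#' @export
per_cell_emission_ratio <- function(table, channel_N = "F66_N",
                                    channel_T = "F66_T") {
  stopifnot(inherits(table, "EventTable"))
  i_n <- channel_column(table, channel_N)
  i_t <- channel_column(table, channel_T)
  keep <- i_t > 0
  if (!any(keep))
    stopf("all %d event(s) have non-positive '%s' intensity; no ratios defined",
          length(i_t), channel_T)
  out <- i_n[keep] / i_t[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Per-sample ratio summary
#'
#' Arithmetic mean (or, optionally, median) and sample standard deviation
#' (n - 1 denominator) of a per-cell ratio vector. Warns, without failing,
#' when fewer than `min_events` events contribute; acquisition protocols for
#' this readout target at least 20,000 living cells per sample.
#'
#' @param ratios non-empty numeric vector from [per_cell_emission_ratio()].
#' @param min_events event count below which a warning is raised.
#' @param sample_meta annotations carried into the summary.
#' @param statistic `"mean"` (default) or `"median"` as the location estimate.
#' @return an object of class `RatioSummary`: list with `mean_ratio`, `sd`,
#'   `n_events`, `statistic`, `sample_meta`.
#' @export
summarize_sample <- function(ratios, min_events = 20000, sample_meta = list(),
                             statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L) stopf("cannot summarize an empty ratio vector")
  if (length(ratios) < min_events)
    warnf("sample has %d events, fewer than min_events = %d",
          length(ratios), min_events)
  loc <- if (statistic == "mean") mean(ratios) else stats::median(ratios)
  structure(
    list(mean_ratio = loc,
         sd = if (length(ratios) > 1L) stats::sd(ratios) else 0,
         n_events = length(ratios),
         statistic = statistic,
         sample_meta = as.list(sample_meta)),
    class = "RatioSummary"
  )
}

#' @export
print.RatioSummary <- function(x, ...) {
  cat(sprintf("<RatioSummary: %s ratio %.4f (sd %.4f, n = %d)>\n",
              x$statistic, x$mean_ratio, x$sd, x$n_events))
  invisible(x)
}

#' Normalize sample summaries to replicate-matched controls
#'
#' Vehicle/control normalization of per-sample mean ratios: each treated mean
#' is divided by the mean of the control sample from the same replicate, so
#' control rows normalize to 1. Exactly one control must match
#' `control_selector` within each replicate.
#'
#' @param samples data.frame with (at least) columns `treatment`,
#'   `concentration`, `replicate` and `mean_ratio`, one row per sample.
#' @param control_selector named list of column = value pairs identifying the
#'   control sample within each replicate, e.g. `list(treatment = "vehicle")`.
#' @return a `DoseResponseTable` data.frame with one row per
#'   (treatment, concentration): `normalized_mean` (mean over replicates),
#'   `sd` and `n_replicates`.
#' @export
normalize_to_control <- function(samples, control_selector) {
  req <- c("treatment", "concentration", "replicate", "mean_ratio")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols))
    stopf("`samples` lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!length(control_selector) || is.null(names(control_selector)))
    stopf("`control_selector` must be a named list of column = value pairs")
  bad <- setdiff(names(control_selector), names(samples))
  if (length(bad))
    stopf("control_selector refers to unknown column(s): %s",
          paste(bad, collapse = ", "))
  if (any(samples$concentration < 0)) stopf("concentrations must be nonnegative")

  is_control <- rep(TRUE, nrow(samples))
  for (k in names(control_selector))
    is_control <- is_control & samples[[k]] == control_selector[[k]]

  samples$normalized <- NA_real_
  for (rep_id in unique(samples$replicate)) {
    in_rep <- samples$replicate == rep_id
    ctrl <- which(in_rep & is_control)
    if (length(ctrl) != 1L)
      stopf("replicate '%s': expected exactly 1 control, found %d (%s)",
            rep_id, length(ctrl),
            if (length(ctrl)) paste(samples$treatment[ctrl], collapse = ", ")
            else "none")
    samples$normalized[in_rep] <- samples$mean_ratio[in_rep] /
      samples$mean_ratio[ctrl]
  }

  key <- interaction(samples$treatment, samples$concentration, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- samples[key == k, , drop = FALSE]
    data.frame(
      treatment = sub$treatment[1],
      concentration = sub$concentration[1],
      normalized_mean = mean(sub$normalized),
      sd = if (nrow(sub) > 1L) stats::sd(sub$normalized) else 0,
      n_replicates = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$treatment, out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DoseResponseTable", "data.frame")
  out
}

#' Histogram of per-cell ratios
#'
#' Fixed-width histogram with left-closed, right-open bins; the last bin is
#' closed on both sides so the maximum of the range is counted. Values
#' outside `range` are excluded and reported.
#'
#' @param ratios non-empty numeric vector.
#' @param n_bins number of bins (>= 1). The default of 256 bins over the
#'   central 99.5% quantile range suits per-cell ratio distributions from
#'   >= 20,000 events.
#' @param range length-2 numeric `c(lo, hi)` with `lo < hi`; default is the
#'   central 99.5% quantile range of the data.
#' @return list with `breaks` (length `n_bins + 1`), `counts` (length
#'   `n_bins`), `n_excluded`.
#' @export
ratio_histogram <- function(ratios, n_bins = 256, range = NULL) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L) stopf("cannot histogram an empty vector")
  if (n_bins < 1L) stopf("`n_bins` must be >= 1")
  auto_range <- is.null(range)
  if (auto_range)
    range <- unname(stats::quantile(ratios, c(0.0025, 0.9975), names = FALSE))
  if (range[2] <= range[1]) {
    if (auto_range) range <- range[1] + c(-0.5, 0.5)  # constant data
    else stopf("degenerate range: hi (%g) must exceed lo (%g)", range[2], range[1])
  }
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  inside <- ratios >= range[1] & ratios <= range[2]
  idx <- findInterval(ratios[inside], breaks)
  idx[idx > n_bins] <- n_bins  # close the last bin
  counts <- tabulate(idx, nbins = n_bins)
  list(breaks = breaks, counts = counts, n_excluded = sum(!inside))
}
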