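#' Polarized intensity reads
#'
#' The four steady-state polarized fluorescence components of an L-format
#' measurement: `Ivv`/`Ivh` are the vertically and horizontally polarized
#' emission after vertically polarized excitation; `Ihv`/`Ihh` the same after
#' horizontally polarized excitation (used for the G factor).
#'
#' @param Ivv,Ivh,Ihv,Ihh finite, nonnegative intensities (arbitrary units).
#' @param meta named list of sample annotations.
#' @return object of class `PolarizedReads`.
#' @export
polarized_reads <- function(Ivv, Ivh, Ihv, Ihh, meta = list()) {
  vals <- c(Ivv = Ivv, Ivh = Ivh, Ihv = Ihv, Ihh = Ihh)
  if (any(!is.finite(vals)) || any(vals < 0))
    stopf("all four polarized components must be finite and >= 0")
  structure(list(Ivv = Ivv, Ivh = Ivh, Ihv = Ihv, Ihh = Ihh,
                 meta = as.list(meta)),
            class = "PolarizedReads")
}

#' Instrument G factor
#'
#' Polarization-sensitivity correction of the detection system,
#' `G = Ihv / Ihh`, measured with horizontally polarized excitation.
#'
#' @param Ihv,Ihh intensities; `Ihh` must be positive.
#' @return the dimensionless G factor.
#' @export
g_factor <- function(Ihv, Ihh) {
  if (any(Ihh <= 0)) stopf("Ihh must be > 0 to define the G factor")
  Ihv / Ihh
}

#' Steady-state fluorescence anisotropy
#'
#' L-format anisotropy `r = (Ivv - G * Ivh) / (Ivv + 2 * G * Ivh)`. For
#' nonnegative inputs with positive denominator `r` lies in `[-0.5, 1]`;
#' values outside the photophysically plausible window `[-0.2, 0.4]` for
#' membrane probes are flagged with a warning but not rejected.
#'
#' @param Ivv,Ivh polarized emission intensities (vertical excitation).
#' @param G instrument correction factor from [g_factor()].
#' @return the anisotropy (vectorized over the inputs).
#' @export
anisotropy <- function(Ivv, Ivh, G = 1) {
  den <- Ivv + 2 * G * Ivh
  if (any(den <= 0)) stopf("anisotropy denominator Ivv + 2*G*Ivh must be > 0")
  r <- (Ivv - G * Ivh) / den
  out_of_range <- r < -0.2 | r > 0.4
  if (any(out_of_range))
    warnf("%d anisotropy value(s) outside the plausible range [-0.2, 0.4]",
          sum(out_of_range))
  r
}

#' Anisotropy of a polarized read set
#'
#' Computes the G factor and anisotropy of one [polarized_reads()] object,
#' optionally subtracting per-component blank (unlabeled-sample) intensities
#' first. A session-level G may be supplied to override the per-sample
#' `Ihv/Ihh` estimate.
#'
#' @param reads a [polarized_reads()] object.
#' @param blank optional [polarized_reads()] with background intensities.
#' @param G optional fixed G factor; default computes `Ihv/Ihh` from `reads`.
#' @return list with `G`, `r` and the (blank-corrected) components.
#' @export
anisotropy_from_reads <- function(reads, blank = NULL, G = NULL) {
  stopifnot(inherits(reads, "PolarizedReads"))
  comp <- reads[c("Ivv", "Ivh", "Ihv", "Ihh")]
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "PolarizedReads"))
    comp <- Map(`-`, comp, blank[c("Ivv", "Ivh", "Ihv", "Ihh")])
  }
  if (is.null(G)) G <- g_factor(comp$Ihv, comp$Ihh)
  list(G = G, r = anisotropy(comp$Ivv, comp$Ivh, G), components = comp)
}

#' Batch anisotropy from a CSV of polarized reads
#'
#' Reads a CSV with columns `sample, Ivv, Ivh, Ihv, Ihh` (optionally
#' `blank_Ivv`, `blank_Ivh`, `blank_Ihv`, `blank_Ihh`) and returns per-sample
#' G and r.
#'
#' @param path CSV file.
#' @param G optional fixed session-level G factor applied to all samples.
#' @return data.frame with columns `sample`, `G`, `r`.
#' @export
anisotropy_table <- function(path, G = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("sample", "Ivv", "Ivh", "Ihv", "Ihh")
  if (!all(req %in% names(df)))
    stopf("anisotropy CSV '%s' must have columns %s", path,
          paste(req, collapse = ", "))
  has_blank <- all(paste0("blank_", c("Ivv", "Ivh", "Ihv", "Ihh")) %in% names(df))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    reads <- polarized_reads(df$Ivv[i], df$Ivh[i], df$Ihv[i], df$Ihh[i])
    blank <- if (has_blank)
      polarized_reads(df$blank_Ivv[i], df$blank_Ivh[i],
                      df$blank_Ihv[i], df$blank_Ihh[i])
    res <- anisotropy_from_reads(reads, blank = blank, G = G)
    data.frame(sample = df$sample[i], G = res$G, r = res$r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
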