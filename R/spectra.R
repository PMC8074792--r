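#' Excitation spectrum scan
#'
#' A fluorescence excitation spectrum: intensities recorded on a strictly
#' increasing wavelength grid at a fixed detection (emission) wavelength.
#' The dipole-potential assay records 380-550 nm with emission at 660 nm.
#'
#' @param wavelengths_nm strictly increasing numeric grid (>= 2 points).
#' @param intensities finite numeric vector, same length (arbitrary units).
#' @param emission_nm fixed detection wavelength in nm.
#' @param meta named list of sample annotations.
#' @return object of class `SpectrumScan`.
#' @export
spectrum_scan <- function(wavelengths_nm, intensities, emission_nm = NA_real_,
                          meta = list()) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) < 2L) stopf("a spectrum needs >= 2 points")
  if (length(intensities) != length(wavelengths_nm))
    stopf("wavelengths and intensities differ in length")
  if (any(diff(wavelengths_nm) <= 0))
    stopf("wavelength grid must be strictly increasing")
  if (any(!is.finite(intensities))) stopf("intensities must be finite")
  structure(
    list(wavelengths_nm = wavelengths_nm, intensities = intensities,
         emission_nm = emission_nm, meta = as.list(meta)),
    class = "SpectrumScan"
  )
}

#' @export
print.SpectrumScan <- function(x, ...) {
  cat(sprintf("<SpectrumScan: %d points, %.0f-%.0f nm, emission %.0f nm>\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$emission_nm))
  invisible(x)
}

#' Read a spectrum from CSV
#'
#' Expects columns `wavelength_nm` and `intensity`.
#'
#' @param path CSV file.
#' @param emission_nm detection wavelength recorded in the scan metadata.
#' @param meta sample annotations.
#' @return a [spectrum_scan()].
#' @export
read_spectrum <- function(path, emission_nm = NA_real_, meta = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stopf("spectrum CSV '%s' must have columns wavelength_nm, intensity", path)
  spectrum_scan(df$wavelength_nm, df$intensity, emission_nm = emission_nm,
                meta = meta)
}

#' Subtract a blank spectrum
#'
#' Pointwise subtraction of a blank (e.g. unlabeled-cell) scan recorded on an
#' identical wavelength grid. Negative results are retained and their count
#' reported in attribute `n_negative`.
#'
#' @param scan,blank_scan [spectrum_scan()] objects on identical grids.
#' @return the background-subtracted [spectrum_scan()].
#' @export
background_subtract <- function(scan, blank_scan) {
  stopifnot(inherits(scan, "SpectrumScan"), inherits(blank_scan, "SpectrumScan"))
  if (length(scan$wavelengths_nm) != length(blank_scan$wavelengths_nm) ||
      any(scan$wavelengths_nm != blank_scan$wavelengths_nm))
    stopf("scan and blank must share an identical wavelength grid")
  out <- scan
  out$intensities <- scan$intensities - blank_scan$intensities
  attr(out, "n_negative") <- sum(out$intensities < 0)
  out
}

#' Integrate a spectral band
#'
#' Trapezoidal integral of the intensity over `[lo_nm, hi_nm]` (band limits
#' inclusive). When a limit falls between grid points the integrand is
#' evaluated there by linear interpolation, so the result is exact for the
#' piecewise-linear interpolant of the sampled spectrum and adjacent bands
#' add: `band(a,b) + band(b,c) = band(a,c)`.
#'
#' @param scan a [spectrum_scan()].
#' @param lo_nm,hi_nm band limits, `lo_nm < hi_nm`, within the scan range.
#' @return the integral in intensity x nm.
#' @export
integrate_band <- function(scan, lo_nm, hi_nm) {
  stopifnot(inherits(scan, "SpectrumScan"))
  wl <- scan$wavelengths_nm
  if (!is_scalar_number(lo_nm) || !is_scalar_number(hi_nm) || lo_nm >= hi_nm)
    stopf("band limits must satisfy lo < hi")
  if (lo_nm < wl[1] || hi_nm > wl[length(wl)])
    stopf("band [%g, %g] outside scan range [%g, %g]",
          lo_nm, hi_nm, wl[1], wl[length(wl)])
  inner <- wl > lo_nm & wl < hi_nm
  y_lo <- stats::approx(wl, scan$intensities, xout = lo_nm)$y
  y_hi <- stats::approx(wl, scan$intensities, xout = hi_nm)$y
  xs <- c(lo_nm, wl[inner], hi_nm)
  ys <- c(y_lo, scan$intensities[inner], y_hi)
  pracma::trapz(xs, ys)
}

#' Dipole-potential-sensitive excitation ratio
#'
#' Ratio of the blue-edge to the red-edge excitation band integral of an
#' electrochromic membrane dye. With the default bands (410-440 nm over
#' 490-520 nm) this ratio positively correlates with the magnitude of the
#' membrane dipole potential: a blue shift of the excitation peak increases
#' it.
#'
#' @param scan a [spectrum_scan()] covering both bands.
#' @param numerator_band,denominator_band length-2 numeric band limits in nm.
#' @return the dimensionless band ratio.
#' @export
excitation_ratio <- function(scan, numerator_band = c(410, 440),
                             denominator_band = c(490, 520)) {
  num <- integrate_band(scan, numerator_band[1], numerator_band[2])
  den <- integrate_band(scan, denominator_band[1], denominator_band[2])
  if (den <= 0)
    stopf("denominator band integral is %g (<= 0); ratio undefined", den)
  num / den
}
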