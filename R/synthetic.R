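#' Simulation configuration
#'
#' Ground-truth configuration shared by all synthetic-data generators. The
#' seed is mandatory: every generator is a pure function of its configuration
#' and produces bit-identical output for identical configurations.
#'
#' `dp_param` is an abstract, unitless dipole-field surrogate (0 = untreated
#' control): raising it blue-shifts the synthetic excitation spectrum and
#' raises the tautomer fraction of the dual-band emission probe, so higher
#' `dp_param` means a lower N*/T* emission ratio and a higher excitation band
#' ratio — the direction structure of dipole-potential-raising treatments.
#'
#' @param seed integer RNG seed (mandatory).
#' @param n_cells number of cells/events per sample.
#' @param dp_param unitless dipole-field surrogate.
#' @param dye_sigma lognormal sigma of the per-cell dye load.
#' @param meas_cv multiplicative measurement coefficient of variation.
#' @param live_fraction,apoptotic_fraction,necrotic_fraction subpopulation
#'   proportions (sum <= 1; the remainder is double-positive).
#' @param kinetics a [two_compartment_params()] for uptake simulations.
#' @param event_rate_hz Poisson event rate of the cytometer stream (cells/s).
#' @param dapi_fraction fraction of dye-positive (non-viable) events in the
#'   uptake stream.
#' @param spectrum_center0_nm excitation peak centre at `dp_param = 0`.
#' @param spectrum_shift_nm blue shift of the peak centre per unit `dp_param`.
#' @param spectrum_sigma_nm Gaussian width of the excitation peak.
#' @param spectrum_amplitude peak intensity (arbitrary units).
#' @param spectrum_noise_sd additive noise SD on the spectrum.
#' @param image_size_px image height/width in pixels.
#' @param cell_radius_px,rim_width_px disk-cell geometry for membrane images.
#' @param gp_true ground-truth generalized polarization of the membrane rim.
#' @param gp_interior ground-truth GP of the cell interior.
#' @param rim_photons expected summed-channel photon count of a rim pixel.
#' @param seed_style `"contours"` (annotator traces the inner and outer
#'   contour of each cell — dense seed rings hugging the membrane) or
#'   `"points"` (one interior, one rim and one background point per cell).
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       n_cells = 20000,
                       dp_param = 0,
                       dye_sigma = 0.35,
                       meas_cv = 0.05,
                       live_fraction = 0.90,
                       apoptotic_fraction = 0.05,
                       necrotic_fraction = 0.03,
                       kinetics = two_compartment_params(),
                       event_rate_hz = 20,
                       dapi_fraction = 0.05,
                       spectrum_center0_nm = 465,
                       spectrum_shift_nm = 5,
                       spectrum_sigma_nm = 40,
                       spectrum_amplitude = 1000,
                       spectrum_noise_sd = 1,
                       image_size_px = c(320, 320),
                       cell_radius_px = 18,
                       rim_width_px = 3,
                       gp_true = 0.2,
                       gp_interior = -0.1,
                       rim_photons = 2000,
                       seed_style = c("contours", "points")) {
  if (missing(seed)) stopf("`seed` is mandatory: no silent entropy")
  if (!is_scalar_number(seed)) stopf("`seed` must be a single number")
  fr <- c(live_fraction, apoptotic_fraction, necrotic_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12)
    stopf("subpopulation fractions must lie in [0, 1] and sum to <= 1")
  if (dye_sigma < 0 || meas_cv < 0) stopf("noise parameters must be >= 0")
  if (spectrum_sigma_nm <= 0) stopf("spectrum sigma must be > 0")
  stopifnot(inherits(kinetics, "TwoCompartmentParams"))
  structure(
    list(seed = as.integer(seed), n_cells = as.integer(n_cells),
         dp_param = dp_param, dye_sigma = dye_sigma, meas_cv = meas_cv,
         live_fraction = live_fraction,
         apoptotic_fraction = apoptotic_fraction,
         necrotic_fraction = necrotic_fraction,
         kinetics = kinetics, event_rate_hz = event_rate_hz,
         dapi_fraction = dapi_fraction,
         spectrum_center0_nm = spectrum_center0_nm,
         spectrum_shift_nm = spectrum_shift_nm,
         spectrum_sigma_nm = spectrum_sigma_nm,
         spectrum_amplitude = spectrum_amplitude,
         spectrum_noise_sd = spectrum_noise_sd,
         image_size_px = rep_len(as.integer(image_size_px), 2L),
         cell_radius_px = cell_radius_px, rim_width_px = rim_width_px,
         gp_true = gp_true, gp_interior = gp_interior,
         rim_photons = rim_photons,
         seed_style = match.arg(seed_style)),
    class = "SimulationConfig"
  )
}

# mean-one multiplicative lognormal noise with coefficient of variation cv
mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Tautomer fraction of the dual-band probe as a function of dp_param
#'
#' Logistic link `f_T = plogis(log(2) + 0.5 * dp_param)`: at `dp_param = 0`
#' the tautomer fraction is 2/3 (noiseless per-cell N*/T* ratio 0.5) and
#' higher `dp_param` monotonically raises `f_T`, hence lowers the N*/T*
#' ratio. The fixed coefficients keep `f_T` in (0, 1) for any `dp_param`.
#'
#' @param dp_param unitless dipole-field surrogate (vectorized).
#' @return tautomer fraction in (0, 1).
#' @export
f66_tautomer_fraction <- function(dp_param) {
  stats::plogis(log(2) + 0.5 * dp_param)
}

#' dp_param presets for the treatment panel
#'
#' Unitless `dp_param` values encoding the direction and ordering of the
#' dipole-potential panel (omega-3 fatty acid below control; saturated and
#' omega-6 fatty acids, sterols and the ketosterol above it, in increasing
#' order). Only the ordering is meaningful; the panel cannot be calibrated to
#' physical units.
#'
#' @return named numeric vector of `dp_param` values.
#' @export
dp_panel <- function() {
  c(ALA = -0.6, control = 0, SA = 0.4, GLA = 0.4,
    `7DHC` = 0.9, cholesterol = 1.3, `6KC` = 1.8)
}

#' Simulate a dual-band emission cytometry population
#'
#' Generates an event table emulating cells labelled with a dual-band ESIPT
#' probe plus viability markers. Per live cell: dye load
#' `L ~ lognormal(log(1000), dye_sigma)`; tautomer fraction
#' `f_T = f66_tautomer_fraction(dp_param)`; band intensities
#' `I_N = L (1 - f_T) eps_N`, `I_T = L f_T eps_T` with mean-one multiplicative
#' measurement noise of CV `meas_cv`. Scatter channels form distinct seeded
#' clusters for live cells versus dead cells/debris, and the necrosis and
#' apoptosis marker channels are populated according to the configured
#' subpopulation fractions (remainder double-positive).
#'
#' Channels: `FSC`, `SSC`, `F66_N`, `F66_T`, `SytoxGreen`, `AnnexinV`.
#' Attribute `truth` carries the per-event state, `f_T`, the marker
#' thresholds and a live scatter gate.
#'
#' @param config a [sim_config()].
#' @return an [event_table()] with attribute `truth`.
#' @export
simulate_f66_population <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_cells
  with_seed(config$seed, {
    probs <- c(live = config$live_fraction,
               apoptotic = config$apoptotic_fraction,
               necrotic = config$necrotic_fraction)
    probs <- c(probs, double_positive = max(0, 1 - sum(probs)))
    state <- sample(names(probs), n, replace = TRUE, prob = probs)
    live <- state == "live"

    f_t <- f66_tautomer_fraction(config$dp_param)
    load <- stats::rlnorm(n, log(1000), config$dye_sigma)
    load[!live] <- load[!live] * 0.3
    i_n <- load * (1 - f_t) * mult_noise(n, config$meas_cv)
    i_t <- load * f_t * mult_noise(n, config$meas_cv)

    fsc <- ifelse(live, stats::rlnorm(n, log(5e4), 0.12),
                  stats::rlnorm(n, log(1.5e4), 0.30))
    ssc <- ifelse(live, stats::rlnorm(n, log(2e4), 0.15),
                  stats::rlnorm(n, log(1.0e4), 0.50))

    nec_pos <- state %in% c("necrotic", "double_positive")
    apo_pos <- state %in% c("apoptotic", "double_positive")
    sytox <- ifelse(nec_pos, stats::rlnorm(n, log(5000), 0.3),
                    stats::rlnorm(n, log(100), 0.4))
    annexin <- ifelse(apo_pos, stats::rlnorm(n, log(5000), 0.3),
                      stats::rlnorm(n, log(100), 0.4))

    events <- cbind(FSC = fsc, SSC = ssc, F66_N = i_n, F66_T = i_t,
                    SytoxGreen = sytox, AnnexinV = annexin)
    out <- event_table(events, channels(colnames(events)),
                       sample_meta = list(dp_param = config$dp_param,
                                          seed = config$seed))
    attr(out, "truth") <- list(
      state = state, f_T = f_t,
      thresholds = c(necrosis = 1000, apoptosis = 1000),
      live_gate = gate_rectangle(c("FSC", "SSC"),
                                 xlim = c(3e4, 8.5e4), ylim = c(1.1e4, 3.6e4))
    )
    out
  })
}

#' Simulate an excitation spectrum
#'
#' Gaussian excitation peak whose centre shifts blue with `dp_param`
#' (`center = center0 - shift * dp_param`), sampled 380-550 nm at 1 nm with
#' additive seeded Gaussian noise. Higher `dp_param` therefore yields a
#' larger [excitation_ratio()].
#'
#' @param config a [sim_config()].
#' @return a [spectrum_scan()] with attribute `truth` (the peak centre).
#' @export
simulate_excitation_spectrum <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  center <- config$spectrum_center0_nm -
    config$spectrum_shift_nm * config$dp_param
  wl <- seq(380, 550, by = 1)
  with_seed(config$seed, {
    intensities <- config$spectrum_amplitude *
      exp(-(wl - center)^2 / (2 * config$spectrum_sigma_nm^2))
    if (config$spectrum_noise_sd > 0)
      intensities <- intensities +
        stats::rnorm(length(wl), 0, config$spectrum_noise_sd)
    scan <- spectrum_scan(wl, intensities, emission_nm = 660,
                          meta = list(dp_param = config$dp_param))
    attr(scan, "truth") <- list(center_nm = center,
                                sigma_nm = config$spectrum_sigma_nm,
                                amplitude = config$spectrum_amplitude)
    scan
  })
}

#' Construct polarized reads with known anisotropy and G factor
#'
#' Algebraically inverts the L-format anisotropy and G-factor definitions:
#' given `r_true` and `G_true` it chooses `Ivh > 0`,
#' `Ivv = G_true * Ivh * (1 + 2 r_true) / (1 - r_true)` (scaled so
#' `Ivv + Ivh` equals `total_intensity`) and `Ihv = G_true * Ihh`, so that
#' [g_factor()] followed by [anisotropy()] recovers `(G_true, r_true)`
#' exactly in the noiseless case.
#'
#' @param r_true anisotropy in the open interval (-0.5, 1).
#' @param G_true instrument factor (> 0).
#' @param total_intensity scale of `Ivv + Ivh`.
#' @return a [polarized_reads()] object.
#' @export
simulate_polarized_reads <- function(r_true, G_true, total_intensity = 1e5) {
  if (!is_scalar_number(r_true) || r_true <= -0.5 || r_true >= 1)
    stopf("r_true must lie strictly inside (-0.5, 1)")
  if (!is_scalar_number(G_true) || G_true <= 0) stopf("G_true must be > 0")
  ivh <- 1
  ivv <- G_true * ivh * (1 + 2 * r_true) / (1 - r_true)
  scale <- total_intensity / (ivv + ivh)
  ihh <- total_intensity / 10
  polarized_reads(Ivv = ivv * scale, Ivh = ivh * scale,
                  Ihv = G_true * ihh, Ihh = ihh,
                  meta = list(r_true = r_true, G_true = G_true))
}

#' Simulate a time-correlated peptide-uptake event stream
#'
#' Events arrive as a seeded Poisson stream over `[0, duration_s]`; each
#' event's pH-insensitive (`AF532`) and quenchable (`NF`) intensities are the
#' two-compartment model curves evaluated at its arrival time, multiplied by
#' a shared per-cell lognormal labelling factor and independent mean-one
#' measurement noise. A configured fraction of events is DAPI-positive
#' (non-viable) with a distinct DAPI intensity distribution.
#'
#' Channels: `AF532`, `NF`, `DAPI`; `time_s` is populated. Attribute `truth`
#' carries the kinetic parameters and the DAPI threshold.
#'
#' @param config a [sim_config()].
#' @param duration_s acquisition duration in seconds (default 1200).
#' @return an [event_table()] with per-event times and attribute `truth`.
#' @export
simulate_uptake_events <- function(config, duration_s = 1200) {
  stopifnot(inherits(config, "SimulationConfig"))
  p <- config$kinetics
  with_seed(config$seed, {
    n <- stats::rpois(1, config$event_rate_hz * duration_s)
    t <- sort(stats::runif(n, 0, duration_s))
    curves <- simulate_two_compartment(p, t)
    load <- stats::rlnorm(n, log(100), config$dye_sigma)
    af <- curves$F_AF * load * mult_noise(n, config$meas_cv)
    nf <- curves$F_NF * load * mult_noise(n, config$meas_cv)
    dapi_pos <- stats::runif(n) < config$dapi_fraction
    dapi <- ifelse(dapi_pos, stats::rlnorm(n, log(5000), 0.3),
                   stats::rlnorm(n, log(50), 0.5))
    events <- cbind(AF532 = af, NF = nf, DAPI = dapi)
    out <- event_table(events, channels(colnames(events)), time_s = t,
                       sample_meta = list(seed = config$seed))
    attr(out, "truth") <- list(params = p, dapi_threshold = 1000,
                               dapi_positive = dapi_pos)
    out
  })
}

#' Simulate a two-channel membrane image with known GP
#'
#' Renders 10-15 non-overlapping disk cells with bright membrane rims on a
#' dim background. The expected summed-channel intensity is `rim_photons` on
#' the rim, a gently domed `rim_photons/10` in the interior (brightest at the
#' cell centre, darkest just inside the rim, as in midplane sections with
#' residual cytosolic dye) and `rim_photons/50` in the background. The
#' per-pixel split into blue and red channels encodes the ground-truth GP
#' (`blue/red = (1 + gp) / (1 - gp)`; rim `gp_true`, interior `gp_interior`,
#' background 0) and both channels receive seeded Poisson photon noise.
#'
#' Seeds are auto-generated in the configured `seed_style`; the true rim mask
#' and `gp_true` are returned for recovery tests.
#'
#' @param config a [sim_config()]; `abs(gp_true) < 1` is required.
#' @return list with `pair` (an [image_pair()]), `seeds` (a [seed_set()]),
#'   `truth_mask` (logical rim mask) and `gp_true`.
#' @export
simulate_membrane_image <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (abs(config$gp_true) >= 1 || abs(config$gp_interior) >= 1)
    stopf("ground-truth GP must lie strictly inside (-1, 1)")
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  radius <- config$cell_radius_px
  rim <- config$rim_width_px
  r_in <- radius - rim
  if (r_in <= 1) stopf("rim width too large for the cell radius")

  with_seed(config$seed, {
    # non-overlapping cell placement on a jittered grid
    spacing <- 2 * (radius + rim) + 6
    rows0 <- seq(spacing / 2 + 2, nr - spacing / 2 - 2, by = spacing)
    cols0 <- seq(spacing / 2 + 2, nc - spacing / 2 - 2, by = spacing)
    slots <- expand.grid(r = rows0, c = cols0)
    n_cells <- sample(10:15, 1)
    if (n_cells > nrow(slots))
      stopf("image too small for %d cells of radius %d", n_cells, radius)
    pick <- sample.int(nrow(slots), n_cells)
    centers <- cbind(slots$r[pick] + stats::runif(n_cells, -3, 3),
                     slots$c[pick] + stats::runif(n_cells, -3, 3))

    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2min <- matrix(Inf, nr, nc)
    nearest <- matrix(0L, nr, nc)
    for (k in seq_len(n_cells)) {
      d2 <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2
      closer <- d2 < d2min
      d2min[closer] <- d2[closer]
      nearest[closer] <- k
    }
    d <- sqrt(d2min)

    is_rim <- d >= r_in & d < radius
    is_interior <- d < r_in
    total <- matrix(config$rim_photons / 50, nr, nc)
    total[is_rim] <- config$rim_photons
    dome <- config$rim_photons * (0.05 + 0.10 * (1 - (d / r_in)^2))
    total[is_interior] <- dome[is_interior]

    gp <- matrix(0, nr, nc)
    gp[is_rim] <- config$gp_true
    gp[is_interior] <- config$gp_interior
    frac_blue <- (1 + gp) / 2
    blue <- matrix(stats::rpois(nr * nc, frac_blue * total), nr, nc)
    red <- matrix(stats::rpois(nr * nc, (1 - frac_blue) * total), nr, nc)

    seeds <- make_image_seeds(config, d, nearest, n_cells, nr, nc)
    list(pair = image_pair(blue, red,
                           meta = list(gp_true = config$gp_true,
                                       seed = config$seed)),
         seeds = seeds, truth_mask = is_rim, gp_true = config$gp_true)
  })
}

make_image_seeds <- function(config, d, nearest, n_cells, nr, nc) {
  radius <- config$cell_radius_px
  r_in <- radius - config$rim_width_px
  corners <- cbind(c(2, 2, nr - 1, nr - 1), c(2, nc - 1, 2, nc - 1))
  membrane <- NULL; interior <- NULL; background <- NULL
  for (k in seq_len(n_cells)) {
    cell <- nearest == k
    rim_idx <- which(cell & d >= r_in & d < radius)
    center_idx <- which(cell & d < 1.5)
    membrane <- rbind(membrane, which_to_coords(rim_idx[1], nr))
    interior <- rbind(interior, which_to_coords(center_idx[1], nr))
    if (config$seed_style == "contours") {
      inner_idx <- which(cell & d >= r_in - 1 & d < r_in)
      outer_idx <- which(cell & d >= radius & d < radius + 1)
      interior <- rbind(interior, which_to_coords(inner_idx, nr))
      background <- rbind(background, which_to_coords(outer_idx, nr))
    } else {
      east_idx <- which(cell & d >= radius + 3 & d < radius + 4)
      background <- rbind(background, which_to_coords(east_idx[1], nr))
    }
  }
  seed_set(membrane, interior, rbind(background, corners))
}

which_to_coords <- function(idx, nr) {
  idx <- idx[!is.na(idx)]
  cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
}

# ---------------------------------------------------------------------------
# peptide mass utility

# IUPAC average residue masses (g/mol), 20 canonical amino acids
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
MASS_WATER <- 18.0153
MASS_AMIDE_DELTA <- -0.9847  # C-terminal OH -> NH2

#' Average molecular mass of a peptide
#'
#' Sums standard IUPAC average residue masses over a one-letter sequence and
#' adds one water for the free-acid C-terminus; an amidated C-terminus
#' replaces the terminal hydroxyl with an amine (net -0.98 g/mol). The mass
#' is additive: `mass(AB) = mass(A) + mass(B) - water`.
#'
#' @param sequence one-letter amino-acid string (20 canonical residues).
#' @param c_terminus `"free-acid"` (default) or `"amide"`.
#' @return average molecular mass in g/mol.
#' @export
peptide_average_mass <- function(sequence, c_terminus = c("free-acid", "amide")) {
  c_terminus <- match.arg(c_terminus)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stopf("`sequence` must be a non-empty one-letter amino-acid string")
  letters_vec <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters_vec, names(AA_RESIDUE_MASS))
  if (length(unknown))
    stopf("unknown amino-acid letter(s): %s", paste(unique(unknown), collapse = ", "))
  mass <- sum(AA_RESIDUE_MASS[letters_vec]) + MASS_WATER
  if (c_terminus == "amide") mass <- mass + MASS_AMIDE_DELTA
  unname(mass)
}
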