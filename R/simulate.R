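#' Response model of the dual-reporter ratiometric probe
#'
#' Describes how the probe's Raman peaks respond to the two metabolites.
#' Each peak is a Lorentzian with a center, half-width at half-maximum and a
#' base amplitude, and belongs to one of three response classes:
#' \describe{
#'   \item{gsh_up}{amplitude rises affinely with GSH concentration
#'     (542, 806, 1023 cm^-1): `amp = base * (1 + gsh_slope * c_gsh)`}
#'   \item{h2o2_down}{amplitude falls affinely with H2O2 concentration,
#'     clipped at `floor * base` (628, 801, 1164, 1426, 1617 cm^-1):
#'     `amp = base * max(floor, 1 - h2o2_slope * c_h2o2)`}
#'   \item{inert}{independent of both; the 928 cm^-1 internal reference}
#' }
#' The affine forms make every noiseless grid intensity affine in the two
#' concentrations, so peak ratios against the inert reference are linear in
#' the corresponding metabolite -- the behavior ratiometric calibration
#' relies on. Default constants are simulator parameters chosen so the
#' noiseless ratios span the probe's reported physiological working ranges
#' (GSH 0.5-20 mM, H2O2 5-200 uM); they are not claims about the physical
#' probe.
#'
#' @param axis Wavenumber grid (default 400-1800 cm^-1 in 2 cm^-1 steps, which
#'   places the three analytically used peaks 542/628/928 exactly on grid).
#' @param peaks Data frame with columns `center`, `width` (HWHM), `base`,
#'   `response`; defaults to the probe's peak table.
#' @param gsh_slope Relative amplitude gain per mM GSH for `gsh_up` peaks.
#' @param h2o2_slope Relative amplitude loss per uM H2O2 for `h2o2_down`
#'   peaks.
#' @param floor Minimum amplitude fraction retained by `h2o2_down` peaks.
#' @return A `sers_probe` model.
#' @export
probe_response_model <- function(axis = seq(400, 1800, by = 2),
                                 peaks = default_peak_table(),
                                 gsh_slope = 0.4,
                                 h2o2_slope = 0.0045,
                                 floor = 0.05) {
  stopifnot(is.numeric(axis), length(axis) >= 2, all(diff(axis) > 0),
            gsh_slope > 0, h2o2_slope > 0, floor >= 0, floor < 1)
  need <- c("center", "width", "base", "response")
  if (!all(need %in% names(peaks))) stop("peak table must have columns ", paste(need, collapse = ", "))
  if (!any(peaks$center == 928 & peaks$response == "inert"))
    stop("the 928 cm^-1 reference peak must be present and inert")
  if (!all(c(542, 806, 1023) %in% peaks$center[peaks$response == "gsh_up"]))
    stop("gsh_up peaks must include 542, 806 and 1023 cm^-1")
  if (!all(c(628, 801, 1164, 1426, 1617) %in% peaks$center[peaks$response == "h2o2_down"]))
    stop("h2o2_down peaks must include 628, 801, 1164, 1426 and 1617 cm^-1")
  if (any(peaks$base < 0) || any(peaks$width <= 0)) stop("peak bases must be >= 0 and widths > 0")
  structure(list(axis = axis, peaks = peaks, gsh_slope = gsh_slope,
                 h2o2_slope = h2o2_slope, floor = floor,
                 gsh_range = c(0.5, 20), h2o2_range = c(5, 200)),
            class = "sers_probe")
}

#' @rdname probe_response_model
#' @export
default_peak_table <- function() {
  data.frame(
    center   = c(542,      806,      1023,     628,        801,        1164,       1426,       1617,       928),
    width    = c(4,        4,        4,        4,          4,          4,          4,          4,          4),
    base     = c(0.25,     0.15,     0.12,     1.5,        0.30,       0.25,       0.20,       0.35,       1.0),
    response = c("gsh_up", "gsh_up", "gsh_up", "h2o2_down", "h2o2_down", "h2o2_down", "h2o2_down", "h2o2_down", "inert"),
    stringsAsFactors = FALSE
  )
}

#' Measurement noise model for simulated spectra
#'
#' Additive white Gaussian noise plus a random low-order polynomial baseline
#' per acquisition. The defaults are mild (noise sd = 1% of the reference
#' peak amplitude) but sufficient to make ratiometric baseline subtraction
#' matter. `noise_model(0, c(0, 0, 0))` turns noise off entirely.
#'
#' @param additive_sd Standard deviation of the white noise (intensity units).
#' @param baseline_max Length-3 non-negative vector: maximum absolute value of
#'   the constant, linear and quadratic baseline coefficients (each drawn
#'   uniformly from `[0, max]` for offset/curvature and `[-max, max]` for the
#'   slope, over a 0..1 normalized axis).
#' @return A `sers_noise` model.
#' @export
noise_model <- function(additive_sd = 0.01, baseline_max = c(0.05, 0.02, 0.03)) {
  stopifnot(additive_sd >= 0, length(baseline_max) == 3, all(baseline_max >= 0))
  structure(list(additive_sd = additive_sd, baseline_max = baseline_max),
            class = "sers_noise")
}

# Noiseless peak amplitudes at one concentration pair.
probe_amplitudes <- function(probe, c_gsh, c_h2o2) {
  p <- probe$peaks
  amp <- p$base
  up <- p$response == "gsh_up"
  dn <- p$response == "h2o2_down"
  amp[up] <- p$base[up] * (1 + probe$gsh_slope * c_gsh)
  amp[dn] <- p$base[dn] * pmax(probe$floor, 1 - probe$h2o2_slope * c_h2o2)
  amp
}

# Noiseless spectrum intensities on the probe axis.
probe_clean_intensities <- function(probe, c_gsh, c_h2o2) {
  amp <- probe_amplitudes(probe, c_gsh, c_h2o2)
  p <- probe$peaks
  y <- numeric(length(probe$axis))
  for (i in seq_len(nrow(p))) {
    y <- y + amp[i] / (1 + ((probe$axis - p$center[i]) / p$width[i])^2)
  }
  y
}

#' Closed-form expected peak ratios of the noiseless probe
#'
#' Returns the analyte-dependent amplitude ratios `r1 = A542/A928` and
#' `r2 = A628/A928` implied by the response model (ignoring Lorentzian tail
#' overlap between peaks). Used as the independent reference when checking
#' ratio extraction and calibration recovery.
#'
#' @param probe A `sers_probe`.
#' @param c_gsh GSH concentration (mM).
#' @param c_h2o2 H2O2 concentration (uM).
#' @return Named list with `r1` and `r2`.
#' @export
probe_expected_ratios <- function(probe, c_gsh, c_h2o2) {
  p <- probe$peaks
  amp <- probe_amplitudes(probe, c_gsh, c_h2o2)
  ref <- amp[p$center == 928 & p$response == "inert"][1]
  list(r1 = amp[p$center == 542][1] / ref,
       r2 = amp[p$center == 628][1] / ref)
}

#' Simulate one probe spectrum at known concentrations
#'
#' Sum of Lorentzian peaks with analyte-responsive amplitudes, plus the noise
#' model's random baseline and white noise. Concentrations outside the
#' probe's validity ranges are simulated but flagged (attribute
#' `extrapolated`).
#'
#' @param c_gsh GSH concentration in mM (>= 0).
#' @param c_h2o2 H2O2 concentration in uM (>= 0).
#' @param probe A `sers_probe`.
#' @param noise A `sers_noise` (use `noise_model(0, c(0,0,0))` for noiseless).
#' @param tissue_class,grid_xy,id Optional labels passed through.
#' @return A `sers_labeled_spectrum` carrying the true concentrations.
#' @export
simulate_spectrum <- function(c_gsh, c_h2o2,
                              probe = probe_response_model(),
                              noise = noise_model(),
                              tissue_class = NA_character_, grid_xy = NULL,
                              id = NA_character_) {
  if (c_gsh < 0 || c_h2o2 < 0) stop("concentrations must be >= 0")
  y <- probe_clean_intensities(probe, c_gsh, c_h2o2)
  n <- length(y)
  if (noise$additive_sd > 0 || any(noise$baseline_max > 0)) {
    t <- seq(0, 1, length.out = n)
    b <- noise$baseline_max
    y <- y + stats::runif(1, 0, b[1]) +
      stats::runif(1, -b[2], b[2]) * t +
      stats::runif(1, 0, b[3]) * t^2
    y <- y + stats::rnorm(n, 0, noise$additive_sd)
    # no clipping at zero: mild negative excursions mirror real
    # baseline-subtracted counts, and clipping would bias replicate averages
  }
  out <- labeled_spectrum(sers_spectrum(probe$axis, y),
                          c_gsh = c_gsh, c_h2o2 = c_h2o2,
                          tissue_class = tissue_class, grid_xy = grid_xy,
                          id = id)
  attr(out, "extrapolated") <-
    c_gsh < probe$gsh_range[1] || c_gsh > probe$gsh_range[2] ||
    c_h2o2 < probe$h2o2_range[1] || c_h2o2 > probe$h2o2_range[2]
  out
}

#' Simulate the full factorial calibration database
#'
#' Every GSH level is crossed with every H2O2 level and each cell is
#' replicated, mirroring a standard-solution calibration design. The default
#' grids are 6 GSH levels \{2,4,6,8,10,16\} mM by 8 H2O2 levels
#' \{1,25,50,75,100,125,150,200\} uM with 200 replicates each: 9600 spectra.
#'
#' @param gsh_levels GSH levels in mM.
#' @param h2o2_levels H2O2 levels in uM.
#' @param replicates Spectra per grid cell.
#' @param probe,noise Simulator models.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return List of `sers_labeled_spectrum` of length
#'   `length(gsh_levels) * length(h2o2_levels) * replicates`.
#' @export
build_calibration_dataset <- function(gsh_levels = c(2, 4, 6, 8, 10, 16),
                                      h2o2_levels = c(1, 25, 50, 75, 100, 125, 150, 200),
                                      replicates = 200,
                                      probe = probe_response_model(),
                                      noise = noise_model(),
                                      seed = 1L) {
  stopifnot(length(gsh_levels) >= 1, length(h2o2_levels) >= 1, replicates >= 1)
  if (anyDuplicated(gsh_levels) || anyDuplicated(h2o2_levels))
    stop("duplicate concentration levels in the calibration design")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  design <- expand.grid(rep = seq_len(replicates),
                        h2o2 = h2o2_levels, gsh = gsh_levels)
  lapply(seq_len(nrow(design)), function(i) {
    simulate_spectrum(design$gsh[i], design$h2o2[i], probe, noise,
                      id = sprintf("g%g_h%g_r%03d", design$gsh[i],
                                   design$h2o2[i], design$rep[i]))
  })
}

#' Per-class concentration distributions for tissue cohorts
#'
#' Mean and SD of the two metabolites per tissue class, defaulting to the
#' in-vivo glioma allograft statistics this package targets: GSH
#' 12.08 +/- 0.53 mM (IDH1-WT) vs 9.20 +/- 0.83 mM (IDH1-MUT) with normal
#' brain below 1 mM, and H2O2 68.54 +/- 4.51 uM (WT) vs 109.3 +/- 9.44 uM
#' (MUT). Normal-brain H2O2 is not reported for this probe; a low
#' physiological level is used.
#'
#' @param stats Data frame with columns `class`, `gsh_mean`, `gsh_sd`,
#'   `h2o2_mean`, `h2o2_sd`.
#' @return A `sers_cohort` parameter object.
#' @export
cohort_params <- function(stats = data.frame(
                            class = c("normal", "WT", "MUT"),
                            gsh_mean = c(0.7, 12.08, 9.20),
                            gsh_sd = c(0.15, 0.53, 0.83),
                            h2o2_mean = c(15, 68.54, 109.3),
                            h2o2_sd = c(5, 4.51, 9.44),
                            stringsAsFactors = FALSE)) {
  stopifnot(all(c("class", "gsh_mean", "gsh_sd", "h2o2_mean", "h2o2_sd") %in% names(stats)),
            all(stats$gsh_sd >= 0), all(stats$h2o2_sd >= 0),
            all(stats$gsh_mean >= 0), all(stats$h2o2_mean >= 0))
  structure(list(stats = stats), class = "sers_cohort")
}

# Normal draw truncated at zero by rejection; sd = 0 returns the mean.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a point-scanned tissue grid for one or more classes
#'
#' Emulates point-by-point Raman scanning of tissue: each grid point draws
#' its true concentrations from the class's zero-truncated normal
#' distribution and a spectrum is simulated from them. Classes are laid out
#' side by side along the x axis (class k occupies columns
#' `(k-1)*cols + 1 .. k*cols`), so a two-class call yields adjacent
#' half-grids.
#'
#' @param cohort A `sers_cohort`.
#' @param classes Character vector of class names to simulate.
#' @param grid_shape `c(rows, cols)` per class.
#' @param probe,noise Simulator models.
#' @param seed Integer seed.
#' @return List of `sers_labeled_spectrum` with `tissue_class` and `grid_xy`.
#' @export
simulate_tissue_grid <- function(cohort = cohort_params(),
                                 classes = c("WT", "MUT"),
                                 grid_shape = c(10, 10),
                                 probe = probe_response_model(),
                                 noise = noise_model(),
                                 seed = 1L) {
  stopifnot(inherits(cohort, "sers_cohort"), all(grid_shape >= 1))
  st <- cohort$stats
  unknown <- setdiff(classes, st$class)
  if (length(unknown) > 0) stop("unknown tissue class: ", paste(unknown, collapse = ", "))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  out <- list()
  for (k in seq_along(classes)) {
    row <- st[st$class == classes[k], ]
    npt <- grid_shape[1] * grid_shape[2]
    gsh <- rtruncnorm0(npt, row$gsh_mean, row$gsh_sd)
    h2o2 <- rtruncnorm0(npt, row$h2o2_mean, row$h2o2_sd)
    coords <- expand.grid(y = seq_len(grid_shape[1]), x = seq_len(grid_shape[2]))
    for (i in seq_len(npt)) {
      out[[length(out) + 1]] <- simulate_spectrum(
        gsh[i], h2o2[i], probe, noise,
        tissue_class = classes[k],
        grid_xy = c(coords$x[i] + (k - 1) * grid_shape[2], coords$y[i]),
        id = sprintf("%s_x%02d_y%02d", classes[k],
                     coords$x[i] + (k - 1) * grid_shape[2], coords$y[i]))
    }
  }
  out
}
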