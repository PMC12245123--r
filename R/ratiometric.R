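#' Baseline-subtracted peak intensity
#'
#' Extracts a peak intensity as the maximum of the spectrum within
#' `center +/- half_window` after subtracting the straight line through the
#' window's two endpoint samples. The local linear baseline makes the
#' extraction robust to slowly varying background and small global offsets;
#' a flat spectrum yields exactly 0.
#'
#' @param s A `sers_spectrum`.
#' @param center Peak position in cm^-1 (must lie within the axis).
#' @param half_window Half-width of the extraction window in cm^-1.
#' @return The baseline-subtracted peak intensity (can be <= 0 for a peakless
#'   window).
#' @export
peak_intensity <- function(s, center, half_window = 15) {
  stopifnot(inherits(s, "sers_spectrum"), half_window > 0)
  wn <- s$wavenumbers
  if (center < wn[1] || center > wn[length(wn)])
    stop(sprintf("peak center %g cm^-1 outside axis range [%g, %g]",
                 center, wn[1], wn[length(wn)]))
  idx <- which(wn >= center - half_window & wn <= center + half_window)
  if (length(idx) < 3)
    stop(sprintf("window +/-%g cm^-1 around %g covers fewer than 3 points", half_window, center))
  w <- wn[idx]; y <- s$intensities[idx]
  k <- length(idx)
  slope <- (y[k] - y[1]) / (w[k] - w[1])
  baseline <- y[1] + slope * (w - w[1])
  max(y - baseline)
}

#' Ratiometric peak ratios of one spectrum
#'
#' Computes the two analyte ratios against the internal reference peak:
#' `r1 = I542/I928` (GSH channel) and `r2 = I628/I928` (H2O2 channel), with
#' peak intensities extracted by [peak_intensity()]. Because both channels
#' are normalized by the same reference, the ratios are invariant to global
#' intensity scaling -- the probe's self-calibration property.
#'
#' @param s A `sers_spectrum`.
#' @param peaks Named numeric vector with elements `gsh`, `h2o2`, `ref`
#'   (default 542, 628, 928 cm^-1).
#' @param half_window Extraction half-window in cm^-1.
#' @return A `sers_ratio`: list with `r1`, `r2` and optional `grid_xy`.
#' @export
compute_ratios <- function(s, peaks = c(gsh = 542, h2o2 = 628, ref = 928),
                           half_window = 15) {
  ls <- NULL
  if (inherits(s, "sers_labeled_spectrum")) { ls <- s; s <- s$spectrum }
  i_ref <- peak_intensity(s, peaks[["ref"]], half_window)
  if (!is.finite(i_ref) || i_ref <= 0)
    stop("reference peak intensity is not positive; point must be masked")
  structure(list(r1 = peak_intensity(s, peaks[["gsh"]], half_window) / i_ref,
                 r2 = peak_intensity(s, peaks[["h2o2"]], half_window) / i_ref,
                 grid_xy = if (!is.null(ls)) ls$grid_xy else NULL),
            class = "sers_ratio")
}

#' Fit a linear ratio-vs-concentration calibration
#'
#' Ordinary least squares of peak ratio on concentration across calibration
#' standards. The fitted line's sign is checked against the probe's known
#' response direction: the GSH channel must have a positive slope, the H2O2
#' channel a negative one; a wrong sign signals a channel mix-up and is an
#' error. The concentration range of the standards is stored as the
#' validity range for later extrapolation flagging.
#'
#' @param ratios Numeric vector of measured ratios.
#' @param concs Numeric vector of concentrations (>= 3 distinct values).
#' @param metabolite `"GSH"` or `"H2O2"`.
#' @return A `sers_calibration` with `slope`, `intercept`, `range`, `fit_r2`.
#' @export
fit_calibration <- function(ratios, concs, metabolite = c("GSH", "H2O2")) {
  metabolite <- match.arg(metabolite)
  stopifnot(length(ratios) == length(concs))
  if (length(unique(concs)) < 3)
    stop("calibration needs at least 3 distinct concentrations")
  fit <- stats::lm(ratios ~ concs)
  fit_r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ratios - mean(ratios))^2)
  slope <- unname(stats::coef(fit)[2])
  if (metabolite == "GSH" && slope <= 0)
    stop("GSH calibration slope must be positive; channels may be swapped")
  if (metabolite == "H2O2" && slope >= 0)
    stop("H2O2 calibration slope must be negative; channels may be swapped")
  structure(list(metabolite = metabolite,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 range = range(concs),
                 fit_r2 = fit_r2),
            class = "sers_calibration")
}

#' @export
print.sers_calibration <- function(x, ...) {
  cat(sprintf("<calibration %s> ratio = %.5g %+.5g * c, valid %g-%g, R2 %.4f\n",
              x$metabolite, x$intercept, x$slope, x$range[1], x$range[2], x$fit_r2))
  invisible(x)
}

#' Invert calibrations to concentrations
#'
#' Applies the inverse fitting formula `c = (ratio - intercept) / slope` to
#' a ratio measurement for each metabolite. Results outside the calibration
#' range are flagged `extrapolated`; negative inversions are clipped to 0
#' and flagged `clipped`.
#'
#' @param m A `sers_ratio`.
#' @param cal_gsh GSH `sers_calibration`.
#' @param cal_h2o2 H2O2 `sers_calibration`.
#' @return List with `c_gsh` (mM), `c_h2o2` (uM) and character vector
#'   `flags`.
#' @export
quantify <- function(m, cal_gsh, cal_h2o2) {
  stopifnot(inherits(m, "sers_ratio"),
            inherits(cal_gsh, "sers_calibration"),
            inherits(cal_h2o2, "sers_calibration"))
  if (cal_gsh$slope == 0 || cal_h2o2$slope == 0) stop("zero calibration slope")
  invert <- function(r, cal) {
    c0 <- (r - cal$intercept) / cal$slope
    flags <- character(0)
    if (c0 < cal$range[1] || c0 > cal$range[2]) flags <- "extrapolated"
    if (c0 < 0) { c0 <- 0; flags <- c(flags, "clipped") }
    if (c0 == 0) flags <- unique(c(flags, "boundary"))
    list(c = c0, flags = flags)
  }
  g <- invert(m$r1, cal_gsh)
  h <- invert(m$r2, cal_h2o2)
  flags <- unique(c(if (length(g$flags)) paste0("gsh_", g$flags),
                    if (length(h$flags)) paste0("h2o2_", h$flags)))
  list(c_gsh = g$c, c_h2o2 = h$c,
       flags = if (is.null(flags)) character(0) else flags)
}

#' Spatial concentration map from point measurements
#'
#' Quantifies every ratio measurement that carries a grid coordinate and
#' assembles a long-format map with one row per grid cell: GSH (mM), H2O2
#' (uM) and their H2O2/GSH ratio layer. Cells never visited, and points
#' whose reference peak failed (passed as `NA` measurements), are masked.
#' The ratio layer is computed from quantified concentrations (uM/mM) by
#' default; `layer = "raw_ratio"` uses the raw `r2/r1` peak-ratio quotient
#' instead for sensitivity analysis.
#'
#' @param points List of `sers_ratio` with non-`NULL`, unique `grid_xy`
#'   (or `NA` entries for masked points).
#' @param cal_gsh,cal_h2o2 Fitted calibrations.
#' @param layer `"concentration"` (default) or `"raw_ratio"` for the
#'   H2O2/GSH layer.
#' @return A `sers_map`: data.frame with columns `x`, `y`, `c_gsh`,
#'   `c_h2o2`, `h2o2_gsh`, `mask` covering the bounding grid.
#' @export
build_map <- function(points, cal_gsh, cal_h2o2,
                      layer = c("concentration", "raw_ratio")) {
  layer <- match.arg(layer)
  keep <- !vapply(points, function(p) length(p) == 1 && is.na(p), logical(1))
  pts <- points[keep]
  xy <- t(vapply(pts, function(p) {
    if (is.null(p$grid_xy)) stop("all map points need grid coordinates")
    as.numeric(p$grid_xy)
  }, numeric(2)))
  if (anyDuplicated(xy)) stop("duplicate grid coordinates in map points")
  grid <- expand.grid(x = seq_len(max(xy[, 1])), y = seq_len(max(xy[, 2])))
  grid$c_gsh <- NA_real_; grid$c_h2o2 <- NA_real_; grid$h2o2_gsh <- NA_real_
  grid$mask <- TRUE
  for (i in seq_along(pts)) {
    q <- quantify(pts[[i]], cal_gsh, cal_h2o2)
    j <- which(grid$x == xy[i, 1] & grid$y == xy[i, 2])
    grid$c_gsh[j] <- q$c_gsh
    grid$c_h2o2[j] <- q$c_h2o2
    grid$h2o2_gsh[j] <- if (layer == "concentration") {
      if (q$c_gsh > 0) q$c_h2o2 / q$c_gsh else NA_real_
    } else {
      if (pts[[i]]$r1 > 0) pts[[i]]$r2 / pts[[i]]$r1 else NA_real_
    }
    grid$mask[j] <- !is.finite(grid$h2o2_gsh[j])
  }
  structure(grid, class = c("sers_map", "data.frame"))
}
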