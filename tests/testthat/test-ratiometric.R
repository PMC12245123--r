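test_that("peak extraction recovers an isolated narrow Lorentzian amplitude", {
  wn <- seq(450, 650, by = 0.5)
  A <- 3.2; gamma <- 1
  s <- sers_spectrum(wn, A / (1 + ((wn - 542) / gamma)^2))
  expect_equal(peak_intensity(s, 542, 15), A, tolerance = 0.01)
  # flat spectrum -> exactly 0 after baseline subtraction
  flat <- sers_spectrum(wn, rep(2.5, length(wn)))
  expect_equal(peak_intensity(flat, 542, 15), 0)
  # peak outside the window contributes only its (subtracted) tail
  expect_lt(abs(peak_intensity(s, 610, 15)), 0.02 * A)
  expect_error(peak_intensity(s, 900, 15), "outside axis")
})

test_that("baseline subtraction removes linear background", {
  wn <- seq(450, 650, by = 0.5)
  A <- 2
  base <- 0.4 + 0.003 * (wn - 450)
  s <- sers_spectrum(wn, base + A / (1 + (wn - 542)^2))
  expect_equal(peak_intensity(s, 542, 15), A, tolerance = 0.01)
})

test_that("ratios are scale-invariant and match construction", {
  wn <- seq(400, 1100, by = 1)
  mk <- function(scale) {
    y <- 1 / (1 + (wn - 542)^2) + 1 / (1 + (wn - 628)^2) + 1 / (1 + (wn - 928)^2)
    sers_spectrum(wn, scale * y)
  }
  r <- compute_ratios(mk(1))
  expect_equal(r$r1, 1, tolerance = 1e-3)  # residual cross-peak tails ~1e-4
  expect_equal(r$r2, 1, tolerance = 1e-3)
  r2 <- compute_ratios(mk(17.3))
  expect_equal(r$r1, r2$r1)
  expect_equal(r$r2, r2$r2)
})

test_that("noiseless simulator ratios equal the closed-form response", {
  probe <- probe_response_model()
  s <- simulate_spectrum(10, 100, probe, noiseless())
  r <- compute_ratios(max_normalize(s$spectrum))
  ex <- probe_expected_ratios(probe, 10, 100)
  expect_equal(r$r1, ex$r1, tolerance = 0.005)
  expect_equal(r$r2, ex$r2, tolerance = 0.005)
})

test_that("calibration fitting recovers exact lines and enforces signs", {
  x <- c(2, 4, 6, 8, 10, 16)
  cal <- fit_calibration(0.2 + 0.05 * x, x, "GSH")
  expect_equal(cal$slope, 0.05)
  expect_equal(cal$intercept, 0.2)
  expect_equal(cal$fit_r2, 1)
  expect_equal(cal$range, c(2, 16))
  expect_error(fit_calibration(c(1, 2), c(1, 2), "GSH"), "3 distinct")
  expect_error(fit_calibration(0.2 - 0.01 * x, x, "GSH"), "positive")
  expect_error(fit_calibration(0.2 + 0.01 * x, x, "H2O2"), "negative")
})

test_that("noiseless calibration recovers the simulator's configured slopes", {
  probe <- probe_response_model()
  pk <- probe$peaks
  base542 <- pk$base[pk$center == 542]
  base628 <- pk$base[pk$center == 628]
  base928 <- pk$base[pk$center == 928]
  gl <- c(2, 4, 6, 8, 10, 16); hl <- c(1, 25, 50, 75, 100, 125, 150, 200)
  # closed-form ratio responses: OLS recovery is exact
  r1 <- vapply(gl, function(g) probe_expected_ratios(probe, g, 50)$r1, numeric(1))
  cal_exact <- fit_calibration(r1, gl, "GSH")
  expect_equal(cal_exact$slope, base542 * probe$gsh_slope / base928, tolerance = 1e-12)
  r2 <- vapply(hl, function(h) probe_expected_ratios(probe, 8, h)$r2, numeric(1))
  cal_exact_h <- fit_calibration(r2, hl, "H2O2")
  expect_equal(cal_exact_h$slope, -base628 * probe$h2o2_slope / base928, tolerance = 1e-12)
  # full spectral route (extraction included) agrees closely
  r1s <- vapply(gl, function(g)
    compute_ratios(simulate_spectrum(g, 50, probe, noiseless())$spectrum)$r1, numeric(1))
  cal_sp <- fit_calibration(r1s, gl, "GSH")
  expect_equal(cal_sp$slope, cal_exact$slope, tolerance = 0.01)
})

test_that("quantify inverts the calibration lines with flags", {
  cal_g <- fit_calibration(0.2 + 0.05 * c(2, 10, 16), c(2, 10, 16), "GSH")
  cal_h <- fit_calibration(1.5 - 0.005 * c(1, 100, 200), c(1, 100, 200), "H2O2")
  m <- structure(list(r1 = 0.7, r2 = 1.0, grid_xy = NULL), class = "sers_ratio")
  q <- quantify(m, cal_g, cal_h)
  expect_equal(q$c_gsh, 10)
  expect_equal(q$c_h2o2, 100)
  expect_length(q$flags, 0)
  # ratio at the intercept -> concentration 0, boundary flag
  m0 <- structure(list(r1 = 0.2, r2 = 1.0), class = "sers_ratio")
  q0 <- quantify(m0, cal_g, cal_h)
  expect_equal(q0$c_gsh, 0)
  expect_true(any(grepl("boundary", q0$flags)))
  # below the intercept -> clipped
  qneg <- quantify(structure(list(r1 = 0.1, r2 = 1.0), class = "sers_ratio"),
                   cal_g, cal_h)
  expect_equal(qneg$c_gsh, 0)
  expect_true(any(grepl("clipped", qneg$flags)))
  # outside the calibration range -> extrapolated
  qex <- quantify(structure(list(r1 = 2.0, r2 = 1.0), class = "sers_ratio"),
                  cal_g, cal_h)
  expect_true(any(grepl("extrapolated", qex$flags)))
})

test_that("quantify is monotone in both ratio channels", {
  cal_g <- fit_calibration(0.2 + 0.05 * c(2, 10, 16), c(2, 10, 16), "GSH")
  cal_h <- fit_calibration(1.5 - 0.005 * c(1, 100, 200), c(1, 100, 200), "H2O2")
  q_at <- function(r1, r2) quantify(structure(list(r1 = r1, r2 = r2),
                                              class = "sers_ratio"), cal_g, cal_h)
  expect_gt(q_at(0.9, 1)$c_gsh, q_at(0.5, 1)$c_gsh)
  expect_lt(q_at(0.5, 1.2)$c_h2o2, q_at(0.5, 0.8)$c_h2o2)
})

test_that("round trip quantify(simulate) is within 1% on the noiseless grid", {
  probe <- probe_response_model()
  grid <- expand.grid(g = c(2, 4, 6, 8, 10, 16),
                      h = c(1, 25, 50, 75, 100, 125, 150, 200))
  pts <- lapply(seq_len(nrow(grid)), function(i)
    compute_ratios(max_normalize(
      simulate_spectrum(grid$g[i], grid$h[i], probe, noiseless())$spectrum)))
  cal_g <- fit_calibration(vapply(pts, function(p) p$r1, numeric(1)), grid$g, "GSH")
  cal_h <- fit_calibration(vapply(pts, function(p) p$r2, numeric(1)), grid$h, "H2O2")
  for (i in seq_len(nrow(grid))) {
    q <- quantify(pts[[i]], cal_g, cal_h)
    expect_lt(abs(q$c_gsh - grid$g[i]) / grid$g[i], 0.01)
    expect_lt(abs(q$c_h2o2 - grid$h[i]) / grid$h[i], 0.01)
  }
})

test_that("maps carry concentrations, the ratio layer and masks", {
  cal_g <- fit_calibration(0.2 + 0.05 * c(2, 10, 16), c(2, 10, 16), "GSH")
  cal_h <- fit_calibration(1.5 - 0.005 * c(1, 100, 200), c(1, 100, 200), "H2O2")
  pt <- function(r1, r2, x, y)
    structure(list(r1 = r1, r2 = r2, grid_xy = c(x, y)), class = "sers_ratio")
  pts <- list(pt(0.7, 1.0, 1, 1), pt(0.7, 1.0, 2, 1),
              pt(0.7, 1.0, 1, 2), NA)
  m <- build_map(pts, cal_g, cal_h)
  expect_equal(nrow(m), 4)             # bounding 2 x 2 grid
  filled <- !m$mask
  expect_equal(sum(filled), 3)
  expect_equal(m$c_gsh[filled], rep(10, 3))
  expect_equal(m$h2o2_gsh[filled], rep(10, 3))   # 100 uM / 10 mM
  expect_true(all(is.na(m$c_gsh[m$mask])))
  # raw-ratio layer mode divides the peak ratios instead
  m2 <- build_map(pts[1:3], cal_g, cal_h, layer = "raw_ratio")
  expect_equal(m2$h2o2_gsh[!m2$mask], rep(1 / 0.7, 3), tolerance = 1e-12)
  expect_error(build_map(list(pt(0.7, 1, 1, 1), pt(0.6, 1, 1, 1)), cal_g, cal_h),
               "duplicate")
})

test_that("MUT half-grids show the higher H2O2/GSH layer", {
  probe <- probe_response_model()
  grid <- simulate_tissue_grid(cohort_params(), c("WT", "MUT"), c(4, 4),
                               probe, noise_model(), seed = 5)
  pts <- lapply(preprocess_spectra(grid), compute_ratios)
  gl <- c(2, 4, 6, 8, 10, 16); hl <- c(1, 25, 50, 75, 100, 125, 150, 200)
  cal_g <- fit_calibration(vapply(gl, function(g) probe_expected_ratios(probe, g, 50)$r1,
                                  numeric(1)), gl, "GSH")
  cal_h <- fit_calibration(vapply(hl, function(h) probe_expected_ratios(probe, 8, h)$r2,
                                  numeric(1)), hl, "H2O2")
  m <- build_map(pts, cal_g, cal_h)
  wt_half <- m$x <= 4; mut_half <- m$x > 4
  expect_gt(mean(m$h2o2_gsh[mut_half], na.rm = TRUE),
            mean(m$h2o2_gsh[wt_half], na.rm = TRUE))
})
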