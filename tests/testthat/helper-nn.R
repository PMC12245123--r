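# Finite-difference gradient check of a layer stack. Compares the analytic
# input gradient and parameter gradients against central differences at a
# random subset of coordinates.
grad_check <- function(layers, x, n_coords = 12, eps = 1e-5, tol = 1e-4) {
  ns <- asNamespace("sersquant")
  fwd <- function(xx) {
    h <- xx
    for (l in layers) h <- l$forward(h, TRUE)
    h
  }
  out <- fwd(x)
  dout <- array(rnorm(length(out)), dim(out))
  d <- dout
  for (l in rev(layers)) d <- l$backward(d)
  ok <- TRUE
  for (i in sample(length(x), min(n_coords, length(x)))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g <- sum(dout * (fwd(xp) - fwd(xm))) / (2 * eps)
    if (abs(g - d[i]) > tol * max(1, abs(g))) ok <- FALSE
  }
  for (l in ns$flatten_layers(layers)) {
    for (p in l$param_names) {
      w <- l[[p]]
      gw <- l[[paste0("g", p)]]
      for (i in sample(length(w), min(6, length(w)))) {
        wp <- w; wp[i] <- wp[i] + eps
        assign(p, wp, envir = l); fp <- sum(dout * fwd(x))
        wm <- w; wm[i] <- wm[i] - eps
        assign(p, wm, envir = l); fm <- sum(dout * fwd(x))
        assign(p, w, envir = l)
        g <- (fp - fm) / (2 * eps)
        if (abs(g - gw[i]) > tol * max(1, abs(g))) ok <- FALSE
      }
    }
  }
  ok
}

# Tiny noiseless toy dataset for memorization tests: 2 x 2 concentration
# grid, short spectra. Peaks are widened so the coarse toy axis still
# samples every band.
toy_problem <- function(n_points = 64, replicates = 8) {
  pk <- default_peak_table()
  pk$width <- 15
  probe <- probe_response_model(axis = seq(400, 1800, length.out = n_points),
                                peaks = pk)
  ds <- preprocess_spectra(build_calibration_dataset(
    c(2, 16), c(25, 200), replicates, probe, noiseless(), seed = 5))
  mats <- spectra_to_matrix(ds)
  n <- nrow(mats$x)
  split <- split_dataset(n, 0.25, 0.25, seed = 5,
                         strata = paste(mats$y[, 1], mats$y[, 2]))
  list(mats = mats, split = split)
}
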