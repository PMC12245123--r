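# Shared fixtures, built in code at test time.

noiseless <- function() noise_model(0, c(0, 0, 0))

# Small probe on a coarse axis for fast tests that do not extract ratios.
coarse_probe <- function(n = 128) {
  probe_response_model(axis = seq(400, 1800, length.out = n))
}

# A tiny labeled noiseless grid dataset (2 GSH x 2 H2O2 x r replicates).
tiny_grid <- function(replicates = 2, probe = probe_response_model(),
                      noise = noiseless(), seed = 11) {
  build_calibration_dataset(c(2, 10), c(25, 150), replicates,
                            probe = probe, noise = noise, seed = seed)
}

# Write a spectra table + manifest into a tempdir; returns the two paths.
write_tiny_table <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sp <- tiny_grid()
  paths <- list(spectra = file.path(dir, "spectra.csv"),
                manifest = file.path(dir, "manifest.csv"))
  write_spectra_table(sp, paths$spectra, paths$manifest)
  paths
}

# Brute-force AUC oracle: enumerate every positive-negative pair,
# counting ties as 1/2.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# Direct Eq.-style RPM oracle: double loop over index pairs.
rpm_by_loops <- function(x) {
  m <- length(x)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) out[i, j] <- x[i] - x[j]
  out
}
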