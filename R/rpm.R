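#' Relative Position Matrix of a spectrum
#'
#' Encodes a 1D spectrum of length M as the M x M image of pairwise
#' intensity differences, `RPM[i, j] = x_i - x_j`. The matrix is
#' antisymmetric with a zero diagonal, invariant to constant intensity
#' offsets, and homogeneous of degree 1 in the intensities. It is the 2D
#' input representation consumed by the image-based regression models.
#'
#' By default the transform is applied to the preprocessed (cropped,
#' max-normalized) intensity vector; no further rescaling of the signed
#' values is performed.
#'
#' @param s A `sers_spectrum`, or a numeric intensity vector of length >= 2.
#' @return An `rpm_image`: list with the M x M `matrix` and `source_length`.
#' @examples
#' rpm(c(1, 2, 4))$matrix
#' @export
rpm <- function(s) {
  x <- if (inherits(s, "sers_spectrum")) s$intensities else as.numeric(s)
  if (length(x) < 2) stop("rpm needs at least 2 points")
  if (any(!is.finite(x))) stop("rpm needs finite intensities")
  structure(list(matrix = outer(x, x, "-"), source_length = length(x)),
            class = "rpm_image")
}

#' @export
print.rpm_image <- function(x, ...) {
  cat(sprintf("<rpm_image> %d x %d\n", x$source_length, x$source_length))
  invisible(x)
}

#' Write an RPM image to a plain text matrix file (debug export)
#'
#' @param img An `rpm_image`.
#' @param path Output path; tab-separated values, one matrix row per line.
#' @return `path`, invisibly.
#' @export
write_rpm <- function(img, path) {
  stopifnot(inherits(img, "rpm_image"))
  utils::write.table(img$matrix, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Batched RPM: spectra as rows of `x` (N x M) -> array (N, M, M).
# RPM[i, j] = x_i - x_j per spectrum, vectorized across the batch.
rpm_batch <- function(x) {
  n <- nrow(x); m <- ncol(x)
  a <- array(0, c(n, m, m))
  xi <- array(rep(x, times = m), c(n, m, m))          # varies over dim 2
  xj <- aperm(xi, c(1, 3, 2))                          # varies over dim 3
  a <- xi - xj
  a
}
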