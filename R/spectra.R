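#' Construct a Raman spectrum
#'
#' A spectrum is a wavenumber axis (cm^-1, strictly increasing) paired with a
#' vector of non-negative intensities (arbitrary counts). This is the basic
#' container every other function in the package consumes.
#'
#' @param wavenumbers Numeric vector of cm^-1 values, strictly increasing.
#'   A single point is legal (it can arise from cropping) but most analyses
#'   require length >= 2.
#' @param intensities Numeric vector of finite intensities of the same length
#'   (arbitrary counts; baseline-subtracted or noisy spectra may dip slightly
#'   below zero).
#' @return An object of class `sers_spectrum` with fields `wavenumbers` and
#'   `intensities`.
#' @examples
#' s <- sers_spectrum(c(540, 542, 544), c(0.1, 1, 0.1))
#' length(s$intensities)
#' @export
sers_spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have identical length")
  if (length(wavenumbers) < 1)
    stop("a spectrum needs at least 1 point")  # single points arise from crops; most analyses need >= 2
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be finite and strictly increasing")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Attach ground-truth labels to a spectrum
#'
#' Wraps a spectrum together with the quantities the calibration and
#' genotyping stages need: GSH concentration (mM), H2O2 concentration (uM),
#' a tissue class and an optional integer grid coordinate for spatial maps.
#' Any label may be missing (`NA`/`NULL`).
#'
#' @param spectrum A `sers_spectrum`.
#' @param c_gsh GSH concentration in mM (>= 0) or `NA`.
#' @param c_h2o2 H2O2 concentration in uM (>= 0) or `NA`.
#' @param tissue_class One of `"normal"`, `"WT"`, `"MUT"` or `NA`.
#' @param grid_xy Integer vector `c(x, y)` or `NULL`.
#' @param id Optional acquisition identifier.
#' @return A `sers_labeled_spectrum`.
#' @export
labeled_spectrum <- function(spectrum, c_gsh = NA_real_, c_h2o2 = NA_real_,
                             tissue_class = NA_character_, grid_xy = NULL,
                             id = NA_character_) {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  if (!is.na(c_gsh) && c_gsh < 0) stop("c_gsh must be >= 0")
  if (!is.na(c_h2o2) && c_h2o2 < 0) stop("c_h2o2 must be >= 0")
  if (!is.na(tissue_class) &&
      !tissue_class %in% c("normal", "WT", "MUT"))
    stop("tissue_class must be one of 'normal', 'WT', 'MUT'")
  if (!is.null(grid_xy)) {
    grid_xy <- as.integer(grid_xy)
    if (length(grid_xy) != 2 || any(is.na(grid_xy)))
      stop("grid_xy must be an integer pair")
  }
  structure(list(spectrum = spectrum,
                 c_gsh = as.numeric(c_gsh), c_h2o2 = as.numeric(c_h2o2),
                 tissue_class = as.character(tissue_class),
                 grid_xy = grid_xy, id = as.character(id)),
            class = "sers_labeled_spectrum")
}

#' Read a delimited spectra table (plus optional label manifest)
#'
#' The canonical on-disk format is a delimited text table whose first column
#' is the wavenumber axis and whose remaining columns hold one acquisition
#' each. Comma or tab separation is auto-detected and `#` comment lines are
#' skipped. An optional manifest CSV with columns
#' `id,c_gsh_mM,c_h2o2_uM,tissue_class,grid_x,grid_y` attaches labels by
#' column name (blank cells mean missing).
#'
#' @param path Path to the spectra table.
#' @param manifest Optional path to the manifest CSV.
#' @return A list of `sers_labeled_spectrum`, one per intensity column, in
#'   column order.
#' @export
read_spectra_table <- function(path, manifest = NULL) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("spectra table needs a wavenumber column plus at least one intensity column")
  for (j in seq_len(ncol(tab))) {
    v <- tab[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric cell in column '%s', data row %d of %s",
                   names(tab)[j], if (is.na(bad)) 1L else bad, path))
    }
  }
  wn <- tab[[1]]
  man <- NULL
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!"id" %in% names(man)) stop("manifest must have an 'id' column")
  }
  lapply(names(tab)[-1], function(id) {
    sp <- sers_spectrum(wn, tab[[id]])
    if (is.null(man)) return(labeled_spectrum(sp, id = id))
    row <- man[man$id == id, , drop = FALSE]
    if (nrow(row) == 0)
      return(labeled_spectrum(sp, id = id))
    grab <- function(col) {
      if (!col %in% names(row)) return(NA)
      v <- row[[col]][1]
      if (is.null(v) || (is.character(v) && !nzchar(v))) NA else v
    }
    gx <- grab("grid_x"); gy <- grab("grid_y")
    labeled_spectrum(sp,
                     c_gsh = as.numeric(grab("c_gsh_mM")),
                     c_h2o2 = as.numeric(grab("c_h2o2_uM")),
                     tissue_class = as.character(grab("tissue_class")),
                     grid_xy = if (!is.na(gx) && !is.na(gy)) c(gx, gy) else NULL,
                     id = id)
  })
}

#' Write spectra (and their labels) to the canonical text format
#'
#' @param spectra List of `sers_labeled_spectrum` sharing one axis.
#' @param path Output path for the spectra table (CSV).
#' @param manifest_path Optional output path for the label manifest CSV.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path, manifest_path = NULL) {
  stopifnot(length(spectra) >= 1)
  wn <- spectra[[1]]$spectrum$wavenumbers
  ids <- vapply(seq_along(spectra), function(i) {
    id <- spectra[[i]]$id
    if (is.na(id)) sprintf("s%04d", i) else id
  }, character(1))
  ids <- make.unique(ids, sep = "_")
  mat <- vapply(spectra, function(ls) {
    if (length(ls$spectrum$intensities) != length(wn))
      stop("all spectra must share one axis to be written together")
    ls$spectrum$intensities
  }, numeric(length(wn)))
  out <- data.frame(wavenumber = wn, mat, check.names = FALSE)
  names(out) <- c("wavenumber", ids)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    man <- data.frame(
      id = ids,
      c_gsh_mM = vapply(spectra, function(l) l$c_gsh, numeric(1)),
      c_h2o2_uM = vapply(spectra, function(l) l$c_h2o2, numeric(1)),
      tissue_class = vapply(spectra, function(l) l$tissue_class, character(1)),
      grid_x = vapply(spectra, function(l) if (is.null(l$grid_xy)) NA_integer_ else l$grid_xy[1], integer(1)),
      grid_y = vapply(spectra, function(l) if (is.null(l$grid_xy)) NA_integer_ else l$grid_xy[2], integer(1))
    )
    utils::write.csv(man, manifest_path, row.names = FALSE)
  }
  invisible(path)
}

detect_sep <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(lines)]
  if (length(lines) == 0) stop("empty spectra table: ", path)
  if (grepl("\t", lines[1])) "\t" else ","
}

#' Keep an index window of a spectrum
#'
#' Crops a spectrum to points `start_index .. end_index`, 1-based and
#' inclusive on both ends, so `crop_window(s, 50, 336)` keeps the 50th to
#' 336th points (287 points) -- the index convention used when trimming
#' instrument spectra before modeling.
#'
#' @param s A `sers_spectrum`.
#' @param start_index,end_index 1-based point indices, `1 <= start <= end <= M`.
#' @return The cropped `sers_spectrum`.
#' @export
crop_window <- function(s, start_index, end_index) {
  stopifnot(inherits(s, "sers_spectrum"))
  m <- length(s$intensities)
  if (start_index < 1 || end_index > m || start_index > end_index)
    stop(sprintf("crop window (%d, %d) out of range for a %d-point spectrum",
                 start_index, end_index, m))
  idx <- start_index:end_index
  sers_spectrum(s$wavenumbers[idx], s$intensities[idx])
}

#' Normalize a spectrum by its maximum intensity
#'
#' Divides every intensity by the spectrum maximum, so the normalized maximum
#' is exactly 1. The operation is idempotent and invariant to positive
#' rescaling of the input.
#'
#' @param s A `sers_spectrum` with positive maximum intensity.
#' @return The normalized `sers_spectrum`.
#' @export
max_normalize <- function(s) {
  stopifnot(inherits(s, "sers_spectrum"))
  mx <- max(s$intensities)
  if (!is.finite(mx) || mx <= 0)
    stop("max_normalize needs a positive maximum intensity")
  sers_spectrum(s$wavenumbers, s$intensities / mx)
}

#' Apply the standard preprocessing to labeled spectra
#'
#' Optional index-window crop followed by max normalization, applied to each
#' record's spectrum while labels are carried through unchanged.
#'
#' @param spectra List of `sers_labeled_spectrum`.
#' @param crop `NULL` or `c(start_index, end_index)` (1-based inclusive).
#' @return List of preprocessed `sers_labeled_spectrum`.
#' @export
preprocess_spectra <- function(spectra, crop = NULL) {
  lapply(spectra, function(ls) {
    s <- ls$spectrum
    if (!is.null(crop)) s <- crop_window(s, crop[1], crop[2])
    ls$spectrum <- max_normalize(s)
    ls
  })
}

#' Train/validation/test split of a dataset
#'
#' Draws `round(n * test_frac)` test records first, then
#' `round(n_rest * val_frac_of_rest)` validation records from the remainder
#' (R's round-half-to-even rule), leaving the rest as training data. With the
#' standard fractions (`0.2` test, then 1/10 of the rest for validation) a
#' 9600-record calibration database splits 6912/768/1920.
#'
#' When `strata` is supplied (e.g. the concentration pair of each record) the
#' split is stratified: each stratum contributes to every part in proportion
#' to its size, with largest-remainder apportionment so the global part sizes
#' are exactly the unstratified ones.
#'
#' @param n Number of records.
#' @param test_frac Fraction held out as the test set (0 < f < 1).
#' @param val_frac_of_rest Fraction of the non-test records used for
#'   validation (0 < f < 1).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param strata Optional length-`n` vector of stratum labels.
#' @return A `sers_split`: list with integer index vectors `train`, `val`,
#'   `test` (disjoint, covering `1..n`) plus the `seed`.
#' @export
split_dataset <- function(n, test_frac = 0.2, val_frac_of_rest = 0.1,
                          seed = 1L, strata = NULL) {
  stopifnot(n >= 3, test_frac > 0, test_frac < 1,
            val_frac_of_rest > 0, val_frac_of_rest < 1)
  n_test <- round(n * test_frac)
  n_val <- round((n - n_test) * val_frac_of_rest)
  if (n_test < 1 || n_val < 1 || n - n_test - n_val < 1)
    stop("n too small for non-empty train/val/test parts")
  if (!is.null(strata) && length(strata) != n)
    stop("strata must have length n")

  old <- local_seed(seed)
  on.exit(restore_seed(old))

  if (is.null(strata)) {
    perm <- sample.int(n)
    test <- perm[seq_len(n_test)]
    val <- perm[n_test + seq_len(n_val)]
    train <- perm[-seq_len(n_test + n_val)]
  } else {
    groups <- split(seq_len(n), as.character(strata))
    groups <- lapply(groups, function(g) g[sample.int(length(g))])
    take <- function(sizes, total) {
      # largest-remainder apportionment of `total` across strata
      ideal <- sizes * total / sum(sizes)
      base <- floor(ideal)
      left <- total - sum(base)
      if (left > 0) {
        ord <- order(ideal - base, decreasing = TRUE)
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
      }
      base
    }
    sizes <- vapply(groups, length, integer(1))
    t_take <- take(sizes, n_test)
    rest <- sizes - t_take
    v_take <- take(rest, n_val)
    test <- integer(0); val <- integer(0); train <- integer(0)
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      test <- c(test, g[seq_len(t_take[i])])
      val <- c(val, g[t_take[i] + seq_len(v_take[i])])
      train <- c(train, g[-seq_len(t_take[i] + v_take[i])])
    }
  }
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 seed = as.integer(seed)),
            class = "sers_split")
}

#' Stack labeled spectra into a numeric design matrix and label table
#'
#' @param spectra List of `sers_labeled_spectrum` sharing one axis.
#' @return List with `x` (N x M intensity matrix), `y` (N x 2 matrix:
#'   c_gsh mM, c_h2o2 uM), `wavenumbers`, and `labels` (data.frame with all
#'   label fields).
#' @export
spectra_to_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  m <- length(spectra[[1]]$spectrum$intensities)
  x <- t(vapply(spectra, function(l) {
    v <- l$spectrum$intensities
    if (length(v) != m) stop("spectra have differing lengths")
    v
  }, numeric(m)))
  labels <- data.frame(
    id = vapply(spectra, function(l) l$id, character(1)),
    c_gsh = vapply(spectra, function(l) l$c_gsh, numeric(1)),
    c_h2o2 = vapply(spectra, function(l) l$c_h2o2, numeric(1)),
    tissue_class = vapply(spectra, function(l) l$tissue_class, character(1)),
    stringsAsFactors = FALSE
  )
  list(x = x, y = cbind(c_gsh = labels$c_gsh, c_h2o2 = labels$c_h2o2),
       wavenumbers = spectra[[1]]$spectrum$wavenumbers, labels = labels)
}
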