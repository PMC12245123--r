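# Internal helpers: scoped RNG state and seed fan-out.

# Set the RNG to `seed`, returning the previous state so callers can restore
# it on exit. Keeps user-level RNG streams untouched by package internals.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a per-stage seed from a global seed
#'
#' One pipeline-level seed fans out to independent stage seeds through a
#' fixed linear-congruential mix, so stages stay reproducible without sharing
#' one RNG stream. Results stay below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character) or index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * (seq_len(nchar(stage)) %% 97 + 1))
  } else as.numeric(stage)
  mixed <- ((as.numeric(seed) %% 2147483647) * 69069 + h * 10007) %% 2147483647
  as.integer(mixed)  # products stay below 2^53, so the double arithmetic is exact
}

# Polynomial rolling hash of a character vector; used for config fingerprints
# in run manifests (no external digest dependency). Arithmetic stays below
# 2^53 so doubles are exact.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
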