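# Minimal matrix-based neural-network engine.
#
# Layers are environments exposing forward()/backward() plus named parameter
# fields (W, b, ...) and matching gradient fields (gW, gb, ...). Convolutions
# are evaluated as matrix products through im2col patch extraction so all the
# heavy lifting is done by BLAS. Composite layers (residual blocks) hold
# sublayers and delegate. Everything is double precision, batch-first:
#   2D tensors: array (N, H, W, C);  1D tensors: array (N, L, C).

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$param_names <- character(0)
  e$sublayers <- NULL
  e
}

he_init <- function(n, fan_in) {
  stats::rnorm(n, 0, sqrt(2 / fan_in))
}

# ---- im2col for 2D tensors -------------------------------------------------

pad2d <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  xp
}

im2col2d <- function(xp, k, stride, out_h, out_w) {
  d <- dim(xp); n <- d[1]; ch <- d[4]
  cols <- matrix(0, n * out_h * out_w, k * k * ch)
  ri <- stride * (seq_len(out_h) - 1)
  rj <- stride * (seq_len(out_w) - 1)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      block <- xp[, ki + ri, kj + rj, , drop = FALSE]
      dim(block) <- c(n * out_h * out_w, ch)
      cols[, ((ki - 1) * k + (kj - 1)) * ch + seq_len(ch)] <- block
    }
  }
  cols
}

col2im2d <- function(dcols, dims_p, k, stride, out_h, out_w) {
  n <- dims_p[1]; ch <- dims_p[4]
  dxp <- array(0, dims_p)
  ri <- stride * (seq_len(out_h) - 1)
  rj <- stride * (seq_len(out_w) - 1)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      block <- dcols[, ((ki - 1) * k + (kj - 1)) * ch + seq_len(ch), drop = FALSE]
      dim(block) <- c(n, out_h, out_w, ch)
      dxp[, ki + ri, kj + rj, ] <- dxp[, ki + ri, kj + rj, , drop = FALSE] + block
    }
  }
  dxp
}

layer_conv2d <- function(in_ch, out_ch, k = 3, stride = 1, pad = 1) {
  e <- new_layer("conv2d")
  e$in_ch <- in_ch; e$out_ch <- out_ch; e$k <- k; e$stride <- stride; e$pad <- pad
  e$W <- matrix(he_init(k * k * in_ch * out_ch, k * k * in_ch), k * k * in_ch, out_ch)
  e$b <- numeric(out_ch)
  e$param_names <- c("W", "b")
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xp <- pad2d(x, e$pad)
    out_h <- (d[2] + 2 * e$pad - e$k) %/% e$stride + 1
    out_w <- (d[3] + 2 * e$pad - e$k) %/% e$stride + 1
    cols <- im2col2d(xp, e$k, e$stride, out_h, out_w)
    out <- sweep(cols %*% e$W, 2, e$b, "+")
    e$cache <- list(cols = cols, dims = d, dims_p = dim(xp),
                    out_h = out_h, out_w = out_w)
    dim(out) <- c(d[1], out_h, out_w, e$out_ch)
    out
  }
  e$backward <- function(dout) {
    cc <- e$cache
    dm <- dout; dim(dm) <- c(cc$dims[1] * cc$out_h * cc$out_w, e$out_ch)
    e$gW <- crossprod(cc$cols, dm)
    e$gb <- colSums(dm)
    dcols <- tcrossprod(dm, e$W)
    dxp <- col2im2d(dcols, cc$dims_p, e$k, e$stride, cc$out_h, cc$out_w)
    if (e$pad > 0) {
      dxp <- dxp[, e$pad + seq_len(cc$dims[2]), e$pad + seq_len(cc$dims[3]), , drop = FALSE]
    }
    dxp
  }
  e
}

# ---- 1D convolution --------------------------------------------------------

pad1d <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3]))
  xp[, p + seq_len(d[2]), ] <- x
  xp
}

layer_conv1d <- function(in_ch, out_ch, k = 5, stride = 1, pad = 2) {
  e <- new_layer("conv1d")
  e$in_ch <- in_ch; e$out_ch <- out_ch; e$k <- k; e$stride <- stride; e$pad <- pad
  e$W <- matrix(he_init(k * in_ch * out_ch, k * in_ch), k * in_ch, out_ch)
  e$b <- numeric(out_ch)
  e$param_names <- c("W", "b")
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xp <- pad1d(x, e$pad)
    out_l <- (d[2] + 2 * e$pad - e$k) %/% e$stride + 1
    n <- d[1]; ch <- d[3]
    cols <- matrix(0, n * out_l, e$k * ch)
    ri <- e$stride * (seq_len(out_l) - 1)
    for (ki in seq_len(e$k)) {
      block <- xp[, ki + ri, , drop = FALSE]
      dim(block) <- c(n * out_l, ch)
      cols[, (ki - 1) * ch + seq_len(ch)] <- block
    }
    out <- sweep(cols %*% e$W, 2, e$b, "+")
    e$cache <- list(cols = cols, dims = d, dims_p = dim(xp), out_l = out_l)
    dim(out) <- c(n, out_l, e$out_ch)
    out
  }
  e$backward <- function(dout) {
    cc <- e$cache
    n <- cc$dims[1]; ch <- cc$dims[3]
    dm <- dout; dim(dm) <- c(n * cc$out_l, e$out_ch)
    e$gW <- crossprod(cc$cols, dm)
    e$gb <- colSums(dm)
    dcols <- tcrossprod(dm, e$W)
    dxp <- array(0, cc$dims_p)
    ri <- e$stride * (seq_len(cc$out_l) - 1)
    for (ki in seq_len(e$k)) {
      block <- dcols[, (ki - 1) * ch + seq_len(ch), drop = FALSE]
      dim(block) <- c(n, cc$out_l, ch)
      dxp[, ki + ri, ] <- dxp[, ki + ri, , drop = FALSE] + block
    }
    if (e$pad > 0) dxp <- dxp[, e$pad + seq_len(cc$dims[2]), , drop = FALSE]
    dxp
  }
  e
}

# ---- elementwise / pooling -------------------------------------------------

layer_relu <- function() {
  e <- new_layer("relu")
  e$forward <- function(x, training = FALSE) {
    e$mask <- x > 0
    x * e$mask
  }
  e$backward <- function(dout) dout * e$mask
  e
}

layer_avgpool2d <- function(k) {
  e <- new_layer("avgpool2d")
  e$k <- k
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[2] %% k != 0 || d[3] %% k != 0)
      stop("avgpool2d input size must be divisible by ", k)
    oh <- d[2] %/% k; ow <- d[3] %/% k
    out <- array(0, c(d[1], oh, ow, d[4]))
    ri <- k * (seq_len(oh) - 1); rj <- k * (seq_len(ow) - 1)
    for (di in seq_len(k)) for (dj in seq_len(k))
      out <- out + x[, di + ri, dj + rj, , drop = FALSE]
    e$cache <- d
    out / (k * k)
  }
  e$backward <- function(dout) {
    d <- e$cache; k <- e$k
    oh <- d[2] %/% k; ow <- d[3] %/% k
    dx <- array(0, d)
    ri <- k * (seq_len(oh) - 1); rj <- k * (seq_len(ow) - 1)
    g <- dout / (k * k)
    for (di in seq_len(k)) for (dj in seq_len(k))
      dx[, di + ri, dj + rj, ] <- g
    dx
  }
  e
}

layer_maxpool2d <- function(k = 3, stride = 2, pad = 1) {
  e <- new_layer("maxpool2d")
  e$k <- k; e$stride <- stride; e$pad <- pad
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xp <- pad2d(x, e$pad)  # zero padding; intended for post-ReLU inputs
    out_h <- (d[2] + 2 * e$pad - e$k) %/% e$stride + 1
    out_w <- (d[3] + 2 * e$pad - e$k) %/% e$stride + 1
    n <- d[1]; ch <- d[4]
    slices <- matrix(0, n * out_h * out_w * ch, e$k * e$k)
    ri <- e$stride * (seq_len(out_h) - 1)
    rj <- e$stride * (seq_len(out_w) - 1)
    for (ki in seq_len(e$k)) for (kj in seq_len(e$k)) {
      block <- xp[, ki + ri, kj + rj, , drop = FALSE]
      slices[, (ki - 1) * e$k + kj] <- as.vector(block)
    }
    amax <- max.col(slices, ties.method = "first")
    out <- slices[cbind(seq_len(nrow(slices)), amax)]
    e$cache <- list(amax = amax, dims = d, dims_p = dim(xp),
                    out_h = out_h, out_w = out_w)
    dim(out) <- c(n, out_h, out_w, ch)
    out
  }
  e$backward <- function(dout) {
    cc <- e$cache
    n <- cc$dims[1]; ch <- cc$dims[4]
    nr <- n * cc$out_h * cc$out_w * ch
    dslices <- matrix(0, nr, e$k * e$k)
    dslices[cbind(seq_len(nr), cc$amax)] <- as.vector(dout)
    dxp <- array(0, cc$dims_p)
    ri <- e$stride * (seq_len(cc$out_h) - 1)
    rj <- e$stride * (seq_len(cc$out_w) - 1)
    for (ki in seq_len(e$k)) for (kj in seq_len(e$k)) {
      block <- dslices[, (ki - 1) * e$k + kj]
      dim(block) <- c(n, cc$out_h, cc$out_w, ch)
      dxp[, ki + ri, kj + rj, ] <- dxp[, ki + ri, kj + rj, , drop = FALSE] + block
    }
    if (e$pad > 0)
      dxp <- dxp[, e$pad + seq_len(cc$dims[2]), e$pad + seq_len(cc$dims[3]), , drop = FALSE]
    dxp
  }
  e
}

layer_global_avgpool2d <- function() {
  e <- new_layer("gap2d")
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    e$cache <- d
    dim(x) <- c(d[1], d[2] * d[3], d[4])
    out <- matrix(0, d[1], d[4])
    for (c in seq_len(d[4])) out[, c] <- rowMeans(x[, , c, drop = FALSE])
    out
  }
  e$backward <- function(dout) {
    d <- e$cache
    hw <- d[2] * d[3]
    dx <- array(0, c(d[1], hw, d[4]))
    for (c in seq_len(d[4])) dx[, , c] <- matrix(dout[, c] / hw, d[1], hw)
    dim(dx) <- d
    dx
  }
  e
}

layer_global_avgpool1d <- function() {
  e <- new_layer("gap1d")
  e$forward <- function(x, training = FALSE) {
    d <- dim(x)
    e$cache <- d
    out <- matrix(0, d[1], d[3])
    for (c in seq_len(d[3])) out[, c] <- rowMeans(x[, , c, drop = FALSE])
    out
  }
  e$backward <- function(dout) {
    d <- e$cache
    dx <- array(0, d)
    for (c in seq_len(d[3])) dx[, , c] <- matrix(dout[, c] / d[2], d[1], d[2])
    dx
  }
  e
}

layer_dense <- function(n_in, n_out) {
  e <- new_layer("dense")
  e$W <- matrix(he_init(n_in * n_out, n_in), n_in, n_out)
  e$b <- numeric(n_out)
  e$param_names <- c("W", "b")
  e$forward <- function(x, training = FALSE) {
    e$cache <- x
    sweep(x %*% e$W, 2, e$b, "+")
  }
  e$backward <- function(dout) {
    e$gW <- crossprod(e$cache, dout)
    e$gb <- colSums(dout)
    tcrossprod(dout, e$W)
  }
  e
}

# ---- residual blocks -------------------------------------------------------

layer_resblock2d <- function(in_ch, out_ch, stride = 1) {
  e <- new_layer("resblock2d")
  e$conv1 <- layer_conv2d(in_ch, out_ch, 3, stride, 1)
  e$relu1 <- layer_relu()
  e$conv2 <- layer_conv2d(out_ch, out_ch, 3, 1, 1)
  e$proj <- if (stride != 1 || in_ch != out_ch) layer_conv2d(in_ch, out_ch, 1, stride, 0) else NULL
  e$relu2 <- layer_relu()
  e$sublayers <- Filter(Negate(is.null), list(e$conv1, e$conv2, e$proj))
  e$forward <- function(x, training = FALSE) {
    h <- e$conv2$forward(e$relu1$forward(e$conv1$forward(x, training), training), training)
    sc <- if (is.null(e$proj)) x else e$proj$forward(x, training)
    e$relu2$forward(h + sc, training)
  }
  e$backward <- function(dout) {
    d <- e$relu2$backward(dout)
    dx1 <- e$conv1$backward(e$relu1$backward(e$conv2$backward(d)))
    dsc <- if (is.null(e$proj)) d else e$proj$backward(d)
    dx1 + dsc
  }
  e
}

layer_resblock1d <- function(in_ch, out_ch, stride = 1) {
  e <- new_layer("resblock1d")
  e$conv1 <- layer_conv1d(in_ch, out_ch, 5, stride, 2)
  e$relu1 <- layer_relu()
  e$conv2 <- layer_conv1d(out_ch, out_ch, 5, 1, 2)
  e$proj <- if (stride != 1 || in_ch != out_ch) layer_conv1d(in_ch, out_ch, 1, stride, 0) else NULL
  e$relu2 <- layer_relu()
  e$sublayers <- Filter(Negate(is.null), list(e$conv1, e$conv2, e$proj))
  e$forward <- function(x, training = FALSE) {
    h <- e$conv2$forward(e$relu1$forward(e$conv1$forward(x, training), training), training)
    sc <- if (is.null(e$proj)) x else e$proj$forward(x, training)
    e$relu2$forward(h + sc, training)
  }
  e$backward <- function(dout) {
    d <- e$relu2$backward(dout)
    dx1 <- e$conv1$backward(e$relu1$backward(e$conv2$backward(d)))
    dsc <- if (is.null(e$proj)) d else e$proj$backward(d)
    dx1 + dsc
  }
  e
}

# ---- batch correlation -----------------------------------------------------

#' Batch-correlation feature update
#'
#' The feature-mixing step at the heart of the dual-branch network: each
#' sample's feature vector is replaced by a convex combination of all
#' feature vectors in the batch, weighted by pairwise cosine similarity,
#' `F'_i = sum_k a_k F_k`. Two weight normalizations are available:
#' \describe{
#'   \item{softmax}{`a_k = softmax_k(sim(F_i, F_k) / temperature)`,
#'     including the self term (`sim(F_i, F_i) = 1`).}
#'   \item{sumpos}{positive-part similarities normalized to sum to 1,
#'     `a_k = max(sim, 0) / sum(max(sim, 0))`; dissimilar samples get zero
#'     weight, so the update can learn to gate out unrelated batch
#'     members.}
#' }
#' With a single row, or when all rows are identical, the update is the
#' identity. It is permutation-equivariant, and every output row lies in
#' the convex hull of the input rows.
#'
#' @param f N x D feature matrix with no zero-norm row.
#' @param method `"softmax"` or `"sumpos"`.
#' @param temperature Softmax temperature (> 0); lower values sharpen the
#'   weights toward the most similar batch members.
#' @return The updated N x D feature matrix.
#' @examples
#' batch_correlation(rbind(c(1, 0), c(0, 1)))  # row 1 -> (0.731, 0.269)
#' @export
batch_correlation <- function(f, method = c("softmax", "sumpos"), temperature = 1) {
  method <- match.arg(method)
  f <- as.matrix(f)
  bc <- bc_forward(f, method, temperature)
  bc$out
}

bc_forward <- function(f, method, temperature) {
  nrm <- sqrt(rowSums(f^2))
  if (any(nrm < 1e-12)) stop("batch correlation undefined for a zero-norm feature row")
  u <- f / nrm
  s <- tcrossprod(u)
  if (method == "softmax") {
    z <- s / temperature
    z <- z - apply(z, 1, max)
    w <- exp(z)
  } else {
    w <- pmax(s, 0)
  }
  a <- w / rowSums(w)
  list(out = a %*% f, a = a, s = s, u = u, nrm = nrm, f = f)
}

bc_backward <- function(cache, dout, method, temperature) {
  a <- cache$a; u <- cache$u; f <- cache$f; nrm <- cache$nrm
  df_direct <- crossprod(a, dout)          # through the combination F' = A F
  da <- tcrossprod(dout, f)                # dL/dA
  if (method == "softmax") {
    ds <- a * (da - rowSums(a * da)) / temperature
  } else {
    s_sum <- rowSums(pmax(cache$s, 0))
    dw <- (da - rowSums(da * a)) / s_sum
    ds <- dw * (cache$s > 0)
  }
  du <- ds %*% u + crossprod(ds, u)        # S = U U^T touches both indices
  df_unit <- (du - u * rowSums(du * u)) / nrm
  df_direct + df_unit
}

layer_batch_correlation <- function(method = "softmax", temperature = 1) {
  e <- new_layer("batch_correlation")
  e$method <- method; e$temperature <- temperature
  e$bc_mode <- "batch"   # flipped to "identity" for per-sample inference
  e$forward <- function(x, training = FALSE) {
    if (e$bc_mode == "identity" || nrow(x) == 1) {
      e$cache <- NULL
      return(x)
    }
    cc <- bc_forward(x, e$method, e$temperature)
    e$cache <- cc
    cc$out
  }
  e$backward <- function(dout) {
    if (is.null(e$cache)) return(dout)
    bc_backward(e$cache, dout, e$method, e$temperature)
  }
  e
}

# ---- parameter bookkeeping -------------------------------------------------

flatten_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (!is.null(l$sublayers)) out <- c(out, flatten_layers(l$sublayers))
    if (length(l$param_names) > 0 && is.null(l$sublayers)) out <- c(out, list(l))
  }
  out
}

n_params <- function(layers) {
  sum(vapply(flatten_layers(layers), function(l)
    sum(vapply(l$param_names, function(p) length(l[[p]]), numeric(1))), numeric(1)))
}

snapshot_params <- function(layers) {
  lapply(flatten_layers(layers), function(l) mget(l$param_names, envir = l))
}

restore_params <- function(layers, snap) {
  flat <- flatten_layers(layers)
  for (i in seq_along(flat))
    for (p in flat[[i]]$param_names) assign(p, snap[[i]][[p]], envir = flat[[i]])
  invisible(NULL)
}

# ---- Nadam optimizer -------------------------------------------------------

nadam_state <- function(layers) {
  flat <- flatten_layers(layers)
  st <- lapply(flat, function(l)
    stats::setNames(lapply(l$param_names, function(p)
      list(m = l[[p]] * 0, v = l[[p]] * 0)), l$param_names))
  list(flat = flat, st = st, t = 0)
}

nadam_step <- function(opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (i in seq_along(opt$flat)) {
    l <- opt$flat[[i]]
    for (p in l$param_names) {
      g <- l[[paste0("g", p)]]
      s <- opt$st[[i]][[p]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      m_hat <- s$m / b1t
      v_hat <- s$v / b2t
      upd <- (beta1 * m_hat + (1 - beta1) * g / b1t) / (sqrt(v_hat) + eps)
      assign(p, l[[p]] - lr * upd, envir = l)
      opt$st[[i]][[p]] <- s
    }
  }
  opt
}
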