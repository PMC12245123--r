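ns <- asNamespace("sersquant")

test_that("batch correlation honors its contract cases", {
  # N = 1: the single weight normalizes to 1
  f1 <- matrix(c(3, -2, 1), 1, 3)
  expect_equal(batch_correlation(f1), f1)
  expect_equal(batch_correlation(f1, "sumpos"), f1)
  # identical rows: convex combination of identical vectors
  fid <- matrix(rep(c(1, 2), each = 4), 4, 2)
  expect_equal(batch_correlation(fid), fid)
  # hand-computed two-row softmax case: weights (e/(e+1), 1/(e+1))
  f2 <- rbind(c(1, 0), c(0, 1))
  w <- exp(1) / (exp(1) + 1)
  expect_equal(batch_correlation(f2),
               rbind(c(w, 1 - w), c(1 - w, w)), tolerance = 1e-6)
  # orthogonal rows under sumpos: only the self term survives
  expect_equal(batch_correlation(f2, "sumpos"), f2)
  expect_error(batch_correlation(rbind(c(0, 0), c(1, 1))), "zero-norm")
})

test_that("batch correlation is permutation-equivariant and convex", {
  withr::with_seed(19, {
    for (method in c("softmax", "sumpos")) {
      f <- matrix(rnorm(6 * 4), 6, 4) + 2
      out <- batch_correlation(f, method)
      perm <- sample(6)
      expect_equal(batch_correlation(f[perm, ], method), out[perm, ])
      # rows lie in the convex hull: weights recovered by least squares are
      # non-negative and sum to 1
      cc <- ns$bc_forward(f, method, 1)
      expect_true(all(cc$a >= 0))
      expect_equal(rowSums(cc$a), rep(1, 6))
      expect_equal(cc$a %*% f, out)
    }
  })
})

test_that("every layer type backpropagates correctly (finite differences)", {
  withr::with_seed(77, {
    x2 <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
    expect_true(grad_check(list(ns$layer_conv2d(3, 4, 3, 2, 1), ns$layer_relu()), x2))
    expect_true(grad_check(list(ns$layer_resblock2d(3, 5, 2)), x2))
    expect_true(grad_check(list(ns$layer_avgpool2d(2)), x2))
    expect_true(grad_check(list(ns$layer_maxpool2d(3, 2, 1)), abs(x2)))
    expect_true(grad_check(list(ns$layer_global_avgpool2d(),
                                ns$layer_dense(3, 2)), x2))
    x1 <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
    expect_true(grad_check(list(ns$layer_conv1d(2, 4, 5, 2, 2)), x1))
    expect_true(grad_check(list(ns$layer_resblock1d(2, 4, 2),
                                ns$layer_global_avgpool1d()), x1))
    xf <- matrix(rnorm(5 * 6), 5, 6)
    expect_true(grad_check(list(ns$layer_batch_correlation("softmax", 1)), xf))
    expect_true(grad_check(list(ns$layer_batch_correlation("softmax", 0.05)), xf))
    expect_true(grad_check(list(ns$layer_batch_correlation("sumpos", 1)), xf))
  })
})

test_that("models expose the contracted I/O shapes and parameter counts", {
  cfg <- model_config(64, pool_input = 2, widths = c(4, 8), branch_hidden = 8)
  m <- build_model(cfg)
  x <- matrix(runif(4 * 64), 4, 64)
  t0 <- proc.time()[3]
  out <- model_forward(m, x)
  expect_lt(proc.time()[3] - t0, 1)       # smoke bound: < 1 s per small batch
  expect_equal(dim(out), c(4, 2))
  expect_true(all(is.finite(out)))
  expect_gt(ns$n_params(ns$all_model_layers(m)), 0)
  expect_error(model_forward(m, matrix(0, 2, 32)), "64-point")
  # 1D baseline
  b1 <- build_baseline("resnet_1d", 64, widths = c(4, 8))
  expect_equal(dim(model_forward(b1, x)), c(4, 2))
  # 2D baseline = DBCNet topology minus branches and batch correlation
  b2 <- build_baseline("resnet_2d", 64, pool_input = 2, widths = c(4, 8))
  expect_null(b2$branches)
  kinds <- vapply(ns$flatten_layers(ns$all_model_layers(b2)), function(l) l$kind, character(1))
  expect_false("batch_correlation" %in% kinds)
  expect_equal(dim(model_forward(b2, x)), c(4, 2))
})

test_that("with batch correlation at identity the dual branches match a plain head topology", {
  cfg <- model_config(32, pool_input = 2, widths = c(3, 6), branch_hidden = 0)
  m <- build_model(cfg)
  x <- matrix(runif(3 * 32), 3, 32)
  # identity mode and batch mode agree when every row is processed alone
  out_id <- model_forward(m, x, bc_mode = "identity")
  one_by_one <- do.call(rbind, lapply(1:3, function(i)
    model_forward(m, x[i, , drop = FALSE], bc_mode = "batch")))
  expect_equal(out_id, one_by_one)
})

test_that("the full resnet18 topology builds and runs forward", {
  cfg <- model_config(64, backbone = "resnet18", init_seed = 2)
  m <- build_model(cfg)
  expect_gt(ns$n_params(ns$all_model_layers(m)), 1e7)  # ~11M, as expected for the named topology
  out <- model_forward(m, matrix(runif(2 * 64), 2, 64))
  expect_equal(dim(out), c(2, 2))
  expect_true(all(is.finite(out)))
})

test_that("training memorizes a noiseless toy grid and predicts it back", {
  toy <- toy_problem()
  cfg <- model_config(64, pool_input = 2, widths = c(4, 8), branch_hidden = 8,
                      init_seed = 1)
  m <- build_model(cfg)
  tcfg <- train_config(epochs = 400, batch_size = 4, seed = 1)
  train_model(m, toy$mats$x, toy$mats$y, toy$split, tcfg)
  expect_true(m$trained)
  # near-zero train MAE on the separable toy problem (internal label scale)
  pred_tr <- predict(m, toy$mats$x[toy$split$train, ], mode = "cohort")
  truth_tr <- toy$mats$y[toy$split$train, ]
  expect_lt(mean(abs(pred_tr[, 1] - truth_tr[, 1])), 0.5)       # mM
  expect_lt(mean(abs(pred_tr[, 2] - truth_tr[, 2])) / 10, 0.5)  # scaled uM
  # training examples recovered within tolerance relative to the label span
  expect_gt(regression_metrics(pred_tr[, 1], truth_tr[, 1])$r2, 0.95)
  expect_gt(regression_metrics(pred_tr[, 2], truth_tr[, 2])$r2, 0.95)
})

test_that("training history applies LR reduction and early stopping", {
  # constant labels make validation loss flatline almost immediately, so
  # small patiences must trigger both the LR cut and the stopper
  toy <- toy_problem(n_points = 32, replicates = 4)
  y_const <- cbind(rep(8, nrow(toy$mats$x)), rep(80, nrow(toy$mats$x)))
  cfg <- model_config(32, pool_input = 2, widths = c(2, 4), branch_hidden = 0,
                      dual_branch = FALSE, init_seed = 3)
  m <- build_model(cfg)
  tcfg <- train_config(epochs = 200, batch_size = 4, lr_patience = 3,
                       early_stop_patience = 10, seed = 3)
  train_model(m, toy$mats$x, y_const, toy$split, tcfg)
  h <- m$history
  expect_lt(nrow(h), 200)                     # early stop triggered
  expect_true(any(h$lr < 0.001))              # at least one reduction
  expect_equal(sort(unique(h$lr), decreasing = TRUE)[2] /
                 sort(unique(h$lr), decreasing = TRUE)[1], 0.1)
  expect_error(train_model(m, toy$mats$x, y_const,
                           list(train = integer(0), val = 1:2), tcfg),
               "non-empty")
})

test_that("per-sample predictions are independent of batch company", {
  toy <- toy_problem()
  cfg <- model_config(64, pool_input = 2, widths = c(4, 8), branch_hidden = 4,
                      init_seed = 9)
  m <- build_model(cfg)
  train_model(m, toy$mats$x, toy$mats$y, toy$split,
              train_config(epochs = 5, batch_size = 8, seed = 9))
  x <- toy$mats$x[1:6, ]
  p <- predict(m, x, mode = "per_sample")
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(predict(m, x[perm, ], mode = "per_sample"), p[perm, ])
  # single-spectrum inference works
  p1 <- predict(m, x[3, , drop = FALSE], mode = "per_sample")
  expect_equal(dim(p1), c(1, 2))
  expect_equal(unname(p1), unname(p[3, , drop = FALSE]))
  # cohort mode on a single spectrum degenerates to the same answer
  expect_equal(unname(predict(m, x[3, , drop = FALSE], mode = "cohort")), unname(p1))
})

test_that("untrained models refuse to predict; checkpoints round-trip", {
  cfg <- model_config(64, pool_input = 2, widths = c(3, 6))
  m <- build_model(cfg)
  expect_error(predict(m, matrix(0.5, 2, 64)), "untrained")
  toy <- toy_problem()
  train_model(m, toy$mats$x, toy$mats$y, toy$split,
              train_config(epochs = 3, batch_size = 8, seed = 2))
  d <- withr::local_tempdir()
  save_model(m, file.path(d, "ckpt.json"))
  back <- load_model(file.path(d, "ckpt.json"))
  x <- toy$mats$x[1:4, ]
  expect_equal(predict(back, x), predict(m, x))
  expect_error(predict(back, matrix(0.5, 2, 16)), "64-point")
})
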