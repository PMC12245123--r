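# Synthetic ratio cohorts used across the classifier tests. Stage-1 signal
# lives in r1 (tumor high), stage-2 in r2 (MUT low, because the H2O2 peak
# falls when H2O2 rises).
make_cohort <- function(n_per = 40, sep = 1, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      tissue_class = rep(c("normal", "WT", "MUT"), each = n_per),
      r1 = c(rnorm(n_per, 0.3, 0.05 / sep),
             rnorm(n_per, 1.4, 0.1 / sep),
             rnorm(n_per, 1.1, 0.1 / sep)),
      r2 = c(rnorm(n_per, 1.4, 0.1 / sep),
             rnorm(n_per, 1.05, 0.05 / sep),
             rnorm(n_per, 0.75, 0.06 / sep)))
  })
}

test_that("well-separated cohorts are classified perfectly and flagged", {
  pts <- make_cohort(sep = 10)
  bundle <- fit_classifier(pts)
  expect_true(any(bundle$separation))
  calls <- classify(pts, bundle)
  expect_equal(calls$label, pts$tissue_class)
  cm <- confusion_matrix(calls, pts$tissue_class)
  expect_equal(unname(diag(cm$table)), rep(40L, 3))
  expect_equal(unname(cm$predictive_value), rep(1, 3))
})

test_that("hierarchical calls are consistent with stage-1 probabilities", {
  pts <- make_cohort(sep = 2, seed = 3)
  bundle <- fit_classifier(pts)
  calls <- classify(pts, bundle)
  tumor_called <- calls$label %in% c("WT", "MUT")
  expect_true(all(calls$p_tumor[tumor_called] >= bundle$threshold))
  expect_true(all(calls$p_tumor[!tumor_called] < bundle$threshold))
  # very low r1 is always normal
  low <- classify(data.frame(r1 = 0.05, r2 = 1), bundle)
  expect_equal(low$label, "normal")
  # tumor-range r1 with low r2 (high H2O2) goes MUT
  mut <- classify(data.frame(r1 = 1.3, r2 = 0.6), bundle)
  expect_equal(mut$label, "MUT")
})

test_that("missing classes and missing features are errors", {
  pts <- make_cohort()
  expect_error(fit_classifier(pts[pts$tissue_class != "MUT", ]), "MUT")
  expect_error(fit_classifier(pts[, c("tissue_class", "r2")]), "r1")
  bundle <- fit_classifier(pts)
  expect_error(classify(data.frame(r2 = 1), bundle), "r1|stage 1")
})

test_that("h2o2_gsh recipe uses the concentration quotient", {
  withr::with_seed(8, {
    n <- 50
    pts <- data.frame(
      tissue_class = rep(c("normal", "WT", "MUT"), each = n),
      c_gsh = c(rnorm(n, 0.7, 0.15), rnorm(n, 12.08, 0.53), rnorm(n, 9.2, 0.83)),
      c_h2o2 = c(rnorm(n, 15, 5), rnorm(n, 68.54, 4.51), rnorm(n, 109.3, 9.44)))
  })
  bundle <- fit_classifier(pts, recipe = "h2o2_gsh")
  calls <- classify(pts, bundle)
  acc <- mean(calls$label == pts$tissue_class)
  expect_gt(acc, 0.9)
})

test_that("multinomial mode agrees with the hierarchy on separable data", {
  skip_if_not_installed("nnet")
  pts <- make_cohort(sep = 5, seed = 11)
  multi <- fit_classifier(pts, mode = "multinomial")
  calls <- classify(pts, multi)
  expect_gt(mean(calls$label == pts$tissue_class), 0.97)
})

test_that("AUC equals brute-force pair enumeration (oracle)", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(4:20, 1)
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
      expect_equal(roc_auc(scores, labels)$auc, auc_by_pairs(scores, labels))
    }
  })
})

test_that("AUC endpoints behave: separation 1, all ties 0.5", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.7, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # curve spans (0,0) to (1,1)
  curve <- roc_auc(runif(20), rep(0:1, 10))$curve
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1); expect_equal(curve$tpr[nrow(curve)], 1)
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    for (i in 1:5) {
      scores <- rnorm(30)
      labels <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(labels)) < 2) next
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("shuffled labels give chance-level AUC", {
  withr::with_seed(13, {
    aucs <- replicate(30, {
      scores <- rnorm(60)
      roc_auc(scores, sample(rep(0:1, 30)))$auc
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("confusion matrices count and score by hand-checkable rules", {
  cm <- confusion_matrix(c("WT", "WT", "MUT"), c("WT", "MUT", "MUT"))
  expect_equal(as.vector(cm$table["WT", ]), c(1, 0))
  expect_equal(as.vector(cm$table["MUT", ]), c(1, 1))
  expect_equal(unname(cm$predictive_value["WT"]), 0.5)
  expect_equal(unname(cm$predictive_value["MUT"]), 1)
  expect_error(confusion_matrix(character(0), character(0)), "no calls")
  expect_error(confusion_matrix(c("WT", "odd"), c("WT", "WT"),
                                levels = c("normal", "WT", "MUT")), "unknown label")
})

test_that("classifier bundles round-trip through JSON", {
  d <- withr::local_tempdir()
  pts <- make_cohort(seed = 2)
  bundle <- fit_classifier(pts)
  write_classifier(bundle, file.path(d, "clf.json"))
  back <- read_classifier(file.path(d, "clf.json"))
  expect_equal(back$stage1$slope, bundle$stage1$slope)
  expect_equal(back$threshold, bundle$threshold)
  expect_equal(classify(pts, back)$label, classify(pts, bundle)$label)
})
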