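#' Two-step logistic classifier for IDH1 genotype calling
#'
#' Fits the hierarchical decision procedure used for intraoperative
#' genotyping: stage 1 separates tumor from normal tissue using the GSH
#' channel (`r1 = I542/I928`, or quantified GSH); stage 2, fitted on tumor
#' points only, separates IDH1-MUT from IDH1-WT using the H2O2 channel --
#' either the raw `r2 = I628/I928` ratio (`recipe = "ratios"`) or the
#' quantified H2O2/GSH concentration quotient (`recipe = "h2o2_gsh"`). Both
#' stages are maximum-likelihood logistic regressions; if a stage is
#' perfectly separated, a ridge-stabilized fit is used instead and flagged.
#'
#' @param points Data frame with a `tissue_class` column
#'   (`normal`/`WT`/`MUT`) plus the feature columns the recipe needs:
#'   `r1` and `r2` for `"ratios"`; `r1` (or `c_gsh`) and `h2o2_gsh` (or
#'   `c_gsh` + `c_h2o2`) for `"h2o2_gsh"`.
#' @param recipe Feature recipe, `"ratios"` or `"h2o2_gsh"`.
#' @param threshold Decision threshold applied to both stages (default 0.5).
#' @param mode `"hierarchical"` (two binary stages, the default workflow) or
#'   `"multinomial"` (a single three-class fit via \pkg{nnet}, for
#'   comparison).
#' @return A `sers_classifier` bundle: stage models, thresholds, recipe and
#'   separation flags.
#' @export
fit_classifier <- function(points, recipe = c("ratios", "h2o2_gsh"),
                           threshold = 0.5,
                           mode = c("hierarchical", "multinomial")) {
  recipe <- match.arg(recipe)
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  points <- as.data.frame(points)
  cls <- points$tissue_class
  if (is.null(cls)) stop("points need a tissue_class column")
  missing_cls <- setdiff(c("normal", "WT", "MUT"), unique(cls))
  if (length(missing_cls) > 0)
    stop("class absent from training points: ", paste(missing_cls, collapse = ", "))

  points$h2o2_gsh <- derive_h2o2_gsh(points, recipe)
  f1 <- stage1_feature(points)
  f2 <- stage2_feature(points, recipe)

  tumor <- as.integer(cls %in% c("WT", "MUT"))
  s1 <- fit_logistic(f1, tumor)
  tum <- cls %in% c("WT", "MUT")
  s2 <- fit_logistic(f2[tum], as.integer(cls[tum] == "MUT"))

  multi <- NULL
  if (mode == "multinomial") {
    if (!requireNamespace("nnet", quietly = TRUE))
      stop("multinomial mode requires the nnet package")
    df <- data.frame(y = factor(cls, levels = c("normal", "WT", "MUT")),
                     f1 = f1, f2 = f2)
    multi <- nnet::multinom(y ~ f1 + f2, df, trace = FALSE)
  }

  structure(list(stage1 = s1, stage2 = s2, threshold = threshold,
                 recipe = recipe, mode = mode, multinomial = multi,
                 separation = c(stage1 = s1$separated, stage2 = s2$separated)),
            class = "sers_classifier")
}

derive_h2o2_gsh <- function(points, recipe) {
  if (!is.null(points$h2o2_gsh)) return(points$h2o2_gsh)
  if (!is.null(points$c_gsh) && !is.null(points$c_h2o2))
    return(points$c_h2o2 / pmax(points$c_gsh, .Machine$double.eps))
  if (recipe == "h2o2_gsh")
    stop("h2o2_gsh recipe needs an h2o2_gsh column or c_gsh + c_h2o2")
  NA_real_
}

stage1_feature <- function(points) {
  if (!is.null(points$r1)) return(points$r1)
  if (!is.null(points$c_gsh)) return(points$c_gsh)
  stop("stage 1 needs r1 or c_gsh")
}

stage2_feature <- function(points, recipe) {
  if (recipe == "ratios") {
    if (is.null(points$r2)) stop("ratios recipe needs an r2 column")
    points$r2
  } else points$h2o2_gsh
}

# Univariate logistic fit with a ridge-stabilized fallback under perfect
# separation (detected through glm's convergence warning or runaway
# coefficients).
fit_logistic <- function(x, y) {
  stopifnot(length(x) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("both outcome classes required for a logistic stage")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  if (separated || any(abs(beta) > 1e3)) {
    separated <- TRUE
    beta <- ridge_logistic(x, y, lambda = 1e-3)
  }
  list(intercept = beta[1], slope = beta[2], separated = separated)
}

# Penalized logistic log-likelihood maximized with optim; lambda penalizes
# the slope only, keeping the fit finite under separation.
ridge_logistic <- function(x, y, lambda = 1e-3) {
  xs <- scale(x)
  nll <- function(b) {
    eta <- b[1] + b[2] * as.numeric(xs)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda * b[2]^2
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS")
  b <- opt$par
  # undo the internal standardization
  slope <- b[2] / attr(xs, "scaled:scale")
  c(b[1] - slope * attr(xs, "scaled:center"), slope)
}

logistic_prob <- function(stage, x) {
  stats::plogis(stage$intercept + stage$slope * x)
}

#' Call the genotype of measurement points
#'
#' Applies a fitted [fit_classifier()] bundle hierarchically: a point whose
#' stage-1 tumor probability is below the threshold is called `normal`;
#' otherwise stage 2 decides `MUT` vs `WT`. A point exactly at the stage-1
#' threshold is called tumor (sensitivity-first tie rule), and at the
#' stage-2 threshold `MUT`.
#'
#' @param points Data frame of measurements with the recipe's feature
#'   columns (as in [fit_classifier()]); `tissue_class` is not required.
#' @param bundle A `sers_classifier`.
#' @return A data.frame of `GenotypeCall`s: columns `label`, `p_tumor`,
#'   `p_mut_given_tumor`.
#' @export
classify <- function(points, bundle) {
  stopifnot(inherits(bundle, "sers_classifier"))
  points <- as.data.frame(points)
  points$h2o2_gsh <- derive_h2o2_gsh(points, bundle$recipe)
  f1 <- stage1_feature(points)
  f2 <- stage2_feature(points, bundle$recipe)
  if (anyNA(f1)) stop("missing stage-1 feature values")
  p_tumor <- logistic_prob(bundle$stage1, f1)
  p_mut <- logistic_prob(bundle$stage2, f2)
  if (bundle$mode == "multinomial") {
    pr <- stats::predict(bundle$multinomial,
                         data.frame(f1 = f1, f2 = f2), type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                       dimnames = list(NULL, names(pr)))
    label <- colnames(pr)[max.col(pr, ties.method = "first")]
  } else {
    is_tumor <- p_tumor >= bundle$threshold
    if (any(is_tumor & !is.finite(f2))) stop("missing stage-2 feature for a tumor call")
    label <- ifelse(!is_tumor, "normal",
                    ifelse(p_mut >= bundle$threshold, "MUT", "WT"))
  }
  data.frame(label = label, p_tumor = p_tumor, p_mut_given_tumor = p_mut,
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC by full threshold sweep
#'
#' Sweeps every distinct score as a threshold (score >= threshold calls
#' positive) and integrates the ROC curve by the trapezoidal rule, which
#' makes the AUC equal to the Mann-Whitney probability that a random
#' positive outscores a random negative, with ties counted 1/2.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2) stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  np <- sum(l == 1); nn <- sum(l == 0)
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last <- !duplicated(s, fromLast = TRUE)  # one operating point per distinct score
  curve <- data.frame(threshold = c(Inf, s[last]),
                      fpr = c(0, fp[last] / nn),
                      tpr = c(0, tp[last] / np))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Confusion matrix with per-class predictive values
#'
#' Cross-tabulates truth (rows) against calls (columns) over the union of
#' observed labels, and reports each class's predictive value (the column's
#' diagonal count divided by its total -- the probability a call of that
#' class is correct).
#'
#' @param calls Character vector of predicted labels, or the data.frame
#'   returned by [classify()].
#' @param truth Character vector of true labels.
#' @param levels Optional label order; defaults to the union of observed
#'   labels in `normal < WT < MUT` order, others appended.
#' @return List with `table` (K x K counts, truth in rows) and
#'   `predictive_value` (named vector; `NaN` for never-called classes).
#' @export
confusion_matrix <- function(calls, truth, levels = NULL) {
  if (is.data.frame(calls)) calls <- calls$label
  if (length(calls) == 0) stop("no calls to tabulate")
  if (length(calls) != length(truth)) stop("calls and truth must align")
  seen <- unique(c(as.character(truth), as.character(calls)))
  if (is.null(levels)) {
    canonical <- c("normal", "WT", "MUT")
    levels <- c(intersect(canonical, seen), setdiff(seen, canonical))
  } else if (!all(seen %in% levels)) {
    stop("unknown label: ", paste(setdiff(seen, levels), collapse = ", "))
  }
  tab <- table(truth = factor(truth, levels),
               call = factor(calls, levels))
  pv <- diag(tab) / colSums(tab)
  list(table = tab, predictive_value = pv)
}

#' Save / load a classifier bundle as JSON
#'
#' @param bundle A `sers_classifier` (hierarchical mode only).
#' @param path JSON path.
#' @return `path` (write) or the restored `sers_classifier` (read).
#' @export
write_classifier <- function(bundle, path) {
  stopifnot(inherits(bundle, "sers_classifier"))
  if (bundle$mode != "hierarchical")
    stop("only hierarchical bundles have a JSON serialization")
  jsonlite::write_json(list(
    recipe = bundle$recipe, threshold = bundle$threshold,
    stage1 = bundle$stage1[c("intercept", "slope", "separated")],
    stage2 = bundle$stage2[c("intercept", "slope", "separated")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stage1 = j$stage1, stage2 = j$stage2,
                 threshold = j$threshold, recipe = j$recipe,
                 mode = "hierarchical", multinomial = NULL,
                 separation = c(stage1 = isTRUE(j$stage1$separated),
                                stage2 = isTRUE(j$stage2$separated))),
            class = "sers_classifier")
}
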