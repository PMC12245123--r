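#' Regression metric suite
#'
#' Computes the four quantities used to compare concentration-prediction
#' models: mean absolute error, the sample standard deviation of the
#' absolute errors, root mean squared error, and the coefficient of
#' determination `R^2 = 1 - sum(e^2) / sum((y - mean(y))^2)`.
#'
#' @param pred Numeric vector of predictions.
#' @param truth Numeric vector of ground truth, same length (>= 2), not
#'   constant.
#' @return Named list: `mae`, `sd_abs_err`, `rmse`, `r2`.
#' @examples
#' regression_metrics(c(1, 2, 4), c(1, 2, 3))
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  if (length(pred) < 2) stop("need at least 2 observations")
  if (stats::var(truth) == 0) stop("truth is constant; R^2 undefined")
  e <- pred - truth
  list(mae = mean(abs(e)),
       sd_abs_err = stats::sd(abs(e)),
       rmse = sqrt(mean(e^2)),
       r2 = 1 - sum(e^2) / sum((truth - mean(truth))^2))
}

#' Evaluation report for one model on one test set
#'
#' @param model_id Model name.
#' @param pred N x 2 prediction matrix (columns: GSH mM, H2O2 uM).
#' @param truth N x 2 truth matrix.
#' @return A `sers_eval_report`: per-metabolite metric lists plus `n`.
#' @export
eval_report <- function(model_id, pred, truth) {
  stopifnot(ncol(pred) == 2, all(dim(pred) == dim(truth)))
  structure(list(model_id = model_id, n = nrow(pred),
                 gsh = regression_metrics(pred[, 1], truth[, 1]),
                 h2o2 = regression_metrics(pred[, 2], truth[, 2])),
            class = "sers_eval_report")
}

#' @export
print.sers_eval_report <- function(x, ...) {
  cat(sprintf("<eval report> %s (n=%d)\n", x$model_id, x$n))
  for (m in c("gsh", "h2o2")) {
    v <- x[[m]]
    cat(sprintf("  %-5s MAE %.4g  SD %.4g  RMSE %.4g  R2 %.4f\n",
                toupper(m), v$mae, v$sd_abs_err, v$rmse, v$r2))
  }
  invisible(x)
}

#' Percentage improvement of each model over a reference model
#'
#' For every non-reference report, computes
#' `(ref_metric - model_metric) / ref_metric * 100` per metabolite and
#' metric (MAE, SD of absolute error, RMSE); positive numbers mean the model
#' beats the reference. `average_enhancement()` flips the viewpoint: it
#' reports one model's improvement averaged across all comparator models per
#' metric, the convention used when summarizing a new model against several
#' baselines.
#'
#' @param reports List of `sers_eval_report`.
#' @param reference_id `model_id` of the reference report.
#' @return A data.frame with columns `model`, `metabolite`, `metric`,
#'   `improvement_pct`.
#' @export
improvement_table <- function(reports, reference_id) {
  ids <- vapply(reports, function(r) r$model_id, character(1))
  if (!reference_id %in% ids) stop("reference model not in reports")
  if (length(reports) < 2) stop("need at least 2 reports")
  ref <- reports[[match(reference_id, ids)]]
  rows <- list()
  for (r in reports[ids != reference_id]) {
    for (met in c("gsh", "h2o2")) {
      for (metric in c("mae", "sd_abs_err", "rmse")) {
        denom <- ref[[met]][[metric]]
        if (denom == 0) stop("reference ", metric, " is zero; improvement undefined")
        rows[[length(rows) + 1]] <- data.frame(
          model = r$model_id, metabolite = met, metric = metric,
          improvement_pct = (denom - r[[met]][[metric]]) / denom * 100)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "convention") <- "improvement = (reference - model)/reference * 100"
  out
}

#' @rdname improvement_table
#' @param model_id Model whose average enhancement over all other reports is
#'   wanted.
#' @return For `average_enhancement()`: data.frame with columns `metabolite`,
#'   `metric`, `mean_improvement_pct` (averaged over comparators), with the
#'   per-comparator values attached as attribute `per_reference`.
#' @export
average_enhancement <- function(reports, model_id) {
  ids <- vapply(reports, function(r) r$model_id, character(1))
  others <- ids[ids != model_id]
  if (length(others) == 0) stop("no comparator reports")
  per <- do.call(rbind, lapply(others, function(ref) {
    tab <- improvement_table(reports, ref)
    tab <- tab[tab$model == model_id, ]
    tab$reference <- ref
    tab
  }))
  agg <- stats::aggregate(improvement_pct ~ metabolite + metric, per, mean)
  names(agg)[3] <- "mean_improvement_pct"
  attr(agg, "per_reference") <- per
  agg
}
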