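#' Default end-to-end run configuration
#'
#' Returns the fully populated configuration list for [run_pipeline()];
#' pass overrides as a nested list (or a YAML file of the same shape) and
#' they are merged over these defaults. Unknown keys are rejected at
#' validation time, before any computation. The single `seed` fans out to
#' independent per-stage seeds via [derive_seed()].
#'
#' @param overrides Nested list of overrides (or `NULL`).
#' @return The merged, validated configuration list.
#' @export
default_run_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    out_dir = "sersquant_run",
    verbose = TRUE,
    simulate = list(
      gsh_levels = c(2, 4, 6, 8, 10, 16),
      h2o2_levels = c(1, 25, 50, 75, 100, 125, 150, 200),
      replicates = 200,
      n_axis_points = 701,
      noise_sd = 0.01,
      grid_shape = c(10, 10),
      classes = c("normal", "WT", "MUT")),
    train = list(
      enabled = FALSE,
      model = "dbcnet",            # dbcnet | resnet1d | resnet2d
      pool_input = 4,
      epochs = 60,
      batch_size = 32,
      eval_mode = "cohort"),
    classify = list(recipe = "ratios", threshold = 0.5)
  )
  merge_config(cfg, overrides)
}

merge_config <- function(base, over) {
  if (is.null(over)) return(base)
  for (k in names(over)) {
    if (!k %in% names(base))
      stop("unknown config key: ", k)
    if (is.list(base[[k]]) && is.list(over[[k]])) {
      base[[k]] <- merge_config(base[[k]], over[[k]])
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Run the full synthetic pipeline
#'
#' simulate -> preprocess -> calibrate -> quantify/map -> classify ->
#' report, with optional network training. Every stage writes plain-text
#' artifacts into `cfg$out_dir`, and a `manifest.json` records the seed,
#' a config fingerprint, per-stage record counts and timings. Deterministic
#' stages reproduce bit-identically for the same configuration.
#'
#' @param cfg Configuration list from [default_run_config()], a nested
#'   override list, or a path to a YAML file of overrides.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = NULL) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- default_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(deparse(cfg)),
                   stages = list())
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  # -- simulate ---------------------------------------------------------
  probe <- probe_response_model(axis = seq(400, 1800, length.out = cfg$simulate$n_axis_points))
  noise <- noise_model(additive_sd = cfg$simulate$noise_sd)
  sim <- clock({
    cal <- build_calibration_dataset(cfg$simulate$gsh_levels,
                                     cfg$simulate$h2o2_levels,
                                     cfg$simulate$replicates,
                                     probe, noise,
                                     seed = derive_seed(cfg$seed, "calibration"))
    tissue <- simulate_tissue_grid(cohort_params(), cfg$simulate$classes,
                                   cfg$simulate$grid_shape, probe, noise,
                                   seed = derive_seed(cfg$seed, "tissue"))
    write_spectra_table(tissue, file.path(cfg$out_dir, "tissue_spectra.csv"),
                        file.path(cfg$out_dir, "tissue_manifest.csv"))
    list(cal = cal, tissue = tissue)
  })
  manifest$stages$simulate <- list(n_calibration = length(sim$value$cal),
                                   n_tissue = length(sim$value$tissue),
                                   seconds = sim$seconds)
  say("simulate: %d calibration + %d tissue spectra [%ss]",
      length(sim$value$cal), length(sim$value$tissue), sim$seconds)

  # -- preprocess + split ----------------------------------------------
  pre <- clock({
    cal_p <- preprocess_spectra(sim$value$cal)
    mats <- spectra_to_matrix(cal_p)
    strata <- paste(mats$y[, 1], mats$y[, 2])
    split <- split_dataset(nrow(mats$x), 0.2, 0.1,
                           seed = derive_seed(cfg$seed, "split"),
                           strata = strata)
    list(mats = mats, split = split, cal_p = cal_p)
  })
  manifest$stages$preprocess <- list(
    n = nrow(pre$value$mats$x),
    split = c(train = length(pre$value$split$train),
              val = length(pre$value$split$val),
              test = length(pre$value$split$test)),
    seconds = pre$seconds)
  say("preprocess: split %d/%d/%d [%ss]", length(pre$value$split$train),
      length(pre$value$split$val), length(pre$value$split$test), pre$seconds)

  # -- calibrate --------------------------------------------------------
  calib <- clock({
    ratios <- lapply(pre$value$cal_p, compute_ratios)
    r1 <- vapply(ratios, function(r) r$r1, numeric(1))
    r2 <- vapply(ratios, function(r) r$r2, numeric(1))
    y <- pre$value$mats$y
    cal_gsh <- fit_calibration(r1, y[, 1], "GSH")
    cal_h2o2 <- fit_calibration(r2, y[, 2], "H2O2")
    jsonlite::write_json(
      list(gsh = unclass(cal_gsh), h2o2 = unclass(cal_h2o2)),
      file.path(cfg$out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
    list(gsh = cal_gsh, h2o2 = cal_h2o2)
  })
  manifest$stages$calibrate <- list(
    gsh_fit_r2 = calib$value$gsh$fit_r2, h2o2_fit_r2 = calib$value$h2o2$fit_r2,
    seconds = calib$seconds)
  say("calibrate: GSH fit R2 %.4f, H2O2 fit R2 %.4f [%ss]",
      calib$value$gsh$fit_r2, calib$value$h2o2$fit_r2, calib$seconds)

  # -- optional network training ---------------------------------------
  if (isTRUE(cfg$train$enabled)) {
    tr <- clock({
      mats <- pre$value$mats
      mcfg <- switch(cfg$train$model,
        dbcnet = model_config(ncol(mats$x), pool_input = cfg$train$pool_input,
                              init_seed = derive_seed(cfg$seed, "init")),
        resnet2d = model_config(ncol(mats$x), dual_branch = FALSE,
                                pool_input = cfg$train$pool_input,
                                init_seed = derive_seed(cfg$seed, "init")),
        resnet1d = model_config(ncol(mats$x), input_mode = "raw_1d",
                                dual_branch = FALSE,
                                init_seed = derive_seed(cfg$seed, "init")),
        stop("unknown model: ", cfg$train$model))
      model <- build_model(mcfg)
      tcfg <- train_config(epochs = cfg$train$epochs,
                           batch_size = cfg$train$batch_size,
                           seed = derive_seed(cfg$seed, "train"))
      train_model(model, mats$x, mats$y, pre$value$split, tcfg)
      pred <- predict(model, mats$x[pre$value$split$test, , drop = FALSE],
                      mode = cfg$train$eval_mode)
      rep <- eval_report(cfg$train$model, pred,
                         mats$y[pre$value$split$test, , drop = FALSE])
      jsonlite::write_json(unclass(rep), file.path(cfg$out_dir, "eval_report.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    })
    manifest$stages$train <- list(model = cfg$train$model,
                                  gsh_r2 = tr$value$gsh$r2,
                                  h2o2_r2 = tr$value$h2o2$r2,
                                  seconds = tr$seconds)
    say("train: %s test R2 GSH %.4f / H2O2 %.4f [%ss]",
        cfg$train$model, tr$value$gsh$r2, tr$value$h2o2$r2, tr$seconds)
  }

  # -- quantify + map + classify ---------------------------------------
  geno <- clock({
    tissue_p <- preprocess_spectra(sim$value$tissue)
    pts <- lapply(tissue_p, compute_ratios)
    map <- build_map(pts, calib$value$gsh, calib$value$h2o2)
    utils::write.csv(as.data.frame(map),
                     file.path(cfg$out_dir, "concentration_map.csv"),
                     row.names = FALSE)
    feats <- data.frame(
      r1 = vapply(pts, function(p) p$r1, numeric(1)),
      r2 = vapply(pts, function(p) p$r2, numeric(1)),
      tissue_class = vapply(tissue_p, function(l) l$tissue_class, character(1)))
    bundle <- fit_classifier(feats, recipe = cfg$classify$recipe,
                             threshold = cfg$classify$threshold)
    calls <- classify(feats, bundle)
    utils::write.csv(cbind(feats, calls),
                     file.path(cfg$out_dir, "genotype_calls.csv"),
                     row.names = FALSE)
    write_classifier(bundle, file.path(cfg$out_dir, "classifier.json"))
    cm <- confusion_matrix(calls, feats$tissue_class)
    tum <- feats$tissue_class != "normal"
    auc2 <- roc_auc(-feats$r2[tum], as.integer(feats$tissue_class[tum] == "MUT"))$auc
    list(map = map, cm = cm, accuracy = sum(diag(cm$table)) / sum(cm$table),
         stage2_auc = auc2)
  })
  manifest$stages$classify <- list(accuracy = geno$value$accuracy,
                                   stage2_auc = geno$value$stage2_auc,
                                   seconds = geno$seconds)
  say("classify: 3-class accuracy %.3f, stage-2 AUC %.4f [%ss]",
      geno$value$accuracy, geno$value$stage2_auc, geno$seconds)

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
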