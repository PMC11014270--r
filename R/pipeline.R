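#' Study configuration
#'
#' Assembles the configuration consumed by [run_study()]. Study-protocol
#' constants (design levels, 70/30 split with seed 42, per-architecture
#' hyperparameters) are the defaults; simulator constants that have no
#' published counterpart (band widths/amplitudes, noise sizes) come from
#' [default_component_library()] and [noise_model()] and are marked
#' `synthetic-default` in the emitted config snapshot.
#'
#' @param instrument `"Micro-NIR"` or `"FT-NIR"`.
#' @param adulterant `"corn_flour"` or `"tapioca_starch"`.
#' @param architectures Character vector of architecture tags to train.
#' @param seed Master seed driving data generation, splitting and training.
#' @param train_fraction Train share of the 70/30 split.
#' @param split_seed Random state of the split (default 42).
#' @param n_repeats Training repetitions per architecture.
#' @param max_epochs Optional cap overriding each architecture's default.
#' @param quick Desk-scale profile: caps epochs at 200 and repeats at 1.
#' @param apply_snv Apply SNV preprocessing (default `TRUE`).
#' @param interpretation_eps Perturbation size for coefficients.
#' @param threshold_fraction Important-feature threshold.
#' @param library Component library for the simulator; a
#'   `component_library` or its plain-list config form.
#' @param noise Noise model for the simulator; a [noise_model()] or a
#'   named list of its arguments.
#' @return A list of class `study_config`.
#' @export
study_config <- function(instrument = "Micro-NIR",
                         adulterant = "corn_flour",
                         architectures = "simple_cnn",
                         seed = 42L,
                         train_fraction = 0.70,
                         split_seed = 42L,
                         n_repeats = 11L,
                         max_epochs = NULL,
                         quick = FALSE,
                         apply_snv = TRUE,
                         interpretation_eps = 1e-6,
                         threshold_fraction = 0.50,
                         library = default_component_library(),
                         noise = noise_model()) {
  architectures <- match.arg(architectures,
                             c("simple_cnn", "s_alexnet", "resnet",
                               "googlenet"), several.ok = TRUE)
  if (isTRUE(quick)) {
    max_epochs <- min(max_epochs %||% 200L, 200L)
    n_repeats <- 1L
  }
  if (!inherits(library, "component_library")) {
    library <- component_library_from_config(library)
  }
  if (!inherits(noise, "noise_model")) {
    noise <- do.call(noise_model, noise)
  }
  structure(list(instrument = instrument, adulterant = adulterant,
                 architectures = architectures, seed = as.integer(seed),
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 n_repeats = as.integer(n_repeats),
                 max_epochs = max_epochs, quick = isTRUE(quick),
                 apply_snv = isTRUE(apply_snv),
                 interpretation_eps = interpretation_eps,
                 threshold_fraction = threshold_fraction,
                 library = library, noise = noise),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' @param path Config file; top-level keys match [study_config()]
#'   arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(study_config, cfg[intersect(names(cfg),
                                      names(formals(study_config)))])
}

# dot-prefixed formals so short stage fields (n, m, seed) in ... can never
# partially match them
stage_log <- function(.manifest, .stage, .t0, ...) {
  elapsed <- as.numeric(difftime(Sys.time(), .t0, units = "secs"))
  message(sprintf("[%s] done in %.1fs", .stage, elapsed))
  .manifest$stages[[.stage]] <- c(list(seconds = round(elapsed, 2)),
                                  list(...))
  .manifest
}

#' Run the full study pipeline
#'
#' Simulate, preprocess, split, train, evaluate, interpret and report for
#' one instrument-adulterant dataset: generates the synthetic design,
#' applies SNV, splits 70/30, trains each configured architecture with the
#' protocol of [train_regressor()], evaluates train and test metrics,
#' computes averaged coefficient profiles with 50%-threshold important
#' features, and persists CSV tables (metrics, predictions with fitted
#' scatter slope/intercept, training history, coefficients, important
#' ranges) plus a JSON run manifest with file checksums.
#'
#' @param config A [study_config()] (or path to a YAML/JSON config).
#' @param outdir Output directory (created if missing).
#' @return The run manifest, invisibly (class `run_manifest`).
#' @export
run_study <- function(config = study_config(), outdir = tempfile("study")) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config_snapshot <- unclass(config)
  config_snapshot$library <- component_library_to_config(config$library)
  config_snapshot$noise <- unclass(config$noise)
  manifest <- list(config = config_snapshot,
                   master_seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package_version = as.character(
                     utils::packageVersion("nirquant")),
                   stages = list(), files = list())

  t0 <- Sys.time()
  stage <- "simulate"
  ds <- generate_design(design_spec(instrument = config$instrument,
                                    adulterant = config$adulterant,
                                    seed = config$seed),
                        library = config$library, noise = config$noise)
  raw_csv <- file.path(outdir, "dataset_raw.csv")
  write_dataset_csv(ds, raw_csv)
  manifest <- stage_log(manifest, stage, t0, n = nrow(ds$absorbance),
                        m = ncol(ds$absorbance),
                        stream_seed = ds$metadata$stream_seed)

  t0 <- Sys.time()
  pp <- if (config$apply_snv) snv_dataset(ds) else ds
  manifest <- stage_log(manifest, "preprocess", t0,
                        snv_applied = config$apply_snv)

  t0 <- Sys.time()
  sp <- split_train_test(pp, config$train_fraction, config$split_seed)
  manifest <- stage_log(manifest, "split", t0,
                        n_train = length(sp$train_idx),
                        n_test = length(sp$test_idx),
                        seed = config$split_seed)

  x <- pp$absorbance
  y <- pp$level_percent
  metric_rows <- list()
  pred_rows <- list()
  hist_rows <- list()
  for (arch in config$architectures) {
    t0 <- Sys.time()
    tc <- training_config(arch, max_epochs = config$max_epochs,
                          n_repeats = config$n_repeats,
                          seed = config$seed)
    fit <- train_regressor(x[sp$train_idx, , drop = FALSE],
                           y[sp$train_idx], tc)
    mtr <- evaluate_regressor(fit, pp, sp$train_idx)
    mte <- evaluate_regressor(fit, pp, sp$test_idx)
    metric_rows[[arch]] <- data.frame(
      Regressor = arch, Epoch = fit$epochs_run,
      train_r2 = mtr$r2, train_rmse = mtr$rmse, train_bias = mtr$bias,
      test_r2 = mte$r2, test_rmse = mte$rmse, test_bias = mte$bias,
      test_rpd = mte$rpd, band = mte$band)
    for (split_name in c("train", "test")) {
      idx <- if (split_name == "train") sp$train_idx else sp$test_idx
      p <- stats::predict(fit, x[idx, , drop = FALSE])
      line <- stats::coef(stats::lm(p ~ y[idx]))
      pred_rows[[paste(arch, split_name)]] <- data.frame(
        Regressor = arch, split = split_name, row = idx,
        existing = y[idx], predicted = p,
        slope = unname(line[2]), intercept = unname(line[1]))
    }
    hist_rows[[arch]] <- cbind(Regressor = arch, fit$history)
    manifest <- stage_log(manifest, paste0("train_", arch), t0,
                          epochs_run = fit$epochs_run,
                          best_validation_loss = fit$best_validation_loss)

    t0 <- Sys.time()
    prof <- mean_coefficients(fit, x[sp$train_idx, , drop = FALSE],
                              axis = pp$axis,
                              eps = config$interpretation_eps,
                              store_per_spectrum = FALSE)
    imp <- select_important(prof, config$threshold_fraction)
    data.table::fwrite(coefficient_table(prof, imp),
                       file.path(outdir,
                                 sprintf("coefficients_%s.csv", arch)))
    data.table::fwrite(imp$ranges,
                       file.path(outdir,
                                 sprintf("important_features_%s.csv", arch)))
    manifest <- stage_log(manifest, paste0("interpret_", arch), t0,
                          n_selected = length(imp$indices))
  }

  metrics <- do.call(rbind, metric_rows)
  data.table::fwrite(metrics, file.path(outdir, "metrics.csv"))
  data.table::fwrite(do.call(rbind, pred_rows),
                     file.path(outdir, "predictions.csv"))
  data.table::fwrite(do.call(rbind, hist_rows),
                     file.path(outdir, "history.csv"))
  best <- report_tables(list(metrics))
  best$instrument <- config$instrument
  best$adulterant <- config$adulterant
  data.table::fwrite(best, file.path(outdir, "best_regressor.csv"))

  files <- list.files(outdir, pattern = "\\.csv$", full.names = TRUE)
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outdir <- outdir
  manifest$metrics <- metrics
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s / %s, %d stage(s), %d file(s)\n",
              x$config$instrument, x$config$adulterant,
              length(x$stages), length(x$files)))
  invisible(x)
}

#' Best-regressor summary across runs
#'
#' Selects, per metrics table, the regressor with the highest test RPD;
#' ties break by lower test RMSE, then lexicographic architecture name.
#'
#' @param metrics_list List of metrics data frames as produced by
#'   [run_study()] (columns `Regressor`, `test_rpd`, `test_rmse`, ...).
#' @return Data frame with one row per input table: the best regressor and
#'   its test RPD.
#' @export
report_tables <- function(metrics_list) {
  if (length(metrics_list) == 0L) stop("no metrics supplied", call. = FALSE)
  rows <- lapply(metrics_list, function(mt) {
    mt <- as.data.frame(mt)
    ord <- order(-mt$test_rpd, mt$test_rmse, mt$Regressor)
    mt[ord[1L], c("Regressor", "test_rpd", "test_rmse"), drop = FALSE]
  })
  out <- do.call(rbind, rows)
  names(out) <- c("best_regressor", "test_rpd", "test_rmse")
  rownames(out) <- NULL
  out
}
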