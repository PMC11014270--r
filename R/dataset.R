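#' Spectral dataset
#'
#' Container pairing an n x m absorbance matrix (log 1/R units) with its
#' spectral axis, per-row sample bookkeeping (sample id, scan replicate,
#' percent-adulteration target) and provenance metadata.
#'
#' @param axis A [spectral_axis()].
#' @param absorbance Numeric matrix, one spectrum per row, `ncol` equal to
#'   the axis length.
#' @param sample_id Character vector of physical-sample identifiers.
#' @param scan Integer scan replicate index (1-3 in the study design).
#' @param level_percent Numeric target, percent w/w adulterant in \[0, 100\].
#' @param metadata Named list; typically `instrument`, `adulterant`
#'   (`"corn_flour"` or `"tapioca_starch"`), and `seed` or `source_file`.
#' @param snv_applied Logical flag set by [snv_dataset()].
#'
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(axis, absorbance, sample_id, scan, level_percent,
                             metadata = list(), snv_applied = FALSE) {
  stopifnot(inherits(axis, "spectral_axis"))
  absorbance <- as.matrix(absorbance)
  n <- nrow(absorbance)
  if (ncol(absorbance) != length(axis$values)) {
    stop(sprintf("absorbance has %d columns but the axis has %d points",
                 ncol(absorbance), length(axis$values)), call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  level_percent <- as.numeric(level_percent)
  if (length(sample_id) != n || length(scan) != n ||
      length(level_percent) != n) {
    stop("sample_id, scan and level_percent must have one entry per row",
         call. = FALSE)
  }
  if (any(!is.finite(level_percent)) || any(level_percent < 0) ||
      any(level_percent > 100)) {
    stop("level_percent must be finite and within [0, 100]", call. = FALSE)
  }
  structure(list(axis = axis,
                 absorbance = absorbance,
                 sample_id = as.character(sample_id),
                 scan = as.integer(scan),
                 level_percent = level_percent,
                 metadata = metadata,
                 snv_applied = isTRUE(snv_applied)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> n=%d spectra x m=%d features (%s, %s)%s\n",
    nrow(x$absorbance), ncol(x$absorbance), x$axis$instrument, x$axis$unit,
    if (x$snv_applied) " [SNV]" else ""))
  if (!is.null(x$metadata$adulterant)) {
    cat("  adulterant:", x$metadata$adulterant, "\n")
  }
  lv <- x$level_percent
  cat(sprintf("  level_percent: %g-%g%%, mean %.2f\n",
              min(lv), max(lv), mean(lv)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

#' Summary statistics of the adulteration target
#'
#' Reports n, m and the min, max, mean and sample standard deviation
#' (n-1 denominator) of the percent-adulteration target over a row
#' selection, matching the bookkeeping a study summary table carries.
#'
#' @param dataset A [spectral_dataset()].
#' @param indices Optional integer row selection (default: all rows).
#' @return A list with elements `n`, `m`, `min`, `max`, `mean`, `sd`.
#' @export
#' @examples
#' ds <- generate_design(design_spec(instrument = "Micro-NIR"))
#' summarize_dataset(ds)$mean   # 14 for the balanced 15-level design
summarize_dataset <- function(dataset, indices = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  y <- dataset$level_percent
  if (!is.null(indices)) {
    if (length(indices) == 0L) stop("empty selection", call. = FALSE)
    if (any(indices < 1L) || any(indices > length(y))) {
      stop("indices out of range", call. = FALSE)
    }
    y <- y[indices]
  }
  list(n = length(y), m = ncol(dataset$absorbance),
       min = min(y), max = max(y), mean = mean(y),
       sd = if (length(y) > 1L) stats::sd(y) else 0)
}

#' Random train/test split
#'
#' Splits `n` rows by a seeded uniform random permutation: the first
#' `floor(train_fraction * n)` permuted rows form the training set, the
#' remainder the test set. With the study's 450 spectra and the default
#' 70/30 fraction this yields the 315:135 partition.
#'
#' @param dataset A [spectral_dataset()], or a single integer row count.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer random state (default 42).
#' @return An object of class `split_indices`: list with `train_idx`,
#'   `test_idx`, `train_fraction`, `seed`.
#' @export
#' @examples
#' sp <- split_train_test(450)
#' length(sp$train_idx)  # 315
split_train_test <- function(dataset, train_fraction = 0.70, seed = 42L) {
  n <- if (inherits(dataset, "spectral_dataset")) {
    nrow(dataset$absorbance)
  } else {
    as.integer(dataset)
  }
  if (!is.finite(n) || n < 2L) stop("need at least 2 rows", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- floor(train_fraction * n)
  structure(list(train_idx = sort(perm[seq_len(n_train)]),
                 test_idx = sort(perm[seq.int(n_train + 1L, n)]),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> %d train : %d test (fraction %.2f, seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$train_fraction,
              x$seed))
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.csv$", ".json", path, ignore.case = TRUE)
}

#' Write a spectral dataset as wide CSV plus JSON sidecar
#'
#' The CSV is wide: columns `sample_id`, `scan`, `level_percent`, then one
#' column per axis position (header printed with four decimals). Metadata
#' (unit, instrument, adulterant, seed, SNV flag) lands in a JSON sidecar
#' next to the CSV (same name, `.json` extension).
#'
#' @param dataset A [spectral_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  dt <- data.table::data.table(sample_id = dataset$sample_id,
                               scan = dataset$scan,
                               level_percent = dataset$level_percent)
  spec <- data.table::as.data.table(dataset$absorbance)
  data.table::setnames(spec, sprintf("%.4f", dataset$axis$values))
  out <- cbind(dt, spec)
  data.table::fwrite(out, path)
  meta <- c(list(unit = dataset$axis$unit,
                 instrument = dataset$axis$instrument,
                 snv_applied = dataset$snv_applied),
            dataset$metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

plausible_unit_range <- function(unit) {
  # NIR working ranges; used to catch a sidecar unit contradicting the header
  if (unit == "nm") c(200, 3000) else c(3000, 30000)
}

#' Read a spectral dataset written by [write_dataset_csv()]
#'
#' Validates shape (no ragged rows), numeric absorbance, and consistency of
#' the header axis with the sidecar's unit and instrument tag; a write/read
#' round trip reproduces the dataset to 1e-9 on absorbance and exactly on
#' metadata.
#'
#' @param path CSV path; the JSON sidecar is expected alongside.
#' @return A [spectral_dataset()].
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mpath <- sidecar_path(path)
  if (!file.exists(mpath)) {
    stop("metadata sidecar not found: ", mpath, call. = FALSE)
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ",", fill = FALSE),
    error = function(e) {
      stop("format error reading ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  need <- c("sample_id", "scan", "level_percent")
  if (!all(need %in% names(dt)[1:3])) {
    stop("format error: first columns must be sample_id, scan, level_percent",
         call. = FALSE)
  }
  axis_cols <- setdiff(names(dt), need)
  axis_vals <- suppressWarnings(as.numeric(axis_cols))
  if (any(is.na(axis_vals))) {
    bad <- axis_cols[which(is.na(axis_vals))[1]]
    stop("format error: non-numeric axis header column \"", bad, "\"",
         call. = FALSE)
  }
  unit <- meta$unit
  if (is.null(unit) || !unit %in% c("nm", "cm-1")) {
    stop("sidecar must declare unit \"nm\" or \"cm-1\"", call. = FALSE)
  }
  rng <- plausible_unit_range(unit)
  if (min(axis_vals) < rng[1] || max(axis_vals) > rng[2]) {
    stop(sprintf(
      "unit mismatch: sidecar declares %s but header axis spans %.4g-%.4g",
      unit, min(axis_vals), max(axis_vals)), call. = FALSE)
  }
  instrument <- if (is.null(meta$instrument)) "custom" else meta$instrument
  if (instrument == "FT-NIR" && (unit != "cm-1" ||
                                 length(axis_vals) != 1102L)) {
    stop("unit mismatch: FT-NIR datasets use 1102 wavenumber (cm-1) columns",
         call. = FALSE)
  }
  if (instrument == "Micro-NIR" && (unit != "nm" ||
                                    length(axis_vals) != 125L)) {
    stop("unit mismatch: Micro-NIR datasets use 125 wavelength (nm) columns",
         call. = FALSE)
  }
  absmat <- as.matrix(dt[, axis_cols, with = FALSE])
  if (!is.numeric(absmat)) {
    bad <- which(!vapply(dt[, axis_cols, with = FALSE], is.numeric,
                         logical(1)))[1]
    stop("format error: non-numeric absorbance in column \"",
         axis_cols[bad], "\"", call. = FALSE)
  }
  if (any(!is.finite(absmat))) {
    idx <- which(!is.finite(absmat), arr.ind = TRUE)[1, ]
    stop(sprintf("format error: non-finite absorbance at row %d, column %s",
                 idx[1], axis_cols[idx[2]]), call. = FALSE)
  }
  # canonical instruments: the header prints rounded axis values, so
  # validate against the exact grid and restore it
  axis <- spectral_axis(axis_vals, unit, instrument)
  if (instrument %in% c("FT-NIR", "Micro-NIR")) {
    canon <- build_instrument_grid(instrument)
    step <- diff(canon$values)[1]
    if (max(abs(axis$values - canon$values)) > step / 2) {
      stop("unit mismatch: header axis does not match the canonical ",
           instrument, " grid", call. = FALSE)
    }
    axis <- canon
  }
  extra <- setdiff(names(meta), c("unit", "instrument", "snv_applied"))
  spectral_dataset(
    axis = axis,
    absorbance = absmat,
    sample_id = dt$sample_id,
    scan = dt$scan,
    level_percent = dt$level_percent,
    metadata = meta[extra],
    snv_applied = isTRUE(meta$snv_applied))
}

# Row subset keeping axis/metadata; used by the pipeline and evaluation.
subset_dataset <- function(dataset, indices) {
  spectral_dataset(dataset$axis,
                   dataset$absorbance[indices, , drop = FALSE],
                   dataset$sample_id[indices],
                   dataset$scan[indices],
                   dataset$level_percent[indices],
                   metadata = dataset$metadata,
                   snv_applied = dataset$snv_applied)
}
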