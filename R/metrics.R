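#' Coefficient of determination
#'
#' `R2 = 1 - sum((E - P)^2) / sum((E - mean(E))^2)` where `E` are the
#' existing (reference) values and `P` the predictions. May be negative
#' for predictors worse than the mean.
#'
#' @param existing,predicted Equal-length numeric vectors (length >= 2).
#' @return Scalar R-squared.
#' @export
r_squared <- function(existing, predicted) {
  check_pair(existing, predicted, min_n = 2L)
  denom <- sum((existing - mean(existing))^2)
  if (denom < 1e-24) {
    stop("R-squared undefined: existing values are constant", call. = FALSE)
  }
  1 - sum((existing - predicted)^2) / denom
}

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((E - P)^2))`, in the target's percent units.
#'
#' @inheritParams r_squared
#' @return Scalar RMSE (>= 0).
#' @export
rmse <- function(existing, predicted) {
  check_pair(existing, predicted)
  sqrt(mean((existing - predicted)^2))
}

#' Signed mean prediction error
#'
#' `Bias = mean(E - P)`: positive when the model under-predicts.
#'
#' @inheritParams r_squared
#' @return Scalar bias (percent units).
#' @export
bias <- function(existing, predicted) {
  check_pair(existing, predicted)
  mean(existing - predicted)
}

check_pair <- function(existing, predicted, min_n = 1L) {
  if (length(existing) != length(predicted)) {
    stop("existing and predicted must have equal length", call. = FALSE)
  }
  if (length(existing) < min_n) {
    stop("need at least ", min_n, " observations", call. = FALSE)
  }
  invisible(NULL)
}

#' Ratio of percent deviation from R-squared
#'
#' `RPD = 1 / sqrt(1 - R2)`, strictly increasing on \[0, 1) with
#' `rpd_from_r2(0) == 1`.
#'
#' @param r2 R-squared value, < 1.
#' @return Scalar RPD.
#' @export
#' @examples
#' rpd_from_r2(0.99)   # 10
rpd_from_r2 <- function(r2) {
  if (!is.numeric(r2) || length(r2) != 1L || !is.finite(r2)) {
    stop("r2 must be a finite scalar", call. = FALSE)
  }
  if (r2 >= 1) {
    stop("RPD is infinite for r2 >= 1 (perfect fit)", call. = FALSE)
  }
  1 / sqrt(1 - r2)
}

# Single source of truth for the quality bands. The published ranges leave
# gaps (3.0-3.1, 4.9-5.0, 6.4-6.5, 8.0-8.1); values in a gap fall to the
# lower band, so the effective upper edges are:
rpd_band_table <- function() {
  data.frame(band = c("poor", "fair", "good", "very_good", "excellent"),
             upper = c(3.1, 5.0, 6.5, 8.1, Inf),
             # half-open [lower, upper) except very_good which closes at 8.1
             stringsAsFactors = FALSE)
}

#' Classify an RPD value into a model-quality band
#'
#' Bands: RPD < 3.0 poor (unreliable); 3.1-4.9 fair (screening); 5.0-6.4
#' good (quality control); 6.5-8.0 very good (process control); > 8.1
#' excellent (any quantitative application). Values in the gaps between
#' the published ranges are assigned to the lower band.
#'
#' @param rpd Positive RPD value.
#' @return One of `"poor"`, `"fair"`, `"good"`, `"very_good"`,
#'   `"excellent"`.
#' @export
#' @examples
#' classify_rpd(2.958)    # poor
#' classify_rpd(20.866)   # excellent
classify_rpd <- function(rpd) {
  if (!is.numeric(rpd) || length(rpd) != 1L || !is.finite(rpd) || rpd <= 0) {
    stop("rpd must be a positive finite scalar", call. = FALSE)
  }
  if (rpd < 3.1) "poor"
  else if (rpd < 5.0) "fair"
  else if (rpd < 6.5) "good"
  else if (rpd <= 8.1) "very_good"
  else "excellent"
}

#' Evaluate a trained regressor on a dataset selection
#'
#' Computes all four statistics (R-squared, RMSE, Bias, RPD from the
#' unrounded R-squared) and the quality band over the selected rows. A
#' perfect fit (R2 == 1) is reported with infinite RPD and band
#' `"excellent"` by convention.
#'
#' @param trained A `trained_regressor`, any object with a `predict`
#'   method returning percent values, or a plain function mapping an
#'   n x m matrix to n predictions.
#' @param dataset A (typically SNV-preprocessed) [spectral_dataset()].
#' @param indices Optional integer row selection (default: all rows).
#' @return A list of class `regression_metrics`: `r2`, `rmse`, `bias`,
#'   `rpd`, `n`, `band`.
#' @export
evaluate_regressor <- function(trained, dataset, indices = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.null(indices)) indices <- seq_len(nrow(dataset$absorbance))
  if (length(indices) == 0L) stop("empty selection", call. = FALSE)
  x <- dataset$absorbance[indices, , drop = FALSE]
  e <- dataset$level_percent[indices]
  p <- if (is.function(trained)) trained(x) else stats::predict(trained, x)
  regression_metrics(e, p)
}

#' Metrics from persisted (existing, predicted) pairs
#'
#' @param existing,predicted Equal-length numeric vectors.
#' @return A `regression_metrics` list.
#' @export
regression_metrics <- function(existing, predicted) {
  r2 <- r_squared(existing, predicted)
  rp <- if (r2 >= 1) Inf else 1 / sqrt(1 - r2)
  structure(list(r2 = r2,
                 rmse = rmse(existing, predicted),
                 bias = bias(existing, predicted),
                 rpd = rp,
                 n = length(existing),
                 band = if (is.infinite(rp)) "excellent" else
                   classify_rpd(max(rp, .Machine$double.eps))),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf(
    "<regression_metrics> n=%d  R2=%.4f  RMSE=%.3f%%  Bias=%.3f  RPD=%.3f (%s)\n",
    x$n, x$r2, x$rmse, x$bias, x$rpd, x$band))
  invisible(x)
}
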