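#' Standard normal variate transform of one spectrum
#'
#' Centers and scales a single spectrum to mean 0 and sample standard
#' deviation 1 (n-1 denominator). SNV is fit-free and per-spectrum, so it
#' removes multiplicative gain and baseline offset exactly:
#' `snv(a*x + b) == snv(x)` for any `a > 0`.
#'
#' @param x Numeric absorbance vector, length >= 2, not constant.
#' @return The standardized vector.
#' @export
#' @examples
#' snv(c(1, 2, 3))   # -1 0 1
snv <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("snv needs a numeric vector of length >= 2", call. = FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop("degenerate input: constant spectrum has no SNV transform",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Row-wise SNV of a dataset
#'
#' Applies [snv()] to every spectrum; targets and metadata are unchanged
#' and the result carries `snv_applied = TRUE`.
#'
#' @param dataset A [spectral_dataset()].
#' @return The transformed [spectral_dataset()].
#' @export
snv_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  x <- dataset$absorbance
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  bad <- which(!is.finite(s) | s < 1e-12)
  if (length(bad) > 0L) {
    stop("degenerate input: constant spectrum in row ", bad[1],
         call. = FALSE)
  }
  spectral_dataset(dataset$axis, xc / s, dataset$sample_id, dataset$scan,
                   dataset$level_percent, metadata = dataset$metadata,
                   snv_applied = TRUE)
}
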