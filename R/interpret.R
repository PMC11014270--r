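# Perturbation-based "regression coefficients" of a trained network:
# forward finite differences, one coordinate at a time, averaged over the
# training spectra, with 50%-of-peak important-wavelength selection.

predictor_fun <- function(trained) {
  if (is.function(trained)) {
    function(x) {
      out <- apply(x, 1L, trained)
      as.numeric(out)
    }
  } else {
    function(x) stats::predict(trained, x)
  }
}

#' Per-spectrum perturbation weights
#'
#' Finite-difference sensitivity of the predictor at one spectrum:
#' `w_j = (f(x + eps * e_j) - f(x)) / eps`, perturbing one coordinate at a
#' time. For an affine predictor this recovers the slope vector exactly up
#' to finite-difference error. The whole evaluation runs in double
#' precision; if every perturbed prediction is bitwise equal to the base
#' prediction, a precision warning recommends a larger `eps`.
#'
#' @param trained A `trained_regressor`, or any function mapping a
#'   length-m numeric vector to a scalar.
#' @param x Length-m numeric vector (an SNV-scaled model input).
#' @param eps Perturbation size (default `1e-6`).
#' @return Length-m numeric weight vector.
#' @export
per_spectrum_weights <- function(trained, x, eps = 1e-6) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  x <- as.numeric(x)
  m <- length(x)
  f <- predictor_fun(trained)
  X <- matrix(x, nrow = m + 1L, ncol = m, byrow = TRUE)
  X[cbind(seq_len(m) + 1L, seq_len(m))] <-
    X[cbind(seq_len(m) + 1L, seq_len(m))] + eps
  pred <- f(X)
  w <- (pred[-1L] - pred[1L]) / eps
  if (all(pred[-1L] == pred[1L])) {
    # every perturbed output identical to the base output
    warning("perturbation eps = ", format(eps), " is below the model's ",
            "numeric resolution; all finite differences are zero - ",
            "consider a larger eps", call. = FALSE)
  }
  w
}

#' Averaged regression-coefficient profile
#'
#' Element-wise mean of the per-spectrum finite-difference weight vectors
#' over all training spectra: the network's "regression coefficient" per
#' wavelength. Deterministic given the trained model and invariant to the
#' row order of `x_train`.
#'
#' @param trained A `trained_regressor` or predictor function.
#' @param x_train n x m matrix of (SNV-scaled) training spectra.
#' @param axis Optional [spectral_axis()] attached to the profile for
#'   reporting in both nm and cm-1.
#' @param eps Perturbation size (default `1e-6`).
#' @param store_per_spectrum Keep the full n x m per-spectrum weight
#'   matrix (default `TRUE`).
#' @return A list of class `coefficient_profile`: `axis`, `mean_weights`
#'   (length m), optional `per_spectrum_weights` (n x m), `eps`, `n`.
#' @export
mean_coefficients <- function(trained, x_train, axis = NULL, eps = 1e-6,
                              store_per_spectrum = TRUE) {
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  m <- ncol(x_train)
  if (n == 0L) stop("x_train is empty", call. = FALSE)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    W[i, ] <- suppressWarnings(
      per_spectrum_weights(trained, x_train[i, ], eps))
  }
  if (all(W == 0)) {
    warning("all per-spectrum finite differences are zero at eps = ",
            format(eps), "; consider a larger eps", call. = FALSE)
  }
  structure(list(axis = axis,
                 mean_weights = colMeans(W),
                 per_spectrum_weights = if (store_per_spectrum) W else NULL,
                 eps = eps, n = n),
            class = "coefficient_profile")
}

#' @export
print.coefficient_profile <- function(x, ...) {
  cat(sprintf(
    "<coefficient_profile> m=%d features, averaged over n=%d spectra, range %.4g to %.4g\n",
    length(x$mean_weights), x$n, min(x$mean_weights), max(x$mean_weights)))
  invisible(x)
}

#' Select important wavelengths by the 50%-of-peak rule
#'
#' Applies a signed threshold: features whose averaged coefficient exceeds
#' `threshold_fraction * max(w)` or falls below
#' `threshold_fraction * min(w)` are selected. Contiguous runs of selected
#' grid indices are merged into reported ranges labeled in both nm and
#' cm-1. Raising the fraction never adds features.
#'
#' @param profile A [mean_coefficients()] profile (or any list with
#'   `mean_weights` and optionally `axis`).
#' @param threshold_fraction Fraction of each peak (default 0.50).
#' @return A list of class `important_features`: `indices` (sorted,
#'   1-based), `positive_cutoff`, `negative_cutoff`,
#'   `threshold_fraction`, and `ranges` (data frame of merged contiguous
#'   intervals with axis labels when an axis is attached).
#' @export
#' @examples
#' prof <- list(mean_weights = c(10, 6, -8, -3))
#' select_important(prof)$indices   # 1 2 3
select_important <- function(profile, threshold_fraction = 0.50) {
  w <- profile$mean_weights
  if (is.null(w)) stop("profile has no mean_weights", call. = FALSE)
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    stop("threshold_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (diff(range(w)) < 1e-24) {
    stop("degenerate profile: all coefficients equal", call. = FALSE)
  }
  pos_cut <- threshold_fraction * max(w)
  neg_cut <- threshold_fraction * min(w)
  sel <- which((max(w) > 0 & w >= pos_cut) | (min(w) < 0 & w <= neg_cut))
  ranges <- merge_index_runs(sel, profile$axis)
  structure(list(indices = sel,
                 positive_cutoff = pos_cut,
                 negative_cutoff = neg_cut,
                 threshold_fraction = threshold_fraction,
                 ranges = ranges),
            class = "important_features")
}

merge_index_runs <- function(idx, axis = NULL) {
  if (length(idx) == 0L) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  starts <- idx[brk[-length(brk)] + 1L]
  ends <- idx[brk[-1L]]
  out <- data.frame(start_idx = starts, end_idx = ends)
  if (!is.null(axis)) {
    lab <- axis_both_units(axis)
    out$start_nm <- lab$axis_nm[starts]
    out$end_nm <- lab$axis_nm[ends]
    out$start_cm1 <- lab$axis_cm1[starts]
    out$end_cm1 <- lab$axis_cm1[ends]
    out$label <- ifelse(
      starts == ends,
      sprintf("%.0f cm-1 (%.0f nm)", pmax(out$start_cm1, out$end_cm1),
              pmin(out$start_nm, out$end_nm)),
      sprintf("%.0f-%.0f cm-1 (%.0f-%.0f nm)",
              pmax(out$start_cm1, out$end_cm1),
              pmin(out$start_cm1, out$end_cm1),
              pmin(out$start_nm, out$end_nm),
              pmax(out$start_nm, out$end_nm)))
  }
  out
}

#' @export
print.important_features <- function(x, ...) {
  cat(sprintf(
    "<important_features> %d features beyond cutoffs (%.4g, %.4g) at fraction %.2f\n",
    length(x$indices), x$negative_cutoff, x$positive_cutoff,
    x$threshold_fraction))
  if (!is.null(x$ranges$label)) {
    cat(" ", paste(x$ranges$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coefficient profile as a report table
#'
#' One row per feature with axis labels in both units, the averaged
#' weight, and the selection flag.
#'
#' @param profile A [mean_coefficients()] profile with an axis attached.
#' @param important Optional [select_important()] result; computed at the
#'   default 50% threshold when missing.
#' @return A data frame with columns `axis_cm1`, `axis_nm`, `mean_weight`,
#'   `selected`.
#' @export
coefficient_table <- function(profile, important = NULL) {
  if (is.null(profile$axis)) stop("profile has no axis", call. = FALSE)
  if (is.null(important)) important <- select_important(profile)
  lab <- axis_both_units(profile$axis)
  data.frame(axis_cm1 = lab$axis_cm1,
             axis_nm = lab$axis_nm,
             mean_weight = profile$mean_weights,
             selected = seq_along(profile$mean_weights) %in%
               important$indices)
}
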