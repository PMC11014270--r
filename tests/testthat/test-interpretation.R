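test_that("finite-difference weights recover an affine predictor's slopes", {
  f <- affine_predictor(c(3, -2), intercept = 1)
  w <- per_spectrum_weights(f, c(0.4, -1.2), eps = 1e-3)
  expect_equal(w, c(3, -2), tolerance = 1e-4)

  # larger affine system, exactness across several evaluation points
  withr::local_seed(21)
  slopes <- rnorm(20)
  g <- affine_predictor(slopes, intercept = -4)
  for (i in 1:3) {
    x <- rnorm(20)
    expect_equal(per_spectrum_weights(g, x, eps = 1e-3), slopes,
                 tolerance = 1e-4)
  }
})

test_that("constant predictors give zero weights and a precision warning", {
  f <- function(x) 5
  expect_warning(w <- per_spectrum_weights(f, rnorm(10)), "resolution")
  expect_equal(w, rep(0, 10))
})

test_that("forward differences agree with a central-difference oracle", {
  # smooth nonlinear surrogate: f(x) = sum(sin(x)) + (x1)^2
  f <- function(x) sum(sin(x)) + x[1]^2
  x <- c(0.3, -0.7, 1.1, 0.05)
  eps <- 1e-5
  w_fwd <- per_spectrum_weights(f, x, eps)
  w_ctr <- vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + eps
    xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  expect_equal(w_fwd, w_ctr, tolerance = 1e-3)
  # and both agree with the analytic gradient cos(x) + 2 x1 e1
  grad <- cos(x); grad[1] <- grad[1] + 2 * x[1]
  expect_equal(w_fwd, grad, tolerance = 1e-3)
})

test_that("mean coefficients average per-spectrum weights element-wise", {
  withr::local_seed(22)
  slopes <- c(2, -1, 0.5)
  f <- affine_predictor(slopes)
  X <- matrix(rnorm(15), 5, 3)
  prof <- mean_coefficients(f, X, eps = 1e-3)
  # linearity: every per-spectrum vector equals the slope vector
  expect_equal(prof$mean_weights, slopes, tolerance = 1e-4)
  for (i in 1:5) {
    expect_equal(prof$per_spectrum_weights[i, ], slopes, tolerance = 1e-4)
  }
  # definition check on a nonlinear predictor
  g <- function(x) sum(x^2)
  pg <- mean_coefficients(g, X, eps = 1e-6)
  expect_equal(pg$mean_weights, colMeans(pg$per_spectrum_weights))
  # row-order invariance
  pg2 <- mean_coefficients(g, X[5:1, ], eps = 1e-6)
  expect_equal(pg$mean_weights, pg2$mean_weights, tolerance = 1e-9)
  expect_error(mean_coefficients(g, X[0, , drop = FALSE]), "empty")
})

test_that("interpretation of a trained network works at the default eps", {
  withr::local_seed(23)
  ds <- tiny_clean_dataset()
  pp <- snv_dataset(ds)
  cfg <- training_config("simple_cnn", max_epochs = 30, n_repeats = 1,
                         seed = 5, batch_size = 30)
  fit <- train_regressor(pp$absorbance, pp$level_percent, cfg)
  prof <- mean_coefficients(fit, pp$absorbance[1:10, ], axis = pp$axis)
  expect_length(prof$mean_weights, 125L)
  expect_gt(max(abs(prof$mean_weights)), 0)  # eps = 1e-6 resolves in double
  imp <- select_important(prof)
  tab <- coefficient_table(prof, imp)
  expect_equal(nrow(tab), 125L)
  expect_equal(sum(tab$selected), length(imp$indices))
  expect_true(all(c("axis_cm1", "axis_nm") %in% names(tab)))
})

test_that("the 50% threshold rule matches brute-force enumeration", {
  w <- c(10, 6, -8, -3)
  imp <- select_important(list(mean_weights = w))
  expect_equal(imp$positive_cutoff, 5)
  expect_equal(imp$negative_cutoff, -4)
  expect_equal(imp$indices, c(1L, 2L, 3L))

  expect_equal(select_important(list(mean_weights = c(1, 0, -1)))$indices,
               c(1L, 3L))
  # fraction 1.0 keeps only the extremes
  expect_equal(
    select_important(list(mean_weights = c(1, 0.5, -0.2, -1, 0.99)),
                     threshold_fraction = 1)$indices,
    c(1L, 4L))

  # randomized brute-force cross-check
  withr::local_seed(24)
  for (i in 1:20) {
    w <- rnorm(40)
    fr <- runif(1, 0.2, 0.9)
    got <- select_important(list(mean_weights = w), fr)$indices
    want <- which(w >= fr * max(w) | w <= fr * min(w))
    expect_identical(got, want)
  }
  expect_error(select_important(list(mean_weights = rep(2, 5))),
               "degenerate")
})

test_that("raising the threshold fraction never adds features", {
  withr::local_seed(25)
  for (i in 1:10) {
    w <- rnorm(60)
    prev <- NULL
    for (fr in c(0.25, 0.5, 0.75, 1)) {
      cur <- select_important(list(mean_weights = w), fr)$indices
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("selected runs merge into contiguous dual-unit ranges", {
  ax <- micro_axis()
  w <- numeric(125)
  w[c(10, 11, 12, 40, 90, 91)] <- 1
  w[60] <- -1
  prof <- list(mean_weights = w, axis = ax)
  imp <- select_important(prof, 0.5)
  expect_equal(imp$indices, c(10L, 11L, 12L, 40L, 60L, 90L, 91L))
  expect_equal(nrow(imp$ranges), 4L)
  expect_equal(imp$ranges$start_idx, c(10L, 40L, 60L, 90L))
  expect_equal(imp$ranges$end_idx, c(12L, 40L, 60L, 91L))
  expect_true(all(grepl("cm-1 \\(", imp$ranges$label)))
  # nm labels ascend while cm-1 labels descend within a range
  r1 <- imp$ranges[1, ]
  expect_lt(r1$start_nm, r1$end_nm)
  expect_gt(r1$start_cm1, r1$end_cm1)
})

test_that("coefficients are invariant to raw-spectrum scaling via SNV", {
  withr::local_seed(26)
  ds <- tiny_clean_dataset(levels = c(1, 20, 50), samples_per_level = 3L)
  f <- affine_predictor(rnorm(125))
  x_raw <- ds$absorbance
  x_scaled <- 2 * x_raw
  snv_rows <- function(m) t(apply(m, 1, snv))
  p1 <- mean_coefficients(f, snv_rows(x_raw), eps = 1e-3)
  p2 <- mean_coefficients(f, snv_rows(x_scaled), eps = 1e-3)
  expect_equal(p1$mean_weights, p2$mean_weights, tolerance = 1e-9)
})
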