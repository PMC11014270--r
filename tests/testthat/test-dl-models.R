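test_that("every architecture builds with a single linear output unit", {
  for (arch in c("simple_cnn", "s_alexnet", "resnet", "googlenet")) {
    m <- if (arch == "s_alexnet") 125L else 32L
    net <- build_model(arch, m, seed = 3)
    expect_s3_class(net, "nn_network")
    expect_gt(net$n_params, 0)
    x <- matrix(rnorm(5 * m), 5, m)
    out <- nirquant:::network_forward(net, nirquant:::as_input_tensor(x))
    expect_equal(dim(out), c(5L, 1L))
    expect_true(all(is.finite(out)))
  }
  expect_error(build_model("vgg", 125), "arg")
  expect_error(build_model("simple_cnn", 10), "minimal admissible length")
  expect_error(build_model("s_alexnet", 30), "minimal admissible length")
})

test_that("residual blocks pass the input through when convolutions are zeroed", {
  net <- build_model("resnet", 125, seed = 1)
  block <- Filter(function(l) inherits(l, "nn_residual"), net$layers)[[1]]
  expect_null(block$children$proj)  # identity shortcut (32 -> 32, stride 1)
  for (nm in c("conv1", "conv2")) {
    ch <- block$children[[nm]]
    ch$params$W[] <- 0
    ch$params$b[] <- 0
  }
  x <- array(abs(rnorm(4 * 30 * 32)), c(4, 30, 32))  # non-negative input
  y <- nirquant:::layer_forward(block, x, training = FALSE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("inception output channels equal the sum of branch channels", {
  net <- build_model("googlenet", 125, seed = 1)
  modules <- Filter(function(l) inherits(l, "nn_inception"), net$layers)
  expect_length(modules, 2L)
  for (mod in modules) {
    expect_equal(mod$out_ch, sum(mod$branch_channels))
    x <- array(rnorm(3 * 20 * mod$in_ch), c(3, 20, mod$in_ch))
    y <- nirquant:::layer_forward(mod, x, training = FALSE)
    expect_equal(dim(y)[3], mod$out_ch)
    expect_equal(dim(y)[2], 20L)  # all branches length-preserving
  }
})

test_that("per-architecture hyperparameter defaults follow the protocol", {
  cfg <- training_config("simple_cnn")
  expect_equal(c(cfg$batch_size, cfg$max_epochs, cfg$patience),
               c(128L, 1000L, 200L))
  expect_equal(cfg$learning_rate, 5e-3)
  expect_equal(cfg$val_fraction, 0.10)
  expect_equal(cfg$n_repeats, 11L)
  cfg <- training_config("s_alexnet")
  expect_equal(c(cfg$batch_size, cfg$max_epochs, cfg$patience),
               c(16L, 300L, 300L))
  expect_equal(cfg$learning_rate, 1e-5)
  for (arch in c("resnet", "googlenet")) {
    cfg <- training_config(arch)
    expect_equal(c(cfg$batch_size, cfg$max_epochs, cfg$patience),
                 c(160L, 1000L, 200L))
    expect_equal(cfg$learning_rate, 1e-5)
  }
})

test_that("validation split arithmetic matches the protocol's 315 -> 32", {
  expect_equal(validation_size(315), 32L)
  for (n in c(10, 45, 100, 283, 315, 450)) {
    expect_equal(validation_size(n), n - floor(0.9 * n))
  }
})

test_that("training fits a constant-target problem to near zero loss", {
  withr::local_seed(4)
  # near-replicate spectra with a constant target: degenerate regression
  base <- snv(rnorm(32))
  x <- matrix(rep(base, each = 60), 60, 32) +
    matrix(rnorm(60 * 32, 0, 0.005), 60, 32)
  y <- rep(7, 60)
  cfg <- training_config("simple_cnn", max_epochs = 400, n_repeats = 1,
                         seed = 9, batch_size = 16, learning_rate = 0.05)
  fit <- train_regressor(x, y, cfg)
  p <- predict(fit, x)
  expect_true(all(abs(p - 7) < 0.1))
  expect_lte(fit$epochs_run, 400L)
})

test_that("training is deterministic under a fixed seed", {
  withr::local_seed(5)
  x <- matrix(rnorm(50 * 32), 50, 32)
  y <- rowSums(x[, 1:4]) + 5
  cfg <- training_config("simple_cnn", max_epochs = 15, n_repeats = 2,
                         seed = 11, batch_size = 25)
  f1 <- train_regressor(x, y, cfg)
  f2 <- train_regressor(x, y, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(predict(f1, x), predict(f2, x), tolerance = 1e-12)
  expect_equal(f1$epochs_run, 30L)  # cumulative across repeats
})

test_that("early stopping restores the best validation weights", {
  withr::local_seed(6)
  x <- matrix(rnorm(60 * 32), 60, 32)
  y <- 2 * x[, 3] + rnorm(60, 0, 0.1) + 10
  cfg <- training_config("simple_cnn", max_epochs = 400, n_repeats = 1,
                         seed = 2, batch_size = 30, patience = 10)
  fit <- train_regressor(x, y, cfg)
  expect_lte(fit$epochs_run, 400L)
  hist <- fit$history
  expect_equal(fit$best_validation_loss, min(hist$val_loss))
  # restored weights reproduce the best validation loss, not the final one
  val_n <- fit$n_val
  expect_true(fit$best_validation_loss <=
                hist$val_loss[nrow(hist)] + 1e-12)
})

test_that("every architecture can fit the noise-free task (capacity)", {
  # noise-free Micro-NIR design, one scan per sample: pure capacity check.
  # The protocol learning rate of the three large architectures (1e-5) is
  # far too small to move predictions meaningfully at desk scale, so the
  # capacity check uses a faster rate; epoch budgets stay at or below the
  # architectures' defaults.
  ds <- generate_design(
    design_spec(levels = c(1, 2, 4, 6, 8, 10, 15, 20, 30, 40, 50),
                samples_per_level = 3L, scans_per_sample = 1L,
                instrument = "Micro-NIR"),
    noise = noise_free())
  pp <- snv_dataset(ds)
  budgets <- list(simple_cnn = c(5e-3, 200),
                  s_alexnet = c(1e-3, 200),
                  resnet = c(1e-3, 200),
                  googlenet = c(1e-3, 800))
  for (arch in names(budgets)) {
    cfg <- training_config(arch, max_epochs = budgets[[arch]][2],
                           n_repeats = 1, seed = 42,
                           learning_rate = budgets[[arch]][1],
                           batch_size = 33,
                           patience = budgets[[arch]][2])
    fit <- train_regressor(pp$absorbance, pp$level_percent, cfg)
    p <- predict(fit, pp$absorbance)
    expect_lt(mean((p - pp$level_percent)^2), 0.5)
  }
})

test_that("prediction is shape-safe and row-equivariant", {
  withr::local_seed(8)
  x <- matrix(rnorm(40 * 32), 40, 32)
  y <- rowMeans(x) * 3
  cfg <- training_config("simple_cnn", max_epochs = 5, n_repeats = 1,
                         seed = 3, batch_size = 20)
  fit <- train_regressor(x, y, cfg)
  expect_identical(predict(fit, x[0, , drop = FALSE]), numeric(0))
  p <- predict(fit, x)
  perm <- sample(40)
  expect_equal(predict(fit, x[perm, ]), p[perm], tolerance = 1e-12)
  expect_error(predict(fit, x[, 1:10]), "expects")
})

test_that("diverging training raises an informative error", {
  withr::local_seed(10)
  x <- matrix(rnorm(40 * 32), 40, 32)
  y <- rnorm(40)
  cfg <- training_config("simple_cnn", max_epochs = 50, n_repeats = 1,
                         seed = 1, batch_size = 20, learning_rate = 1e150)
  expect_error(train_regressor(x, y, cfg), "diverged.*epoch")
})
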