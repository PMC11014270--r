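test_that("wavelength/wavenumber conversion is reciprocal and involutive", {
  expect_equal(round(convert_axis(5176, "cm-1", "nm")), 1932)
  expect_equal(convert_axis(10000, "cm-1", "nm"), 1000)
  expect_identical(convert_axis(1447, "nm", "nm"), 1447)
  for (x in c(1447, 908, 1676, 4000, 12500, 0.5)) {
    expect_equal(convert_axis(convert_axis(x, "nm", "cm-1"), "cm-1", "nm"),
                 x, tolerance = 1e-9)
  }
  expect_error(convert_axis(-3, "nm", "cm-1"), "positive")
  expect_error(convert_axis(0, "cm-1", "nm"), "positive")
})

test_that("canonical instrument grids match the study feature counts", {
  ft <- build_instrument_grid("FT-NIR")
  expect_s3_class(ft, "spectral_axis")
  expect_length(ft$values, 1102L)
  expect_equal(ft$unit, "cm-1")
  expect_equal(range(ft$values), c(4000, 12500))
  expect_equal(diff(ft$values)[1], 8500 / 1101, tolerance = 1e-9)

  mi <- build_instrument_grid("Micro-NIR")
  expect_length(mi$values, 125L)
  expect_equal(mi$unit, "nm")
  expect_equal(mi$values[1], 908)
  expect_equal(mi$values[125], 1676)
  expect_equal(diff(mi$values)[1], 768 / 124, tolerance = 1e-9)

  expect_error(build_instrument_grid("NIR-9000"), "unknown instrument")
})

test_that("axis values must be strictly monotone and positive", {
  expect_error(spectral_axis(c(1, 1, 2), "nm"), "monotone")
  expect_error(spectral_axis(5, "nm"), "at least 2")
  # descending input is normalized to ascending storage
  ax <- spectral_axis(c(12500, 4000), "cm-1")
  expect_equal(ax$values, c(4000, 12500))
})

test_that("train/test split is a seeded permutation with floor sizing", {
  sp <- split_train_test(450, 0.70, 42)
  expect_length(sp$train_idx, 315L)
  expect_length(sp$test_idx, 135L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:450)

  sp2 <- split_train_test(450, 0.70, 42)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(450, 0.70, 43)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  for (case in list(c(10, 0.5), c(7, 0.3), c(101, 0.7))) {
    s <- split_train_test(case[1], case[2], 1)
    expect_length(s$train_idx, floor(case[2] * case[1]))
    expect_length(s$test_idx, case[1] - floor(case[2] * case[1]))
    expect_setequal(c(s$train_idx, s$test_idx), seq_len(case[1]))
  }

  expect_error(split_train_test(450, 1.0), "strictly between")
  expect_error(split_train_test(450, 0), "strictly between")
  expect_error(split_train_test(1), "at least 2")
})

test_that("target summary reproduces the balanced-design statistics", {
  ds <- tiny_clean_dataset(levels = c(1:10, 15, 20, 30, 40, 50),
                           samples_per_level = 2L)
  s <- summarize_dataset(ds)
  expect_equal(s$mean, 14)
  expect_equal(s$min, 1)
  expect_equal(s$max, 50)
  # closed form: sample SD of each level repeated equally often
  expect_equal(s$sd, sd(rep(c(1:10, 15, 20, 30, 40, 50), each = 2)))
  # frozen value for the full 30-replicate design, computed independently
  # from the level table: sd(rep(levels, each = 30)) = 14.322098
  full <- rep(c(1:10, 15, 20, 30, 40, 50), each = 30)
  expect_equal(sd(full), 14.322098, tolerance = 1e-6)

  one <- summarize_dataset(ds, which(ds$level_percent == 5))
  expect_equal(one$sd, 0)
  expect_equal(one$mean, 5)
  expect_error(summarize_dataset(ds, integer(0)), "empty")
})

test_that("CSV round trip preserves data and sidecar metadata", {
  ds <- tiny_clean_dataset()
  path <- file.path(withr::local_tempdir(), "ds.csv")
  write_dataset_csv(ds, path)
  expect_true(file.exists(sub("csv$", "json", path)))
  back <- read_dataset_csv(path)
  expect_equal(back$absorbance, ds$absorbance, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$level_percent, ds$level_percent)
  expect_identical(back$sample_id, ds$sample_id)
  expect_equal(back$axis$values, ds$axis$values, tolerance = 1e-9)
  expect_identical(back$metadata$adulterant, ds$metadata$adulterant)
  expect_identical(back$axis$instrument, "Micro-NIR")
})

test_that("malformed CSV input is rejected with a format error", {
  dir <- withr::local_tempdir()
  ds <- tiny_clean_dataset(levels = c(1, 50), samples_per_level = 2L)
  path <- file.path(dir, "ds.csv")
  write_dataset_csv(ds, path)

  # ragged row: one value short
  lines <- readLines(path)
  parts <- strsplit(lines[2], ",")[[1]]
  bad <- file.path(dir, "ragged.csv")
  writeLines(c(lines[1], paste(parts[-length(parts)], collapse = ",")),
             bad)
  file.copy(sub("csv$", "json", path), sub("csv$", "json", bad))
  expect_error(read_dataset_csv(bad), "format error")

  # sidecar unit contradicting the wavenumber-range header
  meta <- jsonlite::read_json(sub("csv$", "json", path),
                              simplifyVector = TRUE)
  ft <- generate_design(design_spec(levels = c(1, 50),
                                    samples_per_level = 1L,
                                    scans_per_sample = 1L,
                                    instrument = "FT-NIR"),
                        noise = noise_free())
  ftpath <- file.path(dir, "ft.csv")
  write_dataset_csv(ft, ftpath)
  meta_ft <- jsonlite::read_json(sub("csv$", "json", ftpath),
                                 simplifyVector = TRUE)
  meta_ft$unit <- "nm"
  jsonlite::write_json(meta_ft, sub("csv$", "json", ftpath),
                       auto_unbox = TRUE)
  expect_error(read_dataset_csv(ftpath), "mismatch")
})
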