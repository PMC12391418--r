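test_that("spectra CSV writer and reader are inverse", {
  fx <- make_fixtures("small", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(fx$set, path)
  back <- read_spectra_table(path)
  expect_equal(back$spectra, fx$set$spectra, tolerance = 1e-9)
  expect_equal(back$labels, fx$set$labels, tolerance = 1e-12)
  expect_equal(back$meta$combo_id, fx$set$meta$combo_id)
  expect_equal(back$meta$replicate, fx$set$meta$replicate)
  expect_equal(wn_axis(back$grid), wn_axis(fx$set$grid), tolerance = 1e-9)
})

test_that("the reader accepts foreign layouts via a column mapping", {
  fx <- make_fixtures("small")
  path <- withr::local_tempfile(fileext = ".csv")
  dt <- data.table::as.data.table(fx$set$spectra)
  data.table::setnames(dt, sprintf("%.4f", wn_axis(fx$set$grid)))
  dt$UA <- fx$set$labels$uric_acid
  dt$LA <- fx$set$labels$lactate
  dt$grp <- fx$set$meta$combo_id
  data.table::fwrite(dt, path)
  set <- read_spectra_table(path, mapping = list(
    labels = c(uric_acid = "UA", lactate = "LA"), combo_id = "grp"))
  expect_equal(names(set$labels), c("uric_acid", "lactate"))
  expect_equal(set$labels$uric_acid, fx$set$labels$uric_acid)
  expect_equal(set$meta$combo_id, fx$set$meta$combo_id)
  expect_error(read_spectra_table(path, mapping = list(
    labels = c(uric_acid = "missing_col"))), "missing label")
})

test_that("the reader fails informatively on malformed input", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_spectra_table(empty), "no spectra|parse")
  expect_error(read_spectra_table(file.path(tempdir(), "nope.csv")),
               "no such file")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("500.0,501.0,uric_acid_uM", "1.0,oops,5", "2.0,3.0,10"), bad)
  expect_error(read_spectra_table(bad), "non-numeric")
})

test_that("instrument two-column exports feed into vectorize", {
  path <- withr::local_tempfile(fileext = ".txt")
  g <- wn_grid(500, 600, 51)
  ax <- seq(495, 605, by = 0.7)
  writeLines(c("# spectrometer export", paste(ax, ax * 2)), path)
  raw <- read_instrument_spectrum(path)
  expect_equal(names(raw), c("wavenumber", "intensity"))
  v <- vectorize(raw$wavenumber, raw$intensity, g)
  expect_equal(v, wn_axis(g) * 2, tolerance = 1e-9)
})

test_that("fixture bundles have the documented sizes and are seeded", {
  fx <- make_fixtures("small", seed = 9)
  expect_equal(dim(fx$set$spectra), c(24, 200))   # 6 combos x 4 replicates
  expect_equal(nrow(fx$design$combos), 6)
  fx2 <- make_fixtures("small", seed = 9)
  expect_identical(fx$set$spectra, fx2$set$spectra)
  expect_false(identical(make_fixtures("small", seed = 10)$set$spectra,
                         fx$set$spectra))
})

test_that("pipeline config round-trips through JSON", {
  cfg <- pipeline_config(
    grid = desk_grid(120), design = default_design(replicates = 2),
    quantifier = tiny_config(), cv_repeats = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_pipeline_config(cfg, path)
  cfg2 <- read_pipeline_config(path)
  expect_equal(cfg2$grid$axis, cfg$grid$axis)
  expect_equal(cfg2$design$combos, cfg$design$combos, tolerance = 1e-12)
  expect_equal(unclass(cfg2$quantifier), unclass(cfg$quantifier))
  expect_equal(unclass(cfg2$noise), unclass(cfg$noise))
  expect_equal(cfg2$seed, cfg$seed)
  expect_error(pipeline_config(grid = desk_grid(120),
                               quantifier = quantifier_config()),
               "input_dim")
})

test_that("the end-to-end pipeline runs, persists and reproduces", {
  cfg <- pipeline_config(
    grid = desk_grid(120), design = default_design(replicates = 2),
    quantifier = tiny_config(), cv_repeats = 2, shap_samples = 10,
    shap_background = 20, shap_draws = 8,
    out_dir = withr::local_tempdir(), seed = 3)
  res <- run_pipeline(cfg)
  expect_s3_class(res$report, "eval_report")
  expect_setequal(names(res$report), c("uric_acid", "lactate", "tyrosine"))
  expect_setequal(names(res$importance), c("uric_acid", "lactate", "tyrosine"))
  expect_equal(nrow(res$chrono$records), 17)
  for (f in c("config.json", "dataset.csv", "cv_metrics.csv", "report.json",
              "importance_uric_acid.csv", "chrono_profile.csv",
              "pipeline.log"))
    expect_true(file.exists(file.path(cfg$out_dir, f)))
  # reproducibility: rerunning the same config gives identical metrics
  cfg2 <- cfg; cfg2$out_dir <- NULL
  res2 <- run_pipeline(cfg2)
  expect_identical(res2$cv$metrics, res$cv$metrics)
  expect_identical(res2$importance$lactate$importance,
                   res$importance$lactate$importance)
  # a different quantifier seed changes the fit but not the contract
  cfg3 <- cfg; cfg3$out_dir <- NULL; cfg3$quantifier$seed <- 99L
  res3 <- run_pipeline(cfg3)
  expect_false(identical(res3$cv$metrics$r2, res$cv$metrics$r2))
  expect_equal(dim(res3$cv$metrics), dim(res$cv$metrics))
})
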