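test_that("default library carries the printed target band centers", {
  lib <- default_library()
  expect_equal(lib$uric_acid$peaks$center[1], 635)
  expect_equal(lib$lactate$peaks$center[1], 859)
  expect_equal(lib$tyrosine$peaks$center[1], 1353)
  g <- wn_grid()
  centers <- unlist(lapply(lib, function(c) c$peaks$center))
  expect_true(all(centers >= g$start & centers <= g$end))
  # sensitivities put the physiological maxima at comparable band heights
  lv <- metabolite_levels()
  heights <- vapply(names(lv), function(m)
    lib[[m]]$sensitivity * max(lv[[m]]), numeric(1))
  expect_true(max(heights) / min(heights) < 2)
})

test_that("default design realizes 41 combinations x 36 replicates", {
  d <- default_design()
  expect_equal(nrow(d$combos), 41)
  expect_equal(d$replicates, 36)
  expect_equal(nrow(d$combos) * d$replicates, 1476)
  # every printed level of every metabolite appears; tuples are distinct
  lv <- metabolite_levels()
  for (m in names(lv))
    expect_true(all(lv[[m]] %in% d$combos[[m]]))
  expect_false(anyDuplicated(
    d$combos[, c("uric_acid", "lactate", "tyrosine")]) > 0)
  # the design is deterministic
  expect_identical(default_design()$combos, d$combos)
})

test_that("trivial designs and design validation behave", {
  d1 <- mixture_design(data.frame(combo_id = 1, uric_acid = 5), 1)
  expect_equal(nrow(d1$combos) * d1$replicates, 1)
  expect_error(mixture_design(data.frame(combo_id = c(1, 1), uric_acid = 1), 2),
               "unique")
  expect_error(mixture_design(data.frame(combo_id = 1, uric_acid = -2), 2),
               ">= 0")
})

test_that("clean spectra are linear in concentration with saturation off", {
  g <- wn_grid()
  lib <- default_library()
  expect_equal(clean_spectrum(lib, c(uric_acid = 0, lactate = 0), g),
               numeric(g$n_points))
  s40 <- clean_spectrum(lib, c(uric_acid = 40), g)
  s2.5 <- clean_spectrum(lib, c(uric_acid = 2.5), g)
  expect_equal(peak_intensity(s40, g, 635) / peak_intensity(s2.5, g, 635), 16)
  # doubling every concentration doubles the spectrum exactly
  conc <- c(uric_acid = 10, lactate = 5, tyrosine = 100, urea = 4)
  expect_equal(clean_spectrum(lib, 2 * conc, g),
               2 * clean_spectrum(lib, conc, g))
  # peak-center intensity vs concentration is perfectly linear
  cs <- c(0, 2.5, 5, 10, 20, 40)
  peak <- vapply(cs, function(ci)
    peak_intensity(clean_spectrum(lib, c(uric_acid = ci), g), g, 635),
    numeric(1))
  expect_equal(stats::cor(peak, cs), 1, tolerance = 1e-12)
  expect_error(clean_spectrum(lib, c(nonexistent = 1), g), "unknown analyte")
})

test_that("Langmuir saturation is strictly increasing and concave", {
  lib <- default_library()
  lib$uric_acid$saturation_scale <- 20
  g <- wn_grid()
  cs <- seq(0, 80, by = 5)
  peak <- vapply(cs, function(ci)
    max(clean_spectrum(lib, c(uric_acid = ci), g)), numeric(1))
  expect_true(all(diff(peak) > 0))
  expect_true(all(diff(diff(peak)) < 0))
  # linear response bounds the saturated one from above (equal at 0)
  lin <- default_library()
  expect_true(all(peak[-1] <
                    vapply(cs[-1], function(ci)
                      max(clean_spectrum(lin, c(uric_acid = ci), g)),
                      numeric(1))))
})

test_that("generated datasets have the designed shape and are reproducible", {
  g <- desk_grid(150)
  lib <- default_library()
  d <- mixture_design(default_design(replicates = 3)$combos[1:5, ], 3)
  set1 <- generate_dataset(lib, d, noise_model(seed = 42), g)
  expect_equal(dim(set1$spectra), c(15, 150))
  expect_equal(nrow(set1$labels), 15)
  expect_equal(set1$meta$combo_id, rep(d$combos$combo_id, each = 3))
  set2 <- generate_dataset(lib, d, noise_model(seed = 42), g)
  expect_identical(set1$spectra, set2$spectra)
  set3 <- generate_dataset(lib, d, noise_model(seed = 43), g)
  expect_false(identical(set1$spectra, set3$spectra))
  expect_error(generate_dataset(lib, mixture_design(d$combos[0, ], 3),
                                noise_model(), g), "empty")
})

test_that("zero-noise replicates equal the clean spectrum", {
  g <- desk_grid(150)
  lib <- default_library()
  d <- mixture_design(data.frame(combo_id = 1, uric_acid = 10, lactate = 5,
                                 tyrosine = 100), 4)
  set <- generate_dataset(lib, d, zero_noise(), g)
  clean <- clean_spectrum(lib, c(uric_acid = 10, lactate = 5, tyrosine = 100), g)
  for (i in 1:4) expect_equal(set$spectra[i, ], clean)
})

test_that("chamber labels are volume-weighted means of the inlet profile", {
  const <- data.frame(concentration = 80, duration = 20)
  rec <- simulate_chrono_injection(const, 0.25, 0.5)
  expect_true(all(rec$concentration == 80))
  expect_equal(nrow(rec), 10)  # 20 min / 2 min per chamber
  # switch exactly at a chamber boundary
  step <- data.frame(concentration = c(80, 10), duration = c(4, 4))
  rec2 <- simulate_chrono_injection(step, 0.25, 0.5)
  expect_equal(rec2$concentration, c(80, 80, 10, 10))
  # switch mid-chamber: half 80, half 10 -> 45
  step3 <- data.frame(concentration = c(80, 10), duration = c(3, 3))
  rec3 <- simulate_chrono_injection(step3, 0.25, 0.5)
  expect_equal(rec3$concentration[2], 45)
  expect_error(simulate_chrono_injection(const, -1, 0.5), "> 0")
})

test_that("dense chambers track a step profile better than sparse ones", {
  prof <- data.frame(concentration = c(80, 10, 20), duration = c(13, 11, 12))
  dense <- simulate_chrono_injection(prof, 0.25, 0.5)
  sparse <- simulate_chrono_injection(prof, 0.25, 1.5)
  expect_lt(step_tracking_error(dense, prof),
            step_tracking_error(sparse, prof))
})

test_that("library JSON serialization round-trips", {
  lib <- default_library()
  path <- withr::local_tempfile(fileext = ".json")
  write_library_json(lib, path)
  lib2 <- read_library_json(path)
  expect_equal(lib2$uric_acid$peaks, lib$uric_acid$peaks)
  expect_equal(lib2$tyrosine$sensitivity, lib$tyrosine$sensitivity)
  d <- default_design(replicates = 2)
  dpath <- withr::local_tempfile(fileext = ".json")
  write_design_json(d, dpath)
  d2 <- read_design_json(dpath)
  expect_equal(d2$combos, d$combos, tolerance = 1e-12)
  expect_equal(d2$replicates, d$replicates)
})
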