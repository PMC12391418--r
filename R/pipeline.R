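#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings: grid, component library, mixture
#' design, noise model, quantifier configuration, cross-validation
#' settings and the global seed. Serializes to JSON and back losslessly
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param grid a `wn_grid`.
#' @param library a `sers_library`.
#' @param design a `sers_design`.
#' @param noise a `sers_noise`; its seed is overridden by `seed`.
#' @param quantifier a `quantifier_config`; its `input_dim` must match the
#'   grid and its seed is overridden by `seed`.
#' @param cv_repeats,train_fraction cross-validation settings.
#' @param shap_samples,shap_background,shap_draws SHAP stage sizes.
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @param seed global seed driving every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = wn_grid(), library = default_library(),
                            design = default_design(), noise = noise_model(),
                            quantifier = quantifier_config(),
                            cv_repeats = 10, train_fraction = 0.75,
                            shap_samples = 40, shap_background = 100,
                            shap_draws = 32, out_dir = NULL, seed = 1L) {
  stopifnot(inherits(grid, "wn_grid"), inherits(library, "sers_library"),
            inherits(design, "sers_design"), inherits(noise, "sers_noise"),
            inherits(quantifier, "quantifier_config"))
  if (quantifier$input_dim != grid$n_points)
    stop("pipeline_config: quantifier input_dim must equal grid n_points")
  noise$seed <- as.integer(seed)
  quantifier$seed <- as.integer(seed)
  structure(list(grid = grid, library = library, design = design,
                 noise = noise, quantifier = quantifier,
                 cv_repeats = as.integer(cv_repeats),
                 train_fraction = train_fraction,
                 shap_samples = as.integer(shap_samples),
                 shap_background = as.integer(shap_background),
                 shap_draws = as.integer(shap_draws),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- list(
    package_version = as.character(utils::packageVersion("sersquant")),
    grid = config$grid[c("start", "end", "n_points")],
    library = unclass(config$library),
    design = list(combos = config$design$combos,
                  replicates = config$design$replicates),
    noise = unclass(config$noise),
    quantifier = unclass(config$quantifier),
    cv_repeats = config$cv_repeats, train_fraction = config$train_fraction,
    shap_samples = config$shap_samples,
    shap_background = config$shap_background, shap_draws = config$shap_draws,
    seed = config$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- o$quantifier
  pipeline_config(
    grid = wn_grid(o$grid$start, o$grid$end, o$grid$n_points),
    library = sers_library(lapply(o$library, function(comp) {
      comp$peaks <- as.data.frame(comp$peaks); comp
    })),
    design = mixture_design(as.data.frame(o$design$combos),
                            o$design$replicates),
    noise = noise_model(o$noise$amplitude_cv, o$noise$baseline_order,
                        o$noise$baseline_scale, o$noise$white_sigma,
                        o$noise$seed),
    quantifier = quantifier_config(
      q$input_dim, q$hidden_layers, q$hidden_width, q$latent_dim,
      q$batch_size, q$max_epochs, q$lr_initial, q$lr_late,
      q$weight_decay_initial, q$weight_decay_late, q$schedule_epoch,
      q$early_stop_patience, q$loss_weight_lambda, q$head_type,
      q$per_metabolite, q$seed),
    cv_repeats = o$cv_repeats, train_fraction = o$train_fraction,
    shap_samples = o$shap_samples, shap_background = o$shap_background,
    shap_draws = o$shap_draws, seed = o$seed)
}

pipeline_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  log(sprintf("%s: done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full synthetic pipeline
#'
#' Simulate -> normalize -> cross-validate -> evaluate -> train a final
#' model -> SHAP importance per metabolite -> chrono-profile demo. Fully
#' reproducible from the config seed; when `config$out_dir` is set, every
#' stage's outputs, a structured log, and the resolved config (with the
#' package version) are written there.
#'
#' @param config a `pipeline_config`.
#' @param verbose print stage log lines.
#' @return List of class `pipeline_result`: `dataset`, `cv`, `report`,
#'   `model`, `importance` (per metabolite), `chrono` (records + profile),
#'   `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()), msg))
    if (verbose) message(msg)
  }
  log(sprintf("seed = %d", config$seed))

  dataset <- pipeline_stage("simulate", log,
    generate_dataset(config$library, config$design, config$noise, config$grid))
  log(sprintf("simulate: %d spectra x %d points, digest %s",
              nrow(dataset$spectra), ncol(dataset$spectra),
              substr(digest_matrix(dataset$spectra), 1, 12)))
  normed <- pipeline_stage("preprocess", log, minmax_normalize(dataset))
  cv <- pipeline_stage("crossval", log,
    cross_validate(normed, config$quantifier, n_repeats = config$cv_repeats,
                   train_fraction = config$train_fraction))
  report <- pipeline_stage("evaluate", log, eval_report(cv))

  model <- pipeline_stage("final_fit", log, {
    n <- nrow(normed$spectra)
    idx <- with_seed(config$seed + 5000L,
                     sample.int(n, round(config$train_fraction * n)))
    m <- build_quantifier(config$quantifier)
    train_quantifier(m, normed[idx], normed[-idx])
  })

  importance <- pipeline_stage("explain", log, {
    n <- nrow(normed$spectra)
    si <- with_seed(config$seed + 6000L,
                    sample.int(n, min(config$shap_samples, n)))
    bi <- with_seed(config$seed + 7000L,
                    sample.int(n, min(config$shap_background, n)))
    out <- lapply(model$metabolites, function(m)
      shap_importance(model, normed[si], normed[bi], target = m,
                      n_draws = config$shap_draws,
                      seed = config$seed + 8000L))
    names(out) <- model$metabolites
    out
  })

  chrono <- pipeline_stage("profile", log, {
    prof <- data.frame(concentration = c(80, 10, 20),
                       duration = c(13, 11, 12))
    rec <- simulate_chrono_injection(prof, flow_rate = 0.25,
                                     chamber_volume = 0.5, n_chambers = 17)
    noise_ch <- config$noise
    noise_ch$seed <- config$seed + 9000L
    reps <- 6L
    chdesign <- mixture_design(
      data.frame(combo_id = rec$index, uric_acid = rec$concentration,
                 lactate = 5, tyrosine = 100), reps)
    chset <- generate_dataset(config$library, chdesign, noise_ch, config$grid)
    pred <- predict(model, chset)
    pred$chamber <- chset$meta$combo_id
    list(records = rec, profile = assemble_profile(rec, pred),
         sweat_rate = estimate_sweat_rate(rec))
  })

  result <- structure(list(dataset = dataset, cv = cv, report = report,
                           model = model, importance = importance,
                           chrono = chrono, config = config,
                           log = log_lines),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_pipeline_config(config, p("config.json"))
    write_spectra_csv(dataset, p("dataset.csv"))
    utils::write.csv(cv$metrics, p("cv_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(report, function(r) list(
        r2 = r$r2[c("min", "max", "mean")],
        rmse = r$rmse[c("min", "max", "mean")],
        bland_altman = r$bland_altman[c("bias", "loa_low", "loa_high")])),
      p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (m in names(importance))
      utils::write.csv(as.data.frame(importance[[m]]),
                       p(sprintf("importance_%s.csv", m)), row.names = FALSE)
    utils::write.csv(chrono$profile, p("chrono_profile.csv"),
                     row.names = FALSE)
    writeLines(log_lines, p("pipeline.log"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}

# order-stable numeric digest used in the run log
digest_matrix <- function(m) {
  v <- c(dim(m), round(sum(m), 6), round(sum(m * seq_along(m) %% 97), 6))
  paste(sprintf("%x", as.integer(abs(v * 1e3) %% .Machine$integer.max)),
        collapse = "")
}

#' Seeded fixture bundles for tests and examples
#'
#' `"small"`: 6 combinations x 4 replicates on a 200-point grid, for fast
#' tests. `"paper"`: the full reference-scale dataset, 41 combinations x
#' 36 replicates on the 1321-point grid (1476 spectra).
#'
#' @param scale `"small"` or `"paper"`.
#' @param seed noise seed.
#' @return List with `set` (a `spectrum_set`), `library`, `design`,
#'   `noise`, `grid`.
#' @export
make_fixtures <- function(scale = c("small", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  library <- default_library()
  if (scale == "small") {
    grid <- wn_grid(457, 1674, 200)
    full <- default_design(replicates = 4)
    # blank, one level of each metabolite, and the two anchor mixtures
    design <- mixture_design(full$combos[c(1, 4, 9, 14, 17, 18), ], 4)
  } else {
    grid <- wn_grid()
    design <- default_design()
  }
  noise <- noise_model(seed = seed)
  set <- generate_dataset(library, design, noise, grid)
  list(set = set, library = library, design = design, noise = noise,
       grid = grid)
}
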