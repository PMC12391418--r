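#' Measurement-noise model for simulated SERS spectra
#'
#' Per-spectrum signal fluctuation is decomposed into a multiplicative
#' gain (lognormal, mean 1, coefficient of variation `amplitude_cv`,
#' emulating hotspot/enhancement variability), an additive smooth
#' polynomial baseline drift, and additive white noise. Intensities are
#' clipped at zero after noise is applied.
#'
#' @param amplitude_cv coefficient of variation of the per-spectrum gain.
#' @param baseline_order polynomial order of the additive drift.
#' @param baseline_scale intensity scale of the drift (same units as the
#'   clean spectrum; the default library puts analyte maxima near 1). The
#'   drift rides on a constant pedestal of one `baseline_scale` unit,
#'   emulating the ever-present substrate background.
#' @param white_sigma standard deviation of additive white noise.
#' @param seed integer; the same seed and design give a bit-identical dataset.
#' @return An object of class `sers_noise`.
#' @export
noise_model <- function(amplitude_cv = 0.15, baseline_order = 3,
                        baseline_scale = 0.09, white_sigma = 0.015,
                        seed = 1L) {
  if (amplitude_cv < 0 || baseline_scale < 0 || white_sigma < 0)
    stop("noise_model: scales must be >= 0")
  if (baseline_order < 0) stop("noise_model: baseline_order must be >= 0")
  structure(list(amplitude_cv = amplitude_cv,
                 baseline_order = as.integer(baseline_order),
                 baseline_scale = baseline_scale,
                 white_sigma = white_sigma, seed = as.integer(seed)),
            class = "sers_noise")
}

#' @rdname noise_model
#' @export
zero_noise <- function(seed = 1L) noise_model(0, 0, 0, 0, seed)

# unit-height Lorentzian line shape
lorentzian <- function(nu, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((nu - center)^2 + hw2)
}

# concentration -> band amplitude; linear or Langmuir saturation
component_response <- function(comp, conc) {
  s <- comp$saturation_scale
  if (is.null(s) || !is.finite(s)) comp$sensitivity * conc
  else comp$sensitivity * s * conc / (s + conc)
}

#' Noise-free mixture spectrum
#'
#' Forward model: each analyte contributes its Lorentzian bands scaled by
#' `rel_amp` and by the concentration response (linear
#' `sensitivity * c`, or Langmuir `sensitivity * s * c / (s + c)` when a
#' `saturation_scale` is set). Contributions add across analytes.
#'
#' @param library a `sers_library`.
#' @param concentrations named numeric vector of concentrations (>= 0),
#'   names must exist in `library`; analytes omitted are absent.
#' @param grid a `wn_grid`.
#' @return Numeric intensity vector of length `grid$n_points` (all >= 0).
#' @examples
#' g <- wn_grid(); lib <- default_library()
#' s <- clean_spectrum(lib, c(uric_acid = 20), g)
#' @export
clean_spectrum <- function(library, concentrations, grid) {
  stopifnot(inherits(library, "sers_library"), inherits(grid, "wn_grid"))
  nm <- names(concentrations)
  if (length(concentrations) && (is.null(nm) || any(!nzchar(nm))))
    stop("clean_spectrum: concentrations must be named")
  unknown <- setdiff(nm, names(library))
  if (length(unknown))
    stop(sprintf("clean_spectrum: unknown analyte(s): %s",
                 paste(unknown, collapse = ", ")))
  if (any(concentrations < 0))
    stop("clean_spectrum: concentrations must be >= 0")
  nu <- wn_axis(grid)
  out <- numeric(length(nu))
  for (a in nm) {
    amp <- component_response(library[[a]], concentrations[[a]])
    if (amp == 0) next
    pk <- library[[a]]$peaks
    for (i in seq_len(nrow(pk)))
      out <- out + amp * pk$rel_amp[i] * lorentzian(nu, pk$center[i], pk$fwhm[i])
  }
  out
}

#' Generate a labeled synthetic SERS dataset
#'
#' Emits `design$replicates` noisy replicates of the clean mixture spectrum
#' of every design combination:
#' `gain * clean + baseline + white noise`, clipped at zero, with the
#' components defined by [noise_model()]. Output order is combination-major
#' (all replicates of combo 1, then combo 2, ...). Fully reproducible from
#' `noise$seed`.
#'
#' @param library a `sers_library`.
#' @param design a `sers_design`; analyte columns not present in the
#'   library raise an error.
#' @param noise a `sers_noise`.
#' @param grid a `wn_grid`.
#' @param label_analytes which label columns to keep in `$labels`
#'   (default: the three target metabolites present in the design).
#' @return A `spectrum_set` with `nrow = ncombos * replicates`.
#' @export
generate_dataset <- function(library, design, noise, grid,
                             label_analytes = NULL) {
  stopifnot(inherits(library, "sers_library"), inherits(design, "sers_design"),
            inherits(noise, "sers_noise"), inherits(grid, "wn_grid"))
  combos <- design$combos
  if (nrow(combos) < 1L) stop("generate_dataset: empty design")
  analytes <- design$analytes
  unknown <- setdiff(analytes, names(library))
  if (length(unknown))
    stop(sprintf("generate_dataset: design analytes missing from library: %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(label_analytes))
    label_analytes <- intersect(c("uric_acid", "lactate", "tyrosine"), analytes)
  nu <- wn_axis(grid)
  x01 <- seq(-1, 1, length.out = length(nu))
  n_rep <- design$replicates
  n_total <- nrow(combos) * n_rep
  spectra <- matrix(0, n_total, length(nu))
  with_seed(noise$seed, {
    row <- 1L
    for (ci in seq_len(nrow(combos))) {
      conc <- unlist(combos[ci, analytes])
      clean <- clean_spectrum(library, conc, grid)
      for (r in seq_len(n_rep)) {
        y <- clean
        if (noise$amplitude_cv > 0) {
          sdlog <- sqrt(log(1 + noise$amplitude_cv^2))
          y <- y * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
        if (noise$baseline_scale > 0) {
          # drift rides on a one-unit pedestal: substrates contribute a
          # positive background, so blank spectra are never identically zero
          ks <- 0:noise$baseline_order
          coef <- stats::rnorm(length(ks), sd = 1 / (ks + 1))
          y <- y + noise$baseline_scale *
            (1 + drop(outer(x01, ks, `^`) %*% coef))
        }
        if (noise$white_sigma > 0)
          y <- y + stats::rnorm(length(nu), sd = noise$white_sigma)
        spectra[row, ] <- pmax(y, 0)
        row <- row + 1L
      }
    }
  })
  idx <- rep(seq_len(nrow(combos)), each = n_rep)
  labels <- combos[idx, label_analytes, drop = FALSE]
  rownames(labels) <- NULL
  meta <- data.frame(combo_id = combos$combo_id[idx],
                     replicate = rep(seq_len(n_rep), nrow(combos)),
                     source = "synthetic")
  spectrum_set(spectra, labels, grid, meta)
}

#' Simulate sequential chamber filling from a time-varying inlet
#'
#' The inlet concentration follows a step profile; fluid at `flow_rate`
#' fills chambers of `chamber_volume` one after another. Each chamber's
#' label is the volume-weighted mean inlet concentration over its fill
#' window, which is what a spectroscopic readout of the stored aliquot
#' measures. Used to compare sparse (1.5 uL) and dense (0.5 uL) sampling
#' of the same concentration transient.
#'
#' @param profile data.frame with columns `concentration` and `duration`
#'   (minutes); the inlet holds each concentration for its duration.
#' @param flow_rate uL/min (> 0).
#' @param chamber_volume uL (> 0).
#' @param n_chambers optional cap on the number of chambers (e.g. 17).
#' @return data.frame of class `chamber_records` with columns `index`,
#'   `volume`, `fill_start`, `fill_end` (minutes) and `concentration`
#'   (volume-weighted mean); only completely filled chambers are returned.
#' @examples
#' prof <- data.frame(concentration = c(80, 10, 20), duration = c(13, 11, 12))
#' simulate_chrono_injection(prof, flow_rate = 0.25, chamber_volume = 0.5)
#' @export
simulate_chrono_injection <- function(profile, flow_rate, chamber_volume,
                                      n_chambers = NULL) {
  profile <- as.data.frame(profile)
  stopifnot(all(c("concentration", "duration") %in% names(profile)))
  if (any(profile$duration <= 0)) stop("profile durations must be > 0")
  if (flow_rate <= 0) stop("flow_rate must be > 0")
  if (chamber_volume <= 0) stop("chamber_volume must be > 0")
  total_time <- sum(profile$duration)
  fill_time <- chamber_volume / flow_rate
  n_full <- floor(total_time / fill_time + 1e-9)
  if (!is.null(n_chambers)) n_full <- min(n_full, n_chambers)
  if (n_full < 1L)
    stop("profile too short to fill a single chamber")
  seg_end <- cumsum(profile$duration)
  seg_start <- c(0, seg_end[-length(seg_end)])
  rec <- data.frame(index = seq_len(n_full),
                    volume = chamber_volume,
                    fill_start = (seq_len(n_full) - 1) * fill_time,
                    fill_end = seq_len(n_full) * fill_time)
  rec$concentration <- vapply(seq_len(n_full), function(i) {
    t0 <- rec$fill_start[i]; t1 <- rec$fill_end[i]
    ov <- pmax(0, pmin(seg_end, t1) - pmax(seg_start, t0))
    sum(ov * profile$concentration) / (t1 - t0)
  }, numeric(1))
  class(rec) <- c("chamber_records", "data.frame")
  rec
}

#' Worst-case tracking error of a chamber sequence against a step profile
#'
#' Treats the chamber labels as a piecewise-constant reconstruction of the
#' inlet profile (each label held over its fill window) and returns the
#' maximum absolute deviation from the true step profile over time. Denser
#' chambers localize concentration switches better and give a smaller
#' worst-case error.
#'
#' @param records output of [simulate_chrono_injection()].
#' @param profile the step profile the records sampled.
#' @return max over time of `|reconstruction(t) - truth(t)|`.
#' @export
step_tracking_error <- function(records, profile) {
  profile <- as.data.frame(profile)
  seg_end <- cumsum(profile$duration)
  seg_start <- c(0, seg_end[-length(seg_end)])
  err <- 0
  for (i in seq_len(nrow(records))) {
    t0 <- records$fill_start[i]; t1 <- records$fill_end[i]
    ov <- pmin(seg_end, t1) - pmax(seg_start, t0)
    hit <- which(ov > 1e-9)
    if (length(hit))
      err <- max(err, abs(records$concentration[i] -
                            profile$concentration[hit]))
  }
  err
}
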