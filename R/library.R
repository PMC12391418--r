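#' Component library: Raman band models per analyte
#'
#' Each component is described by one or more Lorentzian bands (center, FWHM,
#' relative amplitude in (0, 1]) plus a sensitivity (peak intensity per unit
#' concentration) and an optional Langmuir saturation scale. The three target
#' metabolites carry the band centers used for univariate calibration:
#' uric acid 635 cm^-1, lactate 859 cm^-1, tyrosine 1353 cm^-1.
#'
#' @param components named list; each element a list with fields
#'   `peaks` (data.frame with columns `center`, `fwhm`, `rel_amp`),
#'   `sensitivity` (> 0, intensity per concentration unit) and optionally
#'   `saturation_scale` (concentration at which the response saturates;
#'   `NULL` or `Inf` disables saturation) and `unit` (label, e.g. "uM").
#' @return An object of class `sers_library`.
#' @seealso [default_library()], [clean_spectrum()]
#' @export
sers_library <- function(components) {
  if (!is.list(components) || is.null(names(components)) ||
      any(!nzchar(names(components))))
    stop("sers_library: 'components' must be a named list")
  for (nm in names(components)) {
    comp <- components[[nm]]
    pk <- comp$peaks
    if (is.null(pk) || nrow(pk) < 1L)
      stop(sprintf("component '%s' must have at least one peak", nm))
    if (!all(c("center", "fwhm", "rel_amp") %in% names(pk)))
      stop(sprintf("component '%s': peaks need columns center, fwhm, rel_amp", nm))
    if (any(pk$fwhm <= 0)) stop(sprintf("component '%s': fwhm must be > 0", nm))
    if (any(pk$rel_amp <= 0 | pk$rel_amp > 1))
      stop(sprintf("component '%s': rel_amp must lie in (0, 1]", nm))
    if (is.null(comp$sensitivity) || comp$sensitivity <= 0)
      stop(sprintf("component '%s': sensitivity must be > 0", nm))
    if (!is.null(comp$saturation_scale) &&
        is.finite(comp$saturation_scale) && comp$saturation_scale <= 0)
      stop(sprintf("component '%s': saturation_scale must be > 0", nm))
  }
  structure(components, class = "sers_library")
}

peak_df <- function(center, fwhm, rel_amp) {
  data.frame(center = center, fwhm = fwhm, rel_amp = rel_amp)
}

#' Default component library
#'
#' Band centers for the target metabolites follow the calibration bands
#' (635, 859, 1353 cm^-1); secondary bands and the background species
#' (urea, glucose, creatinine, ascorbic acid, glycine, alanine, glutamate,
#' the artificial-sweat constituents) are plausible placements that create
#' the spectral overlap real sweat exhibits. Sensitivities are scaled so
#' the physiological maximum of each target metabolite produces a primary
#' band of unit height, making band heights of the three analytes
#' comparable across their working ranges.
#'
#' @param include_background include the seven background species.
#' @param fwhm default band full width at half maximum (cm^-1).
#' @return A `sers_library`.
#' @examples
#' lib <- default_library()
#' lib$uric_acid$peaks$center[1]  # 635
#' @export
default_library <- function(include_background = TRUE, fwhm = 12) {
  comps <- list(
    uric_acid = list(
      peaks = peak_df(c(635, 1134, 1008), fwhm, c(1, 0.35, 0.2)),
      sensitivity = 1 / 40, unit = "uM"),
    lactate = list(
      peaks = peak_df(c(859, 1045, 1421), fwhm, c(1, 0.3, 0.2)),
      sensitivity = 1 / 20, unit = "mM"),
    tyrosine = list(
      peaks = peak_df(c(1353, 1175, 831), fwhm, c(1, 0.3, 0.2)),
      sensitivity = 1 / 200, unit = "uM")
  )
  if (include_background) {
    comps <- c(comps, list(
      urea          = list(peaks = peak_df(1003, fwhm, 1), sensitivity = 0.06, unit = "mM"),
      glucose       = list(peaks = peak_df(1125, fwhm, 1), sensitivity = 1.5,  unit = "mM"),
      creatinine    = list(peaks = peak_df(680,  fwhm, 1), sensitivity = 4,    unit = "mM"),
      ascorbic_acid = list(peaks = peak_df(1258, fwhm, 1), sensitivity = 6,    unit = "mM"),
      glycine       = list(peaks = peak_df(893,  fwhm, 1), sensitivity = 0.4,  unit = "mM"),
      alanine       = list(peaks = peak_df(850,  fwhm, 1), sensitivity = 0.4,  unit = "mM"),
      glutamate     = list(peaks = peak_df(940,  fwhm, 1), sensitivity = 0.7,  unit = "mM")
    ))
  }
  sers_library(comps)
}

#' @export
print.sers_library <- function(x, ...) {
  cat(sprintf("<sers_library> %d components\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-14s bands at %s cm^-1 (sensitivity %.4g per %s)\n", nm,
                paste(x[[nm]]$peaks$center, collapse = ", "),
                x[[nm]]$sensitivity, x[[nm]]$unit %||% "unit"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a component library as JSON
#'
#' Human-editable serialization: one object per component with `peaks`
#' (arrays of `center`, `fwhm`, `rel_amp`), `sensitivity`, optional
#' `saturation_scale` and `unit`.
#'
#' @param path file path.
#' @param library a `sers_library`.
#' @return `read_library_json` returns a `sers_library`;
#'   `write_library_json` returns `path` invisibly.
#' @export
read_library_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(raw, function(comp) {
    comp$peaks <- as.data.frame(comp$peaks)
    comp
  })
  sers_library(comps)
}

#' @rdname read_library_json
#' @export
write_library_json <- function(library, path) {
  stopifnot(inherits(library, "sers_library"))
  jsonlite::write_json(unclass(library), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
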