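#' Interpolate a raw instrument spectrum onto the uniform grid
#'
#' Raman instruments report intensities on their own (often non-uniform)
#' shift axis; the model operates on a fixed uniform grid. Linear
#' interpolation maps the raw trace onto that grid.
#'
#' @param wavenumber,intensity raw trace; `wavenumber` sorted increasing and
#'   covering the grid range.
#' @param grid target `wn_grid`.
#' @return Numeric vector of length `grid$n_points`.
#' @export
vectorize <- function(wavenumber, intensity, grid = wn_grid()) {
  stopifnot(inherits(grid, "wn_grid"))
  if (length(wavenumber) != length(intensity))
    stop("vectorize: wavenumber and intensity lengths differ")
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("vectorize: wavenumbers must be strictly increasing")
  if (wavenumber[1] > grid$start + 1e-9 ||
      wavenumber[length(wavenumber)] < grid$end - 1e-9)
    stop(sprintf(
      "vectorize: raw range [%g, %g] does not cover the grid [%g, %g]",
      wavenumber[1], wavenumber[length(wavenumber)], grid$start, grid$end))
  stats::approx(wavenumber, intensity, xout = wn_axis(grid), rule = 1)$y
}

#' Min-max normalization to [0, 1]
#'
#' Rescales each spectrum to the 0--1 range, the preprocessing the model
#' inputs receive. Applied per spectrum (rowwise for matrices and
#' `spectrum_set`s), never per dataset.
#'
#' @param x numeric vector, matrix (spectra in rows) or `spectrum_set`.
#' @return Same shape as `x`; each spectrum has min exactly 0 and max
#'   exactly 1. A `spectrum_set` comes back with `normalized = TRUE`.
#' @export
minmax_normalize <- function(x) {
  norm1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2])
      stop("minmax_normalize: constant spectrum, scaling undefined")
    (v - r[1]) / (r[2] - r[1])
  }
  if (inherits(x, "spectrum_set")) {
    if (x$normalized) return(x)
    out <- x
    out$spectra <- t(apply(x$spectra, 1, norm1))
    out$normalized <- TRUE
    return(out)
  }
  if (is.matrix(x)) return(t(apply(x, 1, norm1)))
  norm1(x)
}

#' Pointwise mean of replicate spectra
#'
#' Repeated accumulations of the same sample are averaged pointwise to
#' suppress per-measurement signal variance.
#'
#' @param spectra list of equal-length numeric vectors, or a matrix with
#'   spectra in rows.
#' @return Numeric vector, the pointwise mean.
#' @export
average_replicates <- function(spectra) {
  if (is.list(spectra)) {
    if (!length(spectra)) stop("average_replicates: empty input")
    len <- lengths(spectra)
    if (length(unique(len)) != 1L)
      stop("average_replicates: spectra differ in length")
    spectra <- do.call(rbind, spectra)
  }
  if (!is.matrix(spectra) || nrow(spectra) < 1L)
    stop("average_replicates: empty input")
  colMeans(spectra)
}

#' Subtract a scaled reference background spectrum
#'
#' Removes substrate contributions (e.g. PDMS/fluorocarbon bands) by
#' subtracting `scale * background`. When `scale` is `NULL` it is fitted by
#' least squares of the background to the spectrum over the reference
#' `windows` (regions where only the substrate contributes); with no
#' windows the whole grid is used. The result is clipped at zero.
#'
#' @param spectrum,background equal-length numeric vectors on `grid`.
#' @param scale fixed scale, or `NULL` to fit.
#' @param windows list of `c(lo, hi)` wavenumber windows used for the fit.
#' @param grid the shared `wn_grid` (needed only when `windows` given).
#' @return List with `spectrum` (corrected, >= 0) and `scale` (used).
#' @export
subtract_background <- function(spectrum, background, scale = NULL,
                                windows = NULL, grid = wn_grid()) {
  if (length(spectrum) != length(background))
    stop("subtract_background: spectrum and background lengths differ")
  if (is.null(scale)) {
    idx <- if (is.null(windows)) seq_along(spectrum)
           else sort(unique(unlist(lapply(windows, function(w)
             grid_window_idx(grid, w[1], w[2])))))
    denom <- sum(background[idx]^2)
    scale <- if (denom == 0) 0 else
      sum(spectrum[idx] * background[idx]) / denom
  }
  list(spectrum = pmax(spectrum - scale * background, 0), scale = scale)
}

#' Baseline-corrected peak intensity in a window
#'
#' Band height as plotted in univariate calibrations: the maximum
#' intensity inside `center +/- half_window` minus a straight local
#' baseline drawn through the window endpoints, evaluated at the maximum.
#'
#' @param spectrum numeric vector on `grid`.
#' @param grid a `wn_grid`.
#' @param center band center (cm^-1).
#' @param half_window half width of the evaluation window (cm^-1).
#' @return Baseline-corrected peak height (can be 0 for a flat spectrum).
#' @export
peak_intensity <- function(spectrum, grid = wn_grid(), center,
                           half_window = 15) {
  idx <- grid_window_idx(grid, center - half_window, center + half_window)
  if (length(idx) < 3L) stop("peak_intensity: window too narrow for the grid")
  seg <- spectrum[idx]
  base <- seq(seg[1], seg[length(seg)], length.out = length(seg))
  i <- which.max(seg)
  seg[i] - base[i]
}

#' Signal-to-noise ratio of a SERS peak
#'
#' Defined as the peak intensity divided by the pooled standard deviation
#' of blank (substrate-only) noise spectra.
#'
#' @param signal_peak peak intensity (e.g. from [peak_intensity()]).
#' @param noise_spectra list of >= 2 numeric vectors, or a matrix with
#'   noise spectra in rows.
#' @return `signal_peak / sd(noise)`.
#' @export
snr <- function(signal_peak, noise_spectra) {
  if (is.matrix(noise_spectra))
    noise_spectra <- split(noise_spectra, row(noise_spectra))
  if (!is.list(noise_spectra) || length(noise_spectra) < 2L)
    stop("snr: need at least 2 noise spectra")
  s <- stats::sd(unlist(noise_spectra))
  if (s == 0) stop("snr: noise spectra have zero variance")
  signal_peak / s
}
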