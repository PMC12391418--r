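#' Labeled spectrum set
#'
#' The package's central container: a matrix of spectra (rows = spectra,
#' columns = grid points) together with per-spectrum concentration labels,
#' replicate/combination metadata and the wavenumber grid.
#'
#' @param spectra numeric matrix, one spectrum per row, `grid$n_points` columns.
#' @param labels data.frame of per-spectrum concentrations (one column per
#'   analyte), `nrow(labels) == nrow(spectra)`.
#' @param grid the `wn_grid` the columns live on.
#' @param meta optional data.frame with columns such as `combo_id`,
#'   `replicate`, `source`.
#' @param normalized logical flag recording whether rows have been min-max
#'   normalized (so downstream stages never double-normalize).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, labels, grid, meta = NULL,
                         normalized = FALSE) {
  spectra <- as.matrix(spectra)
  stopifnot(inherits(grid, "wn_grid"))
  if (ncol(spectra) != grid$n_points)
    stop(sprintf("spectrum_set: spectra have %d columns but grid has %d points",
                 ncol(spectra), grid$n_points))
  if (anyNA(spectra) || any(!is.finite(spectra)))
    stop("spectrum_set: spectra must be finite with no missing values")
  labels <- as.data.frame(labels)
  if (nrow(labels) != nrow(spectra))
    stop("spectrum_set: labels must have one row per spectrum")
  if (is.null(meta))
    meta <- data.frame(combo_id = rep(NA_integer_, nrow(spectra)),
                       replicate = rep(NA_integer_, nrow(spectra)),
                       source = rep("unknown", nrow(spectra)))
  if (nrow(meta) != nrow(spectra))
    stop("spectrum_set: meta must have one row per spectrum")
  structure(list(spectra = spectra, labels = labels, meta = meta,
                 grid = grid, normalized = isTRUE(normalized)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points (%g..%g cm^-1)%s\n",
              nrow(x$spectra), ncol(x$spectra), x$grid$start, x$grid$end,
              if (x$normalized) ", min-max normalized" else ""))
  cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.spectrum_set` <- function(x, i) {
  spectrum_set(x$spectra[i, , drop = FALSE], x$labels[i, , drop = FALSE],
               x$grid, x$meta[i, , drop = FALSE], x$normalized)
}

#' @export
dim.spectrum_set <- function(x) dim(x$spectra)
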