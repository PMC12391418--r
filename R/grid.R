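#' Uniform wavenumber grid
#'
#' All spectra handled by the package live on a fixed, uniformly spaced
#' Raman-shift axis. The default grid spans 457--1674 cm^-1 with 1321 points
#' (spacing ~0.922 cm^-1), the axis on which the quantifier operates.
#'
#' @param start first wavenumber (cm^-1).
#' @param end last wavenumber (cm^-1); must exceed `start`.
#' @param n_points number of grid points (>= 2), endpoints inclusive.
#' @return An object of class `wn_grid` with fields `start`, `end`,
#'   `n_points` and the realized `axis` (strictly increasing, uniform).
#' @examples
#' g <- wn_grid()
#' length(wn_axis(g))  # 1321
#' @export
wn_grid <- function(start = 457, end = 1674, n_points = 1321) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(n_points))
  if (!(start < end)) stop("wn_grid: 'start' must be < 'end'")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("wn_grid: 'n_points' must be >= 2")
  structure(
    list(start = start, end = end, n_points = n_points,
         axis = seq(start, end, length.out = n_points)),
    class = "wn_grid"
  )
}

#' @rdname wn_grid
#' @param grid a `wn_grid`.
#' @export
wn_axis <- function(grid) {
  stopifnot(inherits(grid, "wn_grid"))
  grid$axis
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g..%g cm^-1, %d points (spacing %.4f cm^-1)\n",
              x$start, x$end, x$n_points, x$axis[2] - x$axis[1]))
  invisible(x)
}

# index of grid points falling inside [lo, hi] (cm^-1)
grid_window_idx <- function(grid, lo, hi) {
  ax <- wn_axis(grid)
  if (lo < ax[1] - 1e-9 || hi > ax[length(ax)] + 1e-9)
    stop(sprintf("window [%g, %g] cm^-1 lies outside the grid [%g, %g]",
                 lo, hi, ax[1], ax[length(ax)]))
  which(ax >= lo - 1e-9 & ax <= hi + 1e-9)
}

# evaluate a function with a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
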