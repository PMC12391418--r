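# gradient of a scalar model output wrt the input spectra, one row per input
input_gradient <- function(model, X, target) {
  enc <- nn_forward(model$encoder, X, cache = TRUE)
  k <- model$config$latent_dim
  if (grepl("^latent[0-9]+$", target)) {
    j <- as.integer(sub("latent", "", target))
    if (j < 1L || j > k) stop(sprintf("no latent component '%s'", target))
    dZ <- matrix(0, nrow(X), k); dZ[, j] <- 1
  } else {
    if (model$config$head_type != "logistic")
      stop("head-output attribution requires the logistic head")
    i <- match(target, model$metabolites)
    if (is.na(i))
      stop(sprintf("target '%s' is neither latentK nor a metabolite", target))
    hd <- nn_forward(model$head, enc$out, cache = TRUE)
    dY <- matrix(0, nrow(X), length(model$metabolites)); dY[, i] <- 1
    dZ <- nn_backward(model$head, hd, dY)$dX
  }
  nn_backward(model$encoder, enc, dZ)$dX
}

# scalar model output used in the additivity identity
target_output <- function(model, X, target) {
  Z <- nn_forward(model$encoder, X)$out
  if (grepl("^latent[0-9]+$", target)) {
    Z[, as.integer(sub("latent", "", target))]
  } else {
    i <- match(target, model$metabolites)
    nn_forward(model$head, Z)$out[, i]
  }
}

#' SHAP spectral feature importance
#'
#' Per-wavenumber importance of the encoder (or a prediction-head output):
#' expected-gradients SHAP values are computed per sample against a
#' background set, squared, and averaged across samples, giving a
#' non-negative importance profile that is independent of whether a
#' feature pushes the output up or down. The default attribution target is
#' a latent coordinate (encoder only); head outputs are available via
#' `target = "<metabolite>"`.
#'
#' For each sample and draw, a background spectrum `b` and an
#' interpolation coefficient `a ~ U(0,1)` are sampled and the contribution
#' `(x - b) * grad f(b + a (x - b))` accumulated; the per-sample SHAP value
#' is the mean over draws (completeness: values sum to
#' `f(x) - mean f(background)` in expectation).
#'
#' @param model a trained `sers_quantifier`.
#' @param samples `spectrum_set` (or normalized matrix) to explain.
#' @param background `spectrum_set`/matrix of reference spectra, typically
#'   ~100 random training spectra.
#' @param target `"latent1"`, `"latent2"`, ... or a metabolite name.
#' @param n_draws background/interpolation draws per sample.
#' @param seed RNG seed for the draws.
#' @return An object of class `importance_profile`: data.frame with
#'   columns `wavenumber`, `importance` (>= 0) plus attributes `target`,
#'   `n_samples`, `n_background`, and `shap` (the raw per-sample matrix).
#' @export
shap_importance <- function(model, samples, background, target = "latent1",
                            n_draws = 32, seed = 1L) {
  if (!inherits(model, "sers_quantifier") || !model$trained)
    stop("shap_importance: model must be a trained sers_quantifier")
  Xs <- as_model_input(samples)$X
  Xb <- as_model_input(background)$X
  if (nrow(Xb) < 1L) stop("shap_importance: background is empty")
  check_input_dim(Xs, model)
  check_input_dim(Xb, model)
  grid <- if (inherits(samples, "spectrum_set")) samples$grid else NULL
  n <- nrow(Xs); p <- ncol(Xs)
  phi <- matrix(0, n, p)
  with_seed(seed, {
    for (d in seq_len(n_draws)) {
      bi <- sample.int(nrow(Xb), n, replace = TRUE)
      alpha <- stats::runif(n)
      B <- Xb[bi, , drop = FALSE]
      Xi <- B + (Xs - B) * alpha       # alpha is per-row (length n)
      G <- input_gradient(model, Xi, target)
      phi <- phi + (Xs - B) * G
    }
  })
  phi <- phi / n_draws
  importance <- colMeans(phi^2)
  out <- data.frame(
    wavenumber = if (!is.null(grid)) wn_axis(grid) else seq_len(p),
    importance = importance)
  structure(out, class = c("importance_profile", "data.frame"),
            target = target, n_samples = n, n_background = nrow(Xb),
            shap = phi)
}

#' Highest-importance wavenumbers
#'
#' @param profile an `importance_profile`.
#' @param k number of grid points to return (1 <= k <= nrow(profile)).
#' @return data.frame of the `k` highest-importance points, importance
#'   descending; ties broken toward the lower wavenumber.
#' @export
top_features <- function(profile, k) {
  stopifnot(inherits(profile, "importance_profile"))
  if (k < 1L) stop("top_features: k must be >= 1")
  if (k > nrow(profile))
    stop(sprintf("top_features: k = %d exceeds the %d grid points",
                 k, nrow(profile)))
  ord <- order(-profile$importance, profile$wavenumber)
  out <- profile[ord[seq_len(k)], c("wavenumber", "importance")]
  rownames(out) <- NULL
  out
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("<importance_profile> target %s, %d samples vs %d background\n",
              attr(x, "target"), attr(x, "n_samples"), attr(x, "n_background")))
  tp <- top_features(x, min(5L, nrow(x)))
  cat("  top wavenumbers:", paste(sprintf("%.0f", tp$wavenumber),
                                  collapse = ", "), "cm^-1\n")
  invisible(x)
}

#' Overlay plot of importance vs the mean spectrum
#'
#' @param x an `importance_profile`.
#' @param mean_spectrum optional numeric vector to overlay (rescaled).
#' @param ... passed to [plot()].
#' @export
plot.importance_profile <- function(x, mean_spectrum = NULL, ...) {
  plot(x$wavenumber, x$importance, type = "l",
       xlab = expression(paste("Raman shift (", cm^-1, ")")),
       ylab = "mean squared SHAP importance", ...)
  if (!is.null(mean_spectrum)) {
    sc <- max(x$importance) / max(mean_spectrum)
    graphics::lines(x$wavenumber, mean_spectrum * sc, col = "grey60", lty = 2)
  }
  invisible(x)
}
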