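#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` about the mean of the true values.
#'
#' @param pred,true equal-length numeric vectors (length >= 2); `true` must
#'   not be constant.
#' @return R-squared (<= 1; negative when predictions are worse than the
#'   mean).
#' @export
r_squared <- function(pred, true) {
  if (length(pred) != length(true)) stop("r_squared: lengths differ")
  if (length(true) < 2L) stop("r_squared: need at least 2 observations")
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0) stop("r_squared: 'true' is constant")
  1 - sum((true - pred)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @param pred,true equal-length, non-empty numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(pred, true) {
  if (length(pred) != length(true)) stop("rmse: lengths differ")
  if (!length(pred)) stop("rmse: empty input")
  sqrt(mean((pred - true)^2))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = pred - true`; bias = mean(d); 95% limits of agreement
#' = bias +/- 1.96 sd(d).
#'
#' @param pred,true equal-length numeric vectors of length >= 3.
#' @return List of class `bland_altman` with `bias`, `loa_low`, `loa_high`,
#'   `differences`, `means` (pairwise means, for plotting).
#' @export
bland_altman <- function(pred, true) {
  if (length(pred) != length(true)) stop("bland_altman: lengths differ")
  if (length(pred) < 3L) stop("bland_altman: need at least 3 pairs")
  d <- pred - true
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, differences = d,
                 means = (pred + true) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, 95%% limits [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, length(x$differences)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$differences, xlab = "mean of methods",
       ylab = "difference (pred - true)", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "red", "red"))
  invisible(x)
}

#' Per-level box summary of predictions
#'
#' Quartile summaries of predictions grouped by true concentration level,
#' the numbers behind prediction-vs-true box plots: median, lower/upper
#' quartiles (linear, type-7 interpolation), whisker bounds at
#' `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR`, and the outliers beyond them.
#'
#' @param pred numeric predictions.
#' @param level true concentration level of each prediction.
#' @return data.frame with one row per level: `level`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`, and a list column
#'   `outliers`.
#' @export
box_summary <- function(pred, level) {
  if (length(pred) != length(level)) stop("box_summary: lengths differ")
  if (!length(pred)) stop("box_summary: empty input")
  lv <- sort(unique(level))
  rows <- lapply(lv, function(l) {
    x <- pred[level == l]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    wl <- q[1] - 1.5 * iqr
    wh <- q[3] + 1.5 * iqr
    data.frame(level = l, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = wl, whisker_high = wh,
               outliers = I(list(x[x < wl | x > wh])))
  })
  do.call(rbind, rows)
}

#' Full evaluation report for cross-validated predictions
#'
#' Combines the per-repeat metric distributions with pooled Bland-Altman
#' agreement and per-level box summaries, one block per metabolite.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @return List of class `eval_report`: per metabolite, `r2` (min, max,
#'   mean, per-repeat values), `rmse` (same), `bland_altman`, `boxes`.
#' @export
eval_report <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  per <- lapply(cv$metabolites, function(m) {
    mm <- cv$metrics[cv$metrics$metabolite == m, ]
    pred <- cv$predictions[[paste0("pred_", m)]]
    true <- cv$predictions[[paste0("true_", m)]]
    list(r2 = list(min = min(mm$r2), max = max(mm$r2), mean = mean(mm$r2),
                   values = mm$r2),
         rmse = list(min = min(mm$rmse), max = max(mm$rmse),
                     mean = mean(mm$rmse), values = mm$rmse),
         bland_altman = bland_altman(pred, true),
         boxes = box_summary(pred, true))
  })
  names(per) <- cv$metabolites
  structure(per, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (m in names(x)) {
    cat(sprintf("  %-10s R2 %.2f-%.2f (mean %.2f)  RMSE mean %.3g  bias %.3g\n",
                m, x[[m]]$r2$min, x[[m]]$r2$max, x[[m]]$r2$mean,
                x[[m]]$rmse$mean, x[[m]]$bland_altman$bias))
  }
  invisible(x)
}
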