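#' Chamber fill interval
#'
#' Time to fill one chamber: `volume / flow_rate`. A 0.5 uL chamber at a
#' 0.25 uL/min sweat rate fills in 2 min.
#'
#' @param chamber_volume uL (> 0).
#' @param flow_rate uL/min (> 0).
#' @return Interval in minutes.
#' @export
sampling_interval <- function(chamber_volume, flow_rate) {
  if (any(chamber_volume <= 0)) stop("sampling_interval: volume must be > 0")
  if (any(flow_rate <= 0)) stop("sampling_interval: flow rate must be > 0")
  chamber_volume / flow_rate
}

#' Total sample capacity of a patch
#'
#' @param n_chambers number of chambers (>= 1); the reference patch has 17.
#' @param chamber_volume uL per chamber (> 0); reference 0.5 uL.
#' @return Capacity in uL (`n * volume`; 8.5 uL for the reference patch).
#' @export
patch_capacity <- function(n_chambers, chamber_volume) {
  if (any(n_chambers < 1)) stop("patch_capacity: n_chambers must be >= 1")
  if (any(chamber_volume <= 0)) stop("patch_capacity: volume must be > 0")
  n_chambers * chamber_volume
}

#' Quasi-dynamic sweat-rate estimate from filled chambers
#'
#' Sweat rate from chamber bookkeeping: each filled chamber contributes
#' its volume over its fill window. The per-chamber (windowed) rate is
#' `volume / (fill_end - fill_start)`; the cumulative rate is the filled
#' volume so far divided by the elapsed time; the overall rate (attribute
#' `overall`) is total volume / total time.
#'
#' @param records data.frame with columns `volume`, `fill_start`,
#'   `fill_end` (e.g. [simulate_chrono_injection()] output or chamber
#'   metadata read from file).
#' @return data.frame with columns `index`, `time` (fill_end), `rate`
#'   (per-chamber), `cumulative_rate`; attribute `overall`.
#' @export
estimate_sweat_rate <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("volume", "fill_start", "fill_end") %in% names(records)))
  if (nrow(records) < 1L) stop("estimate_sweat_rate: no filled chambers")
  dur <- records$fill_end - records$fill_start
  if (any(dur <= 0)) stop("estimate_sweat_rate: zero elapsed time")
  t0 <- records$fill_start[1]
  elapsed <- records$fill_end - t0
  if (any(elapsed <= 0)) stop("estimate_sweat_rate: zero elapsed time")
  out <- data.frame(index = seq_len(nrow(records)),
                    time = records$fill_end,
                    rate = records$volume / dur,
                    cumulative_rate = cumsum(records$volume) / elapsed)
  attr(out, "overall") <- sum(records$volume) / (max(records$fill_end) - t0)
  out
}

#' Assemble a chronological concentration profile
#'
#' Joins per-spectrum model predictions to their chambers and summarizes
#' each chamber as mean +/- one standard deviation over its replicate
#' predictions, timestamped at the fill-window midpoint.
#'
#' @param records chamber table with columns `index`, `fill_start`,
#'   `fill_end`.
#' @param predictions data.frame with a `chamber` column (matching
#'   `records$index`) and one prediction column per metabolite.
#' @return data.frame of class `chrono_profile`, tidy: `time`, `chamber`,
#'   `metabolite`, `mean`, `sd`, `n`, ordered by chamber index.
#' @export
assemble_profile <- function(records, predictions) {
  records <- as.data.frame(records)
  predictions <- as.data.frame(predictions)
  stopifnot(all(c("index", "fill_start", "fill_end") %in% names(records)),
            "chamber" %in% names(predictions))
  missing <- setdiff(records$index, predictions$chamber)
  if (length(missing))
    stop(sprintf("assemble_profile: chamber(s) without predictions: %s",
                 paste(missing, collapse = ", ")))
  mets <- setdiff(names(predictions), "chamber")
  records <- records[order(records$index), ]
  rows <- list()
  for (i in seq_len(nrow(records))) {
    ch <- records$index[i]
    mid <- (records$fill_start[i] + records$fill_end[i]) / 2
    sub <- predictions[predictions$chamber == ch, mets, drop = FALSE]
    for (m in mets) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        time = mid, chamber = ch, metabolite = m, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("chrono_profile", "data.frame")
  out
}

#' @export
plot.chrono_profile <- function(x, metabolite = NULL, ...) {
  mets <- unique(x$metabolite)
  m <- metabolite %||% mets[1]
  sub <- x[x$metabolite == m, ]
  ylim <- range(sub$mean - sub$sd, sub$mean + sub$sd)
  plot(sub$time, sub$mean, type = "b", ylim = ylim,
       xlab = "time (min)", ylab = sprintf("%s concentration", m), ...)
  graphics::arrows(sub$time, sub$mean - sub$sd, sub$time, sub$mean + sub$sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
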