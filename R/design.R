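#' Mixture design: concentration combinations and replication
#'
#' A design pairs a table of concentration combinations (one row per
#' combination, one column per analyte, plus a unique `combo_id`) with a
#' replicate count: the simulator emits `replicates` noisy spectra per
#' combination.
#'
#' @param combos data.frame with column `combo_id` (unique) and one numeric
#'   column per analyte (concentrations >= 0, in that analyte's units).
#' @param replicates spectra per combination (>= 1).
#' @return An object of class `sers_design`.
#' @seealso [default_design()], [generate_dataset()]
#' @export
mixture_design <- function(combos, replicates) {
  combos <- as.data.frame(combos)
  if (nrow(combos) < 1L) stop("mixture_design: empty design")
  if (!"combo_id" %in% names(combos))
    stop("mixture_design: combos must have a 'combo_id' column")
  if (anyDuplicated(combos$combo_id))
    stop("mixture_design: combo_id values must be unique")
  conc_cols <- setdiff(names(combos), "combo_id")
  if (length(conc_cols) < 1L) stop("mixture_design: no analyte columns")
  for (cc in conc_cols) {
    if (!is.numeric(combos[[cc]]) || anyNA(combos[[cc]]) || any(combos[[cc]] < 0))
      stop(sprintf("mixture_design: column '%s' must be numeric and >= 0", cc))
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("mixture_design: replicates must be >= 1")
  structure(list(combos = combos, replicates = replicates,
                 analytes = conc_cols),
            class = "sers_design")
}

#' Printed concentration level sets of the three target metabolites
#'
#' Uric acid in uM, lactate in mM, tyrosine in uM.
#' @return named list of numeric level vectors.
#' @export
metabolite_levels <- function() {
  list(uric_acid = c(0, 2.5, 5, 10, 20, 40),
       lactate   = c(0, 1, 2, 5, 10, 20),
       tyrosine  = c(0, 50, 67, 100, 150, 200))
}

#' Default mixture design: 41 combinations x 36 replicates
#'
#' Concentrations are drawn from the printed per-metabolite level sets
#' (uric acid 0--40 uM, lactate 0--20 mM, tyrosine 0--200 uM, six levels
#' each). The design combines 18 single-metabolite calibration rows (each
#' metabolite at each of its six levels, the other two at zero) with 23
#' additional distinct mixture rows sampled from the full level grid under
#' a fixed internal seed, for 41 combinations total. Background-species
#' concentrations (when `include_background`) vary per combination within
#' physiological ranges, emulating chemically diverse sweat backgrounds.
#'
#' @param replicates replicate spectra per combination (default 36).
#' @param n_mixtures number of mixture rows beyond the 18 calibration rows.
#' @param include_background vary the seven background species per combo.
#' @return A `sers_design` with `18 + n_mixtures` combinations.
#' @examples
#' d <- default_design()
#' nrow(d$combos)      # 41
#' d$replicates        # 36
#' @export
default_design <- function(replicates = 36, n_mixtures = 23,
                           include_background = TRUE) {
  lv <- metabolite_levels()
  cal <- do.call(rbind, lapply(names(lv), function(m) {
    d <- data.frame(uric_acid = 0, lactate = 0, tyrosine = 0)[rep(1, 6), ]
    d[[m]] <- lv[[m]]
    d
  }))
  # the three all-zero rows collapse into one blank: 16 calibration rows;
  # two anchor mixtures (all-maximum, all-mid) complete the block at 18
  cal <- cal[!duplicated(cal), ]
  anchors <- data.frame(uric_acid = c(40, 10), lactate = c(20, 5),
                        tyrosine = c(200, 100))
  base <- rbind(cal, anchors)
  combos <- with_seed(48151, {
    grid <- expand.grid(uric_acid = lv$uric_acid, lactate = lv$lactate,
                        tyrosine = lv$tyrosine)
    key <- function(d) paste(d$uric_acid, d$lactate, d$tyrosine)
    pool <- grid[!key(grid) %in% key(base), ]
    mix <- pool[sample.int(nrow(pool), n_mixtures), ]
    out <- rbind(base, mix)
    if (include_background) {
      rng <- list(urea = c(2, 10), glucose = c(0.05, 0.3),
                  creatinine = c(0.02, 0.1), ascorbic_acid = c(0.01, 0.05),
                  glycine = c(0.1, 1), alanine = c(0.1, 1),
                  glutamate = c(0.05, 0.5))
      for (nm in names(rng))
        out[[nm]] <- stats::runif(nrow(out), rng[[nm]][1], rng[[nm]][2])
    }
    out
  })
  combos <- cbind(combo_id = seq_len(nrow(combos)), combos)
  rownames(combos) <- NULL
  mixture_design(combos, replicates)
}

#' @export
print.sers_design <- function(x, ...) {
  cat(sprintf("<sers_design> %d combinations x %d replicates = %d planned spectra\n",
              nrow(x$combos), x$replicates, nrow(x$combos) * x$replicates))
  cat("  analytes:", paste(x$analytes, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname mixture_design
#' @param path file path for JSON serialization.
#' @param design a `sers_design`.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "sers_design"))
  jsonlite::write_json(list(combos = design$combos,
                            replicates = design$replicates),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname mixture_design
#' @export
read_design_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixture_design(as.data.frame(raw$combos), raw$replicates)
}
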