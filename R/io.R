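#' Write / read labeled spectra as CSV
#'
#' Schema: one spectrum per row; the header names the wavenumbers first
#' (one column per grid point), then the label and metadata columns
#' `uric_acid_uM`, `lactate_mM`, `tyrosine_uM`, `combo_id`, `replicate`
#' (label columns carry their unit as a suffix). Any other label column is
#' written under its own name.
#'
#' @param set a `spectrum_set`.
#' @param path output file.
#' @return `write_spectra_csv` returns `path` invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  units <- c(uric_acid = "uric_acid_uM", lactate = "lactate_mM",
             tyrosine = "tyrosine_uM")
  dt <- data.table::as.data.table(set$spectra)
  data.table::setnames(dt, sprintf("%.6f", wn_axis(set$grid)))
  for (m in names(set$labels)) {
    col <- if (m %in% names(units)) units[[m]] else m
    dt[[col]] <- set$labels[[m]]
  }
  dt$combo_id <- set$meta$combo_id
  dt$replicate <- set$meta$replicate
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#'
#' @details `read_spectra_table` resolves columns as follows: columns with
#'   numeric names are intensities (their names define the wavenumber
#'   axis, which must be uniform); `*_uM` / `*_mM` columns map back to the
#'   metabolite labels; `combo_id` / `replicate` become metadata. For
#'   foreign layouts a `mapping` hint names the columns explicitly, e.g.
#'   `list(labels = c(uric_acid = "UA", lactate = "LA"), combo_id = "grp")`;
#'   intensity columns are then every remaining numeric-named column.
#'
#' @param mapping optional column-mapping hint (see Details).
#' @return `read_spectra_table` returns a `spectrum_set`.
#' @export
read_spectra_table <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("read_spectra_table: no such file: ", path)
  dt <- tryCatch(data.table::fread(path, header = TRUE),
                 error = function(e)
                   stop("read_spectra_table: cannot parse '", path, "': ",
                        conditionMessage(e)))
  if (nrow(dt) < 1L || ncol(dt) < 2L)
    stop("read_spectra_table: '", path, "' has no spectra")
  nm <- names(dt)
  wn <- suppressWarnings(as.numeric(nm))
  wn_cols <- which(!is.na(wn))
  if (length(wn_cols) < 2L)
    stop("read_spectra_table: fewer than 2 wavenumber (numeric-named) columns")
  axis <- wn[wn_cols]
  if (is.unsorted(axis, strictly = TRUE))
    stop("read_spectra_table: wavenumber columns are not strictly increasing")
  steps <- diff(axis)
  if (diff(range(steps)) > 1e-3 * mean(steps))
    stop("read_spectra_table: wavenumber axis is not uniform")
  grid <- wn_grid(axis[1], axis[length(axis)], length(axis))
  for (j in wn_cols) {
    col <- dt[[j]]
    if (!is.numeric(col))
      stop(sprintf("read_spectra_table: non-numeric intensities in column '%s'",
                   nm[j]))
    if (anyNA(col))
      stop(sprintf(
        "read_spectra_table: missing intensity at row %d, column '%s'",
        which(is.na(col))[1], nm[j]))
  }
  spectra <- as.matrix(dt[, wn_cols, with = FALSE])
  dimnames(spectra) <- NULL

  label_map <- mapping$labels
  if (is.null(label_map)) {
    known <- c(uric_acid = "uric_acid_uM", lactate = "lactate_mM",
               tyrosine = "tyrosine_uM")
    label_map <- known[known %in% nm]
    extra <- setdiff(nm[-wn_cols], c(known, "combo_id", "replicate"))
    if (length(extra)) label_map <- c(label_map, stats::setNames(extra, extra))
  }
  missing_cols <- setdiff(unname(label_map), nm)
  if (length(missing_cols))
    stop("read_spectra_table: missing label column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!length(label_map))
    stop("read_spectra_table: no label columns found")
  labels <- as.data.frame(dt[, unname(label_map), with = FALSE])
  names(labels) <- names(label_map)
  for (m in names(labels))
    if (!is.numeric(labels[[m]]))
      stop(sprintf("read_spectra_table: non-numeric labels in column '%s'",
                   label_map[[m]]))
  combo_col <- mapping$combo_id %||% "combo_id"
  repl_col <- mapping$replicate %||% "replicate"
  meta <- data.frame(
    combo_id = if (combo_col %in% nm) dt[[combo_col]] else NA_integer_,
    replicate = if (repl_col %in% nm) dt[[repl_col]] else NA_integer_,
    source = "file")
  spectrum_set(spectra, labels, grid, meta)
}

#' Read a two-column instrument export
#'
#' Single-spectrum text files as written by Raman instruments: two
#' whitespace- or comma-separated numeric columns (wavenumber, intensity),
#' optionally with comment lines starting with `#`.
#'
#' @param path file path.
#' @return data.frame with columns `wavenumber`, `intensity`, sorted by
#'   wavenumber. Feed into [vectorize()] to put it on the model grid.
#' @export
read_instrument_spectrum <- function(path) {
  if (!file.exists(path)) stop("read_instrument_spectrum: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("read_instrument_spectrum: no data lines")
  dt <- data.table::fread(text = lines, header = FALSE, sep = "auto")
  if (ncol(dt) < 2L)
    stop("read_instrument_spectrum: expected two columns (wavenumber, intensity)")
  out <- data.frame(wavenumber = as.numeric(dt[[1]]),
                    intensity = as.numeric(dt[[2]]))
  if (anyNA(out)) stop("read_instrument_spectrum: non-numeric values")
  out[order(out$wavenumber), ]
}
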