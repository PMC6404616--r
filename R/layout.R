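#' Compound exposure condition for one plate
#'
#' Records which compound (if any) a plate contains, at what concentration,
#' in how much solvent, and which replicate (trial) the plate belongs to.
#' The reserved compound name `"CONTROL"` denotes the solvent-only plate
#' used for normalization and must carry concentration 0.
#'
#' @param compound Compound name, e.g. `"BHA"`, `"BHT"`, `"BPA"` or
#'   `"CONTROL"`.
#' @param concentration Compound concentration in mM (>= 0).
#' @param solvent_fraction Percent DMSO in the medium (typically 1-2).
#' @param replicate Trial index, integer >= 1.
#' @return An object of class `compound_condition`.
#' @export
compound_condition <- function(compound = "CONTROL", concentration = 0,
                               solvent_fraction = 1, replicate = 1L) {
  stopifnot(is.character(compound), length(compound) == 1L)
  check_scalar_number(concentration, "concentration", min = 0)
  check_scalar_number(solvent_fraction, "solvent_fraction", min = 0)
  check_scalar_number(replicate, "replicate", min = 1)
  if (identical(toupper(compound), "CONTROL") && concentration != 0) {
    ps_abort("CONTROL condition must have concentration 0", "config_error")
  }
  structure(
    list(compound = compound, concentration = concentration,
         solvent_fraction = solvent_fraction,
         replicate = as.integer(replicate)),
    class = "compound_condition"
  )
}

#' Plate layout: grid geometry and position-to-strain map
#'
#' A plate layout ties each grid position of a pinned or spotted plate to a
#' strain identifier, marks which positions carry the wild-type reference
#' strain, and optionally annotates a serial-dilution axis. Positions are
#' 1-based `(row, col)` internally and A1-style externally (see
#' [pos_to_label()]).
#'
#' @param plate_id Plate identifier string.
#' @param n_rows,n_cols Grid dimensions (48-, 96- and 384-position formats
#'   are the common cases; any positive grid is accepted).
#' @param positions data.frame with columns `row`, `col` (1-based integers),
#'   `strain_id` (character; `"EMPTY"` marks unused positions), `is_wt`
#'   (logical) and optionally `dilution_step` (integer; NA when the plate has
#'   no dilution series).
#' @param dilution_axis Optional list with elements `axis` (`"row"` or
#'   `"col"`) and `factors` (ordered dilution factors, e.g.
#'   `10^-(1:5)`).
#' @param condition A [compound_condition()].
#' @param wt_strain Identifier of the wild-type reference strain.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(plate_id, n_rows, n_cols, positions,
                         dilution_axis = NULL,
                         condition = compound_condition(),
                         wt_strain = "wt") {
  check_scalar_number(n_rows, "n_rows", min = 1)
  check_scalar_number(n_cols, "n_cols", min = 1)
  req <- c("row", "col", "strain_id", "is_wt")
  if (!all(req %in% names(positions))) {
    ps_abort(sprintf("positions must have columns %s",
                     paste(req, collapse = ", ")), "layout_error")
  }
  if (is.null(positions$dilution_step)) positions$dilution_step <- NA_integer_
  positions <- positions[order(positions$row, positions$col),
                         c(req, "dilution_step")]
  rownames(positions) <- NULL

  key <- paste(positions$row, positions$col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ps_abort(sprintf("duplicate grid position (%s) in layout '%s'",
                     dup, plate_id), "duplicate_position_error")
  }
  if (any(positions$row < 1 | positions$row > n_rows |
          positions$col < 1 | positions$col > n_cols)) {
    ps_abort("position outside the plate grid", "layout_error")
  }
  wt <- positions$is_wt
  if (any(wt & positions$strain_id != wt_strain)) {
    ps_abort(sprintf(
      "wild-type position mapped to a strain other than '%s'", wt_strain),
      "layout_error")
  }
  if (!is.null(dilution_axis)) {
    if (!dilution_axis$axis %in% c("row", "col")) {
      ps_abort("dilution_axis$axis must be 'row' or 'col'", "layout_error")
    }
  }
  structure(
    list(plate_id = as.character(plate_id),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         positions = positions, dilution_axis = dilution_axis,
         condition = condition, wt_strain = wt_strain),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  n_wt <- sum(x$positions$is_wt)
  cat(sprintf("plate_layout '%s': %d x %d grid, %d mapped positions (%d wt)\n",
              x$plate_id, x$n_rows, x$n_cols, nrow(x$positions), n_wt))
  cat(sprintf("condition: %s %.3g mM (replicate %d)\n",
              x$condition$compound, x$condition$concentration,
              x$condition$replicate))
  invisible(x)
}

#' Wild-type positions of a layout
#'
#' @param layout A [plate_layout()].
#' @return data.frame with columns `row`, `col`.
#' @export
wt_positions <- function(layout) {
  layout$positions[layout$positions$is_wt, c("row", "col")]
}

layout_columns <- c("plate_id", "row", "col", "strain_id", "is_wt",
                    "dilution_step")

#' Read a plate layout from a TSV file
#'
#' The file must be tab-separated with a header row and the fixed columns
#' `plate_id`, `row`, `col`, `strain_id`, `is_wt`, `dilution_step`. Rows are
#' A1-style: the `row` column holds letters, `col` holds numbers. Unknown
#' extra columns are preserved on the returned object (attribute
#' `extra_columns`) but otherwise ignored. `is_wt` is 0/1.
#'
#' @param path Path to the TSV file.
#' @param n_rows,n_cols Grid dimensions; defaults are inferred as the maximum
#'   row/column present.
#' @inheritParams plate_layout
#' @return A [plate_layout()].
#' @export
read_plate_layout <- function(path, n_rows = NULL, n_cols = NULL,
                              dilution_axis = NULL,
                              condition = compound_condition(),
                              wt_strain = "wt") {
  if (!file.exists(path)) {
    ps_abort(sprintf("layout file not found: %s", path), "io_error")
  }
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  missing_cols <- setdiff(layout_columns, names(raw))
  if (length(missing_cols)) {
    ps_abort(sprintf("layout file %s lacks column(s): %s", path,
                     paste(missing_cols, collapse = ", ")), "parse_error")
  }
  n_in <- nrow(raw)
  row_idx <- suppressWarnings(
    ifelse(grepl("^[A-Za-z]+$", raw$row),
           label_to_pos(paste0(raw$row, "1"))$row,
           as.integer(raw$row)))
  col_idx <- suppressWarnings(as.integer(raw$col))
  is_wt <- suppressWarnings(as.integer(raw$is_wt))
  bad <- which(is.na(row_idx) | is.na(col_idx) | is.na(is_wt) |
                 !is_wt %in% c(0L, 1L) | raw$strain_id == "")
  if (length(bad)) {
    ps_abort(sprintf("malformed layout row at line %d of %s",
                     bad[1] + 1L, path), "parse_error",
             line = bad[1] + 1L)
  }
  positions <- data.frame(
    row = row_idx, col = col_idx, strain_id = raw$strain_id,
    is_wt = is_wt == 1L,
    dilution_step = suppressWarnings(as.integer(raw$dilution_step))
  )
  layout <- plate_layout(
    plate_id = raw$plate_id[1],
    n_rows = n_rows %||% max(row_idx), n_cols = n_cols %||% max(col_idx),
    positions = positions, dilution_axis = dilution_axis,
    condition = condition, wt_strain = wt_strain
  )
  stopifnot(nrow(layout$positions) == n_in)  # readers never drop rows
  attr(layout, "extra_columns") <- setdiff(names(raw), layout_columns)
  layout
}

#' Write a plate layout to canonical TSV
#'
#' Writes the fixed column set in canonical order (sorted by row then
#' column, rows as letters, `is_wt` as 0/1, empty `dilution_step` blank).
#' `write_plate_layout(read_plate_layout(f))` is byte-identical to a
#' canonical `f`.
#'
#' @param layout A [plate_layout()].
#' @param path Output path.
#' @export
write_plate_layout <- function(layout, path) {
  p <- layout$positions
  out <- data.frame(
    plate_id = layout$plate_id,
    row = gsub("[0-9]+$", "", pos_to_label(p$row, 1L)),
    col = p$col,
    strain_id = p$strain_id,
    is_wt = as.integer(p$is_wt),
    dilution_step = ifelse(is.na(p$dilution_step), "", p$dilution_step)
  )
  write_tsv_file(out, path)
  invisible(path)
}

# Shared TSV writer: tab separated, no quotes, no row names, "\n" endings.
write_tsv_file <- function(df, path) {
  ok <- tryCatch({
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = "NA"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ps_abort(sprintf("cannot write to %s", path), "io_error")
  invisible(path)
}
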