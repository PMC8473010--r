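#' Text-file dialect for exported force curves
#'
#' Instrument processing software exports force curves as plain-text tables
#' (comment header lines followed by numeric columns). This helper bundles
#' the knobs needed to read such files.
#'
#' @param comment Prefix marking comment/header lines (default `"#"`).
#' @param z_col Column index holding tip-sample separation (default 1).
#' @param force_col Column index holding force (default 2).
#' @param sep Field separator passed to [utils::read.table()]; `""` means
#'   any whitespace.
#' @param segment Which segment to keep when a file contains both an extend
#'   and a retract block: `"approach"` (default), `"retract"` or `"all"`.
#' @return A list of class `curve_dialect`.
#' @export
curve_dialect <- function(comment = "#", z_col = 1L, force_col = 2L,
                          sep = "", segment = c("approach", "retract", "all")) {
  segment <- match.arg(segment)
  structure(list(comment = comment, z_col = as.integer(z_col),
                 force_col = as.integer(force_col), sep = sep,
                 segment = segment),
            class = "curve_dialect")
}

# SI heuristic: values recorded in metres/newtons are ~1e-9 -- 1e-6 in
# magnitude, while nm/nN values are ~0.1 -- 1e3. Anything below 1e-3 is
# taken as SI and scaled by 1e9. Idempotent on already-converted data.
.normalize_units <- function(x) {
  m <- max(abs(x))
  if (m > 0 && m < 1e-3) x * 1e9 else x
}

# Keep the block in which z decreases (weakly) monotonically: that is the
# approach, where breakthrough occurs. Files holding extend + retract are
# split at the z minimum (turning point).
.select_segment <- function(z, f, segment) {
  if (segment == "all") {
    return(list(z = z, f = f, segment = "unknown"))
  }
  turn <- which.min(z)
  approach_idx <- seq_len(turn)
  retract_idx <- if (turn < length(z)) seq(turn, length(z)) else integer(0)
  has_retract <- length(retract_idx) >= 2 &&
    all(diff(z[retract_idx]) >= 0) && !all(diff(z[approach_idx]) >= 0)
  if (segment == "approach") {
    if (has_retract) list(z = z[approach_idx], f = f[approach_idx],
                          segment = "approach")
    else list(z = z, f = f, segment = "approach")
  } else {
    if (!has_retract) stop("no retract segment found in file", call. = FALSE)
    list(z = z[retract_idx], f = f[retract_idx], segment = "retract")
  }
}

#' Read a force curve from a plain-text export
#'
#' Reads one exported force-distance curve (two numeric columns, optional
#' comment header), converts units to nm/nN if the file is in SI units, and
#' keeps the approach segment when both segments are present.
#'
#' Unit detection: columns whose largest absolute value is below `1e-3` are
#' assumed to be SI (metres/newtons) and multiplied by `1e9`; the conversion
#' is idempotent on data already in nm/nN.
#'
#' @param path Path to the text file (or a connection).
#' @param dialect A [curve_dialect()].
#' @param grid_index Optional `c(row, col)` to attach.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, dialect = curve_dialect(),
                             grid_index = NULL) {
  stopifnot(inherits(dialect, "curve_dialect"))
  tab <- tryCatch(
    utils::read.table(path, comment.char = dialect$comment,
                      sep = dialect$sep, header = FALSE,
                      colClasses = "numeric", blank.lines.skip = TRUE),
    error = function(e) {
      stop("malformed force-curve file '", paste(path, collapse = ""),
           "': ", conditionMessage(e), call. = FALSE)
    })
  if (nrow(tab) < 2) {
    stop("malformed force-curve file: fewer than 2 numeric rows",
         call. = FALSE)
  }
  if (max(dialect$z_col, dialect$force_col) > ncol(tab)) {
    stop("file has ", ncol(tab), " columns but dialect asks for column ",
         max(dialect$z_col, dialect$force_col), call. = FALSE)
  }
  z <- tab[[dialect$z_col]]
  f <- tab[[dialect$force_col]]
  bad <- which(!is.finite(z) | !is.finite(f))
  if (length(bad) > 0) {
    stop("non-finite value in force-curve file at data row ", bad[1],
         call. = FALSE)
  }
  z <- .normalize_units(z)
  f <- .normalize_units(f)
  seg <- .select_segment(z, f, dialect$segment)
  src <- if (is.character(path)) basename(path) else ""
  force_curve(seg$z, seg$f, grid_index = grid_index,
              segment = seg$segment, source_id = src)
}

#' Write a force curve as a tab-separated text file
#'
#' The written format (comment header + two numeric columns, nm/nN) is read
#' back by [read_force_curve()] with the default dialect.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# force-distance curve",
               paste0("# segment: ", curve$segment),
               "# columns: z_nm force_nN"), con)
  utils::write.table(
    data.frame(z = format(curve$z, digits = 15),
               force = format(curve$force, digits = 15)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.order_cells <- function(n_rows, n_cols, acquisition_order) {
  cells <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  cells <- cells[, c("row", "col")]
  if (acquisition_order == "serpentine") {
    for (r in seq_len(n_rows)) {
      if (r %% 2L == 0L) {
        sel <- cells$row == r
        cells$col[sel] <- rev(cells$col[sel])
      }
    }
  }
  cells
}

#' Read a directory of force-curve files as a grid
#'
#' Files are assigned to grid cells either through a manifest (CSV with
#' columns `filename,row,col`, 1-based) or, without one, by sorted filename
#' order following the acquisition order (raster: row-major from the top
#' row; serpentine: every second row reversed). Cells beyond the file count
#' stay empty.
#'
#' @param path Directory containing the curve files.
#' @param n_rows,n_cols Grid dimensions.
#' @param physical_size Field size in micrometres (scalar or
#'   `c(width, height)`).
#' @param acquisition_order `"raster"` or `"serpentine"`.
#' @param manifest Optional path to a manifest CSV.
#' @param pattern Filename filter used when no manifest is given (default
#'   `"\\.(txt|tsv|dat)$"`).
#' @param dialect A [curve_dialect()].
#' @return A [force_grid()].
#' @export
read_force_grid <- function(path, n_rows, n_cols, physical_size,
                            acquisition_order = c("raster", "serpentine"),
                            manifest = NULL,
                            pattern = "\\.(txt|tsv|dat)$",
                            dialect = curve_dialect()) {
  acquisition_order <- match.arg(acquisition_order)
  n_cells <- n_rows * n_cols
  curves <- list()
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("filename", "row", "col")
    if (!all(need %in% names(man))) {
      stop("manifest must have columns filename,row,col", call. = FALSE)
    }
    if (nrow(man) > n_cells) {
      stop("manifest lists ", nrow(man), " files but grid has only ",
           n_cells, " cells", call. = FALSE)
    }
    key <- paste(man$row, man$col)
    if (anyDuplicated(key)) {
      stop("ambiguous manifest: cell (",
           key[duplicated(key)][1], ") mapped more than once", call. = FALSE)
    }
    for (i in seq_len(nrow(man))) {
      curves[[i]] <- read_force_curve(
        file.path(path, man$filename[i]), dialect = dialect,
        grid_index = c(man$row[i], man$col[i]))
    }
  } else {
    files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
    if (length(files) > n_cells) {
      stop(length(files), " files found but grid has only ", n_cells,
           " cells", call. = FALSE)
    }
    cells <- .order_cells(n_rows, n_cols, acquisition_order)
    for (i in seq_along(files)) {
      curves[[i]] <- read_force_curve(
        files[i], dialect = dialect,
        grid_index = c(cells$row[i], cells$col[i]))
    }
  }
  force_grid(n_rows, n_cols, physical_size, curves = curves,
             acquisition_order = acquisition_order)
}

#' Write a grid of force curves to a directory with a manifest
#'
#' @param grid A [force_grid()].
#' @param path Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_force_grid <- function(grid, path) {
  stopifnot(inherits(grid, "force_grid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- integer(0); cols <- integer(0); fns <- character(0)
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      fc <- grid_cell(grid, r, cc)
      if (is.null(fc)) next
      fn <- sprintf("curve_r%03d_c%03d.txt", r, cc)
      write_force_curve(fc, file.path(path, fn))
      rows <- c(rows, r); cols <- c(cols, cc); fns <- c(fns, fn)
    }
  }
  man <- file.path(path, "manifest.csv")
  utils::write.csv(data.frame(filename = fns, row = rows, col = cols),
                   man, row.names = FALSE, quote = FALSE)
  invisible(man)
}
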