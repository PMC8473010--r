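#' Force-distance curve
#'
#' Container for a single AFM force-distance curve: tip-sample separation
#' `z` (nm, decreasing toward contact along the approach) and vertical
#' force `F` (nN), sampled at one point of a force-volume grid.
#'
#' @param z Numeric vector of tip-sample separations (nm).
#' @param force Numeric vector of forces (nN), same length as `z`.
#' @param grid_index Optional integer vector `c(row, col)` locating the curve
#'   on the acquisition grid (1-based), or `NULL`.
#' @param segment Which part of the force cycle the samples belong to:
#'   `"approach"`, `"retract"` or `"unknown"`.
#' @param source_id Free-text provenance tag (usually the file name).
#'
#' @return An object of class `force_curve`: a list with elements `z`,
#'   `force`, `grid_index`, `segment`, `source_id`.
#' @examples
#' fc <- force_curve(z = c(10, 5, 0), force = c(0, 0.5, 1))
#' length(fc$z)
#' @export
force_curve <- function(z, force, grid_index = NULL,
                        segment = c("unknown", "approach", "retract"),
                        source_id = "") {
  segment <- match.arg(segment)
  z <- as.numeric(z)
  force <- as.numeric(force)
  if (length(z) != length(force)) {
    stop("z and force must have the same length", call. = FALSE)
  }
  if (length(z) < 2) {
    stop("a force curve needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(z)) || !all(is.finite(force))) {
    bad <- which(!is.finite(z) | !is.finite(force))[1]
    stop("non-finite value in force curve at sample ", bad, call. = FALSE)
  }
  if (!is.null(grid_index)) {
    grid_index <- as.integer(grid_index)
    stopifnot(length(grid_index) == 2L, all(grid_index >= 1L))
  }
  structure(
    list(z = z, force = force, grid_index = grid_index,
         segment = segment, source_id = as.character(source_id)[1]),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat("<force_curve> ", length(x$z), " samples, z [",
      format(min(x$z), digits = 4), ", ", format(max(x$z), digits = 4),
      "] nm, F [", format(min(x$force), digits = 4), ", ",
      format(max(x$force), digits = 4), "] nN, segment = ", x$segment,
      if (nzchar(x$source_id)) paste0(", source = ", x$source_id), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.force_curve <- function(x) length(x$z)

#' Rectangular grid of force curves
#'
#' Represents one force-volume acquisition: an `n_rows` x `n_cols` grid of
#' measurement points over a rectangular field, each cell holding at most one
#' [force_curve()]. Cells without a curve stay empty and are flagged as
#' missing by downstream map assembly.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param physical_size Physical field size in micrometres, either a single
#'   number (square field) or `c(width, height)`.
#' @param curves A list of `force_curve` objects, each carrying a
#'   `grid_index`; or an empty list.
#' @param acquisition_order `"raster"` (row-major, top row first) or
#'   `"serpentine"` (alternate rows reversed). Only used when curves are
#'   assigned to cells by file order.
#'
#' @return An object of class `force_grid`.
#' @examples
#' g <- force_grid(16, 16, physical_size = 5)
#' grid_spacing(g)
#' @export
force_grid <- function(n_rows, n_cols, physical_size, curves = list(),
                       acquisition_order = c("raster", "serpentine")) {
  acquisition_order <- match.arg(acquisition_order)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  physical_size <- as.numeric(physical_size)
  if (length(physical_size) == 1L) physical_size <- rep(physical_size, 2L)
  stopifnot(length(physical_size) == 2L, all(physical_size > 0))
  cells <- vector("list", n_rows * n_cols)
  for (fc in curves) {
    stopifnot(inherits(fc, "force_curve"))
    idx <- fc$grid_index
    if (is.null(idx)) {
      stop("curves stored in a grid must carry a grid_index", call. = FALSE)
    }
    if (idx[1] > n_rows || idx[2] > n_cols) {
      stop("grid_index (", idx[1], ",", idx[2], ") outside ",
           n_rows, "x", n_cols, " grid", call. = FALSE)
    }
    cells[[(idx[1] - 1L) * n_cols + idx[2]]] <- fc
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, physical_size = physical_size,
         cells = cells, acquisition_order = acquisition_order),
    class = "force_grid"
  )
}

#' @export
print.force_grid <- function(x, ...) {
  n_pop <- sum(!vapply(x$cells, is.null, logical(1)))
  cat("<force_grid> ", x$n_rows, "x", x$n_cols, " over ",
      x$physical_size[1], "x", x$physical_size[2], " um, ",
      n_pop, "/", length(x$cells), " cells populated, order = ",
      x$acquisition_order, "\n", sep = "")
  invisible(x)
}

#' Retrieve the curve stored at a grid cell
#'
#' @param grid A [force_grid()].
#' @param row,col 1-based cell index.
#' @return The `force_curve` at that cell, or `NULL` if the cell is empty.
#' @export
grid_cell <- function(grid, row, col) {
  stopifnot(inherits(grid, "force_grid"))
  if (row < 1 || row > grid$n_rows || col < 1 || col > grid$n_cols) {
    stop("cell (", row, ",", col, ") outside grid", call. = FALSE)
  }
  grid$cells[[(row - 1L) * grid$n_cols + col]]
}

#' Distance between neighbouring measurement points
#'
#' For a field of width `w` micrometres divided into `n_cols` columns the
#' spacing between neighbouring measurement points is `w / n_cols`
#' (0.3125 um for a 5 um field on a 16-point grid).
#'
#' @param grid A [force_grid()].
#' @return Spacing in micrometres (scalar, horizontal direction).
#' @examples
#' grid_spacing(force_grid(16, 16, 5)) # 0.3125
#' @export
grid_spacing <- function(grid) {
  stopifnot(inherits(grid, "force_grid"))
  if (grid$n_cols == 0L) stop("grid has zero columns", call. = FALSE)
  grid$physical_size[1] / grid$n_cols
}
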