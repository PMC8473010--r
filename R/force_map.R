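#' Assemble per-cell breakthrough events into a spatial map
#'
#' Builds the spatial reconstruction of a force-volume experiment: one
#' value per grid cell, taken from the chosen channel (breakthrough force
#' or thickness) of the chosen-rank event of that cell. Cells without a
#' surviving event are flagged `missing` (no numeric value); cells with
#' more than one event of the chosen rank take the first and are flagged
#' `multiple`.
#'
#' @param grid A [force_grid()] (supplies shape and physical metadata).
#' @param events Event data frame (as from [analyse_grid()] or
#'   [extract_events()]) with columns `row`, `col`, `rank`, `force`,
#'   `thickness`.
#' @param channel `"force"` (nN) or `"thickness"` (nm).
#' @param rank_used `"primary"` or `"secondary"`.
#' @return An object of class `force_map`: list with `values` (numeric
#'   matrix, `NA` at missing cells), `flags` (character matrix: "ok",
#'   "missing", "multiple"), `channel`, `rank_used`, `physical_size`,
#'   `spacing`.
#' @export
assemble_map <- function(grid, events, channel = c("force", "thickness"),
                         rank_used = c("primary", "secondary")) {
  channel <- match.arg(channel)
  rank_used <- match.arg(rank_used)
  stopifnot(inherits(grid, "force_grid"))
  values <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  flags <- matrix("missing", grid$n_rows, grid$n_cols)
  if (nrow(events) > 0) {
    stopifnot(all(c("row", "col", "rank") %in% names(events)))
    if (any(events$row < 1 | events$row > grid$n_rows |
              events$col < 1 | events$col > grid$n_cols)) {
      stop("event cell index outside the grid", call. = FALSE)
    }
    sel <- events[events$rank == rank_used, , drop = FALSE]
    for (cell in split(sel, paste(sel$row, sel$col))) {
      r <- cell$row[1]; cc <- cell$col[1]
      values[r, cc] <- cell[[channel]][1]
      flags[r, cc] <- if (nrow(cell) > 1) "multiple" else "ok"
    }
  }
  structure(list(values = values, flags = flags, channel = channel,
                 rank_used = rank_used,
                 physical_size = grid$physical_size,
                 spacing = grid_spacing(grid)),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat("<force_map> ", nrow(x$values), "x", ncol(x$values), " ",
      x$channel, " map (", x$rank_used, " events), ",
      sum(x$flags == "missing"), " missing, ",
      sum(x$flags == "multiple"), " multiple\n", sep = "")
  invisible(x)
}

#' Render a force map as a colour raster
#'
#' Missing cells render black, mirroring the dark dots of a reconstructed
#' force map where no rupture event was found; numeric cells are mapped
#' over `value_range` with the given palette.
#'
#' @param map A [assemble_map()] result.
#' @param value_range `c(low, high)` for the colour scale, or `NULL` for
#'   the observed range.
#' @param palette Function `n -> colours` (default viridis).
#' @param n_colours Number of palette levels.
#' @return A character matrix of hex colours, same shape as the map, with
#'   attribute `value_range`.
#' @export
map_to_image <- function(map, value_range = NULL,
                         palette = function(n) grDevices::hcl.colors(n, "viridis"),
                         n_colours = 256L) {
  stopifnot(inherits(map, "force_map"))
  vals <- map$values
  if (is.null(value_range)) {
    value_range <- if (all(is.na(vals))) c(0, 1) else range(vals, na.rm = TRUE)
  }
  if (value_range[1] > value_range[2]) {
    stop("inverted value_range", call. = FALSE)
  }
  cols <- palette(n_colours)
  out <- matrix("#000000", nrow(vals), ncol(vals))
  ok <- !is.na(vals)
  if (any(ok)) {
    span <- value_range[2] - value_range[1]
    frac <- if (span > 0) (vals[ok] - value_range[1]) / span else rep(0.5, sum(ok))
    frac <- pmin(pmax(frac, 0), 1)
    out[ok] <- cols[1L + as.integer(round(frac * (n_colours - 1L)))]
  }
  attr(out, "value_range") <- value_range
  out
}

#' @param x A `force_map`.
#' @param value_range,main Passed through to the renderer / title.
#' @param ... Ignored.
#' @rdname map_to_image
#' @export
plot.force_map <- function(x, value_range = NULL, main = NULL, ...) {
  img <- map_to_image(x, value_range)
  nr <- nrow(img); nc <- ncol(img)
  op <- graphics::par(mar = c(2, 2, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, nc), ylim = c(0, nr), asp = 1,
                 xaxs = "i", yaxs = "i", xlab = "", ylab = "",
                 main = main %||% paste(x$channel, "map"))
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, nc, nr,
                        interpolate = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a rendered map to png, pdf or svg
#'
#' @param map A `force_map`.
#' @param path Output file; the extension selects the device (png, pdf,
#'   svg).
#' @param value_range Optional fixed colour range.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
save_map_image <- function(map, path, value_range = NULL,
                           width = 5, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported image format '", ext, "'", call. = FALSE))
  on.exit(grDevices::dev.off())
  plot(map, value_range = value_range)
  invisible(path)
}

#' Write / read a force map as CSV matrices
#'
#' The map is persisted as a values CSV (empty fields at missing cells)
#' plus a sidecar flags CSV and a small JSON header with channel, rank and
#' geometry, so that a written map reloads identically.
#'
#' @param map A `force_map`.
#' @param path Basename; files `<path>_values.csv`, `<path>_flags.csv`,
#'   `<path>_meta.json` are written.
#' @return For `write_force_map`, the basename invisibly; for
#'   `read_force_map`, the reloaded `force_map`.
#' @export
write_force_map <- function(map, path) {
  stopifnot(inherits(map, "force_map"))
  utils::write.table(map$values, paste0(path, "_values.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, na = "")
  utils::write.table(map$flags, paste0(path, "_flags.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(channel = map$channel, rank_used = map$rank_used,
         physical_size = map$physical_size, spacing = map$spacing),
    paste0(path, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path Basename used by [write_force_map()].
#' @rdname write_force_map
#' @export
read_force_map <- function(path) {
  values <- as.matrix(utils::read.table(paste0(path, "_values.csv"),
                                        sep = ",", header = FALSE,
                                        na.strings = ""))
  flags <- as.matrix(utils::read.table(paste0(path, "_flags.csv"),
                                       sep = ",", header = FALSE,
                                       colClasses = "character"))
  meta <- jsonlite::read_json(paste0(path, "_meta.json"),
                              simplifyVector = TRUE)
  dimnames(values) <- NULL
  dimnames(flags) <- NULL
  storage.mode(values) <- "double"
  structure(list(values = values, flags = flags, channel = meta$channel,
                 rank_used = meta$rank_used,
                 physical_size = meta$physical_size, spacing = meta$spacing),
            class = "force_map")
}
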