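#' Analyse every curve of a force-volume grid
#'
#' Runs the per-curve breakthrough analysis (multi-angle kink detection,
#' opposite-curvature pairing, threshold filtering, primary/secondary
#' ranking) over all populated cells of a grid.
#'
#' @param grid A [force_grid()].
#' @param config A [detection_config()].
#' @param thresholds A [threshold_config()].
#' @return A data frame with one row per surviving event: `row`, `col`,
#'   `curve_id`, `rank`, `force`, `thickness`, `z_start`, `flag`.
#' @export
analyse_grid <- function(grid, config = detection_config(),
                         thresholds = threshold_config()) {
  stopifnot(inherits(grid, "force_grid"))
  out <- list()
  k <- 0L
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      fc <- grid_cell(grid, r, cc)
      if (is.null(fc)) next
      ev <- analyse_curve(fc, config, thresholds)
      if (nrow(ev) == 0) next
      ev$row <- r
      ev$col <- cc
      k <- k + 1L
      out[[k]] <- ev
    }
  }
  if (k == 0L) {
    return(data.frame(curve_id = character(0), rank = character(0),
                      force = numeric(0), thickness = numeric(0),
                      z_start = numeric(0), flag = character(0),
                      row = integer(0), col = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phase analysis of grid events
#'
#' Collects the primary event of every analysed cell, clusters the
#' (force, thickness) points into two groups, assigns Lo/Ld identity and
#' computes the cluster summary and the spatial phase map.
#'
#' @param grid A [force_grid()].
#' @param events Event table from [analyse_grid()].
#' @param seed Clustering seed.
#' @param features Feature mode, see [cluster_two()].
#' @return A list with `points` (primary events + `phase` column),
#'   `summary` (a [phase_summary()]), and `map` (character phase matrix
#'   from [cluster_map()]).
#' @export
phase_analysis <- function(grid, events, seed = 1,
                           features = c("force_thickness", "thickness")) {
  features <- match.arg(features)
  pts <- events[events$rank == "primary", , drop = FALSE]
  labels <- cluster_two(pts, seed = seed, features = features)
  phases <- assign_phases(labels, pts)
  pts$phase <- phases
  list(points = pts,
       summary = phase_summary(phases, pts),
       map = cluster_map(grid, pts, phases))
}

#' Run the full force-map analysis and write all artifacts
#'
#' End-to-end pipeline: analyse every curve of a grid, write the event
#' table, force and thickness maps (CSV + rendered image), the cluster
#' summary and phase map, and a JSON session file from which the maps can
#' be rebuilt without re-running detection.
#'
#' @param grid A [force_grid()].
#' @param out_dir Output directory (created if needed).
#' @param config A [detection_config()].
#' @param thresholds A [threshold_config()].
#' @param rank `"primary"` or `"secondary"`: which events feed the maps.
#' @param seed Clustering seed.
#' @param value_range Optional fixed colour range for rendered maps.
#' @param formats Image formats to write, subset of png/pdf/svg.
#' @param cluster Run the phase-clustering stage (default `TRUE`;
#'   requires events in at least two distinct locations).
#' @return Invisibly, a list with the event table, the two maps, the phase
#'   analysis (or `NULL`) and the session file path.
#' @export
run_analyse <- function(grid, out_dir, config = detection_config(),
                        thresholds = threshold_config(),
                        rank = c("primary", "secondary"), seed = 1,
                        value_range = NULL, formats = "png",
                        cluster = TRUE) {
  rank <- match.arg(rank)
  stopifnot(all(formats %in% c("png", "pdf", "svg")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- analyse_grid(grid, config, thresholds)
  utils::write.csv(events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  fmap <- assemble_map(grid, events, channel = "force", rank_used = rank)
  tmap <- assemble_map(grid, events, channel = "thickness", rank_used = rank)
  write_force_map(fmap, file.path(out_dir, "force_map"))
  write_force_map(tmap, file.path(out_dir, "thickness_map"))
  for (fmt in formats) {
    save_map_image(fmap, file.path(out_dir, paste0("force_map.", fmt)),
                   value_range = value_range)
    save_map_image(tmap, file.path(out_dir, paste0("thickness_map.", fmt)),
                   value_range = value_range)
  }
  ph <- NULL
  if (cluster && sum(events$rank == "primary") >= 2) {
    ph <- phase_analysis(grid, events, seed = seed)
    write_phase_summary(ph$summary,
                        file.path(out_dir, "cluster_summary.csv"))
    utils::write.table(ph$map, file.path(out_dir, "phase_map.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       na = "", quote = FALSE)
  }
  session <- file.path(out_dir, "session.json")
  jsonlite::write_json(
    list(grid = list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                     physical_size = grid$physical_size,
                     acquisition_order = grid$acquisition_order),
         config = unclass(config), thresholds = unclass(thresholds),
         rank = rank, seed = seed,
         events = events),
    session, auto_unbox = TRUE, digits = NA)
  invisible(list(events = events, force_map = fmap, thickness_map = tmap,
                 phase = ph, session = session))
}

#' Reload a saved analysis session and rebuild its maps
#'
#' Re-assembles force and thickness maps from the event table stored in a
#' session file, without re-running detection.
#'
#' @param session Path to a `session.json` written by [run_analyse()].
#' @param rank Optional override of the stored map rank.
#' @return A list with `events`, `force_map`, `thickness_map` and the
#'   stored `config`/`thresholds` lists.
#' @export
reload_session <- function(session, rank = NULL) {
  s <- jsonlite::read_json(session, simplifyVector = TRUE)
  grid <- force_grid(s$grid$n_rows, s$grid$n_cols, s$grid$physical_size,
                     acquisition_order = s$grid$acquisition_order)
  events <- as.data.frame(s$events)
  rank <- rank %||% s$rank
  list(events = events,
       force_map = assemble_map(grid, events, "force", rank),
       thickness_map = assemble_map(grid, events, "thickness", rank),
       config = s$config, thresholds = s$thresholds)
}
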