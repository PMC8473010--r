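#' Two-group k-means clustering of breakthrough points
#'
#' Clusters per-curve (force, thickness) points into two groups. Features
#' are z-score standardized before clustering because nN and nm scales are
#' not commensurate; an option restricts clustering to thickness alone.
#' Multiple random restarts with the best within-cluster sum of squares
#' are used, and the result is deterministic for a given seed.
#'
#' @param points Data frame with columns `force` (nN) and `thickness`
#'   (nm), one row per curve with a surviving primary event.
#' @param seed Integer RNG seed (default 1).
#' @param features `"force_thickness"` (default) or `"thickness"`.
#' @param nstart Number of random restarts (default 10).
#' @return Integer vector of cluster labels (1/2), with the fitted
#'   `stats::kmeans` object as attribute `fit` and the feature mode as
#'   attribute `features`.
#' @export
cluster_two <- function(points, seed = 1,
                        features = c("force_thickness", "thickness"),
                        nstart = 10) {
  features <- match.arg(features)
  stopifnot(all(c("force", "thickness") %in% names(points)))
  x <- if (features == "thickness") {
    cbind(thickness = points$thickness)
  } else {
    cbind(force = points$force, thickness = points$thickness)
  }
  if (nrow(x) < 2) stop("need at least 2 points to cluster", call. = FALSE)
  if (nrow(unique(x)) < 2) {
    stop("degenerate input: all points identical, cannot form two clusters",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  xs <- scale(x, scale = ifelse(sds > 0, sds, 1))
  set.seed(seed)
  fit <- if (nrow(xs) == 2) {
    # Hartigan-Wong needs more points than centres
    stats::kmeans(xs, centers = 2, algorithm = "Lloyd")
  } else {
    stats::kmeans(xs, centers = 2, nstart = nstart, iter.max = 100)
  }
  labels <- fit$cluster
  attr(labels, "fit") <- fit
  attr(labels, "features") <- features
  labels
}

#' Assign Lo/Ld phase identity to two clusters
#'
#' The liquid-disordered (Ld) phase is the cluster with the lower mean
#' breakthrough force; the liquid-ordered (Lo) phase the one with the
#' higher. The assignment is invariant to how the clustering labelled the
#' groups.
#'
#' @param labels Integer labels (two distinct values) from [cluster_two()].
#' @param points The matching points data frame (column `force`).
#' @return Character vector of `"Ld"`/`"Lo"` per point.
#' @export
assign_phases <- function(labels, points) {
  lab <- unique(labels)
  if (length(lab) != 2) {
    stop("expected exactly two clusters, got ", length(lab), call. = FALSE)
  }
  m1 <- mean(points$force[labels == lab[1]])
  m2 <- mean(points$force[labels == lab[2]])
  if (isTRUE(all.equal(m1, m2))) {
    stop("degenerate clustering: clusters tie in mean force", call. = FALSE)
  }
  ld_lab <- if (m1 < m2) lab[1] else lab[2]
  ifelse(labels == ld_lab, "Ld", "Lo")
}

#' Per-phase cluster summary statistics
#'
#' Computes, per phase, the percentage of points inside the cluster, the
#' mean and sample SD of thickness and of force, and two mismatch
#' statistics on the thickness channel: `max_mismatch`, the maximum over
#' Lo points of (Lo thickness minus mean Ld thickness), and
#' `avg_mismatch`, the difference of the two phase thickness means (the
#' quantity comparable with an image-based height mismatch).
#'
#' @param phases Character vector `"Ld"`/`"Lo"` from [assign_phases()].
#' @param points Matching points data frame (`force`, `thickness`).
#' @return A list of class `phase_summary` with `per_phase` (data frame,
#'   one row per phase) and scalars `max_mismatch` and `avg_mismatch`
#'   (nm).
#' @export
phase_summary <- function(phases, points) {
  stopifnot(length(phases) == nrow(points),
            all(phases %in% c("Ld", "Lo")))
  if (!all(c("Ld", "Lo") %in% phases)) {
    stop("both phases must be non-empty", call. = FALSE)
  }
  per <- do.call(rbind, lapply(c("Ld", "Lo"), function(ph) {
    sel <- phases == ph
    data.frame(phase = ph,
               point_fraction = 100 * mean(sel),
               n = sum(sel),
               thickness_mean = mean(points$thickness[sel]),
               thickness_sd = stats::sd(points$thickness[sel]),
               force_mean = mean(points$force[sel]),
               force_sd = stats::sd(points$force[sel]))
  }))
  ld_mean <- per$thickness_mean[per$phase == "Ld"]
  lo_mean <- per$thickness_mean[per$phase == "Lo"]
  structure(list(per_phase = per,
                 max_mismatch = max(points$thickness[phases == "Lo"]) - ld_mean,
                 avg_mismatch = lo_mean - ld_mean),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("<phase_summary>\n")
  print(x$per_phase, row.names = FALSE, digits = 3)
  cat(sprintf("max mismatch: %.2f nm, average mismatch: %.2f nm\n",
              x$max_mismatch, x$avg_mismatch))
  invisible(x)
}

#' Spatial phase map from per-cell cluster assignments
#'
#' @param grid A [force_grid()] (shape metadata).
#' @param cells Data frame with columns `row`, `col` of the clustered
#'   points, aligned with `phases`.
#' @param phases Character vector `"Ld"`/`"Lo"` per point.
#' @return A character matrix (`"Ld"`, `"Lo"`, `NA` for cells that had no
#'   clustered point).
#' @export
cluster_map <- function(grid, cells, phases) {
  stopifnot(inherits(grid, "force_grid"), nrow(cells) == length(phases))
  out <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  for (i in seq_along(phases)) {
    out[cells$row[i], cells$col[i]] <- phases[i]
  }
  out
}

#' Write a cluster summary as CSV
#'
#' One row per phase with the point percentage, thickness mean and SD, and
#' the mismatch statistics repeated for convenience.
#'
#' @param summary A [phase_summary()] result.
#' @param path Output CSV path.
#' @param features Feature mode recorded with the output.
#' @return `path`, invisibly.
#' @export
write_phase_summary <- function(summary, path,
                                features = "force_thickness") {
  stopifnot(inherits(summary, "phase_summary"))
  df <- summary$per_phase
  df$max_mismatch <- summary$max_mismatch
  df$avg_mismatch <- summary$avg_mismatch
  df$features <- features
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
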