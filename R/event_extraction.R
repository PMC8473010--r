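#' Plausibility thresholds for breakthrough events
#'
#' Standard thresholds used to discard implausible kink pairs: at least
#' 0.5 nN of breakthrough force and a membrane thickness between 1.5 and
#' 9 nm. All bounds are inclusive.
#'
#' @param force_min Minimum breakthrough force (nN), default 0.5.
#' @param thickness_min,thickness_max Thickness window (nm), default
#'   1.5 to 9.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(force_min = 0.5, thickness_min = 1.5,
                             thickness_max = 9) {
  stopifnot(is.finite(force_min), force_min > 0,
            is.finite(thickness_min), is.finite(thickness_max),
            thickness_min > 0, thickness_min < thickness_max)
  structure(list(force_min = force_min, thickness_min = thickness_min,
                 thickness_max = thickness_max),
            class = "threshold_config")
}

#' Extract validated breakthrough events from kink pairs
#'
#' Applies the plausibility thresholds to the kink pairs of one curve and
#' ranks the survivors. When several events survive in one curve, the one
#' farthest from the support (largest `z_start`) is the primary event; all
#' others are secondary, the secondaries being closer to the mica support.
#' Curves with more than two surviving events keep them all (rank
#' secondary) and the extra ones are flagged.
#'
#' @param pairs Data frame from [pair_opposite_kinks()]`$pairs` (columns
#'   `force`, `thickness`, `z_start`, ...).
#' @param thresholds A [threshold_config()].
#' @param curve_id Identifier attached to every event (free text).
#' @return A data frame with columns `curve_id`, `rank` ("primary" or
#'   "secondary"), `force`, `thickness`, `z_start`, `flag` ("" or
#'   "extra").
#' @export
extract_events <- function(pairs, thresholds = threshold_config(),
                           curve_id = "") {
  stopifnot(inherits(thresholds, "threshold_config"))
  empty <- data.frame(curve_id = character(0), rank = character(0),
                      force = numeric(0), thickness = numeric(0),
                      z_start = numeric(0), flag = character(0))
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  keep <- pairs$force >= thresholds$force_min &
    pairs$thickness >= thresholds$thickness_min &
    pairs$thickness <= thresholds$thickness_max
  surv <- pairs[keep, , drop = FALSE]
  if (nrow(surv) == 0) return(empty)
  surv <- surv[order(-surv$z_start), , drop = FALSE]
  rank <- c("primary", rep("secondary", nrow(surv) - 1L))
  flag <- rep("", nrow(surv))
  if (nrow(surv) > 2) flag[3:nrow(surv)] <- "extra"
  out <- data.frame(curve_id = curve_id, rank = rank,
                    force = surv$force, thickness = surv$thickness,
                    z_start = surv$z_start, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simple peak statistics over breakthrough events
#'
#' @param events Event data frame from [extract_events()] (possibly
#'   concatenated over many curves).
#' @param rank Which rank to summarize: `"primary"` (default),
#'   `"secondary"` or `"all"`.
#' @return A list with `count`, `force_mean`, `force_sd`, `thickness_mean`,
#'   `thickness_sd` (sample SDs; means are `NA` for an empty selection).
#' @export
peak_statistics <- function(events, rank = c("primary", "secondary", "all")) {
  rank <- match.arg(rank)
  sel <- if (rank == "all") events else events[events$rank == rank, ,
                                               drop = FALSE]
  n <- nrow(sel)
  if (n == 0) {
    return(list(count = 0L, force_mean = NA_real_, force_sd = NA_real_,
                thickness_mean = NA_real_, thickness_sd = NA_real_))
  }
  list(count = n,
       force_mean = mean(sel$force),
       force_sd = if (n > 1) stats::sd(sel$force) else NA_real_,
       thickness_mean = mean(sel$thickness),
       thickness_sd = if (n > 1) stats::sd(sel$thickness) else NA_real_)
}

#' Full per-curve breakthrough analysis
#'
#' Convenience wrapper running kink detection on both curvature classes,
#' merging, pairing, and threshold filtering for one curve.
#'
#' @param curve A [force_curve()].
#' @param config A [detection_config()].
#' @param thresholds A [threshold_config()].
#' @return As [extract_events()], with `curve_id` taken from the curve's
#'   source id or grid index.
#' @export
analyse_curve <- function(curve, config = detection_config(),
                          thresholds = threshold_config()) {
  pos <- detect_kinks(curve, config, sign = 1)
  neg <- detect_kinks(curve, config, sign = -1)
  paired <- pair_opposite_kinks(pos, neg)
  id <- if (!is.null(curve$grid_index)) {
    paste0("r", curve$grid_index[1], "c", curve$grid_index[2])
  } else curve$source_id
  extract_events(paired$pairs, thresholds, curve_id = id)
}
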