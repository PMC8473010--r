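#' Detection configuration for breakthrough kinks
#'
#' @param angles Rotation angles in degrees, ascending and starting at 0.
#'   The defaults span the typical range of contact-region slopes in nN/nm,
#'   so that shoulder-type kinks whose slope change straddles `tan(angle)`
#'   turn into local maxima at some angle in the set.
#' @param delta Peak prominence threshold for [peakdet()], in rotated-frame
#'   force units (nN). Must exceed the noise amplitude of the curves.
#' @param merge_threshold Euclidean distance below which two detections (in
#'   the mixed nN/nm coordinate plane) are treated as the same kink. The
#'   default absorbs the ~1 nm positional jitter of the same kink across
#'   rotation angles on noisy curves.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(angles = c(0, 4.5, 9, 13.5, 18),
                             delta = 0.1, merge_threshold = 2.0) {
  angles <- as.numeric(angles)
  if (length(angles) < 1 || is.unsorted(angles, strictly = TRUE) ||
      angles[1] != 0) {
    stop("angles must be strictly ascending and start at 0", call. = FALSE)
  }
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (!is.finite(merge_threshold) || merge_threshold <= 0) {
    stop("merge_threshold must be > 0", call. = FALSE)
  }
  structure(list(angles = angles, delta = delta,
                 merge_threshold = merge_threshold),
            class = "detection_config")
}

#' Rotate a curve matrix in the force-distance plane
#'
#' Multiplies each row `[F, z]` by the rotation matrix
#' `[[cos phi, sin phi], [-sin phi, cos phi]]`, i.e. row i becomes
#' `[F cos phi - z sin phi, F sin phi + z cos phi]`. `phi = 0` is the
#' identity and rotations compose additively in `phi`.
#'
#' @param mat Numeric matrix with two columns (force, distance).
#' @param phi Rotation angle in degrees.
#' @return The rotated matrix.
#' @export
rotate_curve <- function(mat, phi) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 2, all(is.finite(mat)))
  a <- phi * pi / 180
  rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), nrow = 2)
  mat %*% rot
}

# Detection sequence for a curve at rotation angle phi.
# The curve is recast as rows [F, t] with t = max(z) - z (distance advanced
# toward the support), so z-jumps at constant force tilt downward under the
# positive rotation angles and shoulder kinks become local maxima of the
# rotated force coordinate. sign = -1 reflects the force axis first, which
# turns ascending-shoulder kinks (opposite curvature) into maxima instead:
# reflecting the rotated coordinate is the same as rotating the reflected
# curve -F(z) by the opposite angle.
.rotated_sequence <- function(curve, phi, sign) {
  t_adv <- max(curve$z) - curve$z
  sign * rotate_curve(cbind(curve$force, t_adv), phi)[, 1]
}

#' Detect breakthrough kinks in a force curve
#'
#' Runs [peakdet()] on the curve rotated at each configured angle and
#' collects the union of detections. A kink that is not a local force
#' maximum in the unrotated curve (e.g. a ramp-to-plateau shoulder) becomes
#' one at a nonzero angle once the rotation tilts the slope on one side of
#' the kink below zero. `sign = +1` detects descending-shoulder kinks
#' (rupture onset); `sign = -1` runs the detector on the reflected force
#' `-F(z)` and finds ascending-shoulder kinks (rupture completion, tip
#' meeting the support). Each detection is reported at the curve's original
#' coordinates and carries the smallest angle at which it was seen;
#' redundant detections across angles are then merged with
#' [merge_redundant()].
#'
#' Detections at the first or last sample are discarded (a kink needs
#' neighbours on both sides). Curves are expected in approach order
#' (z decreasing); curves shorter than 3 samples yield an empty result.
#'
#' @param curve A [force_curve()] in nm/nN.
#' @param config A [detection_config()].
#' @param sign `+1` or `-1` (curvature class searched for).
#' @param merge If `TRUE` (default) apply [merge_redundant()] before
#'   returning.
#' @return A data frame with columns `force` (nN), `z` (nm), `angle`
#'   (degrees), `curvature_sign`, `sample_index`.
#' @export
detect_kinks <- function(curve, config = detection_config(), sign = 1,
                         merge = TRUE) {
  stopifnot(inherits(curve, "force_curve"), inherits(config, "detection_config"),
            sign %in% c(-1, 1))
  empty <- data.frame(force = numeric(0), z = numeric(0), angle = numeric(0),
                      curvature_sign = numeric(0), sample_index = integer(0))
  n <- length(curve$z)
  if (n < 3) return(empty)
  idx <- integer(0); ang <- numeric(0)
  for (phi in config$angles) {
    v <- .rotated_sequence(curve, phi, sign)
    det <- peakdet(v, config$delta)$maxima$index
    det <- det[det > 1L & det < n]
    new <- !(det %in% idx)
    idx <- c(idx, det[new])
    ang <- c(ang, rep(phi, sum(new)))
  }
  out <- data.frame(force = curve$force[idx], z = curve$z[idx],
                    angle = ang, curvature_sign = rep(sign, length(idx)),
                    sample_index = idx)
  out <- out[order(out$sample_index), , drop = FALSE]
  rownames(out) <- NULL
  if (merge) out <- merge_redundant(out, config$merge_threshold)
  out
}

#' Merge redundant kink detections
#'
#' The same physical kink is usually detected at several rotation angles at
#' nearly the same coordinates. Detections whose Euclidean distance
#' `sqrt((Fi - Fj)^2 + (zi - zj)^2)` falls below `merge_threshold` are
#' considered the same kink; merging is applied repeatedly (transitively)
#' until no redundant pair remains, and each merged group keeps the
#' detection from the smallest rotation angle, which is the most accurate
#' one. The operation is idempotent.
#'
#' @param detections Data frame as returned by [detect_kinks()]
#'   (`merge = FALSE`).
#' @param merge_threshold Positive distance threshold in the mixed nN/nm
#'   plane.
#' @return The reduced data frame, ordered by `sample_index`.
#' @export
merge_redundant <- function(detections, merge_threshold) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  d <- as.matrix(stats::dist(cbind(detections$force, detections$z)))
  adj <- d < merge_threshold
  comp <- seq_len(n)
  repeat {                       # transitive closure by label propagation
    prev <- comp
    for (i in seq_len(n)) comp[adj[i, ]] <- min(comp[adj[i, ]], comp[i])
    if (identical(prev, comp)) break
  }
  keep <- vapply(unique(comp), function(g) {
    members <- which(comp == g)
    members[order(detections$angle[members],
                  detections$sample_index[members])][1]
  }, integer(1))
  out <- detections[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair opposite-curvature kinks into thickness measurements
#'
#' In a breakthrough curve every rupture-onset kink (positive curvature
#' class) is followed, along the approach direction, by a kink of the
#' opposite curvature where the tip has traversed the membrane. The
#' z-distance between the two is the membrane thickness at that point.
#' Each positive kink is paired with its nearest subsequent (smaller-z)
#' negative kink, each pairing decided independently; positive kinks with
#' no subsequent partner and negative kinks never chosen are reported as
#' unpaired.
#'
#' @param pos_kinks,neg_kinks Data frames from [detect_kinks()] with
#'   `sign = 1` and `sign = -1`, already merged.
#' @return A list with `pairs` (data frame: `force` nN at the start kink,
#'   `thickness` nm, `z_start`, `z_end`, `angle_start`, `angle_end`) and
#'   `unpaired` (the unmatched detections).
#' @export
pair_opposite_kinks <- function(pos_kinks, neg_kinks) {
  pairs <- data.frame(force = numeric(0), thickness = numeric(0),
                      z_start = numeric(0), z_end = numeric(0),
                      angle_start = numeric(0), angle_end = numeric(0))
  if (nrow(pos_kinks) == 0 || is.null(neg_kinks)) {
    return(list(pairs = pairs, unpaired = rbind(pos_kinks, neg_kinks)))
  }
  pos <- pos_kinks[order(-pos_kinks$z, pos_kinks$angle), , drop = FALSE]
  neg <- neg_kinks[order(-neg_kinks$z, neg_kinks$angle), , drop = FALSE]
  used <- rep(FALSE, nrow(neg))
  used_pos <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(pos))) {
    cand <- which(neg$z < pos$z[i])
    if (length(cand) == 0) next
    # nearest subsequent kink along the approach; ties by smaller angle
    dz <- pos$z[i] - neg$z[cand]
    best <- cand[order(dz, neg$angle[cand])][1]
    used[best] <- TRUE
    used_pos[i] <- TRUE
    pairs <- rbind(pairs, data.frame(
      force = pos$force[i], thickness = pos$z[i] - neg$z[best],
      z_start = pos$z[i], z_end = neg$z[best],
      angle_start = pos$angle[i], angle_end = neg$angle[best]))
  }
  unpaired <- rbind(pos[!used_pos, , drop = FALSE],
                    neg[!used, , drop = FALSE])
  rownames(pairs) <- NULL
  rownames(unpaired) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}
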