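# Independent brute-force oracles used by the unit tests.

# Exhaustive alternation oracle for local-extremum detection: instead of a
# single-pass state machine, repeatedly scan all prefixes of the remaining
# sequence. Looking for a maximum, the committed extremum is the earliest
# highest value of the shortest prefix that is followed by a drop >= delta;
# then the roles swap. O(n^2), shares no code with peakdet().
peakdet_oracle <- function(values, delta) {
  n <- length(values)
  max_idx <- integer(0); min_idx <- integer(0)
  start <- 1L
  mode <- "max"
  while (start <= n) {
    seg <- values[start:n]
    ext <- if (mode == "max") cummax(seg) else cummin(seg)
    trigger <- if (mode == "max") which(seg < ext - delta) else
      which(seg > ext + delta)
    if (length(trigger) == 0) break
    j <- trigger[1]
    pos <- if (mode == "max") which(seg[1:j] == ext[j])[1] else
      which(seg[1:j] == ext[j])[1]
    if (mode == "max") {
      max_idx <- c(max_idx, start + pos - 1L)
      mode <- "min"
    } else {
      min_idx <- c(min_idx, start + pos - 1L)
      mode <- "max"
    }
    start <- start + j - 1L
  }
  list(max_idx = max_idx, min_idx = min_idx)
}

# Brute-force transitive merge oracle: single-linkage groups at the given
# distance threshold, keeping the smallest-angle member of each group.
merge_oracle <- function(detections, threshold) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  d <- as.matrix(dist(cbind(detections$force, detections$z)))
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        if (any(d[groups[[a]], groups[[b]], drop = FALSE] < threshold)) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  keep <- sort(vapply(groups, function(g) {
    g[order(detections$angle[g], detections$sample_index[g])][1]
  }, integer(1)))
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive 2-partition k-means cost oracle: evaluates the within-cluster
# sum of squares of every 2-partition and returns the best labelling.
best_two_partition <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- NULL; best_cost <- Inf
  for (code in 1:(2^(n - 1) - 1)) {   # fix point 1 in group 0 (symmetry)
    lab <- c(0L, as.integer(intToBits(code))[1:(n - 1)])
    if (all(lab == 0L)) next
    cost <- 0
    for (g in 0:1) {
      xs <- x[lab == g, , drop = FALSE]
      cost <- cost + sum(scale(xs, scale = FALSE)^2)
    }
    if (cost < best_cost) { best_cost <- cost; best <- lab }
  }
  best
}
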