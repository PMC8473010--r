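#' Local-extremum detection (Billauer peakdet)
#'
#' Scans a sequence once, left to right, and reports alternating local
#' maxima and minima: a candidate maximum is committed as soon as the
#' sequence falls `delta` below it, after which the scan looks for a
#' minimum, committed when the sequence rises `delta` above it, and so on.
#' Every committed maximum therefore exceeds its neighbouring committed
#' minima by at least `delta`, which makes the detector robust to
#' fluctuations smaller than `delta`.
#'
#' @param values Numeric sequence (all finite).
#' @param delta Positive prominence threshold, in the units of `values`.
#' @return A list with data frames `maxima` and `minima`, each with columns
#'   `index` (1-based position) and `value`.
#' @examples
#' peakdet(c(0, 1, 0), delta = 0.5)$maxima
#' @export
peakdet <- function(values, delta) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("empty sequence", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("non-finite value at position ", which(!is.finite(values))[1],
         call. = FALSE)
  }
  if (!is.finite(delta) || delta <= 0) {
    stop("delta must be a positive number", call. = FALSE)
  }
  max_idx <- integer(0); max_val <- numeric(0)
  min_idx <- integer(0); min_val <- numeric(0)
  mx <- -Inf; mn <- Inf
  mxpos <- NA_integer_; mnpos <- NA_integer_
  lookformax <- TRUE
  for (i in seq_along(values)) {
    this <- values[i]
    if (this > mx) { mx <- this; mxpos <- i }
    if (this < mn) { mn <- this; mnpos <- i }
    if (lookformax) {
      if (this < mx - delta) {
        max_idx <- c(max_idx, mxpos); max_val <- c(max_val, mx)
        mn <- this; mnpos <- i
        lookformax <- FALSE
      }
    } else {
      if (this > mn + delta) {
        min_idx <- c(min_idx, mnpos); min_val <- c(min_val, mn)
        mx <- this; mxpos <- i
        lookformax <- TRUE
      }
    }
  }
  list(maxima = data.frame(index = max_idx, value = max_val),
       minima = data.frame(index = min_idx, value = min_val))
}
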