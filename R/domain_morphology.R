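#' AFM height image
#'
#' @param heights Numeric matrix of heights (nm), all finite.
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @param mask Optional logical matrix marking liquid-ordered pixels.
#' @return An object of class `height_image`.
#' @export
height_image <- function(heights, pixel_size, mask = NULL) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) {
    stop("height image contains non-finite values", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(heights)))
  }
  structure(list(heights = heights, pixel_size = pixel_size, mask = mask),
            class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat("<height_image> ", nrow(x$heights), "x", ncol(x$heights),
      " px at ", x$pixel_size, " um/px, heights [",
      format(min(x$heights), digits = 4), ", ",
      format(max(x$heights), digits = 4), "] nm\n", sep = "")
  invisible(x)
}

#' Read a height image from a TIFF file or numeric text matrix
#'
#' @param path Path to a `.tif`/`.tiff` file (read with the tiff package)
#'   or a whitespace-separated numeric matrix text file.
#' @param pixel_size Pixel edge in micrometres per pixel.
#' @return A [height_image()].
#' @export
read_height_image <- function(path, pixel_size) {
  ext <- tolower(tools::file_ext(path))
  heights <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is needed to read TIFF images", call. = FALSE)
    }
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  dimnames(heights) <- NULL
  height_image(heights, pixel_size)
}

#' Otsu threshold of an image histogram
#'
#' Picks the threshold maximizing between-class variance of the two-level
#' split of the intensity histogram.
#'
#' @param x Numeric matrix or vector.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[levels]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, levels)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  breaks[which.max(sigma_b) + 1L]
}

#' Label connected components (8-connectivity)
#'
#' @param mask Logical matrix.
#' @return Integer matrix: background 0, components 1..K (K as attribute
#'   `n`).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {  # propagate the minimum label across 8-neighbourhoods
    prev <- lab
    for (o in offs) {
      nb <- shift(lab, o[1], o[2])
      upd <- mask & nb > 0L & (nb < lab)
      lab[upd] <- nb[upd]
    }
    if (identical(prev, lab)) break
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  attr(lab, "n") <- length(ids)
  lab
}

#' Segment phase domains in a height image
#'
#' Thresholds the image (Otsu by default), labels connected components
#' with 8-connectivity, and drops components smaller than `min_area`
#' pixels. In AFM height images the liquid-ordered phase is the brighter
#' (taller) one; dye-exclusion images have the opposite polarity.
#'
#' @param image A [height_image()] or a numeric matrix.
#' @param threshold `"otsu"` (default) or a numeric threshold on the
#'   height/intensity scale.
#' @param min_area Minimum component size in pixels (default 4).
#' @param polarity `"bright"` (domains above threshold, default) or
#'   `"dark"`.
#' @return Integer label matrix as in [label_components()].
#' @export
segment_domains <- function(image, threshold = "otsu", min_area = 4,
                            polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  h <- if (inherits(image, "height_image")) image$heights else as.matrix(image)
  stopifnot(min_area >= 0)
  if (min(h) == max(h)) {
    out <- matrix(0L, nrow(h), ncol(h))
    attr(out, "n") <- 0L
    return(out)
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(h) else threshold
  mask <- if (polarity == "bright") h > thr else h < thr
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], keep)
  attr(lab, "n") <- length(keep)
  lab
}

# Crofton perimeter from intercept counts in 4 directions (0, 45, 90,
# 135 degrees). Exact in expectation for isotropic boundaries; a raw
# boundary-pixel count would systematically overestimate the perimeter
# and deflate circularity.
.crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  crossings <- function(a, b) sum(abs(a - b))
  c0 <- crossings(m[, -1], m[, -nc])              # horizontal scan lines
  c90 <- crossings(m[-1, ], m[-nr, ])             # vertical scan lines
  c45 <- crossings(m[-1, -1], m[-nr, -nc])        # diagonal
  c135 <- crossings(m[-1, -nc], m[-nr, -1])       # anti-diagonal
  (pi / 8) * (c0 + c90 + (c45 + c135) / sqrt(2))
}

#' Circularity of a shape
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, `pi/4` for a
#' square, smaller for irregular shapes.
#'
#' @param area Shape area.
#' @param perimeter Shape perimeter (same length unit).
#' @param clip Clip the result to at most 1 (default `TRUE`); raw values
#'   slightly above 1 can occur on rasterized shapes.
#' @return Circularity value(s); attribute `clipped` marks entries whose
#'   raw value exceeded 1.
#' @export
circularity <- function(area, perimeter, clip = TRUE) {
  raw <- 4 * pi * area / perimeter^2
  if (!clip) return(raw)
  out <- pmin(raw, 1)
  attr(out, "clipped") <- raw > 1
  out
}

#' Measure per-domain morphometrics
#'
#' One record per labelled domain: area (pixel count times pixel area),
#' Crofton-estimated perimeter, circularity and centroid. This is the
#' particle-analysis step applied to segmented phase domains.
#'
#' @param labels Integer label matrix from [segment_domains()].
#' @param pixel_size Pixel edge in micrometres per pixel (default 1:
#'   pixel units).
#' @return A data frame of class `domain_table` with columns `label`,
#'   `area`, `perimeter`, `circularity`, `circularity_clipped`,
#'   `centroid_row`, `centroid_col`.
#' @export
measure_domains <- function(labels, pixel_size = 1) {
  n <- attr(labels, "n") %||% max(0L, max(labels))
  out <- data.frame(label = integer(0), area = numeric(0),
                    perimeter = numeric(0), circularity = numeric(0),
                    circularity_clipped = logical(0),
                    centroid_row = numeric(0), centroid_col = numeric(0))
  for (k in seq_len(n)) {
    mk <- labels == k
    area <- sum(mk) * pixel_size^2
    per <- .crofton_perimeter(mk) * pixel_size
    circ <- circularity(area, per)
    ij <- which(mk, arr.ind = TRUE)
    out <- rbind(out, data.frame(
      label = k, area = area, perimeter = per,
      circularity = as.numeric(circ),
      circularity_clipped = attr(circ, "clipped"),
      centroid_row = mean(ij[, 1]), centroid_col = mean(ij[, 2])))
  }
  class(out) <- c("domain_table", class(out))
  out
}

#' Height mismatch between Lo and Ld phases
#'
#' Mean height of the liquid-ordered pixels minus mean height of the
#' liquid-disordered pixels. When the Lo mask splits into two or more
#' domains, the SD of the per-domain mismatches is reported as well.
#'
#' @param image A [height_image()].
#' @param mask Logical matrix (`TRUE` = Lo); defaults to the image's own
#'   mask.
#' @return A list with `mismatch` (nm), `sd` (nm across domains, `NA`
#'   with fewer than 2 domains) and `n_domains`.
#' @export
height_mismatch <- function(image, mask = NULL) {
  stopifnot(inherits(image, "height_image"))
  mask <- mask %||% image$mask
  if (is.null(mask)) stop("no phase mask available", call. = FALSE)
  stopifnot(is.logical(mask), all(dim(mask) == dim(image$heights)))
  if (!any(mask) || all(mask)) {
    stop("mask must contain both phases", call. = FALSE)
  }
  ld_mean <- mean(image$heights[!mask])
  lab <- label_components(mask)
  n_dom <- attr(lab, "n")
  per_dom <- vapply(seq_len(n_dom), function(k) {
    mean(image$heights[lab == k]) - ld_mean
  }, numeric(1))
  list(mismatch = mean(image$heights[mask]) - ld_mean,
       sd = if (n_dom >= 2) stats::sd(per_dom) else NA_real_,
       n_domains = n_dom)
}

#' Percent change in domain shape metrics between two conditions
#'
#' @param table_before,table_after [measure_domains()] tables (non-empty).
#' @return A named numeric vector: percent change of the mean `area`,
#'   `perimeter` and `circularity` (`100 * (after - before) / before`).
#' @export
shape_change_summary <- function(table_before, table_after) {
  if (nrow(table_before) == 0 || nrow(table_after) == 0) {
    stop("both domain tables must be non-empty", call. = FALSE)
  }
  vapply(c("area", "perimeter", "circularity"), function(m) {
    b <- mean(table_before[[m]])
    if (b == 0) stop("zero baseline mean for ", m, call. = FALSE)
    100 * (mean(table_after[[m]]) - b) / b
  }, numeric(1))
}

#' Normalized histogram of a shape metric for comparative plots
#'
#' @param values Numeric vector (e.g. per-domain circularities).
#' @param breaks Passed to [graphics::hist()].
#' @return A `hist` object whose `density`-like `counts` sum to 1.
#' @export
normalized_histogram <- function(values, breaks = "Sturges") {
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  h$counts <- h$counts / sum(h$counts)
  h
}
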