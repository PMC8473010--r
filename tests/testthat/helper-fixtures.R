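# Small fixtures built in code.

write_curve_text <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("curve", tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}

# Piecewise-linear approach curve through the given (z, F) anchor points,
# sampled densely. Anchors ordered by decreasing z.
anchored_curve <- function(anchors, dz = 0.1) {
  z <- seq(max(anchors$z), min(anchors$z), by = -dz)
  f <- stats::approx(rev(anchors$z), rev(anchors$force), xout = z)$y
  force_curve(z, f)
}
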