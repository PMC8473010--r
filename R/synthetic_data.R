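#' Parameters for a simulated breakthrough force curve
#'
#' The simulated approach curve has four regimes along decreasing tip-sample
#' separation z: a zero-force baseline above the contact point; a linear
#' indentation ramp with slope `indentation_stiffness` up to the
#' breakthrough force; a breakthrough discontinuity rendered as a z-jump at
#' constant force spanning exactly `thickness` nanometres (the z-length of
#' the discontinuity is what defines bilayer thickness); and a steep
#' hard-support ramp, clamped at a force setpoint. Gaussian noise of SD
#' `noise_sd` is added to the force channel.
#'
#' Defaults reflect a typical supported-bilayer experiment: a 400 nm piezo
#' range sampled at 0.2 nm, contact around 30 nm, membrane stiffness
#' 0.2 nN/nm, rupture at 2 nN over a 4 nm bilayer. With these defaults the
#' rupture onset and completion fall exactly on sample positions, so a
#' noiseless curve carries its ground truth without quantization error.
#'
#' @param contact_z Tip-membrane contact separation (nm).
#' @param indentation_stiffness Slope of the indentation ramp (nN/nm).
#' @param breakthrough_force Rupture force (nN).
#' @param thickness Bilayer thickness (nm), the z-span of the discontinuity.
#' @param noise_sd Gaussian force noise SD (nN), >= 0.
#' @param n_samples Number of samples over `z_range`.
#' @param z_range Total z travel (nm), default 400.
#' @param support_stiffness Post-rupture ramp slope (nN/nm).
#' @param setpoint Force clamp ending the indentation (nN); default
#'   `breakthrough_force + 3`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `curve_sim_params`.
#' @export
curve_sim_params <- function(contact_z = 30, indentation_stiffness = 0.2,
                             breakthrough_force = 2, thickness = 4,
                             noise_sd = 0.02, n_samples = 2000,
                             z_range = 400, support_stiffness = 5,
                             setpoint = breakthrough_force + 3,
                             seed = NULL) {
  stopifnot(breakthrough_force > 0, thickness > 0, thickness < contact_z,
            noise_sd >= 0, indentation_stiffness > 0, z_range > contact_z,
            n_samples >= 10, support_stiffness > 0,
            setpoint > breakthrough_force)
  z_break <- contact_z - breakthrough_force / indentation_stiffness
  if (z_break - thickness < 0) {
    stop("membrane would extend below the support: reduce breakthrough_force",
         " or thickness, or increase contact_z / indentation_stiffness",
         call. = FALSE)
  }
  structure(list(contact_z = contact_z,
                 indentation_stiffness = indentation_stiffness,
                 breakthrough_force = breakthrough_force,
                 thickness = thickness, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), z_range = z_range,
                 support_stiffness = support_stiffness, setpoint = setpoint,
                 seed = seed),
            class = "curve_sim_params")
}

#' Simulate a breakthrough force curve
#'
#' @param params A [curve_sim_params()].
#' @param grid_index Optional `c(row, col)` to attach to the curve.
#' @return A list with `curve` (a [force_curve()] in approach order,
#'   z decreasing) and `truth` (list: `force`, `thickness`, `z_break`,
#'   `z_end`, `contact_z`).
#' @examples
#' sim <- simulate_force_curve(curve_sim_params(noise_sd = 0, seed = 1))
#' analyse_curve(sim$curve)
#' @export
simulate_force_curve <- function(params = curve_sim_params(),
                                 grid_index = NULL) {
  stopifnot(inherits(params, "curve_sim_params"))
  p <- params
  dz <- p$z_range / p$n_samples
  z <- seq(p$z_range, by = -dz, length.out = p$n_samples)
  z_break <- p$contact_z - p$breakthrough_force / p$indentation_stiffness
  z_end <- z_break - p$thickness
  f <- numeric(p$n_samples)
  ramp <- z <= p$contact_z & z > z_break
  f[ramp] <- p$indentation_stiffness * (p$contact_z - z[ramp])
  plateau <- z <= z_break & z >= z_end
  f[plateau] <- p$breakthrough_force
  support <- z < z_end
  f[support] <- p$breakthrough_force +
    p$support_stiffness * (z_end - z[support])
  f <- pmin(f, p$setpoint)
  if (p$noise_sd > 0) {
    if (!is.null(p$seed)) set.seed(p$seed)
    f <- f + stats::rnorm(p$n_samples, sd = p$noise_sd)
  }
  list(curve = force_curve(z, f, grid_index = grid_index,
                           segment = "approach", source_id = "simulated"),
       truth = list(force = p$breakthrough_force, thickness = p$thickness,
                    z_break = z_break, z_end = z_end,
                    contact_z = p$contact_z))
}

#' Parameters for a simulated two-phase force-map grid
#'
#' Emulates a force-volume acquisition over a phase-separated bilayer:
#' circular liquid-ordered (Lo) domains in a liquid-disordered (Ld)
#' background. A grid cell belongs to Lo when its centre lies inside any
#' disc. Per-cell breakthrough force and thickness are drawn from the
#' phase's normal distribution, and a full force curve is synthesized for
#' each cell.
#'
#' Default phase parameters put the Lo phase at higher breakthrough force
#' (6 vs 3 nN) and slightly larger thickness (3.0 vs 2.2 nm), a sub-nm
#' height mismatch typical of SM/Chol domains in a DOPC background.
#'
#' @param n_rows,n_cols Grid dimensions (default 16 x 16).
#' @param physical_size Field size in micrometres (default 5).
#' @param discs Data frame with columns `cx`, `cy`, `r` (um), or `NULL` to
#'   place a single centred disc with area fraction `lo_fraction`.
#' @param lo_fraction Target Lo area fraction used when `discs` is `NULL`
#'   (default 0.25).
#' @param lo_force,ld_force `c(mean, sd)` of breakthrough force per phase
#'   (nN).
#' @param lo_thickness,ld_thickness `c(mean, sd)` of thickness per phase
#'   (nm).
#' @param noise_sd Per-curve force noise SD (nN).
#' @param n_samples Samples per curve (default 2000; 0.2 nm spacing).
#' @param seed Integer master seed (per-cell seeds are derived from it).
#' @return A list of class `map_sim_params`.
#' @export
map_sim_params <- function(n_rows = 16, n_cols = 16, physical_size = 5,
                           discs = NULL, lo_fraction = 0.25,
                           lo_force = c(6, 0.3), ld_force = c(3, 0.3),
                           lo_thickness = c(3, 0.2),
                           ld_thickness = c(2.2, 0.2),
                           noise_sd = 0.02, n_samples = 2000, seed = 1) {
  physical_size <- as.numeric(physical_size)
  if (length(physical_size) == 1L) physical_size <- rep(physical_size, 2L)
  if (is.null(discs)) {
    stopifnot(lo_fraction > 0, lo_fraction < 1)
    r <- sqrt(lo_fraction * physical_size[1] * physical_size[2] / pi)
    discs <- data.frame(cx = physical_size[1] / 2,
                        cy = physical_size[2] / 2, r = r)
  }
  stopifnot(all(c("cx", "cy", "r") %in% names(discs)), all(discs$r > 0),
            all(discs$cx - discs$r >= 0), all(discs$cy - discs$r >= 0),
            all(discs$cx + discs$r <= physical_size[1]),
            all(discs$cy + discs$r <= physical_size[2]),
            all(c(lo_force[2], ld_force[2], lo_thickness[2],
                  ld_thickness[2]) >= 0))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 physical_size = physical_size, discs = discs,
                 lo_force = lo_force, ld_force = ld_force,
                 lo_thickness = lo_thickness, ld_thickness = ld_thickness,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "map_sim_params")
}

#' Simulate a two-phase force-map grid with ground truth
#'
#' @param params A [map_sim_params()].
#' @return A list with `grid` (a [force_grid()]), and `truth`: a list with
#'   `phase` (n_rows x n_cols character matrix, "Lo"/"Ld"), `force` and
#'   `thickness` (matrices of the per-cell drawn values).
#' @export
simulate_force_grid <- function(params = map_sim_params()) {
  stopifnot(inherits(params, "map_sim_params"))
  p <- params
  set.seed(p$seed)
  phase <- matrix("Ld", p$n_rows, p$n_cols)
  force_true <- matrix(NA_real_, p$n_rows, p$n_cols)
  thick_true <- matrix(NA_real_, p$n_rows, p$n_cols)
  curves <- list()
  k <- 0L
  for (r in seq_len(p$n_rows)) {
    for (cc in seq_len(p$n_cols)) {
      cx <- (cc - 0.5) * p$physical_size[1] / p$n_cols
      cy <- (r - 0.5) * p$physical_size[2] / p$n_rows
      in_lo <- any((cx - p$discs$cx)^2 + (cy - p$discs$cy)^2 <=
                     p$discs$r^2)
      phase[r, cc] <- if (in_lo) "Lo" else "Ld"
      fdist <- if (in_lo) p$lo_force else p$ld_force
      tdist <- if (in_lo) p$lo_thickness else p$ld_thickness
      fval <- max(stats::rnorm(1, fdist[1], fdist[2]), 0.6)
      tval <- min(max(stats::rnorm(1, tdist[1], tdist[2]), 1.6), 8.9)
      force_true[r, cc] <- fval
      thick_true[r, cc] <- tval
      cell_seed <- (p$seed * 1009L + (r - 1L) * p$n_cols + cc) %% 2147483647L
      # stiffness scaled with the rupture force so the indentation ramp
      # always spans 10 nm; the stiffer Lo phase also ruptures at higher
      # force, as in real bilayers
      sp <- curve_sim_params(
        breakthrough_force = fval, thickness = tval,
        indentation_stiffness = fval / 10,
        noise_sd = p$noise_sd, n_samples = p$n_samples,
        seed = cell_seed)
      k <- k + 1L
      curves[[k]] <- simulate_force_curve(sp, grid_index = c(r, cc))$curve
    }
  }
  grid <- force_grid(p$n_rows, p$n_cols, p$physical_size, curves = curves)
  list(grid = grid,
       truth = list(phase = phase, force = force_true,
                    thickness = thick_true, discs = p$discs))
}

#' Simulate a two-phase height image with analytic ground truth
#'
#' Builds a height image in which liquid-ordered domains (discs or
#' ellipses) are raised by `step_height` nanometres over a flat background,
#' with optional Gaussian pixel noise. True area, perimeter and circularity
#' come from the continuous shape parameters (ellipse perimeters use the
#' Ramanujan approximation); a pixel belongs to a shape when its centre
#' falls inside.
#'
#' @param shapes Data frame with columns `type` ("disc" or "ellipse"),
#'   `cx`, `cy` (um), `r` (disc radius, um), and for ellipses `a`, `b`
#'   (semi-axes, um) and `theta` (orientation, degrees).
#' @param image_size Image extent in micrometres, scalar or
#'   `c(width, height)`.
#' @param pixel_size Pixel edge in micrometres.
#' @param step_height Lo-over-Ld height step (nm).
#' @param noise_sd Gaussian height noise SD (nm).
#' @param seed Integer seed, or `NULL`.
#' @return A list with `image` (a [height_image()]), `mask` (logical
#'   matrix, `TRUE` = Lo), `true_metrics` (data frame: per-shape `area`,
#'   `perimeter`, `circularity` in continuous um units), and `overlap`
#'   (`TRUE` if any shapes overlapped and were merged in the mask).
#' @export
simulate_domain_image <- function(shapes, image_size = 5, pixel_size = 0.02,
                                  step_height = 1, noise_sd = 0,
                                  seed = NULL) {
  image_size <- as.numeric(image_size)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  stopifnot(pixel_size > 0, noise_sd >= 0, nrow(shapes) >= 1)
  nx <- round(image_size[1] / pixel_size)
  ny <- round(image_size[2] / pixel_size)
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  xs <- matrix(px, ny, nx, byrow = TRUE)
  ys <- matrix(py, ny, nx)
  mask <- matrix(FALSE, ny, nx)
  cover <- matrix(0L, ny, nx)
  metrics <- data.frame(area = numeric(0), perimeter = numeric(0),
                        circularity = numeric(0))
  for (i in seq_len(nrow(shapes))) {
    s <- shapes[i, ]
    if (s$type == "disc") {
      inside <- (xs - s$cx)^2 + (ys - s$cy)^2 <= s$r^2
      area <- pi * s$r^2
      per <- 2 * pi * s$r
    } else if (s$type == "ellipse") {
      th <- s$theta * pi / 180
      xr <- (xs - s$cx) * cos(th) + (ys - s$cy) * sin(th)
      yr <- -(xs - s$cx) * sin(th) + (ys - s$cy) * cos(th)
      inside <- (xr / s$a)^2 + (yr / s$b)^2 <= 1
      area <- pi * s$a * s$b
      per <- pi * (3 * (s$a + s$b) -
                     sqrt((3 * s$a + s$b) * (s$a + 3 * s$b)))
    } else {
      stop("unknown shape type '", s$type, "'", call. = FALSE)
    }
    mask <- mask | inside
    cover <- cover + inside
    metrics <- rbind(metrics, data.frame(
      area = area, perimeter = per,
      circularity = 4 * pi * area / per^2))
  }
  heights <- matrix(0, ny, nx)
  heights[mask] <- step_height
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    heights <- heights + stats::rnorm(length(heights), sd = noise_sd)
  }
  list(image = height_image(heights, pixel_size), mask = mask,
       true_metrics = metrics, overlap = any(cover > 1L))
}
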