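test_that("plain two-column bodies parse into nm/nN curves", {
  p <- write_curve_text(c("# a header", "10 0.0", "0 1.0"))
  fc <- read_force_curve(p)
  expect_s3_class(fc, "force_curve")
  expect_equal(fc$z, c(10, 0))
  expect_equal(fc$force, c(0, 1))
})

test_that("SI-unit exports are auto-converted and conversion is idempotent", {
  p <- write_curve_text(c("1e-8 0", "0 1e-9"))
  fc <- read_force_curve(p)
  expect_equal(fc$z, c(10, 0))
  expect_equal(fc$force, c(0, 1))
  # already-converted values pass through unchanged
  p2 <- write_curve_text(c("10 0", "0 1"))
  fc2 <- read_force_curve(p2)
  expect_equal(fc2$z, fc$z)
  expect_equal(fc2$force, fc$force)
})

test_that("write -> read round-trip preserves values", {
  sim <- simulate_force_curve(curve_sim_params(noise_sd = 0.02, seed = 5))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.txt")
  write_force_curve(sim$curve, path)
  back <- read_force_curve(path)
  expect_equal(length(back$z), length(sim$curve$z))
  expect_equal(back$z, sim$curve$z, tolerance = 1e-9)
  expect_equal(back$force, sim$curve$force, tolerance = 1e-9)
})

test_that("malformed files are rejected with informative errors", {
  expect_error(read_force_curve(write_curve_text("5 1")), "fewer than 2")
  expect_error(read_force_curve(write_curve_text(c("5 a", "1 2"))),
               "malformed")
  p <- write_curve_text(c("5 1", "4 NaN", "3 2"))
  expect_error(read_force_curve(p), "row 2")
})

test_that("the approach block is selected from extend+retract files", {
  # z ramps down then back up; force differs between the two passes
  lines <- c(sprintf("%g %g", 10:1, seq(0, 0.9, by = 0.1)),
             sprintf("%g %g", 1:10, rep(0, 10)))
  fc <- read_force_curve(write_curve_text(lines))
  expect_equal(fc$segment, "approach")
  expect_equal(fc$z, as.numeric(10:1))
  expect_equal(max(fc$force), 0.9)
  rt <- read_force_curve(write_curve_text(lines),
                         dialect = curve_dialect(segment = "retract"))
  expect_equal(rt$segment, "retract")
  expect_true(all(diff(rt$z) >= 0))
})

test_that("grid spacing is field width over column count", {
  expect_equal(grid_spacing(force_grid(16, 16, 5)), 0.3125)
  expect_equal(grid_spacing(force_grid(1, 1, 5)), 5)
  expect_equal(grid_spacing(force_grid(8, 8, 2)), 0.25)
})

test_that("file sets map onto grid cells in acquisition order", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    writeLines(sprintf("%g %g", c(10, 0), c(0, i)),
               file.path(dir, sprintf("c%02d.txt", i)))
  }
  g <- read_force_grid(dir, 2, 2, physical_size = 1)
  expect_false(is.null(grid_cell(g, 1, 1)))
  expect_false(is.null(grid_cell(g, 1, 2)))
  expect_false(is.null(grid_cell(g, 2, 1)))
  expect_null(grid_cell(g, 2, 2))
  expect_equal(grid_cell(g, 1, 2)$force[2], 2)
  # serpentine reverses every second row
  gs <- read_force_grid(dir, 2, 2, physical_size = 1,
                        acquisition_order = "serpentine")
  expect_null(grid_cell(gs, 2, 1))
  expect_equal(grid_cell(gs, 2, 2)$force[2], 3)
})

test_that("empty and oversized file sets are handled", {
  dir <- withr::local_tempdir()
  g <- read_force_grid(dir, 2, 2, physical_size = 1)
  expect_true(all(vapply(g$cells, is.null, logical(1))))
  for (i in 1:5) {
    writeLines(c("1 0", "0 1"), file.path(dir, sprintf("c%d.txt", i)))
  }
  expect_error(read_force_grid(dir, 2, 2, physical_size = 1), "only 4 cells")
})

test_that("a full 256-file export populates a 16x16 grid completely", {
  dir <- withr::local_tempdir()
  for (i in 1:256) {
    writeLines(sprintf("%g %g", c(10, 5, 0), c(0, 0.5, i / 100)),
               file.path(dir, sprintf("curve%03d.txt", i)))
  }
  g <- read_force_grid(dir, 16, 16, physical_size = 5)
  expect_equal(sum(!vapply(g$cells, is.null, logical(1))), 256L)
  expect_equal(grid_spacing(g), 0.3125)
})

test_that("manifest mapping wins over file order and rejects ambiguity", {
  dir <- withr::local_tempdir()
  writeLines(c("10 0", "0 1"), file.path(dir, "a.txt"))
  writeLines(c("10 0", "0 2"), file.path(dir, "b.txt"))
  man <- file.path(dir, "man.csv")
  writeLines(c("filename,row,col", "a.txt,2,2", "b.txt,1,1"), man)
  g <- read_force_grid(dir, 2, 2, physical_size = 1, manifest = man)
  expect_equal(grid_cell(g, 2, 2)$force[2], 1)
  expect_equal(grid_cell(g, 1, 1)$force[2], 2)
  writeLines(c("filename,row,col", "a.txt,1,1", "b.txt,1,1"), man)
  expect_error(read_force_grid(dir, 2, 2, physical_size = 1, manifest = man),
               "ambiguous")
})

test_that("grid write -> read round-trips populated cells", {
  sim <- simulate_force_grid(map_sim_params(n_rows = 3, n_cols = 3,
                                            n_samples = 200, seed = 2))
  dir <- withr::local_tempdir()
  man <- write_force_grid(sim$grid, dir)
  back <- read_force_grid(dir, 3, 3, physical_size = 5, manifest = man)
  fc0 <- grid_cell(sim$grid, 2, 3)
  fc1 <- grid_cell(back, 2, 3)
  expect_equal(fc1$z, fc0$z, tolerance = 1e-9)
  expect_equal(fc1$force, fc0$force, tolerance = 1e-9)
})
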