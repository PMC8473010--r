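raster_disc <- function(r, pad = 14) {
  n <- 2 * r + pad
  c0 <- (n + 1) / 2
  m <- (row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2 <= r^2
  m
}

test_that("circularity follows its closed form and clips at 1", {
  expect_equal(as.numeric(circularity(pi * 2^2, 2 * pi * 2)), 1)
  expect_equal(as.numeric(circularity(3^2, 4 * 3)), pi / 4)
  over <- circularity(100, 30)   # raw 4*pi*100/900 > 1
  expect_equal(as.numeric(over), 1)
  expect_true(attr(over, "clipped"))
})

test_that("a rasterized disc of radius 50 px measures as nearly circular", {
  lab <- label_components(raster_disc(50))
  dt <- measure_domains(lab)
  expect_equal(nrow(dt), 1L)
  expect_lt(abs(dt$area - pi * 50^2) / (pi * 50^2), 0.02)
  expect_gte(dt$circularity, 0.95)
  expect_lte(dt$circularity, 1.0)
})

test_that("connected components use 8-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE      # touch only diagonally
  lab <- label_components(m)
  expect_equal(attr(lab, "n"), 1L)
  m[4, 4] <- TRUE
  expect_equal(attr(label_components(m), "n"), 2L)
})

test_that("segmentation counts discs and honours min_area", {
  img <- simulate_domain_image(
    data.frame(type = "disc", cx = c(1.5, 3.5), cy = c(1.5, 3.5),
               r = c(1, 0.7)),
    image_size = 5, pixel_size = 0.05, step_height = 1, noise_sd = 0)
  lab <- segment_domains(img$image)
  expect_equal(attr(lab, "n"), 2L)
  # a disc below min_area disappears
  tiny <- matrix(0, 20, 20)
  tiny[10, 10] <- 1
  expect_equal(attr(segment_domains(tiny, min_area = 4), "n"), 0L)
  # constant image: no domains, no error
  expect_equal(attr(segment_domains(matrix(1, 10, 10)), "n"), 0L)
})

test_that("otsu thresholding matches the EBImage reference segmentation", {
  set.seed(14)
  x <- matrix(c(rnorm(500, 0.3, 0.05), rnorm(500, 0.7, 0.05)), 40, 25)
  x <- pmin(pmax(x, 0), 1)
  ours <- x > otsu_threshold(x)
  ref <- x > EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  expect_gte(mean(ours == ref), 0.995)
})

test_that("noisy height images segment close to the true domain masks", {
  img <- simulate_domain_image(
    data.frame(type = "disc", cx = c(1.3, 3.6), cy = c(1.4, 3.4),
               r = c(0.9, 0.6)),
    image_size = 5, pixel_size = 0.025, step_height = 1, noise_sd = 0.1,
    seed = 5)
  lab <- segment_domains(img$image, min_area = 10)
  expect_equal(attr(lab, "n"), 2L)
  truth <- label_components(img$mask)
  for (k in 1:2) {
    mk <- lab == k
    ov <- vapply(1:2, function(j) sum(mk & truth == j), numeric(1))
    j <- which.max(ov)
    jac <- sum(mk & truth == j) / sum(mk | truth == j)
    expect_gte(jac, 0.9)
  }
})

test_that("height mismatch reads step heights and flat images", {
  step <- matrix(rep(c(0, 1), each = 50), 10, 10)
  img <- height_image(step, pixel_size = 0.1)
  hm <- height_mismatch(img, step > 0.5)
  expect_equal(hm$mismatch, 1.0)
  flat <- height_image(matrix(2, 10, 10), pixel_size = 0.1)
  expect_equal(height_mismatch(flat, step > 0.5)$mismatch, 0)
  expect_error(height_mismatch(img, matrix(TRUE, 10, 10)), "both phases")
})

test_that("a 1 nm step is recovered within 0.02 nm under noise", {
  set.seed(31)
  n <- 100                         # 1e4 px per phase
  h <- rbind(matrix(rnorm(n * n, 0, 0.3), n, n),
             matrix(rnorm(n * n, 1, 0.3), n, n))
  img <- height_image(h, pixel_size = 0.05)
  mask <- rbind(matrix(FALSE, n, n), matrix(TRUE, n, n))
  expect_lt(abs(height_mismatch(img, mask)$mismatch - 1.0), 0.02)
})

test_that("shape changes are reported as percent of the baseline mean", {
  before <- measure_domains(label_components(raster_disc(40)))
  expect_equal(unname(shape_change_summary(before, before)),
               c(0, 0, 0))
  halved <- before
  halved$area <- halved$area / 2
  expect_equal(unname(shape_change_summary(before, halved)["area"]), -50)
  # shrinking domains to 36% of their area (radius x 0.6)
  after <- measure_domains(label_components(raster_disc(24)))
  ch <- shape_change_summary(before, after)
  expect_lt(abs(ch["area"] - (-64)), 2)
  expect_lt(abs(ch["perimeter"] - (-40)), 2)
  expect_error(shape_change_summary(before, before[0, ]), "non-empty")
})

test_that("circularity is stable across resolution and falls with aspect", {
  c1 <- measure_domains(label_components(raster_disc(30)))$circularity
  c2 <- measure_domains(label_components(raster_disc(60)))$circularity
  expect_lt(abs(c1 - c2), 0.05)
  # ellipses of fixed area, growing aspect ratio
  circs <- vapply(c(1, 1.5, 2.5, 4), function(aspect) {
    a <- 1 * sqrt(aspect); b <- 1 / sqrt(aspect)
    img <- simulate_domain_image(
      data.frame(type = "ellipse", cx = 3, cy = 3, r = NA,
                 a = a, b = b, theta = 20),
      image_size = 6, pixel_size = 0.02, step_height = 1, noise_sd = 0)
    measure_domains(segment_domains(img$image))$circularity
  }, numeric(1))
  expect_true(all(diff(circs) < 0))
})

test_that("normalized histograms sum to one", {
  set.seed(9)
  h <- normalized_histogram(runif(500))
  expect_equal(sum(h$counts), 1)
})

test_that("height images round-trip through text matrices", {
  set.seed(2)
  h <- matrix(rnorm(100), 10, 10)
  path <- file.path(withr::local_tempdir(), "img.txt")
  write.table(h, path, row.names = FALSE, col.names = FALSE)
  img <- read_height_image(path, pixel_size = 0.1)
  expect_equal(img$heights, h, tolerance = 1e-6)
})
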