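test_that("rotation follows the stated matrix and composes additively", {
  expect_equal(rotate_curve(matrix(c(1, 0), 1), 90), matrix(c(0, 1), 1),
               tolerance = 1e-12)
  m <- matrix(rnorm(20), ncol = 2)
  expect_equal(rotate_curve(m, 0), m)
  expect_equal(rotate_curve(rotate_curve(m, 4.5), 13.5), rotate_curve(m, 18),
               tolerance = 1e-12)
})

test_that("a straight line yields no kinks at any angle", {
  fc <- force_curve(z = seq(100, 0, by = -0.5),
                    force = 0.02 * seq(100, 0, by = -0.5) + 1)
  for (phi in c(0, 4.5, 9, 13.5, 18)) {
    cfg <- detection_config(angles = unique(c(0, phi)))
    expect_equal(nrow(detect_kinks(fc, cfg, sign = 1)), 0L)
    expect_equal(nrow(detect_kinks(fc, cfg, sign = -1)), 0L)
  }
})

test_that("a sharp force drop is already detected at zero rotation", {
  # rise to 2 nN, abrupt 1 nN drop, then rise again: a true local maximum
  fc <- anchored_curve(data.frame(z = c(30, 20, 19.9, 10),
                                  force = c(0, 2, 1, 3)))
  det <- detect_kinks(fc, detection_config(), sign = 1, merge = FALSE)
  at_peak <- det[abs(det$z - 20) < 0.3, ]
  expect_gte(nrow(at_peak), 1L)
  expect_true(0 %in% at_peak$angle)
})

test_that("a shoulder kink invisible at 0 degrees appears at a nonzero angle", {
  # slope drops from 0.3 to 0.05 nN/nm at z = 20: monotone force, no local
  # maximum in the unrotated curve
  fc <- anchored_curve(data.frame(z = c(50, 30, 20, 10),
                                  force = c(0, 0, 3, 3.5)))
  cfg0 <- detection_config(angles = 0)
  expect_equal(nrow(detect_kinks(fc, cfg0, sign = 1)), 0L)
  det <- detect_kinks(fc, detection_config(), sign = 1)
  hit <- det[abs(det$z - 20) < 0.5, ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$angle, 0)

  # cross-check by hand: rotate the curve manually at the reported angle
  # and confirm the detector sees a local maximum at the same sample
  a <- hit$angle * pi / 180
  t_adv <- max(fc$z) - fc$z
  v <- cos(a) * fc$force - sin(a) * t_adv
  manual <- peakdet(v, 0.1)$maxima$index
  expect_true(hit$sample_index %in% manual)
})

test_that("multi-angle detection is a superset of zero-angle detection", {
  sim <- simulate_force_curve(curve_sim_params(noise_sd = 0.02, seed = 3))
  d0 <- detect_kinks(sim$curve, detection_config(angles = 0), sign = 1,
                     merge = FALSE)
  dall <- detect_kinks(sim$curve, detection_config(), sign = 1,
                       merge = FALSE)
  expect_true(all(d0$sample_index %in% dall$sample_index))
})

test_that("redundant detections merge onto the smallest angle", {
  det <- data.frame(force = c(2.0, 2.05), z = c(20, 20.3),
                    angle = c(9, 4.5), curvature_sign = 1,
                    sample_index = c(100L, 99L))
  m <- merge_redundant(det, merge_threshold = 2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$angle, 4.5)
  # distant detections are untouched
  det2 <- data.frame(force = c(2, 5), z = c(20, 10), angle = c(4.5, 9),
                     curvature_sign = 1, sample_index = c(100L, 150L))
  expect_equal(nrow(merge_redundant(det2, merge_threshold = 2)), 2L)
})

test_that("chained merges match the brute-force transitive oracle", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    det <- data.frame(force = cumsum(runif(n, 0, 1.5)),
                      z = cumsum(runif(n, 0, 1.5)),
                      angle = sample(c(0, 4.5, 9, 13.5, 18), n,
                                     replace = TRUE),
                      curvature_sign = 1,
                      sample_index = seq_len(n) * 10L)
    got <- merge_redundant(det, merge_threshold = 1.5)
    want <- merge_oracle(det, threshold = 1.5)
    expect_equal(sort(got$sample_index), sort(want$sample_index))
    # idempotent
    again <- merge_redundant(got, merge_threshold = 1.5)
    expect_equal(got, again)
    # order-independent
    perm <- det[sample(n), ]
    got2 <- merge_redundant(perm, merge_threshold = 1.5)
    expect_equal(sort(got2$sample_index), sort(got$sample_index))
  }
})

test_that("opposite-curvature kinks pair along the approach direction", {
  pos <- data.frame(force = 2, z = 5, angle = 4.5, curvature_sign = 1,
                    sample_index = 10L)
  neg <- data.frame(force = 2, z = 2.5, angle = 4.5, curvature_sign = -1,
                    sample_index = 20L)
  res <- pair_opposite_kinks(pos, neg)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$thickness, 2.5)
  expect_equal(res$pairs$force, 2)
  # a positive kink with no subsequent negative stays unpaired
  res2 <- pair_opposite_kinks(pos, neg[0, ])
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(nrow(res2$unpaired), 1L)
  # empty input, empty output
  res3 <- pair_opposite_kinks(pos[0, ], neg[0, ])
  expect_equal(nrow(res3$pairs), 0L)
})

test_that("thickness is recovered from noisy synthetic curves", {
  errs <- vapply(1:20, function(s) {
    sim <- simulate_force_curve(curve_sim_params(thickness = 4,
                                                 noise_sd = 0.02, seed = s))
    pos <- detect_kinks(sim$curve, sign = 1)
    neg <- detect_kinks(sim$curve, sign = -1)
    pr <- extract_events(pair_opposite_kinks(pos, neg)$pairs)
    pr <- pr[pr$rank == "primary", ]
    if (nrow(pr) == 1) pr$thickness - 4 else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(errs, na.rm = TRUE)), 0.3)
})

test_that("detection is unchanged by SI-unit loading", {
  sim <- simulate_force_curve(curve_sim_params(noise_sd = 0.02, seed = 9))
  dir <- withr::local_tempdir()
  p_nm <- file.path(dir, "nm.txt")
  p_si <- file.path(dir, "si.txt")
  writeLines(sprintf("%.12g %.12g", sim$curve$z, sim$curve$force), p_nm)
  writeLines(sprintf("%.12g %.12g", sim$curve$z * 1e-9,
                     sim$curve$force * 1e-9), p_si)
  d1 <- detect_kinks(read_force_curve(p_nm), sign = 1)
  d2 <- detect_kinks(read_force_curve(p_si), sign = 1)
  expect_equal(d1$sample_index, d2$sample_index)
  expect_equal(d1$force, d2$force, tolerance = 1e-6)
})

test_that("curves too short for detection return an empty set", {
  fc <- force_curve(z = c(2, 1), force = c(0, 1))
  expect_equal(nrow(detect_kinks(fc)), 0L)
})
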