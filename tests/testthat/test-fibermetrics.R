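test_that("directional variance matches closed forms of the dispersion functional", {
  # identical orientations: lambda1 = 1 -> V = 0
  d <- c(8, 8, 8)
  o <- make_orient(array(1, d), array(0, d), array(0, d))
  v <- directional_variance(o, 20)
  expect_equal(range(v$values), c(0, 0))
  # two equal orthogonal populations: eigenvalues (1/2, 1/2, 0) -> V = 0.5
  ux <- array(rep(c(1, 0), length.out = prod(d)), d)
  uy <- array(rep(c(0, 1), length.out = prod(d)), d)
  o2 <- make_orient(ux, uy, array(0, d))
  v2 <- directional_variance(o2, 50)   # window spans the volume
  expect_lt(max(abs(v2$values - 0.5)), 1e-9)
  # whole-volume window on a parallel field is exactly 0 (invariant)
  expect_equal(max(directional_variance(o, 1e3)$values), 0)
})

test_that("variance on isotropic axes approaches the Monte-Carlo oracle value", {
  # the dispersion of n = 10^4 isotropic axes computed by direct
  # eigen-decomposition sits near 0.91 (the sqrt amplifies the O(n^-1/2)
  # eigenvalue fluctuation); the windowed metric must land in the same band
  d <- c(22, 22, 22)
  u <- sample_axial_directions(prod(d), "isotropic", seed = 8)
  o <- make_orient(array(u[, 1], d), array(u[, 2], d), array(u[, 3], d))
  v <- directional_variance(o, 1e3)
  expect_gt(median(v$values), 0.87)
  expect_lt(median(v$values), 0.94)
})

test_that("windows with too few voxels are undefined", {
  d <- c(9, 9, 9)
  valid <- array(FALSE, d)
  valid[5, 5, 5] <- TRUE; valid[1, 1, 1] <- TRUE
  o <- make_orient(array(1, d), array(0, d), array(0, d), valid = valid)
  v <- directional_variance(o, 2)
  expect_true(all(is.na(v$values)))    # < 3 on-mask voxels per window
})

test_that("waviness is 0 for straight fibers and increases with crimp", {
  d <- c(10, 10, 10)
  o <- make_orient(array(1, d), array(0, d), array(0, d))
  w <- waviness(o, 6)
  expect_equal(range(w$values), c(0, 0))
  # too-short trace -> undefined
  w2 <- waviness(o, 0.8, step = 0.5)
  expect_true(all(is.na(w2$values)))
  # rasterized sinusoids: median on-fiber W strictly increasing in A/lambda
  p <- default_pitch()
  med <- sapply(c(0, 0.05, 0.1, 0.2), function(r) {
    sp <- make_fiber_spec("sinusoid", anchor = c(0, 10.5, 8.2),
                          axis = c(1, 0, 0), amplitude = r * 12,
                          wavelength = 12, normal = c(0, 0, 1),
                          radius = 1, peak = 200)
    rf <- rasterize_fibers(sp, c(52, 52, 52), p)
    m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
    o <- orientation_field(rf$stack, 2, m)
    w <- waviness(o, 10)
    core <- rf$truth$support & rf$truth$dmin <= 0.5 & is.finite(w$values)
    median(w$values[core])
  })
  expect_lt(med[1], 0.02)
  expect_true(all(diff(med) > 0))
})

test_that("local coverage analytics are exact", {
  # solid block: interior voxel sees a fully covered window
  mask <- array(TRUE, c(15, 15, 15))
  cv <- local_coverage(fiber_mask(mask, pitch = c(1, 1, 1)), 3)
  expect_equal(cv$values[8, 8, 8], 1)
  # isolated voxel, full 5^3 cubic window -> exactly 1/125
  mask2 <- array(FALSE, c(11, 11, 11)); mask2[6, 6, 6] <- TRUE
  cv2 <- local_coverage(fiber_mask(mask2, pitch = c(1, 1, 1)), 2, "cube")
  expect_identical(cv2$values[6, 6, 6], 1 / 125)
  # half-space boundary -> 0.5 within one-voxel discretization
  mask3 <- array(FALSE, c(21, 21, 21)); mask3[, , 1:11] <- TRUE
  cv3 <- local_coverage(fiber_mask(mask3, pitch = c(1, 1, 1)), 4)
  onevox <- 1 / (2 * 4 + 1)
  expect_lt(abs(cv3$values[11, 11, 11] - 0.5), onevox)
  # off-mask voxels are NaN, never 0
  expect_true(all(is.na(cv2$values[!mask2])))
  expect_error(local_coverage(fiber_mask(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("brute-force per-voxel oracles agree with the kernels to 1e-10", {
  rf <- random_fiber_field(10, shape = c(24, 24, 24), seed = 5, radius = 1)
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  o <- orientation_field(rf$stack, 2, m)
  v <- directional_variance(o, 3)$values
  vo <- naive_variance(o, 3)
  expect_identical(is.finite(v), is.finite(vo))
  expect_lt(max(abs(v - vo), na.rm = TRUE), 1e-10)
  cv <- local_coverage(m, 3)$values
  co <- naive_coverage(m$voxels, m$pitch, 3)
  expect_identical(is.finite(cv), is.finite(co))
  expect_lt(max(abs(cv - co), na.rm = TRUE), 1e-10)
  w <- waviness(o, 6)$values
  wo <- naive_waviness(o, 6)
  expect_identical(is.finite(w), is.finite(wo))
  expect_lt(max(abs(w - wo), na.rm = TRUE), 1e-10)
})

test_that("metrics are invariant to global intensity rescaling", {
  rf <- random_fiber_field(8, shape = c(24, 24, 24), seed = 9)
  st2 <- rf$stack; st2$voxels <- st2$voxels * 7.3
  for (st in list(rf$stack)) {
    m1 <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
    m2 <- foreground_mask(st2, "fixed_fraction", 0.1, denoise = FALSE)
    expect_identical(m1$voxels, m2$voxels)
    o1 <- orientation_field(rf$stack, 2, m1)
    o2 <- orientation_field(st2, 2, m2)
    expect_equal(directional_variance(o1, 3)$values,
                 directional_variance(o2, 3)$values, tolerance = 1e-9)
    expect_equal(local_coverage(m1, 3)$values,
                 local_coverage(m2, 3)$values)
    expect_equal(waviness(o1, 6)$values, waviness(o2, 6)$values,
                 tolerance = 1e-9)
  }
})

test_that("metric histograms are normalized probability distributions", {
  vals <- array(NaN, c(10, 10, 4))
  vals[2:9, 2:9, 2] <- 0.4
  h <- metric_histogram(metric_field(vals, "variance"), bins = 50)
  expect_equal(sum(h$probabilities), 1, tolerance = 1e-12)
  expect_equal(h$probabilities[21], 1)   # 0.4 falls in bin [0.40, 0.42)
  expect_equal(h$n_voxels, 64)
  # value exactly 1 lands in the top bin, not out of range
  vals[5, 5, 3] <- 1
  h1 <- metric_histogram(metric_field(vals, "variance"), bins = 50)
  expect_equal(sum(h1$probabilities), 1, tolerance = 1e-12)
  expect_equal(h1$probabilities[50], 1 / 65)
  expect_error(metric_histogram(metric_field(array(NaN, c(2, 2, 2)),
                                             "variance")), "no defined")
})

test_that("merged fields give the count-weighted histogram mixture", {
  set.seed(3)
  a <- array(runif(400), c(20, 20, 1))
  b <- array(runif(100), c(10, 10, 1))
  ha <- metric_histogram(metric_field(a, "coverage"), 20)$probabilities
  hb <- metric_histogram(metric_field(b, "coverage"), 20)$probabilities
  merged <- array(NaN, c(20, 20, 2))
  merged[, , 1] <- a
  merged[1:10, 1:10, 2] <- b
  hm <- metric_histogram(metric_field(merged, "coverage"), 20)$probabilities
  expect_equal(hm, (400 * ha + 100 * hb) / 500, tolerance = 1e-12)
})

test_that("sample summaries honor the chosen statistic", {
  d <- c(6, 6, 2)
  const <- function(x) metric_field(array(x, d), "variance")
  fields <- setNames(lapply(c(.1, .2, .3, .4, .5, .6), const),
                     feature_names())
  for (stat in c("mean", "median")) {
    fv <- summarize_sample(fields, stat, "s1", "normal")
    expect_equal(unname(unlist(fv[feature_names()])),
                 c(.1, .2, .3, .4, .5, .6))
  }
  # mean of an equal {0,1} mixture is 0.5
  half <- array(rep(c(0, 1), length.out = prod(d)), d)
  fields$variance_collagen <- metric_field(half, "variance")
  expect_equal(summarize_sample(fields, "mean")$variance_collagen, 0.5)
  # median resists 5% contamination better than the mean
  base <- array(0.3, c(10, 10, 10))
  contaminated <- base; contaminated[seq_len(50)] <- 1
  fields$variance_collagen <- metric_field(contaminated, "variance")
  m_mean <- summarize_sample(fields, "mean")$variance_collagen
  m_med <- summarize_sample(fields, "median")$variance_collagen
  expect_lt(abs(m_med - 0.3), abs(m_mean - 0.3))
  # fully undefined field errors
  fields$variance_collagen <- metric_field(array(NaN, d), "variance")
  expect_error(summarize_sample(fields), "fully undefined")
})

test_that("crimp hidden along z is seen by 3D but not by 2D analysis", {
  sc <- antiphase_pair_scenario(shape = c(64, 64, 64), n_background = 4, seed = 3)
  cmp <- compare_2d_3d(sc$stack, sc$roi)
  expect_gt(cmp$median_3d["waviness"], 0.15)
  expect_lt(cmp$median_2d["waviness"], 0.05)
  expect_gt(cmp$median_3d["variance"] - cmp$median_2d["variance"], 0.2)
})
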