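test_that("2D weighted vector summation recovers line angles", {
  # line along x (exact)
  img <- matrix(0, 21, 21); img[, 11] <- 100
  o <- orient2d_wvs(img, c(1, 1), 3)
  expect_equal(o$angle[11, 11], 0)
  expect_equal(o$resultant[11, 11], 1)
  # 30-degree line rasterized in physical units with anisotropic pitch
  pitch <- c(0.5, 0.8)
  nx <- 61; ny <- 41
  xs <- (seq_len(nx) - 31) * pitch[1]
  ys <- (seq_len(ny) - 21) * pitch[2]
  dist <- abs(outer(xs, ys, function(x, y) y * cos(pi / 6) - x * sin(pi / 6)))
  img2 <- 100 * exp(-dist^2 / (2 * 0.3^2))
  o2 <- orient2d_wvs(img2, pitch, 3)
  core <- dist < 0.2
  devs <- abs(o2$angle[core] - 30)
  expect_lt(median(pmin(devs, 180 - devs)), 3)
  # uniform image: doubled-angle vectors over the disc cancel
  ou <- orient2d_wvs(matrix(7, 25, 25), c(1, 1), 4)
  expect_lt(max(ou$resultant[5:21, 5:21]), 0.02)
  # empty window
  oz <- orient2d_wvs(matrix(0, 9, 9), c(1, 1), 2)
  expect_true(all(is.na(oz$angle)))
  expect_true(all(oz$resultant == 0))
  expect_error(orient2d_wvs(img, c(1, 1), 1), "2 pixels")
})

test_that("plane angles match analytic projection geometry", {
  rf <- fiber_stack(c(1, 1, 1) / sqrt(3))
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  pa <- plane_angle_fields(rf$stack, 2, m)
  core <- rf$truth$support & rf$truth$dmin <= 0.5
  axdist <- function(a, b) abs((a - b + 90) %% 180 - 90)
  expect_lt(median(axdist(pa$theta[core], 45)), 2.5)
  expect_lt(median(axdist(pa$beta[core], 45)), 2.5)
  # gamma for (1,1,1) is the 135-degree representation of the same line
  # (45 from the -y axis); both give the identical 1/tan^2 in the polar
  # combination
  expect_lt(median(axdist(pa$gamma[core], 135)), 2.5)
})

test_that("degenerate projections are flagged, not invented", {
  # fiber along +x: its yz projection is a point -> gamma has no signal
  rf <- fiber_stack(c(1, 0, 0))
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  pa <- plane_angle_fields(rf$stack, 2, m)
  core <- rf$truth$support & rf$truth$dmin <= 0.5
  axdist <- function(a, b) abs((a - b + 90) %% 180 - 90)
  expect_lt(median(axdist(pa$theta[core], 0)), 0.1)
  expect_lt(median(axdist(pa$beta[core], 0)), 0.1)
  # the degenerate yz projection carries far less resultant signal than
  # the informative planes
  expect_lt(median(pa$conf_gamma[core]), 0.5 * median(pa$conf_theta[core]))
  expect_gt(median(pa$conf_theta[core]), 0.3)
  # fiber along +z: beta and gamma both read 90 degrees
  rfz <- fiber_stack(c(0, 0, 1))
  mz <- foreground_mask(rfz$stack, "fixed_fraction", 0.1, denoise = FALSE)
  paz <- plane_angle_fields(rfz$stack, 2, mz)
  cz <- rfz$truth$support & rfz$truth$dmin <= 0.5
  expect_equal(median(paz$beta[cz]), 90, tolerance = 0.1)
  expect_equal(median(paz$gamma[cz]), 90, tolerance = 0.1)
})

test_that("polar-angle combination follows the squared-cotangent identity", {
  expect_equal(combine_polar(90, 90), 0, tolerance = 1e-9)
  expect_equal(combine_polar(45, 45), 180 / pi * atan(sqrt(2)),
               tolerance = 1e-9)     # 54.7356..., the (1,1,1) direction
  expect_equal(combine_polar(1e-9, 50), 90, tolerance = 1e-6)  # beta -> 0
  # one plane undefined: phi from the defined one alone
  expect_equal(combine_polar(0, NaN, TRUE, FALSE), 90)
  expect_equal(combine_polar(NaN, 90, FALSE, TRUE), 0)
  # both undefined: phi = 90 by contract
  expect_equal(combine_polar(NaN, NaN, FALSE, FALSE), 90)
})

test_that("Eq-consistency: combined polar angle equals acos(|u_z|) to 1e-9", {
  set.seed(2)
  u <- matrix(rnorm(3000), 1000, 3)
  u <- u / sqrt(rowSums(u^2))
  pa <- analytic_plane_angles(u)
  phi <- combine_polar(pa$beta, pa$gamma)
  expect_lt(max(abs(phi - 180 / pi * acos(abs(u[, 3])))), 1e-9)
})

test_that("orientation field recovers straight fibers and is self-consistent", {
  rf <- fiber_stack(c(1, 1, 1) / sqrt(3))
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  o <- orientation_field(rf$stack, 2, m)
  core <- rf$truth$support & rf$truth$dmin <= 0.5 & o$valid
  err <- axial_error_deg(o, rf$truth, core)
  expect_gt(mean(err < 5), 0.8)
  expect_lt(median(err), 3)
  # stored vectors reconstruct exactly from (azimuth, phi)
  az <- o$azimuth[core] * pi / 180; ph <- o$phi[core] * pi / 180
  expect_equal(cbind(sin(ph) * cos(az), sin(ph) * sin(az), cos(ph)),
               cbind(o$ux[core], o$uy[core], o$uz[core]), tolerance = 1e-6)
  # canonical hemisphere and unit length
  expect_true(all(o$uz[core] >= 0))
  expect_equal(o$ux[core]^2 + o$uy[core]^2 + o$uz[core]^2,
               rep(1, sum(core)), tolerance = 1e-9)
  expect_true(all(o$confidence[core] >= 0 & o$confidence[core] <= 1))
  expect_error(orientation_field(rf$stack, 2,
                                 fiber_mask(array(FALSE, dim(rf$stack)))),
               "empty")
})

test_that("axial field is invariant to flipping the stack in z", {
  rf <- fiber_stack(axis_from_angles(60, 40), shape = c(36, 36, 36))
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  o1 <- orientation_field(rf$stack, 2, m)
  fl <- rf$stack; fl$voxels <- fl$voxels[, , dim(fl$voxels)[3]:1]
  mf <- fiber_mask(m$voxels[, , dim(m$voxels)[3]:1], pitch = m$pitch)
  o2 <- orientation_field(fl, 2, mf)
  rev_z <- function(a) a[, , dim(a)[3]:1]
  core <- o1$valid & rev_z(o2$valid)
  # the mirror-blind (theta, phi) representation is identical under the
  # flip; the 3D axes themselves are equivariant (z-component negates)
  expect_equal(rev_z(o2$theta)[core], o1$theta[core], tolerance = 1e-9)
  expect_equal(rev_z(o2$phi)[core], o1$phi[core], tolerance = 1e-9)
  expect_equal(rev_z(o2$confidence)[core], o1$confidence[core],
               tolerance = 1e-9)
  dotm <- abs(o1$ux[core] * rev_z(o2$ux)[core] +
                o1$uy[core] * rev_z(o2$uy)[core] -
                o1$uz[core] * rev_z(o2$uz)[core])
  expect_gt(mean(dotm > 1 - 1e-6), 0.99)
})

test_that("rotating the stack 90 degrees about z rotates theta by 90", {
  rf <- fiber_stack(axis_from_angles(20, 70), shape = c(36, 36, 36))
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  o1 <- orientation_field(rf$stack, 2, m)
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  unrot <- function(a) rot(rot(rot(a)))
  st2 <- intensity_stack(rot(rf$stack$voxels), rf$stack$pitch)
  o2 <- orientation_field(st2, 2, fiber_mask(rot(m$voxels), pitch = m$pitch))
  core1 <- o1$valid & unrot(o2$valid) == TRUE
  th1 <- o1$theta[core1]
  th2 <- unrot(o2$theta)[core1]
  d <- abs((th2 - th1 - 90 + 90) %% 180 - 90)
  expect_lt(median(d), 1e-6)
  ph_d <- abs(unrot(o2$phi)[core1] - o1$phi[core1])
  expect_lt(median(ph_d), 1e-6)
})

test_that("orientation fields serialize to float TIFF and back", {
  rf <- fiber_stack(c(0, 1, 1) / sqrt(2), shape = c(24, 24, 24))
  m <- foreground_mask(rf$stack, "fixed_fraction", 0.1, denoise = FALSE)
  o <- orientation_field(rf$stack, 2, m)
  f <- withr::local_tempfile(fileext = ".tif")
  write_orientation_field(o, f)
  o2 <- read_orientation_field(f)
  expect_equal(o2$valid, o$valid)
  expect_equal(o2$theta[o$valid], o$theta[o$valid], tolerance = 1e-5)
  expect_equal(o2$phi[o$valid], o$phi[o$valid], tolerance = 1e-5)
  expect_equal(o2$confidence[o$valid], o$confidence[o$valid],
               tolerance = 1e-5)
})
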