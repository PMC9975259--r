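#' Specify a synthetic fiber
#'
#' Defines an analytic fiber centerline
#' `r(t) = anchor + t * axis + A * sin(2*pi*t/lambda + psi) * e_osc`
#' (sinusoid; `A = 0` or `kind = "straight"` gives a straight line; a helix
#' uses both transverse directions), with a Gaussian radial intensity
#' profile of nominal radius `rho`. The oscillation direction `e_osc` is
#' perpendicular to `axis`, derived from the oscillation-plane `normal`.
#'
#' @param kind `"straight"`, `"sinusoid"` or `"helix"`.
#' @param anchor centerline anchor point in micrometres.
#' @param axis propagation direction (normalized internally).
#' @param amplitude crimp amplitude A in micrometres (`>= 0`).
#' @param wavelength crimp wavelength in micrometres (`> 0`).
#' @param phase crimp phase psi in radians.
#' @param normal oscillation-plane normal (unit vector, non-parallel to
#'   `axis`); defaults to the coordinate axis least aligned with `axis`.
#' @param radius fiber radius rho in micrometres (`> 0`).
#' @param peak peak intensity at the centerline.
#' @return An object of class `fiber_spec`.
#' @export
make_fiber_spec <- function(kind = c("sinusoid", "straight", "helix"),
                            anchor = c(0, 0, 0), axis = c(1, 0, 0),
                            amplitude = 0, wavelength = 10, phase = 0,
                            normal = NULL, radius = 0.5, peak = 255) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  na <- sqrt(sum(axis^2))
  if (na == 0) stopf("axis must be non-zero")
  axis <- axis / na
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (wavelength <= 0) stopf("wavelength must be > 0")
  if (radius <= 0) stopf("radius must be > 0")
  if (is.null(normal)) {
    cand <- diag(3)[, which.min(abs(axis))]
    normal <- cand - sum(cand * axis) * axis
    normal <- normal / sqrt(sum(normal^2))
  } else {
    normal <- as.numeric(normal) / sqrt(sum(as.numeric(normal)^2))
  }
  if (abs(sum(normal * axis)) > 1 - 1e-9)
    stopf("oscillation-plane normal must not be parallel to axis")
  e1 <- cross3(normal, axis)
  e1 <- e1 / sqrt(sum(e1^2))          # in-plane oscillation direction, _|_ axis
  e2 <- cross3(axis, e1)              # second transverse direction (helix)
  structure(list(kind = kind, anchor = as.numeric(anchor), axis = axis,
                 amplitude = amplitude, wavelength = wavelength,
                 phase = phase, normal = normal, e_osc = e1, e2 = e2,
                 radius = radius, peak = peak),
            class = "fiber_spec")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Evaluate a fiber centerline and its analytic tangent
#'
#' @param spec a [make_fiber_spec()] object.
#' @param t arc parameter values (micrometres along the propagation axis).
#' @return List with `points` (n x 3, um) and `tangents` (n x 3 unit vectors).
#' @export
fiber_centerline <- function(spec, t) {
  n <- length(t)
  ph <- 2 * pi * t / spec$wavelength + spec$phase
  base <- outer(t, spec$axis)
  base <- sweep(base, 2, spec$anchor, "+")
  A <- if (spec$kind == "straight") 0 else spec$amplitude
  if (spec$kind == "helix" && A > 0) {
    pts <- base + A * cos(ph) %o% spec$e_osc + A * sin(ph) %o% spec$e2
    dd <- 2 * pi / spec$wavelength
    tan_raw <- outer(rep(1, n), spec$axis) +
      (-A * dd * sin(ph)) %o% spec$e_osc + (A * dd * cos(ph)) %o% spec$e2
  } else {
    pts <- base + (A * sin(ph)) %o% spec$e_osc
    tan_raw <- outer(rep(1, n), spec$axis) +
      (A * 2 * pi / spec$wavelength * cos(ph)) %o% spec$e_osc
  }
  nrm <- sqrt(rowSums(tan_raw^2))
  list(points = pts, tangents = tan_raw / nrm)
}

#' Map axial vectors onto the canonical hemisphere
#'
#' Axial (undirected) orientations are represented with the convention
#' z-component `>= 0`, ties broken by `y >= 0`, then `x >= 0`.
#'
#' @param v numeric 3-vector or n x 3 matrix of (unit) vectors.
#' @return Same shape, flipped where needed.
#' @export
canonical_axis <- function(v) {
  m <- if (is.matrix(v)) v else matrix(v, ncol = 3)
  flip <- m[, 3] < 0 |
    (m[, 3] == 0 & (m[, 2] < 0 | (m[, 2] == 0 & m[, 1] < 0)))
  m[flip, ] <- -m[flip, , drop = FALSE]
  if (is.matrix(v)) m else drop(m)
}

#' Rasterize fibers into an intensity stack with analytic ground truth
#'
#' Each fiber contributes `peak * exp(-d^2 / (2 * (rho/2)^2))` where `d` is
#' the distance to its centerline; overlapping fibers combine by maximum.
#' Optional additive Gaussian noise is clipped at zero. The ground truth
#' records, for every voxel within `rho` of a centerline, the canonical
#' axial tangent of the nearest centerline point, the fiber id, and each
#' fiber's arc-length / chord-length waviness proxy.
#'
#' @param specs list of [make_fiber_spec()] objects.
#' @param shape voxel grid dimensions `(nx, ny, nz)`.
#' @param pitch voxel pitch (um per axis).
#' @param noise_sd additive Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed for the noise (deterministic output per seed).
#' @param channel,sample_id stack metadata.
#' @return List with `stack` ([intensity_stack()]) and `truth` (class
#'   `fiber_truth`: arrays `ux, uy, uz`, `fiber_id`, logical `support`,
#'   `dmin`, data frame `fibers` with the arc/chord proxy).
#' @export
rasterize_fibers <- function(specs, shape = c(64, 64, 64),
                             pitch = default_pitch(), noise_sd = 0,
                             seed = NULL, channel = "other",
                             sample_id = "synthetic") {
  if (inherits(specs, "fiber_spec")) specs <- list(specs)
  shape <- as.integer(shape)
  stopifnot(all(shape >= 1), all(pitch > 0))
  extent <- (shape - 1L) * pitch
  dt <- min(pitch) / 2
  pts <- tans <- NULL
  fid <- integer(0); peak <- rho <- numeric(0)
  arc <- chord <- rep(NA_real_, length(specs))
  for (f in seq_along(specs)) {
    sp <- specs[[f]]
    corners <- as.matrix(expand.grid(c(0, extent[1]), c(0, extent[2]),
                                     c(0, extent[3])))
    tproj <- (corners - matrix(sp$anchor, 8, 3, byrow = TRUE)) %*% sp$axis
    margin <- sp$amplitude + 3 * sp$radius
    tt <- seq(min(tproj) - margin, max(tproj) + margin, by = dt)
    cl <- fiber_centerline(sp, tt)
    pad <- 1.5 * sp$radius
    inside <- cl$points[, 1] >= -pad & cl$points[, 1] <= extent[1] + pad &
      cl$points[, 2] >= -pad & cl$points[, 2] <= extent[2] + pad &
      cl$points[, 3] >= -pad & cl$points[, 3] <= extent[3] + pad
    if (!any(inside)) {
      warning(sprintf("fiber %d lies entirely outside the volume; skipped", f))
      next
    }
    p <- cl$points[inside, , drop = FALSE]
    arc[f] <- sum(sqrt(rowSums(diff(p)^2)))
    chord[f] <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    pts <- rbind(pts, p)
    tans <- rbind(tans, canonical_axis(cl$tangents[inside, , drop = FALSE]))
    m <- nrow(p)
    fid <- c(fid, rep.int(f, m))
    peak <- c(peak, rep.int(sp$peak, m))
    rho <- c(rho, rep.int(sp$radius, m))
  }
  if (is.null(pts)) stopf("no fiber intersects the volume")
  sp <- cpp_splat_fibers(shape, pitch, pts, tans, fid, peak, rho)
  vox <- sp$intensity
  if (noise_sd > 0) {
    vox <- with_seed(seed, vox + array(rnorm(prod(shape), 0, noise_sd), shape))
    vox[vox < 0] <- 0
  }
  rho_by_fiber <- vapply(specs, function(s) s$radius, numeric(1))
  support <- is.finite(sp$dmin) & !is.na(sp$fiber_id) &
    sp$dmin <= rho_by_fiber[ifelse(is.na(sp$fiber_id), 1L, sp$fiber_id)]
  ux <- sp$tx; uy <- sp$ty; uz <- sp$tz; id <- sp$fiber_id
  ux[!support] <- NaN; uy[!support] <- NaN; uz[!support] <- NaN
  id[!support] <- NA_integer_
  truth <- structure(
    list(ux = ux, uy = uy, uz = uz, fiber_id = id, support = support,
         dmin = sp$dmin,
         fibers = data.frame(fiber = seq_along(specs), arc = arc,
                             chord = chord,
                             waviness_proxy = arc / chord),
         pitch = pitch, seed = seed),
    class = "fiber_truth")
  list(stack = intensity_stack(vox, pitch, channel, sample_id),
       truth = truth)
}

#' @export
print.fiber_truth <- function(x, ...) {
  cat(sprintf("<fiber_truth> %d fibers, %d support voxels\n",
              nrow(x$fibers), sum(x$support)))
  invisible(x)
}

#' Antiphase sinusoid scenario for the 2D-vs-3D comparison
#'
#' Builds a stack containing, inside a marked region of interest, two
#' sinusoidal fibers that propagate along x and oscillate along z with a
#' phase difference of pi, surrounded by wavy fibers outside the ROI. The
#' crimp of the central pair lives entirely in z, so a maximum-intensity
#' xy projection collapses both fibers onto the same nearly straight line:
#' their alignment and crimp can only be resolved by 3D analysis.
#'
#' @param shape voxel grid dimensions.
#' @param pitch voxel pitch (um).
#' @param amplitude,wavelength crimp of the central pair (um).
#' @param n_background number of surrounding wavy fibers.
#' @param seed RNG seed for the background fiber draw.
#' @return List with `stack`, `truth`, `roi` (index ranges `x`, `y`, `z`)
#'   and `pair_ids` (fiber ids of the antiphase pair).
#' @export
antiphase_pair_scenario <- function(shape = c(128, 128, 128), pitch = default_pitch(),
                          amplitude = 2, wavelength = 8,
                          n_background = 16, seed = 7) {
  extent <- (shape - 1L) * pitch
  cy <- extent[2] / 2; cz <- extent[3] / 2
  pair <- lapply(c(0, pi), function(ps)
    make_fiber_spec("sinusoid", anchor = c(0, cy, cz), axis = c(1, 0, 0),
                    amplitude = amplitude, wavelength = wavelength,
                    phase = ps, normal = c(0, -1, 0),  # oscillation along z
                    radius = 0.5, peak = 200))
  bg <- with_seed(seed, {
    lapply(seq_len(n_background), function(i) {
      repeat {
        ay <- runif(1, 2, extent[2] - 2)
        az <- runif(1, 2, extent[3] - 2)
        if (abs(ay - cy) > 6 || abs(az - cz) > amplitude + 4) break
      }
      th <- runif(1, 0, 2 * pi)
      make_fiber_spec("sinusoid", anchor = c(0, ay, az), axis = c(1, 0, 0),
                      amplitude = runif(1, 1, 2.5),
                      wavelength = runif(1, 8, 16),
                      phase = runif(1, 0, 2 * pi),
                      normal = c(0, -sin(th + pi / 2), cos(th + pi / 2)),
                      radius = 0.5, peak = 180)
    })
  })
  out <- rasterize_fibers(c(pair, bg), shape, pitch, noise_sd = 0,
                          channel = "other", sample_id = "antiphase_pair")
  half_y <- 3; half_z <- amplitude + 1.5
  roi <- list(
    x = c(1L + ceiling(2 / pitch[1]), shape[1] - ceiling(2 / pitch[1])),
    y = c(max(1L, floor((cy - half_y) / pitch[2]) + 1L),
          min(shape[2], ceiling((cy + half_y) / pitch[2]) + 1L)),
    z = c(max(1L, floor((cz - half_z) / pitch[3]) + 1L),
          min(shape[3], ceiling((cz + half_z) / pitch[3]) + 1L)))
  c(out, list(roi = roi, pair_ids = c(1L, 2L)))
}

#' Sample axial directions on the canonical hemisphere
#'
#' `"isotropic"` draws uniformly on the sphere; `"concentrated"` draws from
#' a von Mises-Fisher distribution around `mean_axis` with concentration
#' `kappa`. All draws are mapped to the canonical hemisphere.
#'
#' @param n number of draws.
#' @param law `"isotropic"` or `"concentrated"`.
#' @param mean_axis mean direction for the concentrated law.
#' @param kappa concentration (larger = tighter; `Inf` returns `mean_axis`).
#' @param seed RNG seed.
#' @return n x 3 matrix of unit axial vectors.
#' @export
sample_axial_directions <- function(n, law = c("isotropic", "concentrated"),
                                    mean_axis = c(0, 0, 1), kappa = 50,
                                    seed = NULL) {
  law <- match.arg(law)
  mu <- as.numeric(mean_axis); mu <- mu / sqrt(sum(mu^2))
  with_seed(seed, {
    if (law == "isotropic") {
      z <- runif(n, -1, 1)
      az <- runif(n, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      v <- cbind(r * cos(az), r * sin(az), z)
    } else if (!is.finite(kappa)) {
      v <- matrix(mu, n, 3, byrow = TRUE)
    } else {
      # Wood-style inversion for vMF cos-angle around mu
      u <- runif(n)
      w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
      az <- runif(n, 0, 2 * pi)
      # orthonormal frame around mu
      a <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- cross3(a, mu); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- cross3(mu, e1)
      s <- sqrt(pmax(0, 1 - w^2))
      v <- outer(w, mu) + (s * cos(az)) %o% e1 + (s * sin(az)) %o% e2
    }
    canonical_axis(v)
  })
}

#' Random straight-fiber field
#'
#' Rasterizes `n` straight fibers with axes drawn from the requested axial
#' law and anchors uniform in the volume. Deterministic per seed.
#'
#' @param n number of fibers.
#' @param shape,pitch volume geometry.
#' @param orientation_law `"isotropic"` or `"concentrated"`.
#' @param mean_axis,kappa concentrated-law parameters.
#' @param radius,peak fiber radius (um) and peak intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return As [rasterize_fibers()].
#' @export
random_fiber_field <- function(n, shape = c(64, 64, 64),
                               pitch = default_pitch(),
                               orientation_law = c("isotropic", "concentrated"),
                               mean_axis = c(0, 0, 1), kappa = 50,
                               radius = 0.8, peak = 255, noise_sd = 0,
                               seed = 1) {
  orientation_law <- match.arg(orientation_law)
  stopifnot(n >= 1)
  axes <- sample_axial_directions(n, orientation_law, mean_axis, kappa,
                                  seed = seed)
  extent <- (as.integer(shape) - 1L) * pitch
  anchors <- with_seed(seed + 1L, {
    cbind(runif(n, 0, extent[1]), runif(n, 0, extent[2]),
          runif(n, 0, extent[3]))
  })
  specs <- lapply(seq_len(n), function(i)
    make_fiber_spec("straight", anchor = anchors[i, ], axis = axes[i, ],
                    radius = radius, peak = peak))
  rasterize_fibers(specs, shape, pitch, noise_sd = noise_sd, seed = seed + 2L)
}

#' Simulate a tissue-like fiber stack for one channel
#'
#' Named presets emulating the qualitative organization reported for skin:
#' collagen is dense (many fibers, concentrated orientations), elastin is
#' sparse. The `group` modulates the preset in the directions observed in
#' hypertrophic scar: lower orientation concentration and larger crimp in
#' scar for both channels, reduced collagen density but increased elastin
#' density in scar; the boundary (`adjacent`) group is the most aligned and
#' straight with the sparsest elastin.
#'
#' @param channel `"collagen"` or `"elastin"`.
#' @param group `"normal"`, `"scar"` or `"adjacent"`.
#' @param shape,pitch volume geometry.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed.
#' @param sample_id stack id.
#' @return As [rasterize_fibers()].
#' @export
simulate_tissue_stack <- function(channel = c("collagen", "elastin"),
                                  group = c("normal", "scar", "adjacent"),
                                  shape = c(128, 128, 64),
                                  pitch = default_pitch(), noise_sd = 4,
                                  seed = 1, sample_id = NULL) {
  channel <- match.arg(channel)
  group <- match.arg(group)
  p <- if (channel == "collagen") {
    switch(group,
           normal   = list(n = 55, kappa = 30, amp = c(0.3, 0.8)),
           scar     = list(n = 35, kappa = 3,  amp = c(1.2, 2.5)),
           adjacent = list(n = 45, kappa = 60, amp = c(0.1, 0.4)))
  } else {
    switch(group,
           normal   = list(n = 8,  kappa = 30, amp = c(0.3, 0.8)),
           scar     = list(n = 14, kappa = 3,  amp = c(1.2, 2.5)),
           adjacent = list(n = 5,  kappa = 60, amp = c(0.1, 0.4)))
  }
  extent <- (as.integer(shape) - 1L) * pitch
  specs <- with_seed(seed, {
    th <- runif(1, 0, pi); ph <- runif(1, 0.9, 1.6)
    mean_axis <- canonical_axis(c(sin(ph) * cos(th), sin(ph) * sin(th),
                                  cos(ph)))
    axes <- sample_axial_directions(p$n, "concentrated", mean_axis, p$kappa,
                                    seed = NULL)
    lapply(seq_len(p$n), function(i) {
      make_fiber_spec("sinusoid",
                      anchor = c(runif(1, 0, extent[1]),
                                 runif(1, 0, extent[2]),
                                 runif(1, 0, extent[3])),
                      axis = axes[i, ],
                      amplitude = runif(1, p$amp[1], p$amp[2]),
                      wavelength = runif(1, 8, 16),
                      phase = runif(1, 0, 2 * pi),
                      radius = if (channel == "collagen") 0.6 else 0.8,
                      peak = 230)
    })
  })
  rasterize_fibers(specs, shape, pitch, noise_sd = noise_sd, seed = seed + 1L,
                   channel = channel,
                   sample_id = sample_id %||% sprintf("%s_%s", group, channel))
}

#' Project a stack along one axis
#'
#' @param stack an [intensity_stack()] or 3D array.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param mode `"max"` (maximum-intensity projection, the standard display
#'   convention for sparse fluorescent fibers) or `"sum"`.
#' @return 2D matrix over the remaining two axes (in x, y, z order).
#' @export
project_stack <- function(stack, axis = c("z", "x", "y"),
                          mode = c("max", "sum")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  vox <- if (inherits(stack, "intensity_stack")) stack$voxels else stack
  ax <- match(axis, c("x", "y", "z"))
  keep <- setdiff(1:3, ax)
  f <- if (mode == "max") max else sum
  apply(vox, keep, f)
}

#' Crop a stack (and optionally a truth object) to an ROI
#'
#' @param stack an [intensity_stack()].
#' @param roi list with index ranges `x`, `y`, `z` (each `c(from, to)`).
#' @return Cropped [intensity_stack()].
#' @export
crop_stack <- function(stack, roi) {
  ix <- roi$x[1]:roi$x[2]; iy <- roi$y[1]:roi$y[2]; iz <- roi$z[1]:roi$z[2]
  intensity_stack(stack$voxels[ix, iy, iz, drop = FALSE], stack$pitch,
                  stack$channel, paste0(stack$sample_id, "_roi"))
}
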