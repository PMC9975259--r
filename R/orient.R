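#' 2D axial orientation by weighted vector summation
#'
#' For each pixel `p`, every pixel `q` within physical radius `R`
#' contributes the doubled-angle unit vector of the offset `q - p`
#' (axial data: angles taken mod 180 degrees), weighted by the intensity
#' `I(q)`. The local orientation is half the angle of the resultant vector,
#' and the normalized resultant length in `[0, 1]` serves as a confidence:
#' it vanishes on isotropic neighborhoods and approaches 1 along an ideal
#' straight fiber. Anisotropic pixel pitch is honored by measuring offsets
#' in physical units.
#'
#' @param image 2D non-negative matrix, indexed (x, y).
#' @param pitch2d physical pixel pitch (um) along the two axes.
#' @param window_radius window radius R in micrometres (must span at least
#'   two pixels).
#' @param compute logical matrix of pixels to evaluate (default: all).
#' @return List with `angle` (degrees in `[0, 180)`, NaN where the window
#'   holds no intensity) and `resultant` (in `[0, 1]`).
#' @export
orient2d_wvs <- function(image, pitch2d = c(1, 1), window_radius = 2,
                         compute = NULL) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stopf("image must be non-negative")
  if (window_radius < 2 * min(pitch2d))
    stopf("window_radius must span at least 2 pixels in physical units")
  if (is.null(compute)) compute <- matrix(TRUE, nrow(image), ncol(image))
  res <- cpp_wvs2d(image, pitch2d[1], pitch2d[2], window_radius, compute)
  ang <- rad2deg(res$angle)
  ang[!is.na(ang) & ang >= 180] <- 0
  list(angle = ang, resultant = res$resultant)
}

#' Plane projection angles theta, beta, gamma
#'
#' Runs weighted vector summation on the three orthogonal planes through
#' every masked voxel: theta on the xy slice (angle of the fiber's
#' projection on the xy plane versus the x axis), beta on the zx slice
#' (projection on the zx plane versus the x axis), and gamma on the yz
#' slice (projection on the yz plane versus the -y axis). Each plane keeps
#' its resultant length as a per-plane confidence.
#'
#' With `support = "volume"` (the default) all three plane angles are
#' estimated from one spherical 3D window: every in-window voxel
#' contributes its intensity-weighted doubled-angle vector of the offset
#' projected onto each plane. This pools the full tubular neighborhood of
#' a fiber and stays accurate for obliquely oriented fibers, whose
#' footprint on any single slice is only a weakly elongated blob.
#' `support = "slice"` restricts each plane's window to the single slice
#' through the voxel.
#'
#' @param stack an [intensity_stack()].
#' @param window_radius physical window radius R in micrometres (the same
#'   for all three planes, so support is comparable despite anisotropic
#'   pitch).
#' @param mask a `fiber_mask` restricting where angles are computed.
#' @param support `"volume"` (spherical 3D window) or `"slice"`
#'   (single-slice windows per plane).
#' @return Object of class `plane_angles`: arrays `theta`, `beta`, `gamma`
#'   (degrees) and `conf_theta`, `conf_beta`, `conf_gamma`.
#' @export
plane_angle_fields <- function(stack, window_radius = 2, mask,
                               support = c("volume", "slice")) {
  support <- match.arg(support)
  vox <- stack$voxels
  p <- stack$pitch
  d <- dim(vox)
  mvox <- mask$voxels
  if (!any(mvox)) stopf("mask is empty")
  if (support == "volume") {
    r <- cpp_wvs3d_planes(vox, mvox, d, p, window_radius)
    idx <- which(mvox)  # all angle math on mask voxels only
    cv <- function(a, f) { a[idx] <- f(a[idx]); a }
    return(structure(
      list(theta = cv(r$theta, function(x) rad2deg(x) %% 180),
           beta = cv(r$beta, function(x) rad2deg(x) %% 180),
           gamma = cv(r$alpha_yz, function(x) rad2deg((pi - x) %% pi) %% 180),
           conf_theta = r$conf_theta, conf_beta = r$conf_beta,
           conf_gamma = r$conf_gamma, mask = mask, pitch = p,
           params = list(window_radius = window_radius, support = support)),
      class = "plane_angles"))
  }
  theta <- beta <- gamma <- ct <- cb <- cg <- array(NaN, d)
  for (k in seq_len(d[3])) {        # xy slices -> theta
    cm <- mvox[, , k]
    if (!any(cm)) next
    r <- cpp_wvs2d(vox[, , k], p[1], p[2], window_radius, cm)
    theta[, , k] <- r$angle
    ct[, , k] <- r$resultant
  }
  for (j in seq_len(d[2])) {        # zx slices -> beta (x toward z)
    cm <- mvox[, j, ]
    if (!any(cm)) next
    r <- cpp_wvs2d(vox[, j, ], p[1], p[3], window_radius, cm)
    beta[, j, ] <- r$angle
    cb[, j, ] <- r$resultant
  }
  for (i in seq_len(d[1])) {        # yz slices -> gamma (from -y axis)
    cm <- mvox[i, , ]
    if (!any(cm)) next
    r <- cpp_wvs2d(vox[i, , ], p[2], p[3], window_radius, cm)
    gamma[i, , ] <- (pi - r$angle) %% pi
    cg[i, , ] <- r$resultant
  }
  structure(list(theta = rad2deg(theta) %% 180, beta = rad2deg(beta) %% 180,
                 gamma = rad2deg(gamma) %% 180,
                 conf_theta = ct, conf_beta = cb, conf_gamma = cg,
                 mask = mask, pitch = p,
                 params = list(window_radius = window_radius,
                               support = support)),
            class = "plane_angles")
}

#' Resolve the polar angle from the two auxiliary plane angles
#'
#' Combines the zx-plane angle beta and the yz-plane angle gamma into the
#' polar angle phi through `tan^2(phi) = 1/tan^2(gamma) + 1/tan^2(beta)`.
#' Squared tangents discard sign, so phi is reported in `[0, 90]` degrees,
#' consistent with the axial (hemisphere) representation. Degenerate
#' planes (a fiber whose projection collapses to a point) are excluded: if
#' exactly one of beta, gamma is undefined, phi comes from the defined one
#' alone via `tan^2(phi) = 1/tan^2(defined)`; if both are undefined phi is
#' 90 degrees with zero confidence.
#'
#' @param beta,gamma plane angles in degrees (scalars or arrays).
#' @param beta_defined,gamma_defined logical, same shape; defaults to
#'   finiteness of the angles.
#' @return Polar angle phi in degrees, `[0, 90]`, same shape as the input.
#' @export
combine_polar <- function(beta, gamma, beta_defined = NULL,
                          gamma_defined = NULL) {
  bd <- beta_defined %||% is.finite(beta)
  gd <- gamma_defined %||% is.finite(gamma)
  cot2 <- function(a_deg) {
    a <- deg2rad(a_deg)
    s <- sin(a)
    out <- (cos(a) / s)^2
    out[s == 0] <- Inf
    out
  }
  c2b <- cot2(beta); c2g <- cot2(gamma)
  tan2phi <- ifelse(bd & gd, c2b + c2g,
                    ifelse(bd, c2b, ifelse(gd, c2g, Inf)))
  phi <- rad2deg(atan(sqrt(tan2phi)))
  phi[is.infinite(tan2phi)] <- 90
  if (is.array(beta)) dim(phi) <- dim(beta)
  phi
}

#' Voxel-wise 3D axial orientation field
#'
#' Assembles the azimuth theta (xy plane) and the polar angle phi (from
#' beta and gamma via [combine_polar()]) into canonical axial unit vectors
#' `(sin(phi)cos(theta), sin(phi)sin(theta), cos(phi))` per masked voxel.
#' The combined confidence is the geometric mean of the three plane
#' resultants. A plane whose resultant falls below `conf_threshold` is
#' treated as degenerate and excluded from the polar-angle combination.
#'
#' @param stack an [intensity_stack()].
#' @param window_radius physical window radius R in micrometres.
#' @param mask a `fiber_mask` (defaults to [foreground_mask()] of the stack).
#' @param conf_threshold plane resultant below which a plane is degenerate.
#' @param support plane-angle window support, see [plane_angle_fields()].
#' @return Object of class `orientation_field`: `theta` (deg, `[0,180)`),
#'   `phi` (deg, `[0,90]`), unit-vector arrays `ux, uy, uz`, `confidence`,
#'   logical `valid`, plus the underlying `plane_angles`.
#' @export
orientation_field <- function(stack, window_radius = 2, mask = NULL,
                              conf_threshold = 0.05,
                              support = c("volume", "slice")) {
  support <- match.arg(support)
  mask <- mask %||% foreground_mask(stack)
  pa <- plane_angle_fields(stack, window_radius, mask, support)
  d <- dim(pa$theta)
  idx <- which(mask$voxels)  # per-voxel math on mask voxels only
  tb <- pa$theta[idx]; bb <- pa$beta[idx]; gb <- pa$gamma[idx]
  cb <- pa$conf_beta[idx]; cg <- pa$conf_gamma[idx]
  ct <- pa$conf_theta[idx]
  bdv <- is.finite(bb) & cb >= conf_threshold
  gdv <- is.finite(gb) & cg >= conf_threshold
  phv <- combine_polar(bb, gb, bdv, gdv)
  # The three plane angles over-determine the axis (z/x = tan beta and
  # z/y is fixed by gamma), so for a fiber running closer to z than to
  # the xy plane - whose xy projection is a nearly isotropic blob - the
  # azimuth is better reconstructed from the two well-conditioned planes:
  # (x, y) proportional to (cot beta, -cot gamma).
  alt <- bdv & gdv & phv < 45 & ct < pmin(cb, cg)
  alt[!is.finite(alt)] <- FALSE
  if (any(alt)) {
    cotb <- cos(deg2rad(bb[alt])) / sin(deg2rad(bb[alt]))
    cotg <- cos(deg2rad(gb[alt])) / sin(deg2rad(gb[alt]))
    tb[alt] <- rad2deg(atan2(-cotg, cotb)) %% 180
  }
  # a fiber near the z axis has an isotropic xy footprint: theta is then
  # irrelevant for the vector (sin(phi) ~ 0) but must be finite
  tb[!is.finite(tb) & is.finite(phv)] <- 0
  ok <- is.finite(tb) & is.finite(phv)
  cfv <- (pmax(ct, 0) * pmax(cb, 0) * pmax(cg, 0))^(1 / 3)
  cfv[ok & !bdv & !gdv] <- 0
  th <- deg2rad(tb); ph <- deg2rad(phv)
  vx <- sin(ph) * cos(th); vy <- sin(ph) * sin(th); vz <- cos(ph)
  # (theta in [0,180), phi in [0,90]) parameterizes only a quarter-sphere:
  # the same xy-plane line angle theta is shared by the axis and its
  # xy-mirror. beta and gamma carry the missing sign (beta < 90 iff z and
  # x agree in sign), so pick the mirror candidate most consistent with
  # the measured beta/gamma, weighted by their plane confidences.
  axd <- function(a, b) abs((a - b + 90) %% 180 - 90)
  wb <- ifelse(bdv, cb, 0); wg <- ifelse(gdv, cg, 0)
  s1 <- wb * axd(rad2deg(atan2(vz, vx)) %% 180, bb) +
    wg * axd((180 - rad2deg(atan2(vz, vy))) %% 180, gb)
  s2 <- wb * axd(rad2deg(atan2(vz, -vx)) %% 180, bb) +
    wg * axd((180 - rad2deg(atan2(vz, -vy))) %% 180, gb)
  flip <- ok & is.finite(s1) & is.finite(s2) & (s2 < s1)
  vx[flip] <- -vx[flip]; vy[flip] <- -vy[flip]
  az <- rad2deg(atan2(vy, vx)) %% 360
  drop_in <- function(vals) {
    a <- array(NaN, d); a[idx[ok]] <- vals[ok]; a
  }
  theta <- drop_in(tb); azimuth <- drop_in(az); phi <- drop_in(phv)
  ux <- drop_in(vx); uy <- drop_in(vy); uz <- drop_in(vz)
  conf <- drop_in(cfv)
  valid <- array(FALSE, d); valid[idx[ok]] <- TRUE
  structure(list(theta = theta, azimuth = azimuth, phi = phi,
                 ux = ux, uy = uy, uz = uz,
                 confidence = conf, valid = valid, mask = mask,
                 pitch = stack$pitch, plane_angles = pa,
                 params = list(window_radius = window_radius,
                               conf_threshold = conf_threshold,
                               support = support)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf("<orientation_field> %d x %d x %d, %d valid voxels\n",
              d[1], d[2], d[3], sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  median confidence %.3f\n",
                median(x$confidence[x$valid])))
  invisible(x)
}

#' In-plane orientation field for a 2D image
#'
#' Runs weighted vector summation on a single image and wraps the result
#' as a one-slice orientation field with all vectors in the xy plane
#' (phi = 90 degrees). This is the 2D analysis mode used to contrast
#' projection-based analysis with truly 3D analysis.
#'
#' @param image 2D non-negative matrix (x, y).
#' @param pitch2d pixel pitch (um).
#' @param window_radius window radius R (um).
#' @param mask logical matrix (default: thresholded at 10% of max).
#' @return An `orientation_field` with one z-slice and `uz = 0`.
#' @export
orientation_field_2d <- function(image, pitch2d = default_pitch()[1:2],
                                 window_radius = 2, mask = NULL) {
  if (is.null(mask)) mask <- image >= 0.1 * max(image) & image > 0
  o <- orient2d_wvs(image, pitch2d, window_radius, compute = mask)
  d3 <- c(dim(image), 1L)
  theta <- array(o$angle, d3)
  conf <- array(o$resultant, d3)
  valid <- array(mask, d3) & is.finite(theta)
  theta[!valid] <- NaN; conf[!valid] <- NaN
  th <- deg2rad(theta)
  ux <- cos(th); uy <- sin(th); uz <- array(0, d3)
  uz[!valid] <- NaN
  phi <- array(90, d3); phi[!valid] <- NaN
  fm <- fiber_mask(valid, pitch = c(pitch2d, 1),
                   threshold_rule = list(method = "2d"))
  structure(list(theta = theta, azimuth = theta, phi = phi,
                 ux = ux, uy = uy, uz = uz,
                 confidence = conf, valid = valid, mask = fm,
                 pitch = c(pitch2d, 1), plane_angles = NULL,
                 params = list(window_radius = window_radius, mode = "2d")),
            class = "orientation_field")
}

#' Serialize an orientation field as a float TIFF plus JSON metadata
#'
#' Five float pages per z-slice (theta, phi, confidence, valid mask,
#' azimuth) and a JSON sidecar with pitch, dimensions and parameters. The
#' azimuth page carries the mirror-disambiguated vector azimuth in
#' `[0, 360)`, which the map angle theta alone cannot encode.
#'
#' @param orient an `orientation_field`.
#' @param path output TIFF path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_orientation_field <- function(orient, path) {
  d <- dim(orient$theta)
  pages <- array(NaN, c(d[1], d[2], 5 * d[3]))
  for (k in seq_len(d[3])) {
    pages[, , 5 * k - 4] <- orient$theta[, , k]
    pages[, , 5 * k - 3] <- orient$phi[, , k]
    pages[, , 5 * k - 2] <- orient$confidence[, , k]
    pages[, , 5 * k - 1] <- orient$valid[, , k] + 0
    pages[, , 5 * k] <- orient$azimuth[, , k]
  }
  write_float_tiff(pages, path)
  jsonlite::write_json(list(dim = d, pitch = orient$pitch,
                            pages_per_slice = 5, params = orient$params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an orientation field written by [write_orientation_field()]
#'
#' @param path TIFF path (with `<path>.json` sidecar alongside).
#' @return An `orientation_field` (without plane angles).
#' @export
read_orientation_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  pages <- read_tiff_pages(path)
  theta <- phi <- conf <- azimuth <- array(NaN, d)
  valid <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    theta[, , k] <- t(pages[[5 * k - 4]])
    phi[, , k] <- t(pages[[5 * k - 3]])
    conf[, , k] <- t(pages[[5 * k - 2]])
    valid[, , k] <- t(pages[[5 * k - 1]]) > 0.5
    azimuth[, , k] <- t(pages[[5 * k]])
  }
  valid <- valid & is.finite(azimuth) & is.finite(phi)
  az <- deg2rad(azimuth); ph <- deg2rad(phi)
  ux <- sin(ph) * cos(az); uy <- sin(ph) * sin(az); uz <- cos(ph)
  ux[!valid] <- NaN; uy[!valid] <- NaN; uz[!valid] <- NaN
  fm <- fiber_mask(valid, pitch = meta$pitch,
                   threshold_rule = list(method = "deserialized"))
  structure(list(theta = theta, azimuth = azimuth, phi = phi,
                 ux = ux, uy = uy, uz = uz,
                 confidence = conf, valid = valid, mask = fm,
                 pitch = as.numeric(meta$pitch), plane_angles = NULL,
                 params = as.list(meta$params)),
            class = "orientation_field")
}

#' Analytic plane angles of a 3D direction
#'
#' Closed-form theta, beta, gamma for a given axial direction, matching
#' the conventions of [plane_angle_fields()]. Used to validate the
#' polar-angle combination against `acos(|u_z|)`.
#'
#' @param u unit 3-vector or n x 3 matrix.
#' @return Data frame with `theta`, `beta`, `gamma` in degrees.
#' @export
analytic_plane_angles <- function(u) {
  m <- if (is.matrix(u)) u else matrix(u, ncol = 3)
  ax <- function(y, x) rad2deg(atan2(y, x)) %% 180
  data.frame(theta = ax(m[, 2], m[, 1]),
             beta = ax(m[, 3], m[, 1]),
             gamma = (180 - ax(m[, 3], m[, 2])) %% 180)
}
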