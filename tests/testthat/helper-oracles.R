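# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package kernels: plain R
# loops, stats::eigen, and the same stated contracts.

naive_offsets <- function(pitch, radius, dim = c(Inf, Inf, Inf)) {
  m <- pmin(floor(radius / pitch), dim - 1)
  g <- expand.grid(a = -m[1]:m[1], b = -m[2]:m[2], c = -m[3]:m[3])
  d2 <- (g$a * pitch[1])^2 + (g$b * pitch[2])^2 + (g$c * pitch[3])^2
  g[d2 <= radius^2, ]
}

naive_dispersion <- function(U, w = rep(1, nrow(U))) {
  T <- matrix(0, 3, 3)
  for (r in seq_len(nrow(U))) T <- T + w[r] * tcrossprod(U[r, ])
  T <- T / sum(w)
  l1 <- max(eigen(T, symmetric = TRUE, only.values = TRUE)$values)
  min(max(1 - sqrt(max(0, (3 * l1 - 1) / 2)), 0), 1)
}

naive_variance <- function(o, radius, min_count = 3) {
  d <- dim(o$theta)
  off <- naive_offsets(o$pitch, radius)
  out <- array(NaN, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!o$valid[i, j, k]) next
    qi <- i + off$a; qj <- j + off$b; qk <- k + off$c
    inb <- qi >= 1 & qi <= d[1] & qj >= 1 & qj <= d[2] & qk >= 1 & qk <= d[3]
    q <- cbind(qi, qj, qk)[inb, , drop = FALSE]
    on <- o$valid[q] & o$confidence[q] > 0
    if (sum(on) < min_count) next
    q <- q[on, , drop = FALSE]
    out[i, j, k] <- naive_dispersion(cbind(o$ux[q], o$uy[q], o$uz[q]),
                                     o$confidence[q])
  }
  out
}

naive_coverage <- function(mask, pitch, radius) {
  d <- dim(mask)
  off <- naive_offsets(pitch, radius)
  out <- array(NaN, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!mask[i, j, k]) next
    qi <- i + off$a; qj <- j + off$b; qk <- k + off$c
    inb <- qi >= 1 & qi <= d[1] & qj >= 1 & qj <= d[2] & qk >= 1 & qk <= d[3]
    q <- cbind(qi, qj, qk)[inb, , drop = FALSE]
    out[i, j, k] <- sum(mask[q]) / nrow(q)
  }
  out
}

naive_waviness <- function(o, L, step = 0.5 * min(o$pitch)) {
  d <- dim(o$theta)
  p <- o$pitch
  nstep <- floor((L / 2) / step)
  out <- array(NaN, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (!o$valid[i, j, k]) next
    u0 <- c(o$ux[i, j, k], o$uy[i, j, k], o$uz[i, j, k])
    U <- matrix(u0, 1, 3)
    for (sgn in c(1, -1)) {
      pos <- c(i - 1, j - 1, k - 1) * p
      dir <- sgn * u0
      for (s in seq_len(nstep)) {
        pos <- pos + step * dir
        q <- floor(pos / p + 0.5) + 1
        if (any(q < 1) || any(q > d)) break
        if (!o$valid[q[1], q[2], q[3]]) break
        u <- c(o$ux[q[1], q[2], q[3]], o$uy[q[1], q[2], q[3]],
               o$uz[q[1], q[2], q[3]])
        if (sum(u * dir) < 0) u <- -u
        U <- rbind(U, u)
        dir <- u
      }
    }
    if (nrow(U) >= 3) out[i, j, k] <- naive_dispersion(U)
  }
  out
}

# exhaustive-sweep Otsu oracle: threshold maximizing between-class variance
naive_otsu <- function(values) {
  cand <- sort(unique(values))
  best <- -Inf; thr <- cand[1]
  for (t in cand[-1]) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) / length(values)^2 *
      (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; thr <- t }
  }
  thr
}

# Mann-Whitney concordance (half-tie convention)
naive_concordance <- function(scores, positive) {
  mean(outer(scores[positive], scores[!positive],
             function(a, b) (a > b) + 0.5 * (a == b)))
}

# hand-built orientation field from explicit axial vectors
make_orient <- function(ux, uy, uz, valid = NULL, conf = NULL,
                        pitch = c(1, 1, 1)) {
  d <- dim(ux)
  valid <- valid %||% array(TRUE, d)
  conf <- conf %||% array(1, d)
  ux[!valid] <- NaN; uy[!valid] <- NaN; uz[!valid] <- NaN
  conf[!valid] <- NaN
  phi <- acos(pmin(pmax(abs(uz), 0), 1)) * 180 / pi
  theta <- (atan2(uy, ux) * 180 / pi) %% 180
  structure(list(theta = theta, azimuth = (atan2(uy, ux) * 180 / pi) %% 360,
                 phi = phi,
                 ux = ux, uy = uy, uz = uz, confidence = conf,
                 valid = valid,
                 mask = fiber_mask(valid, pitch = pitch),
                 pitch = pitch, plane_angles = NULL,
                 params = list()),
            class = "orientation_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# straight-fiber stack through the volume centre with ground truth
fiber_stack <- function(axis, shape = c(48, 48, 48),
                        pitch = fiberarch::default_pitch(), rho = 1,
                        peak = 200) {
  sp <- make_fiber_spec("straight", anchor = (shape - 1) * pitch / 2,
                        axis = axis, radius = rho, peak = peak)
  rasterize_fibers(sp, shape, pitch)
}

axis_from_angles <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
}

axial_error_deg <- function(o, truth, core) {
  dotp <- abs(o$ux[core] * truth$ux[core] + o$uy[core] * truth$uy[core] +
                o$uz[core] * truth$uz[core])
  180 / pi * acos(pmin(dotp, 1))
}

deg <- function(x) x * pi / 180

# analytic-tangent oracle for the along-path dispersion of a sinusoid:
# median over start phases of the axial dispersion of exact tangents
# sampled at equal arc-length spacing over a path of length L
analytic_path_dispersion <- function(A, lambda, L, step, n_phase = 41) {
  disp <- sapply(seq(0, lambda, length.out = n_phase), function(t0) {
    tt <- seq(t0 - 2 * lambda, t0 + 2 * lambda, by = 0.01)
    sp <- make_fiber_spec("sinusoid", anchor = c(0, 0, 0),
                          axis = c(1, 0, 0), amplitude = A,
                          wavelength = lambda, normal = c(0, 0, 1))
    cl <- fiber_centerline(sp, tt)
    seg <- sqrt(rowSums(diff(cl$points)^2))
    s <- c(0, cumsum(seg))
    s0 <- s[which.min(abs(tt - t0))]
    want <- seq(s0 - L / 2, s0 + L / 2, by = step)
    want <- want[want >= 0 & want <= max(s)]
    ti <- approx(s, tt, xout = want)$y
    u <- fiber_centerline(sp, ti)$tangents
    naive_dispersion(u)
  })
  median(disp)
}
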