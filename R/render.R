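#' Render color-coded maps of a metric or orientation field
#'
#' Writes per-slice PNG images with hue mapped over `[0, 1]` for metric
#' fields or `[0, 180)` degrees for the azimuth of an orientation field.
#' Off-mask (NaN) voxels are black, and a vertical colorbar is embedded at
#' the right edge of every image. Rendering is a pure output operation: the
#' field is never modified.
#'
#' @param field a [metric_field()] or `orientation_field`.
#' @param colormap a palette name understood by [grDevices::hcl.colors()],
#'   or `"rainbow"` (default for azimuth maps, which are cyclic).
#' @param path output path; for multi-slice fields, `_zNNN` is inserted
#'   before the extension.
#' @param slices z-slice indices to render (default: all).
#' @param what for orientation fields, which component to map
#'   (`"theta"`, `"phi"` or `"confidence"`).
#' @return Character vector of written file paths, invisibly.
#' @export
render_metric_map <- function(field, colormap = NULL, path,
                              slices = NULL,
                              what = c("theta", "phi", "confidence")) {
  if (inherits(field, "orientation_field")) {
    what <- match.arg(what)
    vals <- field[[what]]
    vals[!field$valid] <- NaN
    rng <- switch(what, theta = c(0, 180), phi = c(0, 90),
                  confidence = c(0, 1))
    cyclic <- what == "theta"
  } else if (inherits(field, "metric_field")) {
    vals <- field$values
    rng <- c(0, 1)
    cyclic <- FALSE
  } else stopf("cannot render object of class %s", class(field)[1])
  if (!any(is.finite(vals))) stopf("field has no defined voxels to render")
  cols <- if (identical(colormap, "rainbow") || (is.null(colormap) && cyclic))
    grDevices::rainbow(256, end = 0.85)
  else
    hcl.colors(256, colormap %||% "viridis")
  rgbmat <- col2rgb(cols) / 255
  nz <- dim(vals)[3]
  slices <- slices %||% seq_len(nz)
  ext <- sub("^.*(\\.[A-Za-z]+)$", "\\1", path)
  stem <- sub("\\.[A-Za-z]+$", "", path)
  out <- character(0)
  for (k in slices) {
    sl <- vals[, , k]
    idx <- 1 + floor(255 * pmin(pmax((sl - rng[1]) / diff(rng), 0), 1 - 1e-12))
    nx <- nrow(sl); ny <- ncol(sl)
    img <- array(0, dim = c(ny, nx, 3))  # PNG rows = y
    def <- which(is.finite(idx))
    for (ch in 1:3) {
      plane <- matrix(0, nx, ny)
      plane[def] <- rgbmat[ch, idx[def]]
      img[, , ch] <- t(plane)
    }
    img <- embed_colorbar(img, rgbmat)
    f <- if (length(slices) == 1L) path else sprintf("%s_z%03d%s", stem, k, ext)
    png::writePNG(img, f)
    out <- c(out, f)
  }
  invisible(out)
}

# append a vertical colorbar (low at bottom) on the right, with a 2px gap
embed_colorbar <- function(img, rgbmat, width = 12L) {
  h <- dim(img)[1]
  bar <- array(0, dim = c(h, width + 2L, 3))
  lev <- 1 + floor(255 * (rev(seq_len(h)) - 1) / (h - 1))
  for (ch in 1:3) bar[, 3:(width + 2L), ch] <- rgbmat[ch, lev]
  out <- array(0, dim = c(h, dim(img)[2] + width + 2L, 3))
  out[, seq_len(dim(img)[2]), ] <- img
  out[, dim(img)[2] + seq_len(width + 2L), ] <- bar
  out
}
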