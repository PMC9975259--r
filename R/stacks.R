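#' Intensity stack container
#'
#' A 3D grayscale intensity volume with physical voxel pitch and a channel
#' tag. Voxels are indexed `(x, y, z)`; TIFF pages are z-slices. All
#' intensities must be non-negative and the pitch strictly positive.
#'
#' @param voxels 3D numeric array of non-negative intensities, dims (nx, ny, nz).
#' @param pitch physical voxel size in micrometres per axis, length 3.
#' @param channel one of `"collagen"`, `"elastin"`, `"other"`.
#' @param sample_id sample identifier string.
#' @return An object of class `intensity_stack`.
#' @export
intensity_stack <- function(voxels, pitch = default_pitch(),
                            channel = c("other", "collagen", "elastin"),
                            sample_id = "sample") {
  channel <- match.arg(channel)
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L)
    stopf("voxels must be a 3D array (got %d dims)", length(dim(voxels)))
  if (any(dim(voxels) < 1L)) stopf("all three axes must have length >= 1")
  if (anyNA(voxels) || any(voxels < 0))
    stopf("intensities must be finite and non-negative")
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stopf("pitch must be three positive values (um per voxel)")
  structure(list(voxels = voxels, pitch = pitch, channel = channel,
                 sample_id = sample_id),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<intensity_stack> %s [%s]\n", x$sample_id, x$channel))
  cat(sprintf("  %d x %d x %d voxels  (%.1f x %.1f x %.1f um)\n",
              d[1], d[2], d[3],
              d[1] * x$pitch[1], d[2] * x$pitch[2], d[3] * x$pitch[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
as.array.intensity_stack <- function(x, ...) x$voxels

#' @export
dim.intensity_stack <- function(x) dim(x$voxels)

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an [intensity_stack()].
#' Integer pixel data are preserved bit-exactly; IEEE float pages (including
#' NaN) are read natively. Pages are z-slices; within a page, TIFF rows map
#' to the y axis and columns to the x axis.
#'
#' @param path path to a TIFF file.
#' @param channel channel tag for the stack.
#' @param pitch voxel pitch in micrometres; TIFF files carry no reliable
#'   3D pitch metadata here so this is taken from the caller (or config).
#' @param sample_id sample identifier (defaults to the file name).
#' @return An [intensity_stack()].
#' @export
read_stack <- function(path, channel = c("other", "collagen", "elastin"),
                       pitch = default_pitch(),
                       sample_id = sub("\\.tiff?$", "", basename(path))) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- read_tiff_pages(path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stopf("multi-sample (e.g. RGB) TIFF pages are not supported; supply a grayscale channel")
  if (length(pages) == 1L)
    message("single-page TIFF read as a stack with z-length 1: ", path)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]])
  storage.mode(vox) <- "double"
  if (anyNA(vox)) vox[is.na(vox)] <- NaN  # float metric TIFFs carry NaN
  if (all(is.finite(vox)))
    intensity_stack(vox, pitch, channel, sample_id)
  else
    structure(list(voxels = vox, pitch = as.numeric(pitch), channel = channel,
                   sample_id = sample_id), class = "intensity_stack")
}

#' Write a stack or metric field as a multi-page TIFF
#'
#' Integer-valued intensity stacks in `[0, 65535]` are written as 16-bit
#' pages (bit-exact round trip); anything else, and all metric fields, are
#' written as uncompressed 32-bit IEEE float pages with undefined voxels
#' stored as NaN.
#'
#' @param x an [intensity_stack()] or [metric_field()].
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (!dir.exists(dirname(path))) stopf("no such directory: %s", dirname(path))
  vox <- if (inherits(x, "metric_field")) x$values
         else if (inherits(x, "intensity_stack")) x$voxels
         else if (is.array(x)) x
         else stopf("cannot write object of class %s", class(x)[1])
  ints <- all(is.finite(vox)) && max(vox) <= 65535 &&
    isTRUE(all(vox == round(vox)))
  if (ints) {
    pages <- lapply(seq_len(dim(vox)[3]), function(k) t(vox[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    write_float_tiff(vox, path)
  }
  invisible(path)
}

# integer pages unscaled; float pages (NaN-preserving) in native values
read_tiff_pages <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  pages
}

# Minimal uncompressed multi-page 32-bit float grayscale TIFF writer.
# tiff::writeTIFF has no IEEE-float storage mode, and metric fields need
# NaN-preserving float pages; reading back goes through tiff::readTIFF,
# which handles SampleFormat=3 natively.
write_float_tiff <- function(vox, path) {
  if (is.matrix(vox)) dim(vox) <- c(dim(vox), 1L)
  nx <- dim(vox)[1]; ny <- dim(vox)[2]; nz <- dim(vox)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  page_bytes <- nx * ny * 4
  data_off <- 8 + (seq_len(nz) - 1) * page_bytes
  ifd_base <- 8 + nz * page_bytes
  ifd_size <- 2 + 10 * 12 + 4
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42L)
  w32(ifd_base)  # first IFD follows the pixel data
  for (k in seq_len(nz)) {
    # TIFF rows are y; our pages are [x, y], column-major = row-major rows of y
    writeBin(as.numeric(vox[, , k]), con, size = 4, endian = "little")
  }
  for (k in seq_len(nz)) {
    w16(10L)
    entry(256L, 3L, 1L, nx)          # ImageWidth
    entry(257L, 3L, 1L, ny)          # ImageLength
    entry(258L, 3L, 1L, 32L)         # BitsPerSample
    entry(259L, 3L, 1L, 1L)          # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[k]) # StripOffsets
    entry(277L, 3L, 1L, 1L)          # SamplesPerPixel
    entry(278L, 4L, 1L, ny)          # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)  # StripByteCounts
    entry(339L, 3L, 1L, 3L)          # SampleFormat: IEEE float
    w32(if (k < nz) ifd_base + k * ifd_size else 0L)
  }
  invisible(path)
}

#' Foreground fiber mask
#'
#' Delimits fiber-occupied voxels of an intensity stack, either by Otsu's
#' threshold on the global intensity histogram or by a fixed fraction of the
#' maximum intensity. The default pipeline rule is `fixed_fraction` at 0.1
#' of the maximum after slice-wise median-filter denoising (radius 1); the
#' rule actually applied is recorded in `threshold_rule`.
#'
#' @param stack an [intensity_stack()].
#' @param method `"fixed_fraction"` keeps voxels with (denoised) intensity
#'   `>= param * max`; `"otsu"` maximizes between-class variance.
#' @param param fraction of the maximum intensity for `fixed_fraction`;
#'   ignored for `otsu`.
#' @param denoise apply a slice-wise 3x3 median filter (truncated at
#'   borders) before thresholding.
#' @return An object of class `fiber_mask` with logical `voxels` congruent
#'   with the stack and the recorded `threshold_rule`.
#' @export
foreground_mask <- function(stack, method = c("fixed_fraction", "otsu"),
                            param = 0.1, denoise = TRUE) {
  method <- match.arg(method)
  vox <- stack$voxels
  mx <- max(vox)
  if (method == "otsu" && (mx == min(vox)))
    stopf("otsu thresholding needs a non-constant stack")
  if (method == "fixed_fraction" && (param <= 0 || param >= 1))
    stopf("fixed_fraction param must lie in (0, 1)")
  work <- vox
  if (denoise && mx > 0)
    work <- cpp_median3x3(work, dim(work))  # slice-wise 3x3 median
  thr <- if (method == "fixed_fraction") {
    param * max(work)
  } else {
    m2 <- matrix(work / max(work), nrow = dim(work)[1])
    as.numeric(EBImage::otsu(EBImage::Image(m2), range = c(0, 1),
                             levels = 256L)) * max(work)
  }
  mask <- work >= thr & work > 0
  if (!any(mask)) warning("foreground mask is empty")
  structure(list(voxels = mask,
                 threshold_rule = list(method = method, param = param,
                                       threshold = thr, denoise = denoise),
                 pitch = stack$pitch, sample_id = stack$sample_id,
                 channel = stack$channel),
            class = "fiber_mask")
}

#' Construct a fiber mask from a logical array
#'
#' @param voxels logical 3D array.
#' @param pitch voxel pitch (um).
#' @param threshold_rule record of how the mask was produced.
#' @return A `fiber_mask`.
#' @export
fiber_mask <- function(voxels, pitch = default_pitch(),
                       threshold_rule = list(method = "manual")) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3L)
  structure(list(voxels = voxels, threshold_rule = threshold_rule,
                 pitch = as.numeric(pitch), sample_id = "mask",
                 channel = "other"),
            class = "fiber_mask")
}

#' @export
print.fiber_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<fiber_mask> %d x %d x %d, %d on-mask voxels (%.1f%%), rule: %s\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels), x$threshold_rule$method))
  invisible(x)
}

#' Write a fiber mask as an 8-bit TIFF (0/255)
#'
#' @param mask a `fiber_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  vox <- array(ifelse(mask$voxels, 255, 0), dim = dim(mask$voxels))
  pages <- lapply(seq_len(dim(vox)[3]), function(k) t(vox[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Metric field container
#'
#' A voxel-wise scalar field in `[0, 1]` for one organizational metric
#' (directional variance, waviness or local coverage), defined on a fiber
#' mask. Off-mask / undefined voxels are NaN, never a sentinel inside the
#' metric range.
#'
#' @param values 3D numeric array; on-mask values in `[0, 1]`, NaN elsewhere.
#' @param metric one of `"variance"`, `"waviness"`, `"coverage"`.
#' @param mask the `fiber_mask` the field is defined on (may be `NULL`).
#' @param params computation parameters to record.
#' @return An object of class `metric_field`.
#' @export
metric_field <- function(values, metric = c("variance", "waviness", "coverage"),
                         mask = NULL, params = list()) {
  metric <- match.arg(metric)
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3L)
  fin <- values[is.finite(values)]
  if (length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9))
    stopf("defined %s values must lie in [0, 1]", metric)
  structure(list(values = values, metric = metric, mask = mask,
                 params = params,
                 pitch = if (!is.null(mask)) mask$pitch else default_pitch()),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("<metric_field> %s, %d defined voxels", x$metric, length(fin)))
  if (length(fin))
    cat(sprintf(", median %.3f, range [%.3f, %.3f]",
                median(fin), min(fin), max(fin)))
  cat("\n")
  invisible(x)
}
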