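#' Construct a calibrated z-stack
#'
#' A `zstack` is the imaging substrate of the FI assay: a 3-D array of
#' non-negative voxel intensities `[slice, row, col]` with physical
#' calibration.  Slices are optical sections acquired at a constant axial
#' interval (1.08 um by default, matching the acquisition protocol the
#' package emulates).
#'
#' @param voxels 3-D numeric array `[slice, row, col]`, intensities >= 0
#'   (small negative excursions from synthetic noise are clamped at 0).
#' @param pixel_size_um Lateral pixel size in micrometres (> 0).
#' @param z_interval_um Axial slice spacing in micrometres (> 0).
#' @param bit_depth Nominal camera bit depth (metadata only).
#' @param brain_id,condition Optional sample annotations.
#' @return An object of class `zstack`.
#' @export
zstack <- function(voxels, pixel_size_um, z_interval_um = 1.08,
                   bit_depth = 16L, brain_id = NULL, condition = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3-D array [slice, row, col]")
  }
  assert_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_number(z_interval_um, "z_interval_um", positive = TRUE)
  if (dim(voxels)[1] < 1L) stop("a z-stack needs at least one slice")
  voxels[voxels < 0] <- 0
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_interval_um = z_interval_um, bit_depth = bit_depth,
         brain_id = brain_id, condition = condition),
    class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<zstack> %d slices x %d x %d px | %.3g um/px, dz = %.3g um%s%s\n",
    d[1], d[2], d[3], x$pixel_size_um, x$z_interval_um,
    if (!is.null(x$brain_id)) paste0(" | ", x$brain_id) else "",
    if (!is.null(x$condition)) paste0(" (", x$condition, ")") else ""))
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[1]

#' Read a z-stack from a multi-page TIFF
#'
#' Baseline TIFF carries no reliable physical calibration, so pixel size and
#' z-interval must be supplied; quantification without calibration is
#' rejected.  Multi-channel / RGB files are rejected: the assay images a
#' single fluorophore with a monochrome camera.
#'
#' @param path Multi-page single-channel TIFF.
#' @param pixel_size_um,z_interval_um Physical calibration (required).
#' @inheritParams zstack
#' @return A [zstack].
#' @export
read_zstack <- function(path, pixel_size_um = NULL, z_interval_um = 1.08,
                        brain_id = NULL, condition = NULL) {
  if (is.null(pixel_size_um)) {
    stop("missing calibration: 'pixel_size_um' is required")
  }
  if (is.null(z_interval_um)) {
    stop("missing calibration: 'z_interval_um' is required")
  }
  voxels <- read_tiff_stack(path)
  zstack(voxels, pixel_size_um = pixel_size_um,
         z_interval_um = z_interval_um,
         brain_id = brain_id %||% sub("\\.tiff?$", "", basename(path)),
         condition = condition)
}

#' Write a z-stack to a multi-page 16-bit TIFF
#'
#' @param stack A [zstack].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  write_tiff_stack(stack$voxels, path)
}

#' Maximum intensity projection (presentation only)
#'
#' Collapses a z-stack to a 2-D image taking the per-pixel maximum across
#' slices.  MIPs are used to present merged brain images; all FI
#' quantification in this package consumes the 3-D stack, never the MIP.
#'
#' @param stack A [zstack].
#' @return A numeric matrix `[row, col]`.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  v <- stack$voxels
  out <- v[1, , ]
  nz <- dim(v)[1]
  if (nz > 1) for (z in 2:nz) out <- pmax(out, v[z, , ])
  out
}
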