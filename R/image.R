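#' 3D image block
#'
#' A grayscale 3D intensity grid with an origin offset into its parent
#' volume and a per-axis voxel size. The array is indexed `[x, y, z]`
#' (1-based in R); voxel coordinates used throughout the package are
#' 0-based, so voxel `(i, j, k)` is `data[i + 1, j + 1, k + 1]`.
#'
#' @param data 3D numeric/integer array of non-negative intensities.
#' @param origin numeric(3) voxel offset of this block in the parent volume.
#' @param voxel_size numeric(3) micrometre per voxel.
#' @return object of class `image_block`.
#' @export
image_block <- function(data, origin = c(0, 0, 0), voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3) stop("`data` must be a 3D array")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(list(data = data, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size)),
            class = "image_block")
}

#' @export
print.image_block <- function(x, ...) {
  cat(sprintf("<image_block> %s voxels, origin (%s), range [%g, %g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$origin), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

is_image_block <- function(x) inherits(x, "image_block")

block_dim <- function(block) dim(block$data)

#' Read / write a multi-page TIFF image volume
#'
#' Pages of the TIFF are z-slices; within a page, rows are y and columns are
#' x. `read_image_volume` returns integer intensities on the stored bit
#' scale (0..255 for 8-bit); `write_image_volume` is its inverse.
#'
#' @param path TIFF file path.
#' @param voxel_size numeric(3) micrometre per voxel.
#' @return an [image_block()] with origin (0,0,0).
#' @export
read_image_volume <- function(path, voxel_size = c(1, 1, 1)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) arr[, , z] <- t(pages[[z]])
  if (all(arr == round(arr))) storage.mode(arr) <- "integer"
  image_block(arr, origin = c(0, 0, 0), voxel_size = voxel_size)
}

#' @rdname read_image_volume
#' @param block an [image_block()] to write.
#' @param bits bits per sample (8 or 16).
#' @export
write_image_volume <- function(block, path, bits = 8) {
  if (!is_image_block(block)) stop("`block` must be an image_block")
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16")
  scale <- 2^bits - 1
  if (max(block$data) > scale) stop("intensities exceed the bit depth")
  nz <- dim(block$data)[3]
  pages <- lapply(seq_len(nz), function(z) t(block$data[, , z]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Crop an image block around a segment
#'
#' The crop covers the segment's bounding box dilated by `margin` voxels,
#' clipped to the volume; the block origin records the offset so curves
#' traced in block coordinates map back to global coordinates.
#'
#' @param volume an [image_block()] (typically the full volume).
#' @param positions n x 3 matrix of global voxel coordinates (or a segment
#'   with a `positions` element).
#' @param margin dilation in voxels.
#' @return an [image_block()].
#' @export
crop_block <- function(volume, positions, margin = 16) {
  if (!is_image_block(volume)) stop("`volume` must be an image_block")
  if (is.list(positions) && !is.null(positions$positions))
    positions <- positions$positions
  P <- as_points(positions)
  P <- sweep(P, 2, volume$origin)  # to local coordinates
  dims <- block_dim(volume)
  lo <- floor(apply(P, 2, min)) - margin
  hi <- ceiling(apply(P, 2, max)) + margin
  lo <- pmax(lo, 0)
  hi <- pmin(hi, dims - 1)
  if (any(hi < lo)) stop("coordinate error: segment lies outside the volume")
  data <- volume$data[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1,
                      (lo[3]:hi[3]) + 1, drop = FALSE]
  image_block(data, origin = volume$origin + lo,
              voxel_size = volume$voxel_size)
}

# trilinear interpolation of block intensity at continuous local voxel
# coordinates (rows of P); coordinates are clamped to the grid
interp_intensity <- function(block, P) {
  P <- as_points(P)
  img <- as.double(block$data)
  dims <- as.integer(block_dim(block))
  vapply(seq_len(nrow(P)), function(i) {
    cpp_trilinear(img, dims, P[i, 1], P[i, 2], P[i, 3])
  }, numeric(1))
}

#' Maximum intensity projection
#'
#' @param x an [image_block()] or 3D array.
#' @param axis projection axis, one of "x", "y", "z".
#' @return 2D matrix of per-pixel maxima (for axis "z": `[x, y]`).
#' @export
make_mip <- function(x, axis = "z") {
  data <- if (is_image_block(x)) x$data else x
  if (length(dim(data)) != 3) stop("`x` must be a 3D volume")
  keep <- switch(match.arg(axis, c("x", "y", "z")),
                 x = c(2, 3), y = c(1, 3), z = c(1, 2))
  apply(data, keep, max)
}
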