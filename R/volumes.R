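#' Image volume container
#'
#' A minimal 3D image container: a numeric voxel array with voxel spacing
#' (mm) and a world-space origin. Axis order is (x, y, z), voxel indices are
#' 1-based in R; world coordinate of voxel (i, j, k) is
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @param voxels 3D numeric array.
#' @param spacing positive length-3 numeric, voxel spacing in mm.
#' @param origin length-3 numeric, world coordinates of the first voxel (mm).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite values")
  if (any(!is.finite(voxels)))
    stop("voxel intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask companion to an image volume
#'
#' @param voxels 3D array with values in \{0, 1\}.
#' @inheritParams image_volume
#' @return An \code{image_volume} whose voxels are 0/1, additionally classed
#'   \code{tumor_mask}.
#' @export
tumor_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (!all(voxels %in% c(0, 1)))
    stop("mask voxels must be 0 or 1")
  out <- image_volume(voxels, spacing, origin)
  class(out) <- c("tumor_mask", class(out))
  out
}

same_geometry <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} that carry the voxel spacing through the
#' NIfTI pixdim field.
#'
#' @param vol an \code{image_volume}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{write_nifti} returns \code{path} invisibly;
#'   \code{read_nifti} returns an \code{image_volume}.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}
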