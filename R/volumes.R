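#' Construct a diffusion-weighted volume
#'
#' Wraps a 4D signal array (x, y, z, frame) with its voxel-to-mm affine and
#' voxel dimensions. 3D input is promoted to a single-frame 4D array.
#' Voxel coordinates throughout the package are 0-based with half-open
#' voxels `[i, i+1)` per axis, so voxel centres sit at `i + 0.5`.
#'
#' @param data 3D or 4D numeric array of nonnegative intensities.
#' @param voxel_dims Length-3 positive voxel dimensions in mm.
#' @param affine Optional 4x4 voxel-to-mm transform; defaults to a scaling
#'   affine built from `voxel_dims`.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_dims = c(1.88, 1.88, 3), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4) abort("`data` must be a 3D or 4D array.")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3 || any(voxel_dims <= 0)) {
    abort("`voxel_dims` must be 3 positive numbers (mm).")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  }
  structure(list(data = data, affine = affine, voxel_dims = voxel_dims),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_volume> %d x %d x %d, %d frame(s), voxels %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_dims, 4), collapse = " x ")))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file containing a 3D or 4D image.
#' @return A [dwi_volume()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "cannot read NIfTI file '%s': %s", path, conditionMessage(e))))
  arr <- array(as.numeric(img), dim = dim(img))   # strip image attributes
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  vd <- as.numeric(pd[seq_len(min(3, length(pd)))])
  if (length(vd) < 3) vd <- c(vd, rep(1, 3 - length(vd)))
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  dwi_volume(arr, voxel_dims = abs(vd), affine = aff)
}

#' Write a volume (or bare array) as NIfTI-1
#'
#' @param vol A [dwi_volume()] or a 3D/4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_dims Voxel dimensions, used when `vol` is a bare array.
#' @export
write_volume <- function(vol, path, voxel_dims = c(1.88, 1.88, 3)) {
  if (!inherits(vol, "dwi_volume")) vol <- dwi_volume(vol, voxel_dims)
  d <- vol$data
  if (dim(d)[4] == 1L) dim(d) <- dim(d)[1:3]
  img <- RNifti::asNifti(d, reference = NULL)
  # pixdim must match the image dimensionality (4D frames get unit spacing)
  RNifti::pixdim(img) <- c(vol$voxel_dims,
                           rep(1, length(dim(d)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

n_frames <- function(vol) dim(vol$data)[4]
grid_shape <- function(vol) dim(vol$data)[1:3]
voxel_volume <- function(voxel_dims) prod(voxel_dims)
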