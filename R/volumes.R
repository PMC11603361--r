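#' @useDynLib ntatlas, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median runif rnorm rbinom rlnorm setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- constructors -----------------------------------------------------------

#' 3-D scalar volume with world geometry
#'
#' A `volume3d` couples a 3-D numeric array with a 4x4 voxel-to-world affine
#' (RAS orientation, millimetres). Voxel indices are 0-based and a voxel's
#' world position is its centre, following the NIfTI-1 convention.
#'
#' @param data 3-D numeric array of finite values.
#' @param affine 4x4 voxel-index-to-world-mm matrix; the upper-left 3x3 block
#'   must be invertible.
#' @return An object of class `ntatlas_volume` with elements `data` and
#'   `affine`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), diag(4))
#' grid_of(v)
#' @export
volume3d <- function(data, affine) {
  affine <- check_affine(affine)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("all data dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume values must be finite", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, affine = affine), class = "ntatlas_volume")
}

#' 3-D binary mask with world geometry
#'
#' @param data 3-D array of values in \{0, 1\} (logical arrays are accepted).
#' @inheritParams volume3d
#' @return An object of class `ntatlas_mask` (inherits `ntatlas_volume`).
#' @export
mask3d <- function(data, affine) {
  if (is.logical(data)) {
    d <- array(as.double(data), dim = dim(data))
    data <- d
  }
  if (!all(data %in% c(0, 1)))
    stop("mask values must all be 0 or 1", call. = FALSE)
  v <- volume3d(data, affine)
  class(v) <- c("ntatlas_mask", class(v))
  v
}

is_mask <- function(x) inherits(x, "ntatlas_mask")

#' Sampling grid: shape plus voxel-to-world affine
#'
#' @param shape integer vector of 3 positive dimensions.
#' @param affine 4x4 voxel-to-world matrix (0-based indices, RAS mm).
#' @return A `grid_spec` with `shape`, `affine` and the derived
#'   `voxel_volume_mm3` (absolute determinant of the 3x3 block).
#' @export
grid_spec <- function(shape, affine) {
  affine <- check_affine(affine)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  structure(
    list(shape = shape, affine = affine,
         voxel_volume_mm3 = abs(det(affine[1:3, 1:3]))),
    class = "grid_spec")
}

#' Grid of a volume or mask
#' @param vol a `ntatlas_volume` or `ntatlas_mask`.
#' @return The `grid_spec` the object lives on.
#' @export
grid_of <- function(vol) grid_spec(dim(vol$data), vol$affine)

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be 4x4", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine upper-left 3x3 block is singular", call. = FALSE)
  storage.mode(affine) <- "double"
  affine
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "grid_spec")) a else grid_of(a)
  gb <- if (inherits(b, "grid_spec")) b else grid_of(b)
  all(ga$shape == gb$shape) && max(abs(ga$affine - gb$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share shape and affine", call. = FALSE)
  invisible(TRUE)
}

# ---- voxel/world coordinate plumbing ---------------------------------------

# idx: n x 3 matrix of 0-based voxel indices -> n x 3 world mm
voxel_to_world <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3L)
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(pts, affine) {
  pts <- matrix(pts, ncol = 3L)
  h <- cbind(pts, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

# 0-based index matrix of every voxel in a grid, fastest-varying first axis
all_voxel_indices <- function(shape) {
  as.matrix(expand.grid(i = 0:(shape[1] - 1L),
                        j = 0:(shape[2] - 1L),
                        k = 0:(shape[3] - 1L)))
}

# 0-based indices (n x 3) of nonzero voxels
nonzero_indices <- function(mask) {
  w <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) return(matrix(numeric(0), ncol = 3L))
  w - 1
}

# ---- geometric measurements -------------------------------------------------

#' Mask volume in cubic millimetres
#'
#' Counts nonzero voxels and multiplies by the voxel volume (absolute
#' determinant of the affine's 3x3 block). An empty mask has volume 0.
#'
#' @param mask a `ntatlas_mask`.
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  g <- grid_of(mask)
  sum(mask$data != 0) * g$voxel_volume_mm3
}

#' World-space centre of mass of a mask
#'
#' Mean of the world coordinates of the centres of all nonzero voxels.
#'
#' @param mask a nonempty `ntatlas_mask`.
#' @return Length-3 world point (mm).
#' @export
center_of_mass_mm <- function(mask) {
  idx <- nonzero_indices(mask)
  if (nrow(idx) == 0L)
    stop("center of mass of an empty mask is undefined", call. = FALSE)
  colMeans(voxel_to_world(idx, mask$affine))
}

# ---- NIfTI IO ---------------------------------------------------------------

#' Read a volume or mask from a NIfTI-1 file
#'
#' The sform is preferred when both sform and qform are set (RNifti's
#' `xform()` rule). Use `as_mask = TRUE` for segmentations; values are
#' binarised by `!= 0`.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param as_mask read as a binary `ntatlas_mask`?
#' @return `ntatlas_volume` or `ntatlas_mask`.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4L, 4L)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(img))
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim = dim(dat)[1:3])
  if (as_mask) mask3d(array(as.double(dat != 0), dim = dim(dat)), aff)
  else volume3d(dat, aff)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Volumes are stored as float64 and masks as uint8; the affine is written to
#' both sform and qform. Note NIfTI stores the affine rows as float32, so an
#' affine round-trips bit-exactly only when its entries are representable in
#' single precision (integers, halves, ...).
#'
#' @param vol `ntatlas_volume` or `ntatlas_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  dtype <- if (is_mask(vol)) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
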