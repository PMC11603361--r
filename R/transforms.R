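# Spatial transforms are world-mm -> world-mm maps. Every transform exposes a
# forward and an inverse map; displacement-field inverses are numerical
# (fixed-point) with a stated tolerance.

new_transform <- function(kind, fields) {
  structure(c(list(kind = kind), fields),
            class = c(paste0("ntatlas_xf_", kind), "ntatlas_transform"))
}

#' Rigid (rotation + translation) transform
#'
#' @param rotation 3x3 rotation matrix (orthogonal, determinant +1).
#' @param translation length-3 translation in mm.
#' @return A rigid `ntatlas_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("`rotation` must be a proper rotation matrix", call. = FALSE)
  new_transform("rigid", list(rotation = rotation,
                              translation = as.numeric(translation)))
}

#' General affine transform
#'
#' @param matrix 4x4 homogeneous world-to-world matrix with invertible 3x3
#'   block.
#' @return An affine `ntatlas_transform`.
#' @export
affine_transform <- function(matrix) {
  matrix <- check_affine(matrix)
  new_transform("affine", list(matrix = matrix))
}

#' Dense displacement-field transform
#'
#' The field stores world-mm displacement vectors u on a sampling grid; the
#' forward map is x -> x + u(x) with trilinear interpolation (zero
#' displacement outside the field support). The inverse is computed by
#' fixed-point iteration y <- x - u(y), to `tol` mm (default 1e-3) within
#' `max_iter` sweeps; non-convergence is an error.
#'
#' @param field 4-D array (nx x ny x nz x 3) of displacements in mm.
#' @param affine 4x4 voxel-to-world matrix of the field grid.
#' @param tol inverse fixed-point tolerance in mm.
#' @param max_iter maximum fixed-point iterations.
#' @return A displacement-field `ntatlas_transform`.
#' @export
displacement_field_transform <- function(field, affine, tol = 1e-3,
                                         max_iter = 50L) {
  if (length(dim(field)) != 4L || dim(field)[4] != 3L)
    stop("`field` must be an nx x ny x nz x 3 array", call. = FALSE)
  affine <- check_affine(affine)
  storage.mode(field) <- "double"
  new_transform("displacement_field",
                list(field = field, affine = affine,
                     tol = tol, max_iter = as.integer(max_iter)))
}

#' Composition of transforms
#'
#' `composed_transform(a, b)` applies `a` first, then `b`.
#'
#' @param ... transforms, applied left to right.
#' @return A composed `ntatlas_transform`.
#' @export
composed_transform <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "ntatlas_transform"))
    parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, TRUE, "ntatlas_transform")))
  new_transform("composed", list(parts = parts))
}

#' Identity transform
#' @return A rigid transform with zero rotation and translation.
#' @export
identity_transform <- function() rigid_transform()

#' Swap the forward and inverse maps of a transform
#'
#' Rigid and affine transforms invert in closed form; displacement fields and
#' compositions are wrapped so that `xf_forward` of the result calls the
#' original inverse.
#'
#' @param xf a `ntatlas_transform`.
#' @return The inverted transform.
#' @export
invert_transform <- function(xf) {
  switch(xf$kind,
    rigid = rigid_transform(t(xf$rotation),
                            -as.numeric(t(xf$rotation) %*% xf$translation)),
    affine = affine_transform(solve(xf$matrix)),
    composed = composed_transform(lapply(rev(xf$parts), invert_transform)),
    inverted = xf$inner,
    new_transform("inverted", list(inner = xf)))
}

# ---- forward / inverse evaluation ------------------------------------------

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  stopifnot(ncol(pts) == 3L)
  pts
}

#' Apply a transform's forward map
#' @param xf a `ntatlas_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of world points in mm.
#' @return n x 3 matrix of mapped points.
#' @export
xf_forward <- function(xf, pts) {
  pts <- as_points(pts)
  switch(xf$kind,
    rigid = sweep(pts %*% t(xf$rotation), 2, xf$translation, "+"),
    affine = {
      h <- cbind(pts, 1) %*% t(xf$matrix)
      h[, 1:3, drop = FALSE]
    },
    displacement_field = pts + sample_displacement(xf, pts),
    composed = Reduce(function(p, part) xf_forward(part, p), xf$parts, pts),
    inverted = xf_inverse(xf$inner, pts),
    stop("unknown transform kind: ", xf$kind, call. = FALSE))
}

#' Apply a transform's inverse map
#' @inheritParams xf_forward
#' @return n x 3 matrix of inverse-mapped points.
#' @export
xf_inverse <- function(xf, pts) {
  pts <- as_points(pts)
  switch(xf$kind,
    rigid = ,
    affine = xf_forward(invert_transform(xf), pts),
    displacement_field = invert_displacement(xf, pts),
    composed = Reduce(function(p, part) xf_inverse(part, p),
                      rev(xf$parts), pts),
    inverted = xf_forward(xf$inner, pts),
    stop("unknown transform kind: ", xf$kind, call. = FALSE))
}

sample_displacement <- function(xf, pts) {
  vox <- world_to_voxel(pts, xf$affine)
  cbind(trilinear_sample(xf$field[, , , 1], vox),
        trilinear_sample(xf$field[, , , 2], vox),
        trilinear_sample(xf$field[, , , 3], vox))
}

# Fixed-point inverse of x -> x + u(x): iterate y <- x - u(y).
invert_displacement <- function(xf, pts) {
  y <- pts
  for (it in seq_len(xf$max_iter)) {
    y_new <- pts - sample_displacement(xf, y)
    delta <- sqrt(max(rowSums((y_new - y)^2)))
    y <- y_new
    if (delta <= xf$tol) return(y)
  }
  stop("displacement-field inverse did not converge to ", xf$tol,
       " mm in ", xf$max_iter, " iterations", call. = FALSE)
}

# ---- serialization ----------------------------------------------------------

xf_to_list <- function(xf) {
  switch(xf$kind,
    rigid = list(kind = "rigid",
                 matrix = as.numeric(t(rbind(cbind(xf$rotation,
                                                   xf$translation),
                                             c(0, 0, 0, 1))))),
    affine = list(kind = "affine", matrix = as.numeric(t(xf$matrix))),
    composed = list(kind = "composed", parts = lapply(xf$parts, xf_to_list)),
    stop("only rigid, affine and composed transforms serialize to JSON; ",
         "write displacement fields with write_displacement_field()",
         call. = FALSE))
}

xf_from_list <- function(x) {
  kind <- x$kind
  if (kind == "composed")
    return(composed_transform(lapply(x$parts, xf_from_list)))
  m <- matrix(as.numeric(unlist(x$matrix)), 4L, 4L, byrow = TRUE)
  if (kind == "rigid") rigid_transform(m[1:3, 1:3], m[1:3, 4])
  else affine_transform(m)
}

#' Write a rigid/affine/composed transform as JSON
#' @param xf transform; matrices are stored row-major.
#' @param path output .json path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(xf, path) {
  jsonlite::write_json(xf_to_list(xf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform written by [write_transform_json()]
#' @param path .json path.
#' @return A `ntatlas_transform`.
#' @export
read_transform_json <- function(path) {
  xf_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE))
}

#' Write a displacement field as a 4-D NIfTI (3 components, world mm)
#' @param xf a displacement-field transform.
#' @param path output .nii/.nii.gz path.
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(xf, path) {
  stopifnot(xf$kind == "displacement_field")
  img <- RNifti::asNifti(xf$field)
  RNifti::sform(img) <- structure(xf$affine, code = 2L)
  RNifti::qform(img) <- structure(xf$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a displacement field written by [write_displacement_field()]
#' @param path .nii/.nii.gz path.
#' @inheritParams displacement_field_transform
#' @return A displacement-field `ntatlas_transform`.
#' @export
read_displacement_field <- function(path, tol = 1e-3, max_iter = 50L) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img, useQuaternionFirst = FALSE)),
                4L, 4L)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(img))
  displacement_field_transform(dat, aff, tol = tol, max_iter = max_iter)
}
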