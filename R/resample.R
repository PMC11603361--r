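# Vectorised samplers over 3-D arrays. `vox` is an n x 3 matrix of 0-based,
# possibly fractional voxel coordinates; locations outside the array support
# contribute 0 (unreached territory means "no connectivity").

trilinear_sample <- function(arr, vox) {
  d <- dim(arr)
  i0 <- floor(vox)
  f <- vox - i0
  out <- numeric(nrow(vox))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1 &
          kk >= 0 & kk <= d[3] - 1 & w > 0
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- out[ok] + w[ok] * arr[lin]
    }
  }
  out
}

nearest_sample <- function(arr, vox) {
  d <- dim(arr)
  i <- round(vox)
  out <- numeric(nrow(vox))
  ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
        i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
        i[, 3] >= 0 & i[, 3] <= d[3] - 1
  if (any(ok)) {
    lin <- i[ok, 1] + d[1] * (i[ok, 2] + d[2] * i[ok, 3]) + 1
    out[ok] <- arr[lin]
  }
  out
}

#' Resample a volume or mask onto a target grid through a spatial transform
#'
#' Pull-style resampling: each target voxel centre is mapped through the
#' inverse of `xform` (which is read as the source-to-target world map) into
#' the source volume and the value is interpolated there. Locations outside
#' the source support yield 0. Masks must use nearest-neighbour interpolation
#' so the output stays binary.
#'
#' @param vol source `ntatlas_volume` or `ntatlas_mask`.
#' @param xform `ntatlas_transform` mapping source world coordinates to
#'   target world coordinates.
#' @param target `grid_spec` of the output.
#' @param interp `"trilinear"` or `"nearest"`; defaults to `"nearest"` for
#'   masks and `"trilinear"` otherwise.
#' @return Volume or mask (matching the input class) on `target`.
#' @export
resample <- function(vol, xform, target,
                     interp = if (is_mask(vol)) "nearest" else "trilinear") {
  interp <- match.arg(interp, c("trilinear", "nearest"))
  if (is_mask(vol) && interp != "nearest")
    stop("masks must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  tgt_world <- voxel_to_world(all_voxel_indices(target$shape), target$affine)
  src_world <- xf_inverse(xform, tgt_world)
  src_vox <- world_to_voxel(src_world, vol$affine)
  vals <- if (interp == "trilinear") trilinear_sample(vol$data, src_vox)
          else nearest_sample(vol$data, src_vox)
  out <- array(vals, dim = target$shape)
  if (is_mask(vol)) mask3d(out, target$affine)
  else volume3d(out, target$affine)
}
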