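# Minimal TrackVis TRK (version 2) export for streamlines. Coordinates are
# written in TrackVis "voxmm" convention: corner-anchored voxel coordinates
# scaled by the voxel size, with the grid's voxel-to-world affine recorded in
# the header's vox_to_ras field.

#' Write streamlines to a TrackVis .trk file
#'
#' @param streamlines list of `streamline` objects (or n x 3 world-point
#'   matrices).
#' @param path output .trk path.
#' @param grid `grid_spec` the tracks were generated on (used for the header
#'   geometry and the world-to-voxmm conversion).
#' @return `path`, invisibly.
#' @export
write_trk <- function(streamlines, path, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  vox_size <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(grid$shape), con, size = 2)              # dim
  writeBin(as.numeric(vox_size), con, size = 4)                # voxel_size
  writeBin(numeric(3), con, size = 4)                          # origin
  writeBin(integer(2), con, size = 2)                          # n_scalars/props
  writeBin(raw(200 + 200), con)                                # names (unused)
  writeBin(as.numeric(t(grid$affine)), con, size = 4)          # vox_to_ras
  writeBin(raw(444), con)                                      # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1), con)
  writeBin(raw(4 + 24 + 2 + 6), con)    # pad2, image orientation, pad1, flags
  writeBin(length(streamlines), con, size = 4)                 # n_count
  writeBin(2L, con, size = 4)                                  # version
  writeBin(1000L, con, size = 4)                               # hdr_size
  for (sl in streamlines) {
    pts <- if (is.list(sl)) sl$points else sl
    vox <- world_to_voxel(pts, grid$affine)                    # centre-based
    voxmm <- sweep(vox + 0.5, 2, vox_size, "*")                # corner-based mm
    writeBin(nrow(voxmm), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

#' Read a .trk file written by [write_trk()]
#'
#' @param path .trk path.
#' @return List with `points` (list of n x 3 world-mm matrices) and the
#'   header fields `dim`, `voxel_size`, `vox_to_ras`, `n_count`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE); readBin(con, "raw", 1)
  if (!identical(magic, "TRACK")) stop("not a TRK file", call. = FALSE)
  dim3 <- readBin(con, "integer", 3, size = 2)
  vox_size <- readBin(con, "numeric", 3, size = 4)
  readBin(con, "numeric", 3, size = 4)
  ns <- readBin(con, "integer", 1, size = 2)
  np <- readBin(con, "integer", 1, size = 2)
  readBin(con, "raw", 400)
  v2r <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 36)
  n_count <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 2, size = 4)                         # version, hdr
  pts <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    m <- readBin(con, "integer", 1, size = 4)
    voxmm <- matrix(readBin(con, "numeric", 3 * m + ns * m, size = 4),
                    ncol = 3 + ns, byrow = TRUE)[, 1:3, drop = FALSE]
    if (np > 0) readBin(con, "numeric", np, size = 4)
    vox <- sweep(voxmm, 2, vox_size, "/") - 0.5
    pts[[i]] <- voxel_to_world(vox, v2r)
  }
  list(points = pts, dim = dim3, voxel_size = vox_size, vox_to_ras = v2r,
       n_count = n_count)
}
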