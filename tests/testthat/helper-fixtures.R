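# Shared fixtures, built in code at test time.

# isotropic grid with a given resolution and origin
iso_grid <- function(shape, res = 1, origin = c(0, 0, 0)) {
  aff <- diag(c(res, res, res, 1))
  aff[1:3, 4] <- origin
  grid_spec(shape, aff)
}

# smooth analytic test function and a volume sampled from it
smooth_fn <- function(pts) {
  sin(pts[, 1] / 7) * cos(pts[, 2] / 9) + 0.5 * sin(pts[, 3] / 5) + 2
}

smooth_volume <- function(grid) {
  pts <- ntatlas:::voxel_to_world(ntatlas:::all_voxel_indices(grid$shape),
                                  grid$affine)
  volume3d(array(smooth_fn(pts), grid$shape), grid$affine)
}

# axis-aligned straight-column phantom: fibres point +z inside chosen
# (i,j) columns between z slabs; optional gaps interrupt a column.
# Returns field plus seed (bottom slab) and terminus (top slab) masks.
column_phantom <- function(shape = c(10L, 10L, 24L), fibre_cols,
                           gap = NULL, kappa = Inf) {
  grid <- iso_grid(shape)
  dir1 <- array(0, c(shape, 3L))
  tmask <- array(0, shape)
  z_fib <- 2:(shape[3] - 2)          # 1-based slices carrying fibres,
                                     # ending right below the terminus slab
  for (cl in fibre_cols) {
    dir1[cl[1], cl[2], z_fib, 3] <- 1
    tmask[cl[1], cl[2], ] <- 1
  }
  if (!is.null(gap))
    for (g in gap) {
      dir1[g[1], g[2], g[3], ] <- 0   # fibre-free voxel interrupts column
    }
  seed <- array(0, shape); term <- array(0, shape)
  seed[, , 2] <- tmask[, , 2]
  term[, , shape[3] - 1] <- 1
  tmask <- pmax(tmask, term)
  field <- orientation_field(grid, dir1, kappa = kappa,
                             tracking_mask = mask3d(tmask, grid$affine))
  list(grid = grid, field = field,
       seed = mask3d(seed, grid$affine),
       terminus = mask3d(term, grid$affine))
}

# independent voxel-graph reachability oracle for kappa = Inf single-fibre
# fields explored in both orientations: from each voxel step one voxel along
# +/- its fibre; a seed voxel "hits" iff a terminus voxel is reachable.
reachability_oracle <- function(field, seed, terminus) {
  shape <- field$grid$shape
  dirs <- matrix(field$dir1, ncol = 3L)
  term <- terminus$data != 0
  tmask <- field$tracking_mask$data != 0
  n <- prod(shape)
  # successor voxel index (1-based linear) along each orientation, NA = stop
  succ <- function(sign) {
    idx <- ntatlas:::all_voxel_indices(shape)
    nxt <- idx + sign * round(dirs)
    ok <- rowSums(abs(dirs)) > 0 &
      nxt[, 1] >= 0 & nxt[, 1] < shape[1] &
      nxt[, 2] >= 0 & nxt[, 2] < shape[2] &
      nxt[, 3] >= 0 & nxt[, 3] < shape[3]
    lin <- rep(NA_integer_, n)
    lin[ok] <- nxt[ok, 1] + shape[1] * (nxt[ok, 2] + shape[2] * nxt[ok, 3]) + 1
    lin[!tmask] <- NA_integer_
    lin
  }
  reach_term <- term
  for (sgn in c(1, -1)) {
    s <- succ(sgn)
    reached <- term
    repeat {                      # fixed-point: can this voxel walk to term?
      nxt_hit <- !is.na(s) & reached[ifelse(is.na(s), 1L, s)]
      new <- reached | nxt_hit
      if (all(new == reached)) break
      reached <- new
    }
    reach_term <- reach_term | reached
  }
  out <- array(0, shape)
  sel <- seed$data != 0
  out[sel] <- as.numeric(reach_term[sel])
  out
}

# tiny unimodal synthetic atlas: separable triangular peak, max exactly 1
peak_atlas <- function(shape = c(15L, 15L, 15L), peak = c(7, 7, 7), res = 1) {
  grid <- iso_grid(shape, res = res)
  idx <- ntatlas:::all_voxel_indices(shape)
  v <- pmax(0, 1 - abs(idx[, 1] - peak[1]) / 6) *
       pmax(0, 1 - abs(idx[, 2] - peak[2]) / 6) *
       pmax(0, 1 - abs(idx[, 3] - peak[3]) / 6)
  max_normalize(volume3d(array(v, shape), grid$affine))
}
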