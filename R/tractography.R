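# Simplified probabilistic streamline tracker: per seed voxel, the fraction
# of launched streamlines reaching a terminus ROI. Direction fields are
# analytic (up to two unit fibers per voxel with mixture weights and a
# von Mises-Fisher angular concentration), standing in for a fitted
# crossing-fibre diffusion model.

#' Per-voxel fibre orientation field
#'
#' @param grid `grid_spec` of the field.
#' @param dir1 nx x ny x nz x 3 array of primary fibre directions (unit
#'   vectors; all-zero rows mean "no fibre").
#' @param dir2 optional second fibre population, same layout.
#' @param w1 array of mixture weights for the first fibre (only consulted
#'   where both fibres exist); defaults to 1 everywhere.
#' @param kappa angular concentration (scalar or per-voxel array). `Inf`
#'   means no dispersion; finite values must be positive.
#' @param tracking_mask `ntatlas_mask` of valid tracking territory; defaults
#'   to every voxel with a fibre.
#' @return An `orientation_field` object.
#' @export
orientation_field <- function(grid, dir1, dir2 = NULL, w1 = NULL,
                              kappa = Inf, tracking_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  expect_dim <- c(grid$shape, 3L)
  if (!all(dim(dir1) == expect_dim))
    stop("`dir1` must have dimensions shape x 3", call. = FALSE)
  if (is.null(dir2)) dir2 <- array(0, expect_dim)
  if (!all(dim(dir2) == expect_dim))
    stop("`dir2` must have dimensions shape x 3", call. = FALSE)
  norms1 <- sqrt(rowSums(matrix(dir1, ncol = 3L)^2))
  norms2 <- sqrt(rowSums(matrix(dir2, ncol = 3L)^2))
  if (any(abs(norms1[norms1 > 0] - 1) > 1e-6) ||
      any(abs(norms2[norms2 > 0] - 1) > 1e-6))
    stop("fibre directions must be unit vectors (or all-zero)", call. = FALSE)
  if (is.null(w1)) w1 <- array(1, grid$shape)
  if (length(w1) == 1L) w1 <- array(w1, grid$shape)
  if (any(w1 < 0 | w1 > 1)) stop("`w1` must lie in [0,1]", call. = FALSE)
  if (length(kappa) == 1L) kappa <- array(kappa, grid$shape)
  if (any(kappa[is.finite(kappa)] <= 0))
    stop("finite `kappa` must be positive", call. = FALSE)
  if (is.null(tracking_mask)) {
    has_fib <- array(as.double(norms1 > 0 | norms2 > 0), grid$shape)
    tracking_mask <- mask3d(has_fib, grid$affine)
  }
  stop_if_grid_mismatch(tracking_mask, grid, "tracking mask and field grid")
  structure(list(grid = grid, dir1 = dir1, dir2 = dir2, w1 = w1,
                 kappa = kappa, tracking_mask = tracking_mask),
            class = "orientation_field")
}

#' Streamline tracking parameters
#'
#' @param step_mm Euler step length (mm).
#' @param max_steps maximum steps per streamline.
#' @param curvature_limit_deg maximum per-step turning angle (degrees).
#' @param samples_per_seed_voxel streamlines launched per seed voxel.
#' @param rng_seed integer seed; all tracking randomness derives from it via
#'   per-streamline substreams.
#' @param jitter launch from uniformly jittered positions within each seed
#'   voxel (`TRUE`, default) or from voxel centres.
#' @param bidirectional explore both orientations of the initial fibre
#'   (default `FALSE`: each seed fires one random initial sign).
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(step_mm = 0.5, max_steps = 2000L,
                            curvature_limit_deg = 80,
                            samples_per_seed_voxel = 100L, rng_seed = 1L,
                            jitter = TRUE, bidirectional = FALSE) {
  stopifnot(step_mm > 0, samples_per_seed_voxel >= 1,
            curvature_limit_deg > 0, curvature_limit_deg <= 180,
            max_steps >= 1)
  structure(list(step_mm = step_mm, max_steps = as.integer(max_steps),
                 curvature_limit_deg = curvature_limit_deg,
                 samples_per_seed_voxel = as.integer(samples_per_seed_voxel),
                 rng_seed = as.integer(rng_seed), jitter = isTRUE(jitter),
                 bidirectional = isTRUE(bidirectional)),
            class = "tracking_params")
}

field_cpp_args <- function(field) {
  g <- field$grid
  list(dims = g$shape, v2w = g$affine, w2v = solve(g$affine),
       dir1 = as.numeric(field$dir1), dir2 = as.numeric(field$dir2),
       w1 = as.numeric(field$w1), kappa = as.numeric(field$kappa),
       tmask = as.integer(field$tracking_mask$data != 0))
}

point_in_mask <- function(mask, pt) {
  nearest_sample(mask$data, world_to_voxel(pt, mask$affine)) != 0
}

#' Draw fibre step directions at a world point
#'
#' Chooses a fibre population with probability proportional to its weight,
#' perturbs it by a von Mises-Fisher draw with the voxel's concentration, and
#' flips the sign to stay within 90 degrees of `prev_dir` when given. With no
#' previous direction the stored fibre orientation is returned as-is.
#'
#' @param field an `orientation_field`.
#' @param at world point (mm), inside the tracking mask.
#' @param prev_dir previous step direction (unit vector) or `NULL`.
#' @param n number of draws.
#' @param rng_seed substream seed.
#' @return n x 3 matrix of unit vectors, or `NULL` if the voxel holds no
#'   fibre.
#' @export
sample_direction <- function(field, at, prev_dir = NULL, n = 1L,
                             rng_seed = 1L) {
  if (!point_in_mask(field$tracking_mask, at))
    stop("`at` lies outside the tracking mask", call. = FALSE)
  vox <- round(world_to_voxel(at, field$grid$affine))
  lin <- vox[1] + field$grid$shape[1] * (vox[2] + field$grid$shape[2] * vox[3]) + 1
  m1 <- matrix(field$dir1, ncol = 3L); m2 <- matrix(field$dir2, ncol = 3L)
  d1 <- m1[lin, ]; d2 <- m2[lin, ]
  if (sum(d1^2) == 0 && sum(d2^2) == 0) return(NULL)
  out <- cpp_sample_directions(d1, d2, field$w1[lin], field$kappa[lin],
                               if (is.null(prev_dir)) c(0, 0, 0)
                               else as.numeric(prev_dir),
                               !is.null(prev_dir), as.integer(n),
                               as.double(rng_seed))
  out
}

#' Propagate a single streamline
#'
#' Euler integration of `params$step_mm` steps along directions drawn from
#' the field, stopping at the first point inside the terminus, on leaving the
#' tracking mask, on a turn exceeding the curvature limit, on a fibre-free
#' voxel, or at `max_steps`.
#'
#' @param seed world launch point (mm), inside the tracking mask.
#' @param field an `orientation_field`.
#' @param terminus `ntatlas_mask` of the target region (may be all-zero).
#' @param params `tracking_params`.
#' @param init_sign +1 / -1 to force the initial orientation, or 0 (default)
#'   to fire one random sign.
#' @return A `streamline`: list with `points` (n x 3 world mm) and
#'   `termination_reason` in `terminus`, `left_mask`, `max_steps`,
#'   `curvature_stop`, `no_fiber`.
#' @export
propagate_streamline <- function(seed, field, terminus, params = tracking_params(),
                                 init_sign = 0L) {
  if (!point_in_mask(field$tracking_mask, seed))
    stop("seed point lies outside the tracking mask", call. = FALSE)
  stop_if_grid_mismatch(terminus, field$grid, "terminus and field grid")
  a <- field_cpp_args(field)
  res <- cpp_propagate(a$dims, a$v2w, a$w2v, a$dir1, a$dir2, a$w1, a$kappa,
                       a$tmask, as.integer(terminus$data != 0),
                       as.numeric(seed), as.integer(init_sign),
                       params$step_mm, params$max_steps,
                       params$curvature_limit_deg,
                       as.double(params$rng_seed))
  structure(res, class = "streamline")
}

#' Seed-to-terminus hit fractions (the subject "hotspot")
#'
#' For every voxel of the seed ROI, launches `samples_per_seed_voxel`
#' streamlines from uniformly jittered positions within the voxel and records
#' the fraction that reach the terminus ROI. This is the per-subject
#' connectivity statistic the normative atlas is built from.
#'
#' @param field an `orientation_field`.
#' @param seed `ntatlas_mask` of seed voxels (nonempty, on the field grid).
#' @param terminus `ntatlas_mask` of the target region, disjoint from the
#'   seed.
#' @param params `tracking_params`.
#' @return A `hit_fraction_map`: an `ntatlas_volume` on the field grid,
#'   zero outside the seed ROI, values in [0,1], with attribute `n_samples`.
#' @export
seed_to_terminus_fractions <- function(field, seed, terminus,
                                       params = tracking_params()) {
  stop_if_grid_mismatch(seed, field$grid, "seed and field grid")
  stop_if_grid_mismatch(terminus, field$grid, "terminus and field grid")
  seed_idx <- nonzero_indices(seed)
  if (nrow(seed_idx) == 0L) stop("seed ROI is empty", call. = FALSE)
  if (any(seed$data != 0 & terminus$data != 0))
    stop("seed and terminus ROIs overlap", call. = FALSE)
  a <- field_cpp_args(field)
  fr <- cpp_track_fractions(a$dims, a$v2w, a$w2v, a$dir1, a$dir2, a$w1,
                            a$kappa, a$tmask,
                            as.integer(terminus$data != 0),
                            matrix(as.integer(seed_idx), ncol = 3L),
                            params$step_mm, params$max_steps,
                            params$curvature_limit_deg,
                            params$samples_per_seed_voxel,
                            params$jitter, params$bidirectional,
                            as.double(params$rng_seed))
  out <- array(0, field$grid$shape)
  lin <- seed_idx[, 1] + field$grid$shape[1] *
    (seed_idx[, 2] + field$grid$shape[2] * seed_idx[, 3]) + 1
  out[lin] <- fr
  v <- volume3d(out, field$grid$affine)
  attr(v, "n_samples") <- params$samples_per_seed_voxel
  class(v) <- c("hit_fraction_map", class(v))
  v
}
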