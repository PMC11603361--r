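# Normative tractographic atlas construction: warp each subject's hit-
# fraction map to the template grid, take the voxelwise median across
# subjects, and divide by the global maximum so the atlas spans [0, 1].

#' Bundle a subject hotspot with its template-to-subject transform
#'
#' @param map the subject's hit-fraction map (`ntatlas_volume`).
#' @param template_to_subject `ntatlas_transform` mapping template world
#'   coordinates into the subject's world space.
#' @param subject_id identifier string.
#' @return A `subject_hotspot`.
#' @export
subject_hotspot <- function(map, template_to_subject = identity_transform(),
                            subject_id = "subject") {
  stopifnot(inherits(map, "ntatlas_volume"),
            inherits(template_to_subject, "ntatlas_transform"))
  structure(list(map = map, template_to_subject = template_to_subject,
                 subject_id = subject_id),
            class = "subject_hotspot")
}

#' Warp a subject hotspot back to the template grid
#'
#' Trilinear pull-resampling: each template voxel centre is carried into the
#' subject's space by `template_to_subject` and the subject map is sampled
#' there; template voxels outside the subject map's support get 0.
#'
#' @param s a `subject_hotspot`.
#' @param template `grid_spec` of the template space.
#' @return `ntatlas_volume` on the template grid.
#' @export
warp_hotspot_to_template <- function(s, template) {
  # resample() pulls through the inverse of its source-to-target transform,
  # so hand it subject-to-template and it samples at template_to_subject.
  resample(s$map, invert_transform(s$template_to_subject), template,
           interp = "trilinear")
}

#' Voxelwise median of aligned maps
#'
#' With an even number of maps the midpoint of the two central order
#' statistics is used.
#'
#' @param maps nonempty list of `ntatlas_volume`s on one grid.
#' @return `ntatlas_volume` of voxelwise medians.
#' @export
median_combine <- function(maps) {
  if (length(maps) == 0L) stop("no maps to combine", call. = FALSE)
  for (m in maps) stop_if_grid_mismatch(m, maps[[1]], "maps")
  if (length(maps) == 1L) return(maps[[1]])
  stack <- vapply(maps, function(m) as.numeric(m$data),
                  numeric(length(maps[[1]]$data)))
  med <- matrixStats_rowMedians(stack)
  volume3d(array(med, dim(maps[[1]]$data)), maps[[1]]$affine)
}

# row medians without an extra dependency; even counts -> midpoint of the
# two central order statistics (the type-7 default of stats::median)
matrixStats_rowMedians <- function(m) {
  n <- ncol(m)
  srt <- t(apply(m, 1, sort))
  if (n %% 2 == 1) srt[, (n + 1) / 2]
  else (srt[, n / 2] + srt[, n / 2 + 1]) / 2
}

#' Normalize a map by its global maximum
#'
#' @param map `ntatlas_volume` with at least one positive value.
#' @return An `nta_volume`: the map divided by its maximum, so values span
#'   [0, 1] with maximum exactly 1. Attributes record the pre-normalization
#'   maximum (`pre_norm_max`) and `n_subjects` when set by [build_nta()].
#' @export
max_normalize <- function(map) {
  mx <- max(map$data)
  if (mx <= 0)
    stop("map has no positive values; the atlas is undefined", call. = FALSE)
  out <- volume3d(map$data / mx, map$affine)
  attr(out, "pre_norm_max") <- mx
  class(out) <- c("nta_volume", class(out))
  out
}

#' Build the normative tractographic atlas
#'
#' Warps every subject's hit-fraction map to the template grid, median-
#' combines them voxelwise (template voxels a subject's map cannot reach
#' contribute 0), and divides by the global maximum. The result ranges from
#' 0 to 1; subject order does not matter.
#'
#' @param subjects nonempty list of `subject_hotspot`s.
#' @param template `grid_spec` of the template space.
#' @return An `nta_volume` with attributes `n_subjects` and `pre_norm_max`.
#' @export
build_nta <- function(subjects, template) {
  if (length(subjects) == 0L) stop("no subjects", call. = FALSE)
  warped <- lapply(subjects, warp_hotspot_to_template, template = template)
  nta <- max_normalize(median_combine(warped))
  attr(nta, "n_subjects") <- length(subjects)
  nta
}

#' Medial apex of the atlas's hottest voxels
#'
#' Among voxels with value >= `hot_fraction` times the atlas maximum, returns
#' the one whose world x coordinate is smallest in absolute value (most
#' medial), breaking ties by most anterior (largest y) then most superior
#' (largest z). This is the recommended sonication target: aiming at the
#' medial edge of the hotspot compensates for the predominantly
#' inferoanteriolateral spread of ultrasound energy.
#'
#' @param nta an `nta_volume` (or any nonzero `ntatlas_volume`).
#' @param hot_fraction threshold defining "hottest", in (0, 1]; default 0.9.
#' @param ac,pc optional AC / PC world points; when both are given the
#'   result also reports the apex's offsets in the AC-PC frame (lateral to
#'   the midcommissural point, anterior of PC as a fraction of the AC-PC
#'   distance, superior to the intercommissural plane).
#' @return List with `point` (world mm), `value`, `voxel` (0-based index)
#'   and, when landmarks are supplied, `acpc_offsets`.
#' @export
medial_apex <- function(nta, hot_fraction = 0.9, ac = NULL, pc = NULL) {
  if (hot_fraction <= 0 || hot_fraction > 1)
    stop("`hot_fraction` must lie in (0, 1]", call. = FALSE)
  mx <- max(nta$data)
  if (mx <= 0) stop("atlas has no nonzero voxels", call. = FALSE)
  idx <- which(nta$data >= hot_fraction * mx, arr.ind = TRUE) - 1
  pts <- voxel_to_world(idx, nta$affine)
  ord <- order(abs(pts[, 1]), -pts[, 2], -pts[, 3])
  best <- ord[1]
  out <- list(point = pts[best, ],
              value = nta$data[matrix(idx[best, ] + 1, ncol = 3L)],
              voxel = idx[best, ])
  if (!is.null(ac) && !is.null(pc)) {
    ac <- as.numeric(ac); pc <- as.numeric(pc)
    mc <- (ac + pc) / 2
    d <- sqrt(sum((ac - pc)^2))
    y_hat <- (ac - pc) / d
    rel <- out$point - mc
    out$acpc_offsets <- list(
      lateral_mm = rel[1],
      anterior_of_pc_frac = sum((out$point - pc) * y_hat) / d,
      superior_mm = rel[3])
  }
  out
}
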