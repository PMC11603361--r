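# Patient fitting: warp the atlas into the patient's preoperative T1 space,
# bring the postoperative lesion into the same space, and score the lesion
# with the normative tractography coefficient (NTC) — the mean patient-fit
# atlas value over the lesion voxels.

#' Patient coordinate spaces and transforms
#'
#' @param preop_grid `grid_spec` of the preoperative T1 image (the common
#'   scoring frame).
#' @param postop_grid `grid_spec` of the postoperative image holding the
#'   lesion segmentation.
#' @param template_to_patient `ntatlas_transform` from template world space
#'   to preop world space (nonlinear allowed).
#' @param postop_to_preop rigid `ntatlas_transform` from postop to preop
#'   world space.
#' @return A `patient_spaces` object.
#' @export
patient_spaces <- function(preop_grid, postop_grid = preop_grid,
                           template_to_patient = identity_transform(),
                           postop_to_preop = identity_transform()) {
  stopifnot(inherits(preop_grid, "grid_spec"),
            inherits(postop_grid, "grid_spec"),
            inherits(template_to_patient, "ntatlas_transform"),
            inherits(postop_to_preop, "ntatlas_transform"))
  structure(list(preop_grid = preop_grid, postop_grid = postop_grid,
                 template_to_patient = template_to_patient,
                 postop_to_preop = postop_to_preop),
            class = "patient_spaces")
}

#' Warp the normative atlas into a patient's preoperative space
#'
#' Trilinear pull-resampling of the atlas onto the preop grid through the
#' template-to-patient transform; values stay within [0, 1] (convex
#' interpolation, zero outside support).
#'
#' @param nta an `nta_volume` on the template grid.
#' @param spaces a `patient_spaces`.
#' @return `ntatlas_volume` on the preop grid (the patient-fit atlas).
#' @export
fit_nta_to_patient <- function(nta, spaces) {
  resample(nta, spaces$template_to_patient, spaces$preop_grid,
           interp = "trilinear")
}

#' Coregister the postoperative lesion mask into preop space
#'
#' Nearest-neighbour resampling through the rigid postop-to-preop transform;
#' the output is binary. An empty result means the lesion left the preop
#' field of view and is an error.
#'
#' @param lesion `ntatlas_mask` on the postop grid.
#' @param spaces a `patient_spaces`.
#' @return `ntatlas_mask` on the preop grid.
#' @export
coregister_lesion <- function(lesion, spaces) {
  out <- resample(lesion, spaces$postop_to_preop, spaces$preop_grid,
                  interp = "nearest")
  if (!any(out$data != 0))
    stop("coregistered lesion is empty: the lesion left the preop field of view",
         call. = FALSE)
  out
}

#' Normative tractography coefficient of a lesion
#'
#' NTC is the arithmetic mean of the patient-fit atlas over the lesion's
#' voxels. A lesion containing only the voxel where the patient-fit atlas
#' attains its maximum (value 1) scores exactly 1; a lesion disjoint from the
#' atlas support scores exactly 0.
#'
#' @param patient_nta patient-fit atlas (`ntatlas_volume`) on the preop grid.
#' @param lesion nonempty `ntatlas_mask` on the same grid.
#' @param patient_id identifier carried into the result.
#' @return An `ntc_result`: list with `ntc`, `lesion_voxels`,
#'   `lesion_volume_mm3`, `patient_id`.
#' @export
compute_ntc <- function(patient_nta, lesion, patient_id = NA_character_) {
  stop_if_grid_mismatch(patient_nta, lesion, "atlas and lesion")
  sel <- lesion$data != 0
  n <- sum(sel)
  if (n == 0L) stop("lesion mask is empty", call. = FALSE)
  structure(list(ntc = mean(patient_nta$data[sel]),
                 lesion_voxels = n,
                 lesion_volume_mm3 = mask_volume_mm3(lesion),
                 distance_to_target_mm = NA_real_,
                 patient_id = patient_id),
            class = "ntc_result")
}

#' Lesion report: NTC, volume, and distance to a stereotactic target
#'
#' @inheritParams compute_ntc
#' @param target optional world point; when given, the Euclidean distance
#'   from it to the lesion's centre of mass is reported.
#' @return An `ntc_result` with `distance_to_target_mm` filled in when a
#'   target is supplied.
#' @export
lesion_report <- function(patient_nta, lesion, target = NULL,
                          patient_id = NA_character_) {
  res <- compute_ntc(patient_nta, lesion, patient_id = patient_id)
  if (!is.null(target)) {
    com <- center_of_mass_mm(lesion)
    res$distance_to_target_mm <- sqrt(sum((com - as.numeric(target))^2))
  }
  res
}

#' @export
print.ntc_result <- function(x, ...) {
  cat(sprintf("NTC result%s\n",
              if (is.na(x$patient_id)) "" else paste0(" [", x$patient_id, "]")))
  cat(sprintf("  NTC:            %.3f\n", x$ntc))
  cat(sprintf("  lesion voxels:  %d\n", x$lesion_voxels))
  cat(sprintf("  lesion volume:  %.1f mm^3\n", x$lesion_volume_mm3))
  if (!is.na(x$distance_to_target_mm))
    cat(sprintf("  target offset:  %.2f mm\n", x$distance_to_target_mm))
  invisible(x)
}
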