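# Synthetic phantoms and cohorts with known ground truth: a template brain
# window holding a VIM-like seed ellipsoid connected to a precentral-like
# terminus slab through a curved fibre tube; per-subject smooth deformations
# of that template; ellipsoidal ablation lesions with known postop-to-preop
# rigid offsets; and patient cohorts whose QoL and adverse-event outcomes
# depend on lesion volume and NTC in the reported directions.

# ---- seeding ----------------------------------------------------------------

# Named substream seeds: every stage draws from its own deterministic stream
# derived from one base seed, so any stage can be reproduced in isolation.
substream_seed <- function(base, name, index = 0L) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) * 131)) %% 100003
  as.integer((as.double(base) * 48271 + h * 7919 + index * 104729) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- phantom geometry -------------------------------------------------------

#' Specification of the connectivity phantom
#'
#' Describes a right-hemisphere window in a template-like RAS frame: a
#' VIM-like seed ellipsoid, a precentral-like terminus slab near the vertex,
#' and a laterally bowed quadratic-Bezier fibre tube connecting them.
#' Defaults give a 2 mm isotropic 28 x 32 x 40 grid.
#'
#' @param shape,resolution_mm grid dimensions and isotropic voxel size.
#' @param origin world position of voxel (0,0,0).
#' @param vim_center,vim_radii seed ellipsoid centre and radii (mm).
#' @param terminus_lo,terminus_hi corners of the terminus box (mm).
#' @param tube_control control point of the quadratic Bezier centerline from
#'   `vim_center` to the terminus box centre.
#' @param tube_radius fibre tube radius (mm).
#' @param kappa angular concentration of the fibre orientations (`Inf` = no
#'   dispersion).
#' @param rng_seed base seed for subject generation.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(28L, 32L, 40L), resolution_mm = 2,
                         origin = c(-10, -50, -14),
                         vim_center = c(14, -16, 2),
                         vim_radii = c(5, 6, 5),
                         terminus_lo = c(18, -34, 48),
                         terminus_hi = c(38, -6, 58),
                         tube_control = c(32, -14, 18),
                         tube_radius = 5, kappa = Inf, rng_seed = 1L) {
  aff <- diag(c(resolution_mm, resolution_mm, resolution_mm, 1))
  aff[1:3, 4] <- origin
  spec <- list(grid = grid_spec(shape, aff), vim_center = vim_center,
               vim_radii = vim_radii, terminus_lo = terminus_lo,
               terminus_hi = terminus_hi, tube_control = tube_control,
               tube_radius = tube_radius, kappa = kappa,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  spec
}

bezier_eval <- function(p0, p1, p2, t) {
  outer((1 - t)^2, p0) + outer(2 * (1 - t) * t, p1) + outer(t^2, p2)
}

bezier_tangent <- function(p0, p1, p2, t) {
  d <- outer(2 * (1 - t), p1 - p0) + outer(2 * t, p2 - p1)
  d / sqrt(rowSums(d^2))
}

ellipsoid_inside <- function(pts, center, radii) {
  rowSums(sweep(sweep(pts, 2, center), 2, radii, "/")^2) <= 1
}

box_inside <- function(pts, lo, hi) {
  pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
  pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
  pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
}

# Build orientation field + ROI masks for given geometry on a grid.
build_phantom_geometry <- function(grid, vim_center, vim_radii, p0, p1, p2,
                                   tube_radius, terminus_lo, terminus_hi,
                                   kappa) {
  pts <- voxel_to_world(all_voxel_indices(grid$shape), grid$affine)
  n <- nrow(pts)
  ts <- seq(0, 1, length.out = 200L)
  curve <- bezier_eval(p0, p1, p2, ts)
  lo <- pmin(p0, p1, p2) - tube_radius - 2
  hi <- pmax(p0, p1, p2) + tube_radius + 2
  if (any(curve < matrix(voxel_to_world(c(0, 0, 0), grid$affine), 200, 3,
                         byrow = TRUE) - 1) ||
      any(curve > matrix(voxel_to_world(grid$shape - 1, grid$affine), 200, 3,
                         byrow = TRUE) + 1))
    stop("fibre tube leaves the grid", call. = FALSE)
  near <- box_inside(pts, lo, hi)   # only candidates near the tube
  best_d2 <- rep(Inf, n); best_j <- rep(1L, n)
  idx <- which(near)
  sub <- pts[idx, , drop = FALSE]
  bd2 <- rep(Inf, length(idx)); bj <- rep(1L, length(idx))
  for (j in seq_along(ts)) {
    d2 <- (sub[, 1] - curve[j, 1])^2 + (sub[, 2] - curve[j, 2])^2 +
          (sub[, 3] - curve[j, 3])^2
    upd <- d2 < bd2
    bd2[upd] <- d2[upd]; bj[upd] <- j
  }
  best_d2[idx] <- bd2; best_j[idx] <- bj
  in_tube <- best_d2 <= tube_radius^2
  tang <- bezier_tangent(p0, p1, p2, ts)
  # fibre = tube tangent, bent slightly toward the centerline near the rim
  # ((d/R)^2-weighted centripetal term) so tracks stay confined on the bend
  dir1 <- array(0, c(grid$shape, 3L))
  m <- matrix(dir1, ncol = 3L)
  w <- which(in_tube)
  tg <- tang[best_j[w], , drop = FALSE]
  inward <- curve[best_j[w], , drop = FALSE] - pts[w, , drop = FALSE]
  inorm <- sqrt(rowSums(inward^2))
  inward <- inward / pmax(inorm, 1e-9)
  cw <- 0.6 * pmin(inorm / tube_radius, 1)^2
  d <- tg + inward * cw
  d <- d / sqrt(rowSums(d^2))
  m[w, ] <- d
  dir1 <- array(m, c(grid$shape, 3L))

  vim <- ellipsoid_inside(pts, vim_center, vim_radii)
  term <- box_inside(pts, terminus_lo, terminus_hi)
  term <- term & !vim
  tmask <- in_tube | vim | term
  field <- orientation_field(
    grid, dir1, kappa = kappa,
    tracking_mask = mask3d(array(as.double(tmask), grid$shape), grid$affine))
  list(field = field,
       vim = mask3d(array(as.double(vim), grid$shape), grid$affine),
       terminus = mask3d(array(as.double(term), grid$shape), grid$affine),
       in_tube = array(in_tube, grid$shape))
}

# Small random affine (rotation <= ~2 deg, per-axis scale 1 +/- 3%,
# translation <= 3 mm) about a centre point.
random_small_affine <- function(center, rng_seed,
                                max_rot_deg = 2, max_scale = 0.03,
                                max_shift_mm = 3) {
  with_seed(rng_seed, {
    ang <- runif(3, -max_rot_deg, max_rot_deg) * pi / 180
    rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3, 3)
    ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                   sin(ang[2]), 0, cos(ang[2])), 3, 3)
    rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                   0, 0, 0, 1), 3, 3)
    s <- diag(runif(3, 1 - max_scale, 1 + max_scale))
    a3 <- rz %*% ry %*% rx %*% s
    shift <- runif(3, -max_shift_mm, max_shift_mm)
    m <- diag(4)
    m[1:3, 1:3] <- a3
    m[1:3, 4] <- center - a3 %*% center + shift
    affine_transform(m)
  })
}

# Smooth sinusoidal displacement field on a grid: per-component amplitude
# <= amp_mm, wavelength lambda_mm, tapered smoothly to zero within a few
# voxels of the field border so the displacement map stays a contraction
# everywhere (the sampled field is 0 outside its support) and the fixed-point
# inverse converges.
random_sinusoid_field <- function(grid, rng_seed, amp_mm = 1.5,
                                  lambda_mm = 60, taper_voxels = 4) {
  with_seed(rng_seed, {
    idx <- all_voxel_indices(grid$shape)
    pts <- voxel_to_world(idx, grid$affine)
    k <- 2 * pi / lambda_mm
    smoothstep <- function(t) { t <- pmin(pmax(t, 0), 1); t * t * (3 - 2 * t) }
    w <- rep(1, nrow(idx))
    for (ax in 1:3) {
      d <- pmin(idx[, ax], grid$shape[ax] - 1 - idx[, ax])
      w <- w * smoothstep(d / taper_voxels)
    }
    fld <- array(0, c(grid$shape, 3L))
    for (c_i in 1:3) {
      amp <- runif(1, 0.3, 1) * amp_mm
      phase <- runif(3, 0, 2 * pi)
      axis <- sample(1:3, 2)
      u <- amp * sin(k * pts[, axis[1]] + phase[1]) *
                 cos(k * pts[, axis[2]] + phase[2])
      fld[, , , c_i] <- array(u * w, grid$shape)
    }
    displacement_field_transform(fld, grid$affine)
  })
}

#' Generate one synthetic subject: orientation field, ROIs, and transform
#'
#' The subject's anatomy is the template phantom carried through a random
#' template-to-subject map (small affine composed with a smooth sinusoidal
#' displacement field): the VIM centre, tube control points and terminus box
#' are mapped forward and the tube/ellipsoid geometry is rebuilt analytically
#' around them in the subject frame. The returned transform is the exact map
#' that was used, so warping the subject's hotspot back to the template is
#' free of registration error.
#'
#' @param spec a `phantom_spec`.
#' @param subject_seed integer seed for this subject's draws.
#' @param deform generate a deformed subject (`TRUE`) or an identity-
#'   transform copy of the template (`FALSE`).
#' @return List with `field` (`orientation_field`), `vim`, `terminus`
#'   (masks), `template_to_subject` (`ntatlas_transform`) and `subject_id`.
#' @export
make_subject_phantom <- function(spec, subject_seed = spec$rng_seed,
                                 deform = TRUE) {
  grid <- spec$grid
  if (deform) {
    ctr <- as.numeric(spec$vim_center)
    aff <- random_small_affine(ctr, substream_seed(subject_seed, "affine"))
    dfld <- random_sinusoid_field(grid, substream_seed(subject_seed, "field"))
    t2s <- composed_transform(aff, dfld)
  } else {
    t2s <- identity_transform()
  }
  p0 <- as.numeric(xf_forward(t2s, spec$vim_center))
  p1 <- as.numeric(xf_forward(t2s, spec$tube_control))
  term_ctr <- (spec$terminus_lo + spec$terminus_hi) / 2
  p2 <- as.numeric(xf_forward(t2s, term_ctr))
  half <- (spec$terminus_hi - spec$terminus_lo) / 2
  jit <- if (deform)
    with_seed(substream_seed(subject_seed, "shape"),
              list(r = runif(3, 0.9, 1.1), tr = runif(1, 0.9, 1.1)))
  else list(r = c(1, 1, 1), tr = 1)
  geom <- build_phantom_geometry(
    grid, vim_center = p0, vim_radii = spec$vim_radii * jit$r,
    p0 = p0, p1 = p1, p2 = p2,
    tube_radius = spec$tube_radius * jit$tr,
    terminus_lo = p2 - half, terminus_hi = p2 + half,
    kappa = spec$kappa)
  list(field = geom$field, vim = geom$vim, terminus = geom$terminus,
       in_tube = geom$in_tube, template_to_subject = t2s,
       subject_id = sprintf("sub-%04d", subject_seed))
}

#' Track a bank of synthetic subjects and build their hotspots
#'
#' Convenience wrapper: generates `n_subjects` deformed subjects from the
#' spec, runs the tracker in each, and returns `subject_hotspot`s ready for
#' [build_nta()].
#'
#' @param spec a `phantom_spec`.
#' @param n_subjects bank size (the default desk-scale bank is 20).
#' @param params `tracking_params` for the per-subject tracking.
#' @return List of `subject_hotspot` objects.
#' @export
make_subject_bank <- function(spec, n_subjects = 20L,
                              params = tracking_params(
                                samples_per_seed_voxel = 20L,
                                bidirectional = TRUE)) {
  lapply(seq_len(n_subjects), function(i) {
    sseed <- substream_seed(spec$rng_seed, "subject", i)
    ph <- make_subject_phantom(spec, sseed)
    p <- params
    p$rng_seed <- substream_seed(sseed, "track")
    hm <- seed_to_terminus_fractions(ph$field, ph$vim, ph$terminus, p)
    subject_hotspot(hm, ph$template_to_subject, ph$subject_id)
  })
}

# ---- lesions ----------------------------------------------------------------

#' Voxelized ellipsoidal lesion with a known postop-to-preop rigid offset
#'
#' The lesion sits at `center` in preoperative world coordinates; the mask is
#' drawn in the postoperative grid, which is displaced from preop space by
#' the known rigid `postop_offset` (postop -> preop). The voxelized volume
#' matches the analytic ellipsoid volume 4/3 pi abc up to surface
#' discretization.
#'
#' @param center lesion centre in preop world mm.
#' @param radii length-3 ellipsoid radii in mm.
#' @param postop_offset rigid `ntatlas_transform` mapping postop world to
#'   preop world (ground truth; identity by default).
#' @param grid `grid_spec` of the postop image.
#' @return List with `mask` (`ntatlas_mask` on `grid`), `postop_to_preop`
#'   (the supplied rigid), `center_preop` and `analytic_volume_mm3`.
#' @export
make_lesion <- function(center, radii, postop_offset = identity_transform(),
                        grid) {
  center <- as.numeric(center)
  c_post <- as.numeric(xf_inverse(postop_offset, center))
  lo_w <- voxel_to_world(c(0, 0, 0), grid$affine)
  hi_w <- voxel_to_world(grid$shape - 1, grid$affine)
  if (any(c_post - max(radii) < pmin(lo_w, hi_w) - 0.5) ||
      any(c_post + max(radii) > pmax(lo_w, hi_w) + 0.5))
    stop("lesion ellipsoid extends outside the grid", call. = FALSE)
  pts <- voxel_to_world(all_voxel_indices(grid$shape), grid$affine)
  inside <- ellipsoid_inside(pts, c_post, as.numeric(radii))
  if (!any(inside)) stop("lesion contains no voxels at this grid resolution",
                         call. = FALSE)
  list(mask = mask3d(array(as.double(inside), grid$shape), grid$affine),
       postop_to_preop = postop_offset, center_preop = center,
       analytic_volume_mm3 = 4 / 3 * pi * prod(radii))
}

# ---- cohort simulation ------------------------------------------------------

#' Parameters of the simulated patient cohort
#'
#' Effect directions follow the reported clinical findings: larger lesions
#' and lower NTC raise the odds of a "worse" QoL self-assessment and of
#' adverse effects; accumulated dose volume is proportional to lesion volume
#' (about half, in cc) plus noise; subjective tremor suppression is high in
#' the better and worse groups (means 86.8% and 93.2%) and low in the
#' "approximately the same" group (mean 46.7%).
#'
#' @param n_patients cohort size (the reported cohort had 60).
#' @param lesion_volume_median_mm3,lesion_volume_sdlog log-normal lesion
#'   volume distribution (median 120 mm^3 by default).
#' @param placement_jitter_mm per-axis SD of lesion centre jitter around the
#'   patient-space atlas apex.
#' @param adv_factor,adv_noise_cc ADV (cc) = factor x lesion volume (cc) +
#'   Gaussian noise.
#' @param volume_threshold_mm3 generative lesion-volume threshold above which
#'   the odds of a worse outcome jump.
#' @param worse_intercept,worse_beta_threshold,worse_beta_volume,worse_beta_ntc
#'   logistic model of the "worse" outcome: intercept, jump at the volume
#'   threshold, smooth per-mm^3 slope, and NTC coefficient (negative effects
#'   of NTC mean higher NTC protects).
#' @param better_intercept,better_beta_ntc logistic split of the remaining
#'   patients into "better" vs "same".
#' @param suppression_mean,suppression_sd per-QoL-category subjective tremor
#'   suppression (%%), order better / same / worse.
#' @param ae_base_rates named per-AE base probabilities.
#' @param ae_beta_volume,ae_beta_ntc adverse-effect propensity coefficients.
#' @param rng_seed base seed; all stages draw named substreams from it.
#' @return A `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_patients = 60L,
                              lesion_volume_median_mm3 = 120,
                              lesion_volume_sdlog = 0.45,
                              placement_jitter_mm = 1.5,
                              adv_factor = 0.47, adv_noise_cc = 0.008,
                              volume_threshold_mm3 = 127.4,
                              worse_intercept = -2.8,
                              worse_beta_threshold = 2.4,
                              worse_beta_volume = 0.003,
                              worse_beta_ntc = -3.0,
                              better_intercept = 1.0,
                              better_beta_ntc = 2.0,
                              suppression_mean = c(better = 86.8,
                                                   same = 46.7,
                                                   worse = 93.2),
                              suppression_sd = c(better = 19, same = 35,
                                                 worse = 10),
                              ae_base_rates = c(
                                gait_ataxia = 8 / 60,
                                limb_ataxia_weakness = 5 / 60,
                                dysarthria = 4 / 60,
                                taste_smell = 2 / 60,
                                tongue_numbness = 1 / 60,
                                limb_numbness = 1 / 60,
                                dysphagia = 1 / 60,
                                fatigue = 1 / 60,
                                cognitive_behavioral = 4 / 60),
                              ae_beta_volume = 0.012, ae_beta_ntc = -1.2,
                              rng_seed = 1L) {
  stopifnot(n_patients >= 2, lesion_volume_median_mm3 > 0,
            all(ae_base_rates >= 0 & ae_base_rates <= 1))
  structure(as.list(environment()), class = "cohort_sim_params")
}

# Patient-space scoring window: 1 mm isotropic cube centred on a point.
window_grid <- function(center, half_extent_mm = 18, resolution_mm = 1) {
  n <- as.integer(2 * half_extent_mm / resolution_mm + 1)
  aff <- diag(c(resolution_mm, resolution_mm, resolution_mm, 1))
  aff[1:3, 4] <- center - half_extent_mm
  grid_spec(c(n, n, n), aff)
}

atlas_argmax_world <- function(nta) {
  idx <- which(nta$data == max(nta$data), arr.ind = TRUE)[1, , drop = FALSE]
  as.numeric(voxel_to_world(idx - 1, nta$affine))
}

#' Simulate a patient cohort scored through the real patient-fitting path
#'
#' Per patient: a random template-to-patient affine and a small rigid
#' postop-to-preop offset are drawn; an ellipsoidal lesion with log-normal
#' volume is placed with Gaussian jitter around the patient-space atlas
#' apex; the atlas is warped into the patient window, the lesion is
#' coregistered, and the NTC is computed with [compute_ntc()]. QoL, adverse
#' effects, CRST scores and subjective suppression are then drawn from the
#' outcome models. All latent draws are returned for recovery tests.
#'
#' @param params a `cohort_sim_params`.
#' @param nta the normative atlas (`nta_volume`) on the template grid.
#' @return List with `cohort` (data frame in the cohort CSV schema) and
#'   `ground_truth` (per-patient latent values: target volume, jitter,
#'   worse-probability, apex location, ...).
#' @export
simulate_cohort <- function(params, nta) {
  n <- params$n_patients
  apex_t <- atlas_argmax_world(nta)
  meanlog <- log(params$lesion_volume_median_mm3)

  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    lseed <- substream_seed(params$rng_seed, "lesion", i)
    oseed <- substream_seed(params$rng_seed, "outcome", i)

    geom <- with_seed(lseed, {
      t2p <- random_small_affine(apex_t,
                                 substream_seed(lseed, "patient_affine"),
                                 max_rot_deg = 1.5, max_scale = 0.02,
                                 max_shift_mm = 2)
      apex_p <- as.numeric(xf_forward(t2p, apex_t))
      ang <- runif(3, -2, 2) * pi / 180
      rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                     0, 0, 0, 1), 3, 3)
      p2p <- rigid_transform(rz, runif(3, -1.5, 1.5))
      vol_target <- rlnorm(1, meanlog, params$lesion_volume_sdlog)
      r_base <- (3 * vol_target / (4 * pi))^(1 / 3)
      radii <- r_base * c(1.15, 1.0, 1 / 1.15)
      jitter <- rnorm(3, 0, params$placement_jitter_mm)
      list(t2p = t2p, apex_p = apex_p, p2p = p2p, vol_target = vol_target,
           radii = radii, jitter = jitter)
    })

    preop <- window_grid(geom$apex_p)
    spaces <- patient_spaces(preop_grid = preop, postop_grid = preop,
                             template_to_patient = geom$t2p,
                             postop_to_preop = geom$p2p)
    les <- make_lesion(geom$apex_p + geom$jitter, geom$radii,
                       postop_offset = geom$p2p, grid = preop)
    pnta <- fit_nta_to_patient(nta, spaces)
    lesion_pre <- coregister_lesion(les$mask, spaces)
    score <- compute_ntc(pnta, lesion_pre,
                         patient_id = sprintf("pt-%03d", i))
    vol <- score$lesion_volume_mm3
    ntc <- score$ntc

    out <- with_seed(oseed, {
      eta_w <- params$worse_intercept +
        params$worse_beta_threshold * (vol > params$volume_threshold_mm3) +
        params$worse_beta_volume * (vol - params$volume_threshold_mm3) +
        params$worse_beta_ntc * (ntc - 0.5)
      p_worse <- stats::plogis(eta_w)
      qol <- if (runif(1) < p_worse) "worse" else {
        p_better <- stats::plogis(params$better_intercept +
                                    params$better_beta_ntc * (ntc - 0.5))
        if (runif(1) < p_better) "better" else "same"
      }
      supp <- min(100, max(0, rnorm(1, params$suppression_mean[[qol]],
                                    params$suppression_sd[[qol]])))
      eta_ae <- params$ae_beta_volume * (vol - params$lesion_volume_median_mm3) +
        params$ae_beta_ntc * (ntc - 0.5)
      p_ae <- stats::plogis(stats::qlogis(pmin(pmax(params$ae_base_rates,
                                                    1e-4), 1 - 1e-4)) + eta_ae)
      ae <- stats::setNames(runif(length(p_ae)) < p_ae, names(p_ae))
      persistent <- any(ae) && runif(1) < stats::plogis(stats::qlogis(0.35) +
                                                          eta_ae)
      crst_a_pre <- max(4, round(rnorm(1, 18, 4)))
      crst_b_pre <- max(2, round(rnorm(1, 12, 3)))
      crst_c_pre <- max(2, round(rnorm(1, 10, 3)))
      red <- min(0.95, max(0.05, supp / 100 + rnorm(1, 0, 0.1)))
      list(qol = qol, p_worse = p_worse, supp = supp, ae = ae,
           persistent = persistent,
           crst = c(a_pre = crst_a_pre, a_post = round(crst_a_pre * (1 - red)),
                    b_pre = crst_b_pre, b_post = round(crst_b_pre * (1 - red)),
                    c_pre = crst_c_pre, c_post = round(crst_c_pre * (1 - red))),
           sdr = min(0.9, max(0.3, rnorm(1, 0.58, 0.1))),
           followup = max(90, round(rnorm(1, 405, 100))))
    })

    adv <- with_seed(substream_seed(params$rng_seed, "adv", i),
                     max(0.001, params$adv_factor * vol / 1000 +
                           rnorm(1, 0, params$adv_noise_cc)))

    rows[[i]] <- data.frame(
      id = score$patient_id, qol = out$qol,
      crst_a_pre = out$crst[["a_pre"]], crst_a_post = out$crst[["a_post"]],
      crst_b_pre = out$crst[["b_pre"]], crst_b_post = out$crst[["b_post"]],
      crst_c_pre = out$crst[["c_pre"]], crst_c_post = out$crst[["c_post"]],
      subjective_suppression_pct = round(out$supp, 1),
      t(setNames(as.integer(out$ae), paste0("ae_", names(out$ae)))),
      persistent_ae = as.integer(out$persistent),
      lesion_volume_mm3 = round(vol, 3), adv_cc = round(adv, 5),
      ntc = round(ntc, 3), sdr = round(out$sdr, 3),
      followup_days = out$followup)
    truth[[i]] <- list(id = score$patient_id,
                       target_volume_mm3 = geom$vol_target,
                       measured_volume_mm3 = vol, ntc = ntc,
                       jitter_mm = geom$jitter, apex_patient = geom$apex_p,
                       p_worse = out$p_worse)
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  list(cohort = cohort, ground_truth = truth,
       generative_threshold_mm3 = params$volume_threshold_mm3)
}
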