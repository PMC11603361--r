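# Pipeline surface: one structured config drives the synthetic demo stages
# (atlas building, cohort simulation, lesion scoring, cohort analysis), with
# deterministic outputs for fixed seeds and a JSON provenance sidecar next to
# every artifact. A thin command-line wrapper lives in inst/cli/ntapipe.R.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed base seed recorded in every output; all stage seeds derive
#'   from it.
#' @param n_subjects atlas bank size.
#' @param n_patients simulated cohort size.
#' @param samples_per_seed_voxel tracker samples per seed voxel.
#' @param hot_fraction threshold defining the atlas's "hottest voxels" for
#'   the medial-apex target.
#' @param cutoffs operating cutoffs for [classify_by_cutoffs()].
#' @param atlas_path,cohort_path optional existing artifact paths consumed by
#'   the `score-lesion`, `fit-patient` and `analyze-cohort` commands.
#' @param lesion_path,preop_ref_path,transform_path inputs for
#'   `score-lesion`/`fit-patient` (NIfTI lesion, NIfTI preop grid reference,
#'   JSON transform).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("ntatlas-run-"), seed = 1L,
                            n_subjects = 8L, n_patients = 60L,
                            samples_per_seed_voxel = 20L,
                            hot_fraction = 0.9, cutoffs = ntc_cutoffs(),
                            atlas_path = NULL, cohort_path = NULL,
                            lesion_path = NULL, preop_ref_path = NULL,
                            transform_path = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        null = "null", force = TRUE)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

write_provenance <- function(path, config, extra = list()) {
  side <- paste0(path, ".prov.json")
  jsonlite::write_json(c(list(config_hash = config_hash(config),
                              seed = config$seed,
                              package = "ntatlas",
                              version = as.character(
                                utils::packageVersion("ntatlas"))),
                         extra),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

need_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing_input: ", what, " (", if (is.null(path)) "not set"
         else path, ")", call. = FALSE)
  path
}

#' Run a pipeline command
#'
#' Commands: `build-atlas` (synthetic subject bank, tracker, atlas NIfTI +
#' JSON sidecar), `simulate` (cohort CSV + ground-truth JSON from an atlas),
#' `fit-patient` (warp atlas into a patient grid), `score-lesion` (NTC of a
#' lesion NIfTI against a patient-fit atlas; JSON result + appended CSV row),
#' `analyze-cohort` (ROC/cutoff/group-test/AE JSON report from a cohort CSV)
#' and `demo` (build-atlas, simulate, analyze-cohort chained). Outputs are
#' deterministic for a fixed config; partial outputs are removed on failure.
#'
#' @param config a `pipeline_config`.
#' @param command one of the commands above.
#' @return Invisibly, a list of artifact paths (plus the main in-memory
#'   result for programmatic use).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         command = c("demo", "build-atlas", "simulate",
                                     "fit-patient", "score-lesion",
                                     "analyze-cohort")) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  on.exit({
    if (!is.null(attr(made, "failed")))
      unlink(made)
  })
  note <- function(p) { made <<- c(made, p); p }
  res <- tryCatch(
    switch(command,
      "build-atlas" = pipe_build_atlas(config, note),
      "simulate" = pipe_simulate(config, note),
      "fit-patient" = pipe_fit_patient(config, note),
      "score-lesion" = pipe_score_lesion(config, note),
      "analyze-cohort" = pipe_analyze(config, note),
      "demo" = pipe_demo(config, note)),
    error = function(e) {
      attr(made, "failed") <- TRUE
      unlink(made)
      stop(e)
    })
  invisible(res)
}

pipe_build_atlas <- function(config, note) {
  spec <- phantom_spec(rng_seed = substream_seed(config$seed, "bank"))
  bank <- make_subject_bank(
    spec, n_subjects = config$n_subjects,
    params = tracking_params(
      samples_per_seed_voxel = config$samples_per_seed_voxel,
      bidirectional = TRUE))
  nta <- build_nta(bank, spec$grid)
  apex <- medial_apex(nta, config$hot_fraction)
  atlas_path <- note(file.path(config$out_dir, "nta.nii.gz"))
  write_volume(nta, atlas_path)
  side <- note(file.path(config$out_dir, "nta.json"))
  jsonlite::write_json(list(n_subjects = attr(nta, "n_subjects"),
                            pre_norm_max = attr(nta, "pre_norm_max"),
                            hot_fraction = config$hot_fraction,
                            medial_apex = as.numeric(apex$point)),
                       side, auto_unbox = TRUE, digits = NA)
  write_provenance(atlas_path, config)
  list(paths = c(atlas = atlas_path, sidecar = side), nta = nta,
       medial_apex = apex)
}

load_atlas <- function(config) {
  if (!is.null(config$atlas_path)) {
    v <- read_volume(need_input(config$atlas_path, "atlas NIfTI"))
    max_normalize(v)
  } else {
    pipe_build_atlas(config, function(p) p)$nta
  }
}

pipe_simulate <- function(config, note, nta = NULL) {
  if (is.null(nta)) nta <- load_atlas(config)
  sim <- simulate_cohort(
    cohort_sim_params(n_patients = config$n_patients,
                      rng_seed = substream_seed(config$seed, "cohort")),
    nta)
  cohort_path <- note(file.path(config$out_dir, "cohort.csv"))
  write_cohort_csv(sim$cohort, cohort_path)
  gt_path <- note(file.path(config$out_dir, "ground_truth.json"))
  jsonlite::write_json(sim$ground_truth, gt_path, auto_unbox = TRUE,
                       digits = NA)
  write_provenance(cohort_path, config)
  list(paths = c(cohort = cohort_path, ground_truth = gt_path), sim = sim)
}

read_patient_spaces <- function(config, preop) {
  t2p <- if (is.null(config$transform_path)) identity_transform()
         else read_transform_json(need_input(config$transform_path,
                                             "transform JSON"))
  patient_spaces(preop_grid = grid_of(preop), template_to_patient = t2p)
}

pipe_fit_patient <- function(config, note) {
  nta <- load_atlas(config)
  preop <- read_volume(need_input(config$preop_ref_path,
                                  "preop grid reference NIfTI"))
  spaces <- read_patient_spaces(config, preop)
  fit <- fit_nta_to_patient(nta, spaces)
  out <- note(file.path(config$out_dir, "nta_patient.nii.gz"))
  write_volume(fit, out)
  write_provenance(out, config)
  list(paths = c(patient_atlas = out), patient_nta = fit)
}

pipe_score_lesion <- function(config, note) {
  nta <- load_atlas(config)
  preop <- read_volume(need_input(config$preop_ref_path,
                                  "preop grid reference NIfTI"))
  lesion <- read_volume(need_input(config$lesion_path, "lesion NIfTI"),
                        as_mask = TRUE)
  spaces <- read_patient_spaces(config, preop)
  fit <- fit_nta_to_patient(nta, spaces)
  lesion_pre <- coregister_lesion(lesion, spaces)
  res <- lesion_report(fit, lesion_pre, patient_id = basename(config$lesion_path))
  out <- note(file.path(config$out_dir, "ntc_result.json"))
  jsonlite::write_json(unclass(res), out, auto_unbox = TRUE, digits = NA)
  csv <- file.path(config$out_dir, "ntc_scores.csv")
  row <- data.frame(patient_id = res$patient_id, ntc = res$ntc,
                    lesion_voxels = res$lesion_voxels,
                    lesion_volume_mm3 = res$lesion_volume_mm3)
  utils::write.table(row, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv))
  write_provenance(out, config)
  list(paths = c(result = out, scores = csv), result = res)
}

pipe_analyze <- function(config, note, cohort = NULL) {
  if (is.null(cohort))
    cohort <- read_cohort_csv(need_input(config$cohort_path, "cohort CSV"))
  lab <- binarize_qol(cohort$qol) == "better_same"
  roc_of <- function(col, direction) {
    ok <- !is.na(cohort[[col]])
    if (!any(lab[ok]) || all(lab[ok]))    # one-class cohort: no ROC
      return(list(n = sum(ok), note = "single outcome class; ROC undefined"))
    r <- roc_youden(cohort[[col]][ok], lab[ok], direction)
    list(n = sum(ok), auc = r$auc, youden_j = r$youden_j,
         sensitivity = r$sensitivity, specificity = r$specificity,
         optimal_cutoff = r$optimal_cutoff, direction = direction)
  }
  rocs <- list(lesion_volume_mm3 = roc_of("lesion_volume_mm3",
                                          "low_is_positive"),
               adv_cc = roc_of("adv_cc", "low_is_positive"),
               ntc = roc_of("ntc", "high_is_positive"))
  groups <- split(cohort$subjective_suppression_pct, cohort$qol)
  groups <- groups[vapply(groups, length, 0L) > 0]
  kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NULL
  aes <- ae_summary(cohort)
  cls <- vapply(seq_len(nrow(cohort)), function(i)
    isTRUE(classify_by_cutoffs(cohort[i, ], config$cutoffs)$all_favorable),
    TRUE)
  report <- list(n = nrow(cohort), roc = rocs,
                 suppression_kruskal_wallis = if (is.null(kw)) NULL
                   else unclass(kw),
                 ae_summary = aes,
                 n_all_favorable = sum(cls))
  out <- note(file.path(config$out_dir, "cohort_report.json"))
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  write_provenance(out, config)
  list(paths = c(report = out), report = report)
}

pipe_demo <- function(config, note) {
  atlas <- pipe_build_atlas(config, note)
  sim <- pipe_simulate(config, note, nta = atlas$nta)
  analysis <- pipe_analyze(config, note, cohort = sim$sim$cohort)
  list(paths = c(atlas$paths, sim$paths, analysis$paths),
       nta = atlas$nta, cohort = sim$sim$cohort,
       report = analysis$report)
}
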