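# Cohort-level outcome statistics: QoL binarization, ROC curves with
# Youden-optimal cutoffs, group tests, association tests, trend fits, and
# adverse-event summaries.

ae_names <- c("gait_ataxia", "limb_ataxia_weakness", "dysarthria",
              "taste_smell", "tongue_numbness", "limb_numbness",
              "dysphagia", "fatigue", "cognitive_behavioral")

cohort_columns <- function() {
  c("id", "qol", "crst_a_pre", "crst_a_post", "crst_b_pre", "crst_b_post",
    "crst_c_pre", "crst_c_post", "subjective_suppression_pct",
    paste0("ae_", ae_names), "persistent_ae", "lesion_volume_mm3",
    "adv_cc", "ntc", "sdr", "followup_days")
}

#' Binarize quality-of-life self-assessment
#'
#' Patients rating themselves "better" or "approximately the same" form one
#' group; "worse" stands alone.
#'
#' @param qol character vector with values in `better`, `same`, `worse`.
#' @return Factor with levels `better_same`, `worse`.
#' @export
binarize_qol <- function(qol) {
  if (any(is.na(qol))) stop("missing QoL rating", call. = FALSE)
  if (!all(qol %in% c("better", "same", "worse")))
    stop("QoL ratings must be 'better', 'same' or 'worse'", call. = FALSE)
  factor(ifelse(qol == "worse", "worse", "better_same"),
         levels = c("better_same", "worse"))
}

#' Youden's J from sensitivity and specificity
#'
#' @param sensitivity,specificity values in [0, 1].
#' @return J = sensitivity + specificity - 1.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sensitivity + specificity - 1
}

#' ROC curve with Youden-optimal cutoff
#'
#' Sweeps cutoffs at the midpoints between consecutive observed values (plus
#' one beyond each extreme), classifying by a strict inequality in the stated
#' favorable direction: `low_is_positive` predicts the positive class when
#' `value < cutoff`, `high_is_positive` when `value > cutoff`. AUC is the
#' trapezoid area under the empirical ROC, which equals the rank
#' (Mann-Whitney) statistic with half credit for ties. The optimal cutoff
#' maximises J = sensitivity + specificity - 1; ties are broken by higher
#' specificity, then by the more extreme cutoff.
#'
#' @param values numeric predictor, no missing values.
#' @param labels logical (or 0/1) vector: `TRUE` marks the positive class.
#'   Both classes must be present.
#' @param direction `"low_is_positive"` or `"high_is_positive"`.
#' @return A `roc_result`: list with `direction`, `thresholds`, `tpr`,
#'   `fpr`, `auc`, `optimal_cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`, `n_positive`, `n_negative`.
#' @export
roc_youden <- function(values, labels,
                       direction = c("low_is_positive", "high_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels))
    stop("missing values are not allowed; drop incomplete records first",
         call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  # score: larger = more evidence for the positive class
  score <- if (direction == "high_is_positive") values else -values
  npos <- sum(labels); nneg <- sum(!labels)

  # empirical ROC vertices over unique scores (descending) -> trapezoid AUC
  u <- sort(unique(score), decreasing = TRUE)
  tp <- cumsum(vapply(u, function(t) sum(labels & score == t), 0))
  fp <- cumsum(vapply(u, function(t) sum(!labels & score == t), 0))
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  # candidate cutoffs: midpoints between consecutive unique scores, plus one
  # beyond each extreme; classify positive iff score > cutoff
  cand <- c(u[1] + 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] - 1)
  sens <- vapply(cand, function(ct) sum(labels & score > ct) / npos, 0)
  spec <- vapply(cand, function(ct) sum(!labels & score <= ct) / nneg, 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[spec[best] == max(spec[best])]
  if (length(best) > 1) best <- best[which.max(cand[best])]  # most extreme
  cutoff <- cand[best]
  if (direction == "low_is_positive") cutoff <- -cutoff

  structure(list(direction = direction,
                 thresholds = if (direction == "low_is_positive") -cand
                              else cand,
                 tpr = tpr, fpr = fpr, auc = auc,
                 optimal_cutoff = cutoff, youden_j = j[best],
                 sensitivity = sens[best], specificity = spec[best],
                 n_positive = npos, n_negative = nneg),
            class = "roc_result")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H with a chi-square approximation on k - 1 degrees of
#' freedom (delegates to [stats::kruskal.test()]). `pad_to` optionally
#' replicates the reported analysis convention of appending the group mean to
#' any group below a minimum size before testing; it is off by default
#' because padding manufactures data.
#'
#' @param groups nonempty list of nonempty numeric vectors.
#' @param pad_to if not `NULL`, minimum group size; smaller groups have their
#'   mean appended until they reach it.
#' @return A `group_test_result`: list with `statistic` (H), `dof`,
#'   `p_value`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups, pad_to = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) == 0L))
    stop("empty group", call. = FALSE)
  if (!is.null(pad_to)) {
    groups <- lapply(groups, function(g) {
      while (length(g) < pad_to) g <- c(g, mean(g))
      g
    })
  }
  sizes <- vapply(groups, length, 0L)
  x <- unlist(groups)
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, dof = length(groups) - 1L, p_value = 1,
                group_sizes = sizes)
  } else {
    g <- factor(rep(seq_along(groups), sizes))
    kt <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic), dof = unname(kt$parameter),
                p_value = kt$p.value, group_sizes = sizes)
  }
  structure(res, class = "group_test_result")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities (margins fixed) of every table at
#' most as probable as the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(table) == 0) stop("table has no observations", call. = FALSE)
  stats::fisher.test(table)$p.value
}

#' Ordinary least-squares trend fit
#'
#' @param x,y numeric vectors, length >= 3, `x` not constant.
#' @return List with `slope`, `intercept`, `r2` (squared Pearson
#'   correlation).
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit)$r.squared))
}

#' Reported operating cutoffs for favorable QoL outcome
#'
#' Lesion volume below 127.4 mm^3, accumulated dose volume below 0.0594 cc,
#' and NTC above 0.544 select for the better/same QoL outcome.
#'
#' @return Named list of the three cutoffs.
#' @export
ntc_cutoffs <- function() {
  list(lesion_mm3 = 127.4, adv_cc = 0.0594, ntc = 0.544)
}

#' Classify a patient's lesion metrics against the operating cutoffs
#'
#' All comparisons are strict: a lesion of exactly 127.4 mm^3, an ADV of
#' exactly 0.0594 cc, or an NTC of exactly 0.544 is unfavorable.
#'
#' @param record list or one-row data frame with any of `lesion_volume_mm3`,
#'   `adv_cc`, `ntc` (missing entries allowed, but not all).
#' @param cutoffs named list as returned by [ntc_cutoffs()].
#' @return List with per-variable logical `favorable` flags (NA when the
#'   variable is missing) and `all_favorable`.
#' @export
classify_by_cutoffs <- function(record, cutoffs = ntc_cutoffs()) {
  val <- function(name) {
    v <- record[[name]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
  }
  lesion <- val("lesion_volume_mm3"); adv <- val("adv_cc"); ntc <- val("ntc")
  if (is.na(lesion) && is.na(adv) && is.na(ntc))
    stop("no lesion metric present in record", call. = FALSE)
  fav <- list(
    lesion = if (is.na(lesion)) NA else lesion < cutoffs$lesion_mm3,
    adv = if (is.na(adv)) NA else adv < cutoffs$adv_cc,
    ntc = if (is.na(ntc)) NA else ntc > cutoffs$ntc)
  fav$all_favorable <- all(unlist(fav[1:3]), na.rm = TRUE)  # over present vars
  fav
}

#' Adverse-event summary ranked by worse-QoL fraction
#'
#' For every adverse effect experienced by at least one patient: how many
#' patients had it and what fraction of those rated their QoL better, same or
#' worse, ranked by the worse fraction (descending).
#'
#' @param cohort data frame with a `qol` column and logical/0-1 `ae_*`
#'   columns.
#' @return Data frame with columns `ae`, `n`, `frac_better`, `frac_same`,
#'   `frac_worse`.
#' @export
ae_summary <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  cols <- grep("^ae_", names(cohort), value = TRUE)
  rows <- lapply(cols, function(cn) {
    has <- as.logical(cohort[[cn]])
    n <- sum(has)
    if (n == 0L) return(NULL)
    q <- cohort$qol[has]
    data.frame(ae = sub("^ae_", "", cn), n = n,
               frac_better = mean(q == "better"),
               frac_same = mean(q == "same"),
               frac_worse = mean(q == "worse"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(ae = character(), n = integer(),
                      frac_better = numeric(), frac_same = numeric(),
                      frac_worse = numeric()))
  out[order(-out$frac_worse, -out$n), , drop = FALSE]
}

#' Read / write the cohort CSV
#'
#' The schema is one row per patient with columns `id`, `qol`
#' (better/same/worse), CRST sub-scores pre/post (`crst_a_pre`, ...),
#' `subjective_suppression_pct`, one 0/1 column per adverse effect
#' (`ae_gait_ataxia`, `ae_limb_ataxia_weakness`, `ae_dysarthria`,
#' `ae_taste_smell`, `ae_tongue_numbness`, `ae_limb_numbness`,
#' `ae_dysphagia`, `ae_fatigue`, `ae_cognitive_behavioral`),
#' `persistent_ae`, `lesion_volume_mm3`, `adv_cc`, `ntc`, `sdr`,
#' `followup_days`.
#'
#' @param path CSV path.
#' @return `read_cohort_csv`: a data frame; `write_cohort_csv`: `path`,
#'   invisibly.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "qol"), names(df))
  if (length(missing))
    stop("cohort CSV lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
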