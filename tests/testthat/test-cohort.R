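# independent rank-based AUC oracle: concordance fraction with half credit
# for ties (Mann-Whitney)
mw_auc <- function(score, pos) {
  s1 <- score[pos]; s0 <- score[!pos]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("QoL binarization merges better and same", {
  expect_equal(as.character(binarize_qol(c("better", "same", "worse"))),
               c("better_same", "better_same", "worse"))
  expect_error(binarize_qol(c("better", NA)), "missing")
  expect_error(binarize_qol("meh"), "must be")
})

test_that("Youden index reproduces the published operating points", {
  expect_equal(youden_index(0.745, 0.889), 0.634)
  expect_equal(youden_index(0.549, 0.889), 0.438)
  expect_equal(youden_index(1, 1), 1)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("ROC handles perfect separation and pure noise", {
  v <- c(1:10, 101:110)
  lab <- rep(c(TRUE, FALSE), each = 10)
  r <- roc_youden(v, lab, "low_is_positive")
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_true(r$optimal_cutoff > 10 && r$optimal_cutoff < 101)

  set.seed(100)
  v2 <- rnorm(2000); lab2 <- runif(2000) < 0.5
  r2 <- roc_youden(v2, lab2, "high_is_positive")
  n1 <- sum(lab2); n2 <- sum(!lab2)
  expect_lt(abs(r2$auc - 0.5), 3 * sqrt((n1 + n2 + 1) / (12 * n1 * n2)))
  expect_error(roc_youden(v2, rep(TRUE, 2000)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic to 1e-12", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    v <- if (i %% 3 == 0) sample(1:8, n, replace = TRUE)   # heavy ties
         else rnorm(n)
    lab <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(lab) || all(lab)) next
    dir <- sample(c("low_is_positive", "high_is_positive"), 1)
    r <- roc_youden(v, lab, dir)
    score <- if (dir == "high_is_positive") v else -v
    expect_equal(r$auc, mw_auc(score, lab), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips with direction", {
  set.seed(77)
  v <- rlnorm(150); lab <- runif(150) < plogis(scale(log(v)))
  r <- roc_youden(v, lab, "high_is_positive")
  r_mono <- roc_youden(qlogis(v / (max(v) + 1)), lab, "high_is_positive")
  expect_equal(r_mono$auc, r$auc, tolerance = 1e-12)
  r_flip <- roc_youden(v, lab, "low_is_positive")
  expect_equal(r_flip$auc, 1 - r$auc, tolerance = 1e-12)
  expect_gte(r$youden_j, -1); expect_lte(r$youden_j, 1)
})

test_that("ROC agrees with pROC on AUC and on the Youden-optimal operating point", {
  skip_if_not_installed("pROC")
  set.seed(123)
  v <- c(rnorm(60, 1), rnorm(40))
  lab <- rep(c(TRUE, FALSE), c(60, 40))
  r <- roc_youden(v, lab, "high_is_positive")
  pr <- pROC::roc(response = lab, predictor = v, direction = "<",
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  best <- pROC::coords(pr, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"))
  expect_equal(r$optimal_cutoff, best$threshold, tolerance = 1e-9)
  expect_equal(r$sensitivity, best$sensitivity, tolerance = 1e-12)
  expect_equal(r$specificity, best$specificity, tolerance = 1e-12)
})

test_that("with clean separation the optimal cutoff lies between the straddling observations", {
  set.seed(31)
  vstar <- 127.4
  v <- c(runif(40, 60, vstar - 3), runif(25, vstar + 3, 250))
  lab <- v < vstar
  r <- roc_youden(v, lab, "low_is_positive")
  lo <- max(v[v < vstar]); hi <- min(v[v > vstar])
  expect_gt(r$optimal_cutoff, lo)
  expect_lt(r$optimal_cutoff, hi)
})

test_that("Kruskal-Wallis matches a hand-coded tie-corrected oracle", {
  kw_oracle <- function(groups) {
    x <- unlist(groups); n <- length(x); r <- rank(x)
    sizes <- vapply(groups, length, 0L)
    g <- rep(seq_along(groups), sizes)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / sizes) - 3 * (n + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  g1 <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(kruskal_wallis(g1)$statistic, kw_oracle(g1),
               tolerance = 1e-10)
  set.seed(8)
  g2 <- list(sample(1:5, 12, TRUE), sample(1:5, 9, TRUE),
             sample(1:5, 15, TRUE))                      # heavy ties
  res2 <- kruskal_wallis(g2)
  expect_equal(res2$statistic, kw_oracle(g2), tolerance = 1e-10)
  expect_equal(res2$dof, 2)
  expect_equal(res2$p_value,
               stats::pchisq(res2$statistic, 2, lower.tail = FALSE))

  same <- list(c(2, 2, 2), c(2, 2))
  expect_equal(kruskal_wallis(same)$statistic, 0)
  expect_equal(kruskal_wallis(same)$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(14)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(10, -0.5))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x)))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("the opt-in mean-padding rule appends group means up to the minimum size", {
  g <- list(c(90, 95, 92, 96), c(80, 85, 88, 82, 84, 86))
  res <- kruskal_wallis(g, pad_to = 5)
  expect_equal(res$group_sizes, c(5L, 6L))
  oracle <- kruskal_wallis(list(c(90, 95, 92, 96, mean(c(90, 95, 92, 96))),
                                g[[2]]))
  expect_equal(res$statistic, oracle$statistic)
})

test_that("Fisher exact p agrees with exhaustive hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(a)
      dhyper(a, r1, r2, c1), 0)
    p_obs <- dhyper(tab[1, 1], r1, r2, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               enum_fisher(matrix(c(10, 0, 0, 10), 2)), tolerance = 1e-10)
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    expect_equal(fisher_exact_2x2(tab), enum_fisher(tab), tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab)), fisher_exact_2x2(tab))
    expect_equal(fisher_exact_2x2(tab[2:1, ]), fisher_exact_2x2(tab))
    expect_equal(fisher_exact_2x2(tab[, 2:1]), fisher_exact_2x2(tab))
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)), "nonnegative")
})

test_that("least-squares trend fit matches the algebraic oracle", {
  x <- seq(0, 10, length.out = 25)
  fit <- linear_r2(x, 2 * x + 1)
  expect_equal(fit$slope, 2); expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)

  set.seed(44)
  x2 <- rnorm(1e4); y2 <- rnorm(1e4)
  expect_lt(linear_r2(x2, y2)$r2, 0.01)

  y3 <- 0.4 * x2 + rnorm(1e4)
  f3 <- linear_r2(x2, y3)
  ss_res <- sum((y3 - (f3$intercept + f3$slope * x2))^2)
  ss_tot <- sum((y3 - mean(y3))^2)
  expect_equal(f3$r2, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_error(linear_r2(rep(1, 5), 1:5), "constant")
})

test_that("cutoff classification uses strict inequalities in the favorable directions", {
  fav <- classify_by_cutoffs(list(lesion_volume_mm3 = 100, adv_cc = 0.05,
                                  ntc = 0.6))
  expect_true(fav$lesion); expect_true(fav$adv); expect_true(fav$ntc)
  expect_true(fav$all_favorable)

  expect_false(classify_by_cutoffs(list(lesion_volume_mm3 = 127.4))$lesion)
  expect_false(classify_by_cutoffs(list(adv_cc = 0.0594))$adv)
  expect_false(classify_by_cutoffs(list(ntc = 0.544))$ntc)
  expect_true(classify_by_cutoffs(list(ntc = 0.545))$ntc)
  expect_error(classify_by_cutoffs(list()), "no lesion metric")
})

test_that("adverse-event summary tallies and ranks by worse fraction", {
  co <- data.frame(
    qol = c("worse", "worse", "worse", "better", "same", "better", "worse"),
    ae_dysarthria = c(1, 1, 1, 1, 0, 0, 0),
    ae_gait_ataxia = c(1, 0, 0, 1, 1, 1, 0),
    ae_fatigue = 0)
  s <- ae_summary(co)
  expect_equal(s$ae, c("dysarthria", "gait_ataxia"))  # fatigue unseen: dropped
  expect_equal(s$frac_worse[s$ae == "dysarthria"], 0.75)
  expect_equal(s$n[s$ae == "gait_ataxia"], 4)
  expect_equal(s$frac_worse[s$ae == "gait_ataxia"], 0.25)
  # brute-force tally on a random cohort
  set.seed(61)
  co2 <- data.frame(qol = sample(c("better", "same", "worse"), 40, TRUE),
                    ae_a = rbinom(40, 1, 0.3), ae_b = rbinom(40, 1, 0.5))
  s2 <- ae_summary(co2)
  for (nm in c("a", "b")) {
    has <- co2[[paste0("ae_", nm)]] == 1
    expect_equal(s2$frac_worse[s2$ae == nm],
                 sum(co2$qol[has] == "worse") / sum(has))
  }
})

test_that("the cohort CSV round-trips through read/write", {
  nta <- peak_atlas()
  sim <- simulate_cohort(cohort_sim_params(n_patients = 6, rng_seed = 3), nta)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, f)
  back <- read_cohort_csv(f)
  expect_equal(back, sim$cohort)
  expect_error(read_cohort_csv({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), f2, row.names = FALSE)
    f2
  }), "required columns")
})
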