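test_that("Welch comparison matches hand computation and degenerates correctly", {
  gc <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$t, -3.674235, tolerance = 1e-6)
  expect_equal(gc$df, 4, tolerance = 1e-9)
  expect_equal(gc$p, 0.02131164, tolerance = 1e-6)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("group separation power matches the published S1 dural volume contrast", {
  # at the printed S1 dural volume parameters and n = 63/81 the group
  # difference is essentially always significant
  specs <- default_group_specs()
  sig <- vapply(1:200, function(s) {
    coh <- sample_cohort(specs$mfs, specs$non_mfs, 63, 81, seed = s)
    welch_t(coh$dural_volume_S1[coh$group == "MFS"],
            coh$dural_volume_S1[coh$group == "nonMFS"])$p < 0.001
  }, TRUE)
  expect_gte(mean(sig), 0.95)
})

test_that("empirical AUC equals brute-force pair counting, including ties", {
  expect_equal(auc_empirical(c(3, 4), c(1, 2))$auc, 1.0)
  expect_equal(auc_empirical(c(0.3, 0.1), c(0.2, 0.2))$auc, 0.5)
  for (s in 1:20) {
    set.seed(s)
    n1 <- sample(2:200, 1)
    n0 <- sample(2:200, 1)
    ca <- round(rnorm(n1, 0.5), 1)  # rounding forces ties
    co <- round(rnorm(n0), 1)
    est <- auc_empirical(ca, co)
    expect_equal(est$auc, auc_bruteforce(ca, co), tolerance = 1e-12)
    expect_true(est$ci_low >= 0 && est$ci_low <= est$auc &&
                  est$auc <= est$ci_high && est$ci_high <= 1)
  }
  expect_error(auc_empirical(numeric(0), 1), "non-empty")
})

test_that("closed-form AUC reproduces the binormal formula and its symmetries", {
  expect_equal(auc_closed_form(0.41, 0.28, 0.14, 0.06, "normal"),
               pnorm(0.27 / sqrt(0.28^2 + 0.06^2)))
  expect_equal(auc_closed_form(1, 1, 1, 1, "normal"), 0.5)
  expect_equal(auc_closed_form(0.5, 0.2, 0.5, 0.2, "lognormal"), 0.5)
  a <- auc_closed_form(0.41, 0.28, 0.14, 0.06, "normal")
  b <- auc_closed_form(0.14, 0.06, 0.41, 0.28, "normal")
  expect_equal(a + b, 1)
  expect_error(auc_closed_form(1, 0, 1, 1, "normal"), "sds")
  expect_error(auc_closed_form(1, 1, 1, 1, "gamma"))
})

test_that("closed-form AUC agrees with large-sample empirical AUC", {
  set.seed(11)
  ca <- rlnorm(40000, log(0.41), 0.5)
  co <- rlnorm(40000, log(0.14), 0.5)
  m1 <- mean(ca); s1 <- sd(ca); m0 <- mean(co); s0 <- sd(co)
  expect_equal(auc_closed_form(m1, s1, m0, s0, "lognormal"),
               auc_bruteforce(ca[1:2000], co[1:2000]), tolerance = 0.02)
})

test_that("Youden scan finds the exhaustive-search optimum with low-cutoff ties", {
  cp <- youden_cutoff(c(2, 3, 4), c(1, 2))
  expect_equal(cp$cutoff, 3)
  expect_equal(cp$sensitivity, 2 / 3)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$youden_j, 2 / 3)
  expect_equal(cp$ppv, 1)
  expect_equal(cp$npv, 2 / 3)
  expect_equal(youden_cutoff(c(10, 11), c(1, 2))$youden_j, 1)
  expect_equal(youden_cutoff(c(5, 5), c(5, 5))$youden_j, 0)
  # exhaustive verification on random instances
  for (s in 1:10) {
    set.seed(s)
    ca <- round(rnorm(30, 1), 1); co <- round(rnorm(40), 1)
    cp <- youden_cutoff(ca, co)
    cand <- sort(unique(c(ca, co)))
    js <- vapply(cand, function(ct) mean(ca >= ct) + mean(co < ct) - 1, 0)
    expect_equal(cp$youden_j, max(js))
    expect_equal(cp$cutoff, cand[which.max(js)])  # ties -> lowest cutoff
  }
})

test_that("McNemar exact binomial and chi-square variants are correct", {
  expect_equal(mcnemar(10, 2)$p, 2 * (1 + 12 + 66) / 4096)
  expect_equal(mcnemar(8, 0)$p, 2 / 256)
  expect_equal(mcnemar(7, 7)$p, 1)
  expect_equal(mcnemar(0, 0)$p, 1)
  m <- mcnemar(10, 2, method = "chi2_cc")
  expect_equal(m$statistic, (abs(10 - 2) - 1)^2 / 12)
  expect_equal(m$p, pchisq(49 / 12, 1, lower.tail = FALSE))
  expect_error(mcnemar(-1, 2))
})

test_that("AUC and Youden classification are invariant under monotone transforms", {
  set.seed(3)
  ca <- rlnorm(63, -1, 0.6); co <- rlnorm(81, -2, 0.4)
  f <- function(x) exp(2 * x + 1)
  expect_equal(auc_empirical(ca, co)$auc, auc_empirical(f(ca), f(co))$auc)
  c1 <- youden_cutoff(ca, co); c2 <- youden_cutoff(f(ca), f(co))
  expect_identical(c(ca, co) >= c1$cutoff, f(c(ca, co)) >= c2$cutoff)
  expect_equal(c1$youden_j, c2$youden_j)
})

test_that("DeLong 95% CI covers the true AUC at close to nominal rate", {
  true_auc <- auc_closed_form(1, 1, 0, 1, "normal")
  cover <- vapply(1:1000, function(s) {
    set.seed(s)
    est <- auc_empirical(rnorm(63, 1), rnorm(81))
    est$ci_low <= true_auc && true_auc <= est$ci_high
  }, TRUE)
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("per-level evaluation report has the expected structure and invariances", {
  specs <- default_group_specs()
  coh <- sample_cohort(specs$mfs, specs$non_mfs, 63, 81, seed = 2)
  rep2 <- evaluate_table2(coh)
  expect_identical(rep2$level, c("L1", "L2", "L3", "L4", "L5", "S1"))
  expect_true(all(is.na(rep2$auc_dsvr[1:2])))  # DSVR is image-derived, L3-S1 only
  expect_true(all(!is.na(rep2$auc_dsvr[3:6])))
  expect_true(all(!is.na(rep2$auc_dsdr)))
  expect_true(all(!is.na(rep2$mcnemar_p[3:6])))
  # monotone transform of the scores leaves every AUC unchanged
  coh2 <- coh
  for (cn in grep("^ds[vd]r_", names(coh2), value = TRUE))
    coh2[[cn]] <- log(coh2[[cn]])
  rep2b <- evaluate_table2(coh2)
  expect_equal(rep2b$auc_dsvr, rep2$auc_dsvr)
  expect_equal(rep2b$auc_dsdr, rep2$auc_dsdr)
  # single-level cohort restricts the report
  one <- coh[, c("patient_id", "group", "dsvr_S1")]
  r1 <- evaluate_table2(one)
  expect_identical(r1$level, "S1")
  expect_false("auc_dsdr" %in% names(r1) && any(!is.na(r1$auc_dsdr)))
  expect_error(evaluate_table2(coh[, c("patient_id", "group")]), "dsvr/dsdr")
})
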