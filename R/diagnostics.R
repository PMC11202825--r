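# Diagnostic-accuracy stage: group comparisons, ROC/AUC (empirical with
# DeLong confidence intervals, and closed-form under binormal / lognormal
# score models), Youden-optimal cut-offs, and McNemar comparison of paired
# dichotomous classifications.

#' Welch two-sample comparison of a variable between groups
#'
#' Welch's unequal-variance t test with Satterthwaite degrees of freedom,
#' two-sided. Chosen over the pooled-variance test because the group SDs of
#' the dural measurements differ strongly (e.g. 8.4 vs 2.4 mL at S1).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variable Optional variable name carried into the result.
#' @return Object of class `group_comparison`: per-group mean/sd/n, the t
#'   statistic, degrees of freedom and two-sided p value.
#' @export
welch_t <- function(values_a, values_b, variable = NULL) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs n >= 2")
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  structure(list(variable = variable,
                 mean_a = mean(values_a), sd_a = sd(values_a),
                 n_a = length(values_a),
                 mean_b = mean(values_b), sd_b = sd(values_b),
                 n_b = length(values_b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "group_comparison")
}

#' Empirical AUC with DeLong confidence interval
#'
#' Mann-Whitney estimator of the probability that a randomly chosen case
#' scores above a randomly chosen control (ties count 1/2), i.e. the area
#' under the empirical ROC curve with orientation "higher score implies
#' case". The 95% confidence interval is computed by DeLong's method (via
#' pROC) and clipped to \[0, 1\].
#'
#' @param scores_cases,scores_controls Numeric score vectors (non-empty).
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `auc_estimate` with fields `auc`, `ci_low`,
#'   `ci_high`, `method = "empirical_delong"`.
#' @export
auc_empirical <- function(scores_cases, scores_controls, conf_level = 0.95) {
  if (!length(scores_cases) || !length(scores_controls))
    stop("both groups must be non-empty")
  r <- pROC::roc(controls = scores_controls, cases = scores_cases,
                 direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  structure(list(auc = a,
                 ci_low = max(0, min(ci[1], a)),
                 ci_high = min(1, max(ci[3], a)),
                 method = "empirical_delong"),
            class = "auc_estimate")
}

#' Closed-form AUC under a parametric score model
#'
#' For normal score distributions in cases (`mean1`, `sd1`) and controls
#' (`mean0`, `sd0`) the ROC area is
#' `pnorm((mean1 - mean0) / sqrt(sd1^2 + sd0^2))` (the binormal AUC). Under
#' the lognormal family the same expression is applied after moment-matching
#' each group to a log-normal, i.e. on the log scale. This links published
#' per-group means and SDs of an index directly to its expected ROC area
#' without patient-level data.
#'
#' @param mean1,sd1 Case-group mean and SD (SD > 0).
#' @param mean0,sd0 Control-group mean and SD (SD > 0).
#' @param family `"normal"` or `"lognormal"` (means/SDs must be positive
#'   for the lognormal family).
#' @return The AUC as a bare number.
#' @examples
#' auc_closed_form(0.41, 0.28, 0.14, 0.06, "normal")     # ~0.827
#' auc_closed_form(1.11, 0.68, 0.50, 0.14, "lognormal")  # ~0.859
#' @export
auc_closed_form <- function(mean1, sd1, mean0, sd0,
                            family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (sd1 <= 0 || sd0 <= 0) stop("sds must be > 0")
  if (family == "lognormal") {
    p1 <- .lnorm_params(mean1, sd1)
    p0 <- .lnorm_params(mean0, sd0)
    mean1 <- p1[1, "meanlog"]; sd1 <- p1[1, "sdlog"]
    mean0 <- p0[1, "meanlog"]; sd0 <- p0[1, "sdlog"]
  }
  unname(pnorm((mean1 - mean0) / sqrt(sd1^2 + sd0^2)))
}

#' Youden-optimal cut-off and its diagnostic performance
#'
#' Scans every observed score as a candidate threshold for the rule
#' "score >= cutoff is positive (case)" and returns the cut-off maximising
#' the Youden index J = sensitivity + specificity - 1, ties broken towards
#' the lowest cut-off. Predictive values use the sample prevalence.
#'
#' @param scores_cases,scores_controls Numeric score vectors (non-empty).
#' @return Object of class `cutoff_performance` with fields `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden_j`.
#' @export
youden_cutoff <- function(scores_cases, scores_controls) {
  if (!length(scores_cases) || !length(scores_controls))
    stop("both groups must be non-empty")
  cand <- sort(unique(c(scores_cases, scores_controls)))
  sens <- vapply(cand, function(ct) mean(scores_cases >= ct), 0)
  spec <- vapply(cand, function(ct) mean(scores_controls < ct), 0)
  j <- sens + spec - 1
  best <- which.max(j)  # first maximum = lowest cut-off
  ct <- cand[best]
  tp <- sum(scores_cases >= ct); fn <- length(scores_cases) - tp
  fp <- sum(scores_controls >= ct); tn <- length(scores_controls) - fp
  structure(list(cutoff = ct,
                 sensitivity = sens[best], specificity = spec[best],
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 youden_j = j[best]),
            class = "cutoff_performance")
}

#' McNemar test on discordant pair counts
#'
#' Compares two dichotomous classifications of the same subjects through
#' their discordant counts `b` (rule 1 positive, rule 2 negative) and `c`
#' (the reverse). The default is the exact two-sided binomial test,
#' `p = min(1, 2 * P(Bin(b + c, 1/2) <= min(b, c)))`, appropriate for the
#' small discordant counts that arise at cohort sizes around 150; the
#' continuity-corrected chi-square version is available for comparability.
#'
#' @param b,c Non-negative discordant counts.
#' @param method `"exact_binomial"` (default) or `"chi2_cc"`.
#' @return Object of class `mcnemar_result` with fields `b`, `c`,
#'   `statistic`, `p`, `method`. `b = c = 0` gives `p = 1`.
#' @examples
#' mcnemar(10, 2)  # exact p ~0.039
#' @export
mcnemar <- function(b, c, method = c("exact_binomial", "chi2_cc")) {
  method <- match.arg(method)
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (method == "exact_binomial") {
    p <- if (n == 0) 1 else min(1, 2 * pbinom(min(b, c), n, 0.5))
    stat <- NA_real_
  } else {
    if (n == 0) { stat <- 0; p <- 1 }
    else {
      stat <- (abs(b - c) - 1)^2 / n
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(b = b, c = c, statistic = stat, p = p, method = method),
            class = "mcnemar_result")
}

#' Per-level ROC evaluation of volume and diameter ratios
#'
#' For each spinal level present in the cohort, estimates the empirical AUC
#' (with DeLong CI) of the dural sac volume ratio (DSVR) and of the diameter
#' ratio (DSDR) for discriminating MFS from non-MFS, the Youden-optimal
#' cut-off performance of each, and — where both indices exist at a level —
#' the exact McNemar test comparing their Youden-dichotomised
#' classifications on the same patients. DSVR is image-derived and exists
#' for L3-S1; DSDR also exists at L1-L2.
#'
#' @param cohort Data frame with a `group` column (`"MFS"` / `"nonMFS"`) and
#'   columns `dsvr_<level>` / `dsdr_<level>`. If ratio columns are absent
#'   but raw measurement columns are present they are derived via
#'   [compute_ratio_table()].
#' @param levels Levels to evaluate (default L1-S1; levels with no ratio
#'   column are dropped).
#' @return Data frame of class `table2_report`, one row per level:
#'   AUC and CI per index, Youden cut-off with sensitivity/specificity, and
#'   McNemar discordant counts and p value.
#' @export
evaluate_table2 <- function(cohort,
                            levels = c("L1", "L2", "L3", "L4", "L5", "S1")) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (!any(grepl("^ds[vd]r_", names(cohort)))) {
    rt <- compute_ratio_table(cohort)
    cohort <- cbind(cohort, rt[, setdiff(names(rt), names(cohort)), drop = FALSE])
  }
  if (!any(grepl("^ds[vd]r_", names(cohort))))
    stop("cohort has no dsvr/dsdr columns and none could be derived")
  is_case <- cohort$group == "MFS"
  rows <- lapply(levels, function(lv) {
    vcol <- paste0("dsvr_", lv)
    dcol <- paste0("dsdr_", lv)
    has_v <- vcol %in% names(cohort)
    has_d <- dcol %in% names(cohort)
    if (!has_v && !has_d) return(NULL)
    row <- data.frame(level = lv)
    cls_v <- cls_d <- NULL
    if (has_v) {
      sc <- cohort[[vcol]]
      est <- auc_empirical(sc[is_case], sc[!is_case])
      cut <- youden_cutoff(sc[is_case], sc[!is_case])
      cls_v <- sc >= cut$cutoff
      row <- cbind(row, data.frame(
        auc_dsvr = est$auc, auc_dsvr_lo = est$ci_low, auc_dsvr_hi = est$ci_high,
        cutoff_dsvr = cut$cutoff, sens_dsvr = cut$sensitivity,
        spec_dsvr = cut$specificity))
    }
    if (has_d) {
      sc <- cohort[[dcol]]
      est <- auc_empirical(sc[is_case], sc[!is_case])
      cut <- youden_cutoff(sc[is_case], sc[!is_case])
      cls_d <- sc >= cut$cutoff
      row <- cbind(row, data.frame(
        auc_dsdr = est$auc, auc_dsdr_lo = est$ci_low, auc_dsdr_hi = est$ci_high,
        cutoff_dsdr = cut$cutoff, sens_dsdr = cut$sensitivity,
        spec_dsdr = cut$specificity))
    }
    if (has_v && has_d) {
      b <- sum(cls_v & !cls_d)
      cc <- sum(!cls_v & cls_d)
      mc <- mcnemar(b, cc)
      row <- cbind(row, data.frame(mcnemar_b = b, mcnemar_c = cc,
                                   mcnemar_p = mc$p))
    }
    row
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no requested level has ratio columns")
  # pad differing column sets with NA before stacking
  allc <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(allc, names(r))) r[[cn]] <- NA
    r[, allc]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("table2_report", "data.frame")
  out
}
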