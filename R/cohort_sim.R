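# Cohort simulator: per-patient measurement tables whose group-wise
# distributions match the published per-level means and SDs in Marfan (MFS)
# and non-Marfan patients, so the diagnostic-accuracy stage can be exercised
# without patient data.

#' Construct a per-group distribution specification
#'
#' A `group_spec` holds, for one diagnostic group, the marginal mean and
#' standard deviation of every simulated variable together with the sampling
#' family used to realise it (`"lognormal"`, moment-matched, for strictly
#' positive right-skewed measurements; `"truncated_normal"`, truncated at
#' zero without re-standardisation, for demographics), plus an optional
#' correlation matrix applied through a Gaussian copula.
#'
#' @param group Group label, `"MFS"` or `"nonMFS"`.
#' @param variables Data frame with columns `variable`, `mean`, `sd`,
#'   `family`. Means of physical quantities must be positive, SDs
#'   non-negative.
#' @param correlation Optional symmetric positive semi-definite correlation
#'   matrix (unit diagonal) over the variables, in variable order. `NULL`
#'   (the default) means independent sampling.
#' @return An object of class `group_spec`.
#' @seealso [default_group_specs()], [sample_cohort()]
#' @export
group_spec <- function(group = c("MFS", "nonMFS"), variables,
                       correlation = NULL) {
  group <- match.arg(group)
  stopifnot(is.data.frame(variables),
            all(c("variable", "mean", "sd", "family") %in% names(variables)))
  if (any(variables$sd < 0)) stop("all sd must be >= 0")
  if (any(variables$mean <= 0)) stop("means of physical quantities must be > 0")
  bad <- setdiff(unique(variables$family), c("lognormal", "truncated_normal"))
  if (length(bad)) stop("invalid family: ", paste(bad, collapse = ", "))
  if (anyDuplicated(variables$variable)) stop("duplicated variable names")
  if (!is.null(correlation)) {
    p <- nrow(variables)
    if (!is.matrix(correlation) || any(dim(correlation) != p))
      stop("correlation must be a ", p, "x", p, " matrix")
    if (any(abs(correlation - t(correlation)) > 1e-12) ||
        any(abs(diag(correlation) - 1) > 1e-12))
      stop("correlation must be symmetric with unit diagonal")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  }
  structure(list(group = group, variables = variables,
                 correlation = correlation),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat("group_spec:", x$group, "-", nrow(x$variables), "variables",
      if (is.null(x$correlation)) "(independent)" else "(correlated)", "\n")
  print(x$variables, row.names = FALSE)
  invisible(x)
}

# Published per-group parameters, one row per variable:
# mean/sd for the MFS group, then for the non-MFS group.
# Volumes in mL, diameters in mm, ratios dimensionless, height cm, weight kg.
.printed_params <- function() {
  p <- function(variable, m1, s1, m0, s0)
    data.frame(variable = variable, mean_mfs = m1, sd_mfs = s1,
               mean_non = m0, sd_non = s0)
  rbind(
    p("dural_volume_L3", 12.8, 2.8, 9.8, 2.0),
    p("dural_volume_L4", 12.0, 3.3, 8.5, 2.4),
    p("dural_volume_L5", 11.6, 4.2, 7.5, 2.6),
    p("dural_volume_S1", 13.3, 8.4, 4.9, 2.4),
    p("vertebral_volume_L3", 36.7, 7.4, 36.6, 9.6),
    p("vertebral_volume_L4", 37.4, 7.6, 36.8, 8.9),
    p("vertebral_volume_L5", 33.2, 7.8, 34.9, 7.8),
    p("dsvr_L3", 0.36, 0.10, 0.28, 0.07),
    p("dsvr_L4", 0.33, 0.11, 0.24, 0.07),
    p("dsvr_L5", 0.36, 0.14, 0.22, 0.07),
    p("dsvr_S1", 0.41, 0.28, 0.14, 0.06),
    p("dural_diameter_L1", 18.6, 3.3, 16.7, 2.3),
    p("dural_diameter_L2", 17.6, 2.1, 15.7, 2.0),
    p("dural_diameter_L3", 17.0, 2.5, 15.2, 1.9),
    p("dural_diameter_L4", 17.6, 3.0, 14.5, 2.7),
    p("dural_diameter_L5", 19.3, 4.1, 14.9, 3.0),
    p("dural_diameter_S1", 19.1, 6.9, 11.9, 3.3),
    p("vertebral_diameter_L1", 28.6, 5.8, 28.0, 3.8),
    p("vertebral_diameter_L2", 30.1, 4.3, 29.6, 3.6),
    p("vertebral_diameter_L3", 31.5, 3.7, 31.1, 3.7),
    p("vertebral_diameter_L4", 31.7, 3.3, 31.2, 3.6),
    p("vertebral_diameter_L5", 29.5, 3.4, 30.2, 3.1),
    p("vertebral_diameter_S1", 19.3, 4.4, 23.8, 3.2),
    p("dsdr_L1", 0.67, 0.12, 0.60, 0.11),
    p("dsdr_L2", 0.60, 0.11, 0.54, 0.09),
    p("dsdr_L3", 0.55, 0.10, 0.49, 0.09),
    p("dsdr_L4", 0.56, 0.11, 0.48, 0.10),
    p("dsdr_L5", 0.66, 0.16, 0.50, 0.12),
    p("dsdr_S1", 1.11, 0.68, 0.50, 0.14),
    p("nerve_root_sleeve_L5", 6.1, 1.2, 6.0, 1.0),
    p("s1_scalloping", 5.0, 2.5, 3.1, 1.3),
    p("height", 187.8, 10.6, 182.0, 9.8),
    p("weight", 79.4, 13.7, 70.8, 15.5)
  )
}

#' Default MFS and non-MFS distribution specifications
#'
#' Returns the pair of [group_spec] objects pre-loaded with the published
#' per-level group means and standard deviations: dural sac segment volumes
#' L3-S1 and vertebral body volumes L3-L5 (mL), dural sac volume ratios
#' (DSVR) L3-S1, dural sac and vertebral body anteroposterior diameters
#' L1-S1 (mm), diameter ratios (DSDR) L1-S1, L5 nerve root sleeve diameter,
#' S1 scalloping (mm), and height (cm) / weight (kg).
#'
#' Measurement variables default to the moment-matched log-normal family
#' (strictly positive and right-skewed — the S1 ratios, e.g. DSVR
#' 0.41 +/- 0.28 in MFS, imply strong right skew); height and weight use a
#' zero-truncated normal, where truncation is numerically irrelevant.
#'
#' @return Named list with elements `mfs` and `non_mfs`, each a
#'   [group_spec]. Both contain the identical variable set in the same
#'   order.
#' @examples
#' specs <- default_group_specs()
#' subset(specs$mfs$variables, variable == "dsvr_S1")
#' @export
default_group_specs <- function() {
  pp <- .printed_params()
  fam <- ifelse(pp$variable %in% c("height", "weight"),
                "truncated_normal", "lognormal")
  list(
    mfs = group_spec("MFS", data.frame(variable = pp$variable,
                                       mean = pp$mean_mfs, sd = pp$sd_mfs,
                                       family = fam)),
    non_mfs = group_spec("nonMFS", data.frame(variable = pp$variable,
                                              mean = pp$mean_non,
                                              sd = pp$sd_non,
                                              family = fam))
  )
}

# Sample n rows for one group_spec from uniform copula draws U (n x p).
.sample_group <- function(spec, u) {
  v <- spec$variables
  out <- matrix(NA_real_, nrow(u), nrow(v),
                dimnames = list(NULL, v$variable))
  for (j in seq_len(nrow(v))) {
    m <- v$mean[j]; s <- v$sd[j]
    if (s == 0) { out[, j] <- m; next }
    if (v$family[j] == "lognormal") {
      lp <- .lnorm_params(m, s)
      out[, j] <- qlnorm(u[, j], lp[1, "meanlog"], lp[1, "sdlog"])
    } else {  # truncated_normal: N(m, s) conditioned on > 0, moments not re-matched
      p0 <- pnorm(0, m, s)
      out[, j] <- qnorm(p0 + u[, j] * (1 - p0), m, s)
    }
  }
  out
}

.copula_uniform <- function(n, p, correlation) {
  z <- matrix(rnorm(n * p), n, p)
  if (!is.null(correlation)) {
    # PSD but possibly singular: use eigen square root
    e <- eigen(correlation, symmetric = TRUE)
    rt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
    z <- z %*% rt
  }
  matrix(pnorm(z), nrow(z), ncol(z))  # pnorm drops dims on length-0 input
}

#' Simulate a two-group patient cohort
#'
#' Draws `n_mfs` + `n_non` synthetic patient records from a pair of
#' [group_spec] objects. Each variable is sampled from its declared family
#' matched to the specified mean and SD; variables are independent unless
#' the spec carries a correlation matrix, in which case a Gaussian copula
#' imposes the dependence while preserving the marginals.
#'
#' @param spec_mfs,spec_non [group_spec] for the MFS and non-MFS group. The
#'   two must declare the same variables.
#' @param n_mfs,n_non Number of patients per group (non-negative).
#' @param seed Integer seed; required, so that a cohort is a pure function
#'   of `(specs, n, seed)`. The caller's RNG state is left untouched.
#' @return Data frame with columns `patient_id`, `group`, then one column
#'   per variable. Attributes `seed` and `spec_provenance` record how it
#'   was generated.
#' @examples
#' specs <- default_group_specs()
#' coh <- sample_cohort(specs$mfs, specs$non_mfs, 63, 81, seed = 1)
#' table(coh$group)
#' @export
sample_cohort <- function(spec_mfs, spec_non, n_mfs, n_non, seed) {
  stopifnot(inherits(spec_mfs, "group_spec"), inherits(spec_non, "group_spec"))
  if (missing(seed)) stop("seed is a required argument")
  stopifnot(n_mfs >= 0, n_non >= 0)
  if (!identical(spec_mfs$variables$variable, spec_non$variables$variable))
    stop("the two specs must declare the same variable set")
  vars <- spec_mfs$variables$variable
  p <- length(vars)
  .with_seed(seed, {
    u1 <- .copula_uniform(n_mfs, p, spec_mfs$correlation)
    u0 <- .copula_uniform(n_non, p, spec_non$correlation)
    x1 <- .sample_group(spec_mfs, u1)
    x0 <- .sample_group(spec_non, u0)
    ids <- c(sprintf("MFS-%03d", seq_len(n_mfs)),
             sprintf("NON-%03d", seq_len(n_non)))
    out <- data.frame(patient_id = ids,
                      group = rep(c("MFS", "nonMFS"), c(n_mfs, n_non)),
                      rbind(x1, x0), check.names = FALSE)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    attr(out, "spec_provenance") <- list(mfs = spec_mfs, non_mfs = spec_non)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
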