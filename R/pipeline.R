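# End-to-end orchestration: univariate screens, the multivariate adjusted
# model, the frequency-response curve, residue profiling along the
# tonotopic axis, and the parameter-recovery experiment.

.cohort_factor_prep <- function(table) {
  # reference levels: scala vestibuli, slim straight, progressive SNHL;
  # when a reference level is absent from the table (possible in small
  # cohorts) the first observed level serves as reference instead
  relev <- function(x, ref) {
    x <- droplevels(factor(x))
    if (ref %in% levels(x)) stats::relevel(x, ref = ref) else x
  }
  refs <- c(scalar = "SV", array_type = "SSA",
            etiology = "ProgressiveSNHL")
  for (v in names(refs)) {
    if (!is.null(table[[v]])) table[[v]] <- relev(table[[v]], refs[[v]])
  }
  table
}

.check_covariates <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("cohort table is missing covariate column(s): ",
         paste(miss, collapse = ", "))
  }
}

#' Univariate mixed-model screens
#'
#' Fits, for each covariate in turn, a random-intercept linear mixed model
#' with that covariate as the only fixed effect (plus the intercept), the
#' crude-association screen of the analysis. Quantitative impedance and
#' distance enter squared; the frequency term enters as the two-knot cubic
#' spline and is reported per basis column.
#'
#' @param table Cohort table with covariates and `cnf_hz`.
#' @param knots Spline knots in Hz for the frequency term.
#' @return Data frame with one row per estimated coefficient: `covariate`,
#'   `term`, `beta` (crude), `se`, `z`, `p`.
#' @export
run_univariate <- function(table, knots = c(5000, 10000)) {
  .check_covariates(table, c("subject_id", "nrt_threshold_cl"))
  table <- .cohort_factor_prep(table)
  specs <- c(
    age_test_yr = "age_test_yr",
    age_deaf_yr = "age_deaf_yr",
    duration_deaf_yr = "duration_deaf_yr",
    age_implant_yr = "age_implant_yr",
    impedance_sq = "I(impedance_kohm^2)",
    distance_sq = "I(distance_mm^2)",
    cnf_spline = sprintf("tp_spline(cnf_hz, knots = c(%s))",
                         paste(knots, collapse = ", ")),
    scalar = "scalar",
    array_type = "array_type",
    etiology = "etiology"
  )
  vars <- c(age_test_yr = "age_test_yr", age_deaf_yr = "age_deaf_yr",
            duration_deaf_yr = "duration_deaf_yr",
            age_implant_yr = "age_implant_yr",
            impedance_sq = "impedance_kohm", distance_sq = "distance_mm",
            cnf_spline = "cnf_hz", scalar = "scalar",
            array_type = "array_type", etiology = "etiology")
  keep <- names(specs)[vars %in% names(table)]
  if (!length(keep)) stop("no recognized covariate columns in the table")
  out <- list()
  for (nm in keep) {
    if (is.factor(table[[vars[nm]]]) &&
        nlevels(droplevels(table[[vars[nm]]])) < 2) next
    fml <- stats::as.formula(paste("nrt_threshold_cl ~", specs[nm]))
    fit <- nrt_lmm(fml, table, "subject_id")
    cf <- summary(fit)$coefficients
    cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    out[[nm]] <- data.frame(covariate = nm, term = rownames(cf),
                            beta = cf[, 1], se = cf[, 2], z = cf[, 3],
                            p = cf[, 4], row.names = NULL)
  }
  do.call(rbind, out)
}

.multivariate_formula <- function(knots, table) {
  terms <- c(sprintf("tp_spline(cnf_hz, knots = c(%s))",
                     paste(knots, collapse = ", ")),
             "I(impedance_kohm^2)", "I(distance_mm^2)", "scalar",
             "array_type", "etiology", "age_test_yr", "duration_deaf_yr")
  # a factor observed at a single level carries no contrast
  for (v in c("scalar", "array_type", "etiology")) {
    if (nlevels(droplevels(factor(table[[v]]))) < 2) {
      warning("covariate '", v, "' has a single observed level and is ",
              "dropped from the multivariate model")
      terms <- setdiff(terms, v)
    }
  }
  stats::as.formula(paste("nrt_threshold_cl ~",
                          paste(terms, collapse = " + ")))
}

#' Multivariate adjusted mixed model
#'
#' Fits the single mutually adjusted model: spline(CNF) + impedance^2 +
#' distance^2 + scalar placement + array type + etiology + age at test +
#' duration of profound deafness, with a subject random intercept. Age of
#' profound deafness and age at implantation are excluded for their
#' collinearity with age at test (age at implantation is their sum).
#'
#' @param table Cohort table with covariates and `cnf_hz`.
#' @param knots Spline knots in Hz.
#' @return List with `table` (adjusted coefficient data frame: `term`,
#'   `beta`, `se`, `z`, `p`) and `fit` (the [nrt_lmm()] object).
#' @export
run_multivariate <- function(table, knots = c(5000, 10000)) {
  .check_covariates(table, c("subject_id", "nrt_threshold_cl", "cnf_hz",
                             "impedance_kohm", "distance_mm", "scalar",
                             "array_type", "etiology", "age_test_yr",
                             "duration_deaf_yr"))
  table <- .cohort_factor_prep(table)
  fit <- nrt_lmm(.multivariate_formula(knots, table), table,
                 "subject_id")
  cf <- summary(fit)$coefficients
  list(table = data.frame(term = rownames(cf), beta = cf[, 1],
                          se = cf[, 2], z = cf[, 3], p = cf[, 4],
                          row.names = NULL),
       fit = fit)
}

.reference_newdata <- function(fit, table, cnf) {
  # non-frequency covariates held at reference values: means for numeric,
  # the reference (first) level for factors
  nd <- data.frame(cnf_hz = cnf)
  for (v in all.vars(stats::delete.response(fit$terms))) {
    if (v == "cnf_hz") next
    col <- table[[v]]
    nd[[v]] <- if (is.numeric(col)) {
      mean(col)
    } else {
      factor(levels(factor(col))[1], levels = levels(factor(col)))
    }
  }
  nd
}

#' Population-level NRT threshold curve over frequency
#'
#' Evaluates the fitted fixed-effect threshold-frequency relation with 95%
#' confidence band over a log-spaced grid of characteristic neuron
#' frequencies, all other covariates held at reference values (cohort mean
#' for numeric covariates, reference level for categorical ones). The grid
#' is clipped to the observed CNF range, with a warning, since the spline
#' is not meant to extrapolate.
#'
#' @param fit Multivariate (or univariate spline) [nrt_lmm()] fit.
#' @param table The cohort table the model was fitted on.
#' @param n_grid Number of grid points.
#' @param grid Optional explicit frequency grid in Hz.
#' @return Data frame with `cnf_hz`, `fit`, `lwr`, `upr` (C.L.).
#' @export
frequency_curve <- function(fit, table, n_grid = 100, grid = NULL) {
  stopifnot(inherits(fit, "nrt_lmm"))
  rng <- range(table$cnf_hz)
  if (is.null(grid)) {
    grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_grid))
  } else if (any(grid < rng[1] | grid > rng[2])) {
    warning("frequency grid clipped to the observed CNF range [",
            sprintf("%.0f, %.0f", rng[1], rng[2]), "] Hz")
    grid <- pmin(pmax(grid, rng[1]), rng[2])
  }
  table <- .cohort_factor_prep(table)
  nd <- .reference_newdata(fit, table, grid)
  ci <- predict(fit, nd, interval = "confidence")
  data.frame(cnf_hz = grid, fit = ci$fit, lwr = ci$lwr, upr = ci$upr)
}

#' Residue profile along the tonotopic axis
#'
#' Bins the conditional residuals (observed minus fixed-effect prediction
#' minus subject BLUP) of a fitted model into log-spaced characteristic
#' neuron frequency bins and summarizes each bin. Bins whose mean residual
#' exceeds twice its standard error are flagged as candidate regions of
#' abnormal neuron activation: the residue, being subject-independent by
#' construction, is read as a proxy of local auditory-neuron function.
#'
#' @param fit [nrt_lmm()] fit obtained on `table`.
#' @param table The cohort table the model was fitted on.
#' @param bins Number of log-spaced frequency bins.
#' @return Data frame with one row per non-empty bin: `cnf_lo`, `cnf_hi`,
#'   `cnf_mid` (geometric midpoint, Hz), `n`, `mean_residual`, `se`,
#'   `flagged`. Empty bins are dropped with a warning.
#' @export
residue_profile <- function(fit, table, bins = 10) {
  stopifnot(inherits(fit, "nrt_lmm"))
  if (nrow(table) != fit$nobs) {
    stop("'table' does not match the data the model was fitted on")
  }
  res <- residuals(fit, type = "conditional")
  brk <- exp(seq(log(min(table$cnf_hz)), log(max(table$cnf_hz)),
                 length.out = bins + 1))
  # guard the exp(log()) round-trip so the extremes stay inside the bins
  brk[1] <- min(brk[1], min(table$cnf_hz))
  brk[bins + 1] <- max(brk[bins + 1], max(table$cnf_hz))
  idx <- cut(table$cnf_hz, breaks = brk, include.lowest = TRUE,
             labels = FALSE)
  out <- lapply(seq_len(bins), function(b) {
    r <- res[idx == b]
    if (!length(r)) return(NULL)
    m <- mean(r)
    se <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
    data.frame(cnf_lo = brk[b], cnf_hi = brk[b + 1],
               cnf_mid = sqrt(brk[b] * brk[b + 1]), n = length(r),
               mean_residual = m, se = se,
               flagged = is.finite(se) && abs(m) > 2 * se)
  })
  if (any(vapply(out, is.null, logical(1)))) {
    warning("empty frequency bin(s) dropped")
  }
  do.call(rbind, out)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates cohorts from a ground-truth configuration, fits
#' the multivariate adjusted model to each, and aggregates the recovery of
#' selected coefficients: mean estimate, empirical SD, bias, and coverage
#' of the nominal 95% Wald interval. Replicates whose fit fails are
#' recorded and excluded.
#'
#' @param config Ground-truth [generator_config()].
#' @param n_replicates Number of replicate cohorts (>= 2).
#' @param seeds Integer seeds, one per replicate (default `1:n_replicates`).
#' @param coefficients Named character vector mapping design column names
#'   to names of the truth lookup below; defaults to the squared-impedance
#'   and scala-tympani effects.
#' @return List of class `"recovery_result"`: `summary` data frame
#'   (`term`, `truth`, `mean_estimate`, `empirical_sd`, `bias`,
#'   `coverage95`), `estimates` (replicate x term matrix), `n_replicates`,
#'   `n_failed`, `seeds`.
#' @export
recovery_experiment <- function(config = generator_config(),
                                n_replicates = 20,
                                seeds = seq_len(n_replicates),
                                coefficients = c(
                                  `I(impedance_kohm^2)` = "beta_imp_sq",
                                  scalarST = "beta_st")) {
  if (n_replicates < 2) stop("need at least 2 replicates")
  if (length(seeds) != n_replicates) {
    stop("'seeds' must supply one seed per replicate")
  }
  truth <- vapply(unname(coefficients),
                  function(f) config$fixed_effects[[f]], numeric(1))
  names(truth) <- names(coefficients)
  est <- se <- matrix(NA_real_, n_replicates, length(coefficients),
                      dimnames = list(NULL, names(coefficients)))
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[r])
    res <- tryCatch(run_multivariate(generate_cohort(cfg)),
                    error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    for (nm in names(coefficients)) {
      if (nm %in% names(res$fit$coefficients)) {
        est[r, nm] <- res$fit$coefficients[nm]
        se[r, nm] <- res$fit$se[nm]
      }
    }
  }
  ok <- stats::complete.cases(est)
  est_ok <- est[ok, , drop = FALSE]
  se_ok <- se[ok, , drop = FALSE]
  cover <- colMeans(abs(sweep(est_ok, 2, truth)) <=
                      stats::qnorm(0.975) * se_ok)
  smry <- data.frame(
    term = names(coefficients),
    truth = unname(truth),
    mean_estimate = colMeans(est_ok),
    empirical_sd = apply(est_ok, 2, stats::sd),
    bias = colMeans(est_ok) - unname(truth),
    coverage95 = unname(cover),
    row.names = NULL
  )
  structure(list(summary = smry, estimates = est_ok,
                 n_replicates = sum(ok), n_failed = failed,
                 seeds = seeds),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, digits = 4, ...) {
  cat("Parameter recovery over", x$n_replicates, "replicates")
  if (x$n_failed) cat(" (", x$n_failed, " failed, excluded)", sep = "")
  cat(":\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Full analysis report
#'
#' Runs the whole analysis on a cohort table: cohort summary, univariate
#' screens, the multivariate adjusted model, the frequency curve with its
#' 95% band, and the residue profile. A pure function of its inputs:
#' rerunning on the same table yields identical output. Raw (unadjusted)
#' p-values are reported throughout; no multiple-testing correction is
#' applied, matching the two-tailed alpha = 0.05 convention of the
#' original analysis.
#'
#' @param table Cohort table with covariates and `cnf_hz`.
#' @param knots Spline knots in Hz.
#' @param bins Residue-profile bin count.
#' @return List of class `"nrt_report"`: `cohort_summary`, `univariate`,
#'   `multivariate`, `variance_components`, `bic`, `curve`, `residues`.
#' @export
run_report <- function(table, knots = c(5000, 10000), bins = 10) {
  mv <- run_multivariate(table, knots)
  list(
    cohort_summary = summarize_cohort(table),
    univariate = run_univariate(table, knots),
    multivariate = mv$table,
    variance_components = c(sigma2_b = mv$fit$sigma2_b,
                            sigma2_e = mv$fit$sigma2_e),
    bic = mv$fit$bic,
    curve = frequency_curve(mv$fit, table),
    residues = residue_profile(mv$fit, table, bins)
  )
}
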