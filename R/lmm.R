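# Random-intercept linear mixed model, estimated by REML with the
# variance ratio lambda = sigma_b^2 / sigma_e^2 profiled out.
#
# With V0 = I + lambda * Z Z' block-diagonal over subjects, all products
# V0^{-1} M reduce to per-group sweeps (Woodbury on the all-ones block),
# so each profile evaluation is O(n p + p^3).

.lmm_eval <- function(lambda, y, X, gi, ng, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  cg <- lambda / (1 + lambda * ng)
  Vinv <- function(M) M - (cg * rowsum(M, gi))[gi, , drop = FALSE]
  WX <- Vinv(X)
  XtViX <- crossprod(X, WX)
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) {
    return(NULL)
  }
  XtViy <- crossprod(WX, y)
  beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
  r <- y - drop(X %*% beta)
  quad <- sum(r * Vinv(matrix(r)))
  if (reml) {
    sigma2_e <- quad / (n - p)
    loglik <- -0.5 * ((n - p) * log(sigma2_e) +
                        sum(log1p(lambda * ng)) +
                        2 * sum(log(diag(ch))) +
                        (n - p) * (1 + log(2 * pi)))
  } else {
    sigma2_e <- quad / n
    loglik <- -0.5 * (n * log(sigma2_e) +
                        sum(log1p(lambda * ng)) +
                        n * (1 + log(2 * pi)))
  }
  list(beta = drop(beta), chol = ch, resid = r, sigma2_e = sigma2_e,
       loglik = loglik)
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits \eqn{y_{ij} = x_{ij}'\beta + b_i + \epsilon_{ij}} with a
#' subject-specific random intercept \eqn{b_i \sim N(0, \sigma_b^2)} and
#' residual \eqn{\epsilon_{ij} \sim N(0, \sigma_e^2)}, the model used to
#' account for the correlation between repeated per-electrode measurements
#' within a subject.
#'
#' Estimation profiles the restricted likelihood over the single variance
#' ratio \eqn{\lambda = \sigma_b^2/\sigma_e^2}: for each \eqn{\lambda} the
#' fixed effects are the GLS solution and \eqn{\sigma_e^2} has a closed
#' form, leaving a one-dimensional maximization over \eqn{\log\lambda}
#' (derivative-free, bracket \eqn{[10^{-8}, 10^{8}]}, tolerance `1e-8`).
#' The boundary \eqn{\sigma_b^2 = 0} is compared explicitly and reported
#' when it maximizes the criterion (the fit then coincides with OLS).
#'
#' Design columns are rescaled to unit root-mean-square internally for
#' conditioning (cubic spline columns on the Hz scale reach 1e12) and all
#' reported estimates and covariances are back-transformed exactly.
#'
#' @param formula Model formula for the fixed effects, e.g.
#'   `nrt_threshold_cl ~ tp_spline(cnf_hz) + I(impedance_kohm^2) + scalar`.
#' @param data Data frame with one row per (subject, electrode).
#' @param group Grouping variable: a column name, or a one-sided formula
#'   such as `~ subject_id`.
#' @param method `"REML"` (default) or `"ML"`. REML is used for estimation
#'   and reporting; full maximum likelihood is available for comparing
#'   models that differ in their fixed effects, since restricted
#'   likelihoods are only comparable for a common fixed-effect design.
#' @return An object of class `"nrt_lmm"`: list with components
#'   `coefficients`, `se`, `vcov`, `sigma2_b`, `sigma2_e`, `lambda`,
#'   `loglik` (REML), `bic`, `blup` (per-subject shrunken intercepts),
#'   `fitted` (marginal), `residuals_marginal`, `residuals_conditional`,
#'   plus bookkeeping for the methods.
#' @seealso [wald_test()], [model_bic()], [blup_random_intercepts()],
#'   [predict.nrt_lmm()]
#' @export
nrt_lmm <- function(formula, data, group, method = c("REML", "ML")) {
  cl <- match.call()
  method <- match.arg(method)
  reml <- method == "REML"
  if (inherits(group, "formula")) {
    group <- all.vars(group)
  }
  if (!is.character(group) || length(group) != 1L || !group %in% names(data)) {
    stop("'group' must name a column of 'data'")
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  y <- unname(stats::model.response(mf))
  X <- stats::model.matrix(tt, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than fixed-effect columns")
  g <- factor(data[[group]])
  gi <- as.integer(g)
  ng <- as.integer(table(gi))
  G <- length(ng)
  if (G < 2L) stop("need at least 2 groups to separate variance components")

  # conditioning: unit-RMS columns, exact back-transform afterwards
  sc <- apply(X, 2, function(cc) sqrt(mean(cc^2)))
  zero <- sc == 0
  sc[zero] <- 1
  Xs <- sweep(X, 2, sc, "/")
  qx <- qr(Xs)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  singleton <- all(ng == 1L)
  if (singleton) {
    warning("one observation per group: sigma_b^2 and sigma_e^2 are not ",
            "separable; fitting OLS with sigma_b^2 = 0")
  }
  fit0 <- .lmm_eval(0, y, Xs, gi, ng, reml)
  if (singleton) {
    best <- fit0
    lambda <- 0
  } else {
    negll <- function(t) -.lmm_eval(exp(t), y, Xs, gi, ng, reml)$loglik
    opt <- stats::optimize(negll, interval = log(c(1e-8, 1e8)), tol = 1e-8)
    if (!is.finite(opt$objective)) {
      stop("REML profiling did not converge; bracket [1e-8, 1e8] on lambda, ",
           "objective non-finite at lambda = ", exp(opt$minimum))
    }
    if (fit0$loglik >= -opt$objective) {
      best <- fit0
      lambda <- 0
    } else {
      lambda <- exp(opt$minimum)
      best <- .lmm_eval(lambda, y, Xs, gi, ng, reml)
    }
  }

  beta <- best$beta / sc
  names(beta) <- colnames(X)
  vb_s <- best$sigma2_e * chol2inv(best$chol)
  vcov_beta <- vb_s / tcrossprod(sc)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  sigma2_e <- best$sigma2_e
  sigma2_b <- lambda * sigma2_e

  shrink <- lambda * ng / (1 + lambda * ng)
  rbar <- drop(rowsum(best$resid, gi)) / ng
  blup <- unname(shrink * rbar)
  names(blup) <- levels(g)
  resid_marg <- unname(best$resid)
  fitted_marg <- y - resid_marg
  resid_cond <- resid_marg - unname(blup)[gi]

  # undo the column scaling's constant shift of log|X'V^{-1}X| so the
  # restricted likelihood matches the standard definition (the full
  # likelihood carries no X-determinant term)
  ll <- if (reml) best$loglik - sum(log(sc)) else best$loglik
  k <- p + 2
  out <- list(
    coefficients = beta, se = se, vcov = vcov_beta,
    sigma2_b = sigma2_b, sigma2_e = sigma2_e, lambda = lambda,
    loglik = ll, bic = -2 * ll + k * log(n), df = k,
    nobs = n, n_groups = G, group_sizes = ng,
    blup = blup, fitted = fitted_marg,
    residuals_marginal = resid_marg, residuals_conditional = resid_cond,
    y = y, group_index = gi, group_levels = levels(g), group_var = group,
    method = method,
    terms = tt, xlevels = stats::.getXlevels(tt, mf),
    contrasts = attr(X, "contrasts"), formula = formula, call = cl
  )
  class(out) <- "nrt_lmm"
  out
}

#' @export
print.nrt_lmm <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model (", x$method, ")\n", sep = "")
  cat("  formula: ", deparse(x$formula), "\n")
  cat("  groups:  ", x$n_groups, " (", x$group_var, "), obs: ", x$nobs,
      "\n", sep = "")
  cat(sprintf("  sigma_b = %.*g, sigma_e = %.*g, REML logLik = %.*g, BIC = %.*g\n",
              digits, sqrt(x$sigma2_b), digits, sqrt(x$sigma2_e),
              digits, x$loglik, digits, x$bic))
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarize a fitted random-intercept mixed model
#'
#' @param object An [nrt_lmm()] fit.
#' @param ... Unused.
#' @return Object of class `"summary.nrt_lmm"` carrying the coefficient
#'   table (estimate, SE, Wald z, two-sided p) and variance components.
#' @export
summary.nrt_lmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, sigma2_b = object$sigma2_b,
                 sigma2_e = object$sigma2_e, loglik = object$loglik,
                 bic = object$bic, nobs = object$nobs,
                 n_groups = object$n_groups, formula = object$formula),
            class = "summary.nrt_lmm")
}

#' @export
print.summary.nrt_lmm <- function(x, digits = 4, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat("  formula:", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nVariance components: sigma_b^2 = %.4g (between subjects), sigma_e^2 = %.4g (residual)\n",
              x$sigma2_b, x$sigma2_e))
  cat(sprintf("REML logLik %.4f, BIC %.4f, %d obs in %d groups\n",
              x$loglik, x$bic, x$nobs, x$n_groups))
  invisible(x)
}

#' @export
coef.nrt_lmm <- function(object, ...) object$coefficients

#' @export
vcov.nrt_lmm <- function(object, ...) object$vcov

#' @export
nobs.nrt_lmm <- function(object, ...) object$nobs

#' @export
logLik.nrt_lmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            REML = object$method == "REML", class = "logLik")
}

#' @export
fitted.nrt_lmm <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  if (type == "marginal") object$fitted
  else object$fitted + unname(object$blup)[object$group_index]
}

#' Residuals of a random-intercept mixed model
#'
#' @param object An [nrt_lmm()] fit.
#' @param type `"conditional"` (default; observed minus fixed-effect
#'   prediction minus the subject BLUP) or `"marginal"` (observed minus
#'   fixed-effect prediction).
#' @param ... Unused.
#' @return Numeric vector of residuals in response units.
#' @export
residuals.nrt_lmm <- function(object, type = c("conditional", "marginal"),
                              ...) {
  type <- match.arg(type)
  if (type == "conditional") object$residuals_conditional
  else object$residuals_marginal
}

#' Predict population-level means with confidence bands
#'
#' Evaluates the fixed-effect prediction \eqn{x'\hat\beta} for new design
#' rows and, optionally, the population-level 95% band
#' \eqn{x'\hat\beta \pm z_{0.975}\sqrt{x' V x}} where V is the fixed-effect
#' covariance. The band reflects uncertainty in the mean curve only (no
#' random-intercept or residual variance).
#'
#' @param object An [nrt_lmm()] fit.
#' @param newdata Data frame with the covariate columns of the fit; when
#'   omitted, the training design is used.
#' @param interval `"none"` or `"confidence"`.
#' @param level Coverage of the band (default 0.95).
#' @param ... Unused.
#' @return Numeric vector (`interval = "none"`) or data frame with columns
#'   `fit`, `lwr`, `upr`.
#' @export
predict.nrt_lmm <- function(object, newdata = NULL,
                            interval = c("none", "confidence"),
                            level = 0.95, ...) {
  interval <- match.arg(interval)
  tt <- stats::delete.response(object$terms)
  if (is.null(newdata)) {
    est <- object$fitted
    if (interval == "none") return(est)
    stop("confidence bands require explicit 'newdata'")
  }
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                           xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
  if (!identical(colnames(X), names(object$coefficients))) {
    stop("newdata design columns do not match the fitted model; expected: ",
         paste(names(object$coefficients), collapse = ", "))
  }
  est <- drop(X %*% object$coefficients)
  if (interval == "none") {
    return(est)
  }
  half <- stats::qnorm((1 + level) / 2) *
    sqrt(rowSums((X %*% object$vcov) * X))
  data.frame(fit = est, lwr = est - half, upr = est + half)
}

#' Simulate responses from a fitted random-intercept model
#'
#' Draws new random intercepts and residuals at the estimated variance
#' components around the fitted fixed-effect means.
#'
#' @param object An [nrt_lmm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated response per row
#'   of the training data.
#' @export
simulate.nrt_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$nobs
  G <- object$n_groups
  out <- replicate(nsim, {
    b <- stats::rnorm(G, 0, sqrt(object$sigma2_b))
    object$fitted + b[object$group_index] +
      stats::rnorm(n, 0, sqrt(object$sigma2_e))
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.nrt_lmm <- function(x, ...) {
  graphics::plot(fitted(x, "conditional"), residuals(x, "conditional"),
                 xlab = "Conditional fitted (C.L.)",
                 ylab = "Conditional residual (C.L.)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Wald test of a single fixed effect
#'
#' Large-sample Wald test of \eqn{\beta = 0}: \eqn{z = \hat\beta / SE},
#' two-sided p from the standard normal. No degrees-of-freedom correction
#' is applied (Satterthwaite-type corrections are out of scope).
#'
#' @param fit An [nrt_lmm()] fit.
#' @param coefficient Name of a fixed-effect column.
#' @return List with `estimate`, `se`, `z`, `p`.
#' @examples
#' \dontrun{wald_test(fit, "scalarST")}
#' @export
wald_test <- function(fit, coefficient) {
  stopifnot(inherits(fit, "nrt_lmm"))
  if (!coefficient %in% names(fit$coefficients)) {
    stop("unknown coefficient '", coefficient, "'; available: ",
         paste(names(fit$coefficients), collapse = ", "))
  }
  est <- unname(fit$coefficients[coefficient])
  se <- unname(fit$se[coefficient])
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bayesian information criterion of a mixed-model fit
#'
#' \eqn{BIC = -2\,\ell_{REML} + k \ln N} with k the number of estimated
#' parameters (fixed effects plus the two variance components) and N the
#' number of observations. Model selection picks the smallest BIC
#' (the smaller-is-better convention).
#'
#' @param fit An [nrt_lmm()] fit.
#' @return Scalar BIC.
#' @export
model_bic <- function(fit) {
  stopifnot(inherits(fit, "nrt_lmm"))
  fit$bic
}

#' BLUP random intercepts
#'
#' Best linear unbiased predictors of the subject intercepts,
#' \eqn{\hat b_i = \frac{\sigma_b^2 n_i}{\sigma_e^2 + n_i \sigma_b^2}
#' \bar r_i} with \eqn{\bar r_i} the subject's mean marginal residual;
#' they shrink the raw subject means toward zero, fully so when
#' \eqn{\sigma_b^2 = 0}.
#'
#' @param fit An [nrt_lmm()] fit.
#' @return Named numeric vector, one shrunken intercept per subject (C.L.).
#' @export
blup_random_intercepts <- function(fit) {
  stopifnot(inherits(fit, "nrt_lmm"))
  fit$blup
}

#' BIC-based selection of the frequency functional form
#'
#' Fits the candidate fixed-effect shapes for the threshold-frequency
#' relation -- linear, quadratic, cubic, and the two-knot truncated-power
#' cubic spline -- each inside the same random-intercept model, and returns
#' the BIC-best candidate (smallest BIC). Candidates are fitted by full
#' maximum likelihood: the restricted likelihood is defined relative to the
#' fixed-effect design and is not comparable across candidates that differ
#' in it.
#'
#' @param y Response vector (NRT thresholds, C.L.).
#' @param f Frequencies in Hz, same length as `y`.
#' @param group Grouping vector (subject ids), same length as `y`.
#' @param forms Candidate forms, a subset of
#'   `c("linear", "quadratic", "cubic", "spline")`.
#' @param knots Spline knots in Hz for the `"spline"` candidate.
#' @return List with `chosen` (form name), `bic` (named vector over
#'   candidates) and `fits` (the [nrt_lmm()] objects).
#' @export
select_functional_form <- function(y, f, group,
                                   forms = c("linear", "quadratic",
                                             "cubic", "spline"),
                                   knots = c(5000, 10000)) {
  forms <- match.arg(forms, several.ok = TRUE)
  dat <- data.frame(y = y, f = f, g = group)
  rhs <- c(linear = "f", quadratic = "f + I(f^2)",
           cubic = "f + I(f^2) + I(f^3)",
           spline = sprintf("tp_spline(f, knots = c(%s))",
                            paste(knots, collapse = ", ")))
  fits <- list()
  bic <- c()
  for (fo in forms) {
    fit <- tryCatch(
      nrt_lmm(stats::as.formula(paste("y ~", rhs[[fo]])), dat, "g",
              method = "ML"),
      error = function(e) {
        warning("candidate '", fo, "' excluded: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      fits[[fo]] <- fit
      bic[fo] <- fit$bic
    }
  }
  if (!length(bic)) stop("no candidate form could be fitted")
  list(chosen = names(bic)[which.min(bic)], bic = bic, fits = fits)
}
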