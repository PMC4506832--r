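#' Truncated-power cubic spline basis
#'
#' Builds the piecewise-cubic design columns used to model NRT threshold as
#' a function of characteristic neuron frequency: the global polynomial
#' terms `f`, `f^2`, `f^3` plus one truncated cubic `(f - k)^3_+` per knot.
#' The resulting spline is continuous with continuous first and second
#' derivatives across each knot (C2), the defining property of a cubic
#' truncated-power basis.
#'
#' Columns are returned on the raw Hz scale (knots are specified in Hz);
#' numerical conditioning during model fitting is handled internally by the
#' fitter, see [nrt_lmm()].
#'
#' @param f Positive frequencies in Hz.
#' @param knots Strictly increasing positive knot frequencies in Hz;
#'   default `c(5000, 10000)`.
#' @return Numeric matrix with `length(f)` rows and `3 + length(knots)`
#'   columns named `f`, `f2`, `f3`, `k<knot>`.
#' @examples
#' tp_spline(c(4000, 5000, 12000))
#' @export
tp_spline <- function(f, knots = c(5000, 10000)) {
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("'f' must be positive frequencies in Hz")
  }
  if (any(!is.finite(knots)) || any(knots <= 0) ||
      is.unsorted(knots, strictly = TRUE)) {
    stop("'knots' must be strictly increasing positive frequencies in Hz")
  }
  out <- cbind(f = f, f2 = f^2, f3 = f^3)
  for (k in knots) {
    out <- cbind(out, pmax(f - k, 0)^3)
  }
  colnames(out) <- c("f", "f2", "f3", paste0("k", format(knots,
                                                         scientific = FALSE,
                                                         trim = TRUE)))
  out
}

#' Evaluate a spline curve from its coefficients
#'
#' Convenience wrapper: evaluates `tp_spline(f, knots) %*% coefs`. Used for
#' the generator's frequency-profile ground truth and in tests.
#'
#' @param f Frequencies in Hz.
#' @param coefs Coefficient vector on the [tp_spline()] basis
#'   (length `3 + length(knots)`).
#' @param knots Knot frequencies in Hz.
#' @return Numeric vector of curve values (C.L. when `coefs` are threshold
#'   coefficients).
#' @export
eval_tp_spline <- function(f, coefs, knots = c(5000, 10000)) {
  B <- tp_spline(f, knots)
  if (length(coefs) != ncol(B)) {
    stop("'coefs' must have length ", ncol(B), " for ", length(knots),
         " knot(s)")
  }
  drop(B %*% coefs)
}
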