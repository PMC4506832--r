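# Independent brute-force REML oracle: dense-matrix algebra and a grid
# search over the variance ratio, sharing no code with the package fitter.

oracle_reml_loglik <- function(lambda, y, X, g) {
  g <- factor(g)
  Z <- stats::model.matrix(~ g - 1)
  n <- length(y)
  p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  s2 <- quad / (n - p)
  ll <- -0.5 * ((n - p) * log(s2) +
                  as.numeric(determinant(V)$modulus) +
                  as.numeric(determinant(XtViX)$modulus) +
                  (n - p) * (1 + log(2 * pi)))
  list(loglik = ll, beta = drop(beta), sigma2_e = s2,
       sigma2_b = lambda * s2)
}

oracle_reml_fit <- function(y, X, g,
                            grid = c(0, 10^seq(-6, 6, length.out = 241))) {
  lls <- vapply(grid, function(l) oracle_reml_loglik(l, y, X, g)$loglik,
                numeric(1))
  i <- which.max(lls)
  lam <- grid[i]
  if (i > 1 && i < length(grid)) {
    opt <- stats::optimize(
      function(l) -oracle_reml_loglik(l, y, X, g)$loglik,
      interval = c(grid[i - 1], grid[i + 1]), tol = 1e-12)
    if (-opt$objective > lls[i]) lam <- opt$minimum
  }
  oracle_reml_fit_at(lam, y, X, g)
}

oracle_reml_fit_at <- function(lambda, y, X, g) {
  out <- oracle_reml_loglik(lambda, y, X, g)
  out$lambda <- lambda
  out
}
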