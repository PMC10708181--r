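## Independent oracles used to cross-check the package's estimators.

## OLS via R's model fitter (the package computes slopes in closed form).
ols_oracle <- function(tt, yy) {
  fit <- lm(yy ~ tt)
  list(slope = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       se = summary(fit)$coefficients[2, 2])
}

## Brute-force REML profile likelihood for the random-intercept model
## y = a + b*t + u_pep + e, u ~ N(0, sb^2), e ~ N(0, se^2). Profiles the
## ratio theta = sb/se on a grid; beta and the residual variance have
## closed forms given theta. Returns the kd (= -slope) at the optimum.
reml_profile_kd <- function(tt, yy, pep, theta_grid = seq(0, 5, by = 0.0025)) {
  X <- cbind(1, tt)
  Z <- outer(pep, unique(pep), "==") * 1
  n <- length(yy)
  p <- ncol(X)
  crit <- function(theta) {
    V0 <- diag(n) + theta^2 * tcrossprod(Z)
    Vi <- solve(V0)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% yy)
    r <- yy - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    val <- as.numeric(determinant(V0)$modulus) +
      as.numeric(determinant(XtVX)$modulus) +
      (n - p) * (1 + log(2 * pi * s2))
    list(crit = val, slope = beta[2])
  }
  vals <- vapply(theta_grid, function(th) crit(th)$crit, numeric(1))
  best <- theta_grid[which.min(vals)]
  ## local refinement around the coarse optimum
  fine <- seq(max(0, best - 0.005), best + 0.005, by = 1e-4)
  vals_f <- vapply(fine, function(th) crit(th)$crit, numeric(1))
  -crit(fine[which.min(vals_f)])$slope
}

## Benjamini-Hochberg step-up computed literally from its definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

## Two-sample KS statistic as the supremum of the ECDF difference,
## evaluated at every pooled data point.
ks_sup_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(pts, function(v) mean(y <= v), numeric(1))
  max(abs(Fx - Fy))
}
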