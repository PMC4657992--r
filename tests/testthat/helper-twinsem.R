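# Shared builders and independent brute-force oracles.

# Bivariate AE path matrices from heritabilities and component correlations.
biv_paths <- function(h2, rg = 0, re = 0) {
  SA <- diag(sqrt(h2)) %*% matrix(c(1, rg, rg, 1), 2) %*% diag(sqrt(h2))
  SE <- diag(sqrt(1 - h2)) %*% matrix(c(1, re, re, 1), 2) %*% diag(sqrt(1 - h2))
  list(a = t(chol(SA)), e = t(chol(SE)))
}

cont_ph <- function(n) lapply(paste0("t", seq_len(n)), phenotype)

# Brute-force bivariate normal rectangle probability: 2-D Simpson rule on the
# density over the (truncated) rectangle. Independent of the package's
# quadrature (which integrates the conditioned 1-D CDF difference).
bf_rect2 <- function(lower, upper, rho, lim = 8.5, n = 801L) {
  gx <- seq(max(lower[1], -lim), min(upper[1], lim), length.out = n)
  gy <- seq(max(lower[2], -lim), min(upper[2], lim), length.out = n)
  hx <- gx[2] - gx[1]; hy <- gy[2] - gy[1]
  wx <- c(1, rep(c(4, 2), length.out = n - 2), 1); wx[n] <- 1
  wy <- wx
  det <- 1 - rho^2
  f <- outer(gx, gy, function(x, y)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * det)) / (2 * pi * sqrt(det)))
  (hx * hy / 9) * drop(t(wx) %*% f %*% wy)
}

# Brute-force tetrachoric: grid search over rho maximizing the 2x2 multinomial
# likelihood (thresholds from margins), rho in [-0.999, 0.999] step 1e-3.
bf_tetrachoric <- function(tab, step = 1e-3) {
  n <- sum(tab)
  tau_x <- qnorm(1 - sum(tab[2, ]) / n)
  tau_y <- qnorm(1 - sum(tab[, 2]) / n)
  rhos <- seq(-0.999, 0.999, by = step)
  ll <- vapply(rhos, function(r) {
    p11 <- bf_rect2(c(tau_x, tau_y), c(Inf, Inf), r)
    px1 <- pnorm(tau_x, lower.tail = FALSE); py1 <- pnorm(tau_y, lower.tail = FALSE)
    pr <- pmax(c(1 - px1 - py1 + p11, py1 - p11, px1 - p11, p11), 1e-12)
    sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(pr))
  }, 0)
  rhos[which.max(ll)]
}

# Brute-force upper-tail chi-square probability by numerical integration of
# the density.
bf_chi2_sf <- function(x, df) {
  stats::integrate(function(t) stats::dchisq(t, df), x, Inf,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Empirical cross-twin covariance matrix (trait i twin 1 vs trait j twin 2,
# double entered) from a complete-data cohort.
cross_twin_cov <- function(dat, traits, zyg) {
  d <- dat[dat$zygosity == zyg, ]
  X1 <- as.matrix(d[, paste0(traits, "_1")])
  X2 <- as.matrix(d[, paste0(traits, "_2")])
  (cov(X1, X2) + cov(X2, X1)) / 2
}

# Fit object with every parameter fixed at supplied natural values (no free
# parameters): used to evaluate decomposition formulas at known truth.
fixed_fit <- function(model, data, values) {
  fit_twin_model(model, data, starts = 0L, fixed = values, hessian = FALSE)
}
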