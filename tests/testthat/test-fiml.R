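# FIML likelihood correctness: closed-form Gaussian equality on complete
# data, marginalization of missing co-twins, latent-orthant probabilities for
# binary traits, additivity, exchangeability, and standardization identities.

make_biv_model_params <- function(rg = 0.6) {
  ph <- cont_ph(2)
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  pp <- biv_paths(c(0.6, 0.5), rg = rg)
  pv <- par_start(m)
  for (ii in 1:2) for (jj in 1:ii) {
    pv[sprintf("A[%d,%d]", ii, jj)] <- pp$a[ii, jj]
    pv[sprintf("E[%d,%d]", ii, jj)] <- pp$e[ii, jj]
  }
  pv[grepl("^mean", names(pv))] <- c(0.3, -0.2)
  list(model = m, pv = pv)
}

test_that("complete continuous pairs equal the direct multivariate normal density", {
  mp <- make_biv_model_params()
  mom <- expected_moments(mp$model, mp$pv, "DZ")
  set.seed(20)
  for (rep in 1:5) {
    x <- as.numeric(mvtnorm::rmvnorm(1, mom$mean, mom$cov))
    expect_equal(pair_loglik(x, mom),
                 mvtnorm::dmvnorm(x, mom$mean, mom$cov, log = TRUE),
                 tolerance = 1e-10)
  }
  # one twin entirely missing: p-variate marginal
  x <- c(0.5, -1.2, NA, NA)
  expect_equal(pair_loglik(x, mom),
               mvtnorm::dmvnorm(x[1:2], mom$mean[1:2], mom$cov[1:2, 1:2],
                                log = TRUE),
               tolerance = 1e-10)
  expect_error(pair_loglik(rep(NA, 4), mom), "empty")
})

test_that("FIML on complete data equals the complete-data Gaussian -2 log L", {
  mp <- make_biv_model_params()
  sp <- generative_spec(60, 60, cont_ph(2), biv_paths(c(0.6, 0.5), rg = 0.6),
                        missing_record = 0, seed = 21)
  d <- simulate_cohort(sp)
  m2 <- total_minus2LL(mp$model, mp$pv, d)
  # independent oracle: sum of dmvnorm over pairs by zygosity
  ll <- 0
  for (z in c("MZ", "DZ")) {
    mom <- expected_moments(mp$model, mp$pv, z)
    X <- as.matrix(d[d$zygosity == z, c("t1_1", "t2_1", "t1_2", "t2_2")])
    ll <- ll + sum(mvtnorm::dmvnorm(X, mom$mean, mom$cov, log = TRUE))
  }
  expect_equal(m2, -2 * ll, tolerance = 1e-8)
})

test_that("binary orthant contributions match brute-force integration", {
  # single binary trait pair, both affected, standardized AE with rMZ = 0.64
  ph <- list(phenotype("y", "binary", prevalence = 0.1962))
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  pv <- par_start(m)
  pv["A[1,1]"] <- 0.8
  tau <- 0.856
  pv["tau[y]"] <- tau
  mom <- expected_moments(m, pv, "MZ")
  expect_equal(mom$cov[1, 2], 0.64, tolerance = 1e-12)
  ll <- pair_loglik(c(1, 1), mom)
  expect_equal(ll, log(bf_rect2(c(tau, tau), c(Inf, Inf), 0.64)),
               tolerance = 1e-6)
  # discordant pattern
  ll01 <- pair_loglik(c(0, 1), mom)
  expect_equal(ll01, log(bf_rect2(c(-Inf, tau), c(tau, Inf), 0.64)),
               tolerance = 1e-6)
  # binary + continuous conditioning (2 continuous observed, 1 binary)
  mp <- biv_paths(c(0.5, 0.7), rg = 0.5)
  ph2 <- list(phenotype("x"), phenotype("y", "binary", prevalence = 0.3))
  m2 <- twin_model("cholesky", c("A", "E"), ph2, age = FALSE)
  pv2 <- par_start(m2)
  for (ii in 1:2) for (jj in 1:ii) for (co in c("A", "E")) {
    nm <- sprintf("%s[%d,%d]", co, ii, jj)
    if (nm %in% names(pv2)) pv2[nm] <- (if (co == "A") mp$a else mp$e)[ii, jj]
  }
  pv2["mean[x]"] <- 0; pv2["tau[y]"] <- qnorm(0.7)
  mom2 <- expected_moments(m2, pv2, "DZ")
  v <- c(0.4, 1, -0.3, 0)
  o <- c(1, 3); b <- c(2, 4)
  S <- mom2$cov
  K <- S[b, o] %*% solve(S[o, o])
  cmu <- drop(K %*% (v[o] - mom2$mean[o]))
  cS <- S[b, b] - K %*% S[o, b]
  sds <- sqrt(diag(cS))
  rho <- cS[1, 2] / prod(sds)
  tau2 <- qnorm(0.7)
  p_oracle <- bf_rect2((c(tau2, -Inf) - cmu) / sds, (c(Inf, tau2) - cmu) / sds, rho)
  ll_oracle <- mvtnorm::dmvnorm(v[o], mom2$mean[o], S[o, o], log = TRUE) +
    log(p_oracle)
  expect_equal(pair_loglik(v, mom2), ll_oracle, tolerance = 1e-6)
})

test_that("total -2 log L is additive and exchangeable in twin order", {
  mp <- make_biv_model_params()
  sp <- generative_spec(25, 25, cont_ph(2), biv_paths(c(0.6, 0.5), rg = 0.6),
                        missing_record = 0.3, seed = 22)
  d <- simulate_cohort(sp)
  m2 <- total_minus2LL(mp$model, mp$pv, d)
  expect_equal(total_minus2LL(mp$model, mp$pv, rbind(d, d)), 2 * m2,
               tolerance = 1e-9)
  swapped <- d
  swapped[, c("t1_1", "t2_1", "t1_2", "t2_2")] <- d[, c("t1_2", "t2_2", "t1_1", "t2_1")]
  expect_equal(total_minus2LL(mp$model, mp$pv, swapped), m2, tolerance = 1e-9)
})

test_that("saturated likelihood at sample moments equals the closed form", {
  sp <- generative_spec(80, 90, cont_ph(2), biv_paths(c(0.6, 0.5), rg = 0.4),
                        missing_record = 0, seed = 23)
  d <- simulate_cohort(sp)
  m <- twin_model("saturated", phenotypes = cont_ph(2), age = FALSE)
  pv <- par_start(m)
  closed <- 0
  cols <- c("t1_1", "t2_1", "t1_2", "t2_2")
  for (g in c("MZ", "DZ")) {
    X <- as.matrix(d[d$zygosity == g, cols])
    n <- nrow(X)
    mu <- colMeans(X)
    S <- cov(X) * (n - 1) / n    # ML covariance
    L <- t(chol(S))
    for (cc in 1:4) for (rr in cc:4)
      pv[sprintf("L%s[%d,%d]", g, rr, cc)] <- L[rr, cc]
    for (t in 1:2) for (ii in 1:2)
      pv[sprintf("mean_%s_t%d[t%d]", g, t, ii)] <- mu[(t - 1) * 2 + ii]
    closed <- closed + n * (4 * log(2 * pi) + determinant(S)$modulus[1] + 4)
  }
  expect_equal(total_minus2LL(m, pv, d), closed, tolerance = 1e-8)
  # any structured model cannot beat the saturated optimum (nesting)
  fit_sat <- fit_twin_model(m, d, starts = 1, hessian = FALSE)
  expect_lte(fit_sat$minus2LL, closed + 1e-4)
  mp <- make_biv_model_params(rg = 0.4)
  fit_ae <- fit_twin_model(mp$model, d, starts = 1, hessian = FALSE)
  expect_gte(fit_ae$minus2LL, fit_sat$minus2LL - 0.05)
})

test_that("a fully fixed model evaluates without optimization", {
  mp <- make_biv_model_params()
  sp <- generative_spec(40, 40, cont_ph(2), biv_paths(c(0.6, 0.5), rg = 0.6),
                        missing_record = 0, seed = 24)
  d <- simulate_cohort(sp)
  fit <- fixed_fit(mp$model, d, mp$pv)
  expect_identical(fit$k, 0L)
  expect_equal(fit$minus2LL, total_minus2LL(mp$model, mp$pv, d), tolerance = 1e-9)
})

test_that("standardization divides by the implied phenotypic SD", {
  ph <- list(phenotype("y"))
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  sp <- generative_spec(40, 40, ph, list(a = matrix(0.8, 1, 1),
                                         e = matrix(0.6, 1, 1)),
                        missing_record = 0, seed = 25)
  d <- simulate_cohort(sp)
  pv <- par_start(m)
  # already standardized: unchanged
  pv[c("A[1,1]", "E[1,1]", "mean[y]")] <- c(0.8, 0.6, 0)
  f1 <- fixed_fit(m, d, pv)
  s1 <- standardize(f1)
  expect_equal(s1$std$paths$A[1, 1], 0.8, tolerance = 1e-12)
  # a = 1.6, e = 1.2 (variance 4) -> standardized 0.8 / 0.6
  pv[c("A[1,1]", "E[1,1]")] <- c(1.6, 1.2)
  f2 <- fixed_fit(m, d, pv)
  s2 <- standardize(f2)
  expect_equal(s2$std$paths$A[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(s2$std$paths$E[1, 1], 0.6, tolerance = 1e-12)
})

test_that("squared standardized paths per trait sum to one in a fitted model", {
  sp <- generative_spec(150, 150, cont_ph(2), biv_paths(c(0.6, 0.5), rg = 0.6),
                        missing_record = 0.2, seed = 26)
  d <- simulate_cohort(sp)
  m <- twin_model("cholesky", c("A", "E"), cont_ph(2), age = FALSE)
  fit <- standardize(fit_twin_model(m, d, starts = 1, hessian = FALSE))
  sums <- rowSums(fit$std$paths$A^2) + rowSums(fit$std$paths$E^2)
  expect_equal(sums, c(1, 1), tolerance = 1e-6)
})

test_that("parameter recovery is unbiased for ACE and mixed binary models", {
  # ACE univariate at study scale (a2=0.4, c2=0.3, e2=0.3), modest replicates;
  # the AE/ADE recovery at the paper's values runs in the acceptance suite
  ph <- list(phenotype("y"))
  sp <- generative_spec(219, 244, ph,
                        list(a = matrix(sqrt(0.4), 1, 1),
                             c = matrix(sqrt(0.3), 1, 1),
                             e = matrix(sqrt(0.3), 1, 1)),
                        missing_record = 0, seed = 27)
  m <- twin_model("cholesky", c("A", "C", "E"), ph, age = FALSE)
  q <- list(
    a2 = list(fun = function(f) {
      b <- f$structure_at_fit
      b$SA[1, 1] / (b$SA[1, 1] + b$SC[1, 1] + b$SE[1, 1])
    }, truth = 0.4))
  r <- recovery_experiment(sp, m, q, reps = 60, starts = 1)
  expect_lt(abs(r$bias), 0.06)
  # univariate binary AE at the CWP prevalence
  phb <- list(phenotype("y", "binary", prevalence = 0.1962))
  spb <- generative_spec(219, 244, phb,
                         list(a = matrix(sqrt(0.708), 1, 1),
                              e = matrix(sqrt(0.292), 1, 1)),
                         missing_record = 0.44, seed = 28)
  mb <- twin_model("cholesky", c("A", "E"), phb, age = FALSE)
  qb <- list(h2 = list(fun = function(f) {
    b <- f$structure_at_fit
    b$SA[1, 1] / (b$SA[1, 1] + b$SE[1, 1])
  }, truth = 0.708))
  rb <- recovery_experiment(spb, mb, qb, reps = 40, starts = 1)
  expect_lt(abs(rb$bias), 0.1)
})
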