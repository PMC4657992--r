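# Decomposition quantities evaluated at known truth via fully fixed fits,
# plus convergence of a fitted decomposition to the generative values.

fixed_ae_fit <- function(a, e, seed = 33) {
  p <- nrow(a)
  ph <- cont_ph(p)
  sp <- generative_spec(30, 30, ph, list(a = a, e = e), missing_record = 0,
                        seed = seed)
  d <- simulate_cohort(sp)
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  pv <- par_start(m)
  for (ii in seq_len(p)) for (jj in seq_len(ii)) {
    pv[sprintf("A[%d,%d]", ii, jj)] <- a[ii, jj]
    pv[sprintf("E[%d,%d]", ii, jj)] <- e[ii, jj]
  }
  pv[grepl("^mean", names(pv))] <- 0
  fixed_fit(m, d, pv)
}

test_that("heritability is the standardized genetic variance share", {
  f <- fixed_ae_fit(matrix(0.8, 1, 1), matrix(0.6, 1, 1))
  expect_equal(heritability(f)$h2, 64, tolerance = 1e-9)
  # E-dominant truth: near-zero heritability
  f0 <- fixed_ae_fit(matrix(1e-4, 1, 1), matrix(1, 1, 1))
  expect_lt(heritability(f0)$h2, 0.01)
})

test_that("variance percentages square the standardized loadings and sum to 100", {
  # standardized loading 0.6325 on a unit-variance trait -> 40%
  a <- rbind(c(sqrt(0.5), 0), c(0.6325, sqrt(1 - 0.6325^2 - 0.09 - 0.16)))
  e <- rbind(c(sqrt(0.5), 0), c(0.3, 0.4))
  f <- fixed_ae_fit(a, e)
  vp <- variance_percent(f)
  expect_equal(vp["A1", "t2"], 40.00556, tolerance = 1e-3)
  expect_equal(vp["A2", "t1"], 0)
  expect_equal(unname(colSums(vp)), c(100, 100), tolerance = 0.1)
  expect_equal(heritability(f)$h2, unname(colSums(vp[c("A1", "A2"), ])),
               tolerance = 0.1)
})

test_that("genetic correlations follow the Cholesky closed form", {
  a <- rbind(c(0.6, 0), c(0.3, 0.4))
  e <- rbind(c(0.5, 0), c(0, 0.5))
  f <- fixed_ae_fit(a, e)
  rg <- genetic_correlations(f)
  expect_equal(rg[1, 2], 0.18 / (0.6 * 0.5), tolerance = 1e-9)
  expect_equal(diag(rg), c(t1 = 1, t2 = 1))
  # diagonal a: zero off-diagonal rG
  f2 <- fixed_ae_fit(diag(c(0.6, 0.5)), e)
  expect_equal(genetic_correlations(f2)[1, 2], 0)
  # rE with a structural zero prints 0
  expect_equal(environmental_correlations(f)[1, 2], 0)
})

test_that("rG and rE of a fitted model are valid correlation matrices", {
  pp <- default_paths()
  ph <- cont_ph(4)
  sp <- generative_spec(150, 150, ph, pp, missing_record = 0, seed = 34)
  d <- simulate_cohort(sp)
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  fit <- fit_twin_model(m, d, starts = 1, hessian = FALSE)
  for (R in list(genetic_correlations(fit), environmental_correlations(fit))) {
    expect_equal(unname(diag(R)), rep(1, 4))
    expect_true(all(abs(R) <= 1 + 1e-8))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  }
})

test_that("shared genetic variance attributes squared cross-paths by factor origin", {
  # target loads on a single earlier factor
  a <- rbind(c(0.7, 0), c(0.5, 0))
  e <- rbind(c(sqrt(1 - 0.49), 0), c(0, sqrt(1 - 0.25)))
  f <- fixed_ae_fit(a, e)
  sh <- shared_genetic_variance(f, "t2")
  expect_equal(unname(sh$shares["t1"]), 100, tolerance = 1e-9)
  # all cross-paths zero: fully trait-specific
  f2 <- fixed_ae_fit(diag(c(0.7, 0.6)), diag(sqrt(1 - c(0.49, 0.36))))
  sh2 <- shared_genetic_variance(f2, "t2")
  expect_equal(unname(sh2$shares["t2_specific"]), 100, tolerance = 1e-9)
  # known mixed attribution
  a3 <- rbind(c(0.8, 0, 0), c(0.4, 0.6, 0), c(0.3, 0.2, 0.5))
  e3 <- diag(3) * 0.5
  f3 <- fixed_ae_fit(a3, e3)
  sh3 <- shared_genetic_variance(f3, 3)
  tot <- 0.09 + 0.04 + 0.25
  expect_equal(unname(sh3$shares),
               100 * c(0.09, 0.04, 0.25) / tot, tolerance = 1e-9)
  expect_equal(sum(sh3$shares), 100, tolerance = 1e-9)
})

test_that("the default generative structure reproduces the published attribution", {
  # chol of the implied genetic covariance -> CWP genetic variance shares
  pp <- default_paths()
  ph <- cont_ph(4)
  sp <- generative_spec(30, 30, ph, pp, missing_record = 0, seed = 35)
  d <- simulate_cohort(sp)
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  pv <- par_start(m)
  for (ii in 1:4) for (jj in 1:ii) {
    pv[sprintf("A[%d,%d]", ii, jj)] <- pp$a[ii, jj]
    pv[sprintf("E[%d,%d]", ii, jj)] <- pp$e[ii, jj]
  }
  pv[grepl("^mean", names(pv))] <- 0
  f <- fixed_fit(m, d, pv)
  sh <- shared_genetic_variance(f, 4)$shares
  # independent arithmetic: squared fourth-row entries of chol(SA)
  SA <- tcrossprod(pp$a)
  L4 <- t(chol(SA))[4, ]
  expect_equal(unname(sh), unname(100 * L4^2 / sum(L4^2)), tolerance = 1e-9)
  expect_equal(unname(round(sh[1:3])), c(9, 61, 30))
})

test_that("decomposition quantities converge to generative values at large n", {
  pp <- biv_paths(c(0.6, 0.45), rg = 0.7, re = 0.2)
  ph <- cont_ph(2)
  sp <- generative_spec(25000, 25000, ph, pp, missing_record = 0, seed = 36)
  d <- simulate_cohort(sp)
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  fit <- fit_twin_model(m, d, starts = 1, hessian = FALSE)
  expect_lt(max(abs(heritability(fit)$h2 / 100 - c(0.6, 0.45))), 0.02)
  expect_lt(abs(genetic_correlations(fit)[1, 2] - 0.7), 0.02)
  expect_lt(abs(environmental_correlations(fit)[1, 2] - 0.2), 0.02)
  sh <- shared_genetic_variance(fit, 2)$shares / 100
  truthA <- tcrossprod(pp$a)
  L2 <- t(chol(truthA))[2, ]
  expect_lt(max(abs(sh - L2^2 / sum(L2^2))), 0.02)
})

test_that("decomposition reports guard their preconditions", {
  f <- fixed_ae_fit(matrix(0.8, 1, 1), matrix(0.6, 1, 1))
  expect_error(shared_genetic_variance(f, "nope"), "unknown target")
  e_only <- fixed_ae_fit(matrix(1e-7, 1, 1), matrix(1, 1, 1))
  expect_error(shared_genetic_variance(e_only, 1), "zero genetic variance")
  rep <- decomposition_report(f)
  expect_s3_class(rep, "decomposition_report")
  expect_named(rep$shared_genetic, "t1")
})
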