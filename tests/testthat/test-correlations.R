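test_that("pearson correlation recovers known structure with Fisher intervals", {
  set.seed(10)
  x <- rnorm(1e5)
  expect_equal(pearson_corr(x, x)$value, 1, tolerance = 1e-12)
  y <- rnorm(1e5)
  expect_lt(abs(pearson_corr(x, y)$value), 0.02)
  rho <- 0.45
  z <- rho * x + sqrt(1 - rho^2) * rnorm(1e5)
  est <- pearson_corr(x, z)
  expect_equal(est$value, 0.45, tolerance = 0.01)
  expect_true(est$ci_low <= est$value && est$value <= est$ci_high)
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_corr(1:2, 1:2), "3 complete")
})

test_that("tetrachoric ML reproduces closed forms and flags boundaries", {
  # independence: all cells equal
  t0 <- matrix(c(100, 100, 100, 100), 2)
  expect_equal(tetrachoric_corr(t0, B = 0)$value, 0, tolerance = 1e-3)
  # median splits: p11 = 1/4 + arcsin(rho)/(2 pi); table [[200,100],[100,200]]
  t1 <- rbind(c(200, 100), c(100, 200))
  expect_equal(tetrachoric_corr(t1, B = 0)$value, 0.5, tolerance = 1e-3)
  # perfect concordance: boundary
  t2 <- rbind(c(150, 0), c(0, 150))
  est <- tetrachoric_corr(t2, B = 0)
  expect_gte(est$value, 0.998)
  expect_true(est$boundary)
  expect_error(tetrachoric_corr(rbind(c(0, 0), c(5, 5)), B = 0), "margin")
})

test_that("tetrachoric ML agrees with brute-force grid search", {
  set.seed(11)
  tabs <- list(rbind(c(310, 120), c(80, 90)),
               rbind(c(40, 60), c(55, 45)),
               rbind(c(500, 40), c(35, 25)))
  for (tb in tabs) {
    ml <- tetrachoric_corr(tb, B = 0)$value
    expect_equal(ml, bf_tetrachoric(tb), tolerance = 2e-3)
  }
})

test_that("biserial ML recovers the latent correlation", {
  set.seed(12)
  n <- 1e5
  x <- rnorm(n)
  yl <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  y <- as.integer(yl > median(yl))
  expect_equal(biserial_corr(x, y, B = 0)$value, 0.5, tolerance = 0.02)
  y2 <- rbinom(n, 1, 0.3)
  expect_lt(abs(biserial_corr(x, y2, B = 0)$value), 0.02)
  # no-noise degenerate: y = 1{x > median} -> boundary near 1
  y3 <- as.integer(x > median(x))
  est <- biserial_corr(x[1:5000], y3[1:5000], B = 0)
  expect_gte(est$value, 0.99)
  expect_error(biserial_corr(x, rep(1L, n), B = 0), "single category")
})

test_that("bootstrap intervals bracket the estimate and respect the seed", {
  set.seed(13)
  x <- rnorm(400); y <- as.integer(0.6 * x + 0.8 * rnorm(400) > 0.5)
  e1 <- biserial_corr(x, y, B = 200, seed = 42)
  e2 <- biserial_corr(x, y, B = 200, seed = 42)
  expect_identical(e1$ci_low, e2$ci_low)
  expect_true(e1$ci_low <= e1$value && e1$value <= e1$ci_high)
})

test_that("cross-twin cross-trait matrix has the theoretical AE pattern", {
  # univariate AE with a2 = 0.72: rMZ = 0.72, rDZ = 0.36
  ph <- list(phenotype("y"))
  sp <- generative_spec(20000, 20000, ph,
                        list(a = matrix(sqrt(0.72), 1, 1),
                             e = matrix(sqrt(0.28), 1, 1)),
                        missing_record = 0, seed = 14)
  d <- simulate_cohort(sp)
  mz <- ctct_matrix(d, "MZ", ph, B = 0)
  dz <- ctct_matrix(d, "DZ", ph, B = 0)
  expect_equal(mz$value[1, 1], 0.72, tolerance = 0.02)
  expect_equal(dz$value[1, 1], 0.36, tolerance = 0.02)
})

test_that("E-only data give near-zero cross-twin correlations; double entry is symmetric", {
  ph <- cont_ph(2)
  sp <- generative_spec(4000, 4000, ph, list(e = biv_paths(c(0.5, 0.5), re = 0.4)$e *
                                               sqrt(2)),
                        missing_record = 0, seed = 15)
  # scale e so total variance is arbitrary but valid (continuous traits)
  d <- simulate_cohort(sp)
  for (z in c("MZ", "DZ")) {
    cm <- ctct_matrix(d, z, ph, B = 0)
    expect_lt(max(abs(cm$value)), 0.05)
    expect_identical(cm$value, t(cm$value))
  }
})

test_that("cross-twin matrix matches the expected cross-twin covariance at large n", {
  pp <- default_paths()
  ph <- cont_ph(4)
  sp <- generative_spec(25000, 25000, ph, pp, missing_record = 0, seed = 16)
  d <- simulate_cohort(sp)
  SA <- tcrossprod(pp$a)
  for (z in c("MZ", "DZ")) {
    alpha <- if (z == "MZ") 1 else 0.5
    cm <- ctct_matrix(d, z, ph, B = 0)
    expect_lt(max(abs(cm$value - alpha * SA)), 0.02)
  }
  # methods chosen by scale in the mixed default set
  d2 <- simulate_cohort(generative_spec(300, 300, seed = 17))
  cm <- ctct_matrix(d2, "MZ", default_phenotypes(), B = 0)
  expect_identical(cm$method[1, 2], "pearson")
  expect_identical(cm$method[3, 4], "tetrachoric")
  expect_identical(cm$method[1, 3], "biserial")
  expect_error(ctct_matrix(d2, "XX", default_phenotypes()), "zygosity")
})

test_that("MZ cross-twin correlations dominate DZ for all-positive genetic paths", {
  a <- rbind(c(0.7, 0), c(0.4, 0.5))
  e <- rbind(c(sqrt(1 - 0.49), 0),
             c(0.1, sqrt(1 - 0.16 - 0.25 - 0.01)))
  ph <- cont_ph(2)
  sp <- generative_spec(20000, 20000, ph, list(a = a, e = e),
                        missing_record = 0, seed = 18)
  d <- simulate_cohort(sp)
  mz <- ctct_matrix(d, "MZ", ph, B = 0)$value
  dz <- ctct_matrix(d, "DZ", ph, B = 0)$value
  expect_true(all(mz >= dz - 0.02))
})

test_that("phenotypic correlation matrix uses the scale-appropriate estimator", {
  d <- simulate_cohort(generative_spec(400, 400, seed = 19))
  pc <- phenotypic_corr_matrix(d, default_phenotypes(), B = 0)
  expect_identical(pc$method[1, 2], "pearson")     # dheas-fatigue
  expect_identical(pc$method[3, 4], "tetrachoric") # depression-cwp
  expect_identical(pc$method[2, 4], "biserial")    # fatigue-cwp
  expect_equal(diag(pc$value), rep(1, 4), ignore_attr = TRUE)
  expect_identical(pc$value, t(pc$value))
  # the fatigue-CWP phenotypic correlation implied by the default structure
  SP <- tcrossprod(default_paths()$a) + tcrossprod(default_paths()$e)
  expect_equal(pc$value[2, 4], SP[2, 4], tolerance = 0.1)
})
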