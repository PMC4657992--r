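test_that("component_covariance multiplies path matrices correctly", {
  L <- rbind(c(0.6, 0), c(0.3, 0.4))
  expect_equal(component_covariance(L), rbind(c(0.36, 0.18), c(0.18, 0.25)))
  expect_equal(component_covariance(diag(3)), diag(3))
  expect_equal(component_covariance(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_error(component_covariance(matrix(1, 2, 3)), "square")
  expect_error(component_covariance(rbind(c(1, 2), c(0, 1))), "lower-triangular")
})

test_that("expected moments reproduce the classical univariate sharing patterns", {
  ph <- list(phenotype("y"))
  # AE, standardized a = 0.8, e = 0.6
  m <- twin_model("cholesky", c("A", "E"), ph, age = FALSE)
  pv <- par_start(m)
  pv[c("A[1,1]", "E[1,1]", "mean[y]")] <- c(0.8, 0.6, 0)
  expect_equal(expected_moments(m, pv, "MZ")$cov,
               rbind(c(1, 0.64), c(0.64, 1)), tolerance = 1e-12)
  expect_equal(expected_moments(m, pv, "DZ")$cov,
               rbind(c(1, 0.32), c(0.32, 1)), tolerance = 1e-12)
  # ACE with a2=0.5, c2=0.3, e2=0.2: rMZ=0.8, rDZ=0.55
  m <- twin_model("cholesky", c("A", "C", "E"), ph, age = FALSE)
  pv <- par_start(m)
  pv[c("A[1,1]", "C[1,1]", "E[1,1]", "mean[y]")] <- c(sqrt(0.5), sqrt(0.3), sqrt(0.2), 0)
  expect_equal(expected_moments(m, pv, "MZ")$cov[1, 2], 0.8, tolerance = 1e-12)
  expect_equal(expected_moments(m, pv, "DZ")$cov[1, 2], 0.55, tolerance = 1e-12)
  # ADE with a2=0.4, d2=0.3: MZ 0.7, DZ 0.275
  m <- twin_model("cholesky", c("A", "D", "E"), ph, age = FALSE)
  pv <- par_start(m)
  pv[c("A[1,1]", "D[1,1]", "E[1,1]", "mean[y]")] <- c(sqrt(0.4), sqrt(0.3), sqrt(0.3), 0)
  expect_equal(expected_moments(m, pv, "MZ")$cov[1, 2], 0.7, tolerance = 1e-12)
  expect_equal(expected_moments(m, pv, "DZ")$cov[1, 2], 0.275, tolerance = 1e-12)
})

test_that("MZ and DZ moments differ only in cross-twin blocks, by 0.5 SA + 0.75 SD", {
  set.seed(42)
  ph <- cont_ph(3)
  m <- twin_model("cholesky", c("A", "D", "E"), ph, age = FALSE)
  for (rep in 1:10) {
    pv <- par_start(m)
    sel <- grepl("^[ADE]\\[", names(pv))
    pv[sel] <- rnorm(sum(sel), 0, 0.5)
    mz <- expected_moments(m, pv, "MZ")$cov
    dz <- expected_moments(m, pv, "DZ")$cov
    expect_equal(mz[1:3, 1:3], dz[1:3, 1:3], tolerance = 1e-12)
    expect_equal(mz[4:6, 4:6], dz[4:6, 4:6], tolerance = 1e-12)
    bs <- twinsem:::build_structure(m, pv)
    expect_equal(mz[1:3, 4:6] - dz[1:3, 4:6], 0.5 * bs$SA + 0.75 * bs$SD,
                 tolerance = 1e-12)
    # Cholesky-parameterized components are PSD by construction
    for (S in list(bs$SA, bs$SD, bs$SE))
      expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
    expect_gte(min(eigen(mz, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("structural parameter counts match the classical bookkeeping", {
  ph <- default_phenotypes()
  expect_identical(count_free_parameters(twin_model("cholesky", c("A", "D", "E"), ph)), 30L)
  expect_identical(count_free_parameters(twin_model("cholesky", c("A", "E"), ph)), 20L)
  expect_identical(count_free_parameters(
    twin_model("independent_pathway", c("A", "E"), ph, n_factors = 1)), 16L)
  expect_identical(count_free_parameters(
    twin_model("independent_pathway", c("A", "E"), ph, n_factors = 2)), 24L)
  expect_identical(count_free_parameters(
    twin_model("common_pathway", c("A", "E"), ph, n_factors = 1)), 13L)
  # reduced model: dropping 7 paths from the 20-parameter AE Cholesky
  red <- twin_model("cholesky", c("A", "E"), ph,
                    drop = "A[2,1], A[3,2], A[4,4], E[2,1], E[4,1], E[4,2], E[4,3]")
  expect_identical(count_free_parameters(red), 13L)
})

test_that("model validation rejects ill-formed specifications", {
  ph <- default_phenotypes()
  expect_error(twin_model("cholesky", c("A", "C", "D", "E"), ph), "C and D")
  expect_error(twin_model("cholesky", c("A"), ph), "E must always")
  expect_error(twin_model("independent_pathway", c("A", "C", "E"), ph), "A\\+E")
  expect_error(twin_model("cholesky", c("A", "E"), ph, drop = "A[1,2]"),
               "lower-triangular")
  expect_error(twin_model("cholesky", c("A", "E"), ph, drop = "E[4,4]"),
               "binary")
  expect_error(phenotype("x", "binary", prevalence = 1.2), "prevalence")
  # parameter-length mismatch
  m <- twin_model("cholesky", c("A", "E"), cont_ph(2), age = FALSE)
  expect_error(expected_moments(m, c(1, 2), "MZ"))
  expect_error(expected_moments(m, par_start(m), "XX"), "zygosity")
})
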