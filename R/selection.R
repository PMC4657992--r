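## Likelihood-ratio tests, AIC and the four-step model-comparison ladder:
## (1) full ACE and ADE Cholesky vs the fully saturated model (equality-of-
## moments assumption check) and ACE-vs-ADE choice by AIC; (2) dropping C/D;
## (3) AE Cholesky vs independent- and common-pathway alternatives;
## (4) user-declared reduced submodels. Selection: lowest AIC among models not
## rejected by LRT against the full Cholesky base at alpha.

#' Upper-tail chi-square probability
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (positive).
#' @return `P(Chi2_df >= x)`.
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) stop("negative chi-square statistic")
  if (any(df <= 0)) stop("df must be positive")
  pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_sub,fit_full nested [fit_twin_model()] results (sub within
#'   full).
#' @param tol negative-delta tolerance treated as optimizer noise.
#' @return list with `delta` (difference in -2 log L), `df`, `p`.
#' @export
lrt <- function(fit_sub, fit_full, tol = 0.05) {
  delta <- fit_sub$minus2LL - fit_full$minus2LL
  df <- fit_full$k - fit_sub$k
  if (df < 0) stop("submodel has more free parameters than the full model")
  if (delta < -tol)
    stop("negative LRT statistic (", signif(delta, 4),
         "): optimization failure in the full model")
  delta <- max(delta, 0)
  if (df == 0L) return(list(delta = delta, df = 0L, p = NA_real_))
  list(delta = delta, df = df, p = chi2_sf(delta, df))
}

#' Akaike information criterion of a fit
#'
#' `AIC = -2 log L + 2 k` with `k` the number of free parameters; on this
#' additive scale comparisons satisfy
#' `AIC_sub = AIC_base + delta(-2 log L) - 2 delta(df)`.
#'
#' @param fit a [fit_twin_model()] result.
#' @return scalar AIC.
#' @export
aic <- function(fit) fit$minus2LL + 2 * fit$k

#' AIC of a submodel from a base AIC and a comparison row
#'
#' The AIC identity used by printed comparison tables:
#' `AIC_sub = AIC_base + delta - 2 * ddf`.
#'
#' @param base_aic AIC of the base model.
#' @param delta difference in -2 log L (sub minus base).
#' @param ddf difference in free parameters (base minus sub).
#' @return scalar AIC.
#' @export
aic_from_base <- function(base_aic, delta, ddf) base_aic + delta - 2 * ddf

#' Comparison table of submodels against a base fit
#'
#' @param base_fit the base (full) fit.
#' @param sub_fits named list of nested fits.
#' @param base_name label for the base row.
#' @return data.frame with columns `model`, `minus2LL`, `k`, `delta_m2ll`,
#'   `delta_df`, `p`, `AIC`.
#' @export
comparison_table <- function(base_fit, sub_fits, base_name = "base") {
  rows <- list(data.frame(model = base_name, minus2LL = base_fit$minus2LL,
                          k = base_fit$k, delta_m2ll = NA_real_,
                          delta_df = NA_integer_, p = NA_real_,
                          AIC = aic(base_fit)))
  for (nm in names(sub_fits)) {
    f <- sub_fits[[nm]]
    if (f$k >= base_fit$k) {
      rows[[length(rows) + 1L]] <- data.frame(model = nm, minus2LL = f$minus2LL,
                                              k = f$k, delta_m2ll = NA_real_,
                                              delta_df = NA_integer_,
                                              p = NA_real_, AIC = aic(f))
      next
    }
    lr <- lrt(f, base_fit)
    rows[[length(rows) + 1L]] <- data.frame(model = nm, minus2LL = f$minus2LL,
                                            k = f$k, delta_m2ll = lr$delta,
                                            delta_df = lr$df, p = lr$p,
                                            AIC = aic(f))
  }
  do.call(rbind, rows)
}

#' Four-step model comparison ladder
#'
#' Step 1 fits the fully saturated model and the full ACE and ADE Cholesky
#' models, tests the equality-of-moments assumption (LRT of each full Cholesky
#' against saturated; non-significance supports the assumption) and picks the
#' full model by AIC. Step 2 tests dropping C or D (AE Cholesky vs the chosen
#' full). Step 3 compares AE independent-pathway and common-pathway
#' alternatives (1 and 2 factor sets / latent phenotypes) against the full
#' Cholesky base. Step 4 adds user-declared reduced Cholesky AE submodels
#' (path drop lists). The selected model is the lowest-AIC candidate not
#' rejected by LRT against the base at `alpha`; AIC ties break toward fewer
#' parameters.
#'
#' @param data twin dataset.
#' @param phenotypes list of [phenotype()] objects.
#' @param reduced named list of drop lists (see [parse_drop()]) for step 4.
#' @param alpha LRT rejection level.
#' @param age include the linear age covariate.
#' @param starts,seed,control passed to [fit_twin_model()].
#' @param fits optional named list of precomputed fits to reuse (names among
#'   `saturated`, `ACE_cholesky`, `ADE_cholesky`, `AE_cholesky`, `IP_1`,
#'   `IP_2`, `CP_1`, `CP_2`, and the names of `reduced`).
#' @param include_ip2 also fit the two-factor-set IP and two-latent CP models.
#' @return list with `table` (comparison rows), `fits`, `selected` (name),
#'   `assumption` (saturated-check p-values), `base` (name of the full model
#'   chosen in step 1).
#' @export
four_step_compare <- function(data, phenotypes, reduced = NULL, alpha = 0.05,
                              age = TRUE, starts = 3L, seed = 1L,
                              control = list(), fits = list(),
                              include_ip2 = TRUE) {
  get_fit <- function(name, model, warm = NULL) {
    if (!is.null(fits[[name]])) return(fits[[name]])
    st <- NULL
    if (!is.null(warm)) {
      common <- intersect(names(warm$par), par_template(model)$name)
      st <- warm$par[common]
    }
    fit_twin_model(model, data, starts = starts, seed = seed, start = st,
                   hessian = FALSE, control = control)
  }
  fits <- as.list(fits)
  fits$saturated <- get_fit("saturated",
    twin_model("saturated", phenotypes = phenotypes, age = age))
  fits$ACE_cholesky <- get_fit("ACE_cholesky",
    twin_model("cholesky", c("A", "C", "E"), phenotypes, age = age))
  fits$ADE_cholesky <- get_fit("ADE_cholesky",
    twin_model("cholesky", c("A", "D", "E"), phenotypes, age = age))
  assumption <- c(
    ACE = lrt(fits$ACE_cholesky, fits$saturated)$p,
    ADE = lrt(fits$ADE_cholesky, fits$saturated)$p)
  base <- if (aic(fits$ACE_cholesky) <= aic(fits$ADE_cholesky)) "ACE_cholesky" else "ADE_cholesky"
  base_fit <- fits[[base]]
  fits$AE_cholesky <- get_fit("AE_cholesky",
    twin_model("cholesky", c("A", "E"), phenotypes, age = age), warm = base_fit)
  fits$IP_1 <- get_fit("IP_1",
    twin_model("independent_pathway", c("A", "E"), phenotypes, n_factors = 1L, age = age))
  fits$CP_1 <- get_fit("CP_1",
    twin_model("common_pathway", c("A", "E"), phenotypes, n_factors = 1L, age = age))
  if (include_ip2) {
    fits$IP_2 <- get_fit("IP_2",
      twin_model("independent_pathway", c("A", "E"), phenotypes, n_factors = 2L, age = age))
    fits$CP_2 <- get_fit("CP_2",
      twin_model("common_pathway", c("A", "E"), phenotypes, n_factors = 2L, age = age))
  }
  if (!is.null(reduced)) for (nm in names(reduced)) {
    fits[[nm]] <- get_fit(nm,
      twin_model("cholesky", c("A", "E"), phenotypes, drop = reduced[[nm]],
                 age = age), warm = fits$AE_cholesky)
  }
  sub_names <- setdiff(names(fits), c("saturated", base))
  # order candidates: other full model first, then AE, IP/CP, reduced
  tab_full <- comparison_table(fits$saturated,
                               fits[c("ACE_cholesky", "ADE_cholesky")],
                               base_name = "saturated")
  tab <- comparison_table(base_fit,
                          fits[setdiff(sub_names, c("ACE_cholesky", "ADE_cholesky"))],
                          base_name = base)
  cand <- tab$model[is.na(tab$p) & tab$model == base | (!is.na(tab$p) & tab$p >= alpha)]
  cand <- unique(c(base, cand))
  aics <- vapply(cand, function(nm) aic(fits[[nm]]), 0)
  ks <- vapply(cand, function(nm) fits[[nm]]$k, 0L)
  ord <- order(aics, ks)
  selected <- cand[ord[1]]
  list(table = tab, table_step1 = tab_full, fits = fits, selected = selected,
       assumption = assumption, base = base, alpha = alpha)
}
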