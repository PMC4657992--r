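## Headline quantities of a fitted model: per-trait heritabilities, the
## factor-by-trait percentage-of-variance table, genetic and environmental
## correlation matrices, and the Cholesky attribution of a trait's genetic
## variance to the factors first loading on earlier traits.

stopifnot_structured <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  if (fit$model$structure == "saturated")
    stop("decomposition applies to structured (non-saturated) fits")
}

#' Per-trait heritability with confidence interval
#'
#' `100 * SigmaA_ii / (SigmaA + SigmaC + SigmaD + SigmaE)_ii`, with a
#' delta-method Wald interval when the fit carries a Hessian.
#'
#' @param fit a converged [fit_twin_model()] result including an A component.
#' @param level confidence level.
#' @return data.frame with rows per trait: `h2` (%), `lower`, `upper`.
#' @export
heritability <- function(fit, level = 0.95) {
  stopifnot_structured(fit)
  if (!"A" %in% fit$model$components) stop("model has no A component")
  fun <- function(nat) {
    bs <- build_structure(fit$model, nat)
    V <- diag(bs$SA + bs$SC + bs$SD + bs$SE)
    if (any(V <= 0)) stop("zero phenotypic variance")
    100 * diag(bs$SA) / V
  }
  tab <- quantity_ci(fit, fun, level = level)
  data.frame(trait = fit$model$traits, h2 = tab$estimate,
             lower = pmax(tab$lower, 0), upper = pmin(tab$upper, 100))
}

#' Percentage of phenotypic variance per latent factor
#'
#' Entry (factor, trait) is 100 times the squared standardized loading: the
#' share of the trait's phenotypic variance explained by that latent factor.
#' Factor rows are labelled A1..Ap / E1..Ep (Cholesky: factor k originates
#' from trait k), Ac/Ec plus As/Es (independent pathway), or L1.. plus
#' specifics (common pathway). Per trait, entries of one component sum to the
#' component's percentage and all entries sum to 100.
#'
#' @param fit a converged structured fit.
#' @return numeric matrix (factors x traits, percentages).
#' @export
variance_percent <- function(fit) {
  stopifnot_structured(fit)
  sf <- standardize(fit)
  p <- fit$model$p
  tn <- fit$model$traits
  rows <- list()
  if (fit$model$structure == "cholesky") {
    for (co in fit$model$components) {
      L <- sf$std$paths[[co]]
      for (k in seq_len(p)) rows[[paste0(co, k)]] <- 100 * L[, k]^2
    }
  } else if (fit$model$structure == "independent_pathway") {
    f <- fit$model$n_factors
    for (co in c("A", "E")) {
      G <- sf$std$paths[[paste0(co, "_common")]]
      for (k in seq_len(f)) rows[[paste0(co, "c", k)]] <- 100 * G[, k]^2
      rows[[paste0(co, "s")]] <- 100 * sf$std$paths[[paste0(co, "_specific")]]^2
    }
  } else {
    f <- fit$model$n_factors
    Lam <- sf$std$paths$loadings
    sh <- sf$std$paths$share_A
    for (l in seq_len(f)) {
      rows[[paste0("L", l, "_A")]] <- 100 * Lam[, l]^2 * sh[l]
      rows[[paste0("L", l, "_E")]] <- 100 * Lam[, l]^2 * (1 - sh[l])
    }
    rows[["As"]] <- 100 * sf$std$paths$A_specific^2
    rows[["Es"]] <- 100 * sf$std$paths$E_specific^2
  }
  out <- do.call(rbind, rows)
  colnames(out) <- tn
  out
}

component_correlation <- function(S, tol = 1e-10) {
  p <- nrow(S)
  out <- diag(p)
  for (ii in seq_len(p)) for (jj in seq_len(p)) {
    if (ii == jj) next
    vi <- S[ii, ii]; vj <- S[jj, jj]
    if (vi < tol || vj < tol) {
      if (abs(S[ii, jj]) > sqrt(tol))
        stop("zero component variance with nonzero covariance: corrupt fit")
      out[ii, jj] <- 0   # structural zero, printed as 0 by convention
    } else {
      out[ii, jj] <- S[ii, jj] / sqrt(vi * vj)
    }
  }
  dimnames(out) <- dimnames(S)
  out
}

#' Genetic and environmental correlation matrices
#'
#' `rG_ij = SigmaA_ij / sqrt(SigmaA_ii SigmaA_jj)` — the extent to which
#' genetic effects on one trait correlate with genetic effects on another
#' (pleiotropy); `rE` analogously from the non-shared environmental
#' covariance. Entries whose component variance is structurally zero are
#' reported as 0.
#'
#' @param fit a converged structured fit.
#' @return correlation matrix with unit diagonal.
#' @export
genetic_correlations <- function(fit) {
  stopifnot_structured(fit)
  S <- fit$structure_at_fit$SA
  dimnames(S) <- list(fit$model$traits, fit$model$traits)
  component_correlation(S)
}

#' @rdname genetic_correlations
#' @export
environmental_correlations <- function(fit) {
  stopifnot_structured(fit)
  S <- fit$structure_at_fit$SE
  dimnames(S) <- list(fit$model$traits, fit$model$traits)
  component_correlation(S)
}

#' Attribution of a trait's genetic variance to Cholesky sources
#'
#' Decomposes the genetic variance of the target trait into the squared
#' (standardized) genetic cross-paths from the factors that first load on
#' each earlier trait, renormalized to sum to 100% over contributing sources
#' plus the trait-specific factor. The attribution depends on the declared
#' trait (factor) ordering, which is therefore reported alongside the shares.
#'
#' @param fit a converged Cholesky fit with an A component.
#' @param target trait name or index.
#' @return list with `shares` (named percentages), `ordering` (trait order),
#'   `target`.
#' @export
shared_genetic_variance <- function(fit, target) {
  stopifnot_structured(fit)
  if (fit$model$structure != "cholesky")
    stop("shared-genetic-variance attribution is defined for Cholesky fits")
  if (!"A" %in% fit$model$components) stop("model has no A component")
  tn <- fit$model$traits
  t_idx <- if (is.character(target)) match(target, tn) else as.integer(target)
  if (is.na(t_idx) || t_idx < 1 || t_idx > length(tn)) stop("unknown target trait")
  sf <- standardize(fit)
  arow <- sf$std$paths$A[t_idx, ]
  tot <- sum(arow^2)
  if (tot < 1e-10) stop("target trait has zero genetic variance")
  shares <- 100 * arow[seq_len(t_idx)]^2 / tot
  names(shares) <- c(tn[seq_len(t_idx - 1)], paste0(tn[t_idx], "_specific"))[seq_len(t_idx)]
  if (t_idx == 1) names(shares) <- paste0(tn[1], "_specific")
  list(shares = shares, ordering = tn, target = tn[t_idx])
}

#' Full decomposition report
#'
#' Heritabilities with CIs, the factor-by-trait variance-percentage table,
#' genetic and environmental correlations, and per-trait shared-genetic
#' attributions (Cholesky fits), in one object.
#'
#' @param fit a converged structured fit.
#' @param level confidence level for heritability intervals.
#' @return object of class `decomposition_report`.
#' @export
decomposition_report <- function(fit, level = 0.95) {
  stopifnot_structured(fit)
  rep <- list(
    h2 = heritability(fit, level = level),
    variance_percent = variance_percent(fit),
    rG = if ("A" %in% fit$model$components) genetic_correlations(fit) else NULL,
    rE = environmental_correlations(fit),
    ordering = fit$model$traits)
  if (fit$model$structure == "cholesky" && "A" %in% fit$model$components) {
    rep$shared_genetic <- lapply(seq_along(fit$model$traits), function(ii)
      shared_genetic_variance(fit, ii))
    names(rep$shared_genetic) <- fit$model$traits
  }
  structure(rep, class = "decomposition_report")
}

#' @export
print.decomposition_report <- function(x, ...) {
  cat("Heritability (% of phenotypic variance):\n")
  print(transform(x$h2, h2 = round(h2, 1), lower = round(lower, 1),
                  upper = round(upper, 1)), row.names = FALSE)
  cat("\nVariance explained per factor (%):\n")
  print(round(x$variance_percent, 1))
  if (!is.null(x$rG)) { cat("\nGenetic correlations:\n"); print(round(x$rG, 3)) }
  cat("\nNon-shared environmental correlations:\n"); print(round(x$rE, 3))
  if (!is.null(x$shared_genetic)) {
    cat("\nShared genetic variance attribution (factor ordering: ",
        paste(x$ordering, collapse = " > "), "):\n", sep = "")
    for (nm in names(x$shared_genetic))
      cat(" ", nm, ":", paste(sprintf("%s %.0f%%", names(x$shared_genetic[[nm]]$shares),
                                      x$shared_genetic[[nm]]$shares), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a decomposition report as TSV
#'
#' @param x a `decomposition_report`.
#' @param path output file.
#' @export
write_decomposition_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# heritability (%)", con)
  utils::write.table(x$h2, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# variance percent per factor", con)
  utils::write.table(data.frame(factor = rownames(x$variance_percent),
                                x$variance_percent, check.names = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(x$rG)) {
    writeLines("# genetic correlations", con)
    utils::write.table(data.frame(trait = rownames(x$rG), x$rG, check.names = FALSE),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines("# environmental correlations", con)
  utils::write.table(data.frame(trait = rownames(x$rE), x$rE, check.names = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(x$shared_genetic)) {
    writeLines(paste0("# shared genetic variance (ordering: ",
                      paste(x$ordering, collapse = " > "), ")"), con)
    for (nm in names(x$shared_genetic)) {
      sh <- x$shared_genetic[[nm]]$shares
      writeLines(paste(nm, paste(names(sh), round(sh, 1), sep = "=",
                                 collapse = "\t"), sep = "\t"), con)
    }
  }
  invisible(path)
}
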