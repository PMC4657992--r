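#' Declare a phenotype
#'
#' A phenotype is either continuous (modeled with a free mean and free total
#' variance) or binary (modeled as the indicator of a latent standard-normal
#' liability exceeding a threshold; the liability variance is fixed at 1 for
#' identification and the threshold is free).
#'
#' @param name trait name (used as column prefix: `<name>_1`, `<name>_2`).
#' @param scale `"continuous"` or `"binary"`.
#' @param prevalence for binary traits, the population prevalence in (0,1);
#'   determines the generative threshold and the fitting start value.
#' @param mean,sd generative location/scale for continuous traits (liability
#'   scale; `sd` multiplies the unit-variance liability).
#' @param age_slope generative linear age effect per year, on the trait scale
#'   (continuous) or liability scale (binary).
#' @return an object of class `phenotype`.
#' @export
phenotype <- function(name, scale = c("continuous", "binary"), prevalence = NULL,
                      mean = 0, sd = 1, age_slope = 0) {
  scale <- match.arg(scale)
  if (scale == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("binary phenotype '", name, "' needs a prevalence in (0,1)")
    if (sd != 1) stop("binary phenotype '", name, "' must have unit liability sd")
  }
  structure(list(name = name, scale = scale, prevalence = prevalence,
                 mean = mean, sd = sd, age_slope = age_slope),
            class = "phenotype")
}

#' The default four-trait phenotype set
#'
#' DHEAS and fatigue as continuous traits, depression (prevalence 30.06%) and
#' chronic widespread pain (prevalence 19.62%) as binary liability-threshold
#' traits, in the factor order used throughout: DHEAS, fatigue, depression,
#' CWP.
#'
#' @return list of [phenotype()] objects.
#' @export
default_phenotypes <- function() {
  list(
    phenotype("dheas", "continuous", age_slope = -0.02),
    phenotype("fatigue", "continuous", age_slope = 0.005),
    phenotype("depression", "binary", prevalence = 0.3006),
    phenotype("cwp", "binary", prevalence = 0.1962, age_slope = 0.005)
  )
}

trait_names <- function(phenotypes) vapply(phenotypes, `[[`, "", "name")
trait_scales <- function(phenotypes) vapply(phenotypes, `[[`, "", "scale")

#' Parse a path drop list
#'
#' Reduced Cholesky submodels are expressed by fixing individual path entries
#' to zero. Entries are written `"<component>[row,col]"`, e.g.
#' `"A[2,1], E[4,3]"`, with row/column indices in trait order.
#'
#' @param x character vector (or comma-separated string) of entries, or a
#'   data.frame with columns `component`, `row`, `col`.
#' @return data.frame with columns `component`, `row`, `col`.
#' @export
parse_drop <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    stopifnot(all(c("component", "row", "col") %in% names(x)))
    return(x[c("component", "row", "col")])
  }
  parts <- trimws(unlist(strsplit(x, ",(?![^\\[]*\\])", perl = TRUE)))
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([ACDE])\\[([0-9]+)[, ]+([0-9]+)\\]$", parts))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("cannot parse drop entries: ", paste(parts[bad], collapse = ", "))
  data.frame(component = vapply(m, `[[`, "", 2L),
             row = as.integer(vapply(m, `[[`, "", 3L)),
             col = as.integer(vapply(m, `[[`, "", 4L)))
}

#' Declare a twin variance-component model
#'
#' @param structure `"cholesky"`, `"independent_pathway"`, `"common_pathway"`
#'   or `"saturated"`.
#' @param components subset of `c("A","C","D","E")`; `E` is mandatory and `C`
#'   and `D` are mutually exclusive (not jointly identifiable in the classical
#'   design). Independent- and common-pathway structures support `A`+`E` only.
#' @param phenotypes list of [phenotype()] objects (order defines the factor
#'   ordering of the Cholesky decomposition).
#' @param n_factors number of common factor sets (independent pathway) or
#'   latent phenotypes (common pathway).
#' @param drop path entries fixed to zero (Cholesky only); see [parse_drop()].
#' @param age include a linear age covariate on means (continuous) and
#'   liability means (binary).
#' @return an object of class `twin_model`.
#' @export
twin_model <- function(structure = c("cholesky", "independent_pathway",
                                     "common_pathway", "saturated"),
                       components = c("A", "E"), phenotypes = default_phenotypes(),
                       n_factors = 1L, drop = NULL, age = TRUE) {
  structure <- match.arg(structure)
  components <- unique(toupper(components))
  if (!all(components %in% c("A", "C", "D", "E")))
    stop("components must be a subset of A, C, D, E")
  if (!"E" %in% components) stop("E must always be present")
  if (all(c("C", "D") %in% components))
    stop("C and D cannot be estimated in the same model")
  if (structure %in% c("independent_pathway", "common_pathway") &&
      !setequal(components, c("A", "E")))
    stop(structure, " models are implemented for A+E components only")
  p <- length(phenotypes)
  if (p < 1L) stop("at least one phenotype required")
  drop <- parse_drop(drop)
  masks <- NULL
  if (structure == "cholesky") {
    masks <- lapply(setNames(components, components), function(co) {
      m <- lower.tri(matrix(TRUE, p, p), diag = TRUE)
      m
    })
    if (!is.null(drop)) {
      for (r in seq_len(nrow(drop))) {
        co <- drop$component[r]
        if (!co %in% components) stop("drop refers to absent component ", co)
        i <- drop$row[r]; j <- drop$col[r]
        if (i < j || i > p || j < 1) stop("drop entry not lower-triangular: ", co, "[", i, ",", j, "]")
        if (co == "E" && i == j && trait_scales(phenotypes)[i] == "binary")
          stop("cannot drop the non-shared diagonal of a binary trait (identification)")
        masks[[co]][i, j] <- FALSE
      }
    }
  } else if (!is.null(drop)) {
    stop("drop lists are supported for Cholesky models only")
  }
  mod <- structure(list(structure = structure, components = components,
                        phenotypes = phenotypes, p = p,
                        traits = trait_names(phenotypes),
                        scales = trait_scales(phenotypes),
                        n_factors = as.integer(n_factors),
                        drop = drop, masks = masks, age = isTRUE(age)),
                   class = "twin_model")
  mod
}

#' @export
print.twin_model <- function(x, ...) {
  cat("twin_model:", x$structure,
      "(", paste(x$components, collapse = ""), ")",
      "p =", x$p, "traits:", paste(x$traits, collapse = ", "), "\n")
  if (x$structure %in% c("independent_pathway", "common_pathway"))
    cat("  factor sets/latents:", x$n_factors, "\n")
  if (!is.null(x$drop) && nrow(x$drop))
    cat("  dropped paths:", paste0(x$drop$component, "[", x$drop$row, ",", x$drop$col, "]",
                                   collapse = " "), "\n")
  invisible(x)
}

#' Covariance implied by a lower-triangular path matrix
#'
#' Each variance component is parameterized as `L %*% t(L)` for a
#' lower-triangular path matrix `L`, which is symmetric positive semidefinite
#' by construction.
#'
#' @param path square lower-triangular numeric matrix.
#' @return symmetric PSD covariance matrix.
#' @export
component_covariance <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) != ncol(path)) stop("path matrix must be square")
  if (any(abs(path[upper.tri(path)]) > 0)) stop("path matrix must be lower-triangular")
  tcrossprod(path)
}

# MZ/DZ sharing coefficients for the cross-twin covariance block.
zygosity_alphas <- function(zygosity) {
  switch(toupper(zygosity),
         MZ = c(A = 1, C = 1, D = 1, E = 0),
         DZ = c(A = 0.5, C = 1, D = 0.25, E = 0),
         stop("unknown zygosity: ", zygosity))
}

## ---------------------------------------------------------------------------
## Parameter template: one row per free parameter, with the unconstrained
## optimization scale ("id" or "logit") and a naive start value. Binary traits
## have their non-shared diagonal path derived from the unit-liability
## constraint and therefore contribute no free parameter for it.

par_template <- function(model) {
  p <- model$p
  tn <- model$traits
  sc <- model$scales
  rows <- list()
  add <- function(name, block, comp = NA, i = NA, j = NA, transform = "id", start = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(name = name, block = block,
                                             comp = comp, i = i, j = j,
                                             transform = transform, start = start)
  }
  if (model$structure == "cholesky") {
    for (co in model$components) {
      for (jj in seq_len(p)) for (ii in jj:p) {
        if (!model$masks[[co]][ii, jj]) next
        if (co == "E" && ii == jj && sc[ii] == "binary") next  # derived
        add(sprintf("%s[%d,%d]", co, ii, jj), "path", co, ii, jj,
            start = if (ii == jj) 0.6 else 0.1)
      }
    }
  } else if (model$structure == "independent_pathway") {
    for (co in c("A", "E")) for (k in seq_len(model$n_factors)) for (ii in seq_len(p))
      add(sprintf("%sc%d[%d]", co, k, ii), "ip_common", co, ii, k, start = 0.4)
    for (co in c("A", "E")) for (ii in seq_len(p)) {
      if (co == "E" && sc[ii] == "binary") next  # derived
      add(sprintf("%ss[%d]", co, ii), "ip_spec", co, ii, start = 0.4)
    }
  } else if (model$structure == "common_pathway") {
    for (l in seq_len(model$n_factors))
      add(sprintf("share_A[%d]", l), "cp_share", "A", l, transform = "logit", start = 0.5)
    for (l in seq_len(model$n_factors)) for (ii in seq_len(p))
      add(sprintf("load[%d,%d]", ii, l), "cp_load", NA, ii, l, start = 0.5)
    for (co in c("A", "E")) for (ii in seq_len(p)) {
      if (co == "E" && sc[ii] == "binary") next  # derived
      add(sprintf("%ss[%d]", co, ii), "cp_spec", co, ii, start = 0.4)
    }
  } else { # saturated
    for (g in c("MZ", "DZ")) {
      for (cc in seq_len(2 * p)) for (rr in cc:(2 * p)) {
        tr <- (rr - 1L) %% p + 1L
        if (rr == cc && sc[tr] == "binary") next  # derived diagonal
        add(sprintf("L%s[%d,%d]", g, rr, cc), "sat_chol", g, rr, cc,
            start = if (rr == cc) 0.9 else 0.05)
      }
    }
    for (g in c("MZ", "DZ")) for (t in 1:2) for (ii in seq_len(p)) {
      if (sc[ii] == "continuous")
        add(sprintf("mean_%s_t%d[%s]", g, t, tn[ii]), "sat_mean", g, ii, t, start = 0)
      else
        add(sprintf("tau_%s_t%d[%s]", g, t, tn[ii]), "sat_tau", g, ii, t,
            start = qnorm(1 - model$phenotypes[[ii]]$prevalence))
    }
  }
  if (model$structure != "saturated") {
    for (ii in seq_len(p)) {
      if (sc[ii] == "continuous")
        add(sprintf("mean[%s]", tn[ii]), "mean", NA, ii, start = 0)
      else
        add(sprintf("tau[%s]", tn[ii]), "tau", NA, ii,
            start = qnorm(1 - model$phenotypes[[ii]]$prevalence))
    }
  }
  if (model$age) for (ii in seq_len(p))
    add(sprintf("beta[%s]", tn[ii]), "beta", NA, ii, start = 0)
  do.call(rbind, rows)
}

to_free <- function(template, natural) {
  th <- natural
  lg <- template$transform == "logit"
  th[lg] <- qlogis(pmin(pmax(natural[lg], 1e-8), 1 - 1e-8))
  th
}

from_free <- function(template, theta) {
  nat <- theta
  lg <- template$transform == "logit"
  nat[lg] <- plogis(theta[lg])
  names(nat) <- template$name
  nat
}

## Build component structure from a natural-scale parameter vector.
## Returns component covariances, path matrices (with derived entries filled),
## mean/threshold/age vectors, and a smooth penalty that activates when a
## binary trait's non-derived variance share exceeds 1.
build_structure <- function(model, natural) {
  p <- model$p
  sc <- model$scales
  tpl <- attr(model, "template")
  if (is.null(tpl)) tpl <- par_template(model)
  stopifnot(length(natural) == nrow(tpl))
  val <- setNames(as.numeric(natural), tpl$name)
  penalty <- 0
  binidx <- which(sc == "binary")

  if (model$structure == "saturated") {
    rows <- function(block) tpl[tpl$block == block, , drop = FALSE]
    out <- list()
    for (g in c("MZ", "DZ")) {
      L <- matrix(0, 2 * p, 2 * p)
      sel <- tpl$block == "sat_chol" & tpl$comp == g
      L[cbind(tpl$i[sel], tpl$j[sel])] <- val[sel]
      for (rr in seq_len(2 * p)) {
        tr <- (rr - 1L) %% p + 1L
        if (sc[tr] == "binary") {
          rest <- sum(L[rr, seq_len(rr - 1L)]^2)
          d2 <- 1 - rest
          if (d2 < 1e-6) { penalty <- penalty + (rest - (1 - 1e-6))^2; d2 <- 1e-6 }
          L[rr, rr] <- sqrt(d2)
        }
      }
      Sigma <- tcrossprod(L)
      mu <- numeric(2 * p); tau <- rep(NA_real_, 2 * p)
      for (t in 1:2) for (ii in seq_len(p)) {
        idx <- (t - 1L) * p + ii
        if (sc[ii] == "continuous")
          mu[idx] <- val[sprintf("mean_%s_t%d[%s]", g, t, model$traits[ii])]
        else
          tau[idx] <- val[sprintf("tau_%s_t%d[%s]", g, t, model$traits[ii])]
      }
      out[[g]] <- list(Sigma = Sigma, mu = mu, tau = tau)
    }
    beta <- rep(0, p)
    if (model$age) beta <- unname(val[tpl$block == "beta"])
    return(list(saturated = out, beta = beta, penalty = penalty))
  }

  comps <- list(A = matrix(0, p, p), C = matrix(0, p, p),
                D = matrix(0, p, p), E = matrix(0, p, p))
  paths <- list()
  if (model$structure == "cholesky") {
    for (co in model$components) {
      L <- matrix(0, p, p)
      sel <- tpl$block == "path" & tpl$comp == co
      L[cbind(tpl$i[sel], tpl$j[sel])] <- val[sel]
      paths[[co]] <- L
    }
    # derived unit-liability diagonal for binary traits
    for (ii in binidx) {
      rest <- sum(vapply(paths, function(L) sum(L[ii, ]^2), 0)) -
        paths[["E"]][ii, ii]^2
      d2 <- 1 - rest
      if (d2 < 1e-6) { penalty <- penalty + (rest - (1 - 1e-6))^2; d2 <- 1e-6 }
      paths[["E"]][ii, ii] <- sqrt(d2)
    }
    for (co in model$components) comps[[co]] <- tcrossprod(paths[[co]])
  } else if (model$structure == "independent_pathway") {
    f <- model$n_factors
    for (co in c("A", "E")) {
      G <- matrix(0, p, f)
      sel <- tpl$block == "ip_common" & tpl$comp == co
      G[cbind(tpl$i[sel], tpl$j[sel])] <- val[sel]
      s <- numeric(p)
      sel <- tpl$block == "ip_spec" & tpl$comp == co
      s[tpl$i[sel]] <- val[sel]
      paths[[paste0(co, "_common")]] <- G
      paths[[paste0(co, "_specific")]] <- s
    }
    for (ii in binidx) {
      rest <- sum(paths$A_common[ii, ]^2) + sum(paths$E_common[ii, ]^2) +
        paths$A_specific[ii]^2
      d2 <- 1 - rest
      if (d2 < 1e-6) { penalty <- penalty + (rest - (1 - 1e-6))^2; d2 <- 1e-6 }
      paths$E_specific[ii] <- sqrt(d2)
    }
    comps$A <- tcrossprod(paths$A_common) + diag(paths$A_specific^2, p)
    comps$E <- tcrossprod(paths$E_common) + diag(paths$E_specific^2, p)
  } else { # common pathway
    f <- model$n_factors
    sh <- val[tpl$block == "cp_share"]
    Lam <- matrix(0, p, f)
    sel <- tpl$block == "cp_load"
    Lam[cbind(tpl$i[sel], tpl$j[sel])] <- val[sel]
    sA <- numeric(p); sE <- numeric(p)
    sel <- tpl$block == "cp_spec" & tpl$comp == "A"; sA[tpl$i[sel]] <- val[sel]
    sel <- tpl$block == "cp_spec" & tpl$comp == "E"; sE[tpl$i[sel]] <- val[sel]
    for (ii in binidx) {
      rest <- sum(Lam[ii, ]^2) + sA[ii]^2
      d2 <- 1 - rest
      if (d2 < 1e-6) { penalty <- penalty + (rest - (1 - 1e-6))^2; d2 <- 1e-6 }
      sE[ii] <- sqrt(d2)
    }
    comps$A <- Lam %*% diag(sh, f) %*% t(Lam) + diag(sA^2, p)
    comps$E <- Lam %*% diag(1 - sh, f) %*% t(Lam) + diag(sE^2, p)
    paths <- list(loadings = Lam, share_A = sh, A_specific = sA, E_specific = sE)
  }

  mu <- numeric(p); tau <- rep(NA_real_, p)
  sel <- tpl$block == "mean"; mu[tpl$i[sel]] <- val[sel]
  sel <- tpl$block == "tau"; tau[tpl$i[sel]] <- val[sel]
  beta <- rep(0, p)
  if (model$age) beta <- unname(val[tpl$block == "beta"])
  list(SA = comps$A, SC = comps$C, SD = comps$D, SE = comps$E,
       paths = paths, mu = mu, tau = tau, beta = beta, penalty = penalty)
}

#' Expected per-zygosity moments of a twin model
#'
#' The within-twin block of the expected covariance is the sum of the
#' component covariances; the cross-twin block weights them by the sharing
#' coefficients (A, C, D) = (1, 1, 1) for MZ pairs and (0.5, 1, 0.25) for DZ
#' pairs. Non-shared environment is never shared across twins. Means carry the
#' linear age effect when ages are supplied; binary traits report a liability
#' threshold instead of a mean.
#'
#' @param model a [twin_model()].
#' @param params named natural-scale parameter vector in template order (see
#'   [count_free_parameters()]; obtain names via `par_start(model)`).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param age optional length-2 vector of twin ages (years).
#' @return list with `mean` (length `2p`), `cov` (`2p x 2p`), `thresholds`
#'   (length `2p`, `NA` for continuous traits).
#' @export
expected_moments <- function(model, params, zygosity, age = NULL) {
  stopifnot(inherits(model, "twin_model"))
  bs <- build_structure(model, params)
  p <- model$p
  if (model$structure == "saturated") {
    g <- bs$saturated[[toupper(zygosity)]]
    mu <- g$mu; Sigma <- g$Sigma; tau <- g$tau
    if (!is.null(age)) {
      ages <- rep(age, each = p)
      mu <- mu + rep(bs$beta, 2) * ages
    }
    return(list(mean = mu, cov = Sigma, thresholds = tau))
  }
  al <- zygosity_alphas(zygosity)
  within <- bs$SA + bs$SC + bs$SD + bs$SE
  cross <- al["A"] * bs$SA + al["C"] * bs$SC + al["D"] * bs$SD
  Sigma <- rbind(cbind(within, cross), cbind(cross, within))
  mu <- rep(bs$mu, 2)
  if (!is.null(age)) mu <- mu + rep(bs$beta, 2) * rep(age, each = p)
  list(mean = mu, cov = Sigma, thresholds = rep(bs$tau, 2))
}

#' Nominal start vector for a model
#'
#' Returns the template's naive natural-scale start values, named; useful as a
#' skeleton for [expected_moments()] and [total_minus2LL()].
#' @param model a [twin_model()].
#' @return named numeric vector.
#' @export
par_start <- function(model) {
  tpl <- par_template(model)
  setNames(tpl$start, tpl$name)
}

#' Count free structural parameters
#'
#' Nominal structural counts under the convention that every trait is treated
#' as continuous (the identification constraint of binary traits removes the
#' same single parameter from every model, so model *differences* — the df
#' column of a comparison ladder — are unaffected): Cholesky contributes the
#' number of free lower-triangular entries per component (`p(p+1)/2` when
#' full); an independent-pathway model `p` per common loading vector per
#' component per factor set plus `p` trait-specific paths per component; a
#' common-pathway model one standardized A-share per latent plus `p` loadings
#' per latent plus `p` trait-specific paths per component. With
#' `include_means = TRUE`, mean/threshold and age-slope parameters are added
#' (identical across structured models for a fixed phenotype set).
#'
#' @param model a [twin_model()].
#' @param include_means also count means/thresholds/age slopes.
#' @return integer count.
#' @export
count_free_parameters <- function(model, include_means = FALSE) {
  p <- model$p
  n <- switch(model$structure,
    cholesky = sum(vapply(model$masks, sum, 0L)),
    independent_pathway = 2L * model$n_factors * p + 2L * p,
    common_pathway = model$n_factors * (1L + p) + 2L * p,
    saturated = 2L * (2L * p) * (2L * p + 1L) / 2L
  )
  if (include_means) {
    if (model$structure == "saturated") n <- n + 2L * 2L * p
    else n <- n + p
    if (model$age) n <- n + p
  }
  as.integer(n)
}
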