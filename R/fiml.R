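## Full-information maximum likelihood for twin-pair data with mixed
## continuous/binary phenotypes and arbitrary missingness.
##
## Each pair contributes the likelihood of exactly its observed subvector:
## the multivariate-normal density of the observed continuous entries times
## the probability of the latent-normal rectangle consistent with the observed
## binary pattern, conditioned on the continuous entries. Pairs are grouped by
## (zygosity x missingness pattern) so the continuous part and the conditional
## covariance are computed once per group and evaluated vectorized.

prepare_twin_data <- function(model, data) {
  p <- model$p
  tn <- model$traits
  need <- c("zygosity", "age_1", "age_2", paste0(rep(tn, each = 2), "_", 1:2))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  zyg <- toupper(as.character(data$zygosity))
  if (!all(zyg %in% c("MZ", "DZ"))) stop("unknown zygosity label(s): ",
    paste(setdiff(unique(zyg), c("MZ", "DZ")), collapse = ", "))
  X <- as.matrix(data[, c(paste0(tn, "_1"), paste0(tn, "_2"))])
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0
  if (!all(keep)) { X <- X[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]; zyg <- zyg[keep]; data <- data[keep, , drop = FALSE] }
  n <- nrow(X)
  if (n == 0L) stop("no pairs with observed phenotypes")
  age <- cbind(data$age_1, data$age_2)
  age[is.na(age)] <- mean(age, na.rm = TRUE)
  if (anyNA(age)) age[] <- 0   # no ages anywhere: age effect inestimable
  bin <- rep(model$scales == "binary", 2)
  bad <- X[, bin, drop = FALSE]
  if (any(!is.na(bad) & bad != 0 & bad != 1)) stop("binary trait values must be 0/1")
  pat <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- list()
  for (g in c("MZ", "DZ")) for (pt in unique(pat[zyg == g])) {
    rows <- which(zyg == g & pat == pt)
    groups[[length(groups) + 1L]] <- list(zyg = g, rows = rows,
                                          obs = obs[rows[1], ])
  }
  list(X = X, age = age, zyg = zyg, groups = groups, n = n,
       n_mz = sum(zyg == "MZ"), n_dz = sum(zyg == "DZ"),
       bin = bin, p = p)
}

## Core -2 log likelihood on the unconstrained scale.
m2ll_free <- function(theta, model, prep, control) {
  tpl <- attr(model, "template")
  nat <- from_free(tpl, theta)
  m2ll_natural(nat, model, prep, control)
}

m2ll_natural <- function(natural, model, prep, control) {
  bs <- tryCatch(build_structure(model, natural), error = function(e) NULL)
  if (is.null(bs)) return(1e10)
  p <- model$p
  mom <- list()
  for (g in c("MZ", "DZ")) {
    if (model$structure == "saturated") {
      gg <- bs$saturated[[g]]
      mom[[g]] <- list(Sigma = gg$Sigma, mu0 = gg$mu, tau = gg$tau)
    } else {
      al <- zygosity_alphas(g)
      within <- bs$SA + bs$SC + bs$SD + bs$SE
      cross <- al["A"] * bs$SA + al["C"] * bs$SC + al["D"] * bs$SD
      mom[[g]] <- list(Sigma = rbind(cbind(within, cross), cbind(cross, within)),
                       mu0 = rep(bs$mu, 2), tau = rep(bs$tau, 2))
    }
  }
  beta2 <- rep(bs$beta, 2)
  ll <- 0
  for (grp in prep$groups) {
    Sigma <- mom[[grp$zyg]]$Sigma
    mu0 <- mom[[grp$zyg]]$mu0
    tau <- mom[[grp$zyg]]$tau
    o <- which(grp$obs)
    rows <- grp$rows
    agecol <- rep(1:2, each = p)
    mu_mat <- matrix(mu0[o], length(rows), length(o), byrow = TRUE) +
      prep$age[rows, agecol[o], drop = FALSE] *
        matrix(beta2[o], length(rows), length(o), byrow = TRUE)
    oc <- o[!prep$bin[o]]
    ob <- o[prep$bin[o]]
    ic <- which(!prep$bin[o])   # positions within o
    ib <- which(prep$bin[o])
    llg <- 0
    resid <- NULL
    if (length(oc)) {
      S_cc <- Sigma[oc, oc, drop = FALSE]
      U <- tryCatch(chol(S_cc), error = function(e) NULL)
      if (is.null(U)) return(1e10)
      resid <- prep$X[rows, oc, drop = FALSE] - mu_mat[, ic, drop = FALSE]
      z <- backsolve(U, t(resid), transpose = TRUE)
      quad <- colSums(z^2)
      logdet <- 2 * sum(log(diag(U)))
      llg <- llg + sum(-0.5 * (length(oc) * log(2 * pi) + logdet + quad))
    }
    if (length(ob)) {
      if (length(oc)) {
        K <- t(backsolve(U, backsolve(U, t(Sigma[ob, oc, drop = FALSE]),
                                      transpose = TRUE)))
        condS <- Sigma[ob, ob, drop = FALSE] -
          K %*% t(Sigma[ob, oc, drop = FALSE])
        condmu <- mu_mat[, ib, drop = FALSE] + resid %*% t(K)
      } else {
        condS <- Sigma[ob, ob, drop = FALSE]
        condmu <- mu_mat[, ib, drop = FALSE]
      }
      y <- prep$X[rows, ob, drop = FALSE]
      tb <- matrix(tau[ob], length(rows), length(ob), byrow = TRUE)
      lower <- ifelse(y == 1, tb, -Inf) - condmu
      upper <- ifelse(y == 1, Inf, tb) - condmu
      pr <- tryCatch(
        mvn_rect_prob(lower, upper, condS,
                      points = control$points, exact = control$exact),
        error = function(e) NULL)
      if (is.null(pr)) return(1e10)
      llg <- llg + sum(log(pmax(pr, 1e-300)))
    }
    ll <- ll + llg
  }
  -2 * ll + 1e6 * bs$penalty
}

#' Log-likelihood of a single twin pair
#'
#' The FIML contribution of one pair given expected moments: the observed
#' continuous entries contribute a multivariate-normal log-density; observed
#' binary entries the log-probability of the latent-normal orthant consistent
#' with their 0/1 pattern, conditional on the continuous entries; missing
#' entries are marginalized by dropping rows/columns.
#'
#' @param values length-`2p` observation vector (twin 1 traits then twin 2
#'   traits; `NA` = missing; binary traits coded 0/1).
#' @param moments list with `mean`, `cov`, `thresholds` as returned by
#'   [expected_moments()].
#' @param binary logical length-`2p` marker of binary entries; defaults to
#'   `!is.na(moments$thresholds)`.
#' @param exact use the deterministic high-accuracy integrator for binary
#'   blocks of dimension 3+.
#' @return log-likelihood (scalar).
#' @export
pair_loglik <- function(values, moments, binary = NULL, exact = TRUE) {
  v <- as.numeric(values)
  mu <- moments$mean; Sigma <- moments$cov; tau <- moments$thresholds
  if (is.null(binary)) binary <- !is.na(tau)
  o <- which(!is.na(v))
  if (!length(o)) stop("empty observation")
  oc <- o[!binary[o]]; ob <- o[binary[o]]
  ll <- 0; resid <- NULL; U <- NULL
  if (length(oc)) {
    S_cc <- Sigma[oc, oc, drop = FALSE]
    U <- chol(S_cc)
    resid <- v[oc] - mu[oc]
    z <- backsolve(U, resid, transpose = TRUE)
    ll <- ll - 0.5 * (length(oc) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
  }
  if (length(ob)) {
    if (length(oc)) {
      K <- t(backsolve(U, backsolve(U, t(Sigma[ob, oc, drop = FALSE]),
                                    transpose = TRUE)))
      condS <- Sigma[ob, ob, drop = FALSE] - K %*% t(Sigma[ob, oc, drop = FALSE])
      condmu <- mu[ob] + drop(K %*% resid)
    } else {
      condS <- Sigma[ob, ob, drop = FALSE]
      condmu <- mu[ob]
    }
    y <- v[ob]
    lower <- ifelse(y == 1, tau[ob], -Inf) - condmu
    upper <- ifelse(y == 1, Inf, tau[ob]) - condmu
    pr <- mvn_rect_prob(rbind(lower), rbind(upper), condS, exact = exact)
    ll <- ll + log(max(pr, 1e-300))
  }
  ll
}

#' Total -2 log-likelihood of a dataset under a model
#'
#' Sums [pair_loglik()] over all pairs, grouped by zygosity with the matching
#' expected moments (evaluated vectorized by missingness pattern).
#'
#' @param model a [twin_model()].
#' @param params named natural-scale parameter vector (template order; see
#'   [par_start()]).
#' @param data twin dataset (one row per pair; see [simulate_cohort()] for the
#'   column layout).
#' @param exact use the high-accuracy integrator for 3+ dimensional binary
#'   blocks.
#' @param points lattice size for the fast integrator.
#' @return scalar `-2 log L`.
#' @export
total_minus2LL <- function(model, params, data, exact = TRUE, points = 2048L) {
  tpl <- par_template(model)
  attr(model, "template") <- tpl
  prep <- prepare_twin_data(model, data)
  m2ll_natural(setNames(as.numeric(params), tpl$name), model, prep,
               list(points = points, exact = exact))
}

## Data-driven start values on the natural scale.
start_values <- function(model, prep) {
  tpl <- attr(model, "template")
  st <- setNames(tpl$start, tpl$name)
  p <- model$p
  tn <- model$traits
  sc <- model$scales
  X <- prep$X
  # per-trait observed moments pooled over twins
  vhat <- numeric(p); mhat <- numeric(p); phat <- numeric(p); bhat <- numeric(p)
  for (ii in seq_len(p)) {
    xv <- c(X[, ii], X[, p + ii])
    av <- c(prep$age[, 1], prep$age[, 2])
    ok <- !is.na(xv)
    if (sc[ii] == "continuous") {
      mhat[ii] <- mean(xv[ok]); vhat[ii] <- max(var(xv[ok]), 1e-4)
      b <- tryCatch(stats::cov(xv[ok], av[ok]) / max(var(av[ok]), 1e-8),
                    error = function(e) 0)
      bhat[ii] <- ifelse(is.finite(b), b, 0)
    } else {
      phat[ii] <- min(max(mean(xv[ok]), 0.02), 0.98); vhat[ii] <- 1
      bhat[ii] <- 0
    }
  }
  set <- function(nm, v) if (nm %in% names(st)) st[nm] <<- v
  for (ii in seq_len(p)) {
    set(sprintf("mean[%s]", tn[ii]), mhat[ii])
    set(sprintf("tau[%s]", tn[ii]), qnorm(1 - phat[ii]))
    set(sprintf("beta[%s]", tn[ii]), bhat[ii])
  }
  if (model$structure == "cholesky") {
    ncomp <- length(model$components)
    w <- c(A = 0.5, C = 0.2, D = 0.2, E = 0.5)
    for (co in model$components) {
      for (ii in seq_len(p)) {
        set(sprintf("%s[%d,%d]", co, ii, ii), sqrt(w[co] * vhat[ii] / max(1, ncomp - 1)))
        if (ii > 1) for (jj in seq_len(ii - 1))
          set(sprintf("%s[%d,%d]", co, ii, jj), 0.05)
      }
    }
  } else if (model$structure == "independent_pathway") {
    for (co in c("A", "E")) for (k in seq_len(model$n_factors)) for (ii in seq_len(p))
      set(sprintf("%sc%d[%d]", co, k, ii), sqrt(0.15 * vhat[ii]) / k)
    for (co in c("A", "E")) for (ii in seq_len(p))
      set(sprintf("%ss[%d]", co, ii), sqrt(0.3 * vhat[ii]))
  } else if (model$structure == "common_pathway") {
    for (l in seq_len(model$n_factors)) for (ii in seq_len(p))
      set(sprintf("load[%d,%d]", ii, l), sqrt(0.3 * vhat[ii]) / l)
    for (co in c("A", "E")) for (ii in seq_len(p))
      set(sprintf("%ss[%d]", co, ii), sqrt(0.3 * vhat[ii]))
  } else { # saturated: double-entry sample moments per group
    for (g in c("MZ", "DZ")) {
      rows <- prep$zyg == g
      Xg <- X[rows, , drop = FALSE]
      # latent-scale stand-in for binary traits: center at 0/1 minus prevalence
      Z <- Xg
      for (ii in which(sc == "binary")) for (t in 0:1)
        Z[, t * p + ii] <- ifelse(is.na(Xg[, t * p + ii]), NA,
                                  (Xg[, t * p + ii] - phat[ii]) / sqrt(phat[ii] * (1 - phat[ii])))
      S <- tryCatch(stats::cov(Z, use = "pairwise.complete.obs"), error = function(e) NULL)
      if (is.null(S) || anyNA(S)) S <- diag(2 * p)
      # symmetrize across twin order and ridge for safety
      Swap <- rbind(cbind(S[(p + 1):(2 * p), (p + 1):(2 * p)], t(S[1:p, (p + 1):(2 * p)])),
                    cbind(S[1:p, (p + 1):(2 * p)], S[1:p, 1:p]))
      S <- (S + Swap) / 2
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-3) S <- S + diag(1e-3 - min(ev), 2 * p)
      for (ii in which(sc == "binary")) for (t in 0:1) {    # unit liability variance
        idx <- t * p + ii
        f <- sqrt(S[idx, idx]); S[idx, ] <- S[idx, ] / f; S[, idx] <- S[, idx] / f
      }
      L <- t(chol(S))
      for (cc in seq_len(2 * p)) for (rr in cc:(2 * p))
        set(sprintf("L%s[%d,%d]", g, rr, cc), L[rr, cc])
      for (t in 1:2) for (ii in seq_len(p)) {
        xo <- Xg[, (t - 1) * p + ii]
        if (sc[ii] == "continuous")
          set(sprintf("mean_%s_t%d[%s]", g, t, tn[ii]), mean(xo, na.rm = TRUE))
        else {
          pg <- min(max(mean(xo, na.rm = TRUE), 0.02), 0.98)
          set(sprintf("tau_%s_t%d[%s]", g, t, tn[ii]), qnorm(1 - pg))
        }
      }
    }
  }
  st
}

## Flip Cholesky factor columns (and IP/CP factor signs) so that leading
## loadings are non-negative; L %*% t(L) is invariant, fixing the reflection
## indeterminacy without constraining the optimization.
canonicalize_signs <- function(model, natural) {
  tpl <- attr(model, "template")
  val <- setNames(as.numeric(natural), tpl$name)
  p <- model$p
  if (model$structure == "cholesky") {
    for (co in model$components) for (jj in seq_len(p)) {
      nm <- sprintf("%s[%d,%d]", co, jj, jj)
      if (nm %in% names(val) && val[nm] < 0) {
        for (ii in jj:p) {
          nm2 <- sprintf("%s[%d,%d]", co, ii, jj)
          if (nm2 %in% names(val)) val[nm2] <- -val[nm2]
        }
      }
    }
  } else if (model$structure == "independent_pathway") {
    for (co in c("A", "E")) for (k in seq_len(model$n_factors)) {
      nms <- sprintf("%sc%d[%d]", co, k, seq_len(p))
      nms <- nms[nms %in% names(val)]
      if (length(nms) && val[nms[1]] < 0) val[nms] <- -val[nms]
    }
    nms <- grep("^[AE]s\\[", names(val), value = TRUE)
    val[nms] <- abs(val[nms])
  } else if (model$structure == "common_pathway") {
    for (l in seq_len(model$n_factors)) {
      nms <- sprintf("load[%d,%d]", seq_len(p), l)
      nms <- nms[nms %in% names(val)]
      if (length(nms) && val[nms[1]] < 0) val[nms] <- -val[nms]
    }
    nms <- grep("^[AE]s\\[", names(val), value = TRUE)
    val[nms] <- abs(val[nms])
  }
  val
}

#' Fit a twin model by full-information maximum likelihood
#'
#' Minimizes the total `-2 log L` by quasi-Newton (BFGS) local search from
#' multiple jittered start vectors; the best converged solution is reported.
#' Binary-block probabilities use the fast deterministic lattice integrator
#' during optimization and a high-accuracy deterministic evaluation for the
#' reported `-2 log L`. Deterministic given `seed`.
#'
#' @param model a [twin_model()].
#' @param data twin dataset, one row per pair.
#' @param starts number of optimization starts (first is unjittered).
#' @param seed integer seed controlling start jitter.
#' @param start optional named natural-scale start overrides.
#' @param fixed optional named natural-scale parameters to hold fixed.
#' @param hessian compute the numerical Hessian (needed for Wald CIs).
#' @param control list: `points` (lattice size during optimization, default
#'   512), `maxit` (default 1000), `reltol` (default 1e-10), `exact_final`
#'   (default TRUE), `trace` (log per-start convergence).
#' @return an object of class `twin_fit`.
#' @export
fit_twin_model <- function(model, data, starts = 5L, seed = 1L, start = NULL,
                           fixed = NULL, hessian = TRUE, control = list()) {
  stopifnot(inherits(model, "twin_model"))
  ctl <- modifyList(list(points = 512L, maxit = 1000L, reltol = 1e-10,
                         exact_final = TRUE), control)
  tpl <- par_template(model)
  attr(model, "template") <- tpl
  prep <- prepare_twin_data(model, data)
  st <- start_values(model, prep)
  if (!is.null(start)) {
    bad <- setdiff(names(start), names(st))
    if (length(bad)) stop("unknown start parameter(s): ", paste(bad, collapse = ", "))
    st[names(start)] <- start
  }
  free <- rep(TRUE, nrow(tpl))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), tpl$name)
    if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
    free <- !(tpl$name %in% names(fixed))
    st[names(fixed)] <- fixed
  }
  fitctl <- list(points = ctl$points, exact = FALSE)
  theta_full <- to_free(tpl, st)
  obj <- function(th_free) {
    th <- theta_full
    th[free] <- th_free
    m2ll_free(th, model, prep, fitctl)
  }
  k_free <- sum(free)
  best <- NULL
  if (k_free == 0L) {
    val <- obj(numeric(0))
    best <- list(par = numeric(0), value = val, convergence = 0L)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (s in seq_len(max(1L, starts))) {
      th0 <- theta_full[free]
      if (s > 1L) th0 <- th0 + rnorm(k_free, 0, 0.1 * (abs(th0) + 0.2))
      o <- tryCatch(
        optim(th0, obj, method = "BFGS",
              control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
        error = function(e) NULL)
      if (isTRUE(ctl$trace))
        message(sprintf("start %d: -2lnL %s (convergence %s)", s,
                        if (is.null(o)) "failed" else format(o$value, digits = 10),
                        if (is.null(o)) "-" else o$convergence))
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-9) best <- o
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    if (is.null(best)) stop("no optimization start converged")
  }
  theta_hat <- theta_full
  theta_hat[free] <- best$par
  nat <- canonicalize_signs(model, from_free(tpl, theta_hat))
  theta_hat <- to_free(tpl, nat)
  # high-accuracy final -2lnL (matters only when 3+ dim binary blocks exist)
  finctl <- list(points = 16384L, exact = isTRUE(ctl$exact_final))
  m2 <- m2ll_natural(nat, model, prep, finctl)
  H <- NULL; vc <- NULL; singular <- FALSE
  if (hessian && k_free > 0L) {
    hctl <- list(points = max(ctl$points, 2048L), exact = FALSE)
    fn <- function(th_free) { th <- theta_hat; th[free] <- th_free
                              m2ll_free(th, model, prep, hctl) }
    H <- tryCatch(optimHess(theta_hat[free], fn), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (is.null(vc)) {
        ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
        lam <- pmax(ev$values, 1e-8 * max(abs(ev$values), 1))
        vc <- 2 * ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
        singular <- TRUE
      }
    }
  }
  bs <- build_structure(model, nat)
  boundary <- bs$penalty > 0
  structure(list(model = model, template = tpl, free = free,
                 par = nat, theta = theta_hat, minus2LL = m2,
                 k = k_free, converged = !is.null(best) && best$convergence == 0L,
                 vcov_free = vc, vcov_singular = singular,
                 structure_at_fit = bs, boundary = boundary,
                 n_mz = prep$n_mz, n_dz = prep$n_dz, n = prep$n,
                 seed = seed, control = ctl),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat("twin_fit:", x$model$structure,
      paste0("(", paste(x$model$components, collapse = ""), ")"),
      "on", x$n_mz, "MZ +", x$n_dz, "DZ pairs\n")
  cat("  -2 log L =", format(x$minus2LL, digits = 10),
      " free parameters =", x$k,
      " converged =", x$converged, "\n")
  if (x$boundary) cat("  note: boundary solution (unit-liability constraint active)\n")
  invisible(x)
}

#' @export
logLik.twin_fit <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$k, class = "logLik")
}

#' Implied phenotypic covariance and standardized paths
#'
#' Divides every path by the implied phenotypic standard deviation of its row
#' trait, so squared standardized entries per trait sum to 1 across all
#' factors of all components.
#'
#' @param fit a converged [fit_twin_model()] result.
#' @return the fit, augmented with `std` (standardized path matrices and
#'   component covariances) and `phenotypic_var`.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  bs <- fit$structure_at_fit
  if (fit$model$structure == "saturated")
    stop("standardize() applies to structured (non-saturated) fits")
  V <- diag(bs$SA + bs$SC + bs$SD + bs$SE)
  if (any(V <= 0)) stop("zero implied phenotypic variance")
  Dm <- diag(1 / sqrt(V), fit$model$p)
  std <- list()
  if (fit$model$structure == "cholesky") {
    std$paths <- lapply(bs$paths, function(L) Dm %*% L)
  } else if (fit$model$structure == "independent_pathway") {
    std$paths <- list(A_common = Dm %*% bs$paths$A_common,
                      E_common = Dm %*% bs$paths$E_common,
                      A_specific = diag(Dm) * bs$paths$A_specific,
                      E_specific = diag(Dm) * bs$paths$E_specific)
  } else {
    std$paths <- list(loadings = Dm %*% bs$paths$loadings,
                      share_A = bs$paths$share_A,
                      A_specific = diag(Dm) * bs$paths$A_specific,
                      E_specific = diag(Dm) * bs$paths$E_specific)
  }
  std$SA <- Dm %*% bs$SA %*% Dm; std$SC <- Dm %*% bs$SC %*% Dm
  std$SD <- Dm %*% bs$SD %*% Dm; std$SE <- Dm %*% bs$SE %*% Dm
  fit$std <- std
  fit$phenotypic_var <- V
  fit
}

## Delta-method CI for a scalar (or vector) function of the natural parameters.
## fun: natural named vector -> numeric vector.
quantity_ci <- function(fit, fun, level = 0.95) {
  est <- fun(fit$par)
  if (is.null(fit$vcov_free)) {
    return(data.frame(estimate = est, se = NA_real_, lower = NA_real_,
                      upper = NA_real_))
  }
  tpl <- fit$template
  free <- fit$free
  g <- function(th_free) {
    th <- fit$theta; th[free] <- th_free
    fun(canonicalize_signs(fit$model, from_free(tpl, th)))
  }
  J <- numDeriv::jacobian(g, fit$theta[free])
  se <- sqrt(pmax(rowSums((J %*% fit$vcov_free) * J), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se)
}

#' Wald confidence intervals for model parameters
#'
#' Numerical-Hessian Wald intervals computed on the unconstrained scale and
#' transformed back (delta method for derived quantities).
#'
#' @param object a [fit_twin_model()] result with a Hessian.
#' @param parm optional parameter names.
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.twin_fit <- function(object, parm = NULL, level = 0.95, ...) {
  tab <- quantity_ci(object, function(nat) nat, level = level)
  rownames(tab) <- object$template$name
  if (!is.null(parm)) tab <- tab[parm, , drop = FALSE]
  tab
}
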