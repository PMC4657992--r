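## Phenotypic and cross-twin correlation estimation with the correlation type
## matched to the measurement scales: product-moment for continuous pairs,
## tetrachoric (latent bivariate normal, thresholds from the margins) for
## binary pairs, biserial (maximum likelihood under a jointly Gaussian latent)
## for mixed pairs.

cor_estimate <- function(value, method, n, ci_low = NA_real_, ci_high = NA_real_,
                         boundary = FALSE) {
  structure(list(value = value, method = method, n = n,
                 ci_low = ci_low, ci_high = ci_high, boundary = boundary),
            class = "cor_estimate")
}

#' @export
print.cor_estimate <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (95%% CI %.3f to %.3f), n = %d%s\n",
              x$method, x$value, x$ci_low, x$ci_high, x$n,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Pearson product-moment correlation with Fisher-z interval
#'
#' @param x,y numeric vectors (pairwise deletion of missing entries).
#' @param level confidence level.
#' @return a `cor_estimate`.
#' @export
pearson_corr <- function(x, y, level = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  r <- cor(x, y)
  zq <- qnorm(1 - (1 - level) / 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  cor_estimate(r, "pearson", n, tanh(z - zq * se), tanh(z + zq * se))
}

## 2x2 cell probabilities of a thresholded bivariate normal.
## Table convention: rows x in {0,1}, cols y in {0,1}.
tetra_cellprobs <- function(rho, tau_x, tau_y) {
  p11 <- .rect2(rbind(c(tau_x, tau_y)), rbind(c(Inf, Inf)), rho)
  px1 <- pnorm(tau_x, lower.tail = FALSE)
  py1 <- pnorm(tau_y, lower.tail = FALSE)
  p10 <- px1 - p11
  p01 <- py1 - p11
  p00 <- 1 - p11 - p10 - p01
  pmax(rbind(c(p00, p01), c(p10, p11)), 1e-12)
}

tetra_mle <- function(tab) {
  n <- sum(tab)
  px1 <- sum(tab[2, ]) / n
  py1 <- sum(tab[, 2]) / n
  tau_x <- qnorm(1 - px1)
  tau_y <- qnorm(1 - py1)
  nll <- function(rho) -sum(tab * log(tetra_cellprobs(rho, tau_x, tau_y)))
  o <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-9)
  o$minimum
}

#' Tetrachoric correlation (maximum likelihood)
#'
#' Latent correlation of a thresholded bivariate normal, with thresholds fixed
#' at the margin-implied values and the correlation maximizing the 2x2
#' multinomial likelihood. Solutions at |rho| >= 0.999 are flagged as
#' boundary.
#'
#' @param x a 2x2 count table (rows `x` = 0/1, columns `y` = 0/1) or a binary
#'   vector.
#' @param y binary vector when `x` is a vector.
#' @param B bootstrap resamples for the CI (0 disables).
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return a `cor_estimate`.
#' @export
tetrachoric_corr <- function(x, y = NULL, B = 1000L, seed = 1L, level = 0.95) {
  if (is.matrix(x) || is.table(x)) {
    tab <- unclass(as.matrix(x))
    vecs <- NULL
  } else {
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    vecs <- cbind(x, y)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the 2x2 table is zero")
  n <- sum(tab)
  rho <- tetra_mle(tab)
  boundary <- abs(rho) >= 0.999 - 1e-6
  ci <- c(NA_real_, NA_real_)
  if (B > 0L) {
    al <- (1 - level) / 2
    boots <- with_local_seed(seed, {
      if (is.null(vecs)) {
        pr <- as.vector(tab) / n
        vapply(seq_len(B), function(b) {
          tb <- matrix(stats::rmultinom(1, n, pr), 2, 2)
          if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return(NA_real_)
          tetra_mle(tb)
        }, 0)
      } else {
        vapply(seq_len(B), function(b) {
          idx <- sample.int(n, n, replace = TRUE)
          tb <- table(factor(vecs[idx, 1], 0:1), factor(vecs[idx, 2], 0:1))
          if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return(NA_real_)
          tetra_mle(tb)
        }, 0)
      }
    })
    ci <- unname(stats::quantile(boots, c(al, 1 - al), na.rm = TRUE))
  }
  cor_estimate(rho, "tetrachoric", n, ci[1], ci[2], boundary)
}

## Negative log-likelihood of the point-biserial ML model:
## X ~ N(mu, sigma^2); Y = 1{L > tau}, (Xstd, L) bivariate normal corr rho.
biserial_nll <- function(par, x, y) {
  mu <- par[1]; sig <- exp(par[2]); tau <- par[3]; rho <- tanh(par[4])
  z <- (x - mu) / sig
  s <- sqrt(max(1 - rho^2, 1e-12))
  arg <- (tau - rho * z) / s
  lp1 <- pnorm(arg, lower.tail = FALSE, log.p = TRUE)
  lp0 <- pnorm(arg, log.p = TRUE)
  -(sum(stats::dnorm(z, log = TRUE) - log(sig)) +
      sum(ifelse(y == 1, lp1, lp0)))
}

biserial_mle <- function(x, y) {
  mu <- mean(x); sig <- sd(x)
  p1 <- mean(y)
  tau <- qnorm(1 - p1)
  # moment-based start (classical biserial formula)
  r0 <- (mean(x[y == 1]) - mean(x[y == 0])) * p1 * (1 - p1) /
    (sd(x) * stats::dnorm(tau))
  r0 <- min(max(r0, -0.95), 0.95)
  o <- optim(c(mu, log(sig), tau, atanh(r0)), biserial_nll, x = x, y = y,
             method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  tanh(o$par[4])
}

#' Biserial correlation (maximum likelihood)
#'
#' Latent correlation between a continuous variable and the liability of a
#' dichotomous one, assuming joint normality; estimated by full maximum
#' likelihood (point-polyserial form) rather than the classical moment
#' formula, for consistency with the latent-normal model used in fitting.
#'
#' @param x continuous vector.
#' @param y binary 0/1 vector.
#' @inheritParams tetrachoric_corr
#' @return a `cor_estimate`.
#' @export
biserial_corr <- function(x, y, B = 1000L, seed = 1L, level = 0.95) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("zero variance of x")
  if (length(unique(y)) < 2L) stop("y has a single category")
  rho <- biserial_mle(x, y)
  boundary <- abs(rho) >= 0.999
  ci <- c(NA_real_, NA_real_)
  if (B > 0L) {
    al <- (1 - level) / 2
    boots <- with_local_seed(seed, vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L || sd(x[idx]) == 0) return(NA_real_)
      biserial_mle(x[idx], y[idx])
    }, 0))
    ci <- unname(stats::quantile(boots, c(al, 1 - al), na.rm = TRUE))
  }
  cor_estimate(rho, "biserial", n, ci[1], ci[2], boundary)
}

## Dispatch on the two scales.
scale_corr <- function(x, y, scale_x, scale_y, B, seed, level) {
  if (scale_x == "continuous" && scale_y == "continuous") {
    est <- pearson_corr(x, y, level)
    if (B > 0L) {  # optionally replace Fisher CI? keep Fisher for Pearson
    }
    est
  } else if (scale_x == "binary" && scale_y == "binary") {
    tetrachoric_corr(x, y, B = B, seed = seed, level = level)
  } else if (scale_x == "continuous") {
    biserial_corr(x, y, B = B, seed = seed, level = level)
  } else {
    biserial_corr(y, x, B = B, seed = seed, level = level)
  }
}

#' Phenotypic correlation matrix (individual level)
#'
#' Correlations between traits over individuals (both twins stacked), with the
#' correlation type chosen by the trait scales: Pearson for
#' continuous-continuous, tetrachoric for binary-binary, biserial for mixed.
#'
#' @param data twin dataset.
#' @param phenotypes list of [phenotype()] objects.
#' @param B bootstrap resamples for tetrachoric/biserial CIs.
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return object of class `corr_matrix` with matrices `value`, `ci_low`,
#'   `ci_high`, `n` and character matrix `method`.
#' @export
phenotypic_corr_matrix <- function(data, phenotypes, B = 1000L, seed = 1L,
                                   level = 0.95) {
  tn <- trait_names(phenotypes)
  sc <- trait_scales(phenotypes)
  p <- length(tn)
  stacked <- lapply(seq_len(p), function(ii)
    c(data[[paste0(tn[ii], "_1")]], data[[paste0(tn[ii], "_2")]]))
  out <- empty_corr_matrix(tn)
  for (ii in seq_len(p)) for (jj in seq_len(ii)) {
    if (ii == jj) { out$value[ii, ii] <- 1; out$method[ii, ii] <- "-"; next }
    est <- scale_corr(stacked[[ii]], stacked[[jj]], sc[ii], sc[jj],
                      B = B, seed = seed + ii * 131L + jj, level = level)
    out <- fill_corr(out, ii, jj, est)
  }
  out
}

empty_corr_matrix <- function(tn) {
  p <- length(tn)
  m <- matrix(NA_real_, p, p, dimnames = list(tn, tn))
  structure(list(value = m, ci_low = m, ci_high = m, n = m,
                 method = matrix(NA_character_, p, p, dimnames = list(tn, tn)),
                 boundary = matrix(FALSE, p, p, dimnames = list(tn, tn))),
            class = "corr_matrix")
}

fill_corr <- function(out, ii, jj, est) {
  out$value[ii, jj] <- out$value[jj, ii] <- est$value
  out$ci_low[ii, jj] <- out$ci_low[jj, ii] <- est$ci_low
  out$ci_high[ii, jj] <- out$ci_high[jj, ii] <- est$ci_high
  out$n[ii, jj] <- out$n[jj, ii] <- est$n
  out$method[ii, jj] <- out$method[jj, ii] <- est$method
  out$boundary[ii, jj] <- out$boundary[jj, ii] <- est$boundary
  out
}

#' @export
print.corr_matrix <- function(x, digits = 3, ...) {
  cat("correlation matrix (method by scale):\n")
  print(round(x$value, digits))
  invisible(x)
}

#' Cross-twin (cross-trait) correlation matrix
#'
#' Entry (i, j) correlates trait i in one twin with trait j in the co-twin,
#' pooling both twin orderings (double entry), which makes the matrix exactly
#' symmetric; the diagonal is the cross-twin within-trait correlation. The
#' correlation type is chosen by the trait scales as in
#' [phenotypic_corr_matrix()]. Confidence intervals are a nonparametric
#' bootstrap over pairs (twin order is resampled jointly).
#'
#' @param data twin dataset.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param phenotypes list of [phenotype()] objects.
#' @param B bootstrap resamples over pairs for all entries (0 disables).
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return object of class `corr_matrix`.
#' @export
ctct_matrix <- function(data, zygosity, phenotypes, B = 1000L, seed = 1L,
                        level = 0.95) {
  zygosity <- toupper(zygosity)
  if (!zygosity %in% c("MZ", "DZ")) stop("unknown zygosity label: ", zygosity)
  tn <- trait_names(phenotypes)
  sc <- trait_scales(phenotypes)
  p <- length(tn)
  dat <- data[toupper(as.character(data$zygosity)) == zygosity, , drop = FALSE]
  n_pairs <- nrow(dat)
  X1 <- as.matrix(dat[, paste0(tn, "_1"), drop = FALSE])
  X2 <- as.matrix(dat[, paste0(tn, "_2"), drop = FALSE])
  point <- function(rows) {
    est <- empty_corr_matrix(tn)
    for (ii in seq_len(p)) for (jj in seq_len(ii)) {
      xi <- c(X1[rows, ii], X2[rows, ii])
      yj <- c(X2[rows, jj], X1[rows, jj])
      e <- scale_corr(xi, yj, sc[ii], sc[jj], B = 0L, seed = 1L, level = level)
      est <- fill_corr(est, ii, jj, e)
    }
    est
  }
  out <- point(seq_len(n_pairs))
  if (B > 0L) {
    al <- (1 - level) / 2
    arr <- with_local_seed(seed, {
      vapply(seq_len(B), function(b) {
        rows <- sample.int(n_pairs, n_pairs, replace = TRUE)
        tryCatch(point(rows)$value, error = function(e)
          matrix(NA_real_, p, p))
      }, matrix(0, p, p))
    })
    out$ci_low <- apply(arr, c(1, 2), stats::quantile, probs = al, na.rm = TRUE)
    out$ci_high <- apply(arr, c(1, 2), stats::quantile, probs = 1 - al, na.rm = TRUE)
    dimnames(out$ci_low) <- dimnames(out$ci_high) <- list(tn, tn)
  }
  out
}

#' Write a correlation matrix as TSV
#'
#' Long layout: trait_row, trait_col, estimate, method, n, ci_low, ci_high.
#' @param x a `corr_matrix`.
#' @param path output file.
#' @export
write_corr_tsv <- function(x, path) {
  tn <- rownames(x$value)
  p <- length(tn)
  idx <- which(lower.tri(x$value, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(trait_row = tn[idx[, 1]], trait_col = tn[idx[, 2]],
                   estimate = x$value[idx], method = x$method[idx],
                   n = x$n[idx], ci_low = x$ci_low[idx],
                   ci_high = x$ci_high[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
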