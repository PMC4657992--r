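## Config-driven end-to-end pipeline: descriptives -> phenotypic correlations
## -> cross-twin cross-trait correlations -> model-comparison ladder ->
## decomposition, with a machine-readable manifest. Each stage is an exported
## function; the pipeline is a thin, fail-fast driver over them.

#' Read a pipeline configuration
#'
#' YAML with sections: exactly one of `dataset:` (`path:` to a CSV/TSV twin
#' dataset) or `generative:` (arguments of [generative_spec()]; path matrices
#' row-wise as nested lists, or `"default"`); `phenotypes:` (list of `name`,
#' `scale`, optional `prevalence`, `mean`, `sd`, `age_slope`); optional
#' `ladder:` (`reduced:` named drop-list strings, `include_ip2:`); `options:`
#' (`seed`, `bootstrap`, `starts`, `age`, `outdir`, `points`).
#'
#' @param path YAML file path, or an equivalent named list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$dataset) == is.null(cfg$generative))
    stop("config must contain exactly one of 'dataset' or 'generative'")
  if (is.null(cfg$phenotypes)) stop("config lacks 'phenotypes'")
  phenos <- lapply(cfg$phenotypes, function(ph)
    phenotype(ph$name, ph$scale %||% "continuous",
              prevalence = ph$prevalence,
              mean = ph$mean %||% 0, sd = ph$sd %||% 1,
              age_slope = ph$age_slope %||% 0))
  opts <- modifyList(list(seed = 1L, bootstrap = 500L, starts = 3L,
                          age = TRUE, outdir = "results/pipeline",
                          points = 512L, alpha = 0.05), cfg$options %||% list())
  gen <- NULL
  if (!is.null(cfg$generative)) {
    g <- cfg$generative
    paths <- g$paths %||% "default"
    if (identical(paths, "default")) paths <- default_paths()
    else paths <- lapply(paths, function(m) {
      m <- do.call(rbind, lapply(m, as.numeric)); m })
    gen <- generative_spec(
      n_mz = g$n_mz %||% 219L, n_dz = g$n_dz %||% 244L,
      phenotypes = phenos, paths = paths,
      age_mean = g$age_mean %||% 58.39, age_sd = g$age_sd %||% 11.08,
      missing_record = g$missing_record %||% 0.44,
      missing_item = g$missing_item %||% 0,
      seed = g$seed %||% opts$seed)
  }
  structure(list(dataset = cfg$dataset$path, generative = gen,
                 phenotypes = phenos,
                 reduced = lapply(cfg$ladder$reduced %||% NULL, identity),
                 include_ip2 = cfg$ladder$include_ip2 %||% TRUE,
                 options = opts),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes descriptives, phenotypic correlations, cross-twin cross-trait
#' correlations per zygosity, the four-step model ladder and the
#' decomposition of the selected model, writing fixed-name artifacts
#' (`dataset.csv` when simulated, `descriptives.tsv`, `phenotypic_corr.tsv`,
#' `ctct_mz.tsv`, `ctct_dz.tsv`, `ladder.tsv`, `decomposition.tsv`,
#' `manifest.json`) under the configured output directory. A stage failure
#' aborts with the stage name; artifacts of completed stages are preserved.
#'
#' @param config a [pipeline_config()] (or path to one).
#' @return (invisibly) list with all stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  opts <- config$options
  dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  data <- stage("data", {
    if (!is.null(config$generative)) {
      d <- simulate_cohort(config$generative)
      write_twin_data(d, file.path(opts$outdir, "dataset.csv"))
      d
    } else read_twin_data(config$dataset)
  })
  out$data <- data
  out$descriptives <- stage("descriptives", {
    d <- descriptives(data, config$phenotypes)
    utils::write.table(d, file.path(opts$outdir, "descriptives.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    d
  })
  out$phenotypic_corr <- stage("phenotypic_corr", {
    pc <- phenotypic_corr_matrix(data, config$phenotypes, B = opts$bootstrap,
                                 seed = opts$seed)
    write_corr_tsv(pc, file.path(opts$outdir, "phenotypic_corr.tsv"))
    pc
  })
  out$ctct <- stage("ctct", {
    cm <- ctct_matrix(data, "MZ", config$phenotypes, B = opts$bootstrap,
                      seed = opts$seed)
    cd <- ctct_matrix(data, "DZ", config$phenotypes, B = opts$bootstrap,
                      seed = opts$seed + 1L)
    write_corr_tsv(cm, file.path(opts$outdir, "ctct_mz.tsv"))
    write_corr_tsv(cd, file.path(opts$outdir, "ctct_dz.tsv"))
    list(MZ = cm, DZ = cd)
  })
  out$ladder <- stage("ladder", {
    lad <- four_step_compare(data, config$phenotypes, reduced = config$reduced,
                             alpha = opts$alpha, age = opts$age,
                             starts = opts$starts, seed = opts$seed,
                             control = list(points = opts$points),
                             include_ip2 = config$include_ip2)
    tab <- rbind(cbind(step = 1L, lad$table_step1),
                 cbind(step = 2L, lad$table))
    utils::write.table(tab, file.path(opts$outdir, "ladder.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    lad
  })
  out$decomposition <- stage("decomposition", {
    sel <- out$ladder$fits[[out$ladder$selected]]
    sel <- fit_twin_model(sel$model, data, starts = 1L, seed = opts$seed,
                          start = sel$par, hessian = TRUE,
                          control = list(points = opts$points))
    rep <- decomposition_report(sel)
    write_decomposition_tsv(rep, file.path(opts$outdir, "decomposition.tsv"))
    list(fit = sel, report = rep)
  })
  manifest <- stage("manifest", {
    cfgfile <- file.path(opts$outdir, "config_echo.yaml")
    yaml::write_yaml(list(options = opts,
                          phenotypes = lapply(config$phenotypes, unclass)),
                     cfgfile)
    m <- list(seed = opts$seed,
              config_md5 = unname(tools::md5sum(cfgfile)),
              package_version = as.character(utils::packageVersion("twinsem")),
              n_pairs = nrow(data),
              selected_model = out$ladder$selected,
              converged = vapply(out$ladder$fits, `[[`, TRUE, "converged"),
              minus2LL = vapply(out$ladder$fits, `[[`, 0, "minus2LL"))
    jsonlite::write_json(m, file.path(opts$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  })
  out$manifest <- manifest
  invisible(out)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates cohorts from a generative truth, fits a model, and
#' summarizes bias and confidence-interval coverage of scalar quantities of
#' the fit.
#'
#' @param spec a [generative_spec()]; per-replicate seeds are derived from
#'   `spec$seed`.
#' @param model a [twin_model()] to fit.
#' @param quantities named list; each element is
#'   `list(fun = function(fit) ..., truth = <value>)` where `fun` returns a
#'   scalar estimate and, if `ci = TRUE`, `fun_ci(fit)` (a function returning
#'   `c(lower, upper)`) may be supplied for coverage.
#' @param reps number of replicates.
#' @param starts,control passed to [fit_twin_model()].
#' @return data.frame per quantity: truth, mean estimate, bias, sd, coverage
#'   (% of replicate CIs containing the truth; NA without `fun_ci`).
#' @export
recovery_experiment <- function(spec, model, quantities, reps = 200L,
                                starts = 1L, control = list()) {
  est <- matrix(NA_real_, reps, length(quantities),
                dimnames = list(NULL, names(quantities)))
  cover <- matrix(NA, reps, length(quantities),
                  dimnames = list(NULL, names(quantities)))
  has_ci <- vapply(quantities, function(q) !is.null(q$fun_ci), TRUE)
  for (r in seq_len(reps)) {
    sp <- spec
    sp$seed <- spec$seed + r
    dat <- simulate_cohort(sp)
    fit <- tryCatch(
      fit_twin_model(model, dat, starts = starts, seed = sp$seed,
                     hessian = any(has_ci), control = control),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    for (qi in seq_along(quantities)) {
      q <- quantities[[qi]]
      est[r, qi] <- tryCatch(q$fun(fit), error = function(e) NA_real_)
      if (has_ci[qi]) {
        ci <- tryCatch(q$fun_ci(fit), error = function(e) c(NA, NA))
        cover[r, qi] <- !anyNA(ci) && ci[1] <= q$truth && q$truth <= ci[2]
      }
    }
  }
  data.frame(
    quantity = names(quantities),
    truth = vapply(quantities, `[[`, 0, "truth"),
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - vapply(quantities, `[[`, 0, "truth"),
    sd = apply(est, 2, sd, na.rm = TRUE),
    coverage = 100 * colMeans(cover, na.rm = TRUE),
    n_ok = colSums(!is.na(est)),
    row.names = NULL)
}
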