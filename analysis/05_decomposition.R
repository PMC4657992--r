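#!/usr/bin/env Rscript
## 05 — Variance decomposition of the selected model.
##
## Refits the reduced AE Cholesky model (three genetic factors, CWP-specific
## environmental factor) with a Hessian, then reports heritabilities with
## 95% CIs, the factor-by-trait percentage-of-variance table, genetic and
## environmental correlations, and the attribution of CWP's genetic variance
## to the factors originating from DHEAS, fatigue and depression.

suppressPackageStartupMessages(library(twinsem))
cohort <- read_twin_data("results/cohort.csv")
ph <- default_phenotypes()

model <- twin_model("cholesky", c("A", "E"), ph,
                    drop = "A[2,1], A[3,2], A[4,4], E[2,1], E[4,1], E[4,2], E[4,3]",
                    age = TRUE)
start <- NULL
if (file.exists("results/ladder_params.json")) {
  lp <- jsonlite::read_json("results/ladder_params.json")
  if (!is.null(lp$parameters$reduced_AE))
    start <- unlist(lp$parameters$reduced_AE)
}
t0 <- Sys.time()
fit <- fit_twin_model(model, cohort, starts = if (is.null(start)) 3 else 1,
                      seed = 1, start = start, hessian = TRUE,
                      control = list(points = 256))
cat("fit in", round(as.numeric(difftime(Sys.time(), t0, units = "mins")), 1),
    "minutes; -2lnL =", round(fit$minus2LL, 3), "\n\n")

rep <- decomposition_report(fit)
print(rep)
write_decomposition_tsv(rep, "results/decomposition.tsv")

sh <- rep$shared_genetic$cwp$shares
cat(sprintf("\nCWP genetic variance: %.0f%% shared with DHEAS, %.0f%% with fatigue, %.0f%% with depression\n",
            sh["dheas"], sh["fatigue"], sh["depression"]))
cat("wrote results/decomposition.tsv\n")
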