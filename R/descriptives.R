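#' Descriptive statistics by zygosity
#'
#' Per phenotype (plus age): mean (SD) and range for continuous traits, count
#' and percentage for binary traits, overall and by zygosity, with an
#' MZ-vs-DZ comparison p-value (Welch two-sample t-test for continuous,
#' chi-square contingency test for binary) over individuals.
#'
#' @param data twin dataset.
#' @param phenotypes list of [phenotype()] objects.
#' @return data.frame with formatted columns `overall`, `MZ`, `DZ` and the
#'   numeric `p_value`.
#' @export
descriptives <- function(data, phenotypes) {
  if (!nrow(data)) stop("empty dataset")
  tn <- trait_names(phenotypes)
  sc <- trait_scales(phenotypes)
  zyg <- toupper(as.character(data$zygosity))
  stack <- function(prefix) {
    data.frame(value = c(data[[paste0(prefix, "_1")]], data[[paste0(prefix, "_2")]]),
               zyg = rep(zyg, 2))
  }
  fmt_cont <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("-")
    sprintf("%.2f (%.2f) %.2f-%.2f", mean(v), sd(v), min(v), max(v))
  }
  fmt_bin <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("-")
    sprintf("%d (%.2f)", sum(v == 1), 100 * mean(v == 1))
  }
  row_for <- function(label, sdat, scale) {
    groups <- list(overall = sdat$value, MZ = sdat$value[sdat$zyg == "MZ"],
                   DZ = sdat$value[sdat$zyg == "DZ"])
    pv <- tryCatch({
      vm <- groups$MZ[!is.na(groups$MZ)]; vd <- groups$DZ[!is.na(groups$DZ)]
      if (scale == "continuous") {
        if (sd(vm) == 0 && sd(vd) == 0) NA_real_ else t.test(vm, vd)$p.value
      } else {
        tb <- table(factor(c(rep("MZ", length(vm)), rep("DZ", length(vd)))),
                    factor(c(vm, vd), 0:1))
        if (any(colSums(tb) == 0)) NA_real_
        else suppressWarnings(chisq.test(tb)$p.value)
      }
    }, error = function(e) NA_real_)
    fmt <- if (scale == "continuous") fmt_cont else fmt_bin
    data.frame(variable = label,
               overall = fmt(groups$overall), MZ = fmt(groups$MZ),
               DZ = fmt(groups$DZ), p_value = pv)
  }
  rows <- list(row_for("age", data.frame(
    value = c(data$age_1, data$age_2), zyg = rep(zyg, 2)), "continuous"))
  for (ii in seq_along(tn))
    rows[[length(rows) + 1L]] <- row_for(tn[ii], stack(tn[ii]), sc[ii])
  out <- do.call(rbind, rows)
  attr(out, "n_pairs") <- c(overall = nrow(data), MZ = sum(zyg == "MZ"),
                            DZ = sum(zyg == "DZ"))
  out
}
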