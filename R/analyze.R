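#' Run the full cohort analysis
#'
#' Reproduces the study's inference chain on a cohort table: the two-group
#' descriptive comparison (demographics, T-score, EBQ, segmental height
#' loss), the EBQ–height-loss Pearson correlation, the ROC analysis of EBQ
#' against subsidence with a Youden cutoff, the multivariate logistic
#' regression for subsidence risk factors, and the per-level EBQ summary
#' among non-subsided patients.
#'
#' @param cohort an `ebq_cohort` (see [simulate_cohort()], [read_cohort()]).
#'   `height_loss_mm` is derived as `preop_height_mm - final_height_mm`.
#' @param covariates covariate set for the logistic model.
#' @param level confidence level (default 0.95).
#' @return An `ebq_analysis` list: `n`, `n_subsided`, `prevalence`,
#'   `group_comparison` (list of [compare_groups()] results),
#'   `correlation`, `roc`, `logistic`, `per_level`.
#' @export
analyze_cohort <- function(cohort,
                           covariates = c("age", "sex", "smoker", "bmi",
                                          "preop_height_mm", "tscore", "ebq"),
                           level = 0.95) {
  cohort$height_loss_mm <- cohort$preop_height_mm - cohort$final_height_mm
  cont_vars <- c("age", "bmi", "tscore", "ebq", "height_loss_mm")
  cat_vars <- c("sex", "smoker")
  cmp <- lapply(c(cont_vars, cat_vars), function(v)
    compare_groups(cohort, v, level = level))
  names(cmp) <- c(cont_vars, cat_vars)
  structure(list(
    n = nrow(cohort),
    n_subsided = sum(cohort$subsided),
    prevalence = mean(cohort$subsided),
    group_comparison = cmp,
    correlation = pearson_correlation(cohort$ebq, cohort$height_loss_mm),
    roc = roc_youden(cohort$ebq, cohort$subsided),
    logistic = logistic_fit(cohort, covariates),
    per_level = per_level_summary(cohort, level = level)
  ), class = "ebq_analysis")
}

#' @export
print.ebq_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis: n = %d, subsidence %d (%.2f%%)\n",
              x$n, x$n_subsided, 100 * x$prevalence))
  cat(sprintf("EBQ vs height loss: r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p_value))
  print(x$roc)
  print(x$logistic)
  invisible(x)
}

#' Write analysis artifacts to a directory
#'
#' Deterministic writer for the [analyze_cohort()] result: `table1.csv`
#' (group comparison), `table2.csv` (logistic fit), `table3.csv` (per-level
#' EBQ), `roc.csv` (the curve) plus `roc.json` (AUC, CI, cutoff, operating
#' point), and `correlation.json`. Floats are serialised at full precision;
#' display rounding belongs to reports, not data files.
#'
#' @param analysis an `ebq_analysis`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ebq_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- do.call(rbind, lapply(analysis$group_comparison, function(gs) {
    if (!is.data.frame(gs$groups)) {
      counts <- as.data.frame.matrix(gs$groups)
      lev <- rownames(counts)
      g <- data.frame(group = rep(c("non_subsidence", "subsidence"), each = length(lev)),
                      n = c(counts[["FALSE"]], counts[["TRUE"]]),
                      mean = NA_real_, sd = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_)
      g$category <- rep(lev, 2)
    } else {
      g <- gs$groups
      g$category <- NA_character_
    }
    cbind(variable = gs$variable, g, p_value = gs$p_value,
          test_used = gs$test_used)
  }))
  utils::write.csv(t1, file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(analysis$logistic$coefficients, file.path(dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$per_level, file.path(dir, "table3.csv"),
                   row.names = FALSE)
  roc <- analysis$roc
  utils::write.csv(
    data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
               specificity = roc$specificity),
    file.path(dir, "roc.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(auc = roc$auc, auc_ci95 = as.list(roc$auc_ci95), cutoff = roc$cutoff,
         cutoff_sensitivity = roc$cutoff_sensitivity,
         cutoff_specificity = roc$cutoff_specificity,
         youden_j = roc$youden_j, n_pos = roc$n_pos, n_neg = roc$n_neg),
    file.path(dir, "roc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(analysis$correlation, file.path(dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
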