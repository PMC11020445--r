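#' t-based confidence interval for a mean from summary statistics
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` — the convention that
#' reproduces the published per-group confidence bounds from printed
#' mean/SD/n (a normal-quantile interval does not).
#'
#' @param mean,sd,n summary statistics (`n >= 2`, `sd >= 0`).
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' round(t_ci_mean(-1.62, 1.34, 23), 2)  # c(-2.20, -1.04)
#' @export
t_ci_mean <- function(mean, sd, n, level = 0.95) {
  if (any(n < 2)) stop("`n` must be at least 2", call. = FALSE)
  if (any(sd < 0)) stop("`sd` must be nonnegative", call. = FALSE)
  half <- stats::qt((1 + level) / 2, df = n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Two-group comparison of one cohort variable
#'
#' Compares a variable between the subsided and non-subsided groups.
#' Continuous variables are gated per group by a Shapiro-Wilk test at
#' `alpha = 0.05`: if both groups look normal, a two-sided pooled-variance
#' Student t-test is used (Welch available via `welch = TRUE`), otherwise a
#' Mann-Whitney U test (normal approximation with tie correction).
#' Categorical variables use Pearson's chi-square without continuity
#' correction. The chosen test is reported so the decision is transparent.
#'
#' @param cohort an `ebq_cohort` (any data frame with a logical `subsided`
#'   column works).
#' @param variable column name to compare.
#' @param group column defining the two groups (default `"subsided"`).
#' @param level confidence level for the per-group means (default 0.95).
#' @param welch use Welch's t instead of pooled-variance Student t.
#' @return An `ebq_group_summary` list: `variable`, `test_used`
#'   (`"student_t"`, `"mann_whitney"` or `"chi_square"`), `p_value`, and
#'   `groups` — for continuous variables a data frame of per-group `n`,
#'   `mean`, `sd`, `ci_lower`, `ci_upper`; for categorical ones the
#'   contingency table.
#' @export
compare_groups <- function(cohort, variable, group = "subsided", level = 0.95,
                           welch = FALSE) {
  if (!variable %in% names(cohort)) {
    stop("no column `", variable, "` in the cohort", call. = FALSE)
  }
  g <- as.logical(cohort[[group]])
  x <- cohort[[variable]]
  if (length(unique(g)) != 2L) stop("need two nonempty groups", call. = FALSE)
  if (is.numeric(x)) {
    xs <- split(x, g)
    if (any(lengths(xs) < 2L)) stop("need n >= 2 per group", call. = FALSE)
    normal <- vapply(xs, function(v) {
      if (stats::sd(v) == 0) return(FALSE)       # degenerate: not testably normal
      m <- length(v)
      if (m > 5000L) v <- v[seq(1L, m, length.out = 5000L)]
      if (m < 3L) return(FALSE)
      stats::shapiro.test(v)$p.value >= 0.05
    }, logical(1))
    if (all(normal)) {
      test_used <- "student_t"
      p <- stats::t.test(xs[["FALSE"]], xs[["TRUE"]], var.equal = !welch)$p.value
    } else {
      test_used <- "mann_whitney"
      if (stats::sd(x) == 0) {
        p <- 1                                   # all observations tied
      } else {
        p <- stats::wilcox.test(xs[["FALSE"]], xs[["TRUE"]], exact = FALSE,
                                correct = FALSE)$p.value
      }
    }
    groups <- do.call(rbind, lapply(names(xs), function(k) {
      v <- xs[[k]]
      ci <- t_ci_mean(mean(v), stats::sd(v), length(v), level)
      data.frame(group = if (k == "TRUE") "subsidence" else "non_subsidence",
                 n = length(v), mean = mean(v), sd = stats::sd(v),
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
    }))
  } else {
    test_used <- "chi_square"
    tab <- table(x, g)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stop("zero margin in the contingency table for `", variable, "`",
           call. = FALSE)
    }
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    groups <- tab
  }
  structure(list(variable = variable, test_used = test_used, p_value = p,
                 groups = groups), class = "ebq_group_summary")
}

#' @export
print.ebq_group_summary <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (%s)\n", x$variable, x$p_value, x$test_used))
  print(x$groups)
  invisible(x)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' Product-moment correlation between two cohort variables (canonically the
#' preoperative EBQ score and the postoperative segmental height loss),
#' with the p-value from the t transform `r * sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, each with nonzero
#'   variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Per-level EBQ summary among non-subsided patients
#'
#' Mean, SD and t-based 95% CI of the EBQ score at each disc level,
#' restricted to patients without subsidence, ordered cranio-caudally.
#' Levels with fewer than 2 patients are omitted with a warning.
#'
#' @param cohort an `ebq_cohort`.
#' @param level confidence level (default 0.95).
#' @return Data frame with `level`, `n`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`.
#' @export
per_level_summary <- function(cohort, level = 0.95) {
  keep <- !as.logical(cohort$subsided)
  sub <- cohort[keep, , drop = FALSE]
  labs <- if (is.factor(sub$level)) levels(sub$level) else sort(unique(sub$level))
  rows <- lapply(labs, function(lab) {
    v <- sub$ebq[sub$level == lab]
    if (length(v) < 2L) {
      warning("level ", lab, " has fewer than 2 non-subsided patients; omitted",
              call. = FALSE)
      return(NULL)
    }
    ci <- t_ci_mean(mean(v), stats::sd(v), length(v), level)
    data.frame(level = lab, n = length(v), mean = mean(v), sd = stats::sd(v),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
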