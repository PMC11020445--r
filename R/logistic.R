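#' Multivariate logistic regression with Wald odds ratios
#'
#' Fits a binomial GLM of the binary outcome on the requested covariates by
#' iteratively reweighted least squares (tight convergence so the score
#' equations hold to numerical precision), and reports per-covariate
#' log-odds coefficients `B`, Wald standard errors from the inverse
#' observed information, two-sided normal p-values, odds ratios
#' `OR = exp(B)`, and `exp(B +/- 1.96 * se)` Wald CIs. Rank-deficient
#' designs error naming the collinear columns; coefficient blow-up
#' (|B| > 15 on a standardized-scale covariate) is flagged as probable
#' complete separation.
#'
#' @param cohort data frame containing `outcome` and all `covariates`.
#' @param covariates character vector of covariate column names (factors
#'   expand to treatment contrasts).
#' @param outcome binary outcome column name (default `"subsided"`).
#' @return An `ebq_logistic_fit`: `coefficients` data frame (`term`, `b`,
#'   `se`, `p`, `or`, `or_ci_lower`, `or_ci_upper`), `converged`, `n_iter`,
#'   `n`, and the underlying `glm` fit (`fit`).
#' @export
logistic_fit <- function(cohort, covariates, outcome = "subsided") {
  missing_cols <- setdiff(c(covariates, outcome), names(cohort))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- cohort[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y))
  if (length(unique(y)) != 2L) {
    stop("outcome `", outcome, "` must contain both classes", call. = FALSE)
  }
  dat <- cohort[, covariates, drop = FALSE]
  dat$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", covariates),
                                               collapse = " + ")))
  mm <- stats::model.matrix(fml, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[-seq_len(qr_mm$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  # quasi-separated fits warn about fitted probabilities of 0/1; the
  # coefficient screen below turns true separation into an error instead
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # scale-aware separation screen: |B| per covariate SD unit
  sds <- apply(mm, 2, stats::sd)
  sds[1] <- 1
  if (any(abs(b * sds)[-1] > 15) || (!fit$converged && max(abs(b[-1])) > 15)) {
    stop("probable complete separation: coefficient magnitudes are diverging",
         call. = FALSE)
  }
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(b), b = unname(b), se = unname(se),
    p = unname(2 * stats::pnorm(-abs(b / se))),
    or = unname(exp(b)),
    or_ci_lower = unname(exp(b - zq * se)),
    or_ci_upper = unname(exp(b + zq * se)),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, converged = fit$converged,
                 n_iter = fit$iter, n = length(y), fit = fit),
            class = "ebq_logistic_fit")
}

#' @export
print.ebq_logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d, %s in %d IRLS iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged", x$n_iter))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Odds ratio from a log-odds coefficient
#'
#' @param b log-odds coefficient(s).
#' @return `exp(b)`.
#' @examples
#' or_from_coef(c(0.405, -2.126))  # 1.499, 0.119 to 3 dp
#' @export
or_from_coef <- function(b) {
  if (any(!is.finite(b))) stop("`b` must be finite", call. = FALSE)
  exp(b)
}
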