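#' ROC analysis with Youden-index cutoff
#'
#' Builds the ROC curve for a continuous score against a binary outcome,
#' oriented so that a *higher* score predicts the positive class (higher
#' EBQ predicts subsidence). The threshold grid is the midpoints between
#' consecutive distinct scores plus `-Inf`/`+Inf` sentinels; a case is
#' called positive when its score exceeds the threshold. The AUC is
#' computed by the rank (Mann-Whitney) formula with ties counted one half,
#' so it equals the concordant-pair probability exactly; its 95% CI uses
#' DeLong's covariance estimator. The reported cutoff maximises Youden's
#' `J = sensitivity + specificity - 1`; ties on `J` are broken in favour of
#' higher specificity, then lower threshold.
#'
#' @param scores numeric predictor (e.g. EBQ).
#' @param labels binary outcome (logical, or coercible 0/1), `TRUE`/1 =
#'   positive class; both classes must be present.
#' @return An `ebq_roc` list: `thresholds`, `sensitivity`, `specificity`
#'   (per threshold), `auc`, `auc_ci95`, `cutoff`, `cutoff_sensitivity`,
#'   `cutoff_specificity`, `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc; r$cutoff
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  x <- scores[labels]; y <- scores[!labels]

  su <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(x > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(y <= t), numeric(1))

  # AUC by midranks: ties contribute 1/2 exactly
  r_all <- rank(scores)  # midranks
  auc <- (sum(r_all[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # DeLong placement values via midranks (exact, O(n log n))
  v10 <- (r_all[labels] - rank(x)) / n_neg            # per-positive placements
  v01 <- 1 - (r_all[!labels] - rank(y)) / n_pos       # per-negative placements
  var_auc <- stats::var(v10) / n_pos + stats::var(v01) / n_neg
  z <- stats::qnorm(0.975)
  auc_ci95 <- c(lower = auc - z * sqrt(var_auc), upper = auc + z * sqrt(var_auc))

  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-spec[best], thresholds[best])][1]

  structure(list(
    thresholds = thresholds, sensitivity = sens, specificity = spec,
    auc = auc, auc_ci95 = auc_ci95,
    cutoff = thresholds[best], cutoff_sensitivity = sens[best],
    cutoff_specificity = spec[best], youden_j = j[best],
    n_pos = n_pos, n_neg = n_neg), class = "ebq_roc")
}

#' @export
print.ebq_roc <- function(x, ...) {
  cat(sprintf(paste0("ROC: AUC = %.3f (95%% CI %.3f-%.3f), cutoff = %.2f ",
                     "(sens %.1f%%, spec %.1f%%), n = %d pos / %d neg\n"),
              x$auc, x$auc_ci95[["lower"]], x$auc_ci95[["upper"]], x$cutoff,
              100 * x$cutoff_sensitivity, 100 * x$cutoff_specificity,
              x$n_pos, x$n_neg))
  invisible(x)
}
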