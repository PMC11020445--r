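#' Segmental height from radiograph landmarks
#'
#' The distance between the midpoint of the superior endplate of the upper
#' vertebral body and the midpoint of the inferior endplate of the lower
#' vertebral body, across the fused level, on a calibrated lateral
#' radiograph (mm coordinates).
#'
#' @param sup_midpoint_mm,inf_midpoint_mm length-2 (x, y) points in mm.
#' @return Height in mm (Euclidean distance).
#' @examples
#' segmental_height(c(10, 10), c(10, 50))  # 40 mm
#' @export
segmental_height <- function(sup_midpoint_mm, inf_midpoint_mm) {
  a <- as.numeric(sup_midpoint_mm); b <- as.numeric(inf_midpoint_mm)
  if (length(a) != 2L || length(b) != 2L) {
    stop("landmarks must be (x, y) points", call. = FALSE)
  }
  d <- sqrt(sum((a - b)^2))
  if (d == 0) stop("landmark points coincide; height undefined", call. = FALSE)
  d
}

#' Classify cage subsidence
#'
#' Subsidence is a decrease in segmental height strictly exceeding
#' `threshold_mm` (default 2 mm) between the week-1 postoperative
#' radiograph and final follow-up, or migration of the interbody cage into
#' either endplate regardless of height loss. A loss of exactly the
#' threshold is not subsidence; negative loss (apparent height gain, which
#' occurs with measurement noise) is retained and classifies as subsidence
#' only via migration.
#'
#' @param h_postop_mm,h_final_mm segmental heights (mm) at the two
#'   timepoints; must be positive.
#' @param migration logical: cage migration into an endplate (reader call).
#' @param threshold_mm height-loss threshold (default 2).
#' @param id,level optional identifiers carried into the record.
#' @return A one-row data frame (`ebq_subsidence_record`) with `id`,
#'   `level`, `h_postop_mm`, `h_final_mm`, `loss_mm`, `migration`,
#'   `threshold_mm`, `subsided`. Vectorised over patients.
#' @examples
#' classify_subsidence(40, 37.5, migration = FALSE)$subsided  # TRUE
#' classify_subsidence(40, 38.0, migration = FALSE)$subsided  # FALSE (strict)
#' @export
classify_subsidence <- function(h_postop_mm, h_final_mm, migration = FALSE,
                                threshold_mm = 2.0, id = NA_character_,
                                level = NA_character_) {
  if (any(h_postop_mm <= 0) || any(h_final_mm <= 0)) {
    stop("segmental heights must be positive", call. = FALSE)
  }
  if (threshold_mm <= 0) stop("`threshold_mm` must be positive", call. = FALSE)
  n <- max(length(h_postop_mm), length(h_final_mm), length(migration))
  loss <- rep_len(h_postop_mm, n) - rep_len(h_final_mm, n)
  migration <- rep_len(as.logical(migration), n)
  rec <- data.frame(
    id = rep_len(id, n), level = rep_len(level, n),
    h_postop_mm = rep_len(h_postop_mm, n), h_final_mm = rep_len(h_final_mm, n),
    loss_mm = loss, migration = migration, threshold_mm = threshold_mm,
    subsided = loss > threshold_mm | migration,
    stringsAsFactors = FALSE)
  class(rec) <- c("ebq_subsidence_record", "data.frame")
  rec
}
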