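#' CSF reference region
#'
#' A simple polygon (mm coordinates) over the cerebrospinal-fluid space at
#' the cranio-caudal level of T1, whose mean T1-weighted signal is the
#' denominator of the EBQ score.
#'
#' @param polygon numeric matrix with >= 3 (x, y) vertices in mm.
#' @return An object of class `ebq_csf`.
#' @export
csf_region <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop("CSF `polygon` must have >= 3 (x, y) vertices", call. = FALSE)
  }
  if (abs(polygon_area(polygon)) <= 0) {
    stop("CSF polygon has zero area", call. = FALSE)
  }
  structure(list(polygon = polygon), class = "ebq_csf")
}

# signed shoelace area
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Compute the Endplate Bone Quality (EBQ) score
#'
#' EBQ is the mean T1-weighted signal of the subchondral bone within
#' `depth_mm` of the two endplates bounding the operated disc space,
#' divided by the mean CSF signal at T1:
#' `EBQ = ((SI_upper + SI_lower) / 2) / SI_CSF`.
#' Each endplate contributes its own band mean (so unequal band areas do
#' not reweight the score); `combine = "pooled"` instead pools all band
#' pixels into a single mean before normalising. Because EBQ is a ratio of
#' means from the same image, it is invariant under global intensity
#' rescaling — but not under additive offsets.
#'
#' @param image an [image2d()].
#' @param upper,lower [endplate_annotation()]s for the endplates above and
#'   below the operated disc space.
#' @param csf a [csf_region()].
#' @param exclusions optional exclusion geometry: a logical mask, a single
#'   polygon (matrix of mm vertices), or a list of polygons (e.g. Schmorl
#'   nodes). Applied to the endplate bands.
#' @param depth_mm subchondral band depth in mm (default 3).
#' @param rater_id optional identifier carried into the result.
#' @param combine `"average"` (default; mean of the two per-endplate means)
#'   or `"pooled"` (single mean over the union of band pixels).
#' @return An `ebq_measurement`: list with `level`, `rater_id`, `si_upper`,
#'   `si_lower`, `si_csf`, `ebq`, `n_pixels` and `excluded_pixels` (each a
#'   named vector over upper/lower/csf). `ebq` is kept at full precision;
#'   [format()] and [print()] display it to 2 decimals.
#' @examples
#' ph <- generate_phantom(phantom_config(noise_sd = 0, seed = 1))
#' m <- compute_ebq(ph$image, ph$ground_truth$levels[["C5/6"]]$upper,
#'                  ph$ground_truth$levels[["C5/6"]]$lower,
#'                  ph$ground_truth$csf)
#' m$ebq
#' @export
compute_ebq <- function(image, upper, lower, csf, exclusions = NULL,
                        depth_mm = 3.0, rater_id = NA_character_,
                        combine = c("average", "pooled")) {
  combine <- match.arg(combine)
  stopifnot(inherits(csf, "ebq_csf"))
  if (!identical(upper$level, lower$level)) {
    stop("upper and lower annotations are for different levels: ",
         upper$level, " vs ", lower$level, call. = FALSE)
  }
  exc <- resolve_exclusions(image, exclusions)
  mask_u <- extract_band(image, upper, depth_mm)
  mask_l <- extract_band(image, lower, depth_mm)
  mask_c <- polygon_mask(image, csf$polygon, what = "csf")
  mu_u <- mask_mean(image, mask_u, exc)
  mu_l <- mask_mean(image, mask_l, exc)
  mu_c <- mask_mean(image, mask_c)
  if (mu_c$mean <= 0) {
    stop("CSF mean signal is not positive; EBQ undefined", call. = FALSE)
  }
  numerator <- if (combine == "average") {
    (mu_u$mean + mu_l$mean) / 2
  } else {
    both <- (mask_u | mask_l) & if (is.null(exc)) TRUE else !exc
    mean(image$pixels[both])
  }
  structure(list(
    level = upper$level, rater_id = rater_id,
    si_upper = mu_u$mean, si_lower = mu_l$mean, si_csf = mu_c$mean,
    ebq = numerator / mu_c$mean,
    n_pixels = c(upper = mu_u$n_used, lower = mu_l$n_used, csf = mu_c$n_used),
    excluded_pixels = c(upper = mu_u$n_excluded, lower = mu_l$n_excluded, csf = 0L),
    combine = combine
  ), class = "ebq_measurement")
}

resolve_exclusions <- function(image, exclusions) {
  if (is.null(exclusions)) return(NULL)
  if (is.logical(exclusions) && is.matrix(exclusions)) return(exclusions)
  if (is.matrix(exclusions)) exclusions <- list(exclusions)
  if (is.list(exclusions)) {
    m <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
    for (p in exclusions) m <- m | polygon_mask(image, p, what = "exclusion")
    return(m)
  }
  stop("`exclusions` must be a mask, a polygon, or a list of polygons",
       call. = FALSE)
}

#' @export
format.ebq_measurement <- function(x, ...) {
  sprintf("EBQ[%s%s] = %.2f (SI upper %.1f, lower %.1f, CSF %.1f)",
          x$level, if (is.na(x$rater_id)) "" else paste0(", ", x$rater_id),
          x$ebq, x$si_upper, x$si_lower, x$si_csf)
}

#' @export
print.ebq_measurement <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Reconcile EBQ measurements from a rater panel
#'
#' Two primary raters measure independently; if their EBQ values agree to
#' within `threshold` (EBQ units, default 2), the final score is their mean.
#' Otherwise a third rater's confirmatory re-measurement is required and
#' becomes the final score.
#'
#' @param ebq_values numeric vector of >= 2 primary EBQ measurements (the
#'   first two are the primary raters), or a list of `ebq_measurement`s.
#' @param threshold discrepancy threshold in EBQ units (default 2).
#' @param arbiter optional third-rater EBQ value (or `ebq_measurement`).
#' @return List with `final_ebq` and `used_arbiter`.
#' @examples
#' reconcile_raters(c(4.1, 4.3))               # mean, no arbiter
#' reconcile_raters(c(3.0, 5.5), arbiter = 5.2) # arbiter decides
#' @export
reconcile_raters <- function(ebq_values, threshold = 2.0, arbiter = NULL) {
  as_val <- function(v) if (inherits(v, "ebq_measurement")) v$ebq else as.numeric(v)
  if (is.list(ebq_values)) ebq_values <- vapply(ebq_values, as_val, numeric(1))
  if (length(ebq_values) < 2L) {
    stop("need at least two primary measurements", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  e1 <- ebq_values[1]; e2 <- ebq_values[2]
  if (abs(e1 - e2) <= threshold) {
    return(list(final_ebq = mean(c(e1, e2)), used_arbiter = FALSE))
  }
  if (is.null(arbiter)) {
    stop(sprintf(paste0("rater discrepancy |%.2f - %.2f| = %.2f exceeds the ",
                        "threshold of %g: confirmatory re-measurement required"),
                 e1, e2, abs(e1 - e2), threshold), call. = FALSE)
  }
  list(final_ebq = as_val(arbiter), used_arbiter = TRUE)
}
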