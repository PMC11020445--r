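#' Endplate annotation
#'
#' A polyline traced along one endplate of the operated disc space, in mm
#' coordinates, together with a hint point marking which side of the line
#' the vertebral body (and hence the subchondral bone) lies on. `role`
#' records whether this is the endplate above or below the disc space.
#'
#' @param level disc-level label, e.g. `"C5/6"`.
#' @param role `"upper_endplate"` or `"lower_endplate"`.
#' @param polyline numeric matrix with >= 2 rows of (x, y) mm coordinates.
#' @param body_side_hint length-2 numeric (x, y) in mm, off the polyline,
#'   on the vertebral-body side.
#' @return An object of class `ebq_endplate`.
#' @export
endplate_annotation <- function(level, role = c("upper_endplate", "lower_endplate"),
                                polyline, body_side_hint) {
  role <- match.arg(role)
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L || ncol(polyline) != 2L) {
    stop("`polyline` must be a matrix of >= 2 (x, y) points", call. = FALSE)
  }
  seg_len <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                           polyline[-nrow(polyline), , drop = FALSE])^2))
  if (sum(seg_len) <= 0) stop("`polyline` has zero length", call. = FALSE)
  hint <- as.numeric(body_side_hint)
  if (length(hint) != 2L) stop("`body_side_hint` must be an (x, y) point", call. = FALSE)
  d <- point_polyline_distance(matrix(hint, 1), polyline)
  if (d$dist < 1e-9) stop("`body_side_hint` must not lie on the polyline", call. = FALSE)
  structure(list(level = level, role = role, polyline = polyline,
                 body_side_hint = hint),
            class = "ebq_endplate")
}

# Exact point-to-polyline distance with side classification and band
# coverage. points: n x 2 matrix (mm); polyline: m x 2. For every point,
# returns the minimum clamped point-to-segment distance, the sign of the
# 2-D cross product against the *nearest* segment (0 for points exactly on
# the line; at joints the first segment attaining the minimum decides), and
# `covered(depth)`: whether some segment's perpendicular strip (projection
# parameter within [0, 1], perpendicular distance <= depth) contains the
# point. The strip rule gives the band its flat ends: a straight 10 mm
# endplate with a 3 mm depth yields exactly the 10 x 3 mm rectangle, with
# no semicircular caps past the endpoints.
point_polyline_distance <- function(points, polyline, depth = NULL) {
  n <- nrow(points)
  m <- nrow(polyline) - 1L
  best <- rep(Inf, n)
  best_sign <- integer(n)
  covered <- rep(FALSE, n)
  px <- points[, 1]; py <- points[, 2]
  for (k in seq_len(m)) {
    a <- polyline[k, ]; b <- polyline[k + 1L, ]
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    L2 <- vx * vx + vy * vy
    wx <- px - a[1]; wy <- py - a[2]
    tt <- if (L2 > 0) (wx * vx + wy * vy) / L2 else rep(0, n)
    tc <- pmin(1, pmax(0, tt))
    dx <- wx - tc * vx; dy <- wy - tc * vy
    d <- sqrt(dx * dx + dy * dy)
    cr <- vx * wy - vy * wx  # >0: point to the left of a->b in image coords
    upd <- d < best - 1e-12
    best_sign[upd] <- sign(cr[upd])
    best[upd] <- d[upd]
    if (!is.null(depth) && L2 > 0) {
      perp <- abs(cr) / sqrt(L2)
      covered <- covered | (tt >= 0 & tt <= 1 & perp <= depth)
    }
  }
  list(dist = best, side = best_sign, covered = covered)
}

#' Extract the subchondral band mask for one endplate
#'
#' Selects every pixel whose centre lies within `depth_mm` perpendicular
#' distance of some segment of the endplate polyline (with its projection
#' falling on that segment, so the band has flat ends rather than
#' semicircular caps past the endpoints) *and* on the vertebral-body side
#' of it — i.e. the 3 mm subchondral bone band the EBQ score samples. The
#' side is classified by the sign of the 2-D cross product against the
#' nearest segment, anchored by `body_side_hint`; pixels whose centres fall
#' exactly on the polyline belong to neither side and are excluded.
#'
#' @param image an [image2d()].
#' @param ann an [endplate_annotation()].
#' @param depth_mm band depth in mm (default 3).
#' @return A logical matrix congruent with the image (`ebq_mask`), with the
#'   producing annotation attached as attribute `provenance`.
#' @export
extract_band <- function(image, ann, depth_mm = 3.0) {
  stopifnot(is_image2d(image), inherits(ann, "ebq_endplate"))
  if (!is.numeric(depth_mm) || depth_mm <= 0) {
    stop("`depth_mm` must be positive", call. = FALSE)
  }
  ext <- c(ncol(image$pixels), nrow(image$pixels)) * image$spacing_mm
  pl <- ann$polyline
  if (any(pl[, 1] < 0 | pl[, 1] > ext[1] | pl[, 2] < 0 | pl[, 2] > ext[2])) {
    stop(sprintf("polyline for %s %s extends outside the %g x %g mm image",
                 ann$level, ann$role, ext[1], ext[2]), call. = FALSE)
  }
  pc <- pixel_centres(image)
  dp <- point_polyline_distance(cbind(pc$x, pc$y), pl, depth = depth_mm)
  hint <- point_polyline_distance(matrix(ann$body_side_hint, 1), pl)
  mask <- dp$covered & dp$side == hint$side & dp$side != 0L
  dim(mask) <- c(pc$nr, pc$nc)
  if (!any(mask)) {
    stop(sprintf("empty band mask for %s %s (depth %g mm at %g mm spacing)",
                 ann$level, ann$role, depth_mm, image$spacing_mm), call. = FALSE)
  }
  structure(mask, class = c("ebq_mask", class(mask)),
            provenance = sprintf("%s/%s band %g mm", ann$level, ann$role, depth_mm))
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its centre lies inside (or on the
#' boundary of) the polygon, given in mm coordinates.
#'
#' @param image an [image2d()].
#' @param polygon numeric matrix with >= 3 rows of (x, y) mm vertices of a
#'   simple polygon.
#' @param what label recorded as the mask's provenance.
#' @return An `ebq_mask` logical matrix.
#' @export
polygon_mask <- function(image, polygon, what = "polygon") {
  stopifnot(is_image2d(image))
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop("`polygon` must be a matrix of >= 3 (x, y) vertices", call. = FALSE)
  }
  pc <- pixel_centres(image)
  inside <- pracma::inpolygon(pc$x, pc$y, polygon[, 1], polygon[, 2],
                              boundary = TRUE)
  dim(inside) <- c(pc$nr, pc$nc)
  structure(inside, class = c("ebq_mask", class(inside)), provenance = what)
}

#' Mean pixel intensity over a region of interest
#'
#' Arithmetic mean of the image values inside `roi`, after removing any
#' pixels covered by `exclusions` (e.g. a Schmorl node). Errors if nothing
#' measurable remains.
#'
#' @param image an [image2d()].
#' @param roi logical mask congruent with the image.
#' @param exclusions optional logical mask of pixels to drop from `roi`.
#' @return List with `mean`, `n_used`, and `n_excluded` (ROI pixels removed
#'   by the exclusion mask).
#' @export
mask_mean <- function(image, roi, exclusions = NULL) {
  stopifnot(is_image2d(image))
  if (!identical(dim(roi), dim(image$pixels))) {
    stop("`roi` mask shape does not match the image", call. = FALSE)
  }
  use <- roi
  n_exc <- 0L
  if (!is.null(exclusions)) {
    if (!identical(dim(exclusions), dim(image$pixels))) {
      stop("`exclusions` mask shape does not match the image", call. = FALSE)
    }
    n_exc <- sum(roi & exclusions)
    use <- roi & !exclusions
  }
  n <- sum(use)
  if (n == 0L) {
    stop("unmeasurable ROI: no pixels remain", if (n_exc > 0) " after exclusion",
         " (", attr(roi, "provenance") %||% "mask", ")", call. = FALSE)
  }
  list(mean = mean(image$pixels[use]), n_used = as.integer(n),
       n_excluded = as.integer(n_exc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
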