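#' Configuration for a synthetic mid-sagittal phantom
#'
#' Describes a schematic cervical mid-sagittal T1-weighted slice: a stack of
#' vertebral bodies separated by disc spaces, a posterior CSF column, and a
#' subchondral band of configurable depth against each endplate. Tissue
#' classes are `background`, `vertebral_bone`, `endplate_band`, `disc` and
#' `csf`; each pixel draws its value from the Gaussian of its class plus
#' additive Gaussian noise, clipped at zero. On T1-weighted images
#' fat-replaced marrow is brighter than dense bone, so a brighter
#' `endplate_band` relative to `csf` encodes a higher (worse) EBQ.
#'
#' @param image_height_px,image_width_px canvas size in pixels.
#' @param pixel_spacing_mm isotropic spacing, mm per pixel. The default 0.5
#'   makes the 3 mm band 6 pixels deep.
#' @param levels ordered disc-level labels; `length(levels) + 1` vertebral
#'   bodies are drawn.
#' @param tissue_means,tissue_sds named numeric vectors over the five tissue
#'   classes; means must be nonnegative, sds nonnegative.
#' @param band_depth_mm subchondral band depth (default 3 mm).
#' @param noise_sd additive image noise SD (on top of per-tissue SD).
#' @param curvature_amp_mm endplate curvature amplitude; 0 gives straight
#'   endplates, positive values bow each endplate sinusoidally into the disc.
#' @param disc_gap_mm,margin_mm layout knobs: disc-space height and canvas
#'   margin.
#' @param schmorl optional Schmorl-node lesion: a list with `level`,
#'   `radius_mm`, `lesion_mean`, and optionally `endplate`
#'   (`"upper"`/`"lower"`) and `offset_mm` along the polyline.
#' @param seed integer seed driving the phantom's single random stream.
#' @return A validated list of class `ebq_phantom_config`.
#' @export
phantom_config <- function(image_height_px = 256L, image_width_px = 160L,
                           pixel_spacing_mm = 0.5,
                           levels = c("C3/4", "C4/5", "C5/6", "C6/7"),
                           tissue_means = c(background = 20, vertebral_bone = 300,
                                            endplate_band = 430, disc = 120,
                                            csf = 100),
                           tissue_sds = c(background = 0, vertebral_bone = 0,
                                          endplate_band = 0, disc = 0, csf = 0),
                           band_depth_mm = 3.0, noise_sd = 5,
                           curvature_amp_mm = 0, disc_gap_mm = 6, margin_mm = 3,
                           schmorl = NULL, seed = 1L) {
  classes <- c("background", "vertebral_bone", "endplate_band", "disc", "csf")
  if (!all(classes %in% names(tissue_means))) {
    stop("`tissue_means` must name all of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  if (!all(classes %in% names(tissue_sds))) {
    stop("`tissue_sds` must name all of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  if (any(tissue_means < 0)) stop("tissue means must be nonnegative", call. = FALSE)
  if (any(tissue_sds < 0) || noise_sd < 0) {
    stop("tissue/noise SDs must be nonnegative", call. = FALSE)
  }
  stopifnot(image_height_px >= 8, image_width_px >= 8, pixel_spacing_mm > 0,
            band_depth_mm > 0, length(levels) >= 1)
  if (!is.null(schmorl)) {
    if (is.null(schmorl$level) || !schmorl$level %in% levels) {
      stop("schmorl$level must be one of the configured levels", call. = FALSE)
    }
  }
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              pixel_spacing_mm = pixel_spacing_mm, levels = levels,
              tissue_means = tissue_means[classes], tissue_sds = tissue_sds[classes],
              band_depth_mm = band_depth_mm, noise_sd = noise_sd,
              curvature_amp_mm = curvature_amp_mm, disc_gap_mm = disc_gap_mm,
              margin_mm = margin_mm, schmorl = schmorl, seed = as.integer(seed))
  # geometry must fit the canvas; validate now so errors name the dimension
  phantom_geometry(cfg)
  structure(cfg, class = "ebq_phantom_config")
}

# Lay out bodies, disc spaces, band polylines and the CSF column in mm.
phantom_geometry <- function(cfg) {
  s <- cfg$pixel_spacing_mm
  H <- cfg$image_height_px * s
  W <- cfg$image_width_px * s
  L <- length(cfg$levels)
  body_h <- (H - 2 * cfg$margin_mm - L * cfg$disc_gap_mm) / (L + 1)
  if (body_h <= cfg$band_depth_mm) {
    stop(sprintf(paste0("image_height_px = %d gives a vertebral body height of ",
                        "%.2f mm, not greater than band_depth_mm = %g"),
                 cfg$image_height_px, body_h, cfg$band_depth_mm), call. = FALSE)
  }
  x0 <- 0.12 * W; x1 <- 0.55 * W
  csf_x0 <- 0.68 * W; csf_x1 <- 0.85 * W
  if (x1 + cfg$band_depth_mm >= csf_x0) {
    stop(sprintf(paste0("image_width_px = %d leaves no gap between the ",
                        "vertebral column and the CSF column"),
                 cfg$image_width_px), call. = FALSE)
  }
  body_top <- cfg$margin_mm + (seq_len(L + 1) - 1) * (body_h + cfg$disc_gap_mm)
  list(H = H, W = W, body_h = body_h, x0 = x0, x1 = x1,
       csf = cbind(c(csf_x0, csf_x1, csf_x1, csf_x0),
                   c(cfg$margin_mm, cfg$margin_mm, H - cfg$margin_mm,
                     H - cfg$margin_mm)),
       body_top = body_top, body_bottom = body_top + body_h)
}

# Endplate polyline across the body width at height y0, optionally bowed
# towards the disc by `amp` (sign: +1 bows downwards in image coordinates).
endplate_polyline <- function(x0, x1, y0, amp, bow_sign) {
  if (amp == 0) return(cbind(c(x0, x1), c(y0, y0)))
  x <- seq(x0, x1, length.out = 17)
  cbind(x, y0 + bow_sign * amp * sin(pi * (x - x0) / (x1 - x0)))
}

#' Generate a phantom image with known ground truth
#'
#' Rasterizes the geometry described by a [phantom_config()] and draws pixel
#' values from the configured per-tissue Gaussians plus additive noise
#' (clipped at zero). The endplate bands are painted through exactly the
#' same point-in-band predicate that [extract_band()] measures with, and the
#' CSF column through the same polygon test as [polygon_mask()], so at zero
#' noise the measured EBQ equals the configured
#' `endplate_band / csf` mean ratio exactly. Identical config and seed give
#' bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return A list of class `ebq_phantom` with:
#'   * `image`: the [image2d()];
#'   * `ground_truth`: `spacing_mm`, per-level `upper`/`lower`
#'     [endplate_annotation()]s with `exclusions`, the [csf_region()],
#'     `tissue_means`, `true_ebq` (named per level), the tissue-class label
#'     matrix `tissue`, and `band_depth_mm`;
#'   * `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(noise_sd = 0))
#' ph$ground_truth$true_ebq
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "ebq_phantom_config"))
  geo <- phantom_geometry(config)
  s <- config$pixel_spacing_mm
  nr <- config$image_height_px; nc <- config$image_width_px
  img <- image2d(matrix(0, nr, nc), s)
  pc <- pixel_centres(img)
  cx <- pc$x; cy <- pc$y

  tissue <- matrix("background", nr, nc)
  for (b in seq_along(geo$body_top)) {
    inb <- cx >= geo$x0 & cx <= geo$x1 &
      cy >= geo$body_top[b] & cy <= geo$body_bottom[b]
    tissue[matrix(inb, nr, nc)] <- "vertebral_bone"
  }
  L <- length(config$levels)
  for (d in seq_len(L)) {
    ind <- cx >= geo$x0 & cx <= geo$x1 &
      cy > geo$body_bottom[d] & cy < geo$body_top[d + 1]
    tissue[matrix(ind, nr, nc)] <- "disc"
  }
  csf <- csf_region(geo$csf)
  tissue[polygon_mask(img, csf$polygon, "csf")] <- "csf"

  mid_x <- (geo$x0 + geo$x1) / 2
  lv <- list()
  for (d in seq_len(L)) {
    lab <- config$levels[d]
    up <- endplate_annotation(
      lab, "upper_endplate",
      endplate_polyline(geo$x0, geo$x1, geo$body_bottom[d],
                        config$curvature_amp_mm, +1),
      body_side_hint = c(mid_x, geo$body_bottom[d] - config$band_depth_mm / 2))
    lo <- endplate_annotation(
      lab, "lower_endplate",
      endplate_polyline(geo$x0, geo$x1, geo$body_top[d + 1],
                        config$curvature_amp_mm, -1),
      body_side_hint = c(mid_x, geo$body_top[d + 1] + config$band_depth_mm / 2))
    tissue[extract_band(img, up, config$band_depth_mm)] <- "endplate_band"
    tissue[extract_band(img, lo, config$band_depth_mm)] <- "endplate_band"
    lv[[lab]] <- list(upper = up, lower = lo, exclusions = list(),
                      exclusion_masks = list())
  }

  set.seed(config$seed)
  mu <- config$tissue_means[tissue]
  sd_t <- config$tissue_sds[tissue]
  vals <- mu + sd_t * stats::rnorm(nr * nc) + config$noise_sd * stats::rnorm(nr * nc)
  img$pixels <- matrix(pmax(vals, 0), nr, nc)

  truth <- list(
    spacing_mm = s, levels = lv, csf = csf,
    tissue_means = config$tissue_means,
    true_ebq = stats::setNames(
      rep(config$tissue_means[["endplate_band"]] / config$tissue_means[["csf"]], L),
      config$levels),
    tissue = tissue, band_depth_mm = config$band_depth_mm)
  out <- structure(list(image = img, ground_truth = truth, config = config),
                   class = "ebq_phantom")
  if (!is.null(config$schmorl)) {
    out <- do.call(inject_schmorl, c(list(phantom = out), config$schmorl))
  }
  out
}

#' Inject a Schmorl-node lesion into a phantom
#'
#' Paints a half-disc of `lesion_mean` intensity indenting the named
#' endplate (centre on the polyline, extending into the vertebral body) and
#' records the lesion in the ground truth as an exclusion region — both as
#' the exact pixel mask and as a 64-gon polygon for annotation files.
#' `radius_mm = 0` is a no-op.
#'
#' @param phantom an `ebq_phantom` from [generate_phantom()].
#' @param level disc-level label of the affected endplate.
#' @param radius_mm lesion radius; must not exceed the band depth.
#' @param lesion_mean intensity written into the lesion (Schmorl nodes carry
#'   disc material, typically brighter than subchondral bone on T1W).
#' @param endplate `"upper"` or `"lower"` endplate of the disc space.
#' @param offset_mm arc-length position of the lesion centre along the
#'   polyline; default the midpoint.
#' @return The modified `ebq_phantom`.
#' @export
inject_schmorl <- function(phantom, level, radius_mm, lesion_mean,
                           endplate = c("upper", "lower"), offset_mm = NULL) {
  stopifnot(inherits(phantom, "ebq_phantom"))
  endplate <- match.arg(endplate)
  gt <- phantom$ground_truth
  if (!level %in% names(gt$levels)) {
    stop("no such level in the phantom: ", level, call. = FALSE)
  }
  if (radius_mm < 0 || lesion_mean < 0) {
    stop("`radius_mm` and `lesion_mean` must be nonnegative", call. = FALSE)
  }
  if (radius_mm > gt$band_depth_mm) {
    stop(sprintf("lesion radius %g mm exceeds the band depth of %g mm",
                 radius_mm, gt$band_depth_mm), call. = FALSE)
  }
  if (radius_mm == 0) return(phantom)
  ann <- gt$levels[[level]][[endplate]]
  pl <- ann$polyline
  seg <- pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  at <- if (is.null(offset_mm)) total / 2 else offset_mm
  if (at < 0 || at > total) {
    stop(sprintf("offset_mm = %g outside the polyline length %.2f mm", at, total),
         call. = FALSE)
  }
  cum <- c(0, cumsum(seg_len))
  k <- max(1L, findInterval(at, cum, rightmost.closed = TRUE))
  frac <- if (seg_len[k] > 0) (at - cum[k]) / seg_len[k] else 0
  centre <- pl[k, ] + frac * seg[k, ]

  img <- phantom$image
  pc <- pixel_centres(img)
  d_centre <- sqrt((pc$x - centre[1])^2 + (pc$y - centre[2])^2)
  dp <- point_polyline_distance(cbind(pc$x, pc$y), pl)
  hint <- point_polyline_distance(matrix(ann$body_side_hint, 1), pl)
  mask <- d_centre <= radius_mm & dp$side == hint$side & dp$side != 0L
  dim(mask) <- c(pc$nr, pc$nc)
  img$pixels[mask] <- lesion_mean
  if (any(mask)) gt$tissue[mask] <- "schmorl"

  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- cbind(centre[1] + radius_mm * cos(theta),
                centre[2] + radius_mm * sin(theta))
  gt$levels[[level]]$exclusions <- c(gt$levels[[level]]$exclusions, list(poly))
  gt$levels[[level]]$exclusion_masks <- c(gt$levels[[level]]$exclusion_masks,
                                          list(mask))
  phantom$image <- img
  phantom$ground_truth <- gt
  phantom
}

#' Measure EBQ on a phantom's ground-truth annotations
#'
#' Convenience wrapper running [compute_ebq()] on each (or selected) levels
#' of a phantom, using the ground-truth endplate annotations and CSF region,
#' optionally applying the recorded exclusion masks.
#'
#' @param phantom an `ebq_phantom`.
#' @param levels level labels to measure (default all).
#' @param apply_exclusions drop recorded lesion pixels from the bands?
#' @param depth_mm band depth; defaults to the phantom's configured depth.
#' @return A data frame with one row per level: `level`, `ebq`, `si_upper`,
#'   `si_lower`, `si_csf`, `n_excluded`.
#' @export
measure_phantom <- function(phantom, levels = NULL, apply_exclusions = TRUE,
                            depth_mm = NULL) {
  stopifnot(inherits(phantom, "ebq_phantom"))
  gt <- phantom$ground_truth
  if (is.null(levels)) levels <- names(gt$levels)
  if (is.null(depth_mm)) depth_mm <- gt$band_depth_mm
  rows <- lapply(levels, function(lab) {
    e <- gt$levels[[lab]]
    if (is.null(e)) stop("no such level in the phantom: ", lab, call. = FALSE)
    exc <- NULL
    if (apply_exclusions && length(e$exclusion_masks)) {
      exc <- Reduce(`|`, e$exclusion_masks)
    }
    m <- compute_ebq(phantom$image, e$upper, e$lower, gt$csf,
                     exclusions = exc, depth_mm = depth_mm)
    data.frame(level = lab, ebq = m$ebq, si_upper = m$si_upper,
               si_lower = m$si_lower, si_csf = m$si_csf,
               n_excluded = sum(m$excluded_pixels))
  })
  do.call(rbind, rows)
}
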