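# Independent brute-force oracles; deliberately slow and literal so they
# share no code path with the implementation they check.

# Point-in-band test, one pixel at a time: a pixel centre is in the band iff
# some polyline segment has its perpendicular foot on the segment within
# `depth`, and the centre is on the same side of the nearest segment as the
# hint point.
brute_band_mask <- function(image, ann, depth) {
  s <- image$spacing_mm
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  pl <- ann$polyline
  nseg <- nrow(pl) - 1L
  side_of <- function(p) {
    dmin <- Inf; sgn <- 0
    for (k in seq_len(nseg)) {
      a <- pl[k, ]; b <- pl[k + 1L, ]
      v <- b - a; w <- p - a
      t <- max(0, min(1, sum(w * v) / sum(v * v)))
      d <- sqrt(sum((w - t * v)^2))
      if (d < dmin - 1e-12) {
        dmin <- d
        sgn <- sign(v[1] * w[2] - v[2] * w[1])
      }
    }
    sgn
  }
  hint_side <- side_of(ann$body_side_hint)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p <- c((j - 0.5) * s, (i - 0.5) * s)
      in_strip <- FALSE
      for (k in seq_len(nseg)) {
        a <- pl[k, ]; b <- pl[k + 1L, ]
        v <- b - a; w <- p - a
        len2 <- sum(v * v)
        if (len2 == 0) next
        t <- sum(w * v) / len2
        perp <- abs(v[1] * w[2] - v[2] * w[1]) / sqrt(len2)
        if (t >= 0 && t <= 1 && perp <= depth) in_strip <- TRUE
      }
      if (in_strip) {
        sg <- side_of(p)
        out[i, j] <- sg != 0 && sg == hint_side
      }
    }
  }
  out
}

# AUC as the probability of concordance: count pairs, ties worth 1/2.
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  tot / (length(x) * length(y))
}

# Compact single-level phantom used where full-size images would be waste.
small_phantom_config <- function(...) {
  phantom_config(image_height_px = 64L, image_width_px = 64L,
                 levels = "C5/6", ...)
}
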