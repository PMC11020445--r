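# Builds a deterministic scene where the two endplate bands and the CSF
# region have known constant intensities.
scene_with <- function(si_upper, si_lower, si_csf, base = 50) {
  img <- image2d(matrix(base, 64, 64), 0.5)
  up <- endplate_annotation("C5/6", "upper_endplate",
                            rbind(c(4, 12), c(16, 12)), c(10, 9))
  lo <- endplate_annotation("C5/6", "lower_endplate",
                            rbind(c(4, 18), c(16, 18)), c(10, 21))
  csf <- csf_region(rbind(c(22, 4), c(28, 4), c(28, 28), c(22, 28)))
  img$pixels[extract_band(img, up, 3)] <- si_upper
  img$pixels[extract_band(img, lo, 3)] <- si_lower
  img$pixels[polygon_mask(img, csf$polygon)] <- si_csf
  list(img = img, up = up, lo = lo, csf = csf)
}

test_that("EBQ is the endplate-average signal over the CSF signal", {
  sc <- scene_with(120, 80, 100)
  m <- compute_ebq(sc$img, sc$up, sc$lo, sc$csf)
  expect_equal(m$si_upper, 120)
  expect_equal(m$si_lower, 80)
  expect_equal(m$si_csf, 100)
  expect_equal(m$ebq, 1.00)
})

test_that("a 470/100 band-to-CSF contrast gives EBQ 4.70", {
  ph <- generate_phantom(small_phantom_config(
    noise_sd = 0,
    tissue_means = c(background = 20, vertebral_bone = 300,
                     endplate_band = 470, disc = 120, csf = 100)))
  m <- measure_phantom(ph)
  expect_equal(m$ebq, 4.70, tolerance = 1e-12)
})

test_that("EBQ is invariant under global rescaling but not under offsets", {
  sc <- scene_with(180, 140, 110)
  m0 <- compute_ebq(sc$img, sc$up, sc$lo, sc$csf)
  img_scaled <- sc$img
  img_scaled$pixels <- img_scaled$pixels * 3.7
  m1 <- compute_ebq(img_scaled, sc$up, sc$lo, sc$csf)
  expect_equal(m1$ebq, m0$ebq, tolerance = 1e-12)

  img_off <- sc$img
  img_off$pixels <- img_off$pixels + 50
  m2 <- compute_ebq(img_off, sc$up, sc$lo, sc$csf)
  expect_false(isTRUE(all.equal(m2$ebq, m0$ebq, tolerance = 1e-6)))
})

test_that("pooled combination differs from per-endplate averaging when areas differ", {
  sc <- scene_with(200, 100, 100)
  # shorten the lower band so areas differ
  lo2 <- endplate_annotation("C5/6", "lower_endplate",
                             rbind(c(4, 18), c(10, 18)), c(7, 21))
  m_avg <- compute_ebq(sc$img, sc$up, lo2, sc$csf)
  m_pool <- compute_ebq(sc$img, sc$up, lo2, sc$csf, combine = "pooled")
  expect_equal(m_avg$ebq, 1.5)
  expect_gt(m_pool$ebq, m_avg$ebq)  # pooled mean is pulled to the larger band
})

test_that("degenerate CSF signal and mismatched levels are rejected", {
  sc <- scene_with(120, 80, 0)
  expect_error(compute_ebq(sc$img, sc$up, sc$lo, sc$csf), "CSF mean")
  lo_other <- endplate_annotation("C6/7", "lower_endplate",
                                  rbind(c(4, 18), c(16, 18)), c(10, 21))
  expect_error(compute_ebq(sc$img, sc$up, lo_other, sc$csf), "different levels")
})

test_that("rater reconciliation applies the discrepancy rule", {
  r <- reconcile_raters(c(4.1, 4.3))
  expect_equal(r$final_ebq, 4.2)
  expect_false(r$used_arbiter)

  r2 <- reconcile_raters(c(3.0, 5.5), arbiter = 5.2)
  expect_equal(r2$final_ebq, 5.2)
  expect_true(r2$used_arbiter)

  expect_error(reconcile_raters(c(3.0, 5.5)), "re-measurement")
  expect_error(reconcile_raters(4.1), "two primary")
  expect_error(reconcile_raters(c(4, 4.2), threshold = -1), "positive")
  # measurements objects are accepted too
  sc <- scene_with(120, 80, 100)
  m <- compute_ebq(sc$img, sc$up, sc$lo, sc$csf, rater_id = "R1")
  expect_equal(reconcile_raters(list(m, m))$final_ebq, m$ebq)
})
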