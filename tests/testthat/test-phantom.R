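test_that("phantom generation is bit-deterministic in config and seed", {
  a <- generate_phantom(small_phantom_config(seed = 42))
  b <- generate_phantom(small_phantom_config(seed = 42))
  c <- generate_phantom(small_phantom_config(seed = 43))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("zero-noise EBQ equals the configured mean ratio exactly", {
  ph <- generate_phantom(phantom_config(
    noise_sd = 0,
    tissue_means = c(background = 20, vertebral_bone = 300,
                     endplate_band = 200, disc = 120, csf = 100)))
  m <- measure_phantom(ph)
  expect_equal(m$ebq, rep(2, 4), tolerance = 1e-13)
  expect_equal(unname(ph$ground_truth$true_ebq), rep(2, 4))
})

test_that("equal tissue means give EBQ 1 at every level", {
  means <- c(background = 150, vertebral_bone = 150, endplate_band = 150,
             disc = 150, csf = 150)
  ph <- generate_phantom(phantom_config(noise_sd = 0, tissue_means = means))
  expect_equal(measure_phantom(ph)$ebq, rep(1, 4), tolerance = 1e-13)
})

test_that("noisy band means stay within 2 SE of the configured mean", {
  cfg <- small_phantom_config(
    noise_sd = 5, seed = 1,
    tissue_means = c(background = 20, vertebral_bone = 300,
                     endplate_band = 180, disc = 120, csf = 100))
  ph <- generate_phantom(cfg)
  ann <- ph$ground_truth$levels[["C5/6"]]$upper
  mask <- extract_band(ph$image, ann, 3)
  vals <- ph$image$pixels[mask]  # direct pixel-averaging oracle
  se <- 5 / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 180), 2 * se)
})

test_that("geometry that cannot fit the canvas names the offending dimension", {
  expect_error(phantom_config(image_height_px = 32, levels = paste0("L", 1:4)),
               "image_height_px")
  expect_error(phantom_config(image_width_px = 16), "image_width_px")
})

test_that("Schmorl injection raises unexcluded EBQ and exclusion restores it", {
  cfg <- small_phantom_config(
    noise_sd = 0,
    tissue_means = c(background = 20, vertebral_bone = 300,
                     endplate_band = 200, disc = 120, csf = 100))
  ph <- generate_phantom(cfg)
  before <- measure_phantom(ph)$ebq
  ph2 <- inject_schmorl(ph, "C5/6", radius_mm = 2, lesion_mean = 400)

  no_excl <- measure_phantom(ph2, apply_exclusions = FALSE)
  with_excl <- measure_phantom(ph2, apply_exclusions = TRUE)
  expect_gt(no_excl$ebq, before)
  expect_equal(with_excl$ebq, before, tolerance = 1e-13)
  expect_gt(with_excl$n_excluded, 0)

  # pixel-count oracle for the unexcluded mean: (200*(1-f) + 400*f) / 100
  band <- extract_band(ph2$image, ph2$ground_truth$levels[["C5/6"]]$upper, 3)
  lesion <- ph2$ground_truth$levels[["C5/6"]]$exclusion_masks[[1]]
  f <- sum(band & lesion) / sum(band)
  expect_gt(f, 0)
  expect_equal(no_excl$si_upper, 200 * (1 - f) + 400 * f, tolerance = 1e-12)
  expect_equal(no_excl$ebq, ((200 * (1 - f) + 400 * f) + 200) / 2 / 100,
               tolerance = 1e-12)
})

test_that("Schmorl edge cases: zero radius is a no-op, oversize radius errors", {
  ph <- generate_phantom(small_phantom_config(noise_sd = 0))
  ph0 <- inject_schmorl(ph, "C5/6", radius_mm = 0, lesion_mean = 400)
  expect_identical(ph0$image$pixels, ph$image$pixels)
  expect_error(inject_schmorl(ph, "C5/6", radius_mm = 5, lesion_mean = 400),
               "band depth")
  expect_error(inject_schmorl(ph, "C9/9", radius_mm = 1, lesion_mean = 400),
               "no such level")
})

test_that("a configured Schmorl spec is applied at generation time", {
  cfg <- small_phantom_config(
    noise_sd = 0,
    schmorl = list(level = "C5/6", radius_mm = 2, lesion_mean = 500))
  ph <- generate_phantom(cfg)
  expect_length(ph$ground_truth$levels[["C5/6"]]$exclusion_masks, 1)
  expect_equal(measure_phantom(ph)$ebq, 4.3, tolerance = 1e-13)
  expect_gt(measure_phantom(ph, apply_exclusions = FALSE)$ebq, 4.3)
})
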