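# Segmentation, recruitment, ratiometric lipid order, condensate detection,
# granulosity.

test_that("segment_guv recovers the ring and fails cleanly on blank input", {
  blank <- image_channel(matrix(0, 64, 64), 0.05)
  expect_guv_error(segment_guv(blank), "guvphase_no_foreground")

  cfg <- synth_config(seed = 1)
  g <- make_guv_image(cfg)
  mask <- segment_guv(g$membrane)
  expect_lt(abs(mask$area_um2 - g$truth$ring_area_um2) / g$truth$ring_area_um2, 0.15)
})

test_that("Otsu segmentation is offset-invariant and translation-equivariant", {
  cfg <- synth_config(seed = 2)
  g <- make_guv_image(cfg)
  mask <- segment_guv(g$membrane)
  shifted <- image_channel(g$membrane$intensities + 37.5, cfg$pixel_size_um)
  expect_identical(segment_guv(shifted)$flags, mask$flags)

  # translate the image by 5 rows; the mask translates with it
  m <- g$membrane$intensities
  tr <- rbind(m[(nrow(m) - 4):nrow(m), ], m[1:(nrow(m) - 5), ])
  mask_tr <- segment_guv(image_channel(tr, cfg$pixel_size_um))
  expected <- rbind(mask$flags[(nrow(m) - 4):nrow(m), ], mask$flags[1:(nrow(m) - 5), ])
  # ignore the wrap seam introduced by the circular translation
  interior <- 8:(nrow(m) - 8)
  expect_identical(mask_tr$flags[interior, ], expected[interior, ])
})

test_that("recruitment is the mean masked intensity", {
  ps <- 0.1
  uni <- image_channel(matrix(7.5, 32, 32), ps)
  fl <- matrix(FALSE, 32, 32); fl[5:10, 5:20] <- TRUE
  mask <- region_mask(fl, ps)
  m <- quantify_recruitment(uni, mask)
  expect_equal(m$intensity_per_area, 7.5)
  expect_equal(m$integrated_intensity, 7.5 * sum(fl))
  expect_equal(m$area_um2, sum(fl) * ps^2)
  # intensity_per_area == integrated * pixel_area / mask_area
  expect_equal(m$intensity_per_area,
               m$integrated_intensity * ps^2 / m$area_um2)

  one <- matrix(FALSE, 32, 32); one[3, 3] <- TRUE
  img <- matrix(0, 32, 32); img[3, 3] <- 42
  m1 <- quantify_recruitment(image_channel(img, ps), region_mask(one, ps))
  expect_equal(m1$integrated_intensity, 42)
  expect_equal(m1$intensity_per_area, 42)

  empty <- region_mask(matrix(FALSE, 32, 32), ps)
  expect_guv_error(quantify_recruitment(uni, empty), "guvphase_empty_mask")
})

test_that("compute_phi is the ratio of masked sums", {
  ps <- 0.1
  fl <- matrix(FALSE, 16, 16); fl[4:12, 4:12] <- TRUE
  mask <- region_mask(fl, ps)
  a <- image_channel(matrix(runif(256) + 0.5, 16, 16), ps)
  expect_equal(compute_phi(a, a, mask)$phi, 1)
  b2 <- image_channel(2 * a$intensities, ps)
  expect_equal(compute_phi(b2, a, mask)$phi, 2)
  # invariance to common rescaling
  a3 <- image_channel(3 * a$intensities, ps)
  b6 <- image_channel(3 * b2$intensities, ps)
  expect_equal(compute_phi(b6, a3, mask)$phi, 2)
  zero <- image_channel(matrix(0, 16, 16), ps)
  expect_guv_error(compute_phi(a, zero, mask), "guvphase_division_by_zero")
  # ratio map zeroed outside the mask
  pr <- compute_phi(b2, a, mask)
  expect_true(all(pr$ratio_map[!fl] == 0))
  expect_true(all(abs(pr$ratio_map[fl] - 2) < 1e-12))
})

test_that("phi recovery from noisy dye images is within 5%", {
  for (seed in 1:3) {
    cfg <- synth_config(seed = seed, noise_sd = 10)
    out <- make_pk_image(cfg, true_phi = 1.4, amplitude = 200)
    mask <- segment_guv(out$marker)
    phi <- compute_phi(out$blue_green, out$red, mask)$phi
    expect_lt(abs(phi - 1.4) / 1.4, 0.05)
  }
})

test_that("live-cell phi subtracts scalar background and flags dead regions", {
  ps <- 0.1
  img <- function(m) image_channel(m, ps)
  base_bg <- 10
  red <- matrix(base_bg, 32, 32); blue <- matrix(base_bg, 32, 32)
  r1 <- matrix(FALSE, 32, 32); r1[4:8, 4:8] <- TRUE
  r2 <- matrix(FALSE, 32, 32); r2[20:24, 20:24] <- TRUE
  bg <- matrix(FALSE, 32, 32); bg[28:31, 2:10] <- TRUE
  red[r1] <- base_bg + 100; blue[r1] <- base_bg + 120   # phi 1.2
  red[r2] <- base_bg + 100; blue[r2] <- base_bg + 160   # phi 1.6
  res <- compute_phi_live(img(blue), img(red),
                          list(region_mask(r1, ps), region_mask(r2, ps)),
                          region_mask(bg, ps))
  expect_equal(res[[1]]$phi, 1.2)
  expect_equal(res[[2]]$phi, 1.6)
  expect_true(res[[1]]$valid && res[[2]]$valid)

  # uniform extra offset on both channels cancels
  res2 <- compute_phi_live(img(blue + 50), img(red + 50),
                           list(region_mask(r1, ps)), region_mask(bg, ps))
  expect_equal(res2[[1]]$phi, 1.2)

  # zero-background region means: identical to compute_phi per region
  bg0_blue <- blue; bg0_blue[bg] <- 0
  bg0_red <- red; bg0_red[bg] <- 0
  res3 <- compute_phi_live(img(bg0_blue), img(bg0_red),
                           list(region_mask(r1, ps)), region_mask(bg, ps))
  expect_equal(res3[[1]]$phi,
               compute_phi(img(bg0_blue), img(bg0_red), region_mask(r1, ps))$phi)

  # region with no red signal above background is flagged, not dropped
  dead <- matrix(FALSE, 32, 32); dead[12:14, 12:14] <- TRUE
  res4 <- compute_phi_live(img(blue), img(red),
                           list(region_mask(dead, ps)), region_mask(bg, ps))
  expect_false(res4[[1]]$valid)
  expect_true(is.na(res4[[1]]$phi))
  # overlapping background is a usage error
  expect_guv_error(
    compute_phi_live(img(blue), img(red), list(region_mask(r1, ps)),
                     region_mask(r1, ps)),
    "guvphase_parameter_error")
})

test_that("condensate detection recovers count and exact areas", {
  blank <- image_channel(matrix(0, 64, 64), 0.05)
  expect_equal(nrow(detect_condensates(blank)), 0L)

  cfg <- synth_config(seed = 3, shape = c(300, 300), pixel_size_um = 0.05)
  f <- make_condensate_field(cfg, n = 30, area_um2_mean = 0.6, area_um2_sd = 0)
  det <- detect_condensates(f$field)
  expect_equal(nrow(det), 30L)
  expect_equal(sort(det$area_um2), sort(f$truth$true_areas_um2))
  expect_true(all(abs(det$area_um2 - 0.6) <= cfg$pixel_size_um^2))
  # total area exactly recovered
  expect_equal(sum(det$area_um2), sum(f$truth$true_areas_um2))

  # min-area filter
  det_f <- detect_condensates(f$field, min_area_um2 = 1)
  expect_equal(nrow(det_f), 0L)
})

test_that("overlapping disks merge into one 8-connected component", {
  m <- matrix(0, 32, 32)
  m[10:14, 10:14] <- 100
  m[14:18, 14:18] <- 100   # shares the corner pixel (14,14) and overlaps
  det <- detect_condensates(image_channel(m, 0.1), threshold_method = "fixed",
                            fixed_value = 50)
  expect_equal(nrow(det), 1L)
  # purely diagonal contact also merges under 8-connectivity
  m2 <- matrix(0, 32, 32)
  m2[5, 5] <- 100; m2[6, 6] <- 100
  det2 <- detect_condensates(image_channel(m2, 0.1), threshold_method = "fixed",
                             fixed_value = 50)
  expect_equal(nrow(det2), 1L)
})

test_that("granulosity: constant image gives 0, index is scale-invariant", {
  const <- image_channel(matrix(5, 64, 64), 0.1)
  expect_equal(granulosity_index(const, 8)$index, 0)

  cfg <- synth_config(seed = 4, shape = c(64, 64), pixel_size_um = 0.1)
  f <- make_condensate_field(cfg, n = 8, area_um2_mean = 1.5, area_um2_sd = 0.2,
                             amplitude = 50)$field
  g1 <- granulosity_index(f, 8)$index
  g2 <- granulosity_index(image_channel(2.5 * f$intensities, 0.1), 8)$index
  expect_equal(g1, g2, tolerance = 1e-10)

  # condensate-rich frame beats a uniform frame of equal mean
  uni <- image_channel(matrix(mean(f$intensities), 64, 64), 0.1)
  expect_gt(g1, granulosity_index(uni, 8)$index)

  # fully-subtracted image has zero mean: index undefined
  expect_guv_error(granulosity_index(f, 8, background = mean(f$intensities)),
                   "guvphase_undefined_index")
})

test_that("FFT high-pass agrees with the direct DFT oracle", {
  cfg <- synth_config(seed = 9, shape = c(64, 64), pixel_size_um = 0.1)
  f <- make_condensate_field(cfg, n = 6, area_um2_mean = 0.5,
                             area_um2_sd = 0.05, amplitude = 80)$field
  ours <- highpass_filter(f$intensities, 6)
  oracle <- dft_highpass_oracle(f$intensities, 6)
  expect_lt(max(abs(ours - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("granulosity grows with added high-frequency texture at fixed mean", {
  base <- matrix(50, 64, 64)
  withr::with_seed(21, {
    texture <- matrix(rnorm(64 * 64), 64, 64)
    texture <- texture - mean(texture)          # zero-mean texture
  })
  g_prev <- -Inf
  for (amp in c(0, 2, 5, 10, 20)) {
    g <- granulosity_index(image_channel(pmax(base + amp * texture, 0), 0.1), 8)$index
    expect_gte(g, g_prev)
    g_prev <- g
  }
})
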