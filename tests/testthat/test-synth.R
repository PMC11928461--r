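# Generator contracts: determinism, ground-truth consistency, noise model.

test_that("all generators are bit-identical under a fixed seed", {
  cfg <- synth_config(seed = 42, noise_sd = 5)
  expect_identical(make_guv_image(cfg), make_guv_image(cfg))
  expect_identical(make_pk_image(cfg, true_phi = 1.4),
                   make_pk_image(cfg, true_phi = 1.4))
  expect_identical(make_condensate_field(cfg, n = 10),
                   make_condensate_field(cfg, n = 10))
  cfg_t <- synth_config(seed = 42, noise_sd = 0.02)
  expect_identical(make_frap_trace(cfg_t), make_frap_trace(cfg_t))
  expect_identical(make_spectrum(cfg_t, "liquid"), make_spectrum(cfg_t, "liquid"))
  expect_identical(make_deformation_series(cfg_t, E_rel = 2.5),
                   make_deformation_series(cfg_t, E_rel = 2.5))
  expect_identical(make_diffusion_profiles(cfg_t, Rh_nm = 10),
                   make_diffusion_profiles(cfg_t, Rh_nm = 10))
  expect_identical(make_dose_response(cfg_t), make_dose_response(cfg_t))
})

test_that("GUV renderer: zero coat gives pure background, coat is linear", {
  cfg <- synth_config(seed = 1)
  zero <- make_guv_image(cfg, coat_amplitude = 0)
  expect_true(all(zero$protein$intensities == cfg$background_level))
  g100 <- make_guv_image(cfg, coat_amplitude = 100)
  g200 <- make_guv_image(cfg, coat_amplitude = 200)
  # same seed, noise-free: identical geometry, so pixels scale exactly 2x
  expect_equal(g200$protein$intensities, 2 * g100$protein$intensities)
  mask <- segment_guv(g100$membrane)
  r100 <- quantify_recruitment(g100$protein, mask)
  r200 <- quantify_recruitment(g200$protein, mask)
  expect_equal(r200$intensity_per_area / r100$intensity_per_area, 2)
  expect_equal(r200$integrated_intensity / r100$integrated_intensity, 2)
})

test_that("GUV generator rejects rings larger than the field", {
  cfg <- synth_config(seed = 1, shape = c(64, 64), pixel_size_um = 0.05)
  expect_guv_error(make_guv_image(cfg, ring_radius_um = 5), "guvphase_geometry_error")
})

test_that("dye-image generator encodes the configured lipid order exactly", {
  cfg <- synth_config(seed = 7)
  out <- make_pk_image(cfg, true_phi = 1)
  expect_equal(out$blue_green$intensities, out$red$intensities)
  out <- make_pk_image(cfg, true_phi = 1.4)
  mask <- segment_guv(out$marker)
  expect_equal(compute_phi(out$blue_green, out$red, mask)$phi, 1.4)
  expect_guv_error(make_pk_image(cfg, true_phi = 0), "guvphase_parameter_error")
  expect_guv_error(make_pk_image(cfg, true_phi = -1), "guvphase_parameter_error")
})

test_that("condensate field: empty case, exact areas, packing failure", {
  cfg <- synth_config(seed = 3, shape = c(300, 300), pixel_size_um = 0.05)
  blank <- make_condensate_field(cfg, n = 0)
  expect_true(all(blank$field$intensities == cfg$background_level))
  expect_equal(nrow(blank$truth$disks), 0L)

  f <- make_condensate_field(cfg, n = 30, area_um2_mean = 0.6, area_um2_sd = 0)
  expect_equal(f$truth$true_count, 30)
  # rasterization is area-exact to the nearest pixel
  px_area <- cfg$pixel_size_um^2
  expect_true(all(abs(f$truth$true_areas_um2 - 0.6) <= px_area))
  # too many large disks cannot be packed
  tiny <- synth_config(seed = 3, shape = c(40, 40), pixel_size_um = 0.05)
  expect_guv_error(make_condensate_field(tiny, n = 50, area_um2_mean = 0.5),
                   "guvphase_packing_error")
})

test_that("FRAP generator matches its closed form", {
  cfg <- synth_config(seed = 1)
  flat <- make_frap_trace(cfg, mobile_fraction = 0)
  post <- flat$trace$intensities[flat$trace$bleach_index:length(flat$trace$times_s)]
  expect_true(all(abs(post - post[1]) < 1e-12))
  expect_guv_error(make_frap_trace(cfg, n_frames = 12, n_prebleach = 10),
                   "guvphase_parameter_error")
})

test_that("spectrum presets place the carbonyl band per phase", {
  cfg <- synth_config(seed = 1)
  liq <- make_spectrum(cfg, "liquid")
  gel <- make_spectrum(cfg, "gel")
  expect_equal(liq$truth$true_peak_cm1, 1730)
  expect_equal(gel$truth$true_peak_cm1 - liq$truth$true_peak_cm1, 8)
  expect_guv_error(
    make_spectrum(cfg, bands = data.frame(centre_cm1 = 2000, fwhm_cm1 = 20,
                                          amplitude = 1, shape = "lorentzian")),
    "guvphase_parameter_error")
  expect_guv_error(make_spectrum(cfg, step_cm1 = 4), "guvphase_parameter_error")
})

test_that("deformation generator is exactly linear without noise", {
  cfg <- synth_config(seed = 1)
  out <- make_deformation_series(cfg, E_rel = 1)
  fit <- fit_stress_strain(out$series)
  expect_equal(fit$slope, out$truth$true_slope)
  expect_equal(fit$r_squared, 1)
  expect_guv_error(make_deformation_series(cfg, E_rel = -1),
                   "guvphase_parameter_error")
  expect_guv_error(make_deformation_series(cfg, pressures_Pa = c(50, 500)),
                   "guvphase_parameter_error")
})

test_that("noise model: blank-field mean is compatible with the background", {
  cfg <- synth_config(seed = 11, noise_sd = 3, background_level = 100,
                      shape = c(128, 128))
  blank <- make_guv_image(cfg, ring_radius_um = 1, ring_width_um = 0.3,
                          coat_amplitude = 0)
  n <- length(blank$protein$intensities)
  expect_lt(abs(mean(blank$protein$intensities) - 100), 3 * 3 / sqrt(n))
})

test_that("ground truth predicts the noise-free output of each stage", {
  cfg <- synth_config(seed = 5)
  # recruitment: on-ring protein equals the coat amplitude
  g <- make_guv_image(cfg, coat_amplitude = 130)
  exact_ring <- region_mask(g$protein$intensities == 130, cfg$pixel_size_um)
  expect_equal(quantify_recruitment(g$protein, exact_ring)$intensity_per_area, 130)
  # diffusional sizing: truth radius round-trips through the fitter
  prof <- make_diffusion_profiles(cfg, Rh_nm = 12)
  expect_lt(abs(fit_rh(prof$profiles)$rh_nm - prof$truth$true_Rh_nm), 0.1)
})
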