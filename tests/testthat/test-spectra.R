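# IR preprocessing, second-derivative peak analysis, amide-I fractions,
# band ratio maps.

lorentzian_spectrum <- function(centre, fwhm = 20, instrument = "afmir") {
  wn <- seq(1400, 1794, by = 2)
  g <- fwhm / 2
  ir_spectrum(wn, g^2 / ((wn - centre)^2 + g^2), instrument = instrument)
}

test_that("preprocessing normalizes and preserves symmetric peak positions", {
  wn <- seq(1400, 1794, by = 2)
  const <- ir_spectrum(wn, rep(3, length(wn)))
  pp <- preprocess_spectrum(const)
  expect_true(all(abs(pp$absorbance - 1) < 1e-12))
  for (centre in c(1650, 1700, 1745)) {
    pp <- preprocess_spectrum(lorentzian_spectrum(centre))
    expect_equal(max(pp$absorbance), 1)
    expect_lt(abs(pp$wavenumbers_cm1[which.max(pp$absorbance)] - centre), 2 + 1e-9)
  }
  short <- ir_spectrum(seq(1400, 1408, by = 2), rep(1, 5))
  expect_guv_error(preprocess_spectrum(short), "guvphase_parameter_error")
})

test_that("SG second derivative is exact on quadratics and tracks the FD oracle", {
  wn <- seq(1400, 1794, by = 2)
  a <- 3e-4
  quad <- structure(list(wavenumbers_cm1 = wn, absorbance = a * (wn - 1600)^2,
                         instrument = "afmir"), class = "ir_spectrum")
  d2 <- second_derivative(quad)
  interior <- 10:(length(wn) - 10)
  expect_true(all(abs(d2$absorbance[interior] - 2 * a) < 1e-10))

  # smooth synthetic spectrum: agreement with central differences within 2%
  smooth <- structure(list(wavenumbers_cm1 = wn,
                           absorbance = exp(-(wn - 1650)^2 / (2 * 80^2)),
                           instrument = "afmir"), class = "ir_spectrum")
  d2s <- second_derivative(smooth)
  fd <- fd_second_derivative(smooth$absorbance, 2)
  big <- interior[abs(fd[interior]) > 0.2 * max(abs(fd), na.rm = TRUE)]
  expect_lt(max(abs(d2s$absorbance[big] - fd[big]) / abs(fd[big])), 0.02)
})

test_that("carbonyl peak localization hits analytic centres within half a step", {
  for (centre in seq(1710, 1750, by = 5)) {
    pk <- locate_co_peak(second_derivative(preprocess_spectrum(
      lorentzian_spectrum(centre))))
    expect_lt(abs(pk$position_cm1 - centre), 1)
  }
  # multiplicative rescaling does not move the peak
  sp <- lorentzian_spectrum(1745)
  sp_scaled <- ir_spectrum(sp$wavenumbers_cm1, 7 * sp$absorbance)
  p1 <- locate_co_peak(second_derivative(preprocess_spectrum(sp)))
  p2 <- locate_co_peak(second_derivative(preprocess_spectrum(sp_scaled)))
  expect_equal(p1$position_cm1, p2$position_cm1)
  # no negative lobe in the window
  wn <- seq(1400, 1794, by = 2)
  flat <- preprocess_spectrum(ir_spectrum(wn, rep(1, length(wn))))
  expect_guv_error(locate_co_peak(second_derivative(flat)), "guvphase_no_peak")
})

test_that("phase presets give the expected position, width, and 8 cm^-1 shift", {
  cfg <- synth_config(seed = 1)
  liq <- make_spectrum(cfg, "liquid")$spectrum
  gel <- make_spectrum(cfg, "gel")$spectrum
  pk <- locate_co_peak(second_derivative(preprocess_spectrum(liq)))
  expect_lt(abs(pk$position_cm1 - 1730), 2)
  expect_lt(abs(pk$width_cm1 - 20), 2)
  expect_equal(peak_shift(liq, gel), 8, tolerance = 1e-3)
  expect_equal(peak_shift(gel, liq), -peak_shift(liq, gel))
  expect_equal(peak_shift(liq, liq), 0)
})

test_that("amide fractions integrate sub-bands and sum to one exactly", {
  cfg <- synth_config(seed = 1)
  # narrow band wholly inside the alpha-helix window
  alpha_only <- make_amide_spectrum(cfg, c(inter_beta = 0, beta = 0, coil = 0,
                                           alpha = 1, turns = 0), fwhm_cm1 = 4)
  fr <- amide_fractions(alpha_only$spectrum)
  expect_gt(fr[["alpha"]], 0.99)   # Gaussian tails extend slightly past the window
  expect_equal(sum(fr), 1)

  mix <- make_amide_spectrum(cfg, c(inter_beta = 0.30, beta = 0, coil = 0,
                                    alpha = 0.70, turns = 0), fwhm_cm1 = 15)
  frm <- amide_fractions(mix$spectrum)
  expect_equal(sum(frm), 1)
  expect_lt(abs(frm[["inter_beta"]] - 0.30), 0.05)
  # cross-check the windowed integral against the analytic Gaussian oracle
  bands <- mix$truth$bands
  oracle_beta <- sum(vapply(seq_len(nrow(bands)), function(i)
    gauss_window_area(bands$centre_cm1[i], bands$fwhm_cm1[i],
                      bands$amplitude[i], 1610, 1630), numeric(1)))
  oracle_total <- sum(vapply(seq_len(nrow(bands)), function(i)
    gauss_window_area(bands$centre_cm1[i], bands$fwhm_cm1[i],
                      bands$amplitude[i], 1610, 1690), numeric(1)))
  expect_lt(abs(frm[["inter_beta"]] - oracle_beta / oracle_total), 0.02)

  wn <- seq(1400, 1794, by = 2)
  zero <- ir_spectrum(wn, rep(0, length(wn)))
  expect_guv_error(amide_fractions(zero), "guvphase_no_signal")
})

test_that("beta-sheet differences at the few-percent scale are resolved", {
  cfg <- synth_config(seed = 1)
  dispersed <- make_amide_spectrum(cfg, c(inter_beta = 0.20, beta = 0.10,
                                          coil = 0.10, alpha = 0.45, turns = 0.15))
  condensed <- make_amide_spectrum(cfg, c(inter_beta = 0.23, beta = 0.10,
                                          coil = 0.10, alpha = 0.42, turns = 0.15))
  fd <- amide_fractions(dispersed$spectrum)
  fc <- amide_fractions(condensed$spectrum)
  diff_pts <- 100 * (fc[["inter_beta"]] - fd[["inter_beta"]])
  expect_gt(diff_pts, 0)
  expect_lt(diff_pts, 5)
})

test_that("protein:lipid ratio maps flag invalid pixels instead of dividing by 0", {
  ps <- 0.05
  lipid <- matrix(10, 32, 32)
  protein <- matrix(10, 32, 32)
  rm1 <- protein_lipid_ratio_map(image_channel(protein, ps),
                                 image_channel(lipid, ps), floor = 1)
  expect_true(all(rm1$ratio[rm1$valid] == 1))

  lipid0 <- lipid; lipid0[5, 5] <- 0
  rm2 <- protein_lipid_ratio_map(image_channel(protein, ps),
                                 image_channel(lipid0, ps), floor = 1)
  expect_false(rm2$valid[5, 5])
  expect_true(is.na(rm2$ratio[5, 5]))

  # protein-coated half at 2x ratio is recovered by thresholding the map
  coated <- matrix(FALSE, 32, 32); coated[, 17:32] <- TRUE
  protein2 <- ifelse(coated, 20, 10)
  rm3 <- protein_lipid_ratio_map(image_channel(protein2, ps),
                                 image_channel(lipid, ps), floor = 1)
  expect_identical(rm3$ratio > 1.5, coated)
})
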