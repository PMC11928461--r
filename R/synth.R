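#' Configuration shared by all synthetic-data generators
#'
#' Every generator takes a `synth_config` and is fully deterministic given the
#' seed: the same `(seed, parameters)` pair yields bit-identical output. The
#' noise model is additive Gaussian with standard deviation `noise_sd`,
#' clipped at zero.
#'
#' @param seed integer RNG seed.
#' @param pixel_size_um physical pixel size for image generators (micrometres);
#'   the default 0.05 um/px corresponds to Nyquist-sampled high-NA confocal
#'   imaging.
#' @param shape image shape `c(rows, cols)` in pixels.
#' @param noise_sd noise standard deviation; intensity units for image and
#'   trace generators, absorbance units for spectra, strain units for
#'   deformation series.
#' @param background_level constant background added to image generators.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, pixel_size_um = 0.05, shape = c(384L, 384L),
                         noise_sd = 0, background_level = 0) {
  assert_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_number(background_level, "background_level", nonneg = TRUE)
  if (length(shape) != 2L || any(shape < 8))
    stop_guv("guvphase_parameter_error", "`shape` must be c(rows, cols), each >= 8")
  structure(list(seed = as.integer(seed), pixel_size_um = pixel_size_um,
                 shape = as.integer(shape), noise_sd = noise_sd,
                 background_level = background_level),
            class = "synth_config")
}

ground_truth <- function(...) structure(list(...), class = "ground_truth")

# Pixel-centre coordinate grids in micrometres (row = y, col = x).
pixel_grids <- function(shape, pixel_size_um) {
  list(row_um = ((seq_len(shape[1]) - 0.5) * pixel_size_um),
       col_um = ((seq_len(shape[2]) - 0.5) * pixel_size_um))
}

# Annular ring profile in [0, 1]: hard annulus of the given mean radius and
# radial width, with a half-pixel Gaussian roll-off at the edges so masks are
# not aliased. Profiles of several rings are combined with pmax.
ring_profile <- function(shape, pixel_size_um, centres_um, radius_um, width_um) {
  g <- pixel_grids(shape, pixel_size_um)
  edge_sd <- 0.5 * pixel_size_um
  prof <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centres_um))) {
    d <- sqrt(outer((g$row_um - centres_um[i, 1])^2,
                    (g$col_um - centres_um[i, 2])^2, `+`))
    excess <- abs(d - radius_um) - width_um / 2
    p <- ifelse(excess <= 0, 1, exp(-excess^2 / (2 * edge_sd^2)))
    prof <- pmax(prof, p)
  }
  prof
}

place_ring_centres <- function(cfg, n, radius_um, width_um, max_tries = 200L) {
  field_um <- cfg$shape * cfg$pixel_size_um
  margin <- radius_um + width_um / 2 + 2 * cfg$pixel_size_um
  if (any(field_um < 2 * margin))
    stop_guv("guvphase_geometry_error",
             "ring does not fit inside the field at this pixel size")
  centres <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (try in seq_len(max_tries * n)) {
    cand <- c(stats::runif(1, margin, field_um[1] - margin),
              stats::runif(1, margin, field_um[2] - margin))
    ok <- placed == 0L ||
      all(sqrt(rowSums((centres[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2)) >
            2 * radius_um + width_um)
    if (ok) {
      placed <- placed + 1L
      centres[placed, ] <- cand
      if (placed == n) return(centres)
    }
  }
  stop_guv("guvphase_geometry_error",
           sprintf("could not place %d non-overlapping GUVs", n))
}

#' Synthetic GUV membrane + protein-coat image pair
#'
#' Renders `n_guvs` annular membrane rings (equatorial GUV cross-sections) and
#' a protein channel whose on-ring intensity is `coat_amplitude`, emulating a
#' fluorescently labelled protein coat recruited to the vesicle surface.
#'
#' @param cfg a [synth_config].
#' @param ring_radius_um GUV ring radius (micrometres).
#' @param ring_width_um radial width of the membrane ring (micrometres).
#' @param coat_amplitude on-ring protein-channel intensity.
#' @param n_guvs number of vesicles to place (non-overlapping).
#' @param membrane_amplitude on-ring membrane-channel intensity.
#' @return list with `membrane` and `protein` [image_channel]s and `truth`
#'   (centres, radius, width, coat amplitude, analytic ring area
#'   `2*pi*r*w` per vesicle).
#' @export
make_guv_image <- function(cfg, ring_radius_um = 5, ring_width_um = 0.6,
                           coat_amplitude = 100, n_guvs = 1L,
                           membrane_amplitude = 200) {
  stopifnot(inherits(cfg, "synth_config"))
  assert_scalar_number(ring_radius_um, "ring_radius_um", positive = TRUE)
  assert_scalar_number(ring_width_um, "ring_width_um", positive = TRUE)
  assert_scalar_number(coat_amplitude, "coat_amplitude", nonneg = TRUE)
  if (n_guvs < 1L) stop_guv("guvphase_parameter_error", "`n_guvs` must be >= 1")
  withr::with_seed(cfg$seed, {
    centres <- place_ring_centres(cfg, n_guvs, ring_radius_um, ring_width_um)
    prof <- ring_profile(cfg$shape, cfg$pixel_size_um, centres,
                         ring_radius_um, ring_width_um)
    membrane <- add_clipped_noise(cfg$background_level + membrane_amplitude * prof,
                                  cfg$noise_sd)
    protein <- add_clipped_noise(cfg$background_level + coat_amplitude * prof,
                                 cfg$noise_sd)
  })
  truth <- ground_truth(
    centres_um = centres, ring_radius_um = ring_radius_um,
    ring_width_um = ring_width_um, coat_amplitude = coat_amplitude,
    membrane_amplitude = membrane_amplitude,
    ring_area_um2 = 2 * pi * ring_radius_um * ring_width_um)
  list(membrane = image_channel(membrane, cfg$pixel_size_um, "membrane"),
       protein = image_channel(protein, cfg$pixel_size_um, "protein"),
       truth = truth)
}

#' Synthetic two-emission-window solvatochromic dye image
#'
#' Emulates ratiometric lipid-order imaging with a push-pull membrane dye: the
#' per-pixel expected ratio of the blue/green to the red emission window on
#' the membrane equals `true_phi`. A marker channel (the membrane itself)
#' is returned for mask generation. The exact per-pixel ratio contract holds
#' for `background_level = 0` (the default); a positive background is added
#' uniformly to both windows.
#'
#' @param cfg a [synth_config].
#' @param true_phi ground-truth relative lipid order (> 0).
#' @param ring_radius_um,ring_width_um,n_guvs membrane geometry, as in
#'   [make_guv_image()].
#' @param amplitude on-membrane red-window intensity.
#' @return list with `blue_green`, `red`, `marker` [image_channel]s and
#'   `truth` (`true_phi`, geometry).
#' @export
make_pk_image <- function(cfg, true_phi, ring_radius_um = 5, ring_width_um = 0.6,
                          n_guvs = 1L, amplitude = 200) {
  stopifnot(inherits(cfg, "synth_config"))
  assert_scalar_number(true_phi, "true_phi", positive = TRUE)
  assert_scalar_number(amplitude, "amplitude", positive = TRUE)
  withr::with_seed(cfg$seed, {
    centres <- place_ring_centres(cfg, n_guvs, ring_radius_um, ring_width_um)
    prof <- ring_profile(cfg$shape, cfg$pixel_size_um, centres,
                         ring_radius_um, ring_width_um)
    red <- add_clipped_noise(cfg$background_level + amplitude * prof, cfg$noise_sd)
    blue_green <- add_clipped_noise(cfg$background_level + true_phi * amplitude * prof,
                                    cfg$noise_sd)
    marker <- add_clipped_noise(cfg$background_level + amplitude * prof, cfg$noise_sd)
  })
  truth <- ground_truth(true_phi = true_phi, centres_um = centres,
                        ring_radius_um = ring_radius_um,
                        ring_width_um = ring_width_um, amplitude = amplitude)
  list(blue_green = image_channel(blue_green, cfg$pixel_size_um, "blue_green"),
       red = image_channel(red, cfg$pixel_size_um, "red"),
       marker = image_channel(marker, cfg$pixel_size_um, "marker"),
       truth = truth)
}

# Rasterize a disk at an off-lattice centre so that its pixel count equals the
# requested area exactly: pixel-centre distances to a generic centre are
# almost surely distinct, so thresholding the sorted distances at the k-th
# value selects exactly k pixels.
rasterize_disk <- function(shape, pixel_size_um, centre_um, area_um2) {
  target_px <- max(1L, as.integer(round(area_um2 / pixel_size_um^2)))
  r0 <- sqrt(area_um2 / pi)
  half <- ceiling((r0 + 3 * pixel_size_um) / pixel_size_um) + 2L
  ctr_px <- centre_um / pixel_size_um + 0.5
  rows <- max(1L, floor(ctr_px[1]) - half):min(shape[1], ceiling(ctr_px[1]) + half)
  cols <- max(1L, floor(ctr_px[2]) - half):min(shape[2], ceiling(ctr_px[2]) + half)
  g_row <- (rows - 0.5) * pixel_size_um
  g_col <- (cols - 0.5) * pixel_size_um
  d <- sqrt(outer((g_row - centre_um[1])^2, (g_col - centre_um[2])^2, `+`))
  ord <- order(d)
  if (target_px > length(ord))
    stop_guv("guvphase_geometry_error", "disk does not fit in the field")
  sel <- ord[seq_len(target_px)]
  idx <- cbind(rows[(sel - 1L) %% length(rows) + 1L],
               cols[(sel - 1L) %/% length(rows) + 1L])
  list(pixels = idx, area_um2 = target_px * pixel_size_um^2)
}

#' Synthetic field of disk-shaped condensates
#'
#' Places `n` non-overlapping bright disks with areas drawn from a truncated
#' normal distribution. Disk rasterization is area-exact: the pixel count of
#' each disk equals its recorded ground-truth area to the nearest pixel.
#'
#' @param cfg a [synth_config].
#' @param n number of condensates (>= 0).
#' @param area_um2_mean,area_um2_sd mean and sd of condensate area (um^2).
#' @param amplitude disk intensity above background.
#' @return list with `field` ([image_channel]) and `truth` containing a
#'   data frame of centres (um), achieved pixelated areas (um^2) and the field
#'   area in um^2.
#' @export
make_condensate_field <- function(cfg, n, area_um2_mean = 0.6, area_um2_sd = 0.1,
                                  amplitude = 100) {
  stopifnot(inherits(cfg, "synth_config"))
  if (n < 0L) stop_guv("guvphase_parameter_error", "`n` must be >= 0")
  assert_scalar_number(area_um2_mean, "area_um2_mean", positive = TRUE)
  assert_scalar_number(area_um2_sd, "area_um2_sd", nonneg = TRUE)
  ps <- cfg$pixel_size_um
  field_um <- cfg$shape * ps
  field <- matrix(cfg$background_level, cfg$shape[1], cfg$shape[2])
  disks <- data.frame(centre_row_um = numeric(0), centre_col_um = numeric(0),
                      area_um2 = numeric(0))
  withr::with_seed(cfg$seed, {
    if (n > 0L) {
      placed <- 0L
      centres <- matrix(0, n, 2)
      radii <- numeric(n)
      tries <- 0L
      while (placed < n) {
        tries <- tries + 1L
        if (tries > 500L * n)
          stop_guv("guvphase_packing_error",
                   sprintf("could not place %d non-overlapping disks", n))
        a <- stats::rnorm(1, area_um2_mean, area_um2_sd)
        if (a <= ps^2) next
        r <- sqrt(a / pi)
        margin <- r + 3 * ps
        if (any(field_um < 2 * margin))
          stop_guv("guvphase_geometry_error", "disks do not fit in the field")
        cand <- c(stats::runif(1, margin, field_um[1] - margin),
                  stats::runif(1, margin, field_um[2] - margin))
        if (placed > 0L) {
          dist <- sqrt(rowSums((centres[seq_len(placed), , drop = FALSE] -
                                  matrix(cand, placed, 2, byrow = TRUE))^2))
          if (any(dist < r + radii[seq_len(placed)] + 3 * ps)) next
        }
        placed <- placed + 1L
        centres[placed, ] <- cand
        radii[placed] <- r
        disk <- rasterize_disk(cfg$shape, ps, cand, a)
        field[disk$pixels] <- field[disk$pixels] + amplitude
        disks[placed, ] <- c(cand[1], cand[2], disk$area_um2)
      }
    }
    field <- add_clipped_noise(field, cfg$noise_sd)
  })
  truth <- ground_truth(true_count = n, disks = disks,
                        true_areas_um2 = disks$area_um2,
                        field_area_um2 = prod(field_um), amplitude = amplitude)
  list(field = image_channel(field, ps, "condensates"), truth = truth)
}

#' Synthetic FRAP recovery trace
#'
#' Pre-bleach plateau at 1, then
#' `F(t) = (1 - bleach_depth) + bleach_depth * M * (1 - exp(-t/tau))`
#' with `t` measured from the bleach frame, sampled at `dt_s` (default 1/11 s,
#' i.e. 11 Hz acquisition).
#'
#' @param cfg a [synth_config]; `noise_sd` is in normalized-intensity units.
#' @param mobile_fraction mobile fraction M in `[0, 1]`.
#' @param tau_s recovery time constant (s, > 0).
#' @param bleach_depth fraction of intensity removed by the bleach.
#' @param dt_s frame interval (s).
#' @param n_frames total number of frames.
#' @param n_prebleach number of pre-bleach frames (>= 3).
#' @return list with `trace` ([frap_trace]) and `truth`.
#' @export
make_frap_trace <- function(cfg, mobile_fraction = 0.8, tau_s = 3,
                            bleach_depth = 0.9, dt_s = 1 / 11,
                            n_frames = 200L, n_prebleach = 10L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop_guv("guvphase_parameter_error", "`mobile_fraction` must be in [0, 1]")
  assert_scalar_number(tau_s, "tau_s", positive = TRUE)
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop_guv("guvphase_parameter_error", "`bleach_depth` must be in (0, 1]")
  if (n_frames < n_prebleach + 5L)
    stop_guv("guvphase_parameter_error",
             "`n_frames` too small to contain the bleach and a recovery tail")
  times <- (seq_len(n_frames) - 1L) * dt_s
  bleach_index <- n_prebleach + 1L
  t_post <- times[bleach_index:n_frames] - times[bleach_index]
  f <- c(rep(1, n_prebleach),
         (1 - bleach_depth) + bleach_depth * mobile_fraction * (1 - exp(-t_post / tau_s)))
  withr::with_seed(cfg$seed, f <- add_clipped_noise(f, cfg$noise_sd))
  truth <- ground_truth(true_mobile_fraction = mobile_fraction, true_tau_s = tau_s,
                        bleach_depth = bleach_depth)
  list(trace = frap_trace(times, f, bleach_index), truth = truth)
}

lipid_band_presets <- function(phase) {
  # Liquid-phase lipid carbonyl at 1730 cm-1; protein binding shifts it up by
  # 8 cm-1 into the gel-like state. CH2 scissoring near 1465 cm-1.
  co_centre <- switch(phase, liquid = 1730, gel = 1738,
                      stop_guv("guvphase_parameter_error",
                               "`phase` must be 'liquid' or 'gel'"))
  data.frame(centre_cm1 = c(co_centre, 1465),
             fwhm_cm1 = c(20, 15),
             amplitude = c(1, 0.4),
             shape = c("lorentzian", "lorentzian"))
}

amide_band_presets <- function() {
  data.frame(centre_cm1 = c(1620, 1655),
             fwhm_cm1 = c(18, 25),
             amplitude = c(0.25, 0.8),
             shape = c("gaussian", "gaussian"))
}

render_bands <- function(wn, bands) {
  absorb <- rep(0, length(wn))
  for (i in seq_len(nrow(bands))) {
    c0 <- bands$centre_cm1[i]; fwhm <- bands$fwhm_cm1[i]; a <- bands$amplitude[i]
    if (bands$shape[i] == "lorentzian") {
      g <- fwhm / 2
      absorb <- absorb + a * g^2 / ((wn - c0)^2 + g^2)
    } else {
      s <- fwhm / (2 * sqrt(2 * log(2)))
      absorb <- absorb + a * exp(-(wn - c0)^2 / (2 * s^2))
    }
  }
  absorb
}

#' Synthetic lipid / protein IR spectrum
#'
#' Sum of Lorentzian/Gaussian bands on a uniform wavenumber grid. The default
#' presets place the lipid C=O band at 1730 cm^-1 (liquid phase) or
#' 1738 cm^-1 (gel phase, the liquid position plus the 8 cm^-1 phase-transition
#' shift), both with 20 cm^-1 FWHM, plus a CH2 band near 1465 cm^-1.
#'
#' @param cfg a [synth_config]; `noise_sd` in absorbance units.
#' @param phase `"liquid"` or `"gel"`; selects the default lipid band set.
#' @param bands optional data frame (`centre_cm1`, `fwhm_cm1`, `amplitude`,
#'   `shape` in `{"lorentzian", "gaussian"}`) overriding the presets.
#' @param include_protein add default amide-I bands.
#' @param range_cm1 grid range; must cover at least 1400-1794 cm^-1.
#' @param step_cm1 grid step; must be <= 2 cm^-1.
#' @param instrument instrument tag, `"afmir"` or `"ftir"`.
#' @return list with `spectrum` ([ir_spectrum]) and `truth` (`true_peak_cm1`
#'   = C=O band centre, band table).
#' @export
make_spectrum <- function(cfg, phase = c("liquid", "gel"), bands = NULL,
                          include_protein = FALSE, range_cm1 = c(1400, 1794),
                          step_cm1 = 2, instrument = "afmir") {
  stopifnot(inherits(cfg, "synth_config"))
  phase <- match.arg(phase)
  if (step_cm1 > 2 || step_cm1 <= 0)
    stop_guv("guvphase_parameter_error", "`step_cm1` must be in (0, 2]")
  if (range_cm1[1] > 1400 || range_cm1[2] < 1794)
    stop_guv("guvphase_parameter_error", "grid must cover at least 1400-1794 cm^-1")
  wn <- seq(range_cm1[1], range_cm1[2], by = step_cm1)
  if (is.null(bands)) {
    bands <- lipid_band_presets(phase)
    if (include_protein) bands <- rbind(bands, amide_band_presets())
  }
  if (any(bands$centre_cm1 < wn[1]) || any(bands$centre_cm1 > wn[length(wn)]))
    stop_guv("guvphase_parameter_error", "band centres outside the wavenumber grid")
  absorb <- render_bands(wn, bands)
  withr::with_seed(cfg$seed, absorb <- add_clipped_noise(absorb, cfg$noise_sd))
  co <- bands$centre_cm1[which.min(abs(bands$centre_cm1 - 1734))]
  truth <- ground_truth(true_peak_cm1 = co, bands = bands, phase = phase)
  list(spectrum = ir_spectrum(wn, absorb, instrument = instrument), truth = truth)
}

#' Synthetic amide-I spectrum with prescribed secondary-structure fractions
#'
#' Builds one Gaussian band centred inside each amide-I sub-band window with
#' analytic band areas proportional to the requested fractions, emulating
#' dispersed/condensed protein presets that differ in intermolecular
#' beta-sheet content.
#'
#' @param cfg a [synth_config].
#' @param fractions named numeric vector over
#'   `c("inter_beta", "beta", "coil", "alpha", "turns")`, summing to 1.
#' @param fwhm_cm1 FWHM of every sub-band Gaussian (cm^-1).
#' @inheritParams make_spectrum
#' @return list with `spectrum` and `truth` (`true_fractions`).
#' @export
make_amide_spectrum <- function(cfg, fractions = c(inter_beta = 0.2, beta = 0.1,
                                                   coil = 0.1, alpha = 0.45,
                                                   turns = 0.15),
                                fwhm_cm1 = 15, range_cm1 = c(1400, 1794),
                                step_cm1 = 2, instrument = "ftir") {
  stopifnot(inherits(cfg, "synth_config"))
  need <- c("inter_beta", "beta", "coil", "alpha", "turns")
  if (!all(need %in% names(fractions)))
    stop_guv("guvphase_parameter_error",
             sprintf("`fractions` must be named over %s", paste(need, collapse = ", ")))
  fractions <- fractions[need]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop_guv("guvphase_parameter_error", "`fractions` must be non-negative and sum to 1")
  centres <- c(inter_beta = 1620, beta = 1637, coil = 1648.5,
               alpha = 1657, turns = 1672)
  # Equal widths: Gaussian area = amp * fwhm * sqrt(pi / (4 log 2)),
  # so amplitudes proportional to fractions give areas proportional to them.
  bands <- data.frame(centre_cm1 = unname(centres),
                      fwhm_cm1 = fwhm_cm1,
                      amplitude = unname(fractions),
                      shape = "gaussian")
  bands <- bands[bands$amplitude > 0, , drop = FALSE]
  out <- make_spectrum(cfg, phase = "liquid", bands = bands,
                       range_cm1 = range_cm1, step_cm1 = step_cm1,
                       instrument = instrument)
  out$truth <- ground_truth(true_fractions = fractions, bands = bands)
  out
}

#' Reference stiffness constant and condition presets
#'
#' `guv_k_ref_pa` converts pressure to strain for a reference (naked) GUV:
#' `strain = pressure / (guv_k_ref_pa * E_rel)`. `stiffness_presets` holds the
#' relative-modulus presets for the assay conditions; the naked GUV is the
#' unit reference, the protein-coated presets are invented magnitudes chosen
#' to respect the measured fold-change bounds (coated > 2-fold, coated+ALG2
#' > 3-fold, coated+CALC back near naked), not measured values.
#'
#' @export
guv_k_ref_pa <- 4000

#' @rdname guv_k_ref_pa
#' @export
stiffness_presets <- c(naked = 1.0, fl = 2.5, fl_alg2 = 3.5, fl_calc = 1.3)

#' Synthetic GUV deformation (strain vs pressure) series
#'
#' Linear-elastic law `strain = pressure / (guv_k_ref_pa * E_rel)` plus
#' clipped Gaussian noise (`cfg$noise_sd`, strain units).
#'
#' @param cfg a [synth_config].
#' @param E_rel relative elastic modulus (> 0); see [stiffness_presets].
#' @param pressures_Pa applied pressure drops, within 100-1000 Pa.
#' @param direction `"forth"` or `"back"` (push direction through the taper).
#' @param condition free-text condition label.
#' @return list with `series` ([deformation_series]) and `truth`
#'   (`true_E_rel`, `k_ref_pa`, expected slope).
#' @export
make_deformation_series <- function(cfg, E_rel = 1,
                                    pressures_Pa = seq(100, 1000, by = 100),
                                    direction = c("forth", "back"),
                                    condition = "") {
  stopifnot(inherits(cfg, "synth_config"))
  assert_scalar_number(E_rel, "E_rel", positive = TRUE)
  direction <- match.arg(direction)
  if (any(pressures_Pa < 100 - 1e-9) || any(pressures_Pa > 1000 + 1e-9))
    stop_guv("guvphase_parameter_error", "pressures must lie within 100-1000 Pa")
  strain <- pressures_Pa / (guv_k_ref_pa * E_rel)
  withr::with_seed(cfg$seed, strain <- add_clipped_noise(strain, cfg$noise_sd))
  truth <- ground_truth(true_E_rel = E_rel, k_ref_pa = guv_k_ref_pa,
                        true_slope = 1 / (guv_k_ref_pa * E_rel))
  list(series = deformation_series(pressures_Pa, strain, direction, condition),
       truth = truth)
}

#' Synthetic microfluidic diffusional-sizing profiles
#'
#' Runs the forward advection-diffusion model ([simulate_profiles()]) at a
#' known hydrodynamic radius and adds clipped Gaussian noise.
#'
#' @param cfg a [synth_config]; `noise_sd` in normalized-intensity units.
#' @param Rh_nm ground-truth hydrodynamic radius, within 0.1-50 nm.
#' @param geometry a [channel_geometry].
#' @param conditions a [sizing_conditions].
#' @return list with `profiles` ([diffusion_profile_set]) and `truth`
#'   (`true_Rh_nm`).
#' @export
make_diffusion_profiles <- function(cfg, Rh_nm = 18.65,
                                    geometry = channel_geometry(),
                                    conditions = sizing_conditions()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (Rh_nm < 0.1 || Rh_nm > 50)
    stop_guv("guvphase_parameter_error", "`Rh_nm` must lie within 0.1-50 nm")
  ps <- simulate_profiles(Rh_nm, geometry, conditions)
  withr::with_seed(cfg$seed,
                   ps$profiles <- add_clipped_noise(ps$profiles, cfg$noise_sd))
  list(profiles = ps, truth = ground_truth(true_Rh_nm = Rh_nm))
}

#' Synthetic log-dose binding-response data
#'
#' Four-parameter logistic in log10 concentration plus clipped Gaussian noise,
#' emulating equilibrium binding of labelled protein to GUV membranes. Two
#' presets mirror the assay's qualitative contrast: `"ard"` (lipid-site
#' binding that saturates within the tested range) and `"fl"` (collective
#' binding still rising at the highest dose).
#'
#' @param cfg a [synth_config]; `noise_sd` in response units.
#' @param ec50_uM,hill,top,bottom logistic parameters.
#' @param concentrations_uM tested doses (all > 0).
#' @param preset optional `"ard"` or `"fl"`, overriding the parameters.
#' @return list with `concentrations_uM`, `responses`, and `truth`.
#' @export
make_dose_response <- function(cfg, ec50_uM = 2, hill = 1.5, top = 1, bottom = 0,
                               concentrations_uM = 10^seq(-1, 1.48, length.out = 9),
                               preset = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(preset)) {
    pars <- switch(preset,
      ard = list(ec50_uM = 1.5, hill = 2, top = 1, bottom = 0),
      fl = list(ec50_uM = 40, hill = 1, top = 2, bottom = 0),
      stop_guv("guvphase_parameter_error", "`preset` must be 'ard' or 'fl'"))
    ec50_uM <- pars$ec50_uM; hill <- pars$hill; top <- pars$top; bottom <- pars$bottom
  }
  if (any(concentrations_uM <= 0))
    stop_guv("guvphase_parameter_error", "concentrations must be > 0")
  assert_scalar_number(ec50_uM, "ec50_uM", positive = TRUE)
  resp <- bottom + (top - bottom) /
    (1 + 10^(hill * (log10(ec50_uM) - log10(concentrations_uM))))
  withr::with_seed(cfg$seed, resp <- add_clipped_noise(resp, cfg$noise_sd))
  truth <- ground_truth(true_ec50_uM = ec50_uM, true_hill = hill,
                        true_top = top, true_bottom = bottom)
  list(concentrations_uM = concentrations_uM, responses = resp, truth = truth)
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth a `ground_truth` record.
#' @param stem output path stem; writes `<stem>.truth.json`.
#' @return the sidecar path, invisibly.
#' @export
write_truth_json <- function(truth, stem) {
  path <- paste0(stem, ".truth.json")
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
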