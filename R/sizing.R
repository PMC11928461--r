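boltzmann_J_K <- 1.380649e-23

#' Microfluidic channel geometry for diffusional sizing
#'
#' @param width_um channel width, the lateral diffusion axis (um).
#' @param height_um channel height (um); must lie within 25-50 um.
#' @param observation_path_lengths_um 4 strictly increasing downstream
#'   positions at which profiles are imaged (um).
#' @param sample_stream_fraction initial fraction of the width occupied by
#'   the sample stream (0 < f < 1).
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(width_um = 300, height_um = 25,
                             observation_path_lengths_um = c(1000, 5600, 21000, 58500),
                             sample_stream_fraction = 0.25) {
  assert_scalar_number(width_um, "width_um", positive = TRUE)
  if (height_um < 25 || height_um > 50)
    stop_guv("guvphase_parameter_error", "`height_um` must lie within 25-50 um")
  if (length(observation_path_lengths_um) != 4L ||
      is.unsorted(observation_path_lengths_um, strictly = TRUE))
    stop_guv("guvphase_parameter_error",
             "need 4 strictly increasing observation path lengths")
  if (sample_stream_fraction <= 0 || sample_stream_fraction >= 1)
    stop_guv("guvphase_parameter_error", "`sample_stream_fraction` must be in (0, 1)")
  structure(list(width_um = width_um, height_um = height_um,
                 observation_path_lengths_um = observation_path_lengths_um,
                 sample_stream_fraction = sample_stream_fraction),
            class = "channel_geometry")
}

#' Solution conditions for diffusional sizing
#'
#' @param temperature_K absolute temperature (K).
#' @param viscosity_Pa_s dynamic viscosity (Pa s).
#' @param flow_uL_h volumetric flow rate (uL/h); must lie within 20-150.
#' @return an object of class `sizing_conditions`.
#' @export
sizing_conditions <- function(temperature_K = 298.15, viscosity_Pa_s = 8.9e-4,
                              flow_uL_h = 60) {
  assert_scalar_number(temperature_K, "temperature_K", positive = TRUE)
  assert_scalar_number(viscosity_Pa_s, "viscosity_Pa_s", positive = TRUE)
  if (flow_uL_h < 20 || flow_uL_h > 150)
    stop_guv("guvphase_parameter_error", "`flow_uL_h` must lie within 20-150 uL/h")
  structure(list(temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s,
                 flow_uL_h = flow_uL_h),
            class = "sizing_conditions")
}

#' Stokes-Einstein relation and its inverse
#'
#' `D = k_B T / (6 pi eta R_H)`.
#'
#' @param rh_nm hydrodynamic radius (nm, > 0).
#' @param conditions a [sizing_conditions].
#' @return `stokes_einstein()` returns the diffusion coefficient in m^2/s;
#'   `rh_from_diffusion()` inverts it, returning nm.
#' @export
stokes_einstein <- function(rh_nm, conditions = sizing_conditions()) {
  if (any(rh_nm <= 0))
    stop_guv("guvphase_parameter_error", "`rh_nm` must be > 0")
  boltzmann_J_K * conditions$temperature_K /
    (6 * pi * conditions$viscosity_Pa_s * rh_nm * 1e-9)
}

#' @rdname stokes_einstein
#' @param d_m2_s diffusion coefficient (m^2/s, > 0).
#' @export
rh_from_diffusion <- function(d_m2_s, conditions = sizing_conditions()) {
  if (any(d_m2_s <= 0))
    stop_guv("guvphase_parameter_error", "`d_m2_s` must be > 0")
  boltzmann_J_K * conditions$temperature_K /
    (6 * pi * conditions$viscosity_Pa_s * d_m2_s) * 1e9
}

# Residence times (s) at the observation positions under plug flow.
residence_times_s <- function(geometry, conditions) {
  cross_m2 <- geometry$width_um * 1e-6 * geometry$height_um * 1e-6
  q_m3_s <- conditions$flow_uL_h * 1e-9 / 3600
  geometry$observation_path_lengths_um * 1e-6 * cross_m2 / q_m3_s
}

#' Simulate lateral diffusion profiles along the sizing channel
#'
#' Forward model: 1-D diffusion across the channel width with no-flux walls,
#' starting from a top-hat sample stream occupying `sample_stream_fraction`
#' of the width against one wall. Under plug flow the residence time at
#' observation position i is `path_length_i * cross_section / flow`. The
#' solution is a truncated cosine eigenfunction expansion; at zero residence
#' time the exact initial top-hat is returned.
#'
#' @param rh_nm hydrodynamic radius (nm), within 0.1-50.
#' @param geometry a [channel_geometry].
#' @param conditions a [sizing_conditions].
#' @param n_x lateral grid points across the width.
#' @param n_terms series truncation length.
#' @param x_um optional explicit lateral evaluation grid (um), overriding
#'   `n_x` (e.g. to compare against an external solver on its own grid).
#' @param times_s optional explicit residence times (s), overriding the
#'   plug-flow times derived from geometry and flow; a time of 0 returns the
#'   exact initial top-hat at that position.
#' @return an object of class `diffusion_profile_set`: fields `x_um` (lateral
#'   grid), `profiles` (`n_x` x 4 matrix), `geometry`, `conditions`,
#'   `times_s`.
#' @export
simulate_profiles <- function(rh_nm, geometry = channel_geometry(),
                              conditions = sizing_conditions(),
                              n_x = 201L, n_terms = 800L,
                              x_um = NULL, times_s = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(conditions, "sizing_conditions"))
  if (rh_nm < 0.1 || rh_nm > 50)
    stop_guv("guvphase_parameter_error", "`rh_nm` must lie within 0.1-50 nm")
  d <- stokes_einstein(rh_nm, conditions)
  w_m <- geometry$width_um * 1e-6
  s <- geometry$sample_stream_fraction
  x <- if (is.null(x_um)) seq(0, w_m, length.out = n_x) else x_um * 1e-6
  n_x <- length(x)
  times <- if (is.null(times_s)) residence_times_s(geometry, conditions)
           else times_s
  n <- seq_len(n_terms)
  coef <- 2 / (n * pi) * sin(n * pi * s)
  cos_mat <- cos(outer(n * pi / w_m, x))        # n_terms x n_x
  profiles <- vapply(times, function(t) {
    if (t <= 0) return(as.numeric(x < s * w_m) + 0.5 * (x == s * w_m))
    decay <- exp(-d * (n * pi / w_m)^2 * t)
    s + as.numeric((coef * decay) %*% cos_mat)
  }, numeric(n_x))
  structure(list(x_um = x * 1e6, profiles = profiles, geometry = geometry,
                 conditions = conditions, times_s = times, rh_nm = rh_nm),
            class = "diffusion_profile_set")
}

#' @export
print.diffusion_profile_set <- function(x, ...) {
  cat(sprintf("<diffusion_profile_set> %d x-points, 4 positions, t = %s s\n",
              length(x$x_um), paste(signif(x$times_s, 3), collapse = ", ")))
  invisible(x)
}

profile_residual <- function(observed, simulated) {
  # per-profile free linear amplitude (background/gain nuisance)
  total <- 0
  for (i in seq_len(ncol(observed))) {
    o <- observed[, i]; m <- simulated[, i]
    a <- sum(o * m) / sum(m * m)
    total <- total + sum((o - a * m)^2)
  }
  total
}

#' Fit the hydrodynamic radius to observed diffusion profiles
#'
#' Minimises the summed squared mismatch between the observed profiles at the
#' four observation positions and the forward model, over a log-spaced R_H
#' grid in [0.1, 50] nm, then refines between the best grid neighbours by
#' golden-section search (tolerance 0.01 nm). Each profile carries a free
#' linear amplitude (nuisance scale), solved in closed form.
#'
#' @param observed a [diffusion_profile_set] (e.g. measured or from
#'   [make_diffusion_profiles()]).
#' @param grid_n number of radii in the search grid.
#' @param rh_range search range in nm.
#' @return an object of class `sizing_result`: `rh_nm`,
#'   `diffusion_coefficient_m2_s`, `residual`, `rh_grid`, `grid_residuals`;
#'   errors with class `guvphase_unidentifiable` for flat profiles.
#' @export
fit_rh <- function(observed, grid_n = 200L, rh_range = c(0.1, 50)) {
  stopifnot(inherits(observed, "diffusion_profile_set"))
  obs <- observed$profiles
  if (all(apply(obs, 2, stats::sd) < 1e-12))
    stop_guv("guvphase_unidentifiable", "flat observed profiles")
  geometry <- observed$geometry
  conditions <- observed$conditions
  n_x <- length(observed$x_um)
  # precompute the geometry-dependent parts of the forward model
  w_m <- geometry$width_um * 1e-6
  s <- geometry$sample_stream_fraction
  x <- observed$x_um * 1e-6
  times <- residence_times_s(geometry, conditions)
  n <- seq_len(800L)
  coef <- 2 / (n * pi) * sin(n * pi * s)
  cos_mat <- cos(outer(n * pi / w_m, x))
  k2 <- (n * pi / w_m)^2
  model_at <- function(rh) {
    d <- stokes_einstein(rh, conditions)
    vapply(times, function(t) s + as.numeric((coef * exp(-d * k2 * t)) %*% cos_mat),
           numeric(n_x))
  }
  objective <- function(rh) profile_residual(obs, model_at(rh))
  grid <- exp(seq(log(rh_range[1]), log(rh_range[2]), length.out = grid_n))
  resid <- vapply(grid, objective, numeric(1))
  j <- which.min(resid)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(grid_n, j + 1L)]
  opt <- stats::optimize(objective, interval = c(lo, hi), tol = 0.01)
  structure(list(rh_nm = opt$minimum,
                 diffusion_coefficient_m2_s = stokes_einstein(opt$minimum, conditions),
                 residual = opt$objective, rh_grid = grid,
                 grid_residuals = resid),
            class = "sizing_result")
}

#' @export
print.sizing_result <- function(x, ...) {
  cat(sprintf("<sizing_result> R_H = %.3f nm, D = %.3g m^2/s, residual = %.3g\n",
              x$rh_nm, x$diffusion_coefficient_m2_s, x$residual))
  invisible(x)
}
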