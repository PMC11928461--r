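#' GUV deformation series container
#'
#' Strain (fractional elongation of a vesicle pushed into a tapered channel)
#' against the pressure drop applied across the channel.
#'
#' @param pressures_Pa applied pressure drops (Pa).
#' @param strains dimensionless elongations (>= 0), same length.
#' @param direction `"forth"` or `"back"` (push direction through the taper).
#' @param condition free-text condition label.
#' @return an object of class `deformation_series`.
#' @export
deformation_series <- function(pressures_Pa, strains,
                               direction = c("forth", "back"), condition = "") {
  direction <- match.arg(direction)
  if (length(pressures_Pa) != length(strains))
    stop_guv("guvphase_parameter_error", "pressures and strains lengths differ")
  if (any(strains < 0))
    stop_guv("guvphase_parameter_error", "strains must be >= 0")
  structure(list(pressures_Pa = pressures_Pa, strains = strains,
                 direction = direction, condition = as.character(condition)),
            class = "deformation_series")
}

#' Fit the stress-strain relation of a deformation series
#'
#' Ordinary least-squares regression of strain on pressure. The slope
#' (strain per Pa) is the compliance of the vesicle; its inverse, relative to
#' a reference condition, gives the relative elastic modulus
#' ([relative_modulus()]).
#'
#' @param series a [deformation_series] with >= 3 points and >= 2 distinct
#'   pressures.
#' @return an object of class `stiffness_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `slope_se`, `intercept_se`, `n`, `E_rel`
#'   (unset, `NA`); errors with class `guvphase_fit_error` otherwise.
#' @export
fit_stress_strain <- function(series) {
  stopifnot(inherits(series, "deformation_series"))
  if (length(series$pressures_Pa) < 3L)
    stop_guv("guvphase_fit_error", "need at least 3 points")
  if (length(unique(series$pressures_Pa)) < 2L)
    stop_guv("guvphase_fit_error", "zero pressure variance")
  fit <- stats::lm(strains ~ pressures_Pa,
                   data = list(strains = series$strains,
                               pressures_Pa = series$pressures_Pa))
  sm <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate here
  cf <- stats::coef(sm)
  structure(list(slope = cf["pressures_Pa", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 slope_se = cf["pressures_Pa", "Std. Error"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 n = length(series$strains),
                 direction = series$direction, condition = series$condition,
                 E_rel = NA_real_),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("<stiffness_fit> slope = %.4g /Pa, R^2 = %.4f\n",
              x$slope, x$r_squared))
  invisible(x)
}

#' Relative elastic modulus from two stress-strain fits
#'
#' `E_rel = slope(reference) / slope(sample)`: a stiffer membrane deforms
#' less per pascal, so a smaller compliance slope means a larger relative
#' modulus. `relative_modulus(a, b) * relative_modulus(b, a) = 1`.
#'
#' @param sample,reference `stiffness_fit` objects with positive slopes.
#' @return dimensionless relative modulus (> 0).
#' @export
relative_modulus <- function(sample, reference) {
  stopifnot(inherits(sample, "stiffness_fit"), inherits(reference, "stiffness_fit"))
  if (sample$slope <= 0 || reference$slope <= 0)
    stop_guv("guvphase_fit_error", "non-positive compliance slope")
  reference$slope / sample$slope
}

#' Forth/back consistency of a deformation assay
#'
#' Compares the stress-strain fits of the forth and back push directions:
#' reports the slope and intercept differences with standard errors (from the
#' pressure-by-direction interaction model), flags each as consistent when
#' the difference is within `tol_se` standard errors of zero, and returns a
#' pooled fit over both series (the statistics required for a formal ANCOVA
#' are exposed; the test itself is left to the caller).
#'
#' @param forth,back [deformation_series] objects.
#' @param tol_se consistency tolerance in standard errors.
#' @return list with `slope_diff`, `slope_diff_se`, `intercept_diff`,
#'   `intercept_diff_se`, `consistent` (logical), `pooled`
#'   (a `stiffness_fit` over the combined data), and the individual fits.
#' @export
forth_back_consistency <- function(forth, back, tol_se = 2) {
  fit_f <- fit_stress_strain(forth)
  fit_b <- fit_stress_strain(back)
  p <- c(forth$pressures_Pa, back$pressures_Pa)
  s <- c(forth$strains, back$strains)
  g <- factor(rep(c("forth", "back"), c(length(forth$strains), length(back$strains))),
              levels = c("forth", "back"))
  inter <- stats::lm(s ~ p * g)
  cf <- stats::coef(suppressWarnings(summary(inter)))
  slope_diff <- cf["p:gback", "Estimate"]
  slope_diff_se <- cf["p:gback", "Std. Error"]
  intercept_diff <- cf["gback", "Estimate"]
  intercept_diff_se <- cf["gback", "Std. Error"]
  pooled_series <- deformation_series(p, s, direction = "forth",
                                      condition = forth$condition)
  pooled <- fit_stress_strain(pooled_series)
  list(slope_diff = slope_diff, slope_diff_se = slope_diff_se,
       intercept_diff = intercept_diff, intercept_diff_se = intercept_diff_se,
       consistent = abs(slope_diff) <= tol_se * slope_diff_se &&
         abs(intercept_diff) <= tol_se * intercept_diff_se,
       pooled = pooled, forth_fit = fit_f, back_fit = fit_b)
}
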