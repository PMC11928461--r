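#' FRAP trace container
#'
#' @param times_s ascending acquisition times (s).
#' @param intensities measured intensities, same length.
#' @param bleach_index index (1-based) of the first post-bleach frame.
#' @return an object of class `frap_trace`.
#' @export
frap_trace <- function(times_s, intensities, bleach_index) {
  if (length(times_s) != length(intensities))
    stop_guv("guvphase_parameter_error", "times and intensities lengths differ")
  if (is.unsorted(times_s, strictly = TRUE))
    stop_guv("guvphase_parameter_error", "`times_s` must be strictly ascending")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index <= 1L || bleach_index > length(times_s))
    stop_guv("guvphase_parameter_error", "`bleach_index` must satisfy 1 < i <= length")
  structure(list(times_s = times_s, intensities = intensities,
                 bleach_index = bleach_index, normalized = FALSE),
            class = "frap_trace")
}

#' Normalize a FRAP trace to the pre-bleach plateau and bleach floor
#'
#' `F(t) = (I(t) - I_bleach) / (I_pre - I_bleach)` with `I_pre` the mean of
#' the pre-bleach frames and `I_bleach` the first post-bleach frame (no
#' back-extrapolation). `F` is 1 pre-bleach on average and exactly 0 at the
#' bleach frame; the result is invariant to affine rescaling of the raw
#' intensities.
#'
#' @param trace a [frap_trace] with at least 3 pre-bleach frames.
#' @return a normalized [frap_trace]; errors with class `guvphase_no_bleach`
#'   when pre-bleach and bleach intensities coincide.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (trace$bleach_index < 4L)
    stop_guv("guvphase_parameter_error", "need at least 3 pre-bleach frames")
  i_pre <- mean(trace$intensities[seq_len(trace$bleach_index - 1L)])
  i_bleach <- trace$intensities[trace$bleach_index]
  if (abs(i_pre - i_bleach) < 1e-12 * max(abs(i_pre), 1))
    stop_guv("guvphase_no_bleach", "no bleach detected: pre-bleach equals bleach frame")
  out <- trace
  out$intensities <- (trace$intensities - i_bleach) / (i_pre - i_bleach)
  out$normalized <- TRUE
  out
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of `F(t) = M * (1 - exp(-t / tau))` to the post-bleach
#' frames of a normalized trace, with `t` re-zeroed at the bleach frame.
#' `M` is the mobile fraction, `tau` the recovery time constant. Near-flat
#' traces at zero (no recovery) are returned as `M = 0` with a `degenerate`
#' flag rather than failing.
#'
#' @param norm a normalized [frap_trace] with at least 5 post-bleach frames.
#' @return an object of class `recovery_fit` with fields `mobile_fraction`,
#'   `tau_s`, `plateau` (`= M`), `rss`, `degenerate`; errors with class
#'   `guvphase_fit_failure` on non-convergence.
#' @export
fit_recovery <- function(norm) {
  stopifnot(inherits(norm, "frap_trace"))
  if (!isTRUE(norm$normalized))
    stop_guv("guvphase_parameter_error", "trace must be normalized first")
  post <- norm$bleach_index:length(norm$times_s)
  if (length(post) < 5L)
    stop_guv("guvphase_parameter_error", "need at least 5 post-bleach frames")
  t <- norm$times_s[post] - norm$times_s[norm$bleach_index]
  f <- norm$intensities[post]
  if (stats::sd(f) < 1e-10 && abs(mean(f)) < 1e-8) {
    return(structure(list(mobile_fraction = 0, tau_s = max(diff(t)[1], 1e-6),
                          plateau = 0, rss = sum(f^2), degenerate = TRUE),
                     class = "recovery_fit"))
  }
  m0 <- min(max(f[length(f)], 0.05), 1)
  half <- t[which(f >= m0 / 2)[1]]
  tau0 <- if (is.na(half) || half <= 0) max(t) / 5 else half / log(2)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ M * (1 - exp(-t / tau)),
                      start = list(M = m0, tau = tau0),
                      lower = c(M = 0, tau = 1e-8), upper = c(M = 1.5, tau = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_guv("guvphase_fit_failure",
               sprintf("recovery fit failed: %s (rss0 = %.3g)",
                       conditionMessage(e), sum(f^2))))
  cf <- stats::coef(fit)
  structure(list(mobile_fraction = min(unname(cf["M"]), 1),
                 tau_s = unname(cf["tau"]),
                 plateau = min(unname(cf["M"]), 1),
                 rss = sum(stats::resid(fit)^2), degenerate = FALSE),
            class = "recovery_fit")
}

#' Percent fluorescence recovery at a given time after the bleach
#'
#' `100 * M * (1 - exp(-t / tau))` - the summary used to report recovery at
#' fixed times (e.g. 5 s or 15 s post-bleach).
#'
#' @param fit a `recovery_fit`.
#' @param t_s time after the bleach (s).
#' @return percentage in `[0, 100 * M]`.
#' @export
percent_recovery_at <- function(fit, t_s) {
  stopifnot(inherits(fit, "recovery_fit"))
  100 * fit$mobile_fraction * (1 - exp(-t_s / fit$tau_s))
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> M = %.3f, tau = %.3g s%s\n", x$mobile_fraction,
              x$tau_s, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Fit a log-dose binding-response curve
#'
#' Four-parameter logistic in log10 concentration:
#' `R(c) = bottom + (top - bottom) / (1 + 10^(hill * (log10(EC50) - log10(c))))`.
#' The fit is declared saturated when the fitted response at the highest
#' tested dose is within 5% of `top` AND the confidence half-width of `top`
#' is below 20% of its value; `saturation_conc_uM` is then the smallest
#' tested dose whose fitted response is within 5% of `top`. Constant or
#' otherwise degenerate responses are returned with a warning status rather
#' than an error.
#'
#' @param concentrations_uM tested doses (>= 5 distinct values, all > 0).
#' @param responses measured responses, same length.
#' @return an object of class `dose_response` with fields `bottom`, `top`,
#'   `ec50_uM`, `hill`, `saturated`, `saturation_conc_uM`, `status`
#'   (`"ok"` or `"degenerate"`), `top_se`.
#' @export
fit_dose_response <- function(concentrations_uM, responses) {
  if (any(concentrations_uM <= 0))
    stop_guv("guvphase_parameter_error", "concentrations must be > 0")
  if (length(unique(concentrations_uM)) < 5L)
    stop_guv("guvphase_parameter_error", "need at least 5 distinct concentrations")
  if (length(concentrations_uM) != length(responses))
    stop_guv("guvphase_parameter_error", "doses and responses lengths differ")
  lc <- log10(concentrations_uM)
  r <- responses
  degenerate_out <- function() {
    structure(list(bottom = min(r), top = max(r),
                   ec50_uM = 10^mean(lc), hill = NA_real_,
                   saturated = FALSE, saturation_conc_uM = NA_real_,
                   status = "degenerate", top_se = NA_real_),
              class = "dose_response")
  }
  if (stats::sd(r) < 1e-12 * max(abs(r), 1)) {
    warning("constant response: degenerate dose-response fit")
    return(degenerate_out())
  }
  start <- list(bottom = min(r), top = max(r),
                lec50 = stats::median(lc), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lc))),
      start = start,
      lower = c(bottom = -Inf, top = -Inf, lec50 = min(lc) - 3, hill = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("dose-response fit did not converge; returning degenerate summary")
    return(degenerate_out())
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  ec50 <- 10^unname(cf["lec50"]); hill <- unname(cf["hill"])
  pred <- function(c_uM) bottom + (top - bottom) /
    (1 + 10^(hill * (log10(ec50) - log10(c_uM))))
  top_se <- unname(se["top"])
  half_width <- stats::qt(0.975, df = length(r) - 4) * top_se
  cmax <- max(concentrations_uM)
  near_top <- abs(pred(concentrations_uM) - top) <= 0.05 * abs(top)
  saturated <- isTRUE(abs(pred(cmax) - top) <= 0.05 * abs(top)) &&
    is.finite(half_width) && half_width < 0.2 * abs(top)
  structure(list(bottom = bottom, top = top, ec50_uM = ec50, hill = hill,
                 saturated = saturated,
                 saturation_conc_uM = if (saturated && any(near_top))
                   min(concentrations_uM[near_top]) else NA_real_,
                 status = "ok", top_se = top_se),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> EC50 = %.3g uM, hill = %.3g, top = %.3g, saturated = %s\n",
              x$ec50_uM, x$hill, x$top, x$saturated))
  invisible(x)
}
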