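#' Classify a field as condensed or dispersed
#'
#' The condensed-state call uses two statistics of the detected condensates:
#' the mean condensate area and the condensate count normalised to a 90 um^2
#' reference region. A field is condensed iff the mean area exceeds
#' `area_cut_um2` (default 0.4 um^2) AND the normalised count exceeds
#' `count_cut` (default 20 per 90 um^2). An empty condensate table is
#' dispersed, with mean area reported as 0 (the classifier is total).
#'
#' @param condensates a `condensate_table` from [detect_condensates()].
#' @param field_area_um2 imaged field area in um^2 (> 0).
#' @param area_cut_um2 mean-area threshold (um^2).
#' @param count_cut count threshold per 90 um^2.
#' @return list with `state` (`"condensed"` or `"dispersed"`),
#'   `mean_area_um2`, and `count_per_90um2`.
#' @export
classify_phase_state <- function(condensates, field_area_um2,
                                 area_cut_um2 = 0.4, count_cut = 20) {
  assert_scalar_number(field_area_um2, "field_area_um2", positive = TRUE)
  n <- nrow(condensates)
  mean_area <- if (n > 0) mean(condensates$area_um2) else 0
  count_norm <- n / field_area_um2 * 90
  state <- if (mean_area > area_cut_um2 && count_norm > count_cut)
    "condensed" else "dispersed"
  list(state = state, mean_area_um2 = mean_area, count_per_90um2 = count_norm)
}

#' Assemble a phase-diagram observation
#'
#' @param conc_x_uM,conc_y_uM the two varied concentrations (uM, >= 0).
#' @param mean_area_um2,count_per_90um2 condensate statistics.
#' @param state `"condensed"` or `"dispersed"`.
#' @return one-row data frame of class `phase_point`.
#' @export
phase_point <- function(conc_x_uM, conc_y_uM, mean_area_um2 = NA_real_,
                        count_per_90um2 = NA_real_,
                        state = c("condensed", "dispersed")) {
  state <- match.arg(state)
  if (conc_x_uM < 0 || conc_y_uM < 0)
    stop_guv("guvphase_parameter_error", "concentrations must be >= 0")
  out <- data.frame(conc_x_uM = conc_x_uM, conc_y_uM = conc_y_uM,
                    mean_area_um2 = mean_area_um2,
                    count_per_90um2 = count_per_90um2, state = state)
  class(out) <- c("phase_point", "data.frame")
  out
}

#' Fit the condensed/dispersed phase boundary with an SVM
#'
#' Fits a support-vector machine over the two-concentration plane with a
#' linear or second-degree polynomial kernel and reports the training
#' accuracy. The decision surface defines the phase boundary; classify new
#' concentration pairs with [predict.phase_boundary()].
#'
#' @param points data frame with columns `conc_x_uM`, `conc_y_uM`, `state`
#'   (both states must be present).
#' @param kernel `"linear"` or `"poly2"`.
#' @param regularization SVM cost parameter (> 0).
#' @param seed RNG seed for the fit (recorded; the fit itself is
#'   deterministic).
#' @return an object of class `phase_boundary` with fields `model`, `kernel`,
#'   `regularization`, `training_accuracy`, `seed`.
#' @export
fit_phase_boundary <- function(points, kernel = c("linear", "poly2"),
                               regularization = 1, seed = 1L) {
  kernel <- match.arg(kernel)
  assert_scalar_number(regularization, "regularization", positive = TRUE)
  need <- c("conc_x_uM", "conc_y_uM", "state")
  if (!all(need %in% names(points)))
    stop_guv("guvphase_parameter_error",
             sprintf("`points` must have columns %s", paste(need, collapse = ", ")))
  y <- factor(points$state, levels = c("dispersed", "condensed"))
  if (length(unique(y)) < 2L)
    stop_guv("guvphase_degenerate_labels",
             "phase-boundary fit needs points of both states")
  x <- as.matrix(points[, c("conc_x_uM", "conc_y_uM")])
  model <- withr::with_seed(as.integer(seed), {
    if (kernel == "linear") {
      e1071::svm(x, y, kernel = "linear", cost = regularization, scale = TRUE)
    } else {
      # coef0 = 1 gives an inhomogeneous quadratic kernel (linear + cross terms)
      e1071::svm(x, y, kernel = "polynomial", degree = 2, coef0 = 1,
                 cost = regularization, scale = TRUE)
    }
  })
  acc <- mean(stats::predict(model, x) == y)
  structure(list(model = model, kernel = kernel,
                 regularization = regularization,
                 training_accuracy = acc, seed = as.integer(seed)),
            class = "phase_boundary")
}

#' Classify concentration pairs against a fitted phase boundary
#'
#' @param object a `phase_boundary`.
#' @param conc_x_uM,conc_y_uM concentration vectors (uM, >= 0).
#' @param ... unused.
#' @return character vector of states.
#' @export
predict.phase_boundary <- function(object, conc_x_uM, conc_y_uM, ...) {
  if (any(conc_x_uM < 0) || any(conc_y_uM < 0))
    stop_guv("guvphase_parameter_error", "concentrations must be >= 0")
  x <- cbind(conc_x_uM = conc_x_uM, conc_y_uM = conc_y_uM)
  as.character(stats::predict(object$model, x))
}

#' @export
print.phase_boundary <- function(x, ...) {
  cat(sprintf("<phase_boundary> kernel = %s, cost = %.3g, training accuracy = %.3f\n",
              x$kernel, x$regularization, x$training_accuracy))
  invisible(x)
}

#' Rasterize a phase-boundary decision map
#'
#' Evaluates the fitted boundary on a regular concentration grid, for export
#' and plotting.
#'
#' @param boundary a `phase_boundary`.
#' @param x_range,y_range concentration ranges (uM).
#' @param n grid points per axis.
#' @return data frame with `conc_x_uM`, `conc_y_uM`, `state`.
#' @export
boundary_decision_map <- function(boundary, x_range, y_range, n = 50L) {
  gx <- seq(x_range[1], x_range[2], length.out = n)
  gy <- seq(y_range[1], y_range[2], length.out = n)
  grid <- expand.grid(conc_x_uM = gx, conc_y_uM = gy)
  grid$state <- predict(boundary, grid$conc_x_uM, grid$conc_y_uM)
  grid
}
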