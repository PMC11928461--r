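#' Segment the GUV membrane from the membrane channel
#'
#' Gaussian-blurs the membrane channel (default sigma 1.5 px, to suppress
#' detector noise), thresholds by intensity, and returns the resulting mask.
#' The default threshold is Otsu's method (deterministic and parameter-free,
#' with ties broken toward the lower threshold); a fixed intensity value can
#' be supplied instead. The Otsu route is invariant to adding a constant to
#' every pixel.
#'
#' @param membrane an [image_channel].
#' @param blur_sigma_px Gaussian blur sigma, in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold intensity when `threshold_method = "fixed"`.
#' @return a [region_mask]; errors with class `guvphase_no_foreground` when
#'   the threshold yields an empty mask or the image has no variation.
#' @export
segment_guv <- function(membrane, blur_sigma_px = 1.5,
                        threshold_method = c("otsu", "fixed"),
                        fixed_value = NULL) {
  stopifnot(inherits(membrane, "image_channel"))
  threshold_method <- match.arg(threshold_method)
  blurred <- if (blur_sigma_px > 0)
    blur_image(membrane$intensities, blur_sigma_px) else membrane$intensities
  thr <- if (threshold_method == "otsu") {
    otsu_threshold(blurred)
  } else {
    if (is.null(fixed_value))
      stop_guv("guvphase_parameter_error",
               "`fixed_value` is required for threshold_method = 'fixed'")
    fixed_value
  }
  flags <- blurred > thr
  if (!any(flags))
    stop_guv("guvphase_no_foreground", "thresholding produced an empty mask")
  region_mask(flags, membrane$pixel_size_um)
}

blur_image <- function(m, sigma_px) {
  # EBImage::gblur pads by reflection; adequate for interior structures.
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma_px))
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Quantify protein recruitment within a membrane mask
#'
#' Integrated fluorescence intensity of the protein channel within the mask,
#' normalised to the mask area: `intensity_per_area` equals the mean protein
#' intensity over masked pixels (equivalently the integrated intensity times
#' pixel area divided by the mask area in um^2).
#'
#' @param protein an [image_channel].
#' @param mask a [region_mask] over the same grid.
#' @return an object of class `recruitment_measure` with fields
#'   `integrated_intensity`, `area_um2`, `intensity_per_area`.
#' @export
quantify_recruitment <- function(protein, mask) {
  stopifnot(inherits(protein, "image_channel"), inherits(mask, "region_mask"))
  check_same_shape(protein, mask, "protein channel and mask")
  if (!any(mask$flags))
    stop_guv("guvphase_empty_mask", "mask contains no pixels")
  vals <- protein$intensities[mask$flags]
  structure(list(integrated_intensity = sum(vals),
                 area_um2 = mask$area_um2,
                 intensity_per_area = mean(vals)),
            class = "recruitment_measure")
}

#' Relative lipid order from two emission windows
#'
#' The relative lipid order phi is the ratio between the blue/green
#' (449-550 nm) and the red (550-650 nm) emission windows of the
#' solvatochromic membrane dye over a membrane mask. The estimator is the
#' ratio of masked sums (robust to per-pixel division noise); the per-pixel
#' ratio map is returned for display, with out-of-mask pixels set to 0 when
#' `outside_to_zero`.
#'
#' @param blue_green,red [image_channel]s of the two emission windows.
#' @param mask a [region_mask] marking the membrane.
#' @param outside_to_zero zero the ratio map outside the mask.
#' @return an object of class `phi_result` with fields `phi`, `n_pixels`,
#'   and `ratio_map`; errors with class `guvphase_division_by_zero` when the
#'   masked red-window sum is zero.
#' @export
compute_phi <- function(blue_green, red, mask, outside_to_zero = TRUE) {
  stopifnot(inherits(blue_green, "image_channel"), inherits(red, "image_channel"),
            inherits(mask, "region_mask"))
  check_same_shape(blue_green, red)
  check_same_shape(blue_green, mask, "channels and mask")
  red_sum <- sum(red$intensities[mask$flags])
  if (red_sum <= 0)
    stop_guv("guvphase_division_by_zero", "masked red-window sum is zero")
  phi <- sum(blue_green$intensities[mask$flags]) / red_sum
  ratio <- blue_green$intensities / pmax(red$intensities, .Machine$double.eps)
  if (outside_to_zero) ratio[!mask$flags] <- 0
  structure(list(phi = phi, n_pixels = sum(mask$flags), ratio_map = ratio),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("<phi_result> phi = %.4g over %d px\n", x$phi, x$n_pixels))
  invisible(x)
}

#' Per-region relative lipid order with background subtraction (live-cell)
#'
#' Live-cell variant: a per-channel scalar background (the mean over
#' `background_region`) is subtracted from both emission windows before the
#' per-region ratio is computed; negative post-subtraction pixels are clipped
#' to 0. Regions whose background-subtracted red sum is not positive are
#' returned flagged invalid (`valid = FALSE`, `phi = NA`) rather than dropped.
#'
#' @param blue_green,red [image_channel]s.
#' @param lysosome_regions list of [region_mask]s, one per organelle region.
#' @param background_region a [region_mask] disjoint from the regions.
#' @return list of `phi_result` objects, each with an added `valid` flag and
#'   `region` index.
#' @export
compute_phi_live <- function(blue_green, red, lysosome_regions, background_region) {
  stopifnot(inherits(background_region, "region_mask"))
  for (rg in lysosome_regions) {
    stopifnot(inherits(rg, "region_mask"))
    if (any(rg$flags & background_region$flags))
      stop_guv("guvphase_parameter_error",
               "background region overlaps an analysis region")
  }
  bg_bg <- mean(blue_green$intensities[background_region$flags])
  bg_red <- mean(red$intensities[background_region$flags])
  bg_sub <- function(m, b) pmax(m - b, 0)
  bgc <- bg_sub(blue_green$intensities, bg_bg)
  redc <- bg_sub(red$intensities, bg_red)
  lapply(seq_along(lysosome_regions), function(i) {
    fl <- lysosome_regions[[i]]$flags
    red_sum <- sum(redc[fl])
    if (red_sum <= 0) {
      structure(list(phi = NA_real_, n_pixels = sum(fl), ratio_map = NULL,
                     valid = FALSE, region = i), class = "phi_result")
    } else {
      structure(list(phi = sum(bgc[fl]) / red_sum, n_pixels = sum(fl),
                     ratio_map = NULL, valid = TRUE, region = i),
                class = "phi_result")
    }
  })
}

#' Detect condensates as thresholded connected components
#'
#' Threshold (Otsu by default, or a fixed value) followed by 8-connected
#' component labelling; one condensate per component with area at least
#' `min_area_um2`. A blank field yields an empty table, not an error.
#'
#' @param field an [image_channel].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold intensity for the fixed method.
#' @param min_area_um2 discard components smaller than this area.
#' @return data frame of class `condensate_table` with columns
#'   `centroid_row`, `centroid_col` (pixels, 1-based), `area_um2`,
#'   `mean_intensity`.
#' @export
detect_condensates <- function(field, threshold_method = c("otsu", "fixed"),
                               fixed_value = NULL, min_area_um2 = 0) {
  stopifnot(inherits(field, "image_channel"))
  threshold_method <- match.arg(threshold_method)
  m <- field$intensities
  empty <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  class(empty) <- c("condensate_table", "data.frame")
  thr <- if (threshold_method == "fixed") {
    if (is.null(fixed_value))
      stop_guv("guvphase_parameter_error",
               "`fixed_value` is required for threshold_method = 'fixed'")
    fixed_value
  } else {
    t <- tryCatch(otsu_threshold(m), guvphase_no_foreground = function(e) NULL)
    if (is.null(t)) return(empty)
    t
  }
  flags <- m > thr
  if (!any(flags)) return(empty)
  labels <- label_components8(flags)
  n <- max(labels)
  px_area <- field$pixel_size_um^2
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  vals <- m[labels > 0L]
  out <- data.frame(
    centroid_row = as.numeric(tapply(idx[, 1], lab, mean)),
    centroid_col = as.numeric(tapply(idx[, 2], lab, mean)),
    area_um2 = as.numeric(tapply(lab, lab, length)) * px_area,
    mean_intensity = as.numeric(tapply(vals, lab, mean)))
  out <- out[out$area_um2 >= min_area_um2 & out$area_um2 > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("condensate_table", "data.frame")
  out
}

#' Radial high-pass filter in the Fourier domain
#'
#' Zeroes all Fourier components with radial frequency below `highpass_radius`
#' (in cycles per image dimension) except the DC component, which is retained
#' so the filtered image keeps the original mean. The mask is circular in
#' integer frequency index space.
#'
#' @param m numeric matrix.
#' @param highpass_radius cutoff radius, cycles per image dimension.
#' @return filtered matrix (real part of the inverse FFT).
#' @export
highpass_filter <- function(m, highpass_radius) {
  nr <- nrow(m); nc <- ncol(m)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)]
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)]
  radius <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- radius >= highpass_radius
  keep[1, 1] <- TRUE                      # retain DC: mean must stay defined
  ft <- stats::fft(m) * keep
  Re(stats::fft(ft, inverse = TRUE)) / (nr * nc)
}

#' Granulosity index of a fluorescence image
#'
#' After homogeneous background subtraction, the image is Fourier-transformed,
#' high-pass filtered through a circular frequency mask (held constant across
#' a comparison series), and inverse-transformed; the granulosity index G is
#' the ratio of the standard deviation to the mean of the filtered image.
#' The DC component is retained by the filter so the denominator equals the
#' (background-subtracted) image mean; a constant image therefore has G = 0,
#' and G is invariant to multiplying the image by a positive constant.
#'
#' @param image an [image_channel].
#' @param highpass_radius cutoff, cycles per image dimension; must be the same
#'   for every image in a comparison series.
#' @param background constant background level to subtract first.
#' @return an object of class `granulosity_result` with fields `index` and
#'   `highpass_radius`; errors with class `guvphase_undefined_index` when the
#'   filtered mean is not positive.
#' @export
granulosity_index <- function(image, highpass_radius, background = 0) {
  stopifnot(inherits(image, "image_channel"))
  assert_scalar_number(highpass_radius, "highpass_radius", positive = TRUE)
  m <- image$intensities - background
  # cutoff wavelength is dim/highpass_radius pixels; the image must span at
  # least two such wavelengths, i.e. highpass_radius > 2 cycles per dimension
  if (highpass_radius <= 2)
    stop_guv("guvphase_parameter_error",
             "`highpass_radius` must exceed 2 cycles per image dimension")
  filt <- highpass_filter(m, highpass_radius)
  mu <- mean(filt)
  if (mu <= 0)
    stop_guv("guvphase_undefined_index",
             "filtered-image mean is not positive; granulosity undefined")
  n <- length(filt)
  sdev <- sqrt(sum((filt - mu)^2) / (n - 1))
  structure(list(index = sdev / mu, highpass_radius = highpass_radius),
            class = "granulosity_result")
}
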