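#' Image channel with physical pixel size
#'
#' The basic imaging container of the package: a 2-D non-negative intensity
#' matrix together with the physical pixel size in micrometres. All areas
#' reported by downstream stages are in square micrometres, converted via
#' `pixel_size_um^2`. Pixel coordinates are 1-based `(row, col)`.
#'
#' @param intensities numeric matrix of non-negative intensities.
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param label free-text channel label (e.g. `"membrane"`, `"protein"`).
#' @return an object of class `image_channel`.
#' @export
image_channel <- function(intensities, pixel_size_um, label = "") {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_guv("guvphase_parameter_error", "`intensities` must be a numeric matrix")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop_guv("guvphase_parameter_error", "intensities must be finite and >= 0")
  assert_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(intensities = intensities, pixel_size_um = pixel_size_um,
         label = as.character(label)),
    class = "image_channel"
  )
}

#' @export
print.image_channel <- function(x, ...) {
  cat(sprintf("<image_channel '%s'> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              x$label, nrow(x$intensities), ncol(x$intensities),
              x$pixel_size_um, min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.image_channel <- function(x) dim(x$intensities)

#' Boolean region mask tied to an image channel
#'
#' @param flags logical matrix; `TRUE` marks pixels inside the region.
#' @param pixel_size_um pixel size of the source channel, micrometres.
#' @return an object of class `region_mask` with derived field `area_um2`
#'   (`TRUE`-pixel count times `pixel_size_um^2`).
#' @export
region_mask <- function(flags, pixel_size_um) {
  if (!is.matrix(flags) || !is.logical(flags))
    stop_guv("guvphase_parameter_error", "`flags` must be a logical matrix")
  assert_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(flags = flags, pixel_size_um = pixel_size_um,
         area_um2 = sum(flags) * pixel_size_um^2),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d px (%.4g um^2) of %d x %d\n",
              sum(x$flags), x$area_um2, nrow(x$flags), ncol(x$flags)))
  invisible(x)
}

check_same_shape <- function(a, b, what = "channels") {
  da <- if (inherits(a, "image_channel")) dim(a$intensities) else dim(a$flags)
  db <- if (inherits(b, "image_channel")) dim(b$intensities) else dim(b$flags)
  if (!identical(da, db))
    stop_guv("guvphase_parameter_error",
             sprintf("%s have mismatched shapes: %dx%d vs %dx%d",
                     what, da[1], da[2], db[1], db[2]))
  invisible(TRUE)
}

#' Read / write image channels as TIFF with a JSON sidecar
#'
#' Images are stored as 32-bit float TIFF; the physical pixel size and channel
#' label are recorded in a JSON sidecar `<stem>.meta.json` (TIFF resolution
#' tags are also set, but the sidecar is authoritative).
#'
#' @param channel an [image_channel].
#' @param path output TIFF path.
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   returns an [image_channel].
#' @export
write_image_tiff <- function(channel, path) {
  stopifnot(inherits(channel, "image_channel"))
  m <- channel$intensities
  scale <- max(m, 1)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = channel$pixel_size_um, label = channel$label,
               intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path, "meta"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta_path <- sidecar_path(path, "meta")
  if (!file.exists(meta_path))
    stop_guv("guvphase_io_error", sprintf("missing metadata sidecar '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  image_channel(m * scale, meta$pixel_size_um, label = meta$label %||% "")
}

#' Write a region mask as 8-bit TIFF (0/255)
#' @param mask a [region_mask].
#' @param path output TIFF path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  tiff::writeTIFF(ifelse(mask$flags, 1, 0), path, bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size_um),
                       sidecar_path(path, "meta"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path, kind) {
  paste0(tools::file_path_sans_ext(path), ".", kind, ".json")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
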