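# CSV readers/writers for the package's tabular interchange formats.
# Column names are fixed; readers fail naming the missing column.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_guv("guvphase_io_error",
             sprintf("file '%s' is missing required column(s): %s",
                     path, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read / write IR spectra as two-column CSV
#'
#' Columns `wavenumber_cm1`, `absorbance`.
#'
#' @param path CSV path.
#' @param instrument instrument tag for the returned [ir_spectrum].
#' @param spectrum an [ir_spectrum] to write.
#' @return `read_spectrum_csv()` returns an [ir_spectrum].
#' @export
read_spectrum_csv <- function(path, instrument = "afmir") {
  df <- utils::read.csv(path)
  require_columns(df, c("wavenumber_cm1", "absorbance"), path)
  ir_spectrum(df$wavenumber_cm1, df$absorbance, instrument = instrument)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavenumber_cm1 = spectrum$wavenumbers_cm1,
                              absorbance = spectrum$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write FRAP traces as CSV with a JSON sidecar
#'
#' Columns `time_s`, `intensity`; the bleach index is stored in a sidecar
#' `<stem>.meta.json`.
#'
#' @param path CSV path.
#' @param trace a [frap_trace] to write.
#' @return `read_frap_csv()` returns a [frap_trace].
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("time_s", "intensity"), path)
  meta_path <- sidecar_path(path, "meta")
  if (!file.exists(meta_path))
    stop_guv("guvphase_io_error", sprintf("missing sidecar '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frap_trace(df$time_s, df$intensity, meta$bleach_index)
}

#' @rdname read_frap_csv
#' @export
write_frap_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times_s,
                              intensity = trace$intensities),
                   path, row.names = FALSE)
  jsonlite::write_json(list(bleach_index = trace$bleach_index),
                       sidecar_path(path, "meta"), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write deformation series as CSV
#'
#' Columns `pressure_Pa`, `strain`, plus optional `direction`, `condition`.
#'
#' @param path CSV path.
#' @param series a [deformation_series] to write.
#' @return `read_deformation_csv()` returns a [deformation_series].
#' @export
read_deformation_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("pressure_Pa", "strain"), path)
  deformation_series(df$pressure_Pa, df$strain,
                     direction = if ("direction" %in% names(df))
                       df$direction[1] else "forth",
                     condition = if ("condition" %in% names(df))
                       df$condition[1] else "")
}

#' @rdname read_deformation_csv
#' @export
write_deformation_csv <- function(series, path) {
  utils::write.csv(data.frame(pressure_Pa = series$pressures_Pa,
                              strain = series$strains,
                              direction = series$direction,
                              condition = series$condition),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write diffusion profile sets as CSV
#'
#' Columns `x_um`, `intensity`, `position_index` (1-4). Geometry and
#' conditions are stored in a sidecar `<stem>.meta.json`.
#'
#' @param path CSV path.
#' @param profiles a [diffusion_profile_set] to write.
#' @return `read_profiles_csv()` returns a [diffusion_profile_set].
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("x_um", "intensity", "position_index"), path)
  meta_path <- sidecar_path(path, "meta")
  if (!file.exists(meta_path))
    stop_guv("guvphase_io_error", sprintf("missing sidecar '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  geometry <- do.call(channel_geometry, meta$geometry)
  conditions <- do.call(sizing_conditions, meta$conditions)
  idx <- sort(unique(df$position_index))
  x <- df$x_um[df$position_index == idx[1]]
  profiles <- vapply(idx, function(i) df$intensity[df$position_index == i],
                     numeric(length(x)))
  structure(list(x_um = x, profiles = profiles, geometry = geometry,
                 conditions = conditions,
                 times_s = residence_times_s(geometry, conditions)),
            class = "diffusion_profile_set")
}

#' @rdname read_profiles_csv
#' @export
write_profiles_csv <- function(profiles, path) {
  n_pos <- ncol(profiles$profiles)
  df <- data.frame(
    x_um = rep(profiles$x_um, n_pos),
    intensity = as.numeric(profiles$profiles),
    position_index = rep(seq_len(n_pos), each = length(profiles$x_um)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(geometry = unclass(profiles$geometry),
         conditions = unclass(profiles$conditions)),
    sidecar_path(path, "meta"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write phase-diagram points as CSV
#'
#' Columns `conc_x_uM`, `conc_y_uM`, `mean_area_um2`, `count_per_90um2`,
#' `state`.
#'
#' @param path CSV path.
#' @param points a phase-point data frame to write.
#' @return `read_phase_points_csv()` returns a data frame.
#' @export
read_phase_points_csv <- function(path) {
  df <- utils::read.csv(path)
  require_columns(df, c("conc_x_uM", "conc_y_uM", "state"), path)
  df
}

#' @rdname read_phase_points_csv
#' @export
write_phase_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}
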