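# Plain-text serialization: JSON reports and geometry sidecars, CSV tables.

# Polynomial rolling hash of a deparsed object; stamps reports with a
# configuration fingerprint without external dependencies.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write an experiment report to JSON
#'
#' Serializes the per-spindle and per-subject tables, the grand summaries,
#' map correlations and the max-normalized grand activation maps, stamped
#' with a configuration fingerprint and the master seed.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  out <- list(
    package = "spindlesync",
    config_hash = config_hash(report$config),
    seed = report$config$seed,
    n_sources = report$n_sources,
    n_pairs = report$n_pairs,
    nominal_spacing_m = report$nominal_spacing,
    summary = lapply(report$summary, as.list),
    map_correlation = as.list(report$map_correlation),
    map_correlation_per_subject = report$map_correlation_per_subject,
    per_subject = report$per_subject,
    per_spindle = report$per_spindle,
    grand_maps_max1 = lapply(report$maps, function(m) m$max1$values))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an experiment report written by [write_experiment_report()]
#'
#' @param path JSON path.
#' @return A list mirroring the JSON structure.
#' @export
read_experiment_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a geometry sidecar (sensor array or source space) to JSON
#'
#' @param x A `sensor_array` or `source_space`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(x, path) {
  out <- if (inherits(x, "sensor_array")) {
    list(kind = "sensor_array", modality = x$modality,
         channels = cbind(x$channels,
                          as.data.frame(x$position),
                          stats::setNames(as.data.frame(x$orientation),
                                          c("ox", "oy", "oz"))))
  } else if (inherits(x, "source_space")) {
    list(kind = "source_space",
         nominal_spacing_m = x$nominal_spacing,
         radius = x$radius, fold_amplitude = x$fold_amplitude,
         fold_wavenumber = x$fold_wavenumber,
         dipoles = cbind(as.data.frame(x$positions),
                         stats::setNames(as.data.frame(x$orientations),
                                         c("nx", "ny", "nz")),
                         hemisphere = x$hemisphere))
  } else stop("x must be a sensor_array or source_space")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-spindle statistics to CSV
#'
#' @param report An `experiment_report`.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_spindle_csv <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  utils::write.csv(report$per_spindle, path, row.names = FALSE)
  invisible(path)
}
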