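# Structured configuration (YAML with explicit unit strings) and
# report writers.  Parsing and serialization go through the yaml and
# jsonlite packages; this file owns only the schema and its checks.

quantity <- function(value, unit) list(value = value, unit = unit)

read_quantity <- function(node, key, unit, parent) {
  path <- paste(c(parent, key), collapse = ".")
  if (is.null(node)) abort_validation(sprintf("missing required key `%s`", path))
  if (!is.list(node) || !setequal(names(node), c("value", "unit"))) {
    abort_validation(sprintf("`%s` must be a {value, unit} pair", path))
  }
  if (!is.numeric(node$value) || length(node$value) != 1L || is.na(node$value)) {
    abort_validation(sprintf("`%s.value` must be a single number", path))
  }
  if (!identical(node$unit, unit)) {
    abort_validation(sprintf("`%s.unit` must be \"%s\" (got \"%s\")",
                             path, unit, format(node$unit)))
  }
  node$value
}

check_keys <- function(node, allowed, required, parent) {
  unknown <- setdiff(names(node), allowed)
  if (length(unknown)) {
    abort_validation(sprintf("unknown key(s) under `%s`: %s", parent,
                             paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(required, names(node))
  if (length(missing)) {
    abort_validation(sprintf("missing required key(s) under `%s`: %s", parent,
                             paste(missing, collapse = ", ")))
  }
}

read_material <- function(node, parent) {
  check_keys(node, c("name", "mass_attenuation", "density"),
             c("name", "mass_attenuation", "density"), parent)
  material_spec(node$name,
                read_quantity(node$mass_attenuation, "mass_attenuation",
                              "cm^2/g", parent),
                read_quantity(node$density, "density", "g/cm^3", parent))
}

#' Read a scenario configuration file
#'
#' Parses and validates a YAML scenario file.  Every physical quantity
#' must carry its unit explicitly (`cm`, `cm^2/g`, `g/cm^3`); unknown
#' keys are rejected, and a missing `capsule_pitch` defaults to the
#' capsule layer sum with a notice.
#'
#' @param path Path to a YAML file as written by [write_config()].
#' @return A `scenario_bundle` (with empty holders).
#' @seealso [write_config()], [leksell4c_fixture()]
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_config(leksell4c_fixture(), path)
#' read_config(path)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  check_keys(raw, "stacksource_config", "stacksource_config", "(top level)")
  cfg <- raw$stacksource_config
  check_keys(cfg, c("name", "capsule", "geometry"),
             c("capsule", "geometry"), "stacksource_config")

  cap <- cfg$capsule
  check_keys(cap,
             c("active_material", "shell_material", "active_height",
               "shell_front_height", "shell_back_height", "capsule_pitch",
               "active_radius"),
             c("active_material", "shell_material", "active_height",
               "shell_front_height", "shell_back_height"),
             "capsule")
  active <- read_material(cap$active_material, "capsule.active_material")
  shell <- read_material(cap$shell_material, "capsule.shell_material")
  pitch <- if (is.null(cap$capsule_pitch)) NULL else {
    read_quantity(cap$capsule_pitch, "capsule_pitch", "cm", "capsule")
  }
  radius <- if (is.null(cap$active_radius)) 0.05 else {
    read_quantity(cap$active_radius, "active_radius", "cm", "capsule")
  }
  capsule <- capsule_spec(
    active, shell,
    active_height = read_quantity(cap$active_height, "active_height",
                                  "cm", "capsule"),
    shell_front_height = read_quantity(cap$shell_front_height,
                                       "shell_front_height", "cm", "capsule"),
    shell_back_height = read_quantity(cap$shell_back_height,
                                      "shell_back_height", "cm", "capsule"),
    capsule_pitch = pitch, active_radius = radius)

  geo <- cfg$geometry
  check_keys(geo, "source_focus_distance", "source_focus_distance", "geometry")
  geometry <- unit_geometry(read_quantity(geo$source_focus_distance,
                                          "source_focus_distance", "cm",
                                          "geometry"))
  new_scenario_bundle(if (is.null(cfg$name)) "unnamed" else cfg$name,
                      capsule, geometry)
}

#' Write a scenario configuration file
#'
#' Serializes a `scenario_bundle`'s capsule and geometry to the YAML
#' schema that [read_config()] reads back; the round trip is an
#' identity on the physical parameters.
#'
#' @param bundle A `scenario_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  if (!inherits(bundle, "scenario_bundle")) {
    abort_validation("`bundle` must be a scenario_bundle")
  }
  cap <- bundle$capsule
  mat <- function(m) list(name = m$name,
                          mass_attenuation = quantity(m$mass_attenuation, "cm^2/g"),
                          density = quantity(m$density, "g/cm^3"))
  cfg <- list(stacksource_config = list(
    name = bundle$name,
    capsule = list(
      active_material = mat(cap$active_material),
      shell_material = mat(cap$shell_material),
      active_height = quantity(cap$active_height, "cm"),
      shell_front_height = quantity(cap$shell_front_height, "cm"),
      shell_back_height = quantity(cap$shell_back_height, "cm"),
      capsule_pitch = quantity(cap$capsule_pitch, "cm"),
      active_radius = quantity(cap$active_radius, "cm")),
    geometry = list(
      source_focus_distance = quantity(bundle$geometry$source_focus_distance,
                                       "cm"))))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

round6 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 6)
  df
}

#' Three-decimal comparison view of a correction table
#'
#' Rounds the correction fractions half-to-even to three decimals, the
#' precision at which published tabulations of these corrections are
#' printed.
#'
#' @param x A `correction_table` from [relative_air_kerma()].
#' @return The table with `attenuation`, `distance` and `total` rounded
#'   to 3 decimals.
#' @export
comparison_view <- function(x) {
  if (!inherits(x, "correction_table")) {
    abort_validation("`x` must be a correction_table")
  }
  x$attenuation <- round(x$attenuation, 3)
  x$distance <- round(x$distance, 3)
  x$total <- round(x$total, 3)
  x
}

#' Write analysis reports to a directory
#'
#' Writes each result to its CSV or JSON file (correction tables,
#' schedule reports with a JSON action log, Monte Carlo comparisons
#' and tallies) plus a `manifest.json` recording the package version,
#' seed, config hash and file list.  CSV fractions use a '.' decimal
#' separator and 6 decimals.
#'
#' @param results A single result object or a list of them
#'   (`correction_table`, `schedule_report`, `mc_comparison`,
#'   `tally_result`).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed to record in the manifest, if any.
#' @param config_path Config file to hash into the manifest, if any.
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(results, out_dir, seed = NULL, config_path = NULL) {
  known <- c("correction_table", "schedule_report", "mc_comparison",
             "tally_result")
  if (inherits(results, known)) results <- list(results)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort_validation(sprintf("cannot create output directory %s", out_dir))
  }
  written <- character()
  emit <- function(name) {
    path <- file.path(out_dir, name)
    written <<- c(written, path)
    path
  }
  for (res in results) {
    if (inherits(res, "correction_table")) {
      utils::write.csv(round6(as.data.frame(res)), emit("corrections.csv"),
                       row.names = FALSE)
    } else if (inherits(res, "schedule_report")) {
      utils::write.csv(round6(res$table),
                       emit(sprintf("schedule_%s.csv", res$scheme)),
                       row.names = FALSE)
      jsonlite::write_json(res$actions,
                           emit(sprintf("schedule_%s_actions.json", res$scheme)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else if (inherits(res, "mc_comparison")) {
      utils::write.csv(round6(as.data.frame(res)), emit("mc_comparison.csv"),
                       row.names = FALSE)
    } else if (inherits(res, "tally_result")) {
      jsonlite::write_json(unclass(res), emit("tally.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      abort_validation(sprintf("cannot write result of class %s",
                               paste(class(res), collapse = "/")))
    }
  }
  manifest <- list(
    package = "stacksource",
    version = as.character(utils::packageVersion("stacksource")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    },
    files = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(written, file.path(out_dir, "manifest.json")))
}
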