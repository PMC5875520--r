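#' @keywords internal
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("stacksource_validation", "stacksource_error"),
                      call = call))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    abort_validation(sprintf("`%s` must be a numeric value of length %d", name, len))
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    abort_validation(sprintf("`%s` must be %s %s (got %s)", name,
                             if (strict) ">" else ">=", format(lower),
                             paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
      any(x < 0) || any(x != trunc(x))) {
    abort_validation(sprintf("`%s` must be non-negative whole number(s)", name))
  }
  invisible(as.integer(x))
}

#' Radiological material specification
#'
#' A material is characterised, at the 1.25 MeV mean gamma energy of
#' cobalt-60, by its mass attenuation coefficient and its (effective)
#' density; their product is the linear attenuation coefficient used in
#' narrow-beam exponential attenuation.
#'
#' @param name Label for the material.
#' @param mass_attenuation Mass attenuation coefficient in cm^2/g at
#'   1.25 MeV.  Must be non-negative.
#' @param density Density in g/cm^3.  For pellet-packed source columns
#'   this is the effective bulk density including interstitial air.
#'   Must be positive.
#' @return An object of class `material_spec`.
#' @seealso [linear_attenuation()]
#' @examples
#' cobalt <- material_spec("cobalt-60 pellets", 0.0527, 5.88)
#' linear_attenuation(cobalt)
#' @export
material_spec <- function(name, mass_attenuation, density) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    abort_validation("`name` must be a single string")
  }
  check_number(mass_attenuation, "mass_attenuation", lower = 0)
  check_number(density, "density", lower = 0, strict = TRUE)
  structure(list(name = name,
                 mass_attenuation = as.numeric(mass_attenuation),
                 density = as.numeric(density)),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: mu/rho = %g cm^2/g, rho = %g g/cm^3, mu = %g 1/cm\n",
              x$name, x$mass_attenuation, x$density, linear_attenuation(x)))
  invisible(x)
}

#' Encapsulated source capsule specification
#'
#' Describes one encapsulated cylindrical source: an active column of
#' radioactive material between a front and a back shell layer, plus
#' the axial pitch at which successive capsules sit in a stacked
#' holder.  The pitch may exceed the physical capsule height; the
#' difference is an air gap behind each capsule (air attenuation is
#' neglected).
#'
#' @param active_material,shell_material [material_spec()] objects for
#'   the active column and the encapsulation shell.
#' @param active_height Height of the active column, cm.
#' @param shell_front_height,shell_back_height Shell layer thicknesses
#'   in front of and behind the active column, cm.
#' @param capsule_pitch Axial spacing between successive stacked
#'   capsules, cm.  Defaults to the layer sum
#'   `shell_front_height + active_height + shell_back_height`
#'   (a zero air gap), with a notice.
#' @param active_radius Radius of the active column, cm.  Used only by
#'   the Monte Carlo transport model; the closed-form model treats the
#'   source as a point on the axis.
#' @return An object of class `capsule_spec`.
#' @examples
#' fx <- leksell4c_fixture()
#' fx$capsule
#' @export
capsule_spec <- function(active_material, shell_material,
                         active_height, shell_front_height, shell_back_height,
                         capsule_pitch = NULL, active_radius = 0.05) {
  if (!inherits(active_material, "material_spec") ||
      !inherits(shell_material, "material_spec")) {
    abort_validation("`active_material` and `shell_material` must be material_spec objects")
  }
  check_number(active_height, "active_height", lower = 0, strict = TRUE)
  check_number(shell_front_height, "shell_front_height", lower = 0, strict = TRUE)
  check_number(shell_back_height, "shell_back_height", lower = 0, strict = TRUE)
  check_number(active_radius, "active_radius", lower = 0)
  layer_sum <- shell_front_height + active_height + shell_back_height
  if (is.null(capsule_pitch)) {
    capsule_pitch <- layer_sum
    message(sprintf("capsule_pitch not given; defaulting to the layer sum %g cm",
                    layer_sum))
  }
  check_number(capsule_pitch, "capsule_pitch", lower = 0, strict = TRUE)
  structure(list(active_material = active_material,
                 shell_material = shell_material,
                 active_height = as.numeric(active_height),
                 shell_front_height = as.numeric(shell_front_height),
                 shell_back_height = as.numeric(shell_back_height),
                 capsule_pitch = as.numeric(capsule_pitch),
                 active_radius = as.numeric(active_radius)),
            class = "capsule_spec")
}

#' @export
print.capsule_spec <- function(x, ...) {
  cat(sprintf(paste0("<capsule_spec> active %s %g cm (r = %g cm), shell %s ",
                     "%g/%g cm, pitch %g cm\n"),
              x$active_material$name, x$active_height, x$active_radius,
              x$shell_material$name, x$shell_front_height,
              x$shell_back_height, x$capsule_pitch))
  invisible(x)
}

#' Treatment-unit geometry
#'
#' @param source_focus_distance Distance from the reference source
#'   position (the source seated at the holder exit window) to the
#'   machine focus, cm.  Measured centre-of-source to focus.
#' @return An object of class `unit_geometry`.
#' @export
unit_geometry <- function(source_focus_distance) {
  check_number(source_focus_distance, "source_focus_distance",
               lower = 0, strict = TRUE)
  structure(list(source_focus_distance = as.numeric(source_focus_distance)),
            class = "unit_geometry")
}

#' @export
print.unit_geometry <- function(x, ...) {
  cat(sprintf("<unit_geometry> source-focus distance %g cm\n",
              x$source_focus_distance))
  invisible(x)
}

#' One source in a holder inventory
#'
#' @param id Source label; the schedulers use the batch-hyphen-index
#'   convention (e.g. `"1-2"` is the second source of the first batch).
#' @param install_epoch Number of half-lives elapsed when the source was
#'   installed.
#' @param initial_activity Activity at installation, as a fraction of a
#'   nominal new source.  Dummy (filler) sources have activity 0.
#' @param age Half-lives elapsed since installation.
#' @return An object of class `source_record`.
#' @export
source_record <- function(id, install_epoch = 0L, initial_activity = 1,
                          age = 0) {
  if (!is.character(id) || length(id) != 1L || is.na(id)) {
    abort_validation("`id` must be a single string")
  }
  install_epoch <- check_count(install_epoch, "install_epoch")
  check_number(initial_activity, "initial_activity", lower = 0)
  check_number(age, "age", lower = 0)
  structure(list(id = id, install_epoch = install_epoch,
                 initial_activity = as.numeric(initial_activity),
                 age = as.numeric(age)),
            class = "source_record")
}

#' Ordered stack of sources in one holder
#'
#' Index 1 of `sources` is the source at the holder exit window;
#' subsequent indices are progressively further from the focus
#' (position `n` in the correction formulas is `index - 1`).
#'
#' @param sources List of [source_record()] objects, possibly empty.
#' @param capsule A [capsule_spec()].
#' @param geometry A [unit_geometry()].
#' @return An object of class `stack_state`.
#' @export
stack_state <- function(sources = list(), capsule, geometry) {
  if (!is.list(sources) ||
      !all(vapply(sources, inherits, logical(1), "source_record"))) {
    abort_validation("`sources` must be a (possibly empty) list of source_record objects")
  }
  if (!inherits(capsule, "capsule_spec")) {
    abort_validation("`capsule` must be a capsule_spec")
  }
  if (!inherits(geometry, "unit_geometry")) {
    abort_validation("`geometry` must be a unit_geometry")
  }
  structure(list(sources = sources, capsule = capsule, geometry = geometry),
            class = "stack_state")
}

#' @export
print.stack_state <- function(x, ...) {
  cat(sprintf("<stack_state> %d source(s)\n", length(x$sources)))
  for (i in seq_along(x$sources)) {
    s <- x$sources[[i]]
    cat(sprintf("  position %d: %s  activity %.4f x 2^-%g\n",
                i - 1L, s$id, s$initial_activity, s$age))
  }
  invisible(x)
}

#' Cobalt-60 half-life
#'
#' The schedulers and correction formulas work in units of half-lives,
#' so no half-life constant enters any result.  This constant (years)
#' is provided solely for converting calendar time to half-lives.
#'
#' @format A single number, years.
#' @export
co60_half_life_years <- 5.2711

#' Convert calendar time to elapsed half-lives
#'
#' @param years Calendar time in years.
#' @param half_life Half-life in years; defaults to
#'   [co60_half_life_years].
#' @return Elapsed half-lives.
#' @export
years_to_half_lives <- function(years, half_life = co60_half_life_years) {
  check_number(years, "years", lower = 0, len = length(years))
  check_number(half_life, "half_life", lower = 0, strict = TRUE)
  years / half_life
}
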