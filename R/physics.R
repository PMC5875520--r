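#' Radioactive decay fraction after a number of half-lives
#'
#' @param age Elapsed time in half-lives (vectorised).  Must be
#'   non-negative.
#' @return `2^(-age)`, the remaining fraction of the initial activity.
#' @examples
#' decay_fraction(0:3)
#' @export
decay_fraction <- function(age) {
  check_number(age, "age", lower = 0, len = length(age))
  2^(-age)
}

#' Linear attenuation coefficient of a material
#'
#' The product of the mass attenuation coefficient and the (effective)
#' density, in 1/cm, governing narrow-beam exponential attenuation
#' `exp(-mu * l)` over a path length `l`.
#'
#' @param material A [material_spec()].
#' @return Linear attenuation coefficient, 1/cm.
#' @export
linear_attenuation <- function(material) {
  if (!inherits(material, "material_spec")) {
    abort_validation("`material` must be a material_spec")
  }
  material$mass_attenuation * material$density
}

#' Attenuation correction for a source stacked behind newer capsules
#'
#' A source with `n_front` full capsules between it and the exit window
#' is attenuated, in the narrow-beam primary-photon approximation, by
#' `exp(-mu_source * n * h_source) * exp(-mu_shell * n * h_shell)`,
#' where `h_shell` is the combined front and back shell thickness of
#' each front capsule.  Self-attenuation within the source's own
#' capsule cancels in the ratio to the reference position and is not
#' included.
#'
#' @param n_front Number of capsules in front of the source
#'   (non-negative integer, vectorised).
#' @param capsule A [capsule_spec()].
#' @return Transmission fraction in `(0, 1]`.
#' @examples
#' fx <- leksell4c_fixture()
#' attenuation_correction(1:3, fx$capsule)
#' @export
attenuation_correction <- function(n_front, capsule) {
  n_front <- check_count(n_front, "n_front")
  if (!inherits(capsule, "capsule_spec")) {
    abort_validation("`capsule` must be a capsule_spec")
  }
  mu_s <- linear_attenuation(capsule$active_material)
  mu_sh <- linear_attenuation(capsule$shell_material)
  h_shell <- capsule$shell_front_height + capsule$shell_back_height
  exp(-(mu_s * capsule$active_height + mu_sh * h_shell) * n_front)
}

#' Inverse-square distance correction for a pushed-back source
#'
#' Moving a source `n_front` capsule pitches behind the reference
#' position increases its distance to the focus from `d` to
#' `d + n * pitch`; by the inverse-square law its air-kerma rate at the
#' focus scales by `d^2 / (d + n * pitch)^2`.  The point-source formula
#' is accurate to about 0.1% whenever `d / h_source >= 5`
#' (see [point_source_validity()]).
#'
#' @inheritParams attenuation_correction
#' @param geometry A [unit_geometry()].
#' @return Fraction in `(0, 1]`.
#' @examples
#' fx <- leksell4c_fixture()
#' distance_correction(1:3, fx$capsule, fx$geometry)
#' @export
distance_correction <- function(n_front, capsule, geometry) {
  n_front <- check_count(n_front, "n_front")
  if (!inherits(capsule, "capsule_spec")) {
    abort_validation("`capsule` must be a capsule_spec")
  }
  if (!inherits(geometry, "unit_geometry")) {
    abort_validation("`geometry` must be a unit_geometry")
  }
  d <- geometry$source_focus_distance
  (d / (d + n_front * capsule$capsule_pitch))^2
}

#' Relative air-kerma strength of a stacked-back source
#'
#' Combines the attenuation and distance corrections into the total
#' relative air-kerma strength of a source with `n_front` newer
#' capsules in front of it, relative to the same source seated at the
#' exit window.
#'
#' @inheritParams distance_correction
#' @return A `correction_table` data frame with columns `n_front`,
#'   `attenuation`, `distance` and `total` (one row per element of
#'   `n_front`); `total` is exactly `attenuation * distance`.
#' @examples
#' fx <- leksell4c_fixture()
#' relative_air_kerma(0:3, fx$capsule, fx$geometry)
#' @export
relative_air_kerma <- function(n_front, capsule, geometry) {
  n_front <- check_count(n_front, "n_front")
  att <- attenuation_correction(n_front, capsule)
  dist <- distance_correction(n_front, capsule, geometry)
  structure(data.frame(n_front = n_front, attenuation = att,
                       distance = dist, total = att * dist),
            class = c("correction_table", "data.frame"))
}

#' Analytic transmission provider
#'
#' Returns a function mapping the number of front capsules to the total
#' (attenuation times distance) correction from the closed-form model;
#' the form the schedulers and [stack_focus_output()] consume.
#'
#' @inheritParams distance_correction
#' @return A function `f(n_front) -> fraction`.
#' @seealso [table_transmission()] for externally supplied factors
#'   (e.g. Monte Carlo results).
#' @export
analytic_transmission <- function(capsule, geometry) {
  force(capsule); force(geometry)
  function(n_front) relative_air_kerma(n_front, capsule, geometry)$total
}

#' Tabulated transmission provider
#'
#' Wraps externally supplied per-position total-correction factors
#' (for instance Monte Carlo estimates) as a transmission provider.
#' Position 0 defaults to 1 (the reference position) unless supplied.
#'
#' @param total Numeric vector of total corrections.
#' @param n_front Positions the values belong to; defaults to
#'   `seq_along(total)` (i.e. positions 1, 2, ...).
#' @return A function `f(n) -> fraction` that errors on positions not
#'   present in the table.
#' @examples
#' mc_row <- table_transmission(c(0.344, 0.122, 0.043))
#' mc_row(1)
#' @export
table_transmission <- function(total, n_front = seq_along(total)) {
  check_number(total, "total", lower = 0, len = length(total))
  n_front <- check_count(n_front, "n_front")
  if (length(total) != length(n_front) || anyDuplicated(n_front)) {
    abort_validation("`total` and `n_front` must have equal length and unique positions")
  }
  if (!0L %in% n_front) {
    n_front <- c(0L, n_front)
    total <- c(1, total)
  }
  function(n) {
    idx <- match(n, n_front)
    if (anyNA(idx)) {
      abort_validation(sprintf("no transmission entry for position(s) %s",
                               paste(n[is.na(idx)], collapse = ", ")))
    }
    total[idx]
  }
}

#' Focus output of a holder stack
#'
#' Sums the focus contributions of every source in a holder: each
#' source contributes its decayed activity times the total correction
#' for its position (position 0 at the exit window).
#'
#' @param stack A [stack_state()].
#' @param transmission A transmission provider, either
#'   [analytic_transmission()] (default, built from the stack's own
#'   capsule and geometry) or [table_transmission()].
#' @return Total focus output as a fraction of a nominal new source at
#'   the window.
#' @examples
#' fx <- leksell4c_fixture()
#' s <- stack_state(list(source_record("1-1", age = 1),
#'                       source_record("1-2", age = 1)),
#'                  fx$capsule, fx$geometry)
#' stack_focus_output(s, table_transmission(0.344))
#' @export
stack_focus_output <- function(stack, transmission = NULL) {
  if (!inherits(stack, "stack_state")) {
    abort_validation("`stack` must be a stack_state")
  }
  if (is.null(transmission)) {
    transmission <- analytic_transmission(stack$capsule, stack$geometry)
  }
  if (length(stack$sources) == 0L) return(0)
  ages <- vapply(stack$sources, `[[`, numeric(1), "age")
  act <- vapply(stack$sources, `[[`, numeric(1), "initial_activity")
  pos <- seq_along(stack$sources) - 1L
  sum(decay_fraction(ages) * act * transmission(pos))
}

#' Validity of the point-source inverse-square approximation
#'
#' The inverse-square law deviates from the finite-cylinder exposure
#' formula by no more than about 0.1% when the source-focus distance is
#' at least five times the active column height.
#'
#' @inheritParams distance_correction
#' @return A list of class `validity_report` with elements `ratio`
#'   (`d / active_height`), `threshold` (5) and `valid`.  An invalid
#'   geometry raises a warning, not an error.
#' @examples
#' fx <- leksell4c_fixture()
#' point_source_validity(fx$geometry, fx$capsule)
#' @export
point_source_validity <- function(geometry, capsule) {
  if (!inherits(geometry, "unit_geometry")) {
    abort_validation("`geometry` must be a unit_geometry")
  }
  if (!inherits(capsule, "capsule_spec")) {
    abort_validation("`capsule` must be a capsule_spec")
  }
  ratio <- geometry$source_focus_distance / capsule$active_height
  valid <- ratio >= 5
  if (!valid) {
    warning(sprintf(paste0("d/h_source = %.3g < 5: the point-source inverse-square ",
                           "approximation may deviate by more than 0.1%%"), ratio),
            call. = FALSE)
  }
  structure(list(ratio = ratio, threshold = 5, valid = valid),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> d/h_source = %.4g (threshold %g): %s\n",
              x$ratio, x$threshold, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}
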