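# Scenario bundles: a capsule + unit geometry + optional holder
# inventory, reproducible from a seed.  The packaged Leksell 4C set is
# the worked example every analysis stage defaults to.

new_scenario_bundle <- function(name, capsule, geometry, holders = list(),
                                epochs = 0L, seed = NA_integer_) {
  structure(list(name = name, capsule = capsule, geometry = geometry,
                 holders = holders, epochs = as.integer(epochs),
                 seed = seed),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("<scenario_bundle> %s (%d holder(s), %d epoch(s), seed %s)\n",
              x$name, length(x$holders), x$epochs, format(x$seed)))
  print(x$capsule)
  print(x$geometry)
  invisible(x)
}

#' The Leksell 4C Gamma Knife source parameter set
#'
#' The packaged worked example: a cobalt-60 pellet column (effective
#' density 5.88 g/cm^3, mass attenuation 0.0527 cm^2/g at 1.25 MeV) of
#' height 2 cm inside a stainless-steel capsule (7.85 g/cm^3,
#' 0.0535 cm^2/g) with 0.12 cm front and 0.49 cm back shell layers,
#' stacked at a 2.72 cm pitch, 40.1 cm from the focus.  The pitch
#' exceeds the capsule layer sum (2.61 cm) by a 0.11 cm air gap.
#'
#' @param active_radius Active column radius, cm.  No published value
#'   is asserted; the 0.05 cm default is a configurable stand-in used
#'   only by the Monte Carlo model and flagged in its reports.
#' @return A `scenario_bundle` with empty holders.
#' @examples
#' fx <- leksell4c_fixture()
#' relative_air_kerma(1:3, fx$capsule, fx$geometry)
#' @export
leksell4c_fixture <- function(active_radius = 0.05) {
  cobalt <- material_spec("cobalt-60 pellets", 0.0527, 5.88)
  steel <- material_spec("stainless steel", 0.0535, 7.85)
  capsule <- capsule_spec(cobalt, steel,
                          active_height = 2, shell_front_height = 0.12,
                          shell_back_height = 0.49, capsule_pitch = 2.72,
                          active_radius = active_radius)
  new_scenario_bundle("leksell4c", capsule, unit_geometry(40.1))
}

default_ranges <- function() {
  list(mass_attenuation = c(0.01, 0.2),   # cm^2/g
       density = c(0.5, 12),              # g/cm^3
       active_height = c(0.1, 5),         # cm
       shell_height = c(0.02, 0.5),       # cm (each layer)
       pitch_gap = c(0, 0.5),             # cm beyond the layer sum
       active_radius = c(0.01, 0.5),      # cm
       distance = c(10, 100))             # cm
}

check_range <- function(r, name) {
  if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2]) {
    abort_validation(sprintf("range `%s` must be numeric c(lo, hi) with lo <= hi",
                             name))
  }
  r
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

#' Generate a randomized physical scenario
#'
#' Draws a capsule, unit geometry and a small multi-epoch holder
#' inventory from the given ranges, reproducibly from the seed.  By
#' default the source-focus distance is kept at or above five active
#' heights so the point-source inverse-square model is valid;
#' `violate_validity = TRUE` deliberately draws below that threshold to
#' exercise the warning path.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param ranges Named list of `c(lo, hi)` ranges overriding (a subset
#'   of) the defaults: `mass_attenuation` (cm^2/g), `density` (g/cm^3),
#'   `active_height` (cm), `shell_height` (cm per layer), `pitch_gap`
#'   (cm beyond the layer sum), `active_radius` (cm), `distance` (cm).
#' @param violate_validity Draw `d / active_height < 5`?
#' @return A `scenario_bundle`.
#' @examples
#' b <- random_scenario(7)
#' point_source_validity(b$geometry, b$capsule)$valid
#' @export
random_scenario <- function(seed, ranges = list(), violate_validity = FALSE) {
  seed <- check_count(seed, "seed")
  if (!is.list(ranges) ||
      (length(ranges) > 0 && (is.null(names(ranges)) || any(names(ranges) == "")))) {
    abort_validation("`ranges` must be a named list of c(lo, hi) ranges")
  }
  rg <- default_ranges()
  unknown <- setdiff(names(ranges), names(rg))
  if (length(unknown)) {
    abort_validation(sprintf("unknown range name(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  rg[names(ranges)] <- ranges
  for (nm in names(rg)) check_range(rg[[nm]], nm)

  set.seed(seed)
  active <- material_spec("random active", runif_range(rg$mass_attenuation),
                          runif_range(rg$density))
  shell <- material_spec("random shell", runif_range(rg$mass_attenuation),
                         runif_range(rg$density))
  h <- runif_range(rg$active_height)
  capsule <- capsule_spec(active, shell,
                          active_height = h,
                          shell_front_height = runif_range(rg$shell_height),
                          shell_back_height = runif_range(rg$shell_height),
                          active_radius = runif_range(rg$active_radius))
  capsule$capsule_pitch <- capsule$capsule_pitch + runif_range(rg$pitch_gap)

  d_rg <- rg$distance
  if (violate_validity) {
    hi <- min(d_rg[2], 5 * h * 0.99)
    d <- stats::runif(1, hi / 2, hi)
  } else {
    lo <- max(d_rg[1], 5 * h)
    if (lo > d_rg[2]) {
      abort_validation("`distance` range cannot satisfy d/active_height >= 5; widen it or set violate_validity = TRUE")
    }
    d <- stats::runif(1, lo, d_rg[2])
  }
  geometry <- unit_geometry(d)

  n_holders <- sample(1:4, 1)
  holders <- lapply(seq_len(n_holders), function(hld) {
    n_src <- sample(0:4, 1)
    sources <- lapply(seq_len(n_src), function(i) {
      source_record(sprintf("%d-%d", hld, i),
                    install_epoch = sample(0:3, 1),
                    initial_activity = stats::runif(1, 0.1, 1.5),
                    age = sample(0:3, 1))
    })
    stack_state(sources, capsule, geometry)
  })
  new_scenario_bundle(sprintf("random-%d", seed), capsule, geometry,
                      holders = holders, epochs = sample(1:6, 1),
                      seed = seed)
}

#' Holder inventories over a replacement schedule
#'
#' Runs the chosen replacement scheme on the bundle's capsule and
#' geometry and returns the per-epoch holder contents as
#' [stack_state()] objects with batch-hyphen-index source ids,
#' together with the per-epoch actions (sources removed, moved and
#' added).
#'
#' @param bundle A `scenario_bundle`.
#' @param epochs Number of half-life boundaries (>= 1).
#' @param scheme `"push-back"` or `"combine-pairs"`.
#' @param transmission Transmission provider; defaults to the analytic
#'   one built from the bundle.
#' @param capacity Holder capacity for the push-back scheme.
#' @param n_holders Holder count for the pair-combining scheme.
#' @param target Target focus output (per holder).
#' @return A list of class `inventory_timeline`: per epoch, a list with
#'   `epoch`, `holders` (list of `stack_state`) and `action`; the
#'   originating `schedule_report` is in attribute `report`.
#' @examples
#' tl <- inventory_timeline(leksell4c_fixture(), 2, "combine-pairs")
#' tl[[3]]$holders
#' @export
inventory_timeline <- function(bundle, epochs, scheme = c("push-back", "combine-pairs"),
                               transmission = NULL, capacity = 4L,
                               n_holders = 4L, target = 1) {
  if (!inherits(bundle, "scenario_bundle")) {
    abort_validation("`bundle` must be a scenario_bundle")
  }
  scheme <- match.arg(scheme)
  if (is.null(transmission)) {
    transmission <- analytic_transmission(bundle$capsule, bundle$geometry)
  }
  report <- switch(scheme,
    "push-back" = push_back_schedule(epochs, transmission,
                                     capacity = capacity, target = target),
    "combine-pairs" = combine_pairs_schedule(epochs, transmission,
                                             n_holders = n_holders,
                                             target = target))
  out <- lapply(seq_along(report$states), function(i) {
    holders <- lapply(report$states[[i]], function(h) {
      sources <- lapply(seq_len(nrow(h)), function(j) {
        source_record(h$id[j], install_epoch = h$batch[j] - 1L,
                      initial_activity = h$initial_activity[j],
                      age = h$age[j])
      })
      stack_state(sources, bundle$capsule, bundle$geometry)
    })
    list(epoch = report$table$epoch[i], holders = holders,
         action = report$actions[[i]])
  })
  structure(out, class = "inventory_timeline", report = report)
}
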