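# Forced-detection Monte Carlo estimator of relative air kerma at the
# focus for stacked encapsulated cylindrical sources.  Primary photons
# only, mono-energetic 1.25 MeV; every history's contribution is the
# analytically attenuated inverse-square weight of its emission point
# toward the focus, so the only sampled quantity is the emission
# position and the estimator has very low variance.
#
# Axis convention: the stacking axis is z; the holder exit-window plane
# is z = 0, capsules extend toward positive z, and the focus sits on
# the axis at negative z such that the midpoint of the reference
# (window-seated) active column is exactly source_focus_distance from
# the focus.

#' Build the axial region model for a stacked-source channel
#'
#' Lays out `n_front` full capsules (front shell, active column, back
#' shell, air gap) along the axis in front of the emitting capsule.
#' The emitting capsule's own active column is flagged as the emission
#' region and excluded from attenuation (self-attenuation cancels
#' against the reference in the closed-form model); its shell layers
#' are kept as ordinary attenuating regions.  The pitch minus the
#' capsule layer sum is an air gap treated as vacuum; a negative gap is
#' a geometry error.
#'
#' @param capsule A [capsule_spec()].
#' @param geometry A [unit_geometry()].
#' @param n_front Number of capsules in front of the emitting one.
#' @return An object of class `geometry3d`: a data frame of regions
#'   (`material`, `mu`, `z0`, `z1`, `radius`, `role`) plus the
#'   emission region and the focus coordinate.
#' @examples
#' fx <- leksell4c_fixture()
#' build_geometry(fx$capsule, fx$geometry, 1)
#' @export
build_geometry <- function(capsule, geometry, n_front) {
  if (!inherits(capsule, "capsule_spec")) {
    abort_validation("`capsule` must be a capsule_spec")
  }
  if (!inherits(geometry, "unit_geometry")) {
    abort_validation("`geometry` must be a unit_geometry")
  }
  n_front <- check_count(n_front, "n_front")
  if (length(n_front) != 1L) abort_validation("`n_front` must be a single count")

  f <- capsule$shell_front_height
  a <- capsule$active_height
  b <- capsule$shell_back_height
  p <- capsule$capsule_pitch
  gap <- p - (f + a + b)
  if (gap < -1e-12) {
    abort_validation(sprintf(
      paste0("capsule_pitch %g cm is smaller than the layer sum ",
             "%g + %g + %g = %g cm (negative inter-capsule gap)"),
      p, f, a, b, f + a + b))
  }
  mu_sh <- linear_attenuation(capsule$shell_material)
  mu_src <- linear_attenuation(capsule$active_material)
  r <- capsule$active_radius

  one_capsule <- function(offset, role_active) {
    data.frame(
      material = c(capsule$shell_material$name, capsule$active_material$name,
                   capsule$shell_material$name),
      mu = c(mu_sh, mu_src, mu_sh),
      z0 = offset + c(0, f, f + a),
      z1 = offset + c(f, f + a, f + a + b),
      radius = r,
      role = c("shell", role_active, "shell"),
      stringsAsFactors = FALSE)
  }
  regions <- do.call(rbind, c(
    lapply(seq_len(n_front) - 1L, function(k) one_capsule(k * p, "active")),
    list(one_capsule(n_front * p, "emitter"))))

  # focus placed so the reference active-column midpoint is exactly d away
  focus_z <- (f + a / 2) - geometry$source_focus_distance
  if (focus_z >= 0) {
    abort_validation(sprintf(
      "source_focus_distance %g cm places the focus inside the holder",
      geometry$source_focus_distance))
  }
  emit <- regions[regions$role == "emitter", , drop = FALSE]
  structure(list(regions = regions,
                 emit = list(z0 = emit$z0, z1 = emit$z1, radius = r),
                 focus = c(0, 0, focus_z),
                 n_front = n_front, gap = gap,
                 capsule = capsule, unit = geometry),
            class = "geometry3d")
}

#' @export
print.geometry3d <- function(x, ...) {
  cat(sprintf("<geometry3d> %d front capsule(s), gap %g cm, focus at z = %g cm\n",
              x$n_front, x$gap, x$focus[3]))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Sample photon emission points in a cylindrical active region
#'
#' Uniform sampling over the cylinder volume, using the current R
#' random-number stream (callers seed it; all package entry points set
#' the seed themselves).  Degenerate (zero-radius or zero-height)
#' regions collapse to the corresponding point or disc.
#'
#' @param n Number of points.
#' @param radius Cylinder radius, cm.
#' @param z0,z1 Axial extent, cm.
#' @return An `n` x 3 matrix of (x, y, z) coordinates.
#' @export
sample_emission <- function(n, radius, z0, z1) {
  n <- check_count(n, "n")
  check_number(radius, "radius", lower = 0)
  r <- radius * sqrt(stats::runif(n))
  phi <- stats::runif(n, 0, 2 * pi)
  z <- if (z1 > z0) stats::runif(n, z0, z1) else rep(z0, n)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Chord lengths (cm) of segments p -> target inside one finite
# cylinder region (axis = z axis).  Vectorised over points.
region_chords <- function(pts, target, z0, z1, radius) {
  dx <- target[1] - pts[, 1]
  dy <- target[2] - pts[, 2]
  dz <- target[3] - pts[, 3]
  L <- sqrt(dx^2 + dy^2 + dz^2)

  # axial slab [z0, z1] in segment parameter t (0 at p, 1 at target)
  tz_a <- (z0 - pts[, 3]) / dz
  tz_b <- (z1 - pts[, 3]) / dz
  lo <- pmin(tz_a, tz_b)
  hi <- pmax(tz_a, tz_b)
  flat <- abs(dz) < 1e-300
  if (any(flat)) {
    inside <- pts[flat, 3] >= z0 & pts[flat, 3] <= z1
    lo[flat] <- ifelse(inside, 0, Inf)
    hi[flat] <- ifelse(inside, 1, -Inf)
  }

  # infinite cylinder of given radius: quadratic in t
  a <- dx^2 + dy^2
  bq <- 2 * (pts[, 1] * dx + pts[, 2] * dy)
  cq <- pts[, 1]^2 + pts[, 2]^2 - radius^2
  axial <- a < 1e-300
  disc <- bq^2 - 4 * a * cq
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-bq - sq) / (2 * a)
  t2 <- (-bq + sq) / (2 * a)
  r_lo <- ifelse(axial, ifelse(cq <= 0, -Inf, Inf), pmin(t1, t2))
  r_hi <- ifelse(axial, ifelse(cq <= 0, Inf, -Inf), pmax(t1, t2))
  r_lo[!axial & disc < 0] <- Inf
  r_hi[!axial & disc < 0] <- -Inf

  t_lo <- pmax(lo, r_lo, 0)
  t_hi <- pmin(hi, r_hi, 1)
  L * pmax(t_hi - t_lo, 0)
}

#' Optical depth of a ray through the region model
#'
#' Sums `mu * chord` over every attenuating region crossed by the
#' segment from each point to the target, by exact ray/finite-cylinder
#' intersection.  The emitting active region is excluded unless
#' `include_self = TRUE`.
#'
#' @param points An n x 3 matrix (or length-3 vector) of start points.
#' @param target Length-3 end point (typically the focus).
#' @param geometry3d A [build_geometry()] object.
#' @param include_self Include self-attenuation inside the emitting
#'   active column?  Default `FALSE`, matching the closed-form model
#'   which attenuates only by material in front of the source capsule.
#' @return Numeric vector of dimensionless optical depths (0 for rays
#'   missing every region).
#' @export
optical_depth <- function(points, target, geometry3d, include_self = FALSE) {
  if (!inherits(geometry3d, "geometry3d")) {
    abort_validation("`geometry3d` must come from build_geometry()")
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3L || length(target) != 3L) {
    abort_validation("`points` must be n x 3 and `target` length 3")
  }
  reg <- geometry3d$regions
  if (!include_self) reg <- reg[reg$role != "emitter", , drop = FALSE]
  tau <- numeric(nrow(points))
  for (i in seq_len(nrow(reg))) {
    if (reg$mu[i] == 0) next
    tau <- tau + reg$mu[i] *
      region_chords(points, target, reg$z0[i], reg$z1[i], reg$radius[i])
  }
  tau
}

# One forced-detection tally: mean and SE of exp(-tau)/r^2 over
# emission points, in chunks to bound memory.
forced_tally <- function(geom, histories, seed, chunk_size = 1e5) {
  set.seed(seed)
  total <- 0
  total_sq <- 0
  done <- 0
  while (done < histories) {
    m <- min(chunk_size, histories - done)
    pts <- sample_emission(m, geom$emit$radius, geom$emit$z0, geom$emit$z1)
    r2 <- (pts[, 1] - geom$focus[1])^2 + (pts[, 2] - geom$focus[2])^2 +
      (pts[, 3] - geom$focus[3])^2
    w <- exp(-optical_depth(pts, geom$focus, geom)) / r2
    total <- total + sum(w)
    total_sq <- total_sq + sum(w^2)
    done <- done + m
  }
  mean_w <- total / histories
  var_w <- max(total_sq / histories - mean_w^2, 0)
  list(mean = mean_w, se = sqrt(var_w / histories))
}

#' Monte Carlo estimate of the relative air kerma at the focus
#'
#' Forced-detection primary-photon estimator: emission points are
#' sampled uniformly in the emitting active column and each history
#' scores `exp(-optical_depth) / distance^2` toward the focus.  The
#' tally is normalised by the same estimator run on the reference
#' geometry (the same capsule seated at the exit window), giving the
#' relative air-kerma strength that the closed-form
#' [relative_air_kerma()] approximates for a point source.  The
#' standard error of the ratio combines the two tallies' sample
#' variances by the delta method.
#'
#' @inheritParams build_geometry
#' @param histories Number of histories per tally (>= 1).
#' @param seed Integer seed; the reference tally uses `seed + 1`.
#'   Identical (seed, histories, geometry) give bit-identical results.
#' @param chunk_size Histories per vectorised chunk (memory knob;
#'   does not affect the result).
#' @return An object of class `tally_result` with elements `mean`,
#'   `standard_error`, `histories`, `seed` and `n_front`.
#' @examples
#' fx <- leksell4c_fixture()
#' estimate_relative_kerma(fx$capsule, fx$geometry, 1, 1e4, seed = 42)
#' @export
estimate_relative_kerma <- function(capsule, geometry, n_front, histories,
                                    seed, chunk_size = 1e5) {
  histories <- check_count(histories, "histories")
  if (histories < 1L) abort_validation("`histories` must be >= 1")
  seed <- check_count(seed, "seed")
  g_n <- build_geometry(capsule, geometry, n_front)
  g_ref <- build_geometry(capsule, geometry, 0L)
  if (g_n$n_front == 0L) {
    # the reference geometry against itself: deterministically 1
    ratio <- 1
    se <- 0
  } else {
    num <- forced_tally(g_n, histories, seed, chunk_size)
    ref <- forced_tally(g_ref, histories, seed + 1L, chunk_size)
    ratio <- num$mean / ref$mean
    se <- ratio * sqrt((num$se / num$mean)^2 + (ref$se / ref$mean)^2)
  }
  structure(list(mean = ratio, standard_error = se,
                 histories = histories, seed = seed,
                 n_front = check_count(n_front, "n_front"),
                 active_radius = capsule$active_radius),
            class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf(paste0("<tally_result> n_front = %d: relative kerma %.6f ",
                     "+/- %.2g (%g histories, seed %d, source radius %g cm)\n"),
              x$n_front, x$mean, x$standard_error, x$histories, x$seed,
              x$active_radius))
  invisible(x)
}

#' Compare closed-form and Monte Carlo relative air kerma
#'
#' Runs [estimate_relative_kerma()] for each requested number of front
#' capsules and tabulates it against the closed-form
#' [relative_air_kerma()] totals, reporting absolute differences in
#' percentage points.
#'
#' @inheritParams estimate_relative_kerma
#' @param ns Numbers of front capsules to compare (non-empty).
#' @return A `mc_comparison` data frame with columns `n_front`,
#'   `analytic`, `mc_mean`, `mc_se` and `diff_pp`, with the maximum
#'   absolute difference in attribute `max_diff_pp`.
#' @examples
#' fx <- leksell4c_fixture()
#' mc_vs_analytic_table(fx$capsule, fx$geometry, 1:3, 1e4, seed = 42)
#' @export
mc_vs_analytic_table <- function(capsule, geometry, ns, histories, seed,
                                 chunk_size = 1e5) {
  ns <- check_count(ns, "ns")
  if (length(ns) == 0L) abort_validation("`ns` must be non-empty")
  seed <- check_count(seed, "seed")
  analytic <- relative_air_kerma(ns, capsule, geometry)$total
  tallies <- lapply(seq_along(ns), function(i) {
    estimate_relative_kerma(capsule, geometry, ns[i], histories,
                            seed + 2L * (i - 1L), chunk_size)
  })
  out <- data.frame(
    n_front = ns,
    analytic = analytic,
    mc_mean = vapply(tallies, `[[`, numeric(1), "mean"),
    mc_se = vapply(tallies, `[[`, numeric(1), "standard_error"))
  out$diff_pp <- abs(out$analytic - out$mc_mean) * 100
  structure(out, class = c("mc_comparison", "data.frame"),
            max_diff_pp = max(out$diff_pp),
            histories = histories, seed = seed)
}

#' @export
print.mc_comparison <- function(x, ...) {
  cat(sprintf("<mc_comparison> %g histories per tally, seed %d\n",
              attr(x, "histories"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("max |analytic - MC| = %.4g percentage points\n",
              attr(x, "max_diff_pp")))
  invisible(x)
}
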