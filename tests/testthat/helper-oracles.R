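# Independent oracles the implementation is checked against.

# Brute-force narrow-beam transmission: enumerate every layer a ray
# crosses through n front capsules and sum mu * l explicitly.
oracle_attenuation <- function(n, capsule) {
  mu_src <- capsule$active_material$mass_attenuation * capsule$active_material$density
  mu_sh <- capsule$shell_material$mass_attenuation * capsule$shell_material$density
  layers_mu <- c()
  layers_l <- c()
  for (k in seq_len(n)) {
    layers_mu <- c(layers_mu, mu_sh, mu_src, mu_sh)
    layers_l <- c(layers_l, capsule$shell_front_height, capsule$active_height,
                  capsule$shell_back_height)
  }
  exp(-sum(layers_mu * layers_l))
}

# Chord of a segment inside a finite cylinder by dense midpoint
# sampling of the inside indicator (independent of any intersection
# algebra).
oracle_chord <- function(p, q, z0, z1, radius, m = 2e5) {
  t <- (seq_len(m) - 0.5) / m
  x <- p[1] + t * (q[1] - p[1])
  y <- p[2] + t * (q[2] - p[2])
  z <- p[3] + t * (q[3] - p[3])
  inside <- z >= z0 & z <= z1 & (x^2 + y^2) <= radius^2
  sqrt(sum((q - p)^2)) * mean(inside)
}

# Replay a schedule_report's action log from scratch, tracking every
# source's holder, position, installed activity and installation
# epoch, and recompute each epoch's residual output independently.
oracle_replay_residuals <- function(report, transmission) {
  inv <- data.frame(id = character(), holder = integer(),
                    position = integer(), activity = numeric(),
                    add_epoch = numeric(), stringsAsFactors = FALSE)
  residuals <- numeric(length(report$actions))
  for (i in seq_along(report$actions)) {
    act <- report$actions[[i]]
    e <- act$epoch
    if (length(act$removed)) {
      inv <- inv[!inv$id %in% act$removed, , drop = FALSE]
    }
    if (nrow(act$moved)) {
      idx <- match(act$moved$id, inv$id)
      stopifnot(!anyNA(idx))
      inv$holder[idx] <- act$moved$to_holder
      inv$position[idx] <- act$moved$to_position
    }
    residuals[i] <- if (nrow(inv)) {
      sum(inv$activity * 2^(-(e - inv$add_epoch)) *
            vapply(inv$position, transmission, numeric(1)))
    } else 0
    if (nrow(act$added)) {
      inv <- rbind(inv, data.frame(id = act$added$id,
                                   holder = act$added$holder,
                                   position = act$added$position,
                                   activity = act$added$activity,
                                   add_epoch = e, stringsAsFactors = FALSE))
    }
  }
  residuals
}

# A random but physically shaped (decreasing-in-n) transmission
# provider for scheduler property tests.
random_transmission <- function() {
  t1 <- runif(1, 0.05, 0.95)
  decay <- runif(1, 0.2, 0.9)
  function(n) t1^ifelse(n == 0, 0, 1) * decay^pmax(n - 1, 0)
}

tiny_capsule <- function(mu_zero = FALSE, radius = 0) {
  # near-point active column inside a real steel shell: the
  # point-source limits of the transport model
  active <- material_spec("active", if (mu_zero) 0 else 0.0527,
                          if (mu_zero) 1 else 5.88)
  shell <- material_spec("shell", if (mu_zero) 0 else 0.0535,
                         if (mu_zero) 1 else 7.85)
  capsule_spec(active, shell, active_height = 1e-9,
               shell_front_height = 0.12, shell_back_height = 0.49,
               capsule_pitch = 2.72, active_radius = radius)
}
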