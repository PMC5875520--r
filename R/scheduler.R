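# Schedulers work in abstract epochs of exactly one half-life and are
# parameterised by a transmission provider (analytic_transmission() or
# table_transmission()), so the same machinery serves the closed-form
# and the Monte Carlo total-correction rows.

holder_output <- function(holder, transmission, position_offset = 0L) {
  if (nrow(holder) == 0L) return(0)
  sum(decay_fraction(holder$age) * holder$initial_activity *
        transmission(seq_len(nrow(holder)) - 1L + position_offset))
}

empty_holder <- function() {
  data.frame(id = character(), batch = integer(),
             initial_activity = numeric(), age = numeric(),
             stringsAsFactors = FALSE)
}

new_epoch_action <- function(epoch) {
  list(epoch = epoch, removed = character(),
       moved = data.frame(id = character(), from_holder = integer(),
                          from_position = integer(), to_holder = integer(),
                          to_position = integer(), stringsAsFactors = FALSE),
       added = data.frame(id = character(), activity = numeric(),
                          holder = integer(), position = integer(),
                          stringsAsFactors = FALSE))
}

#' Required new-source activity to restore a target output
#'
#' The maintenance condition of the staged-replacement schemes: a new
#' source must make up the difference between the target focus output
#' and the residual output of the sources kept in service.
#'
#' @param target Target focus output (fraction of nominal).
#' @param residual Residual output of retained sources.
#' @return `max(target - residual, 0)`.  A clamp (residual exceeding
#'   the target) is reported with a message.
#' @examples
#' required_new_activity(1, 0.172)
#' required_new_activity(2, 0.672)
#' @export
required_new_activity <- function(target, residual) {
  check_number(target, "target", lower = 0, strict = TRUE)
  check_number(residual, "residual", lower = 0)
  if (residual > target) {
    message(sprintf(paste0("residual output %.4g exceeds target %.4g; ",
                           "new activity clamped at 0"), residual, target))
    return(0)
  }
  target - residual
}

make_report <- function(scheme, table, actions, states, target, n_holders) {
  structure(list(scheme = scheme, target = target, n_holders = n_holders,
                 table = table, actions = actions, states = states),
            class = "schedule_report")
}

#' @export
print.schedule_report <- function(x, ...) {
  cat(sprintf("<schedule_report> scheme %s, %d holder(s), target %g\n",
              x$scheme, x$n_holders, x$target))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Push-back replacement schedule for a single-source holder
#'
#' The holder has `capacity` axial positions.  At installation (epoch
#' 0) one new source sits at the exit window with dummy fillers behind
#' it.  At every subsequent half-life boundary each source ages one
#' half-life and moves back one position (the source falling off the
#' last position is removed), and a new source is added at the window
#' with exactly the activity needed to restore the target output.
#'
#' @param epochs Number of half-life boundaries to simulate (>= 1).
#' @param transmission Transmission provider: a function mapping the
#'   number of front capsules to a total correction.
#' @param capacity Number of source positions in the holder.
#' @param target Target focus output, fraction of a nominal new source.
#' @return A `schedule_report` whose `table` has one row per epoch
#'   (including the installation epoch 0) with columns `epoch`,
#'   `residual_output`, `new_activity_total`, `new_activity_each`,
#'   `n_new`, `activity_saving` and `encapsulation_saving`.  At every
#'   epoch `residual_output + new_activity_total == target`.
#' @examples
#' fx <- leksell4c_fixture()
#' push_back_schedule(4, analytic_transmission(fx$capsule, fx$geometry))
#' @export
push_back_schedule <- function(epochs, transmission, capacity = 4L,
                               target = 1) {
  epochs <- check_count(epochs, "epochs")
  if (epochs < 1L) abort_validation("`epochs` must be >= 1")
  capacity <- check_count(capacity, "capacity")
  if (capacity < 1L) abort_validation("`capacity` must be >= 1")
  check_number(target, "target", lower = 0, strict = TRUE)
  if (!is.function(transmission)) {
    abort_validation("`transmission` must be a function of n_front")
  }

  holder <- empty_holder()
  rows <- vector("list", epochs + 1L)
  actions <- vector("list", epochs + 1L)
  states <- vector("list", epochs + 1L)

  for (e in 0:epochs) {
    act <- new_epoch_action(e)
    if (e > 0L) {
      holder$age <- holder$age + 1
      keep <- seq_len(nrow(holder)) <= (capacity - 1L)
      act$removed <- holder$id[!keep]
      if (any(keep)) {
        act$moved <- data.frame(id = holder$id[keep], from_holder = 1L,
                                from_position = which(keep) - 1L,
                                to_holder = 1L, to_position = which(keep),
                                stringsAsFactors = FALSE)
      }
      holder <- holder[keep, , drop = FALSE]
    }
    # pushed-back sources occupy positions 1..k; the vacancy at the
    # window (position 0) is filled by the new source below
    residual <- holder_output(holder, transmission,
                              position_offset = as.integer(e > 0L))
    new_act <- required_new_activity(target, residual)
    new_id <- sprintf("%d-1", e + 1L)
    holder <- rbind(data.frame(id = new_id, batch = e + 1L,
                               initial_activity = new_act, age = 0,
                               stringsAsFactors = FALSE),
                    holder)
    act$added <- data.frame(id = new_id, activity = new_act, holder = 1L,
                            position = 0L, stringsAsFactors = FALSE)
    rows[[e + 1L]] <- data.frame(
      epoch = e, residual_output = residual, new_activity_total = new_act,
      new_activity_each = new_act, n_new = 1L,
      activity_saving = residual / target, encapsulation_saving = 0)
    actions[[e + 1L]] <- act
    states[[e + 1L]] <- list(holder)
  }
  make_report("push-back", do.call(rbind, rows), actions, states,
              target, 1L)
}

# Restructure multisource holders at one half-life boundary:
# 4-deep holders are retired, the two oldest 2-deep holders merge into
# one 4-deep holder (newer batch in front), and used singles pair up.
combine_step <- function(holders, action) {
  depth <- vapply(holders, nrow, integer(1))

  for (i in which(depth >= 4L)) {
    action$removed <- c(action$removed, holders[[i]]$id)
    holders[[i]] <- empty_holder()
  }
  depth <- vapply(holders, nrow, integer(1))

  two_deep <- which(depth == 2L)
  while (length(two_deep) >= 2L) {
    batches <- vapply(two_deep, function(i) min(holders[[i]]$batch), integer(1))
    pick <- two_deep[order(batches)][1:2]   # oldest two batches merge
    newer <- pick[which.max(vapply(pick, function(i) min(holders[[i]]$batch),
                                   integer(1)))]
    older <- setdiff(pick, newer)
    action$moved <- rbind(action$moved, data.frame(
      id = holders[[older]]$id, from_holder = older,
      from_position = seq_len(2L) - 1L, to_holder = newer,
      to_position = 2:3, stringsAsFactors = FALSE))
    holders[[newer]] <- rbind(holders[[newer]], holders[[older]])
    holders[[older]] <- empty_holder()
    depth <- vapply(holders, nrow, integer(1))
    two_deep <- which(depth == 2L)
  }

  singles <- which(depth == 1L &
                     vapply(holders, function(h) nrow(h) == 1L && h$age[1] >= 1,
                            logical(1)))
  while (length(singles) >= 2L) {
    a <- singles[1]; b <- singles[2]
    action$moved <- rbind(action$moved, data.frame(
      id = holders[[b]]$id, from_holder = b, from_position = 0L,
      to_holder = a, to_position = 1L, stringsAsFactors = FALSE))
    holders[[a]] <- rbind(holders[[a]], holders[[b]])
    holders[[b]] <- empty_holder()
    singles <- singles[-(1:2)]
  }
  list(holders = holders, action = action)
}

#' Pair-combining replacement schedule for a multisource unit
#'
#' Models the staged scheme for multisource units (e.g. a Gamma Knife)
#' on rotating groups of four holders.  At installation every holder
#' carries one new source.  At each half-life boundary the previous
#' batch's single used sources are combined two per holder, pairs of
#' twice-used 2-deep holders merge into one 4-deep holder, and 4-deep
#' holders are retired.  The vacated holders (half as many as there
#' are holders) each receive a new source; the new activity restores
#' the target total output, so after the first combining each new
#' source carries more than nominal activity (132.8% for the packaged
#' fixture with the Monte Carlo transmission factor 0.344) and the
#' per-epoch encapsulation saving is 50%.
#'
#' @inheritParams push_back_schedule
#' @param n_holders Number of holders; must be a positive multiple of 4
#'   (the scheme rotates batches through groups of four holders; an odd
#'   count cannot pair at all).  Savings are per holder and independent
#'   of `n_holders`.
#' @param target Target focus output per holder.
#' @return A `schedule_report`; see [push_back_schedule()] for the
#'   table columns.  Conservation holds per epoch:
#'   `residual_output + new_activity_total == n_holders * target`.
#' @examples
#' combine_pairs_schedule(2, table_transmission(c(0.344, 0.122, 0.043)))
#' @export
combine_pairs_schedule <- function(epochs, transmission, n_holders = 4L,
                                   target = 1) {
  epochs <- check_count(epochs, "epochs")
  if (epochs < 1L) abort_validation("`epochs` must be >= 1")
  n_holders <- check_count(n_holders, "n_holders")
  if (n_holders %% 2L == 1L) {
    abort_validation("`n_holders` is odd: used sources cannot be paired")
  }
  if (n_holders < 4L || n_holders %% 4L != 0L) {
    abort_validation("`n_holders` must be a positive multiple of 4 (rotating groups of four holders)")
  }
  check_number(target, "target", lower = 0, strict = TRUE)
  if (!is.function(transmission)) {
    abort_validation("`transmission` must be a function of n_front")
  }

  holders <- replicate(n_holders, empty_holder(), simplify = FALSE)
  rows <- vector("list", epochs + 1L)
  actions <- vector("list", epochs + 1L)
  states <- vector("list", epochs + 1L)
  total_target <- n_holders * target

  for (e in 0:epochs) {
    act <- new_epoch_action(e)
    if (e > 0L) {
      holders <- lapply(holders, function(h) { h$age <- h$age + 1; h })
      st <- combine_step(holders, act)
      holders <- st$holders
      act <- st$action
    }
    residual <- sum(vapply(holders, holder_output, numeric(1), transmission))
    vacant <- which(vapply(holders, nrow, integer(1)) == 0L)
    n_new <- length(vacant)
    new_total <- required_new_activity(total_target, residual)
    each <- if (n_new > 0L) new_total / n_new else 0
    batch <- e + 1L
    for (k in seq_along(vacant)) {
      id <- sprintf("%d-%d", batch, k)
      holders[[vacant[k]]] <- data.frame(id = id, batch = batch,
                                         initial_activity = each, age = 0,
                                         stringsAsFactors = FALSE)
      act$added <- rbind(act$added, data.frame(
        id = id, activity = each, holder = vacant[k], position = 0L,
        stringsAsFactors = FALSE))
    }
    rows[[e + 1L]] <- data.frame(
      epoch = e, residual_output = residual, new_activity_total = new_total,
      new_activity_each = each, n_new = n_new,
      activity_saving = residual / total_target,
      encapsulation_saving = 1 - n_new / n_holders)
    actions[[e + 1L]] <- act
    states[[e + 1L]] <- holders
  }
  make_report("combine-pairs", do.call(rbind, rows), actions, states,
              target, n_holders)
}
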