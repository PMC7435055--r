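# Closed-form simulation of the three piecewise sub-models. Each regime of
# each model is a first-order linear ODE, so the piecewise solution is a
# chain of exponential relaxations anchored at the regime switch times.

actin_closed_form <- function(p, t) {
  a_tmin <- p$act_min + (p$act0 - p$act_min) * exp(-p$act_depoly1 * p$t_min)
  a_tmax <- p$act_max + (a_tmin - p$act_max) *
    exp(-p$act_poly * (p$t_max - p$t_min))
  out <- numeric(length(t))
  r1 <- t <= p$t_min
  r2 <- t > p$t_min & t <= p$t_max
  r3 <- t > p$t_max
  out[r1] <- p$act_min + (p$act0 - p$act_min) * exp(-p$act_depoly1 * t[r1])
  out[r2] <- p$act_max + (a_tmin - p$act_max) *
    exp(-p$act_poly * (t[r2] - p$t_min))
  out[r3] <- p$act_ss + (a_tmax - p$act_ss) *
    exp(-p$act_depoly2 * (t[r3] - p$t_max))
  out
}

dcd_closed_form <- function(p, t) {
  out <- numeric(length(t))
  pre <- t <= p$t_detach
  out[pre] <- p$dcd0 + p$k_stay * t[pre]
  d_detach <- p$dcd0 + p$k_stay * p$t_detach
  if (any(!pre)) {
    if (p$k_run == 0) {
      # degenerate: push term never engages, drift continues
      out[!pre] <- p$dcd0 + p$k_stay * t[!pre]
    } else {
      lim <- p$dcd_max + p$k_stay / p$k_run
      out[!pre] <- lim + (d_detach - lim) *
        exp(-p$k_run * (t[!pre] - p$t_detach))
    }
  }
  out
}

#' Simulate the actin channel
#'
#' Evaluates the closed-form solution of the three-regime actin model on a
#' sampling grid: decay from `act0` toward `act_min` (rate `act_depoly1`)
#' until `t_min`, saturating rise toward `act_max` (rate `act_poly`) until
#' `t_max`, then relaxation to `act_ss` (rate `act_depoly2`). The trajectory
#' is continuous at both switch times.
#'
#' @param params an [actin_params()] object.
#' @param grid a [time_grid()].
#' @param organoid_id,treatment labels attached to the output.
#' @return A trajectory data frame with columns `organoid_id`, `treatment`,
#'   `channel`, `time_min`, `value`.
#' @export
simulate_actin <- function(params, grid, organoid_id = "sim",
                           treatment = "control") {
  stopifnot(inherits(params, "actin_params"))
  t <- grid_times(grid)
  new_trajectory(organoid_id, treatment, "actin", t,
                 actin_closed_form(params, t))
}

#' Simulate the damaged-area channel
#'
#' Single-exponential repair DA(t) = da0 * exp(-k_repair * t).
#'
#' @inheritParams simulate_actin
#' @param params a [repair_params()] object.
#' @return A trajectory data frame.
#' @export
simulate_damaged_area <- function(params, grid, organoid_id = "sim",
                                  treatment = "control") {
  stopifnot(inherits(params, "repair_params"))
  t <- grid_times(grid)
  new_trajectory(organoid_id, treatment, "damaged_area", t,
                 params$da0 * exp(-params$k_repair * t))
}

#' Simulate the dead-cell-distance channel
#'
#' Linear drift dcd0 + k_stay * t until `t_detach`; afterwards relaxation to
#' the fixed point dcd_max + k_stay / k_run at rate `k_run`. When
#' `k_run = 0` the post-detachment regime degenerates and the linear drift
#' simply continues (no division by zero).
#'
#' @inheritParams simulate_actin
#' @param params an [exfoliation_params()] object.
#' @return A trajectory data frame.
#' @export
simulate_dead_cell <- function(params, grid, organoid_id = "sim",
                               treatment = "control") {
  stopifnot(inherits(params, "exfoliation_params"))
  t <- grid_times(grid)
  new_trajectory(organoid_id, treatment, "dead_cell_distance", t,
                 dcd_closed_form(params, t))
}

features_to_params <- function(features) {
  f <- features
  pick <- function(name, default = NULL) {
    v <- f[[name]]
    if (is.null(v) || is.na(v)) {
      if (is.null(default)) stop(sprintf("feature '%s' missing", name),
                                 call. = FALSE)
      default
    } else v
  }
  list(
    actin = actin_params(pick("act_depoly1"), pick("act_depoly2"),
                         pick("act_poly"), pick("act_max"), pick("act_min"),
                         pick("act_ss"), pick("t_min"), pick("t_max"),
                         act0 = pick("act0", 1.0)),
    repair = repair_params(pick("k_repair"), da0 = pick("da0", 100)),
    exfoliation = exfoliation_params(pick("k_stay"), pick("k_run"),
                                     pick("dcd_max"), pick("t_detach"),
                                     dcd0 = pick("dcd0", 0))
  )
}

#' Simulate all three channels of one organoid
#'
#' @param features named list (or one-row data frame) holding the 13 kinetic
#'   features, optionally with initial conditions `act0`, `da0`, `dcd0`.
#' @param grid a [time_grid()] shared by the three channels.
#' @param organoid_id,treatment labels attached to all three trajectories.
#' @return A data frame stacking the actin, damaged-area and
#'   dead-cell-distance trajectories on the shared grid.
#' @export
simulate_cell <- function(features, grid, organoid_id = "sim",
                          treatment = "control") {
  if (is.data.frame(features)) features <- as.list(features[1, , drop = FALSE])
  p <- features_to_params(features)
  rbind(
    simulate_actin(p$actin, grid, organoid_id, treatment),
    simulate_damaged_area(p$repair, grid, organoid_id, treatment),
    simulate_dead_cell(p$exfoliation, grid, organoid_id, treatment)
  )
}
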