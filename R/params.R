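# Parameter containers for the three piecewise sub-models and the shared
# sampling grid. Validation happens at construction so simulators can assume
# well-formed inputs.

#' Names of the 13 kinetic features of one organoid
#'
#' The per-organoid feature vector produced by the fitting stage: three actin
#' rate constants, three actin levels, the two actin timing events, the
#' damaged-area repair rate, and the four dead-cell exfoliation parameters.
#'
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("act_depoly1", "act_depoly2", "act_poly", "act_max", "act_min", "act_ss",
    "dcd_max", "k_repair", "k_run", "k_stay", "t_detach", "t_max", "t_min")
}

#' Predictor (actin) and response (cell-behavior) feature subsets
#'
#' The actin sub-model contributes eight features describing the molecular
#' response; the damaged-area and dead-cell sub-models contribute five
#' features describing cellular behavior. The machine-learning stage regresses
#' each behavior feature on the actin block.
#'
#' @return Character vector of feature names.
#' @export
actin_feature_names <- function() {
  c("act_depoly1", "act_depoly2", "act_poly", "act_max", "act_min", "act_ss",
    "t_min", "t_max")
}

#' @rdname actin_feature_names
#' @export
behavior_feature_names <- function() {
  c("k_repair", "t_detach", "k_stay", "k_run", "dcd_max")
}

#' Control-cohort reference statistics
#'
#' Mean and standard deviation of each kinetic feature across untreated
#' control organoids, with the units in which they are conventionally
#' reported. These are the defaults for the synthetic-cohort generator and
#' the reference point for the "average control cell".
#'
#' Note on units: the repair and run constants enter their equations as
#' first-order rates (1/min); the printed units reflect the measured channel
#' (area, distance) and are retained for reporting only.
#'
#' @return Data frame with columns `parameter`, `mean`, `sd`, `unit`.
#' @export
control_reference <- function() {
  data.frame(
    parameter = c("act_depoly1", "act_depoly2", "act_poly", "act_max",
                  "act_min", "act_ss", "dcd_max", "k_repair", "k_run",
                  "k_stay", "t_detach", "t_max", "t_min"),
    mean = c(6.024, 0.616, 0.191, 2.484, 0.696, 1.083, 10.507, 0.255, 0.462,
             0.035, 2.749, 5.534, 0.886),
    sd   = c(3.557, 0.39, 0.171, 0.944, 0.115, 0.168, 2.03, 0.08, 0.287,
             0.023, 1.134, 1.185, 0.726),
    unit = c("min^-1", "min^-1", "min^-1", "RLU", "RLU", "RLU", "um",
             "um^2 min^-1", "um min^-1", "um min^-1", "min", "min", "min"),
    stringsAsFactors = FALSE
  )
}

#' Mean control feature vector
#'
#' @param act0 initial actin level (RLU); baseline-normalized default 1.
#' @param da0 initial damaged area (um^2).
#' @param dcd0 initial dead-cell distance (um).
#' @return Named list with the 13 features plus the three initial conditions.
#' @export
control_mean_features <- function(act0 = 1.0, da0 = 100, dcd0 = 0) {
  ref <- control_reference()
  out <- as.list(stats::setNames(ref$mean, ref$parameter))
  out$act0 <- act0
  out$da0 <- da0
  out$dcd0 <- dcd0
  out
}

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Actin sub-model parameters
#'
#' Three-regime hybrid model of the GFP-actin signal after photodamage:
#' exponential decay toward `act_min` until `t_min`, saturating rise toward
#' the theoretical ceiling `act_max` until `t_max`, then exponential
#' relaxation to the steady state `act_ss`.
#'
#' @param act_depoly1 initial depolymerization rate (1/min), active on
#'   `[0, t_min]`.
#' @param act_depoly2 post-peak depolymerization rate (1/min), active after
#'   `t_max`.
#' @param act_poly polymerization rate (1/min), active on `[t_min, t_max]`.
#' @param act_max theoretical maximal actin level (RLU); may exceed the
#'   observed peak.
#' @param act_min minimal actin level (RLU).
#' @param act_ss steady-state actin level (RLU).
#' @param t_min time of the actin minimum (min).
#' @param t_max time of the actin peak (min).
#' @param act0 pre-damage actin level (RLU).
#' @return An object of class `actin_params`.
#' @export
actin_params <- function(act_depoly1, act_depoly2, act_poly, act_max, act_min,
                         act_ss, t_min, t_max, act0 = 1.0) {
  p <- list(act_depoly1 = act_depoly1, act_depoly2 = act_depoly2,
            act_poly = act_poly, act_max = act_max, act_min = act_min,
            act_ss = act_ss, t_min = t_min, t_max = t_max, act0 = act0)
  stop_if(any(!vapply(p, is.numeric, logical(1))) || any(!is.finite(unlist(p))),
          "actin parameters must be finite numerics")
  stop_if(act_depoly1 < 0 || act_depoly2 < 0 || act_poly < 0,
          "actin rate constants must be >= 0")
  stop_if(t_min < 0, "t_min must be >= 0")
  stop_if(t_max <= t_min, "t_max must be strictly greater than t_min")
  stop_if(act_min > act0, "act_min must not exceed the initial level act0")
  stop_if(act_min > act_ss || act_ss > act_max,
          "levels must satisfy act_min <= act_ss <= act_max")
  structure(p, class = "actin_params")
}

#' Damaged-area sub-model parameters
#'
#' Single-stage exponential repair: dDA/dt = -k_repair * DA.
#'
#' @param k_repair first-order repair rate; printed in um^2/min by convention.
#' @param da0 damaged area at t = 0 (um^2), the maximal damage size.
#' @return An object of class `repair_params`.
#' @export
repair_params <- function(k_repair, da0 = 100) {
  stop_if(!is.finite(k_repair) || k_repair < 0, "k_repair must be >= 0")
  stop_if(!is.finite(da0) || da0 <= 0, "da0 must be > 0")
  structure(list(k_repair = k_repair, da0 = da0), class = "repair_params")
}

#' Dead-cell-distance sub-model parameters
#'
#' Two-stage exfoliation: constant background drift at speed `k_stay` until
#' detachment at `t_detach`, after which the saturating push term
#' k_run * (dcd_max - DCD) switches on and the cell accelerates toward its
#' maximal distance.
#'
#' @param k_stay background drift speed (um/min).
#' @param k_run first-order push rate after detachment; printed in um/min.
#' @param dcd_max maximal dead-cell distance (um).
#' @param t_detach time at which the dead cell loses contact with its
#'   neighbors (min).
#' @param dcd0 distance at t = 0 (um); measured from the damage site.
#' @return An object of class `exfoliation_params`.
#' @export
exfoliation_params <- function(k_stay, k_run, dcd_max, t_detach, dcd0 = 0) {
  vals <- c(k_stay, k_run, dcd_max, t_detach, dcd0)
  stop_if(any(!is.finite(vals)), "exfoliation parameters must be finite")
  stop_if(k_stay < 0 || k_run < 0, "k_stay and k_run must be >= 0")
  stop_if(dcd_max <= 0, "dcd_max must be > 0")
  stop_if(t_detach < 0, "t_detach must be >= 0")
  structure(list(k_stay = k_stay, k_run = k_run, dcd_max = dcd_max,
                 t_detach = t_detach, dcd0 = dcd0),
            class = "exfoliation_params")
}

#' Regular sampling grid
#'
#' @param t_start first sample time (min, >= 0).
#' @param t_end last sample time (min).
#' @param dt sampling interval (min).
#' @return An object of class `time_grid`; `times(grid)` gives the sample
#'   times.
#' @export
time_grid <- function(t_start = 0, t_end = 20, dt = 0.5) {
  stop_if(!is.finite(t_start) || !is.finite(t_end) || !is.finite(dt),
          "grid fields must be finite")
  stop_if(t_start < 0, "t_start must be >= 0")
  stop_if(t_start >= t_end, "t_start must be < t_end")
  stop_if(dt <= 0, "dt must be > 0")
  structure(list(t_start = t_start, t_end = t_end, dt = dt),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid a `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  seq(grid$t_start, grid$t_end, by = grid$dt)
}

new_trajectory <- function(organoid_id, treatment, channel, times, values) {
  stop_if(!channel %in% c("actin", "damaged_area", "dead_cell_distance"),
          sprintf("unknown channel '%s'", channel))
  stop_if(length(times) != length(values),
          "times and values must have equal length")
  stop_if(any(diff(times) <= 0), "times must be strictly increasing")
  stop_if(any(!is.finite(values)), "trajectory values must be finite")
  structure(
    data.frame(organoid_id = organoid_id, treatment = treatment,
               channel = channel, time_min = times, value = values,
               stringsAsFactors = FALSE),
    class = c("trajectory", "data.frame")
  )
}
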