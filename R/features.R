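# Direct (non-fitted) feature extraction: the timing events and levels that
# are read straight off a trajectory, and the changepoint search for the
# detachment time.

traj_check <- function(traj, channel, min_points) {
  stopifnot(is.data.frame(traj),
            all(c("time_min", "value") %in% names(traj)))
  if (!is.null(channel) && "channel" %in% names(traj)) {
    stop_if(!all(traj$channel == channel),
            sprintf("expected a single '%s' trajectory", channel))
  }
  stop_if(nrow(traj) < min_points,
          sprintf("trajectory needs at least %d time points", min_points))
  stop_if(any(diff(traj$time_min) <= 0), "times must be strictly increasing")
  invisible(traj)
}

#' Extract actin timing and level features directly from data
#'
#' Locates the post-damage actin minimum and the subsequent peak, and reads
#' the steady-state level from the trajectory tail. The minimum is the global
#' minimum among samples preceding the global maximum; the peak is the global
#' maximum itself. Ties are broken by the earliest occurrence. The
#' steady-state level is the mean of the final `ss_window` samples.
#'
#' Trajectories without the expected dip-then-peak structure (constant or
#' monotone signals, or a peak on the grid boundary) are rejected as
#' non-conforming so the organoid can be flagged upstream.
#'
#' @param actin actin trajectory (data frame with `time_min`, `value`).
#' @param ss_window number of trailing samples averaged for `act_ss`.
#' @return List with `t_min`, `act_min`, `t_max`, `act_ss`, and the sample
#'   indices `i_min`, `i_max` of the two extrema.
#' @export
extract_timing_features <- function(actin, ss_window = 3) {
  traj_check(actin, "actin", 5)
  y <- actin$value
  t <- actin$time_min
  n <- length(y)
  i_max <- which.max(y)          # first occurrence on ties
  if (i_max <= 2L || i_max >= n)
    stop("non-conforming trajectory: no interior actin peak", call. = FALSE)
  i_min <- which.min(y[seq_len(i_max - 1L)])
  if (i_min <= 1L)
    stop("non-conforming trajectory: no initial actin decay", call. = FALSE)
  list(t_min = t[i_min], act_min = y[i_min], t_max = t[i_max],
       act_ss = mean(y[seq.int(n - min(ss_window, n) + 1L, n)]),
       i_min = i_min, i_max = i_max)
}

# Profiled least squares for y ~ offset + C * exp(-k (t - t0)). The linear
# coefficients are solved exactly for a given rate (variable projection), so
# the optimizers only search over the nonlinear rate. Rank deficiency at
# k = 0 (constant basis) is handled by the pivoted fit.
exp_profile_sse <- function(t, y, k, t0, with_offset = TRUE) {
  e <- exp(-k * (t - t0))
  x <- if (with_offset) cbind(1, e) else cbind(e)
  fit <- stats::lm.fit(x, y)
  list(sse = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Detect the dead-cell detachment time by changepoint search
#'
#' Exhaustive two-segment fit over candidate breakpoints on the observed
#' grid: before the candidate the trajectory is modeled as a straight line
#' (background drift), after it as a saturating exponential approach to a
#' plateau. The candidate minimizing the summed squared error of the two
#' segment fits is returned; ties go to the earliest candidate.
#'
#' @param dcd dead-cell-distance trajectory (>= 6 time points).
#' @param rate_upper upper bound (1/min) for the post-detachment rate used in
#'   the profile search.
#' @return List with `t_detach`, its sample `index`, the per-candidate total
#'   `sse`, and `boundary_flag` — `TRUE` when the optimum sits on the first
#'   or last admissible candidate (e.g. a cell that never detaches), in which
#'   case the estimate is not trustworthy.
#' @export
detect_detachment <- function(dcd, rate_upper = 50) {
  traj_check(dcd, "dead_cell_distance", 6)
  t <- dcd$time_min
  y <- dcd$value
  n <- length(y)
  # >= 2 points for the pre-detachment line, >= 3 after for the exponential
  cand <- seq.int(2L, n - 3L)
  sse <- vapply(cand, function(j) {
    pre <- seq_len(j)
    post <- seq.int(j + 1L, n)
    pre_fit <- stats::lm.fit(cbind(1, t[pre]), y[pre])
    post_sse <- stats::optimize(
      function(k) exp_profile_sse(t[post], y[post], k, t[j])$sse,
      lower = 1e-6, upper = rate_upper, tol = 1e-8)$objective
    sum(pre_fit$residuals^2) + post_sse
  }, numeric(1))
  best <- cand[which.min(sse)]
  list(t_detach = t[best], index = best, sse = sse,
       boundary_flag = best == cand[1] || best == cand[length(cand)])
}
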