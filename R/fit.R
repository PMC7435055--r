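# Segment-wise evolutionary least-squares fitting of the rate constants.
# Each regime of each sub-model is an exponential relaxation; the fits run
# on the samples strictly interior to a regime (the extremum samples sit
# nearest the switch and carry the most regime mixing), with linear
# coefficients profiled out so the evolutionary search is low-dimensional.

# collapse an (almost) unidentifiable rate to zero when the zero-rate model
# explains the segment at least as well
collapse_to_zero <- function(sse_fit, sse_zero) {
  sse_zero <= sse_fit * (1 + 1e-9) + 1e-12
}

fit_decay_rate <- function(t, y, t0, config) {
  obj <- function(par) exp_profile_sse(t, y, par[1], t0)$sse
  res <- de_optimize(obj, lower = 0, upper = config$rate_upper, config)
  flat_sse <- sum((y - mean(y))^2)
  if (collapse_to_zero(res$value, flat_sse)) {
    list(rate = 0, sse = flat_sse)
  } else {
    list(rate = res$par[1], sse = res$value)
  }
}

#' Fit the actin rate constants and theoretical maximum
#'
#' Fits each actin rate on its own regime, delimited by the extracted timing
#' features: `act_depoly1` on the initial decay (before the minimum),
#' `act_poly` jointly with `act_max` on the rise (minimum to peak), and
#' `act_depoly2` on the final relaxation (after the peak). Each segment fit
#' minimizes the sum of squared errors of the closed-form regime solution
#' with the seeded evolutionary optimizer; offsets and amplitudes are
#' profiled by exact linear least squares. `act_max` is a free ceiling
#' bounded between the observed peak and `act_max_factor` times the peak, so
#' it may exceed the highest observed value.
#'
#' @param actin actin trajectory.
#' @param timing output of [extract_timing_features()] for the same
#'   trajectory.
#' @param config a [fit_config()].
#' @return List with `act_depoly1`, `act_poly`, `act_depoly2`, `act_max`,
#'   the summed segment `sse`, and `flags` naming segments too short to fit
#'   (their rates are `NA`).
#' @export
fit_actin_rates <- function(actin, timing, config = fit_config()) {
  traj_check(actin, "actin", 5)
  t <- actin$time_min
  y <- actin$value
  n <- length(y)
  flags <- character(0)
  sse <- 0

  # initial decay: samples strictly before the minimum
  idx1 <- seq_len(timing$i_min - 1L)
  if (length(idx1) >= 2) {
    f1 <- fit_decay_rate(t[idx1], y[idx1], t[1], config)
    act_depoly1 <- f1$rate
    sse <- sse + f1$sse
  } else {
    act_depoly1 <- NA_real_
    flags <- c(flags, "actin_decay1_short")
  }

  # rise: samples strictly between minimum and peak; ceiling + rate searched
  # jointly, amplitude profiled
  idx2 <- if (timing$i_max - timing$i_min >= 2) {
    seq.int(timing$i_min + 1L, timing$i_max - 1L)
  } else integer(0)
  peak <- y[timing$i_max]
  if (length(idx2) >= 2) {
    t2 <- t[idx2]; y2 <- y[idx2]
    obj <- function(par) {
      e <- exp(-par[1] * (t2 - timing$t_min))
      c_hat <- sum(e * (y2 - par[2])) / sum(e * e)
      sum((y2 - par[2] - c_hat * e)^2)
    }
    res <- de_optimize(obj, lower = c(0, peak),
                       upper = c(config$rate_upper,
                                 config$act_max_factor * peak), config)
    flat_sse <- sum((y2 - mean(y2))^2)
    if (collapse_to_zero(res$value, flat_sse)) {
      act_poly <- 0
      act_max <- peak
      sse <- sse + flat_sse
    } else {
      act_poly <- res$par[1]
      act_max <- res$par[2]
      sse <- sse + res$value
    }
  } else {
    act_poly <- NA_real_
    act_max <- NA_real_
    flags <- c(flags, "actin_rise_short")
  }

  # final relaxation: samples strictly after the peak
  idx3 <- if (timing$i_max + 1L <= n) seq.int(timing$i_max + 1L, n) else integer(0)
  if (length(idx3) >= 2) {
    f3 <- fit_decay_rate(t[idx3], y[idx3], timing$t_max, config)
    act_depoly2 <- f3$rate
    sse <- sse + f3$sse
  } else {
    act_depoly2 <- NA_real_
    flags <- c(flags, "actin_decay2_short")
  }

  list(act_depoly1 = act_depoly1, act_poly = act_poly,
       act_depoly2 = act_depoly2, act_max = act_max, sse = sse,
       flags = flags)
}

#' Fit the damaged-area repair rate
#'
#' Minimizes the squared error of DA(t) = da0 * exp(-k_repair (t - t_1))
#' with the evolutionary optimizer, `da0` fixed to the first observation.
#' Non-positive observations (noise clipped at the detection floor) are
#' rejected from the fit; at least 3 positive samples must remain. On
#' noiseless data the estimate coincides with the log-linear regression
#' slope (see [loglinear_repair_rate()]), which serves as an independent
#' analytic cross-check.
#'
#' @param da damaged-area trajectory.
#' @param config a [fit_config()].
#' @return List with `k_repair` and the fit `sse`.
#' @export
fit_repair_rate <- function(da, config = fit_config()) {
  traj_check(da, "damaged_area", 3)
  da <- da[da$value > 0, , drop = FALSE]
  stop_if(nrow(da) < 3, "fewer than 3 positive damaged-area observations")
  y <- da$value
  t <- da$time_min - da$time_min[1]
  da0 <- y[1]
  obj <- function(par) sum((y - da0 * exp(-par[1] * t))^2)
  res <- de_optimize(obj, lower = 0, upper = config$rate_upper, config)
  if (collapse_to_zero(res$value, sum((y - da0)^2))) {
    list(k_repair = 0, sse = sum((y - da0)^2))
  } else {
    list(k_repair = res$par[1], sse = res$value)
  }
}

#' Analytic repair-rate estimate by log-linear regression
#'
#' Ordinary least squares of log(DA) on time; the negated slope estimates
#' `k_repair`. Used as the optimizer-independent oracle for
#' [fit_repair_rate()].
#'
#' @param da damaged-area trajectory with strictly positive values.
#' @return The slope-based rate estimate (1/min).
#' @export
loglinear_repair_rate <- function(da) {
  traj_check(da, "damaged_area", 3)
  da <- da[da$value > 0, , drop = FALSE]
  stop_if(nrow(da) < 3, "fewer than 3 positive damaged-area observations")
  -unname(stats::coef(stats::lm(log(value) ~ time_min, data = da))[2])
}

#' Fit the dead-cell exfoliation parameters
#'
#' `k_stay` is the ordinary least-squares slope of the pre-detachment
#' segment (clamped at zero). `k_run` and `dcd_max` come from an
#' evolutionary fit of the post-detachment relaxation toward the plateau
#' dcd_max + k_stay / k_run, with the amplitude profiled out.
#'
#' @param dcd dead-cell-distance trajectory.
#' @param t_detach detachment time, e.g. from [detect_detachment()].
#' @param config a [fit_config()].
#' @return List with `k_stay`, `k_run`, `dcd_max`, fit `sse`, and `flags`
#'   (e.g. a post-detachment segment too short to fit).
#' @export
fit_exfoliation <- function(dcd, t_detach, config = fit_config()) {
  traj_check(dcd, "dead_cell_distance", 6)
  t <- dcd$time_min
  y <- dcd$value
  pre <- which(t <= t_detach)
  post <- which(t > t_detach)
  flags <- character(0)
  stop_if(length(pre) < 2, "pre-detachment segment needs >= 2 points")
  pre_fit <- stats::lm.fit(cbind(1, t[pre]), y[pre])
  k_stay <- max(0, unname(pre_fit$coefficients[2]))
  sse <- sum(pre_fit$residuals^2)
  if (length(post) >= 3) {
    tp <- t[post]; yp <- y[post]
    ymax <- max(y)
    obj <- function(par) {
      lim <- par[2] + k_stay / par[1]
      e <- exp(-par[1] * (tp - t_detach))
      c_hat <- sum(e * (yp - lim)) / sum(e * e)
      sum((yp - lim - c_hat * e)^2)
    }
    res <- de_optimize(obj, lower = c(1e-4, 0.2 * ymax),
                       upper = c(config$rate_upper, 5 * ymax), config)
    k_run <- res$par[1]
    dcd_max <- res$par[2]
    sse <- sse + res$value
  } else {
    k_run <- NA_real_
    dcd_max <- NA_real_
    flags <- c(flags, "dcd_post_short")
  }
  list(k_stay = k_stay, k_run = k_run, dcd_max = dcd_max, sse = sse,
       flags = flags)
}

empty_feature_row <- function(organoid_id, treatment) {
  row <- as.data.frame(as.list(stats::setNames(rep(NA_real_, 13),
                                               feature_names())))
  row$organoid_id <- organoid_id
  row$treatment <- treatment
  row$sse_actin <- NA_real_
  row$sse_da <- NA_real_
  row$sse_dcd <- NA_real_
  row$flags <- ""
  row[, c("organoid_id", "treatment", feature_names(),
          "sse_actin", "sse_da", "sse_dcd", "flags")]
}

#' Fit the full feature vector of one organoid
#'
#' Composes the direct extractions ([extract_timing_features()],
#' [detect_detachment()]) and the segment fits ([fit_actin_rates()],
#' [fit_repair_rate()], [fit_exfoliation()]) into one row of the cohort
#' feature table. Sub-model failures do not abort the organoid: the affected
#' features are `NA` and the failure is recorded in `flags`.
#'
#' @param actin,da,dcd the organoid's three channel trajectories.
#' @param config a [fit_config()].
#' @param organoid_id,treatment labels for the output row; defaults are
#'   taken from the actin trajectory when present.
#' @return One-row data frame: `organoid_id`, `treatment`, the 13 features,
#'   per-channel SSE diagnostics and a semicolon-separated `flags` string.
#' @export
fit_cell <- function(actin, da, dcd, config = fit_config(),
                     organoid_id = NULL, treatment = NULL) {
  if (is.null(organoid_id))
    organoid_id <- if ("organoid_id" %in% names(actin))
      actin$organoid_id[1] else "cell"
  if (is.null(treatment))
    treatment <- if ("treatment" %in% names(actin))
      actin$treatment[1] else "control"
  row <- empty_feature_row(organoid_id, treatment)
  flags <- character(0)

  timing <- tryCatch(extract_timing_features(actin, config$ss_window),
                     error = function(e) e)
  if (inherits(timing, "error")) {
    flags <- c(flags, paste0("actin:", conditionMessage(timing)))
  } else {
    row$t_min <- timing$t_min
    row$act_min <- timing$act_min
    row$t_max <- timing$t_max
    row$act_ss <- timing$act_ss
    rates <- tryCatch(fit_actin_rates(actin, timing, config),
                      error = function(e) e)
    if (inherits(rates, "error")) {
      flags <- c(flags, paste0("actin:", conditionMessage(rates)))
    } else {
      row$act_depoly1 <- rates$act_depoly1
      row$act_poly <- rates$act_poly
      row$act_depoly2 <- rates$act_depoly2
      row$act_max <- rates$act_max
      row$sse_actin <- rates$sse
      flags <- c(flags, rates$flags)
    }
  }

  rep_fit <- tryCatch(fit_repair_rate(da, config), error = function(e) e)
  if (inherits(rep_fit, "error")) {
    flags <- c(flags, paste0("da:", conditionMessage(rep_fit)))
  } else {
    row$k_repair <- rep_fit$k_repair
    row$sse_da <- rep_fit$sse
  }

  det <- tryCatch(detect_detachment(dcd, config$rate_upper),
                  error = function(e) e)
  if (inherits(det, "error")) {
    flags <- c(flags, paste0("dcd:", conditionMessage(det)))
  } else {
    row$t_detach <- det$t_detach
    if (det$boundary_flag) flags <- c(flags, "dcd_boundary_changepoint")
    exf <- tryCatch(fit_exfoliation(dcd, det$t_detach, config),
                    error = function(e) e)
    if (inherits(exf, "error")) {
      flags <- c(flags, paste0("dcd:", conditionMessage(exf)))
    } else {
      row$k_stay <- exf$k_stay
      row$k_run <- exf$k_run
      row$dcd_max <- exf$dcd_max
      row$sse_dcd <- exf$sse
      flags <- c(flags, exf$flags)
    }
  }

  row$flags <- paste(flags, collapse = ";")
  row
}

#' Fit every organoid of a trajectory dataset
#'
#' Splits a tidy long-format trajectory table by organoid and fits each one
#' with [fit_cell()]. Organoids missing any of the three channels are
#' skipped with a message.
#'
#' @param trajectories tidy data frame with columns `organoid_id`,
#'   `treatment`, `channel`, `time_min`, `value`.
#' @param config a [fit_config()].
#' @return Cohort feature table: one row per fitted organoid.
#' @export
fit_cohort <- function(trajectories, config = fit_config()) {
  stopifnot(is.data.frame(trajectories))
  need <- c("organoid_id", "treatment", "channel", "time_min", "value")
  stop_if(!all(need %in% names(trajectories)),
          paste("trajectory table must have columns:",
                paste(need, collapse = ", ")))
  ids <- unique(trajectories$organoid_id)
  stop_if(length(ids) == 0, "no organoids in input")
  rows <- lapply(ids, function(id) {
    sub <- trajectories[trajectories$organoid_id == id, ]
    chans <- split(sub, sub$channel)
    missing <- setdiff(c("actin", "damaged_area", "dead_cell_distance"),
                       names(chans))
    if (length(missing)) {
      message(sprintf("skipping organoid '%s': missing channel(s) %s",
                      id, paste(missing, collapse = ", ")))
      return(NULL)
    }
    sort_traj <- function(x) x[order(x$time_min), ]
    fit_cell(sort_traj(chans$actin), sort_traj(chans$damaged_area),
             sort_traj(chans$dead_cell_distance), config)
  })
  out <- do.call(rbind, rows)
  stop_if(is.null(out) || nrow(out) == 0, "no organoid had all three channels")
  rownames(out) <- NULL
  out
}

#' Per-treatment summary of a cohort feature table
#'
#' Group mean and standard deviation of each kinetic feature, the summary
#' conventionally reported for a control cohort. Missing (flagged) values
#' are excluded pairwise.
#'
#' @param cohort a cohort feature table from [fit_cohort()].
#' @return Data frame with `treatment`, `parameter`, `mean`, `sd`, `n`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(is.data.frame(cohort), "treatment" %in% names(cohort))
  params <- intersect(feature_names(), names(cohort))
  do.call(rbind, lapply(split(cohort, cohort$treatment), function(g) {
    data.frame(treatment = g$treatment[1], parameter = params,
               mean = vapply(params, function(p)
                 mean(g[[p]], na.rm = TRUE), numeric(1)),
               sd = vapply(params, function(p)
                 stats::sd(g[[p]], na.rm = TRUE), numeric(1)),
               n = vapply(params, function(p)
                 sum(!is.na(g[[p]])), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
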