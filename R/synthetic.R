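# Synthetic cohort generator. Per-organoid parameters are drawn around the
# control reference statistics (truncated normal by default), treatment
# effects act multiplicatively on configured targets, an optional coupling
# makes behavior parameters linear functions of the actin peak time, and
# observation noise is added per channel. Ground truth is retained for every
# organoid so parameter-recovery experiments can score the pipeline.

#' Generator configuration for synthetic organoid cohorts
#'
#' @param n_per_group organoids per treatment group (controls included).
#' @param means,sds named per-parameter location and spread; defaults are
#'   the control reference statistics ([control_reference()]).
#' @param treatments named list: drug -> named vector of multiplicative
#'   effects on selected parameters (e.g. `list(drugA = c(k_stay = 0.5))`).
#' @param coupling optional coupling spec from [coupling_spec()] tying
#'   behavior parameters to `t_max`.
#' @param noise_sd per-channel additive Gaussian observation noise, named
#'   vector with entries `actin` (RLU), `damaged_area` (um^2),
#'   `dead_cell_distance` (um).
#' @param grid sampling grid; the default (0-20 min at 0.5 min) covers the
#'   full three-stage actin response at control-typical timing.
#' @param family distribution family for the parameter draws:
#'   `"truncnorm"` (normal truncated at a small positive floor) or
#'   `"lognormal"` (moment-matched, strictly positive).
#' @param act0,da0,dcd0 initial conditions shared by all cells.
#' @param seed RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 20,
                             means = NULL, sds = NULL,
                             treatments = list(),
                             coupling = NULL,
                             noise_sd = c(actin = 0.05, damaged_area = 2,
                                          dead_cell_distance = 0.2),
                             grid = time_grid(0, 20, 0.5),
                             family = c("truncnorm", "lognormal"),
                             act0 = 1.0, da0 = 100, dcd0 = 0,
                             seed = 1L) {
  family <- match.arg(family)
  ref <- control_reference()
  m <- stats::setNames(ref$mean, ref$parameter)
  s <- stats::setNames(ref$sd, ref$parameter)
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  stop_if(any(s < 0), "parameter sds must be >= 0")
  stop_if(n_per_group < 1, "n_per_group must be >= 1")
  for (tr in treatments) {
    stop_if(any(tr <= 0), "treatment multipliers must be > 0")
    stop_if(!all(names(tr) %in% feature_names()),
            "treatment multipliers reference unknown parameters")
  }
  ns <- c(actin = 0.05, damaged_area = 2, dead_cell_distance = 0.2)
  ns[names(noise_sd)] <- noise_sd
  stop_if(any(ns < 0), "noise sds must be >= 0")
  structure(list(n_per_group = n_per_group, means = m, sds = s,
                 treatments = treatments, coupling = coupling,
                 noise_sd = ns, grid = grid, family = family,
                 act0 = act0, da0 = da0, dcd0 = dcd0,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Coupling of behavior parameters to the actin peak time
#'
#' Generative device for planted-signal experiments: each listed response is
#' overwritten by `intercept + slope * t_max + eps`, with Gaussian residual
#' `eps`. `snr` expresses the residual scale as signal-to-noise: the sd of
#' `eps` is `|slope| * sd(t_max) / snr` (with `sd(t_max)` the configured
#' between-cell spread), so `snr = 3` plants a 3:1 signal.
#'
#' @param responses behavior parameters to couple.
#' @param intercept,slope named (or scalar, recycled) coefficients; default
#'   slope scales each response mean by the `t_max` mean so coupled values
#'   stay in a realistic range.
#' @param snr signal-to-noise ratio of the coupling.
#' @return List of class `coupling_spec`.
#' @export
coupling_spec <- function(responses = behavior_feature_names(),
                          intercept = 0, slope = NULL, snr = 3) {
  stop_if(!all(responses %in% feature_names()),
          "coupling references unknown parameter(s)")
  ref <- control_reference()
  m <- stats::setNames(ref$mean, ref$parameter)
  if (is.null(slope)) slope <- m[responses] / m[["t_max"]]
  slope <- rep_len(unlist(slope), length(responses))
  intercept <- rep_len(unlist(intercept), length(responses))
  stopifnot(snr > 0)
  structure(list(responses = responses,
                 intercept = stats::setNames(intercept, responses),
                 slope = stats::setNames(slope, responses), snr = snr),
            class = "coupling_spec")
}

#' Example treatment presets for the perturbation stage
#'
#' Named multiplier sets for a small drug panel, with directions chosen to
#' exercise the chord-edge analysis (e.g. the myosin inhibitor pair acts on
#' `k_stay` and `t_detach` at two strengths; the Rac1 inhibitor boosts
#' `k_repair`). Magnitudes are illustrative defaults for synthetic studies,
#' not measured effect sizes.
#'
#' @return Named list suitable for the `treatments` field of
#'   [generator_config()].
#' @export
treatment_presets <- function() {
  list(
    AMD3100 = c(t_detach = 1.6, act_depoly1 = 0.55),
    Blebbistatin_high = c(k_stay = 0.4, t_detach = 1.5, dcd_max = 0.7),
    Blebbistatin_low = c(k_stay = 0.65, t_detach = 1.25, dcd_max = 0.85),
    NSC23766 = c(k_repair = 1.7, t_max = 1.2, k_run = 0.75),
    ML141 = c(k_repair = 0.6, t_max = 1.3)
  )
}

draw_truncated <- function(n, mean, sd, floor_at, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  for (i in 1:100) {
    x <- stats::rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x > floor_at & x < upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop(sprintf(
    "truncation [%g, %g] infeasible for mean %g, sd %g", floor_at, upper,
    mean, sd), call. = FALSE)
}

draw_lognormal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

#' Draw per-organoid true parameter vectors for one group
#'
#' Independent truncated-normal (or moment-matched lognormal) draws per
#' parameter around the configured means/sds, a positivity floor on every
#' parameter, and `t_min` resampled to stay strictly below `t_max`. The
#' group's treatment multipliers are applied afterwards.
#'
#' Draws consume the caller's RNG stream; seed it (or use
#' [generate_cohort()], which seeds from the config) for reproducibility.
#'
#' @param config a [generator_config()].
#' @param group treatment label; `"control"` applies no multipliers.
#' @return Data frame of true feature vectors, one row per organoid, with
#'   `organoid_id` and `treatment` columns.
#' @export
sample_parameters <- function(config, group = "control") {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_per_group
  floor_at <- 1e-6
  draw <- function(p, upper = Inf) {
    if (config$family == "lognormal" && config$sds[[p]] > 0) {
      x <- draw_lognormal(n, config$means[[p]], config$sds[[p]])
      x[x >= upper] <- upper * 0.999  # lognormal has no hard upper bound
      x
    } else {
      draw_truncated(n, config$means[[p]], config$sds[[p]], floor_at, upper)
    }
  }
  cells <- as.data.frame(stats::setNames(
    lapply(feature_names(), function(p) {
      if (p == "t_min") return(rep(NA_real_, n))
      # the actin minimum cannot exceed the (shared) pre-damage baseline
      if (p == "act_min") return(draw(p, upper = config$act0))
      draw(p)
    }), feature_names()))
  # t_min drawn conditional on each cell's t_max to keep t_min < t_max
  cells$t_min <- vapply(cells$t_max, function(tm) {
    draw_truncated(1, config$means[["t_min"]], config$sds[["t_min"]],
                   floor_at, upper = 0.9 * tm)
  }, numeric(1))
  if (group != "control" && !is.null(config$treatments[[group]])) {
    mult <- config$treatments[[group]]
    for (p in names(mult)) cells[[p]] <- cells[[p]] * mult[[p]]
    bad <- cells$t_min >= cells$t_max
    cells$t_min[bad] <- 0.9 * cells$t_max[bad]
  }
  # keep level ordering act_min <= act_ss <= act_max (and act_min below the
  # baseline) so every cell is a valid three-stage responder
  cells$act_min <- pmin(cells$act_min, config$act0, cells$act_max)
  cells$act_ss <- pmin(pmax(cells$act_ss, cells$act_min), cells$act_max)
  cells$organoid_id <- sprintf("%s_%03d", group, seq_len(n))
  cells$treatment <- group
  cells[, c("organoid_id", "treatment", feature_names())]
}

#' Overwrite coupled behavior parameters as functions of `t_max`
#'
#' Applies the [coupling_spec()]: each coupled response becomes
#' `intercept + slope * t_max + eps` (floored at a small positive value so
#' the result remains a valid rate/level). Residuals are returned so the
#' planted signal can be audited.
#'
#' @param cells data frame of true feature vectors.
#' @param config a [generator_config()] whose `coupling` is set.
#' @return `cells` with coupled columns replaced; attribute `"residuals"`
#'   holds the per-response residual matrix.
#' @export
apply_coupling <- function(cells, config) {
  cp <- config$coupling
  if (is.null(cp)) return(cells)
  stopifnot(inherits(cp, "coupling_spec"))
  stop_if(!all(cp$responses %in% names(cells)),
          "coupling references unknown parameter(s)")
  sd_tmax <- config$sds[["t_max"]]
  resid <- matrix(0, nrow(cells), length(cp$responses),
                  dimnames = list(NULL, cp$responses))
  for (r in cp$responses) {
    eps_sd <- abs(cp$slope[[r]]) * sd_tmax / cp$snr
    eps <- stats::rnorm(nrow(cells), 0, eps_sd)
    resid[, r] <- eps
    cells[[r]] <- pmax(1e-6, cp$intercept[[r]] + cp$slope[[r]] * cells$t_max +
                         eps)
  }
  bad <- !is.na(cells$t_detach) & cells$t_detach >= 0.95 * max(grid_times(config$grid))
  cells$t_detach[bad] <- 0.95 * max(grid_times(config$grid))
  attr(cells, "residuals") <- resid
  cells
}

#' Generate a synthetic trajectory dataset with retained ground truth
#'
#' Draws true parameters per organoid ([sample_parameters()]), applies the
#' optional coupling, simulates the three channels on the shared grid with
#' the closed-form models, adds per-channel Gaussian observation noise
#' (area and distance clipped at zero), and returns both the tidy
#' trajectory table and the ground-truth feature table.
#'
#' @param config a [generator_config()].
#' @return List with `trajectories` (tidy long data frame), `truth` (true
#'   feature table incl. treatment), and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  groups <- c("control", names(config$treatments))
  truth <- do.call(rbind, lapply(groups, function(g)
    sample_parameters(config, g)))
  truth <- apply_coupling(truth, config)

  t <- grid_times(config$grid)
  ns <- config$noise_sd
  trajs <- lapply(seq_len(nrow(truth)), function(i) {
    feats <- as.list(truth[i, feature_names()])
    feats$act0 <- config$act0
    feats$da0 <- config$da0
    feats$dcd0 <- config$dcd0
    sim <- simulate_cell(feats, config$grid, truth$organoid_id[i],
                         truth$treatment[i])
    noise <- stats::rnorm(nrow(sim), 0,
                          unname(ns[match(sim$channel, names(ns))]))
    sim$value <- sim$value + noise
    clip <- sim$channel %in% c("damaged_area", "dead_cell_distance")
    sim$value[clip] <- pmax(0, sim$value[clip])
    sim
  })
  trajectories <- do.call(rbind, trajs)
  rownames(trajectories) <- NULL
  list(trajectories = trajectories, truth = truth, config = config)
}
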