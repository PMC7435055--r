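# Shared fixtures: control-average parameter objects and noiseless
# generator configurations. Everything is built in code at test time.

control_means <- function() {
  ref <- control_reference()
  as.list(stats::setNames(ref$mean, ref$parameter))
}

control_actin <- function(act0 = 1.0) {
  m <- control_means()
  actin_params(m$act_depoly1, m$act_depoly2, m$act_poly, m$act_max,
               m$act_min, m$act_ss, m$t_min, m$t_max, act0 = act0)
}

control_repair <- function(da0 = 100) {
  repair_params(control_means()$k_repair, da0 = da0)
}

control_exfoliation <- function() {
  m <- control_means()
  exfoliation_params(m$k_stay, m$k_run, m$dcd_max, m$t_detach)
}

zero_sds <- function() stats::setNames(rep(0, 13), feature_names())

no_noise <- function() {
  c(actin = 0, damaged_area = 0, dead_cell_distance = 0)
}

# noiseless, zero-variance cohort at the control means
noiseless_config <- function(n = 1, dt = 0.1, t_end = 20, seed = 1) {
  generator_config(n_per_group = n, sds = zero_sds(), noise_sd = no_noise(),
                   grid = time_grid(0, t_end, dt), seed = seed)
}

# random valid parameter draws for property-style loops
random_actin_params <- function() {
  t_min <- stats::runif(1, 0.3, 3)
  t_max <- t_min + stats::runif(1, 1, 6)
  act_min <- stats::runif(1, 0.2, 0.9)
  act_ss <- stats::runif(1, act_min, act_min + 1)
  act_max <- act_ss + stats::runif(1, 0.1, 3)
  actin_params(stats::runif(1, 0, 10), stats::runif(1, 0, 2),
               stats::runif(1, 0, 1), act_max, act_min, act_ss,
               t_min, t_max, act0 = stats::runif(1, act_min, 2))
}

random_repair_params <- function() {
  repair_params(stats::runif(1, 0, 1), da0 = stats::runif(1, 10, 200))
}

random_exfoliation_params <- function() {
  exfoliation_params(stats::runif(1, 0, 0.2), stats::runif(1, 0, 2),
                     stats::runif(1, 2, 20), stats::runif(1, 0.5, 8))
}
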