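# Synthetic cohort generator: determinism, distributional recovery,
# treatment effects, coupling, and structural validity of the trajectories.

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_per_group = 5, seed = 21,
                          treatments = list(d = c(k_stay = 0.5)))
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$trajectories, g2$trajectories)
  expect_identical(g1$truth, g2$truth)
})

test_that("zero variance collapses every cell onto the configured means", {
  gen <- generate_cohort(noiseless_config(n = 4, dt = 0.5))
  truth <- gen$truth
  ref <- control_reference()
  for (p in feature_names())
    expect_true(all(truth[[p]] == ref$mean[ref$parameter == p]))
})

test_that("sample means converge to the configured means (law of large numbers)", {
  cfg <- generator_config(n_per_group = 10000, seed = 2)
  set.seed(2)
  cells <- sample_parameters(cfg)
  se <- 0.08 / sqrt(10000)
  expect_lt(abs(mean(cells$k_repair) - 0.255), 2 * se)
  # truncation keeps everything positive and ordered
  expect_true(all(cells[feature_names()] > 0))
  expect_true(all(cells$t_min < cells$t_max))
  expect_true(all(cells$act_min <= cells$act_ss))
  expect_true(all(cells$act_ss <= cells$act_max))
})

test_that("lognormal family matches the first two moments", {
  cfg <- generator_config(n_per_group = 20000, family = "lognormal",
                          seed = 6)
  set.seed(6)
  cells <- sample_parameters(cfg)
  expect_equal(mean(cells$k_run), 0.462, tolerance = 0.02)
  expect_equal(stats::sd(cells$k_run), 0.287, tolerance = 0.05)
  expect_true(all(cells$k_run > 0))
})

test_that("treatment multipliers scale the targeted parameters", {
  cfg <- generator_config(n_per_group = 500, seed = 9,
                          treatments = list(drug = c(k_stay = 0.5,
                                                     t_max = 1.3)))
  set.seed(9)
  ctrl <- sample_parameters(cfg, "control")
  set.seed(9)
  drug <- sample_parameters(cfg, "drug")
  expect_equal(mean(drug$k_stay) / mean(ctrl$k_stay), 0.5,
               tolerance = 1e-10)
  expect_equal(mean(drug$t_max) / mean(ctrl$t_max), 1.3, tolerance = 1e-10)
  expect_equal(mean(drug$k_repair), mean(ctrl$k_repair))
})

test_that("coupling plants the configured linear signal", {
  cfg <- generator_config(n_per_group = 400,
                          coupling = coupling_spec(responses = "k_repair",
                                                   snr = 3), seed = 13)
  set.seed(13)
  cells <- sample_parameters(cfg)
  coupled <- apply_coupling(cells, cfg)
  r <- stats::cor(coupled$t_max, coupled$k_repair)
  expect_gt(r, 0.9)   # 3:1 signal-to-noise implies r ~ 0.95
  # zero slope reverts to pure noise around the intercept
  cfg0 <- cfg
  cfg0$coupling <- coupling_spec(responses = "k_repair", intercept = 0.3,
                                 slope = 0, snr = 3)
  # slope 0 makes the residual sd zero as well: constant response
  coupled0 <- apply_coupling(cells, cfg0)
  expect_true(all(coupled0$k_repair == 0.3))
  # noiseless nonzero slope: perfect correlation
  cfg1 <- cfg
  cfg1$coupling <- coupling_spec(responses = "k_repair", slope = 0.05,
                                 snr = 1e9)
  expect_equal(stats::cor(apply_coupling(cells, cfg1)$t_max,
                          apply_coupling(cells, cfg1)$k_repair), 1,
               tolerance = 1e-6)
  # unknown response is rejected
  expect_error(coupling_spec(responses = "nope"), "unknown")
})

test_that("zero-noise generation equals the closed-form simulation", {
  gen <- generate_cohort(noiseless_config(n = 1, dt = 0.5))
  feats <- control_mean_features()
  sim <- simulate_cell(feats, time_grid(0, 20, 0.5),
                       gen$truth$organoid_id[1], "control")
  expect_equal(gen$trajectories$value, sim$value, tolerance = 1e-12)
})

test_that("generated actin keeps the three-stage shape at typical values", {
  # the control-average cell has a clean dip-then-peak-then-relax shape
  gen <- generate_cohort(noiseless_config(n = 1, dt = 0.5))
  actin <- gen$trajectories[gen$trajectories$channel == "actin", ]
  tim <- extract_timing_features(actin)
  expect_lt(tim$t_min, tim$t_max)
  # a heterogeneous cohort mostly conforms; fast events can fall below the
  # 0.5-min sampling resolution, so a minority of cells is non-conforming
  gen2 <- generate_cohort(generator_config(n_per_group = 40,
                                           noise_sd = no_noise(), seed = 4))
  ok <- vapply(unique(gen2$trajectories$organoid_id), function(id) {
    a <- gen2$trajectories[gen2$trajectories$organoid_id == id &
                             gen2$trajectories$channel == "actin", ]
    !inherits(tryCatch(extract_timing_features(a), error = identity),
              "error")
  }, logical(1))
  expect_gt(mean(ok), 0.6)
})

test_that("invalid generator settings are rejected", {
  expect_error(generator_config(n_per_group = 0), "n_per_group")
  expect_error(generator_config(treatments = list(d = c(k_stay = -1))),
               "multipliers")
  expect_error(generator_config(treatments = list(d = c(bogus = 2))),
               "unknown")
  expect_error(generator_config(sds = c(k_repair = -1)), "sds")
})
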