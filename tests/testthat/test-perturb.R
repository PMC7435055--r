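# Percent-change matrix and chord-edge reduction.

make_cohort <- function(groups) {
  # groups: named list treatment -> named list of per-parameter means;
  # builds a degenerate cohort (every organoid at its group mean)
  rows <- lapply(names(groups), function(g) {
    base <- control_mean_features()
    base[names(groups[[g]])] <- groups[[g]]
    df <- as.data.frame(base[feature_names()])
    df <- df[rep(1, 4), ]
    df$organoid_id <- paste0(g, "_", 1:4)
    df$treatment <- g
    df
  })
  do.call(rbind, rows)
}

test_that("percent change is exact arithmetic on group means", {
  cohort <- make_cohort(list(
    control = list(k_repair = 0.2),
    drugA = list(k_repair = 0.3)
  ))
  pct <- percent_change_table(cohort, "control")
  expect_equal(unname(pct["drugA", "k_repair"]), 50)
  # identical groups give all-zero changes
  cohort2 <- make_cohort(list(control = list(), drugB = list()))
  expect_true(all(percent_change_table(cohort2, "control") == 0))
})

test_that("zero control means are reported as missing", {
  cohort <- make_cohort(list(control = list(), drugA = list()))
  cohort$k_stay[cohort$treatment == "control"] <- 0
  pct <- percent_change_table(cohort, "control")
  expect_true(is.na(pct["drugA", "k_stay"]))
})

test_that("missing control group is an error", {
  cohort <- make_cohort(list(drugA = list()))
  expect_error(percent_change_table(cohort, "control"), "control")
})

test_that("per-drug edges pick the extreme positive and negative changes", {
  pct <- matrix(c(10, -20, 5), nrow = 1,
                dimnames = list("drugA", c("t_max", "k_repair", "k_run")))
  edges <- max_effects_per_drug(pct)
  expect_equal(nrow(edges), 2)
  act <- edges[edges$direction == "activation", ]
  inh <- edges[edges$direction == "inhibition", ]
  expect_equal(act$parameter, "t_max")
  expect_equal(inh$parameter, "k_repair")
  expect_equal(inh$percent_change, -20)
  # all-positive row: a single activation edge
  allpos <- matrix(c(10, 20, 5), nrow = 1,
                   dimnames = list("drugB", c("a", "b", "c")))
  e2 <- max_effects_per_drug(allpos)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$direction, "activation")
  expect_equal(e2$parameter, "b")
})

test_that("edge counts are bounded by two per drug and per parameter", {
  set.seed(8)
  pct <- matrix(stats::rnorm(5 * 13, sd = 30), nrow = 5,
                dimnames = list(paste0("drug", 1:5), feature_names()))
  by_drug <- max_effects_per_drug(pct)
  counts <- table(by_drug$drug)
  expect_true(all(counts >= 1 & counts <= 2))
  by_par <- max_effects_per_parameter(pct)
  expect_true(all(table(by_par$parameter) <= 2))
  # direction always matches the sign
  expect_true(all((by_drug$percent_change > 0) ==
                    (by_drug$direction == "activation")))
})

test_that("a parameter moved one way by all drugs yields a single edge", {
  pct <- matrix(c(10, 20, -5, -8), nrow = 2,
                dimnames = list(c("d1", "d2"), c("t_max", "k_stay")))
  edges <- max_effects_per_parameter(pct)
  expect_equal(nrow(edges[edges$parameter == "t_max", ]), 1)
  expect_equal(edges$drug[edges$parameter == "t_max"], "d2")
  expect_equal(nrow(edges[edges$parameter == "k_stay", ]), 1)
  expect_equal(edges$drug[edges$parameter == "k_stay"], "d2")
  # symmetric effects in both directions: two edges
  pct2 <- matrix(c(15, -15), nrow = 2,
                 dimnames = list(c("d1", "d2"), "k_run"))
  expect_equal(nrow(max_effects_per_parameter(pct2)), 2)
})

test_that("ties resolve deterministically to the first column", {
  pct <- matrix(c(10, 10, -3), nrow = 1,
                dimnames = list("d", c("p1", "p2", "p3")))
  edges <- max_effects_per_drug(pct)
  expect_equal(edges$parameter[edges$direction == "activation"], "p1")
})

test_that("swapping treatment and control flips the sign structure", {
  cohort <- make_cohort(list(
    control = list(k_repair = 0.2, k_stay = 0.05),
    drugA = list(k_repair = 0.35, k_stay = 0.02)
  ))
  pct_fwd <- percent_change_table(cohort, "control")
  cohort_sw <- cohort
  cohort_sw$treatment <- ifelse(cohort$treatment == "control", "drugA",
                                "control")
  pct_rev <- percent_change_table(cohort_sw, "control")
  expect_true(all(sign(pct_rev) == -sign(pct_fwd)))
})

test_that("configured multipliers are recovered from a fitted cohort", {
  cfg <- generator_config(
    n_per_group = 4, sds = zero_sds(), noise_sd = no_noise(),
    grid = time_grid(0, 20, 0.1),
    treatments = list(drugX = c(k_stay = 0.5, k_repair = 1.4)), seed = 3)
  gen <- generate_cohort(cfg)
  cohort <- fit_cohort(gen$trajectories)
  pct <- percent_change_table(cohort, "control")
  expect_equal(unname(pct["drugX", "k_stay"]), -50, tolerance = 0.05)
  expect_equal(unname(pct["drugX", "k_repair"]), 40, tolerance = 0.05)
  edges <- max_effects_per_drug(pct)
  inh <- edges[edges$drug == "drugX" & edges$direction == "inhibition", ]
  expect_equal(inh$parameter, "k_stay")
})

test_that("chord edge CSV round-trips, including the empty case", {
  pct <- matrix(c(10, -20), nrow = 1, dimnames = list("d", c("a", "b")))
  edges <- max_effects_per_drug(pct)
  path <- tempfile(fileext = ".csv")
  export_chord_edges(edges, path)
  back <- read_chord_edges(path)
  expect_equal(back$source, edges$drug)
  expect_equal(back$target, edges$parameter)
  expect_equal(back$percent_change, edges$percent_change)
  # empty edge list: header-only file
  export_chord_edges(NULL, path)
  empty <- read_chord_edges(path)
  expect_equal(nrow(empty), 0)
  expect_setequal(names(empty),
                  c("source", "target", "percent_change", "direction"))
})
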