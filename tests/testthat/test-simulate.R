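# synthetic-data generator

test_that("the deterministic full-survival case has exact tree arithmetic", {
  sched <- event_schedule(c(2, 2))
  cfg <- simulation_config(sched, survival_params(sched, c(1, 1)), G = 5,
                           component_means = c(71, 90),
                           component_sds = c(4, 3), seed = 1)
  hist <- simulate_history(cfg)
  expect_equal(nrow(hist$leaves), 20)          # 4 genes per root
  expect_equal(sum(hist$pairs$event == 1), 5 * 4)
  expect_equal(sum(hist$pairs$event == 2), 5 * 2)
  sim <- emit_similarities(hist, cfg)
  expect_equal(profile_values(sim$truth_profile)[["t1,t1,t2"]], 5 * 4)
  expect_equal(sum(sim$truth_profile$value), 5 * choose(4, 3))
})

test_that("extinct-to-one histories have no pairs", {
  sched <- event_schedule(c(2, 2))
  cfg <- simulation_config(sched, survival_params(sched, c(0, 0)), G = 10,
                           component_means = c(71, 90),
                           component_sds = c(4, 3), seed = 2)
  hist <- simulate_history(cfg)
  expect_equal(nrow(hist$leaves), 10)
  expect_equal(nrow(hist$pairs), 0)
})

test_that("a fixed seed reproduces the simulation exactly", {
  cfg <- simulation_config(G = 500, seed = 33)
  a <- simulate_pairs(cfg)
  b <- simulate_pairs(cfg)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth_profile, b$truth_profile)
})

test_that("similarities follow the event components", {
  sched <- event_schedule(c(3, 2))
  cfg <- simulation_config(sched, survival_params(sched, c(0.3, 0.4)),
                           G = 3000, component_means = c(71, 90),
                           component_sds = c(4, 3), seed = 5)
  sim <- simulate_pairs(cfg)
  tp <- sim$truth_pairs
  for (e in 1:2) {
    xs <- tp$similarity[tp$event == e]
    mu <- cfg$component_means[e]; sd <- cfg$component_sds[e]
    expect_gt(length(xs), 1000)
    expect_lt(abs(mean(xs) - mu), 3 * sd / sqrt(length(xs)) + 0.02)
    expect_true(all(xs > 0 & xs <= 100))
  }

  # degenerate sd collapses each event onto its mean
  cfg0 <- simulation_config(sched, survival_params(sched, c(0.3, 0.4)),
                            G = 200, component_means = c(71, 90),
                            component_sds = c(1e-9, 1e-9), seed = 6)
  sim0 <- simulate_pairs(cfg0)
  expect_equal(unique(round(sim0$truth_pairs$similarity[sim0$truth_pairs$event == 1], 6)), 71)
})

test_that("empirical pair and triple frequencies converge to expectations", {
  sched <- event_schedule(c(3, 2))
  params <- survival_params(sched, c(0.3, 0.4))
  G <- 4000
  seeds <- 1:5
  pair_mat <- NULL; trip_mat <- NULL
  for (s in seeds) {
    cfg <- simulation_config(sched, params, G = G,
                             component_means = c(71, 90),
                             component_sds = c(4, 3), seed = s)
    sim <- simulate_pairs(cfg)
    hist_pairs <- table(factor(sim$truth_pairs$event, levels = 1:2))
    pair_mat <- rbind(pair_mat, as.numeric(hist_pairs) / G)
    trip_mat <- rbind(trip_mat, profile_values(sim$truth_profile) / G)
  }
  exp_pairs <- expected_pair_counts(sched, params)
  exp_prof <- profile_values(expected_triplet_profile(sched, params))
  for (j in 1:2) {
    se <- stats::sd(pair_mat[, j]) / sqrt(length(seeds))
    expect_lt(abs(mean(pair_mat[, j]) - exp_pairs[j]), 3 * se + 0.01)
  }
  for (j in seq_along(exp_prof)) {
    se <- stats::sd(trip_mat[, j]) / sqrt(length(seeds))
    expect_lt(abs(mean(trip_mat[, j]) - exp_prof[j]), 3 * se + 0.01)
  }
})

test_that("fixtures round-trip and contaminants are removed by the filter", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(G = 300, contaminant_rate = 0.2, seed = 9)
  paths <- make_fixture(cfg, dir)
  expect_true(all(file.exists(paths)))
  pairs <- expect_no_warning(read_pairs(paths[["pairs"]]))
  expect_gt(sum(pairs$similarity > 98), 0)
  kept <- filter_pairs(pairs, 50, 98)
  expect_equal(sum(kept$similarity > 98), 0)

  # regeneration with the same seed is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- make_fixture(cfg, dir2)
  expect_identical(readLines(paths[["pairs"]]), readLines(paths2[["pairs"]]))

  cfgj <- jsonlite::fromJSON(paths[["config"]])
  expect_equal(cfgj$schedule, c(3, 2))
  expect_equal(cfgj$seed, 9)
})

test_that("configuration validation catches inconsistent inputs", {
  sched <- event_schedule(c(3, 2))
  params <- survival_params(sched, c(0.3, 0.4))
  expect_error(simulation_config(sched, params, G = 10,
                                 component_means = c(90, 71),
                                 component_sds = c(4, 3), seed = 1),
               "increase")
  expect_error(simulation_config(sched, params, G = 10,
                                 component_means = c(71, 90),
                                 component_sds = c(4, -1), seed = 1),
               "positive")
  expect_error(simulation_config(sched, params, G = 10,
                                 component_means = c(71, 90),
                                 component_sds = c(4, 3)),
               "seed")
})
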