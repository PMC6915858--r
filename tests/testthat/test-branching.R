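# branching process: genealogy enumeration, trajectory probabilities,
# expected counts, survival-parameter estimation

test_that("genealogy enumeration covers the small single-event cases", {
  g2 <- enumerate_genealogies(event_schedule(2), survival_params(2, 0.5))
  expect_equal(nrow(g2), 2)
  expect_equal(sort(g2$weight), c(0.5, 0.5))
  expect_equal(sort(g2$n_leaves), c(1L, 2L))

  sched3 <- event_schedule(3)
  g3 <- enumerate_genealogies(sched3, survival_params(sched3, 0, surv3 = 1))
  expect_equal(sum(g3$weight > 0), 1)
  expect_equal(g3$n_leaves[g3$weight > 0], 3L)
  expect_equal(sum(g3$weight), 1)
})

test_that("genealogy weights sum to 1 and expectations match on a grid", {
  for (sched in list(c(2, 2), c(3, 2), c(2, 3), c(3, 3))) {
    for (params in param_grid(sched, values = c(0.1, 0.35, 0.55))) {
      g <- enumerate_genealogies(event_schedule(sched), params)
      expect_equal(sum(g$weight), 1, tolerance = 1e-12)
      expect_equal(sum(g$weight * g$n_leaves),
                   expected_gene_count(event_schedule(sched), params),
                   tolerance = 1e-12)
    }
  }
  # spec example: (2,2) with u = v = 0.5
  s <- event_schedule(c(2, 2))
  p <- survival_params(s, c(0.5, 0.5))
  expect_equal(expected_gene_count(s, p, "enumeration"), 2.25)
  expect_equal(expected_gene_count(s, p, "product"), 2.25)
})

test_that("trajectory probabilities follow the multinomial product form", {
  s2 <- event_schedule(2)
  p2 <- survival_params(s2, 0.5)
  expect_equal(trajectory_probability(s2, p2, list(c(1, 0))), 0.5)
  expect_equal(trajectory_probability(s2, p2, list(c(0, 1))), 0.5)

  s22 <- event_schedule(c(2, 2))
  p22 <- survival_params(s22, c(0.5, 0.5))
  expect_equal(trajectory_probability(s22, p22, list(c(0, 1), c(0, 2))), 0.125)

  # invalid counts rejected
  expect_error(trajectory_probability(s22, p22, list(c(0, 1), c(3, 0))),
               "identities")
  expect_error(trajectory_probability(s22, p22, list(c(1, 1), c(0, 1))),
               "identities")
})

test_that("trajectory probabilities sum to 1 and reproduce Eq. 3 expectations", {
  for (sched in list(c(2, 2), c(3, 2), c(3, 3))) {
    s <- event_schedule(sched)
    for (p in param_grid(sched, values = c(0.2, 0.45))) {
      trajs <- wgdtriplets:::all_trajectories(s)
      probs <- vapply(trajs, function(a) trajectory_probability(s, p, a),
                      numeric(1))
      expect_equal(sum(probs), 1, tolerance = 1e-12)
      leaves <- vapply(trajs, function(a) {
        sum(seq_along(a[[length(a)]]) * a[[length(a)]])
      }, numeric(1))
      expect_equal(sum(probs * leaves), expected_gene_count(s, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("triplet classification finds pairwise divergence events", {
  g <- deterministic_33()
  paths <- g$paths[[1]]
  expect_equal(nrow(paths), 9)
  in_lineage <- which(paths[, 1] == paths[1, 1])
  expect_equal(classify_triplet(paths, in_lineage[1:3]), c(2, 2, 2))
  one_each <- c(which(paths[, 1] == 1)[1], which(paths[, 1] == 2)[1],
                which(paths[, 1] == 3)[1])
  expect_equal(classify_triplet(paths, one_each), c(1, 1, 1))
  mixed <- c(in_lineage[1:2], which(paths[, 1] != paths[1, 1])[1])
  expect_equal(classify_triplet(paths, mixed), c(1, 1, 2))
  expect_error(classify_triplet(paths, c(1, 1, 2)), "distinct")
  expect_error(classify_triplet(paths, c(1, 2, 99)), "unknown")
})

test_that("brute-force profiles match the hand-derived small cases", {
  s22 <- event_schedule(c(2, 2))
  p22 <- survival_params(s22, c(0.5, 0.5))
  prof <- expected_triplet_profile(s22, p22, method = "enumeration")
  expect_equal(prof$value[prof$type == "t1,t1,t2"], 0.75)
  expect_equal(sum(prof$value), 0.75)

  s33 <- event_schedule(c(3, 3))
  p33 <- survival_params(s33, c(0, 0), surv3 = c(1, 1))
  prof33 <- expected_triplet_profile(s33, p33, method = "enumeration")
  expect_equal(
    unname(profile_values(prof33)),
    c(27, 54, 0, 3)
  )
  expect_equal(sum(prof33$value), choose(9, 3))
})

test_that("expected pair counts agree across routes and small cases", {
  s22 <- event_schedule(c(2, 2))
  p22 <- survival_params(s22, c(0.5, 0.5))
  expect_equal(expected_pair_counts(s22, p22),
               c(t1 = 1.125, t2 = 0.75))
  expect_equal(expected_pair_counts(s22, p22, method = "product"),
               c(t1 = 1.125, t2 = 0.75))
  expect_equal(unname(expected_pair_counts(event_schedule(2),
                                           survival_params(2, 0))), 0)
  s3 <- event_schedule(3)
  expect_equal(unname(expected_pair_counts(s3, survival_params(s3, 0, surv3 = 1))), 3)
  for (sched in list(c(3, 2), c(3, 3))) {
    for (p in param_grid(sched, values = c(0.15, 0.4))) {
      expect_equal(expected_pair_counts(event_schedule(sched), p),
                   expected_pair_counts(event_schedule(sched), p, method = "product"),
                   tolerance = 1e-12)
    }
  }
})

test_that("schedule and parameter validation rejects malformed input", {
  expect_error(event_schedule(c(2, 4)), "2 .* or 3|must be 2")
  expect_error(event_schedule(integer(0)), "at least one")
  expect_error(survival_params(event_schedule(c(2, 2)), c(0.5)), "one probability per event")
  expect_error(survival_params(event_schedule(3), 0.7, surv3 = 0.7), "outside")
  expect_error(enumerate_genealogies(event_schedule(c(2, 2)),
                                     survival_params(event_schedule(c(3, 2)),
                                                     c(0.2, 0.2))),
               "different event sequences")
  expect_error(shape_err <- wgdtriplets:::shape_table(c(2, 3, 3, 3), max_shapes = 100),
               "configurations")
})

test_that("estimation inverts exact expectations and flags boundaries", {
  s22 <- event_schedule(c(2, 2))
  truth <- survival_params(s22, c(0.3, 0.6))
  obs <- 1000 * expected_pair_counts(s22, truth, method = "product")
  genes <- 1000 * wgdtriplets:::expected_genes_per_root(truth, "all")
  fit <- estimate_survival_params(s22, obs, genes, genes = "all")
  expect_equal(fit$params$surv2, c(0.3, 0.6), tolerance = 1e-6)
  expect_equal(fit$G, 1000, tolerance = 1e-4)

  # same inversion under the paired-genes convention
  genes_p <- 1000 * wgdtriplets:::expected_genes_per_root(truth, "paired")
  fit_p <- estimate_survival_params(s22, obs, genes_p, genes = "paired")
  expect_equal(fit_p$params$surv2, c(0.3, 0.6), tolerance = 1e-6)

  # tripling with the squared constraint
  s33 <- event_schedule(c(3, 3))
  truth33 <- survival_params(s33, c(0.3, 0.4), squared = TRUE)
  obs33 <- 500 * expected_pair_counts(s33, truth33, method = "product")
  genes33 <- 500 * wgdtriplets:::expected_genes_per_root(truth33, "all")
  fit33 <- estimate_survival_params(s33, obs33, genes33, genes = "all")
  expect_equal(fit33$params$surv2, c(0.3, 0.4), tolerance = 1e-6)

  # all-zero young-event pairs pushes v to the boundary with a warning
  obs0 <- c(obs[1], 0)
  expect_warning(
    fit0 <- estimate_survival_params(s22, obs0, genes, genes = "all"),
    "boundary"
  )
  expect_lt(fit0$params$surv2[2], 1e-6)

  expect_error(estimate_survival_params(s22, c(0, 0), genes), "unidentifiable")
})

test_that("the Poisson-likelihood refinement agrees on exact data", {
  s32 <- event_schedule(c(3, 2))
  truth <- survival_params(s32, c(0.3, 0.4))
  obs <- 2000 * expected_pair_counts(s32, truth, method = "product")
  genes <- 2000 * wgdtriplets:::expected_genes_per_root(truth, "all")
  fit <- estimate_survival_params(s32, obs, genes, genes = "all", method = "ml")
  expect_equal(fit$params$surv2, c(0.3, 0.4), tolerance = 1e-4)
})
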