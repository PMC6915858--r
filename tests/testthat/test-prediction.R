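# predicted profiles, category probabilities, model ranking

# minimal constructors for mixture / covariance stand-ins
toy_mixture <- function(means, sds) {
  structure(list(
    components = tibble::tibble(
      component = seq_along(means), mean = means, sd = sds,
      proportion = rep(1 / length(means), length(means)),
      fixed = FALSE
    ),
    loglik = NA_real_, iterations = 0L, converged = TRUE, n = 0L
  ), class = "similarity_mixture")
}

toy_cov <- function(variances, covariances = rep(0, length(variances))) {
  structure(list(
    table = tibble::tibble(
      event = seq_along(variances), n_values = 100L,
      variance = variances, n_pairs = 50L,
      covariance = covariances, fallback = FALSE
    ),
    m = length(variances)
  ), class = "triplet_covariance")
}

test_that("category masses sum to 1 and factor for diagonal covariance", {
  mx <- toy_mixture(c(71, 90), c(4, 3))
  cv <- toy_cov(c(16, 9))
  cp <- category_probability(c(1, 1, 2), mx, cv, cutoffs = 80)
  expect_equal(sum(cp$mass), 1, tolerance = 1e-6)

  # diagonal structure: each ordered cell is a product of univariate terms
  p_obs112 <- cp$mass[cp$type == "t1,t1,t2"]
  p1_below <- pnorm(80, 71, 4); p2_above <- 1 - pnorm(80, 90, 3)
  p1_above <- 1 - p1_below; p2_below <- 1 - p2_above
  manual <- p1_below * p1_below * p2_above +
    2 * p1_below * p1_above * p2_below
  expect_equal(p_obs112, manual, tolerance = 1e-8)
})

test_that("category masses sum to 1 for random PSD covariance structures", {
  withr::with_seed(31, {
    for (i in 1:5) {
      mx <- toy_mixture(c(71, 90), runif(2, 2, 5))
      v <- runif(2, 4, 25)
      cv <- toy_cov(v, runif(2, -0.3, 0.6) * v)
      for (delta in list(c(1, 1, 1), c(1, 1, 2), c(2, 2, 2))) {
        cp <- quiet(category_probability(delta, mx, cv, cutoffs = 80))
        expect_equal(sum(cp$mass), 1, tolerance = 1e-6)
      }
    }
  })
})

test_that("a cutoff at the upper bound sends all mass to the oldest category", {
  mx <- toy_mixture(c(71, 90), c(1, 1))
  cv <- toy_cov(c(1, 1))
  cp <- category_probability(c(1, 1, 2), mx, cv, cutoffs = 100)
  expect_equal(cp$mass[cp$type == "t1,t1,t1"], 1, tolerance = 1e-6)
})

test_that("unrealizable types are rejected", {
  mx <- toy_mixture(c(71, 90), c(4, 3))
  cv <- toy_cov(c(16, 9))
  expect_error(category_probability(c(1, 2, 2), mx, cv, 80), "realizable")
})

test_that("raising the cutoff never decreases the all-oldest mass", {
  mx <- toy_mixture(c(71, 90), c(4, 3))
  cv <- toy_cov(c(16, 9), c(3, 2))
  last <- -1
  for (H in c(75, 80, 85, 92)) {
    cp <- category_probability(c(1, 1, 2), mx, cv, cutoffs = H)
    mass <- cp$mass[cp$type == "t1,t1,t1"]
    expect_gte(mass, last)
    last <- mass
  }
})

test_that("widely separated components make predicted equal underlying", {
  sched <- event_schedule(c(3, 2))
  params <- survival_params(sched, c(0.3, 0.4))
  mx <- toy_mixture(c(40, 95), c(1, 1))
  cv <- toy_cov(c(1, 1), c(0.2, 0.2))
  pred <- predicted_profile(sched, params, mx, cv, cutoffs = 70,
                            observed_total = 1000)
  under <- underlying_profile(sched, params, 1000)
  expect_lt(max(abs(pred$value - under$value)), 1e-6)
  expect_equal(sum(pred$value), 1000, tolerance = 1e-9)
})

test_that("overlapping components leak mass into structurally zero types", {
  sched <- event_schedule(c(2, 2))
  params <- survival_params(sched, c(0.4, 0.4))
  mx <- toy_mixture(c(71, 79), c(4, 4))
  cv <- toy_cov(c(16, 16))
  pred <- predicted_profile(sched, params, mx, cv,
                            cutoffs = 75, observed_total = 1000)
  under <- underlying_profile(sched, params, 1000)
  expect_equal(under$value[under$type == "t1,t1,t1"], 0)
  expect_gt(pred$value[pred$type == "t1,t1,t1"], 0)
})

test_that("profile comparison ranks and guards correctly", {
  obs <- new_profile(c(10, 60, 5, 25), 2, "observed")
  cand_exact <- new_profile(c(10, 60, 5, 25), 2, "predicted")
  cand_off <- new_profile(c(0, 75, 0, 25), 2, "predicted")
  cmp <- compare_profiles(obs, list(exact = cand_exact, off = cand_off))
  expect_equal(cmp$model[1], "exact")
  expect_equal(cmp$chisq[1], 0)
  expect_equal(cmp$l1[1], 0)
  # epsilon guard keeps zero-expectation cells finite
  expect_true(is.finite(cmp$chisq[2]))
  expect_equal(cmp$chisq[cmp$model == "off"],
               (10 - 0)^2 / 0.5 + (60 - 75)^2 / 75 + 5^2 / 0.5 + 0)

  bad <- new_profile(rep(10, 10), 3, "predicted")
  expect_error(compare_profiles(obs, list(bad = bad)), "mismatched")
  off_total <- new_profile(c(10, 60, 5, 30), 2, "predicted")
  expect_error(compare_profiles(obs, list(x = off_total)), "total")
})
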