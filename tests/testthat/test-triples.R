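# triangle extraction, observed profiles, covariance estimation

make_pairs <- function(edges, sims) {
  tibble::tibble(
    gene_a = pmin(edges[, 1], edges[, 2]),
    gene_b = pmax(edges[, 1], edges[, 2]),
    similarity = sims
  )
}

test_that("triangles are enumerated exactly once, deterministically", {
  tri <- extract_triples(make_pairs(cbind(c("a", "b", "a"), c("b", "c", "c")),
                                    c(80, 81, 82)))
  expect_equal(nrow(tri), 1)
  expect_equal(tri$gene_a, "a")
  expect_equal(tri$sim_ab, 80)
  expect_equal(tri$sim_bc, 81)

  expect_equal(nrow(extract_triples(make_pairs(cbind(c("a", "b"), c("b", "c")),
                                               c(80, 81)))), 0)

  clique <- t(utils::combn(c("a", "b", "c", "d"), 2))
  tri4 <- extract_triples(make_pairs(clique, 70 + seq_len(6)))
  expect_equal(nrow(tri4), choose(4, 3))

  expect_equal(nrow(extract_triples(make_pairs(clique, 70 + seq_len(6))[0, ])), 0)
})

test_that("triangle extraction matches brute force on random graphs", {
  for (seed in 1:3) {
    pairs <- withr::with_seed(seed, {
      genes <- sprintf("g%02d", 1:30)
      idx <- which(upper.tri(matrix(0, 30, 30)), arr.ind = TRUE)
      take <- sample(nrow(idx), 120)
      make_pairs(cbind(genes[idx[take, 1]], genes[idx[take, 2]]),
                 runif(120, 55, 95))
    })
    tri <- extract_triples(pairs)
    key <- paste(pairs$gene_a, pairs$gene_b)
    genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
    combos <- utils::combn(genes, 3)
    brute <- sum(vapply(seq_len(ncol(combos)), function(i) {
      g <- combos[, i]
      all(paste(c(g[1], g[1], g[2]), c(g[2], g[3], g[3])) %in% key)
    }, logical(1)))
    expect_equal(nrow(tri), brute)
  }
})

test_that("filtering commutes with triangle extraction", {
  pairs <- withr::with_seed(4, {
    genes <- sprintf("g%02d", 1:20)
    idx <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
    take <- sample(nrow(idx), 80)
    make_pairs(cbind(genes[idx[take, 1]], genes[idx[take, 2]]),
               runif(80, 40, 100))
  })
  f <- filter_pairs(pairs, 50, 98)
  a <- extract_triples(f)
  b <- extract_triples(pairs)
  b <- b[b$sim_ab > 50 & b$sim_ab <= 98 &
           b$sim_ac > 50 & b$sim_ac <= 98 &
           b$sim_bc > 50 & b$sim_bc <= 98, ]
  expect_equal(a, b)
})

test_that("observed profiles classify and collapse octants correctly", {
  tri <- tibble::tibble(
    gene_a = c("a", "d"), gene_b = c("b", "e"), gene_c = c("c", "f"),
    sim_ab = c(70, 90), sim_ac = c(72, 91), sim_bc = c(90, 92)
  )
  prof <- observed_profile(tri, cutoffs = 80)
  expect_equal(profile_values(prof),
               c("t1,t1,t1" = 0, "t1,t1,t2" = 1, "t1,t2,t2" = 0,
                 "t2,t2,t2" = 1))
  expect_equal(sum(prof$value), nrow(tri))

  # three-event classification with two cutoffs
  tri3 <- tibble::tibble(gene_a = "a", gene_b = "b", gene_c = "c",
                         sim_ab = 70, sim_ac = 80, sim_bc = 90)
  prof3 <- observed_profile(tri3, cutoffs = c(73, 85))
  expect_equal(prof3$value[prof3$type == "t1,t2,t3"], 1)
  expect_equal(sum(prof3$value), 1)

  # re-running is bit-identical
  expect_identical(observed_profile(tri, 80), observed_profile(tri, 80))
})

test_that("triplet covariance matches a direct two-pass computation", {
  tri <- tibble::tibble(
    gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4), gene_c = paste0("c", 1:4),
    sim_ab = c(70, 72, 68, 71),
    sim_ac = c(71, 69, 70, 73),
    sim_bc = c(90, 88, 91, 92)
  )
  cov <- quiet(estimate_triplet_covariance(tri, cutoffs = 80))
  tab <- cov$table

  # independent oracle: explicit loops over same-event values and pairs
  vals1 <- c(tri$sim_ab, tri$sim_ac)
  expect_equal(tab$variance[1], stats::var(vals1))
  px <- c(); py <- c()
  for (i in 1:4) {
    v <- c(tri$sim_ab[i], tri$sim_ac[i])  # the two event-1 similarities
    px <- c(px, v[1], v[2]); py <- c(py, v[2], v[1])
  }
  expect_equal(tab$covariance[1], stats::cov(px, py))

  # event 2 has one similarity per triple: variance defined, no pairs
  expect_equal(tab$variance[2], stats::var(tri$sim_bc))
  expect_equal(tab$covariance[2], 0)
  expect_equal(tab$n_pairs[2], 0L)
})

test_that("equal same-event similarities give zero variance and fallbacks log", {
  tri <- tibble::tibble(
    gene_a = paste0("a", 1:3), gene_b = paste0("b", 1:3), gene_c = paste0("c", 1:3),
    sim_ab = rep(70, 3), sim_ac = rep(70, 3), sim_bc = c(90, 91, 92)
  )
  cov <- quiet(estimate_triplet_covariance(tri, cutoffs = 80))
  expect_equal(cov$table$variance[1], 0)

  # an event with no data needs the mixture fallback
  tri2 <- tri[1:2, ]
  tri2$sim_bc <- c(70, 71)
  fit <- fit_mixture(two_component_sample(500, 500), 2)
  expect_message(
    cov2 <- estimate_triplet_covariance(tri2, cutoffs = 80, mixture = fit),
    "falling back"
  )
  expect_equal(cov2$table$variance[2], fit$components$sd[2]^2)
  expect_true(cov2$table$fallback[2])
  expect_error(quiet(estimate_triplet_covariance(tri2, cutoffs = 80)), "fallback")
})

test_that("assembled covariance matrices are symmetric PSD with zero cross-event terms", {
  tri <- tibble::tibble(
    gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5), gene_c = paste0("c", 1:5),
    sim_ab = c(70, 74, 68, 71, 69),
    sim_ac = c(71, 67, 73, 70, 72),
    sim_bc = c(90, 88, 91, 92, 89)
  )
  cov <- quiet(estimate_triplet_covariance(tri, cutoffs = 80))
  sig <- quiet(wgdtriplets:::assemble_sigma(c(1, 1, 2), cov))
  expect_equal(sig, t(sig))
  expect_identical(sig[1, 3], 0)
  expect_identical(sig[2, 3], 0)
  expect_gte(min(eigen(sig, symmetric = TRUE)$values), -1e-10)
})
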