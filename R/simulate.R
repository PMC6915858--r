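# Synthetic-data generator: the branching process over G independent root
# genes, followed by Gaussian similarity divergence per pair, emitted in
# the canonical pair-list format with ground-truth labels.

#' Simulation configuration
#'
#' The stated world of the generator: G root genes each undergo the
#' scheduled polyploidy events with the given survival probabilities; each
#' surviving pair's similarity is drawn from the normal component of its
#' event of origin (older event, lower mean).  Defaults mirror the package
#' worked example: a tripling followed by a doubling, u = 0.3, v = 0.4,
#' components N(71, 4) and N(90, 3), G = 20000.
#'
#' @param schedule An [event_schedule()] (default `(3,2)`).
#' @param params Matching [survival_params()] (default u = 0.3, v = 0.4
#'   with the squared constraint at triplings).
#' @param G Number of independent root genes.
#' @param component_means,component_sds Per-event similarity components,
#'   means ascending with event index (older = lower).
#' @param background_rate Expected number of spurious low-similarity pairs
#'   (uniform on (40, 60]) per root, joining random genes across roots.
#' @param contaminant_rate Expected number of near-identical contaminant
#'   pairs (uniform on (98, 100]) per root, emulating tandem/allelic pairs
#'   removed by the high exclusion cutoff.
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(schedule = event_schedule(c(3, 2)),
                              params = survival_params(schedule, c(0.3, 0.4)),
                              G = 20000,
                              component_means = c(71, 90),
                              component_sds = c(4, 3),
                              background_rate = 0,
                              contaminant_rate = 0,
                              seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    rlang::abort("`seed` is mandatory for reproducible simulation")
  }
  schedule <- check_consistent(schedule, params)
  m <- length(schedule)
  if (length(component_means) != m || length(component_sds) != m) {
    rlang::abort("need one similarity component per event")
  }
  if (any(diff(component_means) <= 0)) {
    rlang::abort("component means must increase with event index (older event = lower similarity)")
  }
  if (any(component_sds <= 0)) rlang::abort("component sds must be positive")
  if (G < 1) rlang::abort("`G` must be at least 1")
  structure(
    list(schedule = schedule, params = params, G = as.integer(G),
         component_means = as.numeric(component_means),
         component_sds = as.numeric(component_sds),
         background_rate = background_rate,
         contaminant_rate = contaminant_rate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate genealogies for G root genes
#'
#' Draws G independent realizations of the branching process and labels
#' every extant within-root gene pair by its divergence event (the first
#' event at which the two lineages separate).
#'
#' @param config A [simulation_config()].
#' @return List with `leaves` (tibble: `gene`, `root`, ancestor path
#'   columns `a1..am`), `pairs` (tibble: `gene_a`, `gene_b`, `root`,
#'   `event`) and the config.
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  r <- unclass(config$schedule)
  m <- length(r)
  G <- config$G
  withr::with_seed(config$seed, {
    root <- seq_len(G)
    paths <- matrix(integer(0), nrow = G, ncol = 0)
    for (i in seq_len(m)) {
      n <- length(root)
      j <- sample.int(r[i], n, replace = TRUE, prob = config$params$p[[i]])
      rep_idx <- rep.int(seq_len(n), j)
      child <- sequence(j)
      root <- root[rep_idx]
      paths <- cbind(paths[rep_idx, , drop = FALSE], child)
    }
  })
  ord <- order(root)
  root <- root[ord]
  paths <- paths[ord, , drop = FALSE]
  colnames(paths) <- paste0("a", seq_len(m))
  n_leaf <- length(root)
  idx_in_root <- sequence(rle(root)$lengths)
  gene <- sprintf("g%07d_%02d", root, idx_in_root)

  # all within-root leaf pairs, via cached index templates per root size
  sizes <- rle(root)$lengths
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  i1 <- integer(0); i2 <- integer(0)
  for (n in unique(sizes[sizes >= 2])) {
    cmb <- utils::combn(n, 2)
    st <- starts[sizes == n]
    i1 <- c(i1, rep(cmb[1, ], times = length(st)) +
              rep(st - 1L, each = ncol(cmb)))
    i2 <- c(i2, rep(cmb[2, ], times = length(st)) +
              rep(st - 1L, each = ncol(cmb)))
  }
  if (length(i1) > 0) {
    eq <- rep(TRUE, length(i1))
    event <- rep(1L, length(i1))
    for (l in seq_len(m)) {
      same <- paths[i1, l] == paths[i2, l]
      event <- event + (eq & same)
      eq <- eq & same
    }
    a <- pmin(gene[i1], gene[i2])
    b <- pmax(gene[i1], gene[i2])
    pairs <- tibble::tibble(gene_a = a, gene_b = b,
                            root = root[i1], event = event)
  } else {
    pairs <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                            root = integer(0), event = integer(0))
  }
  list(
    leaves = tibble::tibble(gene = gene, root = root,
                            tibble::as_tibble(paths)),
    pairs = pairs,
    config = config
  )
}

#' Attach similarities and assemble the simulated pair list
#'
#' Draws each labelled pair's similarity from its event's normal component
#' truncated to (0, 100] (redrawn up to 100 times, then clamped), appends
#' any background / contaminant pairs, and returns the pair list plus
#' truth tables.
#'
#' @param history Output of [simulate_history()].
#' @param config The same [simulation_config()].
#' @return List with `pairs` (tibble `gene_a`, `gene_b`, `similarity`),
#'   `truth_pairs` (adds `event`; background/contaminant rows have event
#'   `NA`), `truth_profile` (observed triple types under the true labels)
#'   and the config.
#' @export
emit_similarities <- function(history, config) {
  m <- length(config$schedule)
  pairs <- history$pairs
  withr::with_seed(config$seed + 1L, {
    sim <- rtrunc_normal(config$component_means[pairs$event],
                         config$component_sds[pairs$event])
    extra <- simulate_extra_pairs(history$leaves$gene, config)
  })
  truth <- tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    similarity = sim, event = pairs$event
  )
  truth <- dplyr::bind_rows(truth, extra)
  truth_profile <- truth_triple_profile(history, truth, m)
  list(
    pairs = truth[, c("gene_a", "gene_b", "similarity")],
    truth_pairs = truth,
    truth_profile = truth_profile,
    config = config
  )
}

rtrunc_normal <- function(mu, sd, lo = 0, hi = 100, max_redraw = 100) {
  x <- stats::rnorm(length(mu), mu, sd)
  for (i in seq_len(max_redraw)) {
    bad <- x <= lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  }
  pmin(pmax(x, lo + 1e-6), hi)
}

simulate_extra_pairs <- function(genes, config) {
  out <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                        similarity = numeric(0), event = integer(0))
  n_bg <- stats::rpois(1, config$background_rate * config$G)
  n_ct <- stats::rpois(1, config$contaminant_rate * config$G)
  draw <- function(n, lo, hi) {
    if (n == 0 || length(genes) < 2) return(NULL)
    a <- sample(genes, n, replace = TRUE)
    b <- sample(genes, n, replace = TRUE)
    keep <- a != b
    tibble::tibble(gene_a = pmin(a[keep], b[keep]),
                   gene_b = pmax(a[keep], b[keep]),
                   similarity = stats::runif(sum(keep), lo, hi),
                   event = NA_integer_)
  }
  dplyr::bind_rows(out, draw(n_bg, 40, 60), draw(n_ct, 98, 100))
}

# true triple-type counts: every within-root leaf triple, typed by the
# true pair events (independent of any similarity cutoff)
truth_triple_profile <- function(history, truth, m) {
  leaves <- history$leaves
  sizes <- rle(leaves$root)$lengths
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  i1 <- integer(0); i2 <- integer(0); i3 <- integer(0)
  for (n in unique(sizes[sizes >= 3])) {
    cmb <- utils::combn(n, 3)
    st <- starts[sizes == n]
    add <- function(rowv) rep(rowv, times = length(st)) +
      rep(st - 1L, each = ncol(cmb))
    i1 <- c(i1, add(cmb[1, ])); i2 <- c(i2, add(cmb[2, ])); i3 <- c(i3, add(cmb[3, ]))
  }
  types <- triplet_types(m)$type
  counts <- stats::setNames(rep(0, length(types)), types)
  if (length(i1) > 0) {
    pev <- history$pairs$event
    key <- paste(history$pairs$gene_a, history$pairs$gene_b, sep = "\r")
    evmap <- stats::setNames(pev, key)
    g <- leaves$gene
    pk <- function(i, j) paste(pmin(g[i], g[j]), pmax(g[i], g[j]), sep = "\r")
    e12 <- evmap[pk(i1, i2)]; e13 <- evmap[pk(i1, i3)]; e23 <- evmap[pk(i2, i3)]
    lo <- pmin(e12, e13, e23)
    hi <- pmax(e12, e13, e23)
    tab <- table(type_label(lo, e12 + e13 + e23 - lo - hi, hi))
    counts[names(tab)] <- as.numeric(tab)
  }
  new_profile(counts, m, "truth")
}

#' Simulate a complete pair list
#'
#' Convenience wrapper: [simulate_history()] then [emit_similarities()].
#'
#' @param config A [simulation_config()].
#' @return See [emit_similarities()].
#' @export
simulate_pairs <- function(config) {
  emit_similarities(simulate_history(config), config)
}

#' Write a simulated fixture to disk
#'
#' Writes `pairs.tsv` (canonical 3-column pair list), `truth_pairs.tsv`,
#' `truth_profile.tsv` and `config.json`.  Byte-identical for a fixed
#' seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
make_fixture <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_pairs(config)
  paths <- c(
    pairs = file.path(dir, "pairs.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_profile = file.path(dir, "truth_profile.tsv"),
    config = file.path(dir, "config.json")
  )
  write_pairs(sim$pairs, paths[["pairs"]])
  readr::write_tsv(sim$truth_pairs, paths[["truth_pairs"]])
  readr::write_tsv(sim$truth_profile, paths[["truth_profile"]])
  cfg <- list(
    schedule = as.integer(unclass(config$schedule)),
    surv2 = config$params$surv2,
    surv3 = config$params$surv3,
    G = config$G,
    component_means = config$component_means,
    component_sds = config$component_sds,
    background_rate = config$background_rate,
    contaminant_rate = config$contaminant_rate,
    seed = config$seed
  )
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             paths[["config"]])
  invisible(paths)
}
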