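# Genealogy enumeration for the branching process.
#
# A genealogy is a rooted tree: one root gene, levels correspond to the
# successive polyploidy events, a node at level i has between 1 and r_i
# surviving children.  Children subtrees are exchangeable, so we enumerate
# *unordered* survivor-count configurations and fold the orbit size
# (number of ordered realizations) into the weight.  The enumeration is
# exhaustive and duplicate-free; weights sum to 1.

.shape_cache <- new.env(parent = emptyenv())

# non-decreasing j-tuples of indices from 1..S (multisets with repetition)
multiset_tuples <- function(S, j) {
  if (j == 1) return(matrix(seq_len(S), nrow = 1))
  cmb <- utils::combn(S + j - 1, j)
  cmb - (seq_len(j) - 1)
}

# number of unordered configurations for the schedule (guard before building)
shape_count <- function(schedule) {
  r <- unclass(as_schedule(schedule))
  s <- 1
  for (i in rev(seq_along(r))) {
    s <- sum(vapply(seq_len(r[i]), function(j) choose(s + j - 1, j), numeric(1)))
  }
  s
}

slot_offsets <- function(r) c(0L, cumsum(r))[seq_along(r)]

# Build the parameter-free shape table for a schedule: exponent matrix over
# the p_j^(i) slots, orbit multiplicities, leaf counts, per-event pair
# counts, per-type triple counts and leaf path matrices.
shape_table <- function(schedule, max_shapes = 2e5) {
  schedule <- as_schedule(schedule)
  r <- unclass(schedule)
  m <- length(r)
  if (m > 4) {
    rlang::abort("genealogy enumeration is capped at 4 events; use method = \"product\"")
  }
  key <- paste(r, collapse = ",")
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  total <- shape_count(schedule)
  if (total > max_shapes) {
    rlang::abort(sprintf(
      "schedule (%s) has %.3g survivor-count configurations (cap %g); use method = \"product\"",
      key, total, max_shapes
    ))
  }
  nslot <- sum(r)
  off <- slot_offsets(r)
  ntype <- n_triplet_types(m)
  types <- triplet_types(m)
  tidx <- function(a, b, c) {
    which(types$e1 == a & types$e2 == b & types$e3 == c)
  }

  # shapes for a single gene entering event i, bottom-up
  shapes <- list(list(list(
    n = 1L, pr = numeric(m), tr = numeric(ntype),
    ex = integer(nslot), mult = 1,
    paths = matrix(integer(0), nrow = 1, ncol = 0)
  )))
  for (i in rev(seq_len(m))) {
    prev <- shapes[[1]]
    out <- list(); k <- 0L
    for (j in seq_len(r[i])) {
      tuples <- multiset_tuples(length(prev), j)
      for (col in seq_len(ncol(tuples))) {
        idx <- tuples[, col]
        kids <- prev[idx]
        n_t <- vapply(kids, function(s) s$n, integer(1))
        N <- sum(n_t)
        pr <- Reduce(`+`, lapply(kids, function(s) s$pr))
        tr <- Reduce(`+`, lapply(kids, function(s) s$tr))
        pr[i] <- pr[i] + (N^2 - sum(n_t^2)) / 2
        if (j >= 3) {
          tr[tidx(i, i, i)] <- tr[tidx(i, i, i)] +
            (N^3 - 3 * N * sum(n_t^2) + 2 * sum(n_t^3)) / 6
        }
        if (j >= 2 && i < m) {
          for (l in (i + 1):m) {
            pl <- vapply(kids, function(s) s$pr[l], numeric(1))
            tr[tidx(i, i, l)] <- tr[tidx(i, i, l)] + sum(pl * (N - n_t))
          }
        }
        ex <- Reduce(`+`, lapply(kids, function(s) s$ex))
        ex[off[i] + j] <- ex[off[i] + j] + 1L
        dup <- table(idx)
        mult <- factorial(j) / prod(factorial(dup)) *
          prod(vapply(kids, function(s) s$mult, numeric(1)))
        paths <- do.call(rbind, lapply(seq_along(kids), function(t) {
          cbind(rep(t, kids[[t]]$n), kids[[t]]$paths)
        }))
        k <- k + 1L
        out[[k]] <- list(n = N, pr = pr, tr = tr, ex = ex, mult = mult,
                         paths = paths)
      }
    }
    shapes <- list(out)
  }
  sh <- shapes[[1]]
  tab <- list(
    schedule = schedule,
    EX = do.call(rbind, lapply(sh, function(s) s$ex)),
    mult = vapply(sh, function(s) s$mult, numeric(1)),
    leaves = vapply(sh, function(s) s$n, integer(1)),
    pairs = do.call(rbind, lapply(sh, function(s) s$pr)),
    triples = do.call(rbind, lapply(sh, function(s) s$tr)),
    paths = lapply(sh, function(s) s$paths)
  )
  .shape_cache[[key]] <- tab
  tab
}

# weight of every shape for given survival parameters
shape_weights <- function(tab, params) {
  pslot <- unlist(params$p, use.names = FALSE)
  lp <- suppressWarnings(log(pslot))
  zero <- !is.finite(lp)
  w <- numeric(length(tab$mult))
  if (any(zero)) {
    killed <- rowSums(tab$EX[, zero, drop = FALSE]) > 0
  } else {
    killed <- rep(FALSE, length(w))
  }
  keep <- !killed
  if (any(keep)) {
    w[keep] <- tab$mult[keep] *
      exp(tab$EX[keep, !zero, drop = FALSE] %*% lp[!zero])
  }
  w
}

#' Enumerate all genealogies of the branching process
#'
#' Exhaustively enumerates the survivor-count configurations a single root
#' gene can realize under the schedule, duplicate-free, with each
#' configuration's probability (orbit multiplicity times the product of the
#' independent per-node survival probabilities).  Weights sum to 1.
#'
#' @param schedule An [event_schedule()].
#' @param params Matching [survival_params()].
#' @param max_shapes Guard on the number of configurations (4-event
#'   schedules with several triplings exceed any practical cap; use the
#'   product-form expectations instead).
#' @return A tibble with one row per genealogy: `id`, `weight`, `n_leaves`,
#'   and list-columns `pairs` (leaf pairs by divergence event), `triples`
#'   (leaf triples by type) and `paths` (leaf-by-event ancestor matrix, the
#'   input to [classify_triplet()]).
#' @examples
#' g <- enumerate_genealogies(event_schedule(2), survival_params(2, 0.5))
#' sum(g$weight)
#' @export
enumerate_genealogies <- function(schedule, params, max_shapes = 2e5) {
  schedule <- check_consistent(schedule, params)
  tab <- shape_table(schedule, max_shapes)
  w <- shape_weights(tab, params)
  m <- length(schedule)
  types <- triplet_types(m)$type
  tibble::tibble(
    id = seq_along(w),
    weight = w,
    n_leaves = tab$leaves,
    pairs = lapply(seq_along(w), function(i) {
      stats::setNames(tab$pairs[i, ], paste0("t", seq_len(m)))
    }),
    triples = lapply(seq_along(w), function(i) {
      stats::setNames(tab$triples[i, ], types)
    }),
    paths = tab$paths
  )
}

#' Probability of an aggregated trajectory
#'
#' Computes the probability of a trajectory of the branching process given
#' by the survivor counts \eqn{a_j^{(i)}} (number of genes at event i with
#' exactly j surviving progeny): the product over events of the multinomial
#' coefficient times the survival-probability powers.
#'
#' @param schedule An [event_schedule()].
#' @param params Matching [survival_params()].
#' @param counts List with one integer vector per event; element `j` of
#'   vector `i` is \eqn{a_j^{(i)}}.  Must satisfy the bookkeeping
#'   identities: one root gene, and genes at event i+1 equal surviving
#'   progeny of event i.
#' @return The trajectory probability.
#' @examples
#' sched <- event_schedule(c(2, 2))
#' par <- survival_params(sched, c(0.5, 0.5))
#' trajectory_probability(sched, par, list(c(0, 1), c(0, 2)))  # 0.5 * 0.25
#' @export
trajectory_probability <- function(schedule, params, counts) {
  schedule <- check_consistent(schedule, params)
  r <- unclass(schedule)
  m <- length(r)
  if (!is.list(counts) || length(counts) != m) {
    rlang::abort("`counts` must be a list with one survivor-count vector per event")
  }
  mi <- 1
  prob <- 1
  for (i in seq_len(m)) {
    a <- counts[[i]]
    if (length(a) != r[i] || any(a < 0) || any(a != round(a))) {
      rlang::abort(sprintf("counts for event %d must be %d non-negative integers", i, r[i]))
    }
    if (sum(a) != mi) {
      rlang::abort(sprintf(
        "counts violate the trajectory identities at event %d: sum(a) = %d but m_%d = %d",
        i, sum(a), i, mi
      ))
    }
    coef <- factorial(mi) / prod(factorial(a))
    prob <- prob * coef * prod(params$p[[i]]^a)
    mi <- sum(seq_len(r[i]) * a)
  }
  prob
}

# all valid survivor-count trajectories (oracle-grade, small m only)
all_trajectories <- function(schedule) {
  r <- unclass(as_schedule(schedule))
  m <- length(r)
  compositions <- function(n, k) {
    if (k == 1) return(matrix(n, nrow = 1))
    out <- NULL
    for (first in 0:n) {
      rest <- compositions(n - first, k - 1)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  grow <- function(i, mi, acc) {
    if (i > m) return(list(acc))
    comps <- compositions(mi, r[i])
    res <- list()
    for (row in seq_len(nrow(comps))) {
      a <- as.integer(comps[row, ])
      nxt <- sum(seq_len(r[i]) * a)
      res <- c(res, grow(i + 1, nxt, c(acc, list(a))))
    }
    res
  }
  grow(1L, 1L, list())
}

#' Expected number of extant genes per root
#'
#' The expectation of the leaf count of the branching process, either by the
#' product of per-event expected survivor counts (exact, any m) or by
#' summing weight times leaf count over the full genealogy enumeration.
#'
#' @param schedule An [event_schedule()].
#' @param params Matching [survival_params()].
#' @param method `"product"` (default) or `"enumeration"`.
#' @return Expected number of genes descending from one root.
#' @examples
#' sched <- event_schedule(c(2, 2))
#' expected_gene_count(sched, survival_params(sched, c(0.5, 0.5)))  # 2.25
#' @export
expected_gene_count <- function(schedule, params,
                                method = c("product", "enumeration")) {
  schedule <- check_consistent(schedule, params)
  method <- match.arg(method)
  if (method == "product") {
    prod(event_factors(params)$leaf)
  } else {
    g <- enumerate_genealogies(schedule, params)
    sum(g$weight * g$n_leaves)
  }
}

#' Classify a leaf triple within a genealogy
#'
#' Given the leaf path matrix of a genealogy (one row per extant gene, one
#' column per event, entries are the child slot taken at that event) and
#' three leaf row indices, returns the multiset of the three pairwise
#' last-common-ancestor events, sorted ascending.
#'
#' @param paths Leaf path matrix (from [enumerate_genealogies()]'s `paths`
#'   list-column, or [simulate_history()]).
#' @param leaves Three distinct leaf row indices.
#' @return Sorted integer vector of the three pairwise divergence events.
#' @export
classify_triplet <- function(paths, leaves) {
  leaves <- as.integer(leaves)
  if (length(leaves) != 3 || anyDuplicated(leaves)) {
    rlang::abort("`leaves` must be three distinct leaf indices")
  }
  if (any(leaves < 1 | leaves > nrow(paths))) {
    rlang::abort("unknown leaf index")
  }
  lca <- function(i, j) {
    diffs <- which(paths[i, ] != paths[j, ])
    if (length(diffs) == 0) {
      rlang::abort("leaves share an identical path; genealogy is malformed")
    }
    diffs[1]
  }
  sort(c(lca(leaves[1], leaves[2]),
         lca(leaves[1], leaves[3]),
         lca(leaves[2], leaves[3])))
}
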