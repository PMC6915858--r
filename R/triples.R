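# Gene triples (triangles in the similarity graph), the observed profile,
# and the within-triplet covariance structure used by the prediction step.

#' Extract gene triples from a filtered pair list
#'
#' Enumerates every triangle in the graph whose vertices are genes and
#' whose edges are the (filtered) syntenic pairs.  Each triangle is
#' reported once, genes sorted within the triple and rows sorted, so the
#' output is deterministic.
#'
#' @param pairs Pair tibble from [read_pairs()] / [filter_pairs()].
#' @return Tibble `gene_a`, `gene_b`, `gene_c` (sorted within row) and the
#'   pairwise similarities `sim_ab`, `sim_ac`, `sim_bc`.
#' @export
extract_triples <- function(pairs) {
  empty <- tibble::tibble(
    gene_a = character(0), gene_b = character(0), gene_c = character(0),
    sim_ab = numeric(0), sim_ac = numeric(0), sim_bc = numeric(0)
  )
  if (nrow(pairs) == 0) return(empty)
  g <- igraph::graph_from_data_frame(
    pairs[, c("gene_a", "gene_b")], directed = FALSE
  )
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(empty)
  nm <- igraph::V(g)$name
  mat <- matrix(nm[as.integer(tri)], ncol = 3, byrow = TRUE)
  mat <- t(apply(mat, 1, sort))
  ord <- order(mat[, 1], mat[, 2], mat[, 3])
  mat <- mat[ord, , drop = FALSE]
  simkey <- stats::setNames(pairs$similarity,
                            paste(pairs$gene_a, pairs$gene_b, sep = "\r"))
  look <- function(a, b) unname(simkey[paste(a, b, sep = "\r")])
  tibble::tibble(
    gene_a = mat[, 1], gene_b = mat[, 2], gene_c = mat[, 3],
    sim_ab = look(mat[, 1], mat[, 2]),
    sim_ac = look(mat[, 1], mat[, 3]),
    sim_bc = look(mat[, 2], mat[, 3])
  )
}

#' Observed triplet profile
#'
#' Classifies each triple's three similarities by [classify_similarity()]
#' and counts the resulting type multisets.  With `k - 1` cutoffs the
#' \eqn{k^3} ordered outcomes ("octants" for k = 2) collapse into the
#' \eqn{k(k+1)(k+2)/6} triplet types.
#'
#' @param triples Triple tibble from [extract_triples()].
#' @param cutoffs Transition points from [ml_transition_points()] (or a
#'   plain numeric vector).
#' @param m Number of events; defaults to `length(cutoffs) + 1`.
#' @return A profile tibble (label `"observed"`, integer counts).
#' @export
observed_profile <- function(triples, cutoffs, m = length(cutoffs) + 1L) {
  types <- triplet_types(m)$type
  counts <- stats::setNames(rep(0, length(types)), types)
  if (nrow(triples) > 0) {
    e_ab <- classify_similarity(triples$sim_ab, cutoffs)
    e_ac <- classify_similarity(triples$sim_ac, cutoffs)
    e_bc <- classify_similarity(triples$sim_bc, cutoffs)
    lo <- pmin(e_ab, e_ac, e_bc)
    hi <- pmax(e_ab, e_ac, e_bc)
    lab <- type_label(lo, e_ab + e_ac + e_bc - lo - hi, hi)
    tab <- table(lab)
    counts[names(tab)] <- as.numeric(tab)
  }
  new_profile(counts, m, "observed")
}

#' Estimate the within-triplet covariance structure
#'
#' For each event, estimates the variance of the similarities classified
#' to that event across all triples, and the within-triplet covariance
#' between two same-event similarities (from triples containing at least
#' two of them).  Cross-event covariance is fixed at 0, reflecting the
#' Markov structure of the branching process.  A triple whose three
#' similarities all classify to the same event contributes its three
#' unordered pairs unless `first_pair_only = TRUE`.
#'
#' @param triples Triple tibble from [extract_triples()].
#' @param cutoffs Transition points.
#' @param mixture Optional `similarity_mixture`; its component sd is the
#'   fallback variance when an event has too little data (covariance 0).
#' @param first_pair_only Use only the first same-event pair per triple in
#'   the covariance estimate.
#' @param unique_values Use each distinct similarity value once per event
#'   in the variance estimate instead of once per triple occurrence.
#' @param m Number of events.
#' @return A `triplet_covariance`: tibble with `event`, `n_values`,
#'   `variance`, `n_pairs`, `covariance`, `fallback`.
#' @export
estimate_triplet_covariance <- function(triples, cutoffs, mixture = NULL,
                                        first_pair_only = FALSE,
                                        unique_values = FALSE,
                                        m = length(cutoffs) + 1L) {
  sims <- as.matrix(triples[, c("sim_ab", "sim_ac", "sim_bc")])
  ev <- matrix(classify_similarity(as.numeric(sims), cutoffs), ncol = 3)
  out <- tibble::tibble(
    event = seq_len(m), n_values = 0L, variance = NA_real_,
    n_pairs = 0L, covariance = 0, fallback = FALSE
  )
  for (e in seq_len(m)) {
    sel <- ev == e
    vals <- sims[sel]
    if (unique_values) vals <- unique(vals)
    # within-triplet same-event pairs (both orders, so the estimate is
    # symmetric in the arbitrary coordinate order)
    pair_cols <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    used <- rep(FALSE, nrow(sims))
    xs <- list(); ys <- list()
    for (pc in pair_cols) {
      hit <- ev[, pc[1]] == e & ev[, pc[2]] == e
      if (first_pair_only) {
        hit <- hit & !used
        used <- used | hit
      }
      if (any(hit)) {
        xs[[length(xs) + 1]] <- sims[hit, pc[1]]
        ys[[length(ys) + 1]] <- sims[hit, pc[2]]
      }
    }
    xv <- unlist(xs); yv <- unlist(ys)
    px <- c(xv, yv); py <- c(yv, xv)
    if (length(vals) >= 2) {
      out$variance[out$event == e] <- stats::var(vals)
      out$n_values[out$event == e] <- length(vals)
    } else {
      fb <- if (!is.null(mixture) && e <= nrow(mixture$components)) {
        mixture$components$sd[e]^2
      } else {
        NA_real_
      }
      if (is.na(fb)) {
        rlang::abort(sprintf(
          "event %d has fewer than 2 classified similarities and no mixture fallback", e
        ))
      }
      rlang::inform(sprintf(
        "event %d: too few similarities; falling back to mixture sd^2 = %.3g with zero covariance",
        e, fb
      ))
      out$variance[out$event == e] <- fb
      out$fallback[out$event == e] <- TRUE
    }
    if (length(px) >= 4 && !out$fallback[out$event == e]) {
      out$covariance[out$event == e] <- stats::cov(px, py)
      out$n_pairs[out$event == e] <- length(px) / 2L
    }
  }
  structure(list(table = out, m = m), class = "triplet_covariance")
}

#' @export
print.triplet_covariance <- function(x, ...) {
  cat("<triplet_covariance> ", x$m, " event(s); cross-event covariance fixed at 0\n",
      sep = "")
  print(x$table)
  invisible(x)
}

# assemble the 3x3 covariance matrix for an underlying type (sorted event
# triple); same-event off-diagonals from the within-triplet covariance,
# cross-event entries 0; repaired to PSD by shrinking off-diagonals
assemble_sigma <- function(delta, cov) {
  tab <- cov$table
  v <- tab$variance[match(delta, tab$event)]
  cv <- tab$covariance[match(delta, tab$event)]
  sig <- diag(v, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    if (delta[i] == delta[j]) {
      sig[i, j] <- sig[j, i] <- cv[i]
    }
  }
  repaired <- FALSE
  for (it in 1:200) {
    if (min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10) break
    off <- sig; diag(off) <- 0
    sig <- diag(diag(sig)) + off * 0.9
    repaired <- TRUE
  }
  if (min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    sig <- diag(diag(sig))
    repaired <- TRUE
  }
  if (repaired) {
    rlang::inform("covariance matrix repaired towards positive semi-definiteness")
  }
  attr(sig, "repaired") <- repaired
  sig
}
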