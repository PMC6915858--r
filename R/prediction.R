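# Predicted profiles: graft the Gaussian divergence model onto the
# branching-process expectations.  For each underlying triplet type the
# three similarities follow a trivariate normal (component means, the
# estimated within-event covariance, zero cross-event covariance); the
# transition points carve similarity space into cells whose rectangle
# probabilities redistribute the underlying mass into observed categories.

#' Observed-category probabilities for one underlying triplet type
#'
#' For an underlying type, builds the trivariate normal of its three pair
#' similarities and integrates it over every ordered classification cell
#' defined by the transition points ("octants" for two events), collapsing
#' ordered cells into category multisets.  Masses sum to 1 within the
#' integration tolerance.
#'
#' @param delta Underlying type: sorted integer triple of event indices
#'   (or a label like `"t1,t1,t2"`).
#' @param mixture A `similarity_mixture`; component k supplies the mean of
#'   event-k similarities.
#' @param cov A `triplet_covariance` from [estimate_triplet_covariance()].
#' @param cutoffs Transition points (length `k - 1`).
#' @return Tibble `type`, `mass` over all category multisets.
#' @export
category_probability <- function(delta, mixture, cov, cutoffs) {
  if (is.character(delta)) delta <- parse_type(delta)
  delta <- sort(as.integer(delta))
  if (delta[1] != delta[2]) {
    rlang::abort("`delta` is not a realizable triplet type (oldest event must repeat)")
  }
  comps <- mixture$components
  k <- length(cutoffs) + 1L
  if (nrow(comps) < max(delta)) {
    rlang::abort("mixture has fewer components than the largest event index in `delta`")
  }
  mu <- comps$mean[delta]
  sig <- assemble_sigma(delta, cov)
  bounds <- c(-Inf, sort(as.numeric(cutoffs)), Inf)
  types <- triplet_types(k)
  mass <- stats::setNames(rep(0, nrow(types)), types$type)
  cells <- expand.grid(c1 = seq_len(k), c2 = seq_len(k), c3 = seq_len(k))
  for (r in seq_len(nrow(cells))) {
    cell <- as.integer(cells[r, ])
    p <- mvn_rectangle_prob(bounds[cell], bounds[cell + 1L], mu, sig)
    lab <- do.call(type_label, as.list(sort(cell)))
    mass[lab] <- mass[lab] + p
  }
  tot <- sum(mass)
  if (abs(tot - 1) > 1e-4) {
    rlang::warn(sprintf("category masses sum to %.6f; integration may be inaccurate", tot))
  }
  tibble::tibble(type = names(mass), mass = unname(mass))
}

#' Predicted triplet profile for a model
#'
#' Weights each underlying type's category probabilities by its expected
#' count and sums, then rescales so the total equals the observed triple
#' count.
#'
#' @param schedule An [event_schedule()] (the model).
#' @param params Matching [survival_params()] (typically from
#'   [estimate_survival_params()]).
#' @param mixture A `similarity_mixture` with at least m components.
#' @param cov A `triplet_covariance`.
#' @param cutoffs Transition points (length m - 1).
#' @param observed_total Observed number of triples (> 0).
#' @return A profile tibble (label `"predicted"`).
#' @export
predicted_profile <- function(schedule, params, mixture, cov, cutoffs,
                              observed_total) {
  schedule <- check_consistent(schedule, params)
  m <- length(schedule)
  if (length(cutoffs) != m - 1) {
    rlang::abort("need exactly one transition point between each pair of adjacent events")
  }
  stopifnot(observed_total > 0)
  W <- profile_values(expected_triplet_profile(schedule, params), m)
  types <- triplet_types(m)
  pred <- stats::setNames(rep(0, nrow(types)), types$type)
  for (i in seq_len(nrow(types))) {
    if (W[[i]] <= 0) next
    cp <- category_probability(c(types$e1[i], types$e2[i], types$e3[i]),
                               mixture, cov, cutoffs)
    pred <- pred + W[[i]] * stats::setNames(cp$mass, cp$type)[names(pred)]
  }
  normalize_profile(new_profile(pred, m, "predicted"), observed_total)
}

#' Rank candidate models against the observed profile
#'
#' Compares each candidate profile to the observed profile with a
#' chi-square-style statistic \eqn{\sum (O-E)^2 / \max(E, 0.5)} and the L1
#' distance; models are ranked by the chi-square statistic, ties broken by
#' L1.  The full table is always returned.
#'
#' @param observed Observed profile tibble.
#' @param candidates Named list of candidate profiles (underlying or
#'   predicted), all sharing the observed type set and total.
#' @param epsilon Floor on expected counts in the chi-square denominator.
#' @return A `profile_comparison`: tibble `model`, `chisq`, `l1`, `rank`.
#' @export
compare_profiles <- function(observed, candidates, epsilon = 0.5) {
  if (length(candidates) == 0) rlang::abort("no candidate profiles supplied")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    rlang::abort("`candidates` must be a named list")
  }
  obs <- profile_values(observed)
  res <- purrr::map_dfr(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    if (!setequal(cand$type, names(obs))) {
      rlang::abort(sprintf("candidate '%s' has a mismatched triplet type set", nm))
    }
    ev <- profile_values(cand)[names(obs)]
    if (abs(sum(ev) - sum(obs)) > 1e-6 * max(1, sum(obs))) {
      rlang::abort(sprintf("candidate '%s' total differs from the observed total", nm))
    }
    tibble::tibble(
      model = nm,
      chisq = sum((obs - ev)^2 / pmax(ev, epsilon)),
      l1 = sum(abs(obs - ev))
    )
  })
  res <- dplyr::arrange(res, .data$chisq, .data$l1, .data$model)
  res$rank <- seq_len(nrow(res))
  structure(res, class = c("profile_comparison", class(res)))
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("<profile_comparison> best model:", x$model[1], "\n")
  NextMethod()
  invisible(x)
}
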