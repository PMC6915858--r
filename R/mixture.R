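# Univariate Gaussian mixture decomposition of the paralog similarity
# distribution.  Each component corresponds to one polyploidy event
# (oldest event = lowest mean).  EM with deterministic initialization;
# selected component means may be held fixed (the cabbage-style analysis
# pins the two oldest components and frees the rest).

#' Fit a Gaussian mixture to paralog similarities
#'
#' Expectation-maximization fit of a k-component univariate normal mixture
#' on the percent-similarity scale.  Initialization is deterministic
#' (quantile-spaced means, pooled sd, equal proportions), so fits are
#' reproducible without a seed.  Components whose means are pinned via
#' `fixed_means` keep them exactly; their sd and proportion still update.
#'
#' @param similarities Numeric vector of percent similarities.
#' @param k Number of components (>= 1); needs at least `10 * k` points.
#' @param fixed_means Optional numeric vector of length `k`; non-`NA`
#'   entries pin the mean of the corresponding component.  Must be
#'   strictly increasing over its non-`NA` entries.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param sd_floor Lower bound on component standard deviations.
#' @return A `similarity_mixture`: tibble of `components` (mean, sd,
#'   proportion, ascending mean), plus `loglik`, `iterations`, `converged`.
#' @examples
#' x <- c(rnorm(500, 71, 4), rnorm(500, 90, 3))
#' fit_mixture(x, k = 2)
#' @export
fit_mixture <- function(similarities, k, fixed_means = NULL,
                        max_iter = 500, tol = 1e-8, sd_floor = 1e-3) {
  x <- as.numeric(similarities)
  x <- x[is.finite(x)]
  k <- as.integer(k)
  if (k < 1) rlang::abort("`k` must be at least 1")
  n <- length(x)
  if (n < 10 * k) {
    rlang::abort(sprintf("need at least %d data points for k = %d", 10 * k, k))
  }
  if (stats::sd(x) < sd_floor) {
    rlang::abort("degenerate data: all similarities are (nearly) identical")
  }
  if (!is.null(fixed_means)) {
    if (length(fixed_means) != k) {
      rlang::abort("`fixed_means` must have length k (use NA for free components)")
    }
    fm <- fixed_means[!is.na(fixed_means)]
    if (length(fm) > 1 && any(diff(fm) <= 0)) {
      rlang::abort("`fixed_means` must be strictly increasing")
    }
  } else {
    fixed_means <- rep(NA_real_, k)
  }

  fixed <- !is.na(fixed_means)
  mu <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  mu[fixed] <- fixed_means[fixed]
  sigma <- rep(max(stats::sd(x) / k, sd_floor), k)
  prop <- rep(1 / k, k)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      prop[j] * stats::dnorm(x, mu[j], sigma[j])
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    for (j in seq_len(k)) {
      if (!fixed[j]) mu[j] <- sum(resp[, j] * x) / nk[j]
      sigma[j] <- sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j])
      if (!is.finite(sigma[j]) || sigma[j] < sd_floor) sigma[j] <- sd_floor
    }
    prop <- nk / n
  }
  loglik <- ll_trace[length(ll_trace)]
  if (!converged) {
    rlang::warn(sprintf("EM did not converge in %d iterations; returning best fit", max_iter))
  }
  ord <- order(mu)
  if (any(fixed) && !identical(ord, seq_len(k))) {
    # a free mean wandered across a pinned one; keep ascending order
    rlang::warn("component order changed during EM; components re-sorted by mean")
  }
  comps <- tibble::tibble(
    component = seq_len(k),
    mean = mu[ord], sd = sigma[ord], proportion = prop[ord] / sum(prop),
    fixed = fixed[ord]
  )
  if (k > 1 && any(diff(comps$mean) <= 0)) {
    rlang::abort("fitted component means are not strictly increasing; reduce k or pin means")
  }
  structure(
    list(components = comps, loglik = loglik, loglik_trace = ll_trace,
         iterations = iter, converged = converged, n = n),
    class = "similarity_mixture"
  )
}

#' @export
print.similarity_mixture <- function(x, ...) {
  cat("<similarity_mixture> ", nrow(x$components), " component(s), n = ",
      x$n, ", logLik = ", format(x$loglik), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Tidy a similarity mixture fit
#'
#' @param x A `similarity_mixture` from [fit_mixture()].
#' @param ... Unused.
#' @return `tidy()`: one row per component; `glance()`: one-row model
#'   summary.
#' @method tidy similarity_mixture
#' @export
tidy.similarity_mixture <- function(x, ...) x$components

#' @rdname tidy.similarity_mixture
#' @method glance similarity_mixture
#' @export
glance.similarity_mixture <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$components), n = x$n, loglik = x$loglik,
    iterations = x$iterations, converged = x$converged
  )
}

#' Serialize a mixture and its transition points to JSON
#'
#' @param mixture A `similarity_mixture`.
#' @param cutoffs Optional `transition_points`.
#' @param exclusions Optional `c(low, high)` similarity exclusion cutoffs.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
mixture_to_json <- function(mixture, cutoffs = NULL, exclusions = NULL,
                            path = NULL) {
  obj <- list(
    components = mixture$components[, c("mean", "sd", "proportion")],
    cutoffs = if (is.null(cutoffs)) numeric(0) else as.numeric(cutoffs),
    exclusions = list(
      low = if (is.null(exclusions)) NULL else exclusions[[1]],
      high = if (is.null(exclusions)) NULL else exclusions[[2]]
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Classify a similarity by event of origin
#'
#' Returns `1 +` the number of transition points strictly below `x`; a
#' similarity exactly at a cutoff is assigned to the older event (at or
#' below H means event of the lower component).
#'
#' @param x Percent similarities in (0, 100].
#' @param cutoffs Transition points (ascending), e.g. from
#'   [ml_transition_points()].
#' @return Integer event indices (1 = oldest).
#' @examples
#' classify_similarity(c(70, 80, 90), cutoffs = 80)  # 1 1 2
#' @export
classify_similarity <- function(x, cutoffs) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 100)) {
    rlang::abort("similarities must lie in (0, 100]")
  }
  cutoffs <- sort(as.numeric(cutoffs))
  if (length(cutoffs) == 0) return(rep(1L, length(x)))
  1L + vapply(x, function(xi) sum(cutoffs < xi), integer(1))
}
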