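# Maximum-likelihood transition (discrimination) points between adjacent
# mixture components.  The objective scores every similarity at or below h
# under the lower component's full normal density and every similarity
# above h under the upper component's; it is piecewise constant in h with
# jumps exactly at the data values, so the default search walks the data
# breakpoints and returns the midpoint of the maximal plateau.

transition_objective_terms <- function(x, lower_mean, lower_sd,
                                       upper_mean, upper_sd) {
  stats::dnorm(x, lower_mean, lower_sd, log = TRUE) -
    stats::dnorm(x, upper_mean, upper_sd, log = TRUE)
}

#' ML transition point between two mixture components
#'
#' Finds the cutoff H in the open interval between the two component means
#' that maximizes the product of the lower component's density over
#' similarities at or below H and the upper component's density over
#' similarities above H.  Complete normal densities are used; mixture
#' proportions are not part of the objective.  The objective only changes
#' when H crosses a data value, so by default the exact breakpoint plateau
#' is located and its midpoint returned; `grid_step` switches to a grid
#' search (plateau midpoint on the grid).
#'
#' @param similarities Percent similarities (already filtered to any
#'   exclusion window).
#' @param lower,upper Lists (or one-row data frames) with `mean` and `sd`
#'   of the flanking components, `lower$mean < upper$mean`.
#' @param grid_step `NULL` (default, exact breakpoint search) or a grid
#'   step in percentage points.
#' @return The transition point H (percent).
#' @examples
#' ml_transition_point(c(69, 71, 89, 91),
#'                     lower = list(mean = 70, sd = 10),
#'                     upper = list(mean = 90, sd = 10))  # 80
#' @export
ml_transition_point <- function(similarities, lower, upper, grid_step = NULL) {
  x <- sort(as.numeric(similarities))
  mu1 <- lower$mean; s1 <- lower$sd
  mu2 <- upper$mean; s2 <- upper$sd
  if (!(mu1 < mu2)) rlang::abort("`lower$mean` must be below `upper$mean`")
  if (!any(x > mu1 & x < mu2)) {
    rlang::abort("no similarities strictly between the component means")
  }
  delta <- transition_objective_terms(x, mu1, s1, mu2, s2)

  objective_at <- function(h) {
    vapply(h, function(hi) sum(delta[x <= hi]), numeric(1))
  }

  if (!is.null(grid_step)) {
    grid <- seq(mu1 + grid_step, mu2 - grid_step / 2, by = grid_step)
    if (length(grid) == 0) rlang::abort("grid step too coarse for the mean interval")
    vals <- objective_at(grid)
    best <- which(vals > max(vals) - 1e-9)
    runs <- split(best, cumsum(c(1, diff(best) != 1)))
    plateau <- runs[[1]]
    return((grid[plateau[1]] + grid[plateau[length(plateau)]]) / 2)
  }

  # breakpoints: h sweeping (mu1, mu2); the achievable objective values are
  # the cumulative sums of delta at data values; the plateau holding the
  # max runs from its breakpoint to the next data value (or mu2)
  inside <- which(x > mu1 & x < mu2)
  base <- sum(delta[x <= mu1])
  # collapse tied data values: h can only include all copies of a value
  xi <- x[inside]                      # already sorted
  grp <- cumsum(!duplicated(xi))
  ux <- xi[!duplicated(xi)]
  cum <- base + cumsum(as.numeric(rowsum(delta[inside], grp)))
  cand_vals <- c(base, cum)            # value for h below all inside values, then after each
  cand_lo <- c(mu1, ux)                # plateau left edges
  cand_hi <- c(ux, mu2)                # plateau right edges
  best <- which(cand_vals > max(cand_vals) - 1e-9)
  runs <- split(best, cumsum(c(1, diff(best) != 1)))
  plateau <- runs[[1]]
  lo <- cand_lo[plateau[1]]
  hi <- cand_hi[plateau[length(plateau)]]
  (lo + hi) / 2
}

#' ML transition points for a fitted mixture
#'
#' Applies [ml_transition_point()] to every adjacent component pair, each
#' on the data restricted to (previous cutoff, next flanking component
#' mean), and returns the strictly increasing cutoffs.
#'
#' @param similarities Percent similarities.
#' @param mixture A `similarity_mixture` from [fit_mixture()].
#' @param grid_step Passed to [ml_transition_point()].
#' @return Numeric vector of `k - 1` cutoffs (class `transition_points`);
#'   empty for `k = 1`.
#' @export
ml_transition_points <- function(similarities, mixture, grid_step = NULL) {
  comps <- mixture$components
  k <- nrow(comps)
  if (k < 2) return(structure(numeric(0), class = "transition_points"))
  x <- as.numeric(similarities)
  H <- numeric(k - 1)
  for (j in seq_len(k - 1)) {
    lo_bound <- if (j > 1) H[j - 1] else -Inf
    hi_bound <- if (j + 2 <= k) comps$mean[j + 2] else Inf
    xs <- x[x > lo_bound & x < hi_bound]
    H[j] <- ml_transition_point(xs,
                                lower = list(mean = comps$mean[j], sd = comps$sd[j]),
                                upper = list(mean = comps$mean[j + 1], sd = comps$sd[j + 1]),
                                grid_step = grid_step)
  }
  if (any(diff(H) <= 0)) {
    rlang::abort("internal error: transition points are not strictly increasing")
  }
  structure(H, class = "transition_points")
}

#' @export
print.transition_points <- function(x, ...) {
  if (length(x) == 0) {
    cat("<transition_points> (none; single component)\n")
  } else {
    cat("<transition_points> H =", paste(format(unclass(x)), collapse = ", "), "\n")
  }
  invisible(x)
}
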