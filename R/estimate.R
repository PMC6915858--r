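# Survival-parameter estimation from observed per-event pair counts and a
# gene count.  Moment matching (default) minimizes the squared relative
# error between observations and G times the per-root expectations; the
# "ml" flag maximizes an independent-Poisson likelihood over the same
# observables.

# expected genes per root under a gene-count convention: "all" counts every
# extant gene; "paired" counts only genes with at least one paralog (a root
# surviving as a single copy contributes nothing to a pair list)
expected_genes_per_root <- function(params, genes = c("all", "paired")) {
  genes <- match.arg(genes)
  e_all <- prod(event_factors(params)$leaf)
  if (genes == "all") return(e_all)
  p_single <- prod(vapply(params$p, function(pi) pi[1], numeric(1)))
  e_all - p_single
}

params_from_theta <- function(schedule, theta, squared) {
  r <- unclass(schedule)
  if (squared) {
    survival_params(schedule, surv2 = theta, squared = TRUE)
  } else {
    m <- length(r)
    s2 <- theta[seq_len(m)]
    s3 <- rep(NA_real_, m)
    s3[r == 3L] <- theta[m + seq_len(sum(r == 3L))]
    survival_params(schedule, surv2 = s2, surv3 = s3)
  }
}

theta_bounds <- function(schedule, squared) {
  r <- unclass(schedule)
  m <- length(r)
  if (squared) {
    # p1 = 1 - u - u^2 >= 0 at triplings caps u at the golden-ratio root
    upper <- ifelse(r == 3L, (sqrt(5) - 1) / 2, 1)
    list(lower = rep(0, m), upper = upper, n = m)
  } else {
    n <- m + sum(r == 3L)
    list(lower = rep(0, n), upper = rep(1, n), n = n)
  }
}

#' Estimate fractionation survival parameters from pair counts
#'
#' Finds survival probabilities (and the implied root-gene count G) such
#' that G times the per-root expected pair counts and gene count match the
#' observations.  The default is bounded least squares on relative error
#' (moment matching standing in for maximum likelihood); `method = "ml"`
#' maximizes an independent-Poisson likelihood on the same observables.
#'
#' @param schedule An [event_schedule()].
#' @param pair_counts Observed pair counts per divergence event (oldest
#'   first), length m.
#' @param total_genes Observed gene count; its meaning is set by `genes`.
#' @param genes `"paired"` (default): `total_genes` counts genes appearing
#'   in the pair list, i.e. genes with at least one surviving paralog —
#'   the only count observable from a pair list.  `"all"`: `total_genes`
#'   is the full gene inventory including paralog-less singletons.
#' @param squared Enforce `surv3 = surv2^2` at tripling events (default);
#'   otherwise triplings get a free third-survivor probability.
#' @param method `"moment"` (default) or `"ml"` (Poisson likelihood).
#' @param n_starts Multi-start count for the bounded optimizer.
#' @return A `survival_fit` list: `params`, `G`, `fitted` (fitted pair
#'   counts and gene count), `residual` (objective at the optimum),
#'   `convergence`.
#' @examples
#' sched <- event_schedule(c(2, 2))
#' truth <- survival_params(sched, c(0.3, 0.6))
#' obs <- 1000 * expected_pair_counts(sched, truth, method = "product")
#' genes <- 1000 * expected_genes_per_root(truth, "all")
#' estimate_survival_params(sched, obs, genes, genes = "all")
#' @export
estimate_survival_params <- function(schedule, pair_counts, total_genes,
                                     genes = c("paired", "all"),
                                     squared = TRUE,
                                     method = c("moment", "ml"),
                                     n_starts = 8) {
  schedule <- as_schedule(schedule)
  genes <- match.arg(genes)
  method <- match.arg(method)
  m <- length(schedule)
  if (length(pair_counts) != m) {
    rlang::abort("`pair_counts` must have one count per event")
  }
  if (any(pair_counts < 0) || total_genes <= 0) {
    rlang::abort("counts must be non-negative and `total_genes` positive")
  }
  if (all(pair_counts == 0)) {
    rlang::abort("all pair counts are zero; parameters are unidentifiable")
  }
  bounds <- theta_bounds(schedule, squared)

  eval_point <- function(theta) {
    par <- params_from_theta(schedule, theta, squared)
    eg <- expected_genes_per_root(par, genes)
    ep <- product_pair_counts(par)
    list(par = par, eg = eg, ep = ep)
  }
  objective <- function(theta) {
    pt <- try(eval_point(theta), silent = TRUE)
    if (inherits(pt, "try-error")) return(1e12)
    if (pt$eg <= 0 || any(!is.finite(pt$ep))) return(1e12)
    G <- total_genes / pt$eg
    if (method == "moment") {
      sum(((G * pt$ep - pair_counts) / pmax(pair_counts, 1))^2)
    } else {
      lam <- pmax(G * pt$ep, 1e-300)
      -(sum(pair_counts * log(lam) - lam))
    }
  }

  starts <- lapply(seq_len(n_starts), function(s) {
    frac <- (s - 0.5) / n_starts
    bounds$lower + frac * (bounds$upper - bounds$lower)
  })
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, objective, method = "L-BFGS-B",
                            lower = bounds$lower + 1e-12,
                            upper = bounds$upper - 1e-12,
                            control = list(maxit = 500, factr = 1e1)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    rlang::abort("no feasible survival parameters found in [0, 1]")
  }
  polish <- if (bounds$n == 1) {
    opt <- stats::optimize(objective, c(bounds$lower, bounds$upper), tol = 1e-12)
    list(par = opt$minimum, value = opt$objective, convergence = 0L)
  } else {
    try(stats::optim(best$par, objective, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 5000)),
        silent = TRUE)
  }
  if (!inherits(polish, "try-error") && polish$value <= best$value) {
    polish$par <- pmin(pmax(polish$par, bounds$lower), bounds$upper)
    best <- polish
  }
  theta <- best$par
  theta[theta < 1e-8] <- 0
  pt <- eval_point(theta)
  G <- total_genes / pt$eg
  if (any(pt$par$surv2 < 1e-6)) {
    rlang::warn(paste0(
      "survival probability estimated at the boundary 0 for event(s) ",
      paste(which(pt$par$surv2 < 1e-6), collapse = ", ")
    ))
  }
  if (method == "moment" && best$value > 1e-2) {
    rlang::warn(sprintf(
      "moment matching left a residual of %.4g; observed counts may not be compatible with the model",
      best$value
    ))
  }
  structure(
    list(schedule = schedule, params = pt$par, G = G,
         fitted = list(pair_counts = G * pt$ep,
                       total_genes = G * pt$eg),
         observed = list(pair_counts = as.numeric(pair_counts),
                         total_genes = total_genes),
         genes = genes, method = method,
         residual = best$value, convergence = best$convergence),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit> schedule ", format(x$schedule), "\n", sep = "")
  cat(sprintf("  surv2: %s\n", paste(signif(x$params$surv2, 4), collapse = ", ")))
  if (any(!is.na(x$params$surv3))) {
    cat(sprintf("  surv3: %s\n", paste(signif(x$params$surv3, 4), collapse = ", ")))
  }
  cat(sprintf("  G = %.1f roots, residual = %.3g (%s)\n",
              x$G, x$residual, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a survival-parameter fit
#'
#' @param x A `survival_fit` from [estimate_survival_params()].
#' @param ... Unused.
#' @return One row per event: ploidy and estimated survival probabilities.
#' @method tidy survival_fit
#' @export
tidy.survival_fit <- function(x, ...) {
  tibble::tibble(
    event = seq_along(x$params$surv2),
    ploidy = as.integer(unclass(x$schedule)),
    surv2 = x$params$surv2,
    surv3 = x$params$surv3
  )
}

#' @rdname tidy.survival_fit
#' @method glance survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble::tibble(
    model = format(x$schedule),
    G = x$G,
    residual = x$residual,
    method = x$method,
    convergence = x$convergence
  )
}
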