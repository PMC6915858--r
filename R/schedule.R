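#' Define a sequence of polyploidy events
#'
#' An event schedule is the ordered ploidy sequence \eqn{(r_1, \dots, r_m)} of
#' successive polyploidizations, oldest event first.  Each \eqn{r_i} is the
#' number of progeny every gene is replaced by at event \eqn{i}: 2 for a
#' whole-genome doubling (WGD), 3 for a tripling (WGT).  The set of all
#' \eqn{2^m} schedules of length \eqn{m} is the candidate model set.
#'
#' @param ploidies Integer vector of ploidies, oldest event first.  Every
#'   entry must be 2 or 3.
#' @return An `event_schedule` object (an integer vector with a class).
#' @examples
#' event_schedule(c(3, 2))   # a tripling followed by a doubling
#' @export
event_schedule <- function(ploidies) {
  ploidies <- as.integer(ploidies)
  if (length(ploidies) < 1) {
    rlang::abort("an event schedule needs at least one event")
  }
  if (!all(ploidies %in% c(2L, 3L))) {
    rlang::abort(paste0(
      "every ploidy must be 2 (WGD) or 3 (WGT); got: ",
      paste(ploidies[!ploidies %in% c(2L, 3L)], collapse = ", ")
    ))
  }
  structure(ploidies, class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat("<event_schedule> (", paste(unclass(x), collapse = ","), "), ",
      length(x), " event(s)\n", sep = "")
  invisible(x)
}

#' @export
format.event_schedule <- function(x, ...) {
  paste0("(", paste(unclass(x), collapse = ","), ")")
}

as_schedule <- function(x) {
  if (inherits(x, "event_schedule")) x else event_schedule(x)
}

#' All candidate schedules of a given length
#'
#' Enumerates the \eqn{2^m} ploidy sequences mixing doublings and triplings.
#'
#' @param m Number of events.
#' @return Named list of [event_schedule()] objects; names like `"(3,2)"`.
#' @examples
#' names(candidate_schedules(2))
#' @export
candidate_schedules <- function(m) {
  m <- as.integer(m)
  stopifnot(m >= 1)
  grid <- expand.grid(rep(list(c(2L, 3L)), m))[, m:1, drop = FALSE]
  scheds <- apply(as.matrix(grid), 1L, event_schedule, simplify = FALSE)
  names(scheds) <- vapply(scheds, format, character(1))
  scheds
}

#' Per-event survival probabilities
#'
#' At event \eqn{i} each gene is replaced by \eqn{r_i} progeny of which
#' \eqn{j \ge 1} survive to the next event (or to the present) with
#' probability \eqn{p_j^{(i)}}; loss of all copies is conditioned away.  In
#' the two-event notation, `surv2` holds \eqn{u, v, \dots} (exactly two
#' progeny survive) and `surv3` holds \eqn{u', v', \dots} (all three survive,
#' tripling events only).
#'
#' @param schedule An [event_schedule()] (or plain ploidy vector).
#' @param surv2 Numeric vector, one value per event: probability that exactly
#'   two progeny survive.
#' @param surv3 Probability that three progeny survive, one value per event
#'   (`NA` or 0 at doubling positions).  When `NULL` and `squared = TRUE`,
#'   tripling events get `surv3 = surv2^2`.
#' @param squared Apply the squared constraint \eqn{u' = u^2} at tripling
#'   events when `surv3` is not supplied.
#' @return A `survival_params` object: per-event probability vectors
#'   \eqn{(p_1, p_2[, p_3])}.
#' @examples
#' survival_params(event_schedule(c(3, 2)), surv2 = c(0.3, 0.4))
#' @export
survival_params <- function(schedule, surv2, surv3 = NULL, squared = TRUE) {
  schedule <- as_schedule(schedule)
  m <- length(schedule)
  if (length(surv2) != m) {
    rlang::abort("`surv2` must have one probability per event")
  }
  if (is.null(surv3)) {
    if (!squared && any(schedule == 3L)) {
      rlang::abort("`surv3` required for tripling events unless `squared = TRUE`")
    }
    surv3 <- ifelse(schedule == 3L, surv2^2, NA_real_)
  } else {
    if (length(surv3) != m) {
      rlang::abort("`surv3` must have one value per event")
    }
    surv3 <- ifelse(schedule == 3L, surv3, NA_real_)
    if (any(schedule == 3L & is.na(surv3))) {
      rlang::abort("`surv3` missing for a tripling event")
    }
  }
  p <- vector("list", m)
  for (i in seq_len(m)) {
    if (schedule[i] == 2L) {
      pi <- c(1 - surv2[i], surv2[i])
    } else {
      pi <- c(1 - surv2[i] - surv3[i], surv2[i], surv3[i])
    }
    if (any(pi < -1e-12) || any(pi > 1 + 1e-12)) {
      rlang::abort(sprintf(
        "survival probabilities for event %d fall outside [0, 1] (p = %s)",
        i, paste(signif(pi, 4), collapse = ", ")
      ))
    }
    p[[i]] <- pmin(pmax(pi, 0), 1)
  }
  structure(
    list(schedule = schedule, p = p,
         surv2 = as.numeric(surv2),
         surv3 = as.numeric(surv3)),
    class = "survival_params"
  )
}

#' @export
print.survival_params <- function(x, ...) {
  cat("<survival_params> schedule ", format(x$schedule), "\n", sep = "")
  for (i in seq_along(x$p)) {
    cat(sprintf("  event %d (r=%d): p = %s\n", i, x$schedule[i],
                paste(signif(x$p[[i]], 4), collapse = ", ")))
  }
  invisible(x)
}

check_consistent <- function(schedule, params) {
  schedule <- as_schedule(schedule)
  if (!inherits(params, "survival_params")) {
    rlang::abort("`params` must be a `survival_params` object")
  }
  if (length(schedule) != length(params$schedule) ||
      any(unclass(schedule) != unclass(params$schedule))) {
    rlang::abort("schedule and survival parameters describe different event sequences")
  }
  schedule
}

# per-event factors used throughout the expectation algebra:
#   leaf_factor  e_i = E[survivors per gene]          (1+u or 1+u+2u')
#   pair_factor  q_i = E[pairs of survivors per gene] (u or u+3u')
#   trip_factor  s_i = E[surviving triples per gene]  (0 or u')
event_factors <- function(params) {
  r <- unclass(params$schedule)
  p2 <- params$surv2
  p3 <- ifelse(is.na(params$surv3), 0, params$surv3)
  list(
    leaf = 1 + p2 + 2 * p3,
    pair = p2 + 3 * p3,
    trip = ifelse(r == 3L, p3, 0)
  )
}
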