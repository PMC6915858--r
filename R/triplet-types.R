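#' Enumerate triplet types for m events
#'
#' A triplet type is the multiset of the three pairwise divergence events of
#' a gene triple, e.g. `{t1,t1,t2}`.  For `m` events there are
#' \eqn{m(m+1)(m+2)/6} types (the tetrahedral numbers: 4, 10, 20 for
#' m = 2, 3, 4).  A type is *realizable* under the ultrametric branching
#' process only when its oldest event index occurs at least twice: the two
#' younger pairwise divergences of a triple always share their oldest
#' divergence.
#'
#' @param m Number of events.
#' @return A tibble with one row per type: `type` (label like `"t1,t1,t2"`),
#'   `e1`, `e2`, `e3` (sorted event indices) and `realizable`.
#' @examples
#' triplet_types(2)
#' @export
triplet_types <- function(m) {
  m <- as.integer(m)
  stopifnot(m >= 1)
  combos <- expand.grid(e3 = 1:m, e2 = 1:m, e1 = 1:m)
  combos <- combos[combos$e1 <= combos$e2 & combos$e2 <= combos$e3, c("e1", "e2", "e3")]
  combos <- combos[order(combos$e1, combos$e2, combos$e3), ]
  tibble::tibble(
    type = type_label(combos$e1, combos$e2, combos$e3),
    e1 = combos$e1, e2 = combos$e2, e3 = combos$e3,
    realizable = combos$e1 == combos$e2
  )
}

type_label <- function(e1, e2, e3) {
  paste0("t", e1, ",t", e2, ",t", e3)
}

# index of sorted multiset (a <= b <= c) within triplet_types(m) row order
type_index <- function(a, b, c, m) {
  lab <- type_label(a, b, c)
  match(lab, triplet_types(m)$type)
}

parse_type <- function(type) {
  as.integer(sub("^t", "", strsplit(type, ",", fixed = TRUE)[[1]]))
}

#' Number of triplet types for m events
#'
#' The tetrahedral number \eqn{m(m+1)(m+2)/6}.
#'
#' @param m Number of events.
#' @return Integer count.
#' @examples
#' n_triplet_types(2:4)  # 4, 10, 20
#' @export
n_triplet_types <- function(m) {
  as.integer(round(m * (m + 1) * (m + 2) / 6))
}

#' Build a triplet profile tibble
#'
#' A profile maps every triplet type of an m-event analysis to a
#' non-negative value: expected counts (underlying), empirical triangle
#' counts (observed) or model expectations after divergence (predicted).
#'
#' @param values Numeric vector in `triplet_types(m)` row order, or a named
#'   vector keyed by type label (missing types filled with 0).
#' @param m Number of events.
#' @param label One of `"underlying"`, `"observed"`, `"predicted"` (free
#'   text is allowed for intermediate results).
#' @return A tibble with columns `type`, `value`, `label`.
#' @export
new_profile <- function(values, m, label) {
  types <- triplet_types(m)$type
  if (!is.null(names(values))) {
    v <- stats::setNames(rep(0, length(types)), types)
    unknown <- setdiff(names(values), types)
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown triplet type(s): ", paste(unknown, collapse = ", ")))
    }
    v[names(values)] <- values
    values <- unname(v)
  }
  if (length(values) != length(types)) {
    rlang::abort("`values` must cover every triplet type")
  }
  if (any(values < -1e-9)) {
    rlang::abort("profile values must be non-negative")
  }
  tibble::tibble(type = types, value = pmax(values, 0), label = label)
}

profile_values <- function(profile, m = NULL) {
  if (is.null(m)) {
    m <- parse_type(profile$type[nrow(profile)])[3]
  }
  types <- triplet_types(m)$type
  if (!setequal(profile$type, types)) {
    rlang::abort("profile does not cover the expected triplet type set")
  }
  stats::setNames(profile$value[match(types, profile$type)], types)
}

#' Rescale a profile to a target total
#'
#' Underlying and predicted profiles are normalized so their total matches
#' the observed number of triples before comparison.
#'
#' @param profile A profile tibble from [new_profile()].
#' @param total Target total (> 0).
#' @return The rescaled profile.
#' @export
normalize_profile <- function(profile, total) {
  s <- sum(profile$value)
  if (s <= 0) {
    rlang::abort("cannot normalize an all-zero profile (degenerate parameters)")
  }
  profile$value <- profile$value * (total / s)
  profile
}
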