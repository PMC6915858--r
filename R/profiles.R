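# Expected pair and triplet profiles per root gene.

# product-form expectations from the per-event factors:
#   E[leaves]            = prod_i e_i
#   E[pairs at event l]  = (prod_{i<l} e_i) q_l (prod_{i>l} e_i)^2
#   W({a,a,a})           = (prod_{i<a} e_i) s_a (prod_{i>a} e_i)^3
#   W({a,a,b}), b > a    = (prod_{i<a} e_i) 2 q_a
#                          * (prod_{a<i<b} e_i) q_b (prod_{i>b} e_i)^2
#                          * (prod_{i>a} e_i)
# (pair of lineages split at a, one carrying a pair diverged at b, the
#  other a single leaf; every other type is a structural zero)
product_pair_counts <- function(params) {
  f <- event_factors(params)
  m <- length(f$leaf)
  vapply(seq_len(m), function(l) {
    prod(f$leaf[seq_len(l - 1)]) * f$pair[l] *
      prod(f$leaf[seq_len(m)[-seq_len(l)]])^2
  }, numeric(1))
}

product_profile <- function(params) {
  f <- event_factors(params)
  m <- length(f$leaf)
  pre <- cumprod(c(1, f$leaf))[seq_len(m)]          # prod_{i<a} e_i
  post <- rev(cumprod(c(1, rev(f$leaf))))[-1]       # prod_{i>a} e_i
  vals <- numeric(0)
  for (a in seq_len(m)) {
    vals[type_label(a, a, a)] <- pre[a] * f$trip[a] * post[a]^3
    if (a < m) {
      for (b in (a + 1):m) {
        mid <- prod(f$leaf[seq_len(m)][seq_len(m) > a & seq_len(m) < b])
        vals[type_label(a, a, b)] <-
          pre[a] * 2 * f$pair[a] * mid * f$pair[b] * post[b]^2 * post[a]
      }
    }
  }
  vals
}

#' Expected triplet profile per root gene
#'
#' The expected number of gene triples of each type produced by one root
#' gene under the branching process.  Three routes are available:
#' `"closed"` evaluates the tabulated polynomials (2 or 3 events),
#' `"enumeration"` sums over the exhaustive genealogy enumeration, and
#' `"product"` multiplies out per-event leaf/pair/triple factors (any
#' number of events).  `"auto"` picks the closed form when available and
#' the product form otherwise.  All routes agree to floating tolerance.
#'
#' @param schedule An [event_schedule()].
#' @param params Matching [survival_params()].
#' @param method One of `"auto"`, `"closed"`, `"enumeration"`, `"product"`.
#' @param max_shapes Enumeration guard, see [enumerate_genealogies()].
#' @return A profile tibble (label `"underlying"`), per-root expectations.
#' @examples
#' sched <- event_schedule(c(2, 2))
#' expected_triplet_profile(sched, survival_params(sched, c(0.5, 0.5)))
#' @export
expected_triplet_profile <- function(schedule, params,
                                     method = c("auto", "closed",
                                                "enumeration", "product"),
                                     max_shapes = 2e5) {
  schedule <- check_consistent(schedule, params)
  method <- match.arg(method)
  m <- length(schedule)
  if (method == "auto") {
    method <- if (m <= 3) "closed" else "product"
  }
  switch(method,
    closed = closed_form_profile(schedule, params),
    product = new_profile(product_profile(params), m, "underlying"),
    enumeration = {
      tab <- shape_table(schedule, max_shapes)
      w <- shape_weights(tab, params)
      new_profile(as.numeric(crossprod(w, tab$triples)), m, "underlying")
    }
  )
}

#' Expected paralog pair counts per root gene
#'
#' Expected number of extant gene pairs whose divergence traces to each
#' event, per root gene.
#'
#' @inheritParams expected_triplet_profile
#' @param method `"enumeration"` (default; classify leaf pairs in every
#'   genealogy) or `"product"` (per-event factor products, any m).
#' @return Named numeric vector `t1..tm`.
#' @examples
#' sched <- event_schedule(c(2, 2))
#' expected_pair_counts(sched, survival_params(sched, c(0.5, 0.5)))
#' @export
expected_pair_counts <- function(schedule, params,
                                 method = c("enumeration", "product"),
                                 max_shapes = 2e5) {
  schedule <- check_consistent(schedule, params)
  method <- match.arg(method)
  m <- length(schedule)
  nm <- paste0("t", seq_len(m))
  if (method == "product") {
    return(stats::setNames(product_pair_counts(params), nm))
  }
  tab <- shape_table(schedule, max_shapes)
  w <- shape_weights(tab, params)
  stats::setNames(as.numeric(crossprod(w, tab$pairs)), nm)
}

#' Underlying profile scaled to an observed total
#'
#' The per-root expected triplet profile of a model, normalized so its
#' total matches the observed number of triples (the form in which
#' underlying profiles are compared to data).
#'
#' @inheritParams expected_triplet_profile
#' @param observed_total Total to scale to (> 0).
#' @return A profile tibble (label `"underlying"`).
#' @export
underlying_profile <- function(schedule, params, observed_total,
                               method = c("auto", "closed",
                                          "enumeration", "product")) {
  stopifnot(observed_total > 0)
  prof <- expected_triplet_profile(schedule, params, method = match.arg(method))
  normalize_profile(prof, observed_total)
}

#' Write or read a profile as tab-separated text
#'
#' @param profile A profile tibble.
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns the profile tibble.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    type = readr::col_character(),
    value = readr::col_double(),
    label = readr::col_character()
  ))
}
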