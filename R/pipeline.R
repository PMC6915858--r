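# End-to-end orchestration: read -> filter -> mixture fit -> transition
# points -> triangles -> covariance -> per-model profiles -> ranking.

#' Run the full ploidy-inference pipeline
#'
#' Reads a syntenic pair list, filters it to the exclusion window, fits a
#' k-component Gaussian mixture, finds the ML transition points, extracts
#' gene triangles and the observed profile, estimates per-model survival
#' parameters from the classified pair counts, builds underlying and
#' predicted profiles for every candidate model and ranks them against the
#' observed profile.
#'
#' @param input Path to a tab-separated pair list, or a pair tibble.
#' @param k Number of mixture components (= number of events analysed).
#' @param fix_means Optional length-k vector pinning component means
#'   (`NA` = free), e.g. `c(71, 79.5, NA)` for a cabbage-style analysis.
#' @param exclude_below,exclude_above Similarity exclusion cutoffs
#'   (defaults: pairs must exceed 50 percent similarity and pairs above 98
#'   percent are treated as non-polyploid).
#' @param models Candidate schedules: `NULL` (all `2^k` k-event models), a
#'   list of [event_schedule()]s, or a character vector like `"(3,2)"`.
#' @param squared Apply the squared constraint at tripling events during
#'   estimation.
#' @param grid_step Passed to [ml_transition_points()].
#' @param out Optional output directory; when given, writes
#'   `ranking.tsv`, `profiles.tsv`, `mixture.json` and `run.log`.
#' @return A `triplet_analysis` list: `mixture`, `cutoffs`, `pairs`
#'   (filtered), `pair_counts`, `triples` count, `observed`, `fits`
#'   (per-model `survival_fit`), `profiles` (long tibble of
#'   underlying/predicted/observed), `comparison`, `log`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(G = 2000, seed = 42)
#' sim <- simulate_pairs(cfg)
#' res <- run_pipeline(sim$pairs, k = 2)
#' res$comparison
#' }
#' @export
run_pipeline <- function(input, k = 2, fix_means = NULL,
                         exclude_below = 50, exclude_above = 98,
                         models = NULL, squared = TRUE,
                         grid_step = NULL, out = NULL) {
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    rlang::inform(msg)
  }
  collect <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) {
        log_lines <<- c(log_lines, paste("warning:", conditionMessage(w)))
        rlang::cnd_muffle(w)
      },
      message = function(m) {
        log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
        rlang::cnd_muffle(m)
      }
    )
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }

  pairs <- stage("read", {
    if (is.character(input)) {
      if (!file.exists(input)) rlang::abort(paste0("input file not found: ", input))
      collect(read_pairs(input))
    } else {
      input
    }
  })
  note("read %d pairs", nrow(pairs))
  pairs <- stage("filter", filter_pairs(pairs, exclude_below, exclude_above))
  note("filtered to %d pairs (removed %d low, %d high; window (%g, %g])",
       nrow(pairs), attr(pairs, "n_removed_low"), attr(pairs, "n_removed_high"),
       exclude_below, exclude_above)

  mixture <- stage("fit", collect(fit_mixture(pairs$similarity, k, fixed_means = fix_means)))
  note("mixture: k = %d, means %s, logLik %.2f%s", k,
       paste(signif(mixture$components$mean, 4), collapse = ", "),
       mixture$loglik, if (mixture$converged) "" else " (EM not converged)")
  cutoffs <- stage("cutoffs", ml_transition_points(pairs$similarity, mixture, grid_step))
  note("transition points: %s", paste(signif(unclass(cutoffs), 4), collapse = ", "))

  triples <- stage("triples", extract_triples(pairs))
  observed <- stage("profile", observed_profile(triples, cutoffs, m = k))
  note("%d triples; observed profile: %s", nrow(triples),
       paste(sprintf("%s=%d", observed$type, as.integer(observed$value)), collapse = ", "))
  if (nrow(triples) == 0) rlang::abort("[profile] no gene triangles in the filtered pair list")

  cov <- stage("covariance",
               collect(estimate_triplet_covariance(triples, cutoffs, mixture = mixture, m = k)))

  ev <- classify_similarity(pairs$similarity, cutoffs)
  pair_counts <- vapply(seq_len(k), function(e) sum(ev == e), numeric(1))
  genes_obs <- length(unique(c(pairs$gene_a, pairs$gene_b)))
  note("classified pair counts: %s; %d paralog-bearing genes",
       paste(pair_counts, collapse = ", "), genes_obs)

  if (is.null(models)) {
    models <- candidate_schedules(k)
  } else if (is.character(models)) {
    models <- lapply(models, function(s) {
      event_schedule(as.integer(strsplit(gsub("[() ]", "", s), ",")[[1]]))
    })
    names(models) <- vapply(models, format, character(1))
  } else {
    models <- lapply(models, as_schedule)
    names(models) <- vapply(models, format, character(1))
  }
  if (any(vapply(models, length, integer(1)) != k)) {
    rlang::abort("[models] every candidate schedule must have k events")
  }

  total <- sum(observed$value)
  fits <- list(); underlying <- list(); predicted <- list()
  for (nm in names(models)) {
    sched <- models[[nm]]
    fit <- stage(paste0("estimate ", nm),
                 collect(estimate_survival_params(sched, pair_counts, genes_obs,
                                                  genes = "paired", squared = squared)))
    fits[[nm]] <- fit
    underlying[[nm]] <- underlying_profile(sched, fit$params, total)
    predicted[[nm]] <- stage(paste0("predict ", nm),
                             collect(predicted_profile(sched, fit$params, mixture,
                                                       cov, cutoffs, total)))
    note("model %s: surv2 = %s, G = %.0f, residual %.3g", nm,
         paste(signif(fit$params$surv2, 3), collapse = ", "), fit$G, fit$residual)
  }
  comparison <- stage("compare", compare_profiles(observed, predicted))
  note("ranking: %s", paste(comparison$model, collapse = " > "))

  profiles <- dplyr::bind_rows(
    dplyr::mutate(observed, model = NA_character_),
    purrr::imap_dfr(underlying, ~ dplyr::mutate(.x, model = .y)),
    purrr::imap_dfr(predicted, ~ dplyr::mutate(.x, model = .y))
  )

  res <- structure(
    list(mixture = mixture, cutoffs = cutoffs, pairs = pairs,
         pair_counts = pair_counts, genes_observed = genes_obs,
         n_triples = nrow(triples), observed = observed,
         covariance = cov, fits = fits,
         profiles = profiles, comparison = comparison,
         settings = list(k = k, fix_means = fix_means,
                         exclude_below = exclude_below,
                         exclude_above = exclude_above, squared = squared),
         log = log_lines),
    class = "triplet_analysis"
  )
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(comparison), file.path(out, "ranking.tsv"))
    readr::write_tsv(profiles, file.path(out, "profiles.tsv"))
    mixture_to_json(mixture, cutoffs,
                    exclusions = c(exclude_below, exclude_above),
                    path = file.path(out, "mixture.json"))
    writeLines(log_lines, file.path(out, "run.log"))
  }
  res
}

#' @export
print.triplet_analysis <- function(x, ...) {
  cat("<triplet_analysis> k =", x$settings$k, "events,",
      nrow(x$pairs), "pairs,", x$n_triples, "triples\n")
  cat("  transition points:",
      paste(signif(unclass(x$cutoffs), 4), collapse = ", "), "\n")
  cat("  best model:", x$comparison$model[1], "\n")
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `triplet_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: the model ranking; `glance()`: a one-row summary.
#' @method tidy triplet_analysis
#' @export
tidy.triplet_analysis <- function(x, ...) tibble::as_tibble(x$comparison)

#' @rdname tidy.triplet_analysis
#' @method glance triplet_analysis
#' @export
glance.triplet_analysis <- function(x, ...) {
  tibble::tibble(
    k = x$settings$k,
    n_pairs = nrow(x$pairs),
    n_triples = x$n_triples,
    best_model = x$comparison$model[1],
    best_chisq = x$comparison$chisq[1]
  )
}
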