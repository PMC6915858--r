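# ggplot2 diagnostics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a similarity mixture fit
#'
#' Histogram of the similarities with the fitted component densities and,
#' optionally, the transition points.
#'
#' @param object A `similarity_mixture`.
#' @param similarities The data the mixture was fitted to.
#' @param cutoffs Optional transition points to draw.
#' @param binwidth Histogram bin width (percent).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_mixture
#' @export
autoplot.similarity_mixture <- function(object, similarities, cutoffs = NULL,
                                        binwidth = 0.5, ...) {
  df <- tibble::tibble(similarity = as.numeric(similarities))
  comps <- object$components
  grid <- seq(min(df$similarity), max(df$similarity), length.out = 400)
  dens <- purrr::pmap_dfr(comps, function(component, mean, sd, proportion, ...) {
    tibble::tibble(
      similarity = grid,
      density = proportion * stats::dnorm(grid, mean, sd),
      component = factor(component)
    )
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$similarity)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey80",
                            colour = "grey60", linewidth = 0.2) +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component),
                       linewidth = 0.8) +
    ggplot2::labs(x = "similarity (%)", y = "density",
                  colour = "component")
  if (!is.null(cutoffs) && length(cutoffs) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(cutoffs),
                                 linetype = "dashed")
  }
  p
}

#' Plot observed vs candidate profiles
#'
#' Grouped bar chart of the observed profile next to each model's
#' predicted (or underlying) profile.
#'
#' @param object A `triplet_analysis` from [run_pipeline()].
#' @param which Profile label to compare against the observation
#'   (`"predicted"` or `"underlying"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triplet_analysis
#' @export
autoplot.triplet_analysis <- function(object, which = "predicted", ...) {
  prof <- object$profiles
  obs <- prof[prof$label == "observed", ]
  cand <- prof[prof$label == which, ]
  df <- dplyr::bind_rows(
    dplyr::mutate(obs, series = "observed"),
    dplyr::mutate(cand, series = .data$model)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$value,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "triplet type", y = "triples", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.triplet_analysis
#' @param analysis A `triplet_analysis`.
#' @export
plot_profiles <- function(analysis, which = "predicted") {
  autoplot.triplet_analysis(analysis, which = which)
}
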