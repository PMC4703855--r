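#' Plot eigenvector component profiles
#'
#' Bar profile of the leading right, left and reactivity eigenvector
#' magnitudes per species, animals first, each guild sorted by degree when
#' a network is supplied. Localized communities show a few dominant bars;
#' extended ones a flat profile near `1 / sqrt(S)`.
#'
#' @param object A [spectral_summary()].
#' @param net Optional [bipartite_network()] used to sort species by guild
#'   and degree.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_summary <- function(object, net = NULL, ...) {
  df <- tidy(object)
  df <- tidyr::pivot_longer(df, c("v1", "u1", "wH"),
                            names_to = "eigenvector", values_to = "component")
  df$component <- abs(df$component)
  if (!is.null(net)) {
    td <- tidy(net)
    df <- dplyr::left_join(df, td, by = "species")
    lev <- td$species[order(td$guild, -td$degree)]
    df$species <- factor(df$species, levels = lev)
  } else {
    df$species <- factor(df$species, levels = object$labels)
  }
  S <- length(object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 / sqrt(S), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$eigenvector), ncol = 1) +
    ggplot2::labs(x = NULL, y = "|component|",
                  caption = "dashed line: extended-state level 1/sqrt(S)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a null-ensemble comparison
#'
#' Histogram of the null sample with the observed value marked; the gap
#' between them is what the ratio and empirical p-value quantify.
#'
#' @param object A `null_ensemble` from [null_ensemble()], [ripr()] or
#'   [relative_amplitude()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = object$statistic_name,
      title = sprintf("%s vs %s: ratio %.3f, p = %.3g",
                      object$statistic_name, object$model,
                      object$ratio, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation trajectory
#'
#' Per-species trajectories of the linearized response to a pulse, with the
#' norm envelope overlaid; a transiently rising envelope at a stable
#' equilibrium is the signature of reactivity.
#'
#' @param object A `propagation` from [propagate()].
#' @param max_species Show at most this many species (largest initial
#'   impact first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.propagation <- function(object, max_species = 20, ...) {
  df <- tidy(object)
  keep <- utils::head(object$spectral$labels[order(-abs(object$xi))], max_species)
  df <- df[df$species %in% keep, ]
  env <- tibble(time = object$t,
                value = object$envelope * sqrt(sum(object$xi^2)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$species)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = env, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "time", y = "perturbation",
                  caption = "red: L2 envelope of the full response") +
    ggplot2::theme_minimal()
}
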