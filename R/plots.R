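#' Plot a simulated trajectory
#'
#' Colony-type frequencies over (rescaled) time, with the mutant-allele
#' frequency in the mating pools overlaid as a dashed line.
#'
#' @param object a [simulate_dynamics()] trajectory.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sterility_trajectory <- function(object, ...) {
  long <- tidy(object)
  af <- tibble(
    time = object$times,
    frequency = apply(object$states, 1, mutant_allele_frequency, object$params)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$frequency)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$colony)) +
    ggplot2::geom_line(data = af, linetype = "dashed") +
    ggplot2::labs(
      x = "time (rescaled units)", y = "frequency",
      colour = "colony type",
      title = sprintf("n = %d, %s sterility allele", object$params$n,
                      object$params$dominance),
      subtitle = "dashed: mutant-allele frequency in the mating pools"
    )
}

#' Plot a phase diagram
#'
#' Raster of the regime (or per-n invasion outcome) over the two varied
#' colony-efficiency axes.
#'
#' @param object a [phase_diagram()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  axes <- attr(object, "axes")
  labs <- sprintf("r at z = %s", axes)
  if (attr(object, "what") == "regime") {
    ggplot2::ggplot(object, ggplot2::aes(.data$r_z1, .data$r_z2,
                                         fill = .data$regime)) +
      ggplot2::geom_raster() +
      ggplot2::labs(x = labs[1], y = labs[2], fill = "regime")
  } else {
    long <- tidyr::pivot_longer(as_tibble(object),
                                dplyr::starts_with("invades_"),
                                names_to = "n", names_prefix = "invades_n",
                                values_to = "invades")
    ggplot2::ggplot(long, ggplot2::aes(.data$r_z1, .data$r_z2,
                                       fill = .data$invades)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~n, labeller = ggplot2::label_both) +
      ggplot2::labs(x = labs[1], y = labs[2], fill = "invades")
  }
}

#' Plot outcome probabilities
#'
#' Bar chart of the four mutually exclusive experiment outcomes with
#' Monte-Carlo standard-error bars where applicable.
#'
#' @param object an outcome-probability tibble from
#'   [invasion_outcome_probabilities()] or
#'   [regime_outcome_probabilities()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.outcome_probabilities <- function(object, ...) {
  d <- as_tibble(object)
  d$outcome <- factor(d$outcome, levels = d$outcome)
  ggplot2::ggplot(d, ggplot2::aes(.data$outcome, .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$probability - 2 * .data$standard_error,
                   ymax = .data$probability + 2 * .data$standard_error),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "probability",
                  title = attr(object, "scenario"),
                  subtitle = sprintf("method: %s", attr(object, "method")))
}
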