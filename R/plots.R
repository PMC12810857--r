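#' Plot a trajectory of the three strategy shares
#'
#' @param object A `game_trajectory`.
#' @param ... Unused.
#' @return A ggplot: shares vs time, one line per population.
#' @method autoplot game_trajectory
#' @export
autoplot.game_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("delta", "eta", "zeta"),
    names_to = "share", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time, y = .data$value, colour = .data$share
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(labels = c(
      delta = "public participation (δ)",
      eta = "institution compliance (η)",
      zeta = "strict supervision (ζ)"
    )) +
    ggplot2::labs(x = "time", y = "strategy share", colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot corner-equilibrium eigenvalues
#'
#' @param object A `game_stability` object.
#' @param ... Unused.
#' @return A ggplot: the three Jacobian eigenvalues per corner, coloured by
#'   classification.
#' @method autoplot game_stability
#' @export
autoplot.game_stability <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$equilibria, c("lambda1", "lambda2", "lambda3"),
    names_to = "eigenvalue", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$label, y = .data$value, shape = .data$eigenvalue,
    colour = .data$classification
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "corner equilibrium", y = "Jacobian eigenvalue")
}

#' Plot a parameter sweep
#'
#' @param object A `game_sweep`.
#' @param ... Unused.
#' @return A ggplot; line (1 swept parameter) or tile map (2).
#' @method autoplot game_sweep
#' @export
autoplot.game_sweep <- function(object, ...) {
  metric <- attr(object, "metric_name")
  swept <- setdiff(names(object), c("metric", "value"))
  if (length(swept) == 1) {
    ggplot2::ggplot(object, ggplot2::aes(
      x = .data[[swept[1]]], y = .data$value
    )) +
      (if (is.numeric(object$value)) ggplot2::geom_line()
       else ggplot2::geom_point()) +
      ggplot2::geom_point() +
      ggplot2::labs(x = swept[1], y = metric)
  } else {
    ggplot2::ggplot(object, ggplot2::aes(
      x = .data[[swept[1]]], y = .data[[swept[2]]], fill = .data$value
    )) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = swept[1], y = swept[2], fill = metric)
  }
}

#' Plot sensitivity indices
#'
#' @param object A `game_sensitivity`.
#' @param ... Unused.
#' @return A ggplot bar chart of first-order indices.
#' @method autoplot game_sensitivity
#' @export
autoplot.game_sensitivity <- function(object, ...) {
  idx <- object$indices
  ggplot2::ggplot(idx, ggplot2::aes(
    x = stats::reorder(.data$parameter, .data$first_order),
    y = .data$first_order
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "first-order sensitivity index of final η")
}
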