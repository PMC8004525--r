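species_labels <- c(V = "fox (V)", S = "cottontail (S)", L = "hare (L)")

#' Plot a trajectory
#'
#' Densities of the three species against time.
#'
#' @param object An `hp_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_trajectory <- function(object, ...) {
  df <- tidy.hp_trajectory(object)
  df$species <- factor(species_labels[df$species],
    levels = unname(species_labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$density, colour = .data$species
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (years)", y = "density (per km²)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a one-parameter sweep
#'
#' Attractor label along the swept parameter, with the localized
#' transcritical thresholds as dashed lines.
#'
#' @param object An `hp_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_sweep <- function(object, ...) {
  g <- ggplot2::ggplot(object$grid, ggplot2::aes(
    x = .data$value, y = .data$label, colour = .data$label
  )) +
    ggplot2::geom_point(na.rm = TRUE, show.legend = FALSE) +
    ggplot2::labs(x = object$parameter, y = "attractor") +
    ggplot2::theme_minimal()
  if (nrow(object$points) > 0) {
    g <- g + ggplot2::geom_vline(
      xintercept = object$points$critical_value, linetype = "dashed",
      colour = "grey40"
    )
  }
  g
}

#' Plot per-bin log-hare versus fox regressions
#'
#' Scatter of `log(L)` against `V` for the usable records of each
#' cottontail-density bin, with the fitted least-squares lines.
#'
#' @param object An `hp_binfit` from [fit_loghare_vs_fox()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_binfit <- function(object, ...) {
  pts <- attr(object, "data")
  if (is.null(pts) || nrow(pts) == 0) {
    abort("no usable records to plot", class = "hp_invalid_input")
  }
  lines <- tibble::as_tibble(object)[object$defined, ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$V, y = .data$ln_L)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      colour = "firebrick"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$bin)) +
    ggplot2::labs(
      x = "fox density V (per km²)", y = "log hare density ln(L)"
    ) +
    ggplot2::theme_minimal()
}
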