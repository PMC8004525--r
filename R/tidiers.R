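#' Tidy an equilibrium census
#'
#' Flattens the list-columns: one row per equilibrium with the smallest
#' feasibility and stability margins and the leading eigenvalue's real
#' part.
#'
#' @param x An `hp_equilibria` tibble.
#' @param ... Unused.
#' @return A tibble with atomic columns only.
#' @export
tidy.hp_equilibria <- function(x, ...) {
  dplyr::mutate(
    tibble::as_tibble(x)[, c("label", "V", "S", "L", "feasible", "stable")],
    min_feas_margin = vapply(x$feas_margins, min, double(1)),
    min_stab_margin = vapply(x$stab_margins, min, double(1)),
    leading_re = vapply(x$eigenvalues, function(ev) max(Re(ev)), double(1))
  )
}

#' @rdname tidy.hp_equilibria
#' @export
glance.hp_equilibria <- function(x, ...) {
  hit <- x[x$feasible & x$stable, ]
  tibble(
    n_feasible = sum(x$feasible),
    n_stable = sum(x$stable),
    attractor = if (nrow(hit) == 1) hit$label else NA_character_
  )
}

#' Tidy a trajectory into long species-by-time form
#'
#' @param x An `hp_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `density`.
#' @export
tidy.hp_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), c("V", "S", "L"),
    names_to = "species", values_to = "density"
  )
}

#' @rdname tidy.hp_trajectory
#' @export
glance.hp_trajectory <- function(x, ...) {
  fin <- attr(x, "final_state")
  tibble(
    t_end = max(x$time), converged = attr(x, "converged"),
    V_final = fin[["V"]], S_final = fin[["S"]], L_final = fin[["L"]],
    max_total = boundedness_audit(x)
  )
}

#' Tidy a one-parameter sweep
#'
#' @param x An `hp_sweep`.
#' @param ... Unused.
#' @return The detected bifurcation points as a tibble.
#' @export
tidy.hp_sweep <- function(x, ...) {
  tibble::as_tibble(x$points)
}

#' @rdname tidy.hp_sweep
#' @export
glance.hp_sweep <- function(x, ...) {
  tibble(
    parameter = x$parameter,
    n_grid = nrow(x$grid),
    n_boundary_samples = sum(is.na(x$grid$label)),
    n_points = nrow(x$points),
    chain = paste(x$chain, collapse = " -> ")
  )
}

#' Summaries of an ensemble run
#'
#' @param x An `hp_ensemble`.
#' @param ... Unused.
#' @return `glance()` reports run counts and the worst closed-form
#'   deviation.
#' @export
glance.hp_ensemble <- function(x, ...) {
  tibble(
    n_converged = nrow(x),
    n_excluded = nrow(attr(x, "excluded") %||% x[0, ]),
    n_labelled = sum(!is.na(x$label)),
    max_cf_dev = suppressWarnings(max(x$cf_dev, na.rm = TRUE)),
    seed = attr(x, "seed")
  )
}

#' @rdname glance.hp_ensemble
#' @export
tidy.hp_ensemble <- function(x, ...) {
  dplyr::count(tibble::as_tibble(x), .data$label)
}

#' Summaries of per-bin regressions
#'
#' @param x An `hp_binfit`.
#' @param ... Unused.
#' @return `tidy()` returns the per-bin lines; `glance()` the slope trend.
#' @export
tidy.hp_binfit <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "bin", "n_used", "slope", "intercept", "slope_se", "defined"
  )]
}

#' @rdname tidy.hp_binfit
#' @export
glance.hp_binfit <- function(x, ...) {
  slope_trend(x)
}
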