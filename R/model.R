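# State vectors are length-3 numerics ordered (V, S, L):
# fox, cottontail, hare densities per km^2.
as_state <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, c("V", "S", "L")])
  state <- as.double(state)
  if (length(state) != 3) {
    abort("a state has exactly three components (V, S, L)",
      class = "hp_invalid_input"
    )
  }
  setNames(state, c("V", "S", "L"))
}

check_state <- function(state) {
  if (any(!is.finite(state))) {
    abort("state components must be finite", class = "hp_invalid_input")
  }
  if (any(state < 0)) {
    abort("state components must be nonnegative", class = "hp_invalid_input")
  }
  invisible(state)
}

# Unchecked right-hand side; the hot path for integration and ensembles.
rhs_raw <- function(state, params) {
  V <- state[[1]]
  S <- state[[2]]
  L <- state[[3]]
  c(
    V * (params$r - params$c_VV * V - params$m +
      params$e * params$a * S + params$e * params$b * L),
    S * (params$s - params$c_SS * S - params$n - params$a * V),
    L * (params$u - params$c_LL * L - params$p - params$b * V)
  )
}

jacobian_raw <- function(state, params) {
  V <- state[[1]]
  S <- state[[2]]
  L <- state[[3]]
  with(params, matrix(
    c(
      r - 2 * c_VV * V - m + e * a * S + e * b * L, e * a * V, e * b * V,
      -a * S, s - 2 * c_SS * S - n - a * V, 0,
      -b * L, 0, u - 2 * c_LL * L - p - b * V
    ),
    nrow = 3, byrow = TRUE, dimnames = list(c("V", "S", "L"), c("V", "S", "L"))
  ))
}

#' Per-capita growth balance: the model right-hand side
#'
#' The instantaneous rates of change of the three densities. Foxes (`V`)
#' grow logistically with separate reproduction `r` and mortality `m` and
#' gain `e * (a S + b L)` per fox from predation; cottontails (`S`) and
#' hares (`L`) grow logistically and are removed at bilinear (Holling
#' type I) rates `a V` and `b V` respectively. Each component carries its
#' own population as a factor, so the extinction faces `V = 0`, `S = 0`,
#' `L = 0` are invariant.
#'
#' @param state Numeric length-3 `(V, S, L)`, nonnegative.
#' @param params An [hp_params] object with hunting rates set.
#' @return Named numeric length-3: `(dV/dt, dS/dt, dL/dt)`.
#' @examples
#' growth_rates(c(0.4, 1, 3), reference_params(a = 0.2, b = 0.5))
#' @export
growth_rates <- function(state, params) {
  state <- check_state(as_state(state))
  require_hunting_rates(params)
  setNames(rhs_raw(state, params), c("V", "S", "L"))
}

#' Jacobian of the model right-hand side
#'
#' Analytic 3x3 Jacobian, rows and columns ordered (V, S, L). The two prey
#' never interact directly, so the (S, L) and (L, S) entries are exactly
#' zero; at the origin the matrix is diagonal with the net reproduction
#' rates r - m, `s - n`, `u - p`.
#'
#' @inheritParams growth_rates
#' @return A 3x3 numeric matrix with dimnames `c("V", "S", "L")`.
#' @examples
#' jacobian_matrix(c(0, 0, 0), reference_params(a = 0.2, b = 0.5))
#' @export
jacobian_matrix <- function(state, params) {
  state <- check_state(as_state(state))
  require_hunting_rates(params)
  jacobian_raw(state, params)
}

#' Total environmental population
#'
#' The sum `A = V + S + L`, the quantity whose boundedness confines all
#' trajectories to a compact set.
#'
#' @param state Numeric length-3 `(V, S, L)`, or a data frame with columns
#'   `V`, `S`, `L` (summed row-wise).
#' @return A single density, or a vector of densities for a data frame.
#' @examples
#' total_population(c(0.4, 1, 3))
#' @export
total_population <- function(state) {
  if (is.data.frame(state)) {
    return(state$V + state$S + state$L)
  }
  sum(check_state(as_state(state)))
}
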