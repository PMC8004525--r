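#' Model parameter set
#'
#' Bundles the twelve nonnegative rates of the fox-cottontail-hare system:
#' reproduction rates `r`, `s`, `u` and mortality rates `m`, `n`, `p`
#' (per year) for fox, cottontail and hare respectively; intraspecific
#' competition coefficients `c_VV`, `c_SS`, `c_LL`
#' (per individual/km^2 per year); the prey-to-predator conversion
#' coefficient `e` (dimensionless, in (0, 1]); and the fox hunting rates
#' `a` (on cottontails) and `b` (on hares), per individual/km^2 per year.
#' Time is measured in years and densities in individuals per km^2
#' throughout the package.
#'
#' The hunting rates may be left `NA` in a reference set and supplied later
#' by scenario code; every analysis function that needs them checks first.
#'
#' @param r,s,u Reproduction rates (per year) of fox, cottontail, hare.
#' @param m,n,p Mortality rates (per year) of fox, cottontail, hare.
#' @param c_VV,c_SS,c_LL Intraspecific competition coefficients.
#' @param e Conversion coefficient of captured prey, in (0, 1].
#' @param a,b Fox hunting rates on cottontails and hares; may be `NA`.
#'
#' @return An object of class `hp_params`: a named list of the twelve rates.
#' @examples
#' hp_params(
#'   r = log(3), m = 2 / 7, c_VV = log(3) - 2 / 7, e = 0.91,
#'   s = log(4.5), n = 0.8, c_SS = (log(4.5) - 0.8) / 100,
#'   u = log(5), p = 2 / 11, c_LL = (log(5) - 2 / 11) / 30,
#'   a = 0.2, b = 0.5
#' )
#' @export
hp_params <- function(r, s, u, m, n, p, c_VV, c_SS, c_LL, e,
                      a = NA_real_, b = NA_real_) {
  x <- list(
    r = r, s = s, u = u, m = m, n = n, p = p,
    c_VV = c_VV, c_SS = c_SS, c_LL = c_LL, e = e, a = a, b = b
  )
  x <- lapply(x, as.double)
  validate_params(x)
  structure(x, class = "hp_params")
}

param_names <- c(
  "r", "s", "u", "m", "n", "p",
  "c_VV", "c_SS", "c_LL", "e", "a", "b"
)

validate_params <- function(x) {
  bad_len <- names(x)[lengths(x) != 1L]
  if (length(bad_len) > 0) {
    abort(paste0("parameters must be scalars: ", toString(bad_len)),
      class = "hp_invalid_input"
    )
  }
  vals <- unlist(x)
  known <- vals[!is.na(vals)]
  if (any(!is.finite(known))) {
    abort("parameters must be finite", class = "hp_invalid_input")
  }
  neg <- names(vals)[!is.na(vals) & vals < 0]
  if (length(neg) > 0) {
    abort(paste0("parameters must be nonnegative: ", toString(neg)),
      class = "hp_invalid_input"
    )
  }
  core <- setdiff(param_names, c("a", "b"))
  missing_core <- core[vapply(x[core], is.na, logical(1))]
  if (length(missing_core) > 0) {
    abort(paste0("parameters may not be NA: ", toString(missing_core)),
      class = "hp_invalid_input"
    )
  }
  if (is.na(x$e) || x$e <= 0 || x$e > 1) {
    abort("conversion coefficient e must lie in (0, 1]",
      class = "hp_invalid_input"
    )
  }
  invisible(x)
}

# Error early and clearly when scenario code forgot to set hunting rates.
require_hunting_rates <- function(params) {
  if (is.na(params$a) || is.na(params$b)) {
    abort("hunting rates a and b must be set (not NA) for this computation",
      class = "hp_invalid_input"
    )
  }
  invisible(params)
}

# Positive competition coefficients are needed for every closed-form
# equilibrium denominator.
require_competition <- function(params) {
  cc <- unlist(params[c("c_VV", "c_SS", "c_LL")])
  if (any(cc <= 0)) {
    abort("degenerate model: competition coefficients must be > 0",
      class = "hp_degenerate_model"
    )
  }
  invisible(params)
}

#' @export
as_tibble.hp_params <- function(x, ...) {
  tibble::as_tibble(x[param_names])
}

#' @export
print.hp_params <- function(x, ...) {
  cat("<hp_params> fox-cottontail-hare model rates (per year, per km^2)\n")
  print(as_tibble(x))
  invisible(x)
}

#' Mortality rate from mean lifespan
#'
#' Under exponential decay at rate `mu`, the mean lifetime is `1/mu`, so a
#' species with mean lifespan `T` years has mortality `1/T` per year.
#'
#' @param lifespan Mean lifespan in years, strictly positive. Vectorized.
#' @return Mortality rate(s) per year.
#' @examples
#' mortality_from_lifespan(3.5) # fox, ~0.28571
#' @export
mortality_from_lifespan <- function(lifespan) {
  if (!is.numeric(lifespan) || any(!is.finite(lifespan)) ||
    any(lifespan <= 0)) {
    abort("lifespan must be a positive number of years",
      class = "hp_invalid_input"
    )
  }
  1 / lifespan
}

#' Reproduction rate from an annual multiplication factor
#'
#' If a population multiplies by `factor` over one year under exponential
#' growth, `P(1) = factor * P(0) = exp(r) * P(0)`, so the per-year rate is
#' `log(factor)`.
#'
#' @param factor Annual multiplication ratio `P(1)/P(0)`, strictly positive.
#'   Vectorized.
#' @return Reproduction rate(s) per year.
#' @examples
#' reproduction_from_annual_factor(3) # fox population triples: log(3)
#' @export
reproduction_from_annual_factor <- function(factor) {
  if (!is.numeric(factor) || any(!is.finite(factor)) || any(factor <= 0)) {
    abort("annual multiplication factor must be positive",
      class = "hp_invalid_input"
    )
  }
  log(factor)
}

#' Intraspecific competition coefficient from a carrying capacity
#'
#' A species alone settles at the single-species equilibrium
#' `(growth - mortality) / c`, so the coefficient pinning that equilibrium
#' at a target density `K` is `(growth - mortality) / K`.
#'
#' @param growth Reproduction rate per year.
#' @param mortality Mortality rate per year.
#' @param capacity Target single-species density (individuals per km^2),
#'   strictly positive.
#' @return Competition coefficient(s); warns when `growth <= mortality`
#'   (zero or negative coefficient, a population that cannot persist alone).
#' @examples
#' competition_from_capacity(log(3), 1 / 3.5, 1) # fox, ~0.81290
#' @export
competition_from_capacity <- function(growth, mortality, capacity) {
  if (!is.numeric(capacity) || any(!is.finite(capacity)) ||
    any(capacity <= 0)) {
    abort("carrying capacity must be positive", class = "hp_invalid_input")
  }
  if (any(!is.finite(growth)) || any(!is.finite(mortality))) {
    abort("rates must be finite", class = "hp_invalid_input")
  }
  if (any(growth <= mortality)) {
    warn("growth <= mortality: nonpositive competition coefficient")
  }
  (growth - mortality) / capacity
}

#' Reference life-history table for the three species
#'
#' Field-derived life-history quantities: mean lifespans of 3.5 y (fox),
#' 1.25 y (cottontail, the ~15-month average rather than the 5-y maximum)
#' and 5.5 y (hare); annual multiplication factors 3, 4.5 and 5; and
#' carrying capacities of 1, 100 and 30 individuals per km^2.
#'
#' @return A tibble with columns `species`, `lifespan`, `annual_factor`,
#'   `capacity`.
#' @export
life_history_table <- function() {
  tibble(
    species = c("fox", "cottontail", "hare"),
    lifespan = c(3.5, 1.25, 5.5),
    annual_factor = c(3, 4.5, 5),
    capacity = c(1, 100, 30)
  )
}

#' Derive model rates from life-history quantities
#'
#' Converts per-species lifespans, annual multiplication factors and
#' carrying capacities into the mortality, reproduction and competition
#' rates of the model, via [mortality_from_lifespan()],
#' [reproduction_from_annual_factor()] and [competition_from_capacity()].
#'
#' @param life_history A data frame with columns `species` (containing
#'   `"fox"`, `"cottontail"`, `"hare"`), `lifespan`, `annual_factor`,
#'   `capacity`; defaults to [life_history_table()].
#' @param e Conversion coefficient, default 0.91 (fox digestibility of
#'   lagomorph prey).
#' @param a,b Hunting rates; `NA` by default, to be set by scenarios.
#' @return An [hp_params] object.
#' @examples
#' derive_params()
#' @export
derive_params <- function(life_history = life_history_table(), e = 0.91,
                          a = NA_real_, b = NA_real_) {
  lh <- as_tibble(life_history)
  need <- c("species", "lifespan", "annual_factor", "capacity")
  miss <- setdiff(need, names(lh))
  if (length(miss) > 0) {
    abort(paste0("life_history lacks columns: ", toString(miss)),
      class = "hp_invalid_input"
    )
  }
  row_of <- function(sp) {
    i <- which(lh$species == sp)
    if (length(i) != 1) {
      abort(paste0("life_history needs exactly one row for ", sp),
        class = "hp_invalid_input"
      )
    }
    lh[i, ]
  }
  fox <- row_of("fox")
  cot <- row_of("cottontail")
  hare <- row_of("hare")
  rate <- function(row) {
    g <- reproduction_from_annual_factor(row$annual_factor)
    mu <- mortality_from_lifespan(row$lifespan)
    c(g, mu, competition_from_capacity(g, mu, row$capacity))
  }
  f <- rate(fox)
  s <- rate(cot)
  h <- rate(hare)
  hp_params(
    r = f[1], m = f[2], c_VV = f[3],
    s = s[1], n = s[2], c_SS = s[3],
    u = h[1], p = h[2], c_LL = h[3],
    e = e, a = a, b = b
  )
}

#' Reference parameter set
#'
#' The fixed rates used throughout the simulations, stored as exact
#' expressions and evaluated lazily: r = log 3, `m = 2/7`,
#' `c_VV = log 3 - 2/7`, `e = 0.91`; `s = log 4.5`, `n = 4/5`,
#' `c_SS = (log 4.5 - 4/5)/100`; `u = log 5`, `p = 2/11`,
#' `c_LL = (log 5 - 2/11)/30`. The implied single-species densities are
#' 1 fox, 100 cottontails and 30 hares per km^2. Hunting rates are left
#' unset unless supplied.
#'
#' @param a,b Optional hunting rates for a scenario.
#' @return An [hp_params] object.
#' @examples
#' reference_params()
#' reference_params(a = 0.2, b = 0.5)
#' @export
reference_params <- function(a = NA_real_, b = NA_real_) {
  hp_params(
    r = log(3), m = 2 / 7, c_VV = log(3) - 2 / 7, e = 0.91,
    s = log(4.5), n = 4 / 5, c_SS = (log(4.5) - 4 / 5) / 100,
    u = log(5), p = 2 / 11, c_LL = (log(5) - 2 / 11) / 30,
    a = a, b = b
  )
}
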