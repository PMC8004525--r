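eq_labels <- paste0("E", 0:7)

# Closed-form equilibrium candidates, unclamped: components may be negative,
# in which case the candidate is infeasible but remains an exact root of the
# right-hand side.
equilibrium_states <- function(params) {
  with(params, {
    D3 <- a^2 * e + c_VV * c_SS
    D5 <- b^2 * e + c_VV * c_LL
    D7 <- b^2 * e * c_SS + a^2 * e * c_LL + c_VV * c_SS * c_LL
    list(
      E0 = c(0, 0, 0),
      E1 = c((r - m) / c_VV, 0, 0),
      E2 = c(0, (s - n) / c_SS, 0),
      E3 = c(
        (a * e * (s - n) + c_SS * (r - m)) / D3,
        (a * (m - r) + c_VV * (s - n)) / D3, 0
      ),
      E4 = c(0, 0, (u - p) / c_LL),
      E5 = c(
        (b * e * (u - p) + c_LL * (r - m)) / D5, 0,
        (b * (m - r) + c_VV * (u - p)) / D5
      ),
      E6 = c(0, (s - n) / c_SS, (u - p) / c_LL),
      E7 = c(
        (b * e * c_SS * (u - p) + a * e * c_LL * (s - n) +
          c_SS * c_LL * (r - m)) / D7,
        (a * b * e * (p - u) + b^2 * e * (s - n) +
          a * c_LL * (m - r) + c_VV * c_LL * (s - n)) / D7,
        (a^2 * e * (u - p) + a * b * e * (n - s) +
          b * c_SS * (m - r) + c_VV * c_SS * (u - p)) / D7
      )
    )
  })
}

check_label <- function(label) {
  label <- as.character(label)
  if (length(label) != 1 || !label %in% eq_labels) {
    abort(paste0("label must be one of ", toString(eq_labels)),
      class = "hp_invalid_input"
    )
  }
  label
}

#' Feasibility of one equilibrium candidate
#'
#' Evaluates the closed-form feasibility conditions for a labelled
#' equilibrium: every inequality is reported as a margin (left minus right
#' of the "satisfied" orientation), so positive margins mean feasible.
#' Margins for the two- and three-species points are the closed-form
#' population numerators, which share their zero sets with the population
#' components themselves.
#'
#' Boundary ties (a margin of exactly zero) are classified infeasible and
#' flagged: the bifurcation machinery owns boundaries.
#'
#' @param label One of `"E0"`..`"E7"`.
#' @param params An [hp_params] object with hunting rates set.
#' @return A list with `feasible` (logical), `margins` (named numeric) and
#'   `boundary` (logical, any margin exactly zero).
#' @export
feasibility <- function(label, params) {
  label <- check_label(label)
  require_hunting_rates(params)
  require_competition(params)
  margins <- with(params, switch(label,
    E0 = c(none = Inf),
    E1 = c(net_fox = r - m),
    E2 = c(net_cottontail = s - n),
    E4 = c(net_hare = u - p),
    E3 = c(
      V3_num = a * e * (s - n) + c_SS * (r - m),
      S3_num = a * (m - r) + c_VV * (s - n)
    ),
    E5 = c(
      V5_num = b * e * (u - p) + c_LL * (r - m),
      L5_num = b * (m - r) + c_VV * (u - p)
    ),
    E6 = c(net_cottontail = s - n, net_hare = u - p),
    E7 = c(
      V7_num = b * e * c_SS * (u - p) + a * e * c_LL * (s - n) +
        c_SS * c_LL * (r - m),
      S7_num = a * b * e * (p - u) + b^2 * e * (s - n) +
        a * c_LL * (m - r) + c_VV * c_LL * (s - n),
      L7_num = a^2 * e * (u - p) + a * b * e * (n - s) +
        b * c_SS * (m - r) + c_VV * c_SS * (u - p)
    )
  ))
  list(
    feasible = all(margins > 0),
    margins = margins,
    boundary = any(margins == 0)
  )
}

#' Local stability of one equilibrium candidate
#'
#' Evaluates the closed-form local-stability conditions for a labelled
#' equilibrium as margins (positive = stable). For the one- and
#' two-species points these are the explicit eigenvalue sign conditions;
#' for coexistence the three Routh-Hurwitz quantities are reported, which
#' are all positive whenever the point is feasible, making coexistence
#' unconditionally stable when it exists.
#'
#' Stability is evaluated for infeasible candidates too (needed to draw
#' equilibrium-exchange diagrams) but [classify_attractor()] never returns
#' such a candidate. The closed-form conditions are equivalent to the
#' Jacobian eigenvalue signs only at feasible candidates: their
#' Routh-Hurwitz reductions assume nonnegative populations, so for an
#' infeasible candidate the margins are formal quantities.
#'
#' @inheritParams feasibility
#' @return A list with `stable` (logical), `margins` (named numeric) and
#'   `boundary` (logical).
#' @export
stability <- function(label, params) {
  label <- check_label(label)
  require_hunting_rates(params)
  require_competition(params)
  E <- equilibrium_states(params)
  margins <- with(params, switch(label,
    E0 = c(fox_decay = m - r, cottontail_decay = n - s, hare_decay = p - u),
    E1 = {
      V1 <- E$E1[1]
      c(
        net_fox = r - m,
        cottontail_excluded = n + a * V1 - s,
        hare_excluded = p + b * V1 - u
      )
    },
    E2 = {
      S2 <- E$E2[2]
      c(
        fox_excluded = m - (r + e * a * S2),
        net_cottontail = s - n,
        hare_decay = p - u
      )
    },
    E3 = c(hare_excluded = p + b * E$E3[1] - u),
    E4 = {
      L4 <- E$E4[3]
      c(
        fox_excluded = m - (r + e * b * L4),
        cottontail_decay = n - s,
        net_hare = u - p
      )
    },
    E5 = c(cottontail_excluded = n + a * E$E5[1] - s),
    E6 = c(fox_excluded = m - (r + e * a * E$E6[2] + e * b * E$E6[3])),
    E7 = {
      J <- jacobian_raw(E$E7, params)
      neg_tr <- -sum(diag(J))
      m2 <- sum_principal_minors2(J)
      neg_det <- -det(J)
      c(
        neg_trace = neg_tr, neg_det = neg_det,
        routh_hurwitz = neg_tr * m2 - neg_det
      )
    }
  ))
  list(
    stable = all(margins > 0),
    margins = margins,
    boundary = any(margins == 0)
  )
}

sum_principal_minors2 <- function(J) {
  (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) +
    (J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1]) +
    (J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2])
}

#' All eight equilibrium candidates
#'
#' Returns the closed-form equilibria of the system: total extinction
#' (`E0`), the three single-species points (`E1` foxes, `E2` cottontails,
#' `E4` hares), the three two-species points (`E3` foxes-cottontails,
#' `E5` foxes-hares, `E6` cottontails-hares) and coexistence (`E7`).
#' Candidates with negative components are kept and flagged infeasible;
#' they remain exact roots of the right-hand side.
#'
#' @param params An [hp_params] object with hunting rates set and all
#'   competition coefficients positive.
#' @return A tibble of class `hp_equilibria` with one row per candidate:
#'   `label`, populations `V`, `S`, `L`, `feasible`, `stable`, `boundary`,
#'   and list-columns `eigenvalues` (complex, decreasing real part),
#'   `feas_margins`, `stab_margins`.
#' @examples
#' equilibria(reference_params(a = 0.2, b = 0.5))
#' @export
equilibria <- function(params) {
  require_hunting_rates(params)
  require_competition(params)
  E <- equilibrium_states(params)
  rows <- purrr::map(eq_labels, function(lab) {
    x <- E[[lab]]
    fz <- feasibility(lab, params)
    st <- stability(lab, params)
    ev <- sort_eigenvalues(eigen(jacobian_raw(x, params),
      only.values = TRUE
    )$values)
    tibble(
      label = lab, V = x[1], S = x[2], L = x[3],
      feasible = fz$feasible, stable = st$stable,
      boundary = fz$boundary || st$boundary,
      eigenvalues = list(ev),
      feas_margins = list(fz$margins),
      stab_margins = list(st$margins)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hp_equilibria", class(out))
  attr(out, "params") <- params
  out
}

sort_eigenvalues <- function(ev) {
  ev <- as.complex(ev)
  ev[order(-Re(ev), -Im(ev))]
}

#' The attracting equilibrium of a parameter set
#'
#' Selects the unique candidate that is both feasible and (locally) stable.
#' Away from bifurcation boundaries exactly one such candidate exists, and
#' local stability implies global stability for this system, so this is the
#' long-run state of every positive initial condition. Zero or multiple
#' candidates signal boundary or degenerate parameters and raise a
#' classification error.
#'
#' @inheritParams equilibria
#' @return A one-row `hp_equilibria` tibble.
#' @examples
#' classify_attractor(reference_params(a = 0.2, b = 0.5))
#' @export
classify_attractor <- function(params) {
  eq <- equilibria(params)
  hit <- eq[eq$feasible & eq$stable, ]
  if (nrow(hit) != 1) {
    abort(
      paste0(
        nrow(hit), " feasible-and-stable equilibria found; ",
        "parameters lie on or near a bifurcation boundary"
      ),
      class = "hp_classification_error"
    )
  }
  hit
}

#' Regime thresholds on the competition coefficients
#'
#' The four competition-rate thresholds that organize the outcome taxonomy:
#' `k1 = a (r - m)/(s - n)` and `k2 = b (r - m)/(u - p)` bound the fox
#' competition coefficient, `h2 = a e (s - n)/(m - r)` and
#' `g2 = b e (u - p)/(m - r)` bound the prey coefficients when foxes
#' cannot persist alone. Each is `NA` when its denominator vanishes.
#'
#' @inheritParams equilibria
#' @return A one-row tibble: `k1`, `k2`, `h2`, `g2`, `net_fox`,
#'   `net_cottontail`, `net_hare`.
#' @export
regime_thresholds <- function(params) {
  require_hunting_rates(params)
  with(params, {
    safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
    tibble(
      k1 = safe_div(a * (r - m), s - n),
      k2 = safe_div(b * (r - m), u - p),
      h2 = safe_div(a * e * (s - n), m - r),
      g2 = safe_div(b * e * (u - p), m - r),
      net_fox = r - m,
      net_cottontail = s - n,
      net_hare = u - p
    )
  })
}

#' Outcome regime from the signs of the net reproduction rates
#'
#' Maps the sign pattern of `(r - m, s - n, u - p)` to one of eight regimes
#' and, inside each regime, uses the closed-form threshold comparisons on
#' the competition coefficients to name the admissible (feasible and
#' stable) equilibria. This is the taxonomic shortcut; it agrees with the
#' full margin evaluation of [classify_attractor()].
#'
#' @inheritParams equilibria
#' @return A one-row tibble: `case` (1-8), `pattern` (e.g. `"+-+"` for the
#'   signs of the fox, cottontail and hare net rates), and a list-column
#'   `admissible` of equilibrium labels.
#' @export
regime_case <- function(params) {
  require_hunting_rates(params)
  require_competition(params)
  net <- with(params, c(r - m, s - n, u - p))
  if (any(net == 0)) {
    abort("a net reproduction rate is exactly zero: boundary case",
      class = "hp_boundary_case"
    )
  }
  pos <- net > 0
  pattern <- paste(ifelse(pos, "+", "-"), collapse = "")
  th <- regime_thresholds(params)
  E <- equilibrium_states(params)
  # Stability tails used in the mixed-prey regimes.
  e3_stab <- with(params, p + b * E$E3[1] - u > 0)
  e5_stab <- with(params, n + a * E$E5[1] - s > 0)
  e6_stab <- with(params, m - (r + e * a * E$E6[2] + e * b * E$E6[3]) > 0)
  adm <- switch(pattern,
    "---" = "E0",
    "+--" = "E1",
    "-+-" = if (params$c_SS < th$h2) "E3" else "E2",
    "++-" = if (params$c_VV < th$k1) "E1" else "E3",
    "--+" = if (params$c_LL < th$g2) "E5" else "E4",
    "+-+" = if (params$c_VV < th$k2) "E1" else "E5",
    "-++" = c(
      if (params$c_SS < th$h2 && e3_stab) "E3",
      if (params$c_LL < th$g2 && e5_stab) "E5",
      if (e6_stab) "E6",
      # both prey can jointly sustain a fox population that neither
      # sustains alone, so coexistence is possible here too
      if (feasibility("E7", params)$feasible) "E7"
    ),
    "+++" = c(
      if (params$c_VV < th$k1 && params$c_VV < th$k2) "E1",
      if (params$c_VV > th$k1 && e3_stab) "E3",
      if (params$c_VV > th$k2 && e5_stab) "E5",
      if (feasibility("E7", params)$feasible) "E7"
    )
  )
  case <- match(pattern, c("---", "+--", "-+-", "++-", "--+", "+-+", "-++", "+++"))
  tibble(case = case, pattern = pattern, admissible = list(adm))
}
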