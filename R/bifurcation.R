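# Species present at each equilibrium; two equilibria can exchange
# stability through a transcritical bifurcation exactly when one extends
# the other by a single species.
eq_species <- list(
  E0 = character(0), E1 = "V", E2 = "S", E3 = c("V", "S"),
  E4 = "L", E5 = c("V", "L"), E6 = c("S", "L"), E7 = c("V", "S", "L")
)

#' Equilibrium-exchange graph
#'
#' The twelve admissible transcritical arcs between the eight equilibria:
#' each arc joins two equilibria whose surviving-species sets differ by a
#' single species (the one whose density crosses zero at the exchange).
#'
#' @return A tibble with columns `from`, `to`, `species`.
#' @export
exchange_graph <- function() {
  pairs <- utils::combn(eq_labels, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    A <- pairs[1, i]
    B <- pairs[2, i]
    sp <- exchange_species(A, B)
    if (is.null(sp)) {
      return(NULL)
    }
    tibble(from = A, to = B, species = sp)
  })
  dplyr::bind_rows(rows)
}

# NULL when the pair is not adjacent; otherwise the exchanging species.
exchange_species <- function(A, B) {
  sa <- eq_species[[A]]
  sb <- eq_species[[B]]
  d1 <- setdiff(sa, sb)
  d2 <- setdiff(sb, sa)
  if (length(d1) + length(d2) != 1) {
    return(NULL)
  }
  c(d1, d2)
}

larger_of <- function(A, B) {
  if (length(eq_species[[A]]) > length(eq_species[[B]])) A else B
}

# The closed-form population numerator of `species` at equilibrium `label`,
# a polynomial of degree <= 2 in every single model parameter. Its zero set
# is the feasibility boundary crossed at a transcritical exchange.
num_margin <- function(label, species, params) {
  key <- paste0(species, substr(label, 2, 2), "_num")
  mg <- feasibility(label, params)$margins
  if (key %in% names(mg)) {
    return(unname(mg[key]))
  }
  alt <- c(V = "net_fox", S = "net_cottontail", L = "net_hare")[species]
  unname(mg[alt])
}

#' Jacobian eigenvalues at an equilibrium candidate
#'
#' Numeric eigenvalues of the analytic Jacobian evaluated at the
#' closed-form candidate populations, sorted by decreasing real part.
#' At the origin these are exactly the net reproduction rates
#' `(r - m, s - n, u - p)`.
#'
#' @inheritParams feasibility
#' @return Complex vector of length 3.
#' @examples
#' eigenvalues_at("E0", reference_params(a = 0.2, b = 0.5))
#' @export
eigenvalues_at <- function(label, params) {
  label <- check_label(label)
  require_hunting_rates(params)
  require_competition(params)
  x <- equilibrium_states(params)[[label]]
  if (any(!is.finite(x))) {
    abort("equilibrium populations are not finite", class = "hp_invalid_input")
  }
  sort_eigenvalues(eigen(jacobian_raw(x, params), only.values = TRUE)$values)
}

set_param <- function(params, name, value) {
  params[[name]] <- value
  params
}

sweepable_params <- c("a", "b", "r", "s", "u", "c_VV", "c_SS", "c_LL")

check_sweep_param <- function(parameter) {
  if (!is.character(parameter) || length(parameter) != 1 ||
    !parameter %in% sweepable_params) {
    abort(paste0("parameter must be one of ", toString(sweepable_params)),
      class = "hp_invalid_input"
    )
  }
  parameter
}

# Exact quadratic coefficients of f(t) (polynomial of degree <= 2) via
# Newton divided differences on three nodes.
poly2_coef <- function(f, t0, t1) {
  tm <- (t0 + t1) / 2
  f0 <- f(t0)
  fm <- f(tm)
  f1 <- f(t1)
  c1 <- (fm - f0) / (tm - t0)
  c2 <- ((f1 - fm) / (t1 - tm) - c1) / (t1 - t0)
  A <- c2
  B <- c1 - c2 * (t0 + tm)
  C <- f0 - c1 * t0 + c2 * t0 * tm
  c(A = A, B = B, C = C)
}

poly2_roots <- function(co) {
  A <- co[["A"]]
  B <- co[["B"]]
  C <- co[["C"]]
  scale <- max(abs(co), 1e-300)
  if (abs(A) < 1e-12 * scale) {
    if (abs(B) < 1e-12 * scale) {
      return(numeric(0))
    }
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    return(numeric(0))
  }
  # numerically stable quadratic formula
  q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  roots <- c(q / A, if (q != 0) C / q else -B / A)
  sort(unique(roots))
}

#' Locate a transcritical threshold between two equilibria
#'
#' Solves for the critical value of one model parameter at which the given
#' pair of equilibria exchange stability. The exchanged species' population
#' numerator in the larger equilibrium is affine or quadratic in every
#' single parameter, so the root is obtained from the exact polynomial
#' coefficients, cross-checked by bisection whenever the margin changes
#' sign, and verified by a zero eigenvalue of both Jacobians at the
#' critical point. Each point is then classified via [sotomayor_check()].
#'
#' Quadratic margins can carry two roots in the bracket (re-entrant
#' coexistence windows); both are returned as separate rows.
#'
#' @param pair Character vector of two equilibrium labels joined by an arc
#'   of [exchange_graph()].
#' @param parameter One of `"a"`, `"b"`, `"r"`, `"s"`, `"u"`, `"c_VV"`,
#'   `"c_SS"`, `"c_LL"`.
#' @param params An [hp_params] object (the swept entry is overridden).
#' @param bracket Numeric length-2 search interval for the parameter.
#' @return A tibble of class `hp_bifpoints`, one row per root: `parameter`,
#'   `critical_value`, `from`, `to`, `species`, `kind`, the three
#'   Sotomayor transversality scalars, `bisection_value` (NA at a
#'   tangency), and `eigen_gap` (smallest |Re eigenvalue| across the pair
#'   at the critical point).
#' @examples
#' threshold_solve(c("E5", "E1"), "b",
#'   reference_params(a = 29, b = 1),
#'   bracket = c(0.5, 3)
#' )
#' @export
threshold_solve <- function(pair, parameter, params, bracket) {
  parameter <- check_sweep_param(parameter)
  pair <- unname(vapply(pair, check_label, character(1)))
  if (length(pair) != 2) {
    abort("pair must contain two labels", class = "hp_invalid_input")
  }
  sp <- exchange_species(pair[1], pair[2])
  if (is.null(sp)) {
    abort(
      paste0(
        "equilibria ", pair[1], " and ", pair[2],
        " share no transcritical arc"
      ),
      class = "hp_not_found"
    )
  }
  bracket <- sort(as.double(bracket))
  big <- larger_of(pair[1], pair[2])
  f <- function(t) num_margin(big, sp, set_param(params, parameter, t))
  co <- poly2_coef(f, bracket[1], bracket[2])
  roots <- poly2_roots(co)
  tol_br <- 1e-12 * max(1, abs(bracket))
  roots <- roots[roots >= bracket[1] - tol_br & roots <= bracket[2] + tol_br]
  if (length(roots) == 0) {
    abort(
      paste0(
        "no ", pair[1], "-", pair[2], " threshold in ",
        parameter, " over [", bracket[1], ", ", bracket[2], "]"
      ),
      class = "hp_not_found"
    )
  }
  # bisection cross-check on sub-brackets isolating each root
  cuts <- c(bracket[1], zoo_midpoints(roots), bracket[2])
  bis <- vapply(seq_along(roots), function(i) {
    lo <- cuts[i]
    hi <- cuts[i + 1]
    if (sign(f(lo)) * sign(f(hi)) < 0) {
      uniroot(f, c(lo, hi), tol = 1e-12)$root
    } else {
      NA_real_ # tangency: no sign change to bisect
    }
  }, double(1))
  rows <- purrr::map(seq_along(roots), function(i) {
    crit <- roots[i]
    p_crit <- set_param(params, parameter, crit)
    gap <- min(vapply(
      pair,
      function(lab) min(abs(Re(eigenvalues_at(lab, p_crit)))),
      double(1)
    ))
    soto <- sotomayor_scalars(pair, parameter, crit, params)
    tibble(
      parameter = parameter, critical_value = crit,
      from = pair[1], to = pair[2], species = sp,
      kind = soto$kind,
      w_Fmu = soto$w_Fmu, w_DFmu_v = soto$w_DFmu_v,
      w_D2F_vv = soto$w_D2F_vv, w_D3F_vvv = soto$w_D3F_vvv,
      bisection_value = bis[i], eigen_gap = gap
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hp_bifpoints", class(out))
  out
}

empty_bifpoints <- function() {
  out <- tibble(
    parameter = character(0), critical_value = double(0),
    from = character(0), to = character(0), species = character(0),
    kind = character(0), w_Fmu = double(0), w_DFmu_v = double(0),
    w_D2F_vv = double(0), w_D3F_vvv = double(0),
    bisection_value = double(0), eigen_gap = double(0)
  )
  class(out) <- c("hp_bifpoints", class(out))
  out
}

zoo_midpoints <- function(x) {
  if (length(x) < 2) {
    return(numeric(0))
  }
  (x[-1] + x[-length(x)]) / 2
}

# Analytic derivative of the right-hand side with respect to one parameter.
rhs_param_deriv <- function(state, params, parameter) {
  V <- state[[1]]
  S <- state[[2]]
  L <- state[[3]]
  e <- params$e
  switch(parameter,
    a = c(e * S * V, -S * V, 0),
    b = c(e * L * V, 0, -L * V),
    r = c(V, 0, 0),
    s = c(0, S, 0),
    u = c(0, 0, L),
    c_VV = c(-V^2, 0, 0),
    c_SS = c(0, -S^2, 0),
    c_LL = c(0, 0, -L^2)
  )
}

jac_param_deriv <- function(state, params, parameter) {
  V <- state[[1]]
  S <- state[[2]]
  L <- state[[3]]
  e <- params$e
  M <- function(...) matrix(c(...), nrow = 3, byrow = TRUE)
  switch(parameter,
    a = M(e * S, e * V, 0, -S, -V, 0, 0, 0, 0),
    b = M(e * L, 0, e * V, 0, 0, 0, -L, 0, -V),
    r = M(1, 0, 0, 0, 0, 0, 0, 0, 0),
    s = M(0, 0, 0, 0, 1, 0, 0, 0, 0),
    u = M(0, 0, 0, 0, 0, 0, 0, 0, 1),
    c_VV = M(-2 * V, 0, 0, 0, 0, 0, 0, 0, 0),
    c_SS = M(0, 0, 0, 0, -2 * S, 0, 0, 0, 0),
    c_LL = M(0, 0, 0, 0, 0, 0, 0, 0, -2 * L)
  )
}

# Bilinear form D^2F(x, y); the Hessians are constant because the vector
# field is quadratic, and all third derivatives vanish identically, which
# rules pitchfork bifurcations out.
rhs_second_deriv <- function(params, x, y) {
  with(params, c(
    -2 * c_VV * x[1] * y[1] + e * a * (x[1] * y[2] + x[2] * y[1]) +
      e * b * (x[1] * y[3] + x[3] * y[1]),
    -a * (x[1] * y[2] + x[2] * y[1]) - 2 * c_SS * x[2] * y[2],
    -b * (x[1] * y[3] + x[3] * y[1]) - 2 * c_LL * x[3] * y[3]
  ))
}

rhs_second_deriv_vv <- function(params, v) {
  rhs_second_deriv(params, v, v)
}

null_vector <- function(M) {
  ev <- eigen(M)
  i <- which.min(abs(Re(ev$values)))
  v <- Re(ev$vectors[, i])
  v <- v / sqrt(sum(v^2))
  j <- which(abs(v) > 1e-10)[1]
  if (v[j] < 0) v <- -v
  list(value = ev$values[i], vector = v, others = abs(Re(ev$values[-i])))
}

sotomayor_scalars <- function(pair, parameter, critical_value, params,
                              tol = 1e-8) {
  p_crit <- set_param(params, parameter, critical_value)
  # at the threshold the pair coincide; the smaller label has exact zeros
  small <- setdiff(pair, larger_of(pair[1], pair[2]))
  x0 <- equilibrium_states(p_crit)[[small]]
  J <- jacobian_raw(x0, p_crit)
  rv <- null_vector(J)
  lv <- null_vector(t(J))
  scale <- max(1, max(abs(J)))
  if (min(rv$others) < tol * scale || abs(Re(rv$value)) > 1e-6 * scale) {
    return(list(
      kind = "degenerate", w_Fmu = NA_real_, w_DFmu_v = NA_real_,
      w_D2F_vv = NA_real_, w_D3F_vvv = 0
    ))
  }
  v <- rv$vector
  w <- lv$vector
  w_Fmu <- sum(w * rhs_param_deriv(x0, p_crit, parameter))
  # The persisting equilibrium moves with the parameter, so the
  # transversality is evaluated in coordinates pinning it at the origin:
  # the parameter derivative of the Jacobian picks up the branch motion,
  # DF_mu + D^2F(dx0/dmu, .). The corrected scalar equals the speed at
  # which the critical eigenvalue crosses zero (up to the w.v factor).
  h <- 1e-6 * max(1, abs(critical_value))
  x_up <- equilibrium_states(
    set_param(params, parameter, critical_value + h)
  )[[small]]
  x_dn <- equilibrium_states(
    set_param(params, parameter, critical_value - h)
  )[[small]]
  dx0 <- (x_up - x_dn) / (2 * h)
  w_DFmu_v <- drop(w %*% jac_param_deriv(x0, p_crit, parameter) %*% v) +
    sum(w * rhs_second_deriv(p_crit, dx0, v))
  w_D2F_vv <- sum(w * rhs_second_deriv_vv(p_crit, v))
  kind <- if (abs(w_Fmu) > tol) {
    if (abs(w_D2F_vv) > tol) "saddle-node" else "degenerate"
  } else if (abs(w_DFmu_v) > tol && abs(w_D2F_vv) > tol) {
    "transcritical"
  } else {
    "degenerate"
  }
  list(
    kind = kind, w_Fmu = w_Fmu, w_DFmu_v = w_DFmu_v,
    w_D2F_vv = w_D2F_vv, w_D3F_vvv = 0
  )
}

#' Sotomayor classification of a located bifurcation point
#'
#' Evaluates the three Sotomayor transversality scalars at a critical
#' point: with `w`, `v` the left and right null eigenvectors of the
#' Jacobian at the coinciding equilibrium, a transcritical exchange
#' requires `w . F_mu = 0`, `w . (DF_mu v) != 0` and
#' `w . D2F(v, v) != 0`; a nonzero `w . F_mu` (with curvature) signals a
#' saddle-node instead. The pitchfork scalar `w . D3F(v, v, v)` vanishes
#' identically because the vector field is quadratic. Null eigenvectors
#' are normalized to unit length with first nonzero component positive.
#'
#' The boundary equilibrium moves with the bifurcation parameter, so the
#' transversality scalar is evaluated in coordinates pinning it at the
#' origin: `w . (DF_mu v + D2F(dx0/dmu, v))`, which equals the crossing
#' speed of the critical eigenvalue up to the positive factor `w . v`.
#' Without the branch term the scalar would vanish spuriously whenever
#' the parameter does not appear in the critical species' equation.
#'
#' @param point A one-row tibble (or list) with fields `parameter`,
#'   `critical_value`, `from`, `to`, as produced by [threshold_solve()].
#' @param params The [hp_params] object the point was located in.
#' @param tol Absolute tolerance separating "zero" from "nonzero" scalars.
#' @return A one-row tibble: `kind` plus the four scalar tests.
#' @export
sotomayor_check <- function(point, params, tol = 1e-8) {
  res <- sotomayor_scalars(
    c(point$from, point$to), point$parameter,
    point$critical_value, params, tol = tol
  )
  tibble(
    kind = res$kind, w_Fmu = res$w_Fmu, w_DFmu_v = res$w_DFmu_v,
    w_D2F_vv = res$w_D2F_vv, w_D3F_vvv = res$w_D3F_vvv
  )
}

#' Classify the attractor along a one-parameter section
#'
#' Classifies the feasible-and-stable equilibrium on a grid of values of
#' one parameter, then localizes every label change with
#' [threshold_solve()]. When consecutive grid labels are not adjacent in
#' the exchange graph (a window narrower than the grid step), the common
#' neighbour is tried so the intermediate regime is recovered.
#'
#' @inheritParams threshold_solve
#' @param range Numeric length-2 interval for the swept parameter.
#' @param n_grid Number of grid points.
#' @return An object of class `hp_sweep`: a list with `parameter`, `grid`
#'   (tibble of `value`, `label`; `NA` label marks a boundary sample),
#'   `points` (an `hp_bifpoints` tibble), `chain` (ordered run of labels)
#'   and `params`.
#' @examples
#' sweep_attractor("a", c(0.02, 0.4),
#'   n_grid = 101,
#'   params = reference_params(b = 0.3)
#' )
#' @export
sweep_attractor <- function(parameter, range, n_grid = 201, params) {
  parameter <- check_sweep_param(parameter)
  range <- sort(as.double(range))
  values <- seq(range[1], range[2], length.out = n_grid)
  labels <- vapply(values, function(t) {
    tryCatch(
      classify_attractor(set_param(params, parameter, t))$label,
      hp_classification_error = function(e) NA_character_
    )
  }, character(1))
  grid <- tibble(value = values, label = labels)
  ok <- which(!is.na(labels))
  runs <- rle(labels[ok])
  chain <- runs$values
  ends <- ok[cumsum(runs$lengths)]
  starts <- ok[c(1, utils::head(cumsum(runs$lengths), -1) + 1)]
  points <- list()
  all_resolved <- TRUE
  if (length(chain) > 1) {
    for (k in seq_len(length(chain) - 1)) {
      A <- chain[k]
      B <- chain[k + 1]
      lo <- values[ends[k]]
      hi <- values[starts[k + 1]]
      pt <- solve_change(A, B, parameter, params, c(lo, hi))
      if (is.null(pt)) all_resolved <- FALSE else {
        points[[length(points) + 1]] <- pt
      }
    }
  }
  points <- dplyr::bind_rows(c(list(empty_bifpoints()), points))
  # splice inferred intermediate regimes into the chain; if any change
  # resisted localization, keep the observed grid chain instead
  if (nrow(points) > 0 && all_resolved) {
    ord <- order(points$critical_value)
    points <- points[ord, ]
    chain <- chain_from_points(chain[1], points)
  }
  structure(
    list(
      parameter = parameter, grid = grid, points = points,
      chain = chain, params = params
    ),
    class = "hp_sweep"
  )
}

# Resolve one observed label change, going through a common neighbour when
# the two regimes are not adjacent in the exchange graph.
solve_change <- function(A, B, parameter, params, bracket) {
  if (!is.null(exchange_species(A, B))) {
    return(tryCatch(
      threshold_solve(c(A, B), parameter, params, bracket),
      hp_not_found = function(e) NULL
    ))
  }
  nbrs <- intersect(neighbours_of(A), neighbours_of(B))
  for (K in nbrs) {
    p1 <- tryCatch(threshold_solve(c(A, K), parameter, params, bracket),
      hp_not_found = function(e) NULL
    )
    p2 <- tryCatch(threshold_solve(c(K, B), parameter, params, bracket),
      hp_not_found = function(e) NULL
    )
    if (!is.null(p1) && !is.null(p2)) {
      return(dplyr::bind_rows(p1, p2))
    }
  }
  NULL
}

neighbours_of <- function(A) {
  g <- exchange_graph()
  c(g$to[g$from == A], g$from[g$to == A])
}

chain_from_points <- function(first, points) {
  lab <- first
  out <- first
  for (i in seq_len(nrow(points))) {
    nxt <- if (points$from[i] == lab) points$to[i] else points$from[i]
    out <- c(out, nxt)
    lab <- nxt
  }
  out
}

#' @export
print.hp_sweep <- function(x, ...) {
  cat(
    "<hp_sweep> parameter", x$parameter, "over [",
    min(x$grid$value), ",", max(x$grid$value), "]\n"
  )
  cat("attractor chain:", paste(x$chain, collapse = " -> "), "\n")
  if (nrow(x$points) > 0) {
    cat("thresholds at:", toString(signif(x$points$critical_value, 6)), "\n")
  }
  invisible(x)
}

#' Lyapunov quadratic-form matrix
#'
#' Builds the equilibrium-independent matrix of the quadratic form that
#' certifies global stability: diagonal `-w_i c_ii`, fox-cottontail entry
#' `a (w_V e - w_S)/2`, fox-hare entry `b (w_V e - w_L)/2`, and zero
#' prey-prey coupling. The weights `(1, e, e)` cancel both off-diagonal
#' entries, leaving a diagonal negative-definite form; negative
#' definiteness is reported through the leading principal minors.
#'
#' @param params An [hp_params] object with hunting rates set.
#' @param weights Three positive weights of the Lyapunov candidate, in the
#'   order (fox, cottontail, hare); default `c(1, e, e)`.
#' @return A list: `A` (symmetric 3x3 matrix), `minors` (leading principal
#'   minors), `negative_definite`.
#' @examples
#' lyapunov_matrix(reference_params(a = 0.2, b = 0.5))
#' @export
lyapunov_matrix <- function(params, weights = NULL) {
  require_hunting_rates(params)
  if (is.null(weights)) weights <- c(1, params$e, params$e)
  weights <- as.double(weights)
  if (length(weights) != 3 || any(!is.finite(weights)) || any(weights <= 0)) {
    abort("weights must be three positive numbers",
      class = "hp_invalid_input"
    )
  }
  A <- with(params, {
    off_s <- a * (weights[1] * e - weights[2]) / 2
    off_l <- b * (weights[1] * e - weights[3]) / 2
    matrix(
      c(
        -weights[1] * c_VV, off_s, off_l,
        off_s, -weights[2] * c_SS, 0,
        off_l, 0, -weights[3] * c_LL
      ),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("V", "S", "L"), c("V", "S", "L"))
    )
  })
  minors <- c(
    A[1, 1],
    det(A[1:2, 1:2]),
    det(A)
  )
  list(
    A = A, minors = minors,
    negative_definite = all(minors * c(-1, 1, -1) > 0)
  )
}
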