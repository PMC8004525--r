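# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Uniformly jittered parameter draws around a reference set
#'
#' Draws `n` parameter sets, each entry independent and uniform on
#' `[p (1 - semiwidth), p (1 + semiwidth)]` around the reference value
#' `p`. By default all twelve rates are jittered, including the hunting
#' rates; set `jitter_hunting = FALSE` to hold `a` and `b` at their
#' reference values (the same random stream is consumed either way, so
#' the two options are comparable draw by draw).
#'
#' @param reference An [hp_params] with hunting rates set.
#' @param semiwidth Relative semiwidth of the jitter interval, in `[0, 1)`;
#'   default 0.09 (plus/minus 9 percent).
#' @param n Number of draws.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param jitter_hunting Jitter `a` and `b` too? Default `TRUE`.
#' @return A tibble with `.draw` and the twelve parameter columns.
#' @examples
#' sample_parameters(reference_params(a = 0.2, b = 0.5), n = 3, seed = 1)
#' @export
sample_parameters <- function(reference, semiwidth = 0.09, n = 500,
                              seed = 1, jitter_hunting = TRUE) {
  require_hunting_rates(reference)
  if (!is.numeric(semiwidth) || length(semiwidth) != 1 ||
    !is.finite(semiwidth) || semiwidth < 0 || semiwidth >= 1) {
    abort("semiwidth must lie in [0, 1)", class = "hp_invalid_input")
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive count", class = "hp_invalid_input")
  }
  n <- as.integer(n)
  ref <- unlist(reference[param_names])
  U <- with_local_seed(seed, matrix(runif(n * length(ref)), nrow = n))
  draws <- sweep(1 + semiwidth * (2 * U - 1), 2, ref, `*`)
  colnames(draws) <- param_names
  if (!jitter_hunting) {
    draws[, "a"] <- ref[["a"]]
    draws[, "b"] <- ref[["b"]]
  }
  dplyr::bind_cols(tibble(.draw = seq_len(n)), as_tibble(draws))
}

#' Run a randomized steady-state ensemble
#'
#' Emulates the randomized simulation study behind the hyperpredation
#' conclusion: `n` parameter sets jittered by `semiwidth` around the
#' reference values (with the given hunting rates), each integrated from
#' `init` until the steady-state criterion holds (the horizon doubles from
#' 500 years up to `t_max` for runs that sit near a bifurcation boundary
#' and converge slowly). The integrated steady state is cross-checked
#' against the closed-form populations of the classified attractor.
#'
#' @inheritParams sample_parameters
#' @param a,b Hunting rates of the study scenario (default `a = 0.2`,
#'   `b = 0.5`).
#' @param init Initial densities, default `(0.4, 1, 3)` per km^2.
#' @param tol Steady-state tolerance.
#' @param t_max Maximum integration horizon in years.
#' @param mode `"converged"` (default) integrates each run until the
#'   steady-state criterion holds, so extinct species sit at exactly zero;
#'   `"fixed_horizon"` records the state at `t_end` years regardless of
#'   convergence, so a hare population on its way to extinction is
#'   captured at a small positive density. The second mode mimics
#'   recording simulation endpoints and lets the log-hare regressions see
#'   the runs that drive the hyperpredation signature; no run is excluded.
#' @param t_end Horizon for `mode = "fixed_horizon"`.
#' @return A tibble of class `hp_ensemble`, one row per converged run:
#'   `.draw`, the twelve parameters, steady `V`, `S`, `L`, the attractor
#'   `label` (`NA` if classification sat on a boundary), `t_converge`,
#'   and `cf_dev`, the largest absolute deviation between the integrated
#'   steady state and the closed-form attractor populations.
#'   Non-converged runs are excluded and reported via the
#'   `excluded` attribute and a message.
#' @examples
#' run_ensemble(reference_params(), n = 5, seed = 1)
#' @export
run_ensemble <- function(reference = reference_params(),
                         a = 0.2, b = 0.5, init = c(0.4, 1, 3),
                         n = 500, semiwidth = 0.09, seed = 1,
                         jitter_hunting = TRUE,
                         tol = 1e-8, t_max = 64000,
                         mode = c("converged", "fixed_horizon"),
                         t_end = 500) {
  mode <- match.arg(mode)
  base <- reference
  base$a <- a
  base$b <- b
  validate_params(base)
  init <- check_state(as_state(init))
  draws <- sample_parameters(base,
    semiwidth = semiwidth, n = n, seed = seed,
    jitter_hunting = jitter_hunting
  )
  rows <- purrr::map(seq_len(n), function(i) {
    pars <- do.call(hp_params, as.list(draws[i, param_names]))
    run <- if (mode == "converged") {
      integrate_to_steady(pars, init, tol = tol, t_max = t_max)
    } else {
      integrate_fixed(pars, init, t_end = t_end, tol = tol)
    }
    label <- tryCatch(
      classify_attractor(pars)$label,
      hp_classification_error = function(e) NA_character_
    )
    cf_dev <- if (is.na(label)) {
      NA_real_
    } else {
      cf <- equilibrium_states(pars)[[label]]
      max(abs(run$state - cf))
    }
    dplyr::bind_cols(
      draws[i, ],
      tibble(
        V = run$state[["V"]], S = run$state[["S"]], L = run$state[["L"]],
        label = label, converged = run$converged,
        t_converge = run$time, cf_dev = cf_dev
      )
    )
  })
  records <- dplyr::bind_rows(rows)
  excluded <- if (mode == "converged") {
    records[!records$converged, ]
  } else {
    records[0, ]
  }
  if (mode == "converged") records <- records[records$converged, ]
  if (nrow(excluded) > 0) {
    message(nrow(excluded), " run(s) did not converge by t = ", t_max,
      " and were excluded")
  }
  class(records) <- c("hp_ensemble", class(records))
  attr(records, "excluded") <- excluded
  attr(records, "init") <- init
  attr(records, "seed") <- seed
  attr(records, "semiwidth") <- semiwidth
  records
}

#' Bin ensemble records by steady-state cottontail density
#'
#' Partitions records into half-open cottontail-density intervals,
#' open on the left and closed on the right (a record with `S` exactly on
#' an edge joins the lower bin). The default edges give the six intervals
#' (1,3], (3,5], (5,7], (7,9], (9,11], (11,13]. Records outside every bin
#' keep an `NA` bin and are counted in the `n_out_of_range` attribute.
#'
#' @param records An `hp_ensemble` (or any data frame with an `S` column).
#' @param edges Strictly increasing bin edges; default `seq(1, 13, by = 2)`.
#' @return The records with a `bin` factor column added.
#' @export
bin_by_cottontail <- function(records, edges = seq(1, 13, by = 2)) {
  edges <- as.double(edges)
  if (length(edges) < 2 || any(diff(edges) <= 0)) {
    abort("edges must be strictly increasing", class = "hp_invalid_input")
  }
  out <- dplyr::mutate(
    records,
    bin = cut(.data$S, breaks = edges, right = TRUE)
  )
  attr(out, "n_out_of_range") <- sum(is.na(out$bin))
  out
}

# Ordinary least squares of y on x from the normal equations; returns the
# same numbers lm() would, but the arithmetic is explicit.
ols_line <- function(x, y) {
  n <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (n < 2 || sxx == 0) {
    return(list(
      slope = NA_real_, intercept = NA_real_,
      slope_se = NA_real_, defined = FALSE
    ))
  }
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  rss <- sum((y - intercept - slope * x)^2)
  slope_se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, slope_se = slope_se,
    defined = TRUE)
}

#' Per-bin regression of log hare density on fox density
#'
#' For each cottontail-density bin, fits an ordinary least-squares line of
#' `log(L)` on `V` from the normal equations. Records whose steady hare
#' density lies below `floor` (effectively extinct hares, for which the
#' logarithm is undefined) are excluded from the fit and tallied. Bins
#' with fewer than two usable records, or with no spread in `V`, carry an
#' undefined-fit flag.
#'
#' @param binned Records with a `bin` column, from [bin_by_cottontail()];
#'   a plain record set is treated as a single bin.
#' @param floor Hare-density floor below which records are excluded.
#' @return A tibble of class `hp_binfit`: `bin`, `n`, `n_used`,
#'   `n_excluded`, `slope`, `intercept`, `slope_se`, `defined`. The usable
#'   points are kept in the `data` attribute for plotting.
#' @export
fit_loghare_vs_fox <- function(binned, floor = 1e-6) {
  if (!"bin" %in% names(binned)) {
    binned <- dplyr::mutate(binned, bin = factor("all"))
  }
  groups <- dplyr::filter(binned, !is.na(.data$bin))
  lv <- levels(groups$bin)
  used <- list()
  rows <- purrr::map(lv, function(bn) {
    g <- groups[groups$bin == bn, ]
    usable <- g[g$L >= floor, ]
    fit <- ols_line(usable$V, log(usable$L))
    if (fit$defined) {
      used[[bn]] <<- dplyr::mutate(usable, ln_L = log(.data$L))
    }
    tibble(
      bin = bn, n = nrow(g), n_used = nrow(usable),
      n_excluded = nrow(g) - nrow(usable),
      slope = fit$slope, intercept = fit$intercept,
      slope_se = fit$slope_se, defined = fit$defined
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hp_binfit", class(out))
  attr(out, "data") <- dplyr::bind_rows(used)
  attr(out, "floor") <- floor
  out
}

#' Slope trend across cottontail-density bins
#'
#' Summarizes the fitted per-bin slopes in order of increasing cottontail
#' density and reports the hyperpredation signature: whether the
#' hare-fox association weakens as cottontails become more abundant
#' (non-increasing slopes) and whether it ends negative.
#'
#' @param binned An `hp_binfit` tibble from [fit_loghare_vs_fox()].
#' @return A one-row tibble: `n_bins_fitted`, `slopes` (list-column, in
#'   bin order), `trend` (`"decreasing"`, `"non-increasing"`, `"mixed"`,
#'   or `"undefined"` when fewer than two bins are fitted), and
#'   `ends_negative`.
#' @export
slope_trend <- function(binned) {
  fitted <- binned[binned$defined, ]
  slopes <- fitted$slope
  if (length(slopes) < 2) {
    return(tibble(
      n_bins_fitted = length(slopes), slopes = list(slopes),
      trend = "undefined", ends_negative = NA
    ))
  }
  d <- diff(slopes)
  trend <- if (all(d < 0)) {
    "decreasing"
  } else if (all(d <= 0)) {
    "non-increasing"
  } else {
    "mixed"
  }
  last_neg <- slopes[length(slopes)] < 0
  tibble(
    n_bins_fitted = length(slopes), slopes = list(slopes),
    trend = trend, ends_negative = last_neg
  )
}
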