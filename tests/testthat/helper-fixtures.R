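# Random valid parameter sets spanning all sign regimes; caller controls
# the RNG seed.
random_params <- function() {
  hp_params(
    r = runif(1, 0.05, 2), s = runif(1, 0.05, 2), u = runif(1, 0.05, 2),
    m = runif(1, 0.05, 2), n = runif(1, 0.05, 2), p = runif(1, 0.05, 2),
    c_VV = runif(1, 0.02, 1), c_SS = runif(1, 0.02, 1),
    c_LL = runif(1, 0.02, 1),
    e = runif(1, 0.5, 1), a = runif(1, 0, 3), b = runif(1, 0, 3)
  )
}

# Central finite-difference Jacobian of the right-hand side.
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- dn <- state
    up[j] <- up[j] + h
    dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (growth_rates(up, params) - growth_rates(dn, params)) /
      (up[j] - dn[j])
  }
  J
}

# Smallest |margin| across every feasibility/stability inequality of every
# candidate: a gauge of distance from bifurcation boundaries.
min_abs_margin <- function(params) {
  eq <- equilibria(params)
  min(abs(unlist(c(eq$feas_margins[-1], eq$stab_margins))))
}
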