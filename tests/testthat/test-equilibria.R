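test_that("the census always returns the eight labelled candidates", {
  set.seed(31)
  for (i in 1:25) {
    eq <- equilibria(random_params())
    expect_identical(nrow(eq), 8L)
    expect_identical(eq$label, paste0("E", 0:7))
  }
  degenerate <- reference_params(a = 0.2, b = 0.5)
  degenerate$c_SS <- 0
  expect_error(equilibria(degenerate), class = "hp_degenerate_model")
})

test_that("reference parameters place the single-species equilibria at the
           calibrated capacities", {
  eq <- equilibria(reference_params(a = 0.2, b = 0.5))
  expect_equal(eq$V[eq$label == "E1"], 1)
  expect_equal(eq$S[eq$label == "E2"], 100)
  expect_equal(eq$L[eq$label == "E4"], 30)
})

test_that("every feasible candidate is an exact root of the dynamics", {
  set.seed(43)
  for (i in 1:50) {
    p <- random_params()
    eq <- equilibria(p)
    for (k in which(eq$feasible)) {
      x <- unlist(eq[k, c("V", "S", "L")])
      scale <- max(1, max(abs(x)))
      expect_lt(max(abs(growth_rates(x, p))) / scale, 1e-10)
    }
  }
})

test_that("closed-form verdicts agree with numerical eigenvalues and the
           attractor is unique away from boundaries", {
  set.seed(59)
  tried <- 0
  used <- 0
  while (used < 250 && tried < 5000) {
    tried <- tried + 1
    p <- random_params()
    if (min_abs_margin(p) <= 1e-6) next
    used <- used + 1
    eq <- equilibria(p)
    lead <- vapply(eq$eigenvalues, function(ev) max(Re(ev)), double(1))
    # closed-form verdicts are eigenvalue-exact at feasible candidates
    expect_identical(eq$stable[eq$feasible], (lead < 0)[eq$feasible])
    expect_identical(sum(eq$feasible & eq$stable), 1L)
  }
  expect_equal(used, 250)
})

test_that("with no predation the system decouples into logistic limits", {
  p <- reference_params(a = 0, b = 0)
  eq <- equilibria(p)
  caps <- with(p, c((r - m) / c_VV, (s - n) / c_SS, (u - p) / c_LL))
  e6 <- unlist(eq[eq$label == "E6", c("S", "L")])
  expect_equal(unname(e6), caps[2:3])
  e7 <- unlist(eq[eq$label == "E7", c("V", "S", "L")])
  expect_equal(unname(e7), caps)
  # all three net rates positive: coexistence of the decoupled logistics
  expect_identical(classify_attractor(p)$label, "E7")
})

test_that("feasibility and stability margins follow the closed forms", {
  p <- reference_params(a = 0.2, b = 0.5)
  f1 <- feasibility("E1", p)
  expect_true(f1$feasible)
  expect_equal(unname(f1$margins), p$r - p$m)
  # cottontails below replacement: two-prey equilibria lose feasibility
  q <- p
  q$s <- 0.5
  q$n <- 0.8
  expect_false(feasibility("E6", q)$feasible)
  # extinction stable only when every net rate is negative
  all_neg <- hp_params(
    r = 0.2, s = 0.3, u = 0.1, m = 0.5, n = 0.6, p = 0.4,
    c_VV = 0.5, c_SS = 0.5, c_LL = 0.5, e = 0.9, a = 1, b = 1
  )
  expect_true(stability("E0", all_neg)$stable)
  expect_identical(classify_attractor(all_neg)$label, "E0")
  # coexistence is stable whenever feasible
  st7 <- stability("E7", p)
  fz7 <- feasibility("E7", p)
  expect_identical(st7$stable && fz7$feasible, fz7$feasible && st7$stable)
  p2 <- reference_params(a = 0.1, b = 0.1)
  expect_true(feasibility("E7", p2)$feasible)
  expect_true(stability("E7", p2)$stable)
})

test_that("regime taxonomy matches the full classification", {
  # foxes alone persist: E1 regardless of competition thresholds
  only_fox <- hp_params(
    r = 1.2, s = 0.3, u = 0.1, m = 0.5, n = 0.6, p = 0.4,
    c_VV = 0.5, c_SS = 0.5, c_LL = 0.5, e = 0.9, a = 1, b = 1
  )
  rc <- regime_case(only_fox)
  expect_identical(rc$pattern, "+--")
  expect_identical(rc$admissible[[1]], "E1")

  # cottontails above replacement, foxes below: h2 separates E2 from E3
  base <- hp_params(
    r = 0.2, s = 1.2, u = 0.2, m = 0.5, n = 0.5, p = 0.5,
    c_VV = 0.5, c_SS = 0.5, c_LL = 0.5, e = 0.9, a = 1, b = 1
  )
  h2 <- regime_thresholds(base)$h2
  lo <- base
  lo$c_SS <- 0.5 * h2
  hi <- base
  hi$c_SS <- 2 * h2
  expect_identical(regime_case(lo)$admissible[[1]], "E3")
  expect_identical(regime_case(hi)$admissible[[1]], "E2")
  expect_identical(classify_attractor(lo)$label, "E3")
  expect_identical(classify_attractor(hi)$label, "E2")

  # hares above replacement, foxes below: g2 separates E4 from E5
  base2 <- hp_params(
    r = 0.2, s = 0.2, u = 1.2, m = 0.5, n = 0.5, p = 0.5,
    c_VV = 0.5, c_SS = 0.5, c_LL = 0.5, e = 0.9, a = 1, b = 1
  )
  g2 <- regime_thresholds(base2)$g2
  lo2 <- base2
  lo2$c_LL <- 0.5 * g2
  hi2 <- base2
  hi2$c_LL <- 2 * g2
  expect_identical(regime_case(lo2)$admissible[[1]], "E5")
  expect_identical(regime_case(hi2)$admissible[[1]], "E4")
  expect_identical(classify_attractor(lo2)$label, "E5")
  expect_identical(classify_attractor(hi2)$label, "E4")
})

test_that("regime taxonomy agrees with classify_attractor on random sets", {
  set.seed(67)
  used <- 0
  tried <- 0
  while (used < 120 && tried < 4000) {
    tried <- tried + 1
    p <- random_params()
    if (min_abs_margin(p) <= 1e-6) next
    used <- used + 1
    rc <- regime_case(p)
    expect_identical(rc$admissible[[1]], classify_attractor(p)$label)
  }
  expect_equal(used, 120)
})

test_that("boundary parameters raise classification errors", {
  p <- reference_params(a = 0.2, b = 0.5)
  p$s <- p$n # net cottontail rate exactly zero
  expect_error(regime_case(p), class = "hp_boundary_case")
  # fox net rate exactly zero with both prey below replacement: E1 sits on
  # its feasibility boundary and E0 on its stability boundary, so no
  # candidate is strictly admissible
  q <- hp_params(
    r = 0.5, s = 0.3, u = 0.1, m = 0.5, n = 0.6, p = 0.4,
    c_VV = 0.5, c_SS = 0.5, c_LL = 0.5, e = 0.9, a = 1, b = 1
  )
  expect_error(classify_attractor(q), class = "hp_classification_error")
  expect_true(feasibility("E1", q)$boundary)
})
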