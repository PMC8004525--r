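test_that("eigenvalues at boundary equilibria match their closed forms", {
  set.seed(71)
  for (i in 1:20) {
    p <- random_params()
    ev0 <- eigenvalues_at("E0", p)
    expect_equal(
      sort(Re(ev0)),
      sort(c(p$r - p$m, p$s - p$n, p$u - p$p))
    )
    expect_identical(max(abs(Im(ev0))), 0)
    # cottontail-hare point: the prey directions contract at -c_ii * N_i
    eq <- equilibria(p)
    S6 <- eq$S[eq$label == "E6"]
    L6 <- eq$L[eq$label == "E6"]
    ev6 <- Re(eigenvalues_at("E6", p))
    expect_true(any(abs(ev6 - (-p$c_SS * S6)) < 1e-12))
    expect_true(any(abs(ev6 - (-p$c_LL * L6)) < 1e-12))
  }
})

test_that("feasible coexistence always attracts: negative real parts", {
  set.seed(73)
  found <- 0
  tried <- 0
  while (found < 100 && tried < 20000) {
    tried <- tried + 1
    p <- random_params()
    if (!feasibility("E7", p)$feasible) next
    found <- found + 1
    expect_lt(max(Re(eigenvalues_at("E7", p))), 0)
  }
  expect_equal(found, 100)
})

test_that("the fox-hare to fox-only threshold solves to its closed form", {
  p <- reference_params(a = 29, b = 1)
  pt <- threshold_solve(c("E5", "E1"), "b", p, bracket = c(0.5, 3))
  expect_identical(nrow(pt), 1L)
  b_star <- with(p, c_VV * (u - p) / (r - m))
  expect_equal(pt$critical_value, b_star, tolerance = 1e-12)
  expect_equal(pt$bisection_value, b_star, tolerance = 1e-9)
  expect_identical(pt$kind, "transcritical")
  expect_lt(pt$eigen_gap, 1e-8)
  # no exchange where the margin keeps its sign
  expect_error(
    threshold_solve(c("E5", "E1"), "b", p, bracket = c(0.1, 0.5)),
    class = "hp_not_found"
  )
  # no arc joins the two single-prey equilibria
  expect_error(
    threshold_solve(c("E1", "E2"), "b", p, bracket = c(0.5, 3)),
    class = "hp_not_found"
  )
})

test_that("a quadratic margin yields both roots of a re-entrant window", {
  p <- reference_params(b = 0.3)
  pts <- threshold_solve(c("E7", "E3"), "a", p, bracket = c(0.02, 0.15))
  expect_identical(nrow(pts), 2L)
  expect_equal(pts$critical_value, c(0.0515087, 0.0964462), tolerance = 1e-5)
  expect_equal(pts$critical_value, pts$bisection_value, tolerance = 1e-9)
  expect_true(all(pts$kind == "transcritical"))
  expect_true(all(pts$eigen_gap < 1e-8))
})

test_that("Sotomayor scalars certify transcritical exchanges", {
  p <- reference_params(a = 29, b = 1)
  pt <- threshold_solve(c("E5", "E1"), "b", p, bracket = c(0.5, 3))
  chk <- sotomayor_check(pt, p)
  expect_identical(chk$kind, "transcritical")
  expect_lt(abs(chk$w_Fmu), 1e-8)
  expect_gt(abs(chk$w_DFmu_v), 1e-8)
  expect_gt(abs(chk$w_D2F_vv), 1e-8)
  # the cubic term of a quadratic vector field vanishes identically
  expect_identical(chk$w_D3F_vvv, 0)
  # hunting-rate derivative of the flow vanishes on the exchanging
  # boundary equilibrium, here with respect to a as well
  p2 <- reference_params(b = 0.3)
  pts <- threshold_solve(c("E7", "E3"), "a", p2, bracket = c(0.02, 0.15))
  expect_true(all(abs(pts$w_Fmu) < 1e-8))
  expect_true(all(pts$w_D3F_vvv == 0))
})

test_that("sweeps recover the re-entrant coexistence transition chains", {
  # hares-then-cottontails exchange while raising the cottontail hunt
  sw <- sweep_attractor("a", c(0.02, 0.4),
    n_grid = 151,
    params = reference_params(b = 0.3)
  )
  expect_identical(sw$chain, c("E7", "E3", "E7", "E5"))
  expect_equal(
    sw$points$critical_value,
    c(0.0515087, 0.0964462, 0.198169),
    tolerance = 1e-5
  )
  # symmetric structure raising the hare hunt
  sw2 <- sweep_attractor("b", c(0.02, 1),
    n_grid = 151,
    params = reference_params(a = 0.2)
  )
  expect_identical(sw2$chain, c("E7", "E5", "E7", "E3"))
  # invasion-like chain: alien-free, coexistence, hares extinct
  sw3 <- sweep_attractor("b", c(0.2, 1),
    n_grid = 151,
    params = reference_params(a = 0.3)
  )
  expect_identical(sw3$chain, c("E5", "E7", "E3"))
  expect_equal(
    sw3$points$critical_value, c(0.565123, 0.631985),
    tolerance = 1e-5
  )
  # prey-collapse chain at heavy hare hunting
  sw4 <- sweep_attractor("a", c(0.5, 1),
    n_grid = 101,
    params = reference_params(b = 2)
  )
  expect_identical(sw4$chain, c("E3", "E1"))
  expect_equal(sw4$points$critical_value, 0.704077, tolerance = 1e-5)
  # a flat section: one label, no points
  sw5 <- sweep_attractor("a", c(2, 4),
    n_grid = 21,
    params = reference_params(b = 2)
  )
  expect_identical(sw5$chain, "E1")
  expect_identical(nrow(sw5$points), 0L)
})

test_that("feasibility and stability boundaries coincide at an exchange", {
  # the coexistence hare-loss locus equals the fox-cottontail stability
  # boundary, located by two independently coded margins
  p <- reference_params(a = 0.2)
  feas_root <- threshold_solve(c("E7", "E3"), "b", p,
    bracket = c(0.4, 0.6)
  )$critical_value
  stab_root <- uniroot(
    function(b) {
      q <- p
      q$b <- b
      stability("E3", q)$margins[["hare_excluded"]]
    },
    c(0.4, 0.6),
    tol = 1e-12
  )$root
  expect_equal(feas_root, stab_root, tolerance = 1e-9)
  # and the fox-hare loss of cottontail exclusion against coexistence
  feas_root2 <- threshold_solve(c("E7", "E5"), "b", p,
    bracket = c(0.2, 0.4)
  )$critical_value
  stab_root2 <- uniroot(
    function(b) {
      q <- p
      q$b <- b
      stability("E5", q)$margins[["cottontail_excluded"]]
    },
    c(0.2, 0.4),
    tol = 1e-12
  )$root
  expect_equal(feas_root2, stab_root2, tolerance = 1e-9)
})

test_that("no Hopf scenario: critical eigenvalues are real", {
  sw <- sweep_attractor("b", c(0.02, 1),
    n_grid = 101,
    params = reference_params(a = 0.2)
  )
  expect_gt(nrow(sw$points), 0)
  for (i in seq_len(nrow(sw$points))) {
    pt <- sw$points[i, ]
    p_crit <- reference_params(a = 0.2, b = pt$critical_value)
    for (lab in c(pt$from, pt$to)) {
      ev <- eigenvalues_at(lab, p_crit)
      near <- ev[which.min(abs(Re(ev)))]
      expect_lt(abs(Im(near)), 1e-6)
    }
  }
})

test_that("discovered exchanges stay inside the admissible arc graph", {
  g <- exchange_graph()
  expect_identical(nrow(g), 12L)
  arcs <- paste(g$from, g$to)
  set.seed(97)
  checked <- 0
  for (i in 1:12) {
    p <- random_params()
    parm <- sample(c("a", "b", "s", "u"), 1)
    sw <- sweep_attractor(parm, c(0.01, 3), n_grid = 61, params = p)
    if (nrow(sw$points) == 0) next
    checked <- checked + nrow(sw$points)
    key <- paste(
      pmin(sw$points$from, sw$points$to),
      pmax(sw$points$from, sw$points$to)
    )
    expect_true(all(key %in% arcs))
  }
  expect_gt(checked, 0)
})

test_that("the Lyapunov quadratic form is diagonal under conversion
           weights and loses definiteness under distorted ones", {
  p <- reference_params(a = 0.2, b = 0.5)
  ly <- lyapunov_matrix(p)
  expect_identical(ly$A[1, 2], 0)
  expect_identical(ly$A[1, 3], 0)
  expect_true(ly$negative_definite)
  expect_identical(ly$A, t(ly$A))
  bad <- lyapunov_matrix(p, weights = c(1, 500, 0.91))
  expect_false(bad$negative_definite)
  expect_identical(bad$A, t(bad$A))
  expect_error(lyapunov_matrix(p, weights = c(1, -1, 1)),
    class = "hp_invalid_input"
  )
})
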