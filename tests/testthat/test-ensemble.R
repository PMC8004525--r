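test_that("parameter jitter is uniform, bounded and reproducible", {
  ref <- reference_params(a = 0.2, b = 0.5)
  refv <- unlist(ref[c(
    "r", "s", "u", "m", "n", "p",
    "c_VV", "c_SS", "c_LL", "e", "a", "b"
  )])
  d1 <- sample_parameters(ref, semiwidth = 0.09, n = 200, seed = 42)
  d2 <- sample_parameters(ref, semiwidth = 0.09, n = 200, seed = 42)
  expect_identical(d1, d2)
  d3 <- sample_parameters(ref, semiwidth = 0.09, n = 200, seed = 43)
  expect_false(identical(d1, d3))
  for (nm in names(refv)) {
    expect_true(all(d1[[nm]] >= refv[[nm]] * 0.91 - 1e-12))
    expect_true(all(d1[[nm]] <= refv[[nm]] * 1.09 + 1e-12))
  }
  # zero semiwidth: exact copies of the reference
  d0 <- sample_parameters(ref, semiwidth = 0, n = 5, seed = 1)
  for (nm in names(refv)) expect_true(all(d0[[nm]] == refv[[nm]]))
  # frozen hunting rates on request
  df <- sample_parameters(ref, n = 20, seed = 9, jitter_hunting = FALSE)
  expect_true(all(df$a == 0.2) && all(df$b == 0.5))
  expect_error(sample_parameters(ref, semiwidth = 1.2),
    class = "hp_invalid_input"
  )
})

test_that("ensemble runs agree with the closed-form attractor and rerun
           bit-identically", {
  ens1 <- run_ensemble(n = 12, seed = 5)
  ens2 <- run_ensemble(n = 12, seed = 5)
  expect_identical(as.data.frame(ens1), as.data.frame(ens2))
  expect_true(all(ens1$converged))
  expect_true(all(ens1$cf_dev < 1e-5, na.rm = TRUE))
  # a zero-jitter single run reproduces the reference attractor
  one <- run_ensemble(n = 1, semiwidth = 0, seed = 1)
  expect_identical(one$label, "E3")
  att <- classify_attractor(reference_params(a = 0.2, b = 0.5))
  expect_lt(max(abs(unlist(one[, c("V", "S", "L")]) -
    unlist(att[, c("V", "S", "L")]))), 1e-6)
})

test_that("cottontail bins use right-closed intervals and report
           out-of-range records", {
  rec <- tibble::tibble(
    S = c(1, 3, 3.5, 13, 13.2, 0.5),
    V = 1:6, L = 1:6
  )
  b <- bin_by_cottontail(rec)
  expect_identical(levels(b$bin)[1], "(1,3]")
  expect_identical(as.character(b$bin[2]), "(1,3]") # edge joins lower bin
  expect_identical(as.character(b$bin[3]), "(3,5]")
  expect_identical(as.character(b$bin[4]), "(11,13]")
  expect_true(is.na(b$bin[1 + 4])) # 13.2 above the last edge
  expect_true(is.na(b$bin[6])) # 0.5 below the first edge
  expect_true(is.na(b$bin[1])) # 1 sits on the open left edge
  expect_identical(attr(b, "n_out_of_range"), 3L)
  empty <- bin_by_cottontail(rec[0, ])
  expect_identical(nrow(empty), 0L)
  expect_identical(length(levels(empty$bin)), 6L)
  expect_error(bin_by_cottontail(rec, edges = c(3, 1)),
    class = "hp_invalid_input"
  )
})

test_that("the normal-equation regression interpolates, flags degenerate
           designs, and matches lm", {
  two <- tibble::tibble(V = c(1, 2), L = exp(c(0.3, 0.8)))
  f <- fit_loghare_vs_fox(two)
  expect_true(f$defined)
  expect_equal(f$slope, 0.5)
  expect_equal(f$intercept, -0.2)
  flat <- tibble::tibble(V = c(1, 1, 1), L = exp(c(0.1, 0.4, 0.2)))
  expect_false(fit_loghare_vs_fox(flat)$defined)
  lone <- tibble::tibble(V = 1, L = 2)
  expect_false(fit_loghare_vs_fox(lone)$defined)
  # cross-check against lm on a noisy group
  set.seed(101)
  g <- tibble::tibble(V = runif(40, 0, 3), L = exp(1 - 0.7 * runif(40, 0, 3)))
  g$L <- g$L * exp(rnorm(40, 0, 0.2))
  f2 <- fit_loghare_vs_fox(g)
  ref <- lm(log(L) ~ V, data = g)
  expect_equal(f2$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(f2$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(f2$slope_se,
    summary(ref)$coefficients["V", "Std. Error"],
    tolerance = 1e-12
  )
})

test_that("regression recovers a known line from noisy synthetic groups", {
  set.seed(113)
  for (i in 1:10) {
    slope <- runif(1, -3, 3)
    intercept <- runif(1, -2, 2)
    V <- runif(60, 0.2, 4)
    lnL <- intercept + slope * V + rnorm(60, 0, 0.3)
    g <- tibble::tibble(V = V, L = exp(lnL))
    f <- fit_loghare_vs_fox(g)
    expect_lt(abs(f$slope - slope), 3 * f$slope_se)
  }
})

test_that("extinct-hare records are excluded and tallied", {
  g <- tibble::tibble(
    V = c(1, 2, 3, 4), L = c(exp(0.2), exp(0.6), 0, 1e-9)
  )
  f <- fit_loghare_vs_fox(g)
  expect_identical(f$n_used, 2L)
  expect_identical(f$n_excluded, 2L)
  expect_true(f$defined)
})

test_that("slope trends summarize the hyperpredation signature", {
  fits <- tibble::tibble(
    bin = c("a", "b", "c"),
    slope = c(0.5, 0.1, -0.2), defined = TRUE
  )
  tr <- slope_trend(fits)
  expect_identical(tr$trend, "decreasing")
  expect_true(tr$ends_negative)
  fits2 <- tibble::tibble(bin = "a", slope = 0.5, defined = TRUE)
  expect_identical(slope_trend(fits2)$trend, "undefined")
  fits3 <- tibble::tibble(
    bin = c("a", "b", "c"),
    slope = c(0.1, 0.4, -0.2), defined = TRUE
  )
  expect_identical(slope_trend(fits3)$trend, "mixed")
})
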