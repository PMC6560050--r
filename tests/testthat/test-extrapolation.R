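h <- function(x) quantity(x, "hartree")

test_that("two-point power-law form matches hand-derived closed forms", {
  # constant series is its own limit (weights sum to 1)
  expect_equal(qty_value(two_point_power_cbs(h(-1), h(-1), 3, 4, 3)), -1)
  # oracle: solve E(X) = E_CBS + A X^-3 through (3, -0.9), (4, -0.95) by hand
  expect_equal(qty_value(two_point_power_cbs(h(-0.9), h(-0.95), 3, 4, 3)),
               (64 * (-0.95) - 27 * (-0.9)) / 37, tolerance = 1e-12)
  expect_equal(qty_value(two_point_power_cbs(h(-0.9), h(-0.95), 3, 4, 3)),
               -0.986486, tolerance = 1e-6)
  # generator inversion: exact recovery of a planted power-law limit
  e <- function(x, p) -2.0 + 0.5 * x^(-p)
  expect_equal(qty_value(two_point_power_cbs(h(e(2, 2.13)), h(e(3, 2.13)),
                                             2, 3, 2.13)),
               -2.0, tolerance = 1e-12)
  expect_error(two_point_power_cbs(h(-1), h(-2), 3, 3, 3), "differ")
  expect_error(two_point_power_cbs(h(-1), h(-2), 4, 3, 3), "exceed")
  expect_error(two_point_power_cbs(h(-1), h(-2), 2, 3, 0), "> 0")
  expect_error(two_point_power_cbs(h(-1), quantity(-2, "eV"), 2, 3, 3),
               "unit mismatch")
})

test_that("two-point weights sum to one for any exponent and cardinal pair", {
  for (p in c(0.5, 2.13, 3, 4.93)) {
    for (xs in list(c(2, 3), c(3, 4), c(2, 4))) {
      # E_CBS of the constant-one series must be one
      expect_equal(qty_value(two_point_power_cbs(h(1), h(1), xs[1], xs[2], p)),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("DZ/TZ scheme coefficients match high-precision evaluation", {
  # HF coefficient on the TZ point: 3^4.93 / (3^4.93 - 2^4.93),
  # cross-checked by extended-precision evaluation
  expect_equal(3^4.93 / (3^4.93 - 2^4.93), 1.156709111977987, tolerance = 1e-12)
  dz <- component_energy(h(-99.5), h(-0.8))
  tz <- component_energy(h(-99.8), h(-0.9))
  res <- scheme1_cbs(dz, tz)
  whi_a <- 3^4.93 / (3^4.93 - 2^4.93); wlo_a <- 2^4.93 / (3^4.93 - 2^4.93)
  whi_b <- 3^2.13 / (3^2.13 - 2^2.13); wlo_b <- 2^2.13 / (3^2.13 - 2^2.13)
  expect_equal(qty_value(res$cbs_hf), whi_a * -99.8 - wlo_a * -99.5,
               tolerance = 1e-12)
  expect_equal(qty_value(res$cbs_corr), whi_b * -0.9 - wlo_b * -0.8,
               tolerance = 1e-12)
  expect_equal(qty_value(res$cbs_total),
               qty_value(res$cbs_hf) + qty_value(res$cbs_corr),
               tolerance = 1e-9)
  # constant components: the result is the constant
  cst <- scheme1_cbs(dz, dz)
  expect_equal(qty_value(cst$cbs_total), qty_value(dz$total))
})

test_that("exponential HF fit inverts an exact exponential series", {
  e <- function(x) h(-100 + exp(-x))
  expect_equal(qty_value(hf_exponential_cbs(e(2), e(3), e(4))), -100,
               tolerance = 1e-9)
  # stated intermediate values
  expect_equal(qty_value(e(2)), -99.864665, tolerance = 1e-6)
  for (B in c(0.7, 1.4, 2.5)) {
    for (A in c(0.05, -0.3)) {
      f <- function(x) h(-50 + A * exp(-B * x))
      expect_equal(qty_value(hf_exponential_cbs(f(2), f(3), f(4))), -50,
                   tolerance = 1e-10)
    }
  }
  # degenerate inputs are rejected with the offending differences named
  expect_error(hf_exponential_cbs(h(-1), h(-1), h(-1)), "contracting")
  expect_error(hf_exponential_cbs(h(-1), h(-2), h(-3)), "contracting")
  expect_error(hf_exponential_cbs(h(-1), h(-2), h(-1.5)), "contracting")
})

test_that("full scheme II recovers planted limits and flags wrong cardinals", {
  model_hf <- function(x) -120 + 0.08 * exp(-1.4 * x)
  model_corr <- function(x) -2.5 + 0.15 * x^(-3)
  ce <- function(x) component_energy(h(model_hf(x)), h(model_corr(x)))
  res <- scheme2_cbs(ce(2), ce(3), ce(4))
  expect_equal(qty_value(res$cbs_hf), -120, tolerance = 1e-10)
  expect_equal(qty_value(res$cbs_corr), -2.5, tolerance = 1e-10)
  expect_equal(qty_value(res$cbs_total), -122.5, tolerance = 1e-10)
  # eq2 mode reuses the DZ/TZ power-law for HF: differs from the
  # exponential fit by the closed-form mismatch
  res_eq2 <- scheme2_cbs(ce(2), ce(3), ce(4),
                         cbs_params(hf_cbs_mode = "eq2"))
  whi <- 3^4.93 / (3^4.93 - 2^4.93); wlo <- 2^4.93 / (3^4.93 - 2^4.93)
  expect_equal(qty_value(res_eq2$cbs_hf),
               whi * model_hf(3) - wlo * model_hf(2), tolerance = 1e-12)
  expect_false(qty_value(res_eq2$cbs_hf) == qty_value(res$cbs_hf))
})

test_that("power-law HF input gives scheme-dependent limits, as closed forms say", {
  # exactly power-law HF passed to the exponential fit: result differs from
  # the power-law limit by an amount both closed forms predict
  hfpl <- function(x) -80 + 0.2 * x^(-4.93)
  s1 <- qty_value(two_point_power_cbs(h(hfpl(2)), h(hfpl(3)), 2, 3, 4.93))
  d1 <- hfpl(2) - hfpl(3); d2 <- hfpl(3) - hfpl(4)
  aitken <- hfpl(4) - d2^2 / (d1 - d2)
  s2 <- qty_value(hf_exponential_cbs(h(hfpl(2)), h(hfpl(3)), h(hfpl(4))))
  expect_equal(s1, -80, tolerance = 1e-10)
  expect_equal(s2, aitken, tolerance = 1e-12)
  expect_gt(abs(s2 - s1), 1e-6)
})

test_that("the linear extrapolations commute with differencing; the exponential does not", {
  set.seed(42)
  for (rep in 1:5) {
    a <- stats::rnorm(2); b <- stats::rnorm(2)
    lin <- function(v) qty_value(two_point_power_cbs(h(v[1]), h(v[2]),
                                                     3, 4, 3))
    expect_equal(lin(a - b), lin(a) - lin(b), tolerance = 1e-10)
  }
  # constructed counterexample for the exponential three-point form
  f <- function(x) -10 + 0.3 * exp(-0.9 * x)
  g <- function(x) -12 + 0.1 * exp(-2.0 * x)
  ext <- function(fn) qty_value(hf_exponential_cbs(h(fn(2)), h(fn(3)),
                                                   h(fn(4))))
  diff_of_ext <- ext(f) - ext(g)
  ext_of_diff <- ext(function(x) f(x) - g(x))
  expect_gt(abs(diff_of_ext - ext_of_diff), 1e-8)
})

test_that("CBS limits sit below the largest-basis value for decreasing series", {
  # mirrors the uniformly negative CBS-minus-QZ differences of the study
  fx <- load_paper_fixtures()
  expect_true(all(fx$table3$scheme1_cbs < fx$table2$mp2_qz))
  expect_true(all(fx$table4$scheme2_cbs < fx$table2$mp2_qz))
  # and synthetically: monotone decreasing series extrapolate below QZ
  dec <- function(x) -300 / 627.509474 + 0.01 * x^(-3)
  lim <- qty_value(two_point_power_cbs(h(dec(3)), h(dec(4)), 3, 4, 3))
  expect_lt(lim, dec(4))
})
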