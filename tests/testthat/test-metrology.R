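# Add-in-quadrature uncertainty propagation and Welch power analysis.

test_that("quadrature addition behaves like a Euclidean norm", {
  expect_equal(quad_add(c(3, 4)), 5)
  expect_equal(quad_add(c(7, 0)), 7)
  expect_error(quad_add(c(1, -1)), class = "tendonmech_domain")

  set.seed(2)
  for (i in 1:10) {
    terms <- runif(sample(2:6, 1), 0, 5)
    expect_equal(quad_add(terms), sqrt(sum(terms^2)))
    # symmetric, and bounded between the largest term and the plain sum
    expect_equal(quad_add(rev(terms)), quad_add(terms))
    expect_gte(quad_add(terms), max(terms))
    expect_lte(quad_add(terms), sum(terms))
  }
})

test_that("multiplicative propagation reproduces the worked examples", {
  # strain: x = 1.00 mm with delta_x = 0.01 mm at eps = 0.2 gives 0.002
  expect_equal(quad_mul(0.2, 0.01 / 1.00), 0.002)

  # stress: d = 0.1 mm (delta 0.0025), P = 100 g (delta 1e-4),
  # sigma = 58.2 MPa gives 2 MPa at one significant figure
  rel_A <- sqrt(2) * 0.0025 / 0.1
  d_sigma <- quad_mul(58.2, c(1e-4 / 100, rel_A))
  expect_equal(signif(d_sigma, 1), 2)

  expect_equal(quad_mul(123, c(0, 0)), 0)
  expect_error(quad_mul(1, -0.1), class = "tendonmech_domain")
})

test_that("the assembled budget covers the derived quantities", {
  bud <- uncertainty_budget(x = 1.00, L0 = 5, d = 0.1, P = 100,
                            sigma = 58.2, E = 619, D = 400)
  get <- function(q, col) bud[[col]][bud$quantity == q]

  expect_equal(get("eps", "value"), 0.2)
  expect_equal(get("eps", "delta"), 0.002)
  # the extensibility SEM of 0.005 is 2.5 times the strain uncertainty
  expect_equal(0.005 / get("eps", "delta"), 2.5)

  expect_equal(signif(get("A", "value"), 1), 8e-3)
  expect_equal(signif(get("A", "delta"), 1), 3e-4)
  expect_equal(signif(get("sigma", "delta"), 1), 2)
  expect_equal(signif(get("a_f", "value"), 1), 1e5)
  expect_equal(get("field_area", "value"), 2e7)
  expect_equal(signif(get("field_area", "delta"), 1), 3e3)

  # an all-zero instrument budget propagates to all-zero deltas
  bud0 <- uncertainty_budget(x = 1, L0 = 5, d = 0.1, P = 100, sigma = 58.2,
                             E = 619, D = 400,
                             budget = instrument_budget(0, 0, 0, 0))
  expect_true(all(bud0$delta == 0))
})

test_that("Monte-Carlo propagation agrees with the quadrature deltas", {
  budget <- instrument_budget()
  # strain eps = x / L0 (L0 treated as exact, as in the budget)
  mc_eps <- mc_propagate(function(v) v$x / 5,
                         values = c(x = 1.00),
                         deltas = c(x = budget$delta_x),
                         n = 1e5, seed = 10)
  expect_lt(abs(mc_eps$sd - 0.002) / 0.002, 0.05)

  # stress sigma = P / A over the independently budgeted inputs P and A
  # (the area's uncertainty is assembled first, then enters as one term)
  g2n <- 9.80665e-3
  A <- pi * 0.1^2 / 4
  dA <- quad_mul(A, sqrt(2) * budget$delta_d / 0.1)
  f_sigma <- function(v) v$P * g2n / v$A
  mc_sig <- mc_propagate(f_sigma,
                         values = c(P = 100, A = A),
                         deltas = c(P = budget$delta_P, A = dA),
                         n = 1e5, seed = 11)
  quad_sig <- quad_mul(f_sigma(list(P = 100, A = A)),
                       c(budget$delta_P / 100, dA / A))
  expect_lt(abs(mc_sig$sd - quad_sig) / quad_sig, 0.05)
})

test_that("Welch power is exact at the null and matches simulation", {
  # zero effect: the rejection rate is exactly alpha
  expect_equal(welch_power(10, 10, 2, 3, 5, 7, alpha = 0.05), 0.05,
               tolerance = 1e-6)
  expect_equal(welch_power(0, 0, 1, 1, 4, 4, alpha = 0.01), 0.01,
               tolerance = 1e-6)

  # power rises monotonically with the effect size
  pw <- vapply(seq(0, 30, by = 2), function(d)
    welch_power(50, 50 + d, 8, 10, 4, 3), numeric(1))
  expect_true(all(diff(pw) > 0))
  # ... with sample size, and falls with dispersion
  expect_gt(welch_power(50, 60, 8, 8, 8, 8), welch_power(50, 60, 8, 8, 4, 4))
  expect_lt(welch_power(50, 60, 16, 16, 4, 4), welch_power(50, 60, 8, 8, 4, 4))
  expect_true(all(pw > 0 & pw < 1))

  expect_error(welch_power(1, 2, 0, 0, 4, 4), class = "tendonmech_domain")
  expect_error(welch_power(1, 2, 1, 1, 1, 4), class = "tendonmech_domain")

  # simulation oracle on three design-sized fixtures (n >= 6 per group;
  # below that the fixed-df noncentral-t approximation visibly departs
  # from the true rejection rate of the estimated-df Welch test)
  fixtures <- list(
    list(m1 = 26.6, m2 = 42.6, sd1 = sd_from_sem(3.2, 3),
         sd2 = sd_from_sem(3.4, 3), n1 = 6, n2 = 6, sides = 2),
    list(m1 = 376.9, m2 = 574.4, sd1 = sd_from_sem(61.3, 3),
         sd2 = sd_from_sem(52.2, 3), n1 = 8, n2 = 8, sides = 2),
    list(m1 = 50, m2 = 60, sd1 = 8, sd2 = 10, n1 = 10, n2 = 10,
         sides = 1))
  for (fx in fixtures) {
    analytic <- welch_power(fx$m1, fx$m2, fx$sd1, fx$sd2, fx$n1, fx$n2,
                            sides = fx$sides)
    mc <- welch_power_mc(fx$m1, fx$m2, fx$sd1, fx$sd2, fx$n1, fx$n2,
                         sides = fx$sides, nrep = 2e4, seed = 21)
    expect_lt(abs(analytic - mc), 0.02)
  }
})

test_that("SDs recovered from SEMs scale with the square root of n", {
  expect_equal(sd_from_sem(4.1, 3), 4.1 * sqrt(3))
  expect_error(sd_from_sem(1, 1), class = "tendonmech_domain")
})
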