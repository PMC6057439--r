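# Trace zeroing, stress-strain conversion, landmark location, energy
# partition and aggregation.

test_that("zeroing finds the first sample at the load cutoff and sets L0", {
  # linear-scan oracle over all indices for the documented example
  loads <- c(0.1, 0.4, 1.0, 40, 100)
  disp <- c(0, 1, 2, 3, 4) + 2   # shift so L0 > 0 at the origin
  tr <- mtt_trace(time_ms = 1:5, disp_mv = disp, load_mv = loads,
                  disp_mm = disp, load_g = loads)
  cfg <- analysis_config(0.1, laststrainpt = 0.5)
  z <- zero_trace(tr, cfg)
  oracle <- min(which(loads >= 0.01 * max(loads)))
  expect_equal(z$origin_index, oracle)
  expect_equal(z$origin_index, 3L)
  expect_equal(z$L0, disp[3])
  expect_equal(z$disp, c(0, 1, 2))
  expect_equal(z$load, loads[3:5] - loads[3])

  # first sample already above cutoff: origin at index 1
  tr2 <- linear_trace()
  z2 <- zero_trace(tr2, cfg)
  expect_equal(z2$origin_index, 1L)
  expect_equal(z2$disp, tr2$disp_mm - tr2$disp_mm[1])

  # all-zero load is degenerate
  tr3 <- mtt_trace(1:3, 1:3, 1:3, c(1, 2, 3), c(0, 0, 0))
  expect_error(zero_trace(tr3, cfg), class = "tendonmech_degenerate_trace")

  # manual truncation honours the caller-supplied start index
  cfgm <- analysis_config(0.1, laststrainpt = 0.5, loadat1percent = FALSE,
                          start_index = 2L)
  zm <- zero_trace(tr, cfgm)
  expect_equal(zm$origin_index, 2L)
  expect_equal(zm$L0, disp[2])
})

test_that("stress-strain conversion uses sigma = P/A and eps = x/L0", {
  # area from thickness: d = 0.1 mm gives A = pi d^2 / 4 = 8e-3 mm^2 (1 s.f.)
  geom <- fascicle_geometry(0.1)
  expect_equal(signif(geom$A, 1), 8e-3)
  expect_equal(geom$A, pi * 0.01 / 4, tolerance = 1e-15)

  cfg <- analysis_config(0.1, laststrainpt = 0.5)
  z <- list(disp = c(0, 1.00), load = c(0, 100), L0 = 5)
  curve <- to_stress_strain(z, geometry = geom, cfg = cfg)
  expect_equal(curve$strain[2], 0.2)          # x = 1.00 mm over L0 = 5 mm
  expect_equal(curve$stress[1], 0)            # zero load at the origin
  expect_equal(curve$stress[2], 100 * 9.80665e-3 / geom$A)
})

test_that("yield location matches the analytic max-slope point", {
  # logistic stress law: analytic max slope 50 * 100 / 4 = 1250 MPa at 0.05
  eps <- seq(0, 0.12, length.out = 500)
  sig <- 50 / (1 + exp(-100 * (eps - 0.05)))
  curve <- structure(list(strain = eps, stress = sig, L0 = 5, A = 8e-3),
                     class = "stress_strain_curve")
  y <- locate_yield(curve, orderpoly = 5)
  step <- eps[2] - eps[1]
  expect_lt(abs(y$eps_Y - 0.05), step + 1e-12)
  expect_lt(abs(y$E - 1250) / 1250, 0.03)

  # exactly linear data: constant gradient, tie broken to the earliest index
  eps2 <- seq(0, 0.1, length.out = 200)
  curve2 <- structure(list(strain = eps2, stress = 600 * eps2),
                      class = "stress_strain_curve")
  expect_warning(y2 <- locate_yield(curve2, orderpoly = 3),
                 class = "tendonmech_boundary")
  expect_equal(y2$p, 1L)
  expect_equal(y2$E, 600, tolerance = 1e-6)

  # too few samples before the peak
  curve3 <- structure(list(strain = c(0, 0.01, 0.02), stress = c(0, 1, 2)),
                      class = "stress_strain_curve")
  expect_error(locate_yield(curve3, orderpoly = 5),
               class = "tendonmech_numeric")
})

test_that("yield location converges with grid density on smooth curves", {
  for (n in c(125, 250, 500)) {
    eps <- seq(0, 0.12, length.out = n)
    sig <- 50 / (1 + exp(-100 * (eps - 0.05)))
    curve <- structure(list(strain = eps, stress = sig),
                       class = "stress_strain_curve")
    y <- locate_yield(curve, orderpoly = 6)
    step <- eps[2] - eps[1]
    expect_lt(abs(y$eps_Y - 0.05), step + 1e-12)  # within one grid step
  }
})

test_that("rupture index honours the strain estimate with a safe fallback", {
  eps <- seq(0, 0.15, length.out = 151)
  sig <- ifelse(eps <= 0.1, eps * 100, 10 - (eps - 0.1) * 50)
  curve <- structure(list(strain = eps, stress = sig),
                     class = "stress_strain_curve")
  q <- which.max(sig)
  # scan oracle: last sample with strain <= laststrainpt
  r <- locate_rupture(curve, 0.12, q = q)
  expect_equal(r, max(which(eps <= 0.12)))
  # estimate beyond the record: final sample
  expect_equal(locate_rupture(curve, 0.5, q = q), length(eps))
  # estimate below the peak strain: fallback to final sample with a warning
  expect_warning(r3 <- locate_rupture(curve, 0.05, q = q),
                 class = "tendonmech_rupture_fallback")
  expect_equal(r3, length(eps))
})

test_that("strain energy partition is trapezium-exact and additive", {
  # linear ramp to (0.1, 10 MPa): resilience is the triangle area 0.5 MPa
  eps <- seq(0, 0.1, length.out = 11)
  curve <- structure(list(strain = eps, stress = 100 * eps),
                     class = "stress_strain_curve")
  en <- strain_energy_partition(curve, p = 11L, q = 11L, r = 11L)
  expect_equal(en$u_Y, 0.5, tolerance = 1e-12)
  expect_equal(en$u_P, 0); expect_equal(en$u_R, 0)
  expect_identical(en$u_0, en$u_Y)

  # quadratic law sigma = 100 eps^2 on [0, 0.1]: analytic integral 1/30
  eps2 <- seq(0, 0.1, length.out = 1000)
  curve2 <- structure(list(strain = eps2, stress = 100 * eps2^2),
                      class = "stress_strain_curve")
  en2 <- strain_energy_partition(curve2, p = 1000L, q = 1000L, r = 1000L)
  expect_equal(en2$u_Y, 100 * 0.1^3 / 3, tolerance = 1e-5)

  # segments share endpoints: the parts always sum to the whole, exactly
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    eps3 <- sort(runif(n, 0, 0.2)); eps3[1] <- 0
    sig3 <- cumsum(abs(rnorm(n))); sig3 <- sig3 - sig3[1]
    curve3 <- structure(list(strain = eps3, stress = sig3),
                        class = "stress_strain_curve")
    lm_ <- sort(sample(2:n, 3))
    en3 <- strain_energy_partition(curve3, lm_[1], lm_[2], lm_[3])
    expect_identical(en3$u_0, en3$u_Y + en3$u_P + en3$u_R)
    expect_identical(en3$u_F, en3$u_P + en3$u_R)
    expect_true(all(c(en3$u_Y, en3$u_P, en3$u_R) >= 0))
  }
})

test_that("full pipeline recovers generator ground truth", {
  p <- trace_params(seed = 42)
  sim <- simulate_trace(p)
  pr <- derive_properties(sim$trace,
                          analysis_config(p$d, laststrainpt = 0.2,
                                          orderpoly = 7))
  expect_lt(abs(pr$E - p$truth$E) / p$truth$E, 0.05)
  expect_lt(abs(pr$sigma_U - p$truth$sigma_U) / p$truth$sigma_U, 0.05)
  expect_lt(abs(pr$u_0 - p$truth$u_0) / p$truth$u_0, 0.10)
  # structural invariants of every processed curve
  expect_identical(pr$u_0, pr$u_Y + pr$u_P + pr$u_R)
  expect_gte(pr$E, pr$sigma_U / pr$eps_U)  # max slope >= mean slope
  expect_lte(pr$eps_Y, pr$eps_U)
  expect_true(all(c(pr$eps_Y, pr$eps_U, pr$u_Y, pr$u_P, pr$u_R) >= 0))

  # noise-free, no-slack plateau family: taut from the first sample, so the
  # manual-truncation mode passes the trace through and the pipeline
  # strength equals the plateau exactly
  pp <- trace_params(E_true = 600, sigmaY_true = 20, sigmaU_true = 35,
                     epsY_true = 0.05, epsU_true = 0.10,
                     rupture_eps = 0.14, end_stress_frac = 1,
                     slack_mm = 0, noise_sd_g = 0)
  simp <- simulate_trace(pp)
  prp <- derive_properties(simp$trace,
                           analysis_config(pp$d, laststrainpt = 0.2,
                                           loadat1percent = FALSE,
                                           start_index = 1L))
  expect_equal(prp$sigma_U, 35, tolerance = 1e-9)

  # a trace that cannot be zeroed names the failing stage
  dead <- mtt_trace(1:3, 1:3, 1:3, c(1, 2, 3), c(0, 0, 0))
  err <- tryCatch(derive_properties(dead, analysis_config(0.1, 0.2)),
                  error = identity)
  expect_match(conditionMessage(err), "zero_trace")
})

test_that("aggregation averages specimens to tails, then tails to groups", {
  # 2 tails with tail means 10 and 20: group mean 15, SEM 5
  df <- specimen_records(rep("01M", 4), c(1, 1, 2, 2), c(8, 12, 18, 22))
  agg <- aggregate_properties(df)
  expect_equal(agg$tail$E, c(10, 20))
  expect_equal(agg$age_group$mean_E, 15)
  expect_equal(agg$age_group$sem_E, 5)

  # single tail: mean passes through, SEM is reported missing
  one <- specimen_records("04M", 1, 7)
  agg1 <- aggregate_properties(one)
  expect_equal(agg1$age_group$mean_sU, 7)
  expect_true(is.na(agg1$age_group$sem_sU))

  expect_error(aggregate_properties(one[0, ]), class = "tendonmech_contract")

  # random nested fixture equals the brute-force two-stage average
  set.seed(9)
  big <- data.frame(age_group = sample(c("01M", "11M"), 60, TRUE),
                    sample = sample(1:3, 60, TRUE))
  for (pp in c("sY", "sU", "E", "uY", "uP", "uR", "uF", "u0", "uY_sY", "uF_sU"))
    big[[pp]] <- rnorm(60)
  agg2 <- aggregate_properties(big)
  for (g in unique(big$age_group)) {
    tails <- unique(big$sample[big$age_group == g])
    tail_means <- vapply(tails, function(s)
      mean(big$E[big$age_group == g & big$sample == s]), numeric(1))
    expect_equal(agg2$age_group$mean_E[agg2$age_group$age_group == g],
                 mean(tail_means))
    expect_equal(agg2$age_group$sem_E[agg2$age_group$age_group == g],
                 sd(tail_means) / sqrt(length(tail_means)))
  }
})
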