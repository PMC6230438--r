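# Closed-form phase and cycle durations.

test_that("rational-form coefficients follow from the half-center parameters", {
  p <- ref_params()
  co <- rational_coefficients(p)
  expect_equal(co$a, p$hc1$x0 + p$hc2$x0)      # -0.0007 + 2.4256 = 2.4249
  expect_equal(co$a, 2.4249)
  expect_equal(co$b, 1.1085)
  expect_equal(co$c_t, 0.6203 * 0.4882)

  sym <- limb_cpg_params(half_center_params(1, 0), half_center_params(1, 0))
  cs <- rational_coefficients(sym)
  expect_equal(unclass(cs), list(a = 2, b = 0, a_t = 1, b_t = 0, c_t = 0))

  gains <- limb_cpg_params(half_center_params(0, 1), half_center_params(0, 1))
  cg <- rational_coefficients(gains)
  expect_equal(unclass(cg), list(a = 0, b = 2, a_t = 0, b_t = 0, c_t = 1))
})

test_that("Taylor phase duration is the reciprocal effective rate", {
  expect_equal(phase_duration_taylor(half_center_params(2.4256, 0.4882),
                                     u = 4.7824),
               0.2100678072, tolerance = 1e-9)
  expect_equal(phase_duration_taylor(half_center_params(1, 0), u = 99), 1.0)
})

test_that("non-positive effective rate is rejected with the minimal admissible drive", {
  hc <- half_center_params(-0.0007, 0.6203)
  err <- expect_error(phase_duration_taylor(hc, u = 0),
                      class = "cpg_nonpositive_rate_error")
  expect_equal(err$u_min, 0.0007 / 0.6203)
  expect_match(conditionMessage(err), "minimal admissible")
})

test_that("exact phase duration matches an independent numerical integration", {
  # frozen from adaptive ODE root-finding (lsodar, rtol 1e-12) of
  # xdot = x0 + g*u + r*x from 0 to the threshold
  expect_equal(phase_duration_exact(half_center_params(2.4256, 0.4882),
                                    r_leak = -0.0094, u = 4.7824),
               0.2102754845, tolerance = 1e-8)
  expect_equal(phase_duration_exact(half_center_params(-0.0007, 0.6203),
                                    r_leak = -0.0094, u = 4.7824),
               0.3377100290, tolerance = 1e-8)
})

test_that("zero leak reduces the exact solution to the Taylor form exactly", {
  for (d in draw_admissible(10, seed = 7L)) {
    expect_identical(phase_duration_exact(d$params$hc1, 0, d$u),
                     phase_duration_taylor(d$params$hc1, d$u))
  }
})

test_that("leak saturation below threshold is a distinct error class", {
  hc <- half_center_params(0.001, 0)
  expect_error(phase_duration_exact(hc, r_leak = -0.0094, u = 1),
               class = "cpg_saturation_error")
  # distinguishable from the non-positive-rate failure
  expect_error(phase_duration_exact(half_center_params(-1, 0), -0.0094, 1),
               class = "cpg_nonpositive_rate_error")
})

test_that("cycle duration sums the two phases and carries the phase label on error", {
  p <- ref_params()
  cs <- cycle_duration(p, 4.7824, "taylor")
  expect_equal(cs$Tc, cs$tau1 + cs$tau2)
  expect_equal(cs$Tc, 0.5472423771, tolerance = 1e-9)

  sym <- limb_cpg_params(half_center_params(0, 1), half_center_params(0, 1))
  expect_equal(cycle_duration(sym, 2, "taylor")$Tc, 1.0)

  err <- expect_error(cycle_duration(p, 0, "taylor"), class = "cpg_error")
  expect_equal(err$phase, 1L)
  expect_match(conditionMessage(err), "phase 1")
})

test_that("exact and Taylor cycle durations differ by under 1% at the reference drive", {
  p <- ref_params()
  te <- cycle_duration(p, 4.7824, "exact")$Tc
  tt <- cycle_duration(p, 4.7824, "taylor")$Tc
  expect_lt(abs(te - tt) / tt, 0.01)
  expect_gt(te, tt)  # negative leak slows the approach to threshold
})

test_that("Taylor cycle duration is algebraically the rational form", {
  for (d in draw_admissible(25, seed = 11L)) {
    tc <- cycle_duration(d$params, d$u, "taylor")$Tc
    rf <- rational_cycle_duration(rational_coefficients(d$params), d$u)
    expect_equal(tc, rf, tolerance = 1e-12)
  }
})

test_that("exact converges to Taylor roughly linearly as the leak vanishes", {
  hc <- half_center_params(2.4256, 0.4882)
  u <- 4.7824
  tt <- phase_duration_taylor(hc, u)
  errs <- vapply(c(1e-2, 1e-4, 1e-6), function(r)
    abs(phase_duration_exact(hc, -r, u) - tt), numeric(1))
  expect_true(all(diff(errs) < 0))
  # error ratio tracks the |r| ratio (first-order in the leak)
  expect_equal(errs[1] / errs[2], 100, tolerance = 0.05)
  expect_equal(errs[2] / errs[3], 100, tolerance = 0.05)
})

test_that("cycle duration decreases strictly with drive for the reference parameters", {
  p <- ref_params()
  u <- seq(1, 10, by = 0.25)
  for (m in c("taylor", "exact")) {
    tc <- vapply(u, function(ui) cycle_duration(p, ui, m)$Tc, numeric(1))
    expect_true(all(diff(tc) < 0))
  }
})

test_that("with negative leak the exact phase duration dominates the Taylor one", {
  for (d in draw_admissible(25, seed = 13L)) {
    expect_gte(phase_duration_exact(d$params$hc1, d$params$r_leak, d$u),
               phase_duration_taylor(d$params$hc1, d$u))
  }
})

test_that("parameter constructors enforce model invariants", {
  expect_error(limb_cpg_params(half_center_params(1, 1),
                               half_center_params(1, 1), r_leak = 0.01),
               "r_leak")
  expect_error(half_center_params(NaN, 1))
  expect_equal(ref_params()$threshold, 1)
})
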