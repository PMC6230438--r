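# Event-detecting time-domain simulation.

test_that("unit ramp produces phase events exactly at integer seconds", {
  p <- limb_cpg_params(half_center_params(1, 0), half_center_params(1, 0),
                       r_leak = 0)
  sim <- simulate_cpg(p, 0, t_end = 4.5, dt = 1e-3)
  expect_equal(sim$events$time, 1:4, tolerance = 1e-9)
  expect_equal(sim$events$duration, rep(1, 4), tolerance = 1e-9)
  expect_equal(sim$events$ending_state, c(1L, 2L, 1L, 2L))
  expect_equal(sim$events$cycle_index, c(1L, 1L, 2L, 2L))
})

test_that("exactly one state is active and the inactive state is clamped at 0", {
  sim <- simulate_cpg(ref_params(), 4.7824, t_end = 2, dt = 1e-3)
  tr <- sim$trajectory
  expect_true(all(tr$active %in% c(1L, 2L)))
  expect_true(all(tr$x1[tr$active == 2L] == 0))
  expect_true(all(tr$x2[tr$active == 1L] == 0))
  active_x <- ifelse(tr$active == 1L, tr$x1, tr$x2)
  expect_true(all(active_x >= 0 & active_x <= 1))
  expect_true(all(diff(tr$time) > 0))
})

test_that("simulated phase durations match the closed-form exact solution", {
  # oracle equivalence across random admissible draws
  for (d in draw_admissible(50, seed = 99L)) {
    tau1 <- phase_duration_exact(d$params$hc1, d$params$r_leak, d$u)
    tau2 <- phase_duration_exact(d$params$hc2, d$params$r_leak, d$u)
    sim <- simulate_cpg(d$params, d$u, t_end = 2.2 * (tau1 + tau2), dt = 1e-4)
    ev <- sim$events
    expect_gte(nrow(ev), 3L)
    got1 <- ev$duration[ev$ending_state == 1L]
    got2 <- ev$duration[ev$ending_state == 2L]
    expect_lt(max(abs(got1 - tau1) / tau1), 1e-3)
    expect_lt(max(abs(got2 - tau2) / tau2), 1e-3)
  }
})

test_that("halving dt at least halves the Euler stepper's phase-duration error", {
  p <- ref_params()
  u <- 4.7824
  tau1 <- phase_duration_exact(p$hc1, p$r_leak, u)
  err_at <- function(dt) {
    sim <- simulate_cpg(p, u, t_end = 1.2, dt = dt, stepper = "euler")
    abs(sim$events$duration[1] - tau1)
  }
  e1 <- err_at(2e-3); e2 <- err_at(1e-3); e3 <- err_at(5e-4)
  expect_lt(e2, e1 / 2 * 1.1)   # ~first order, 10% slack on the constant
  expect_lt(e3, e2 / 2 * 1.1)
  expect_lt(e3 / tau1, 1e-3)
})

test_that("a drive step mid-phase changes later durations without breaking reciprocity", {
  p <- ref_params()
  sig <- input_signal(c(4.7824, 9), start = c(0, 0.8))
  sim <- simulate_cpg(p, sig, t_end = 3, dt = 1e-3)
  ev <- sim$events
  expect_true(all(diff(ev$ending_state) != 0))  # strict alternation
  early <- ev$duration[ev$time < 0.8 & ev$ending_state == 1L]
  late <- ev$duration[ev$time > 1.5 & ev$ending_state == 1L]
  expect_gt(min(early), max(late))  # higher drive shortens phases
  tr <- sim$trajectory
  expect_true(all(tr$x1 == 0 | tr$x2 == 0))     # never both active
})

test_that("inadmissible drive stalls the oscillator with the stall time", {
  err <- expect_error(simulate_cpg(ref_params(), 0, t_end = 1),
                      class = "cpg_stalled_error")
  expect_equal(err$active, 1L)
  expect_equal(err$time, 0)
})

test_that("measure_cycles pairs alternating phases and guards malformed input", {
  ev <- data.frame(time = cumsum(c(0.337, 0.21, 0.337, 0.21)),
                   ending_state = c(1L, 2L, 1L, 2L),
                   duration = c(0.337, 0.21, 0.337, 0.21),
                   cycle_index = c(1L, 1L, 2L, 2L))
  cyc <- measure_cycles(ev)
  expect_equal(nrow(cyc), 2L)
  expect_equal(cyc$Tc, c(0.547, 0.547))

  # unpaired trailing phase discarded
  cyc3 <- measure_cycles(ev[1:3, ])
  expect_equal(nrow(cyc3), 1L)

  expect_warning(out <- measure_cycles(ev[1, ]), "fewer than 2")
  expect_equal(nrow(out), 0L)

  bad <- ev; bad$ending_state <- c(1L, 1L, 2L, 2L)
  expect_error(measure_cycles(bad), "alternate")
})

test_that("input_signal validates its schedule", {
  expect_error(input_signal(c(1, 2), start = c(0.5, 1)), "start at t = 0")
  expect_error(input_signal(c(1, 2), start = c(0, 0)), "strictly increasing")
  expect_s3_class(input_signal(3), "input_signal")
})
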