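# The three-unit activity-based network: output function, right-hand sides,
# integration, event detection and regime classification.

test_that("the piecewise-linear output clamps between its thresholds", {
  expect_equal(output_function(-50), 0)
  expect_equal(output_function(0), 1)
  expect_equal(output_function(-25), 0.5)
  expect_equal(output_function(-80), 0)
  expect_equal(output_function(30), 1)
  v <- seq(-70, 10, by = 0.1)
  f <- output_function(v)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(!is.unsorted(f))
})

test_that("gating curves hit printed half-activation values", {
  expect_equal(reduced_m_inf(-40), 0.5)
  expect_equal(reduced_h_inf(-59), 0.5)
  expect_equal(reduced_tau_h(-59), 5000)
  # activation increases with voltage despite the negative slope constant
  expect_true(all(diff(reduced_m_inf(seq(-70, 0, by = 1))) > 0))
  expect_true(all(diff(reduced_h_inf(seq(-70, 0, by = 1))) < 0))
})

test_that("synaptic current vanishes at its reversal and when outputs are zero", {
  p <- reduced_params()
  # all units at the synaptic reversal: coupling has no effect on dv
  d_coupled <- reduced_derivatives(rep(-10, 3), rep(0.5, 3), w = 5, params = p)
  d_uncoupl <- reduced_derivatives(rep(-10, 3), rep(0.5, 3), w = 0, params = p)
  expect_equal(d_coupled$dv, d_uncoupl$dv)
  # all units below the output threshold: f = 0, intrinsic dynamics only
  d1 <- reduced_derivatives(c(-60, -62, -64), rep(0.6, 3), w = 4, params = p)
  d0 <- reduced_derivatives(c(-60, -62, -64), rep(0.6, 3), w = 0, params = p)
  expect_equal(d1$dv, d0$dv)
  expect_equal(d1$dh, d0$dh)
})

test_that("trajectories are deterministic with bounded h and f", {
  a <- simulate_reduced(w = 2, duration = 30000)
  b <- simulate_reduced(w = 2, duration = 30000)
  expect_identical(a, b)
  expect_true(all(a$h1 >= 0 & a$h1 <= 1))
  expect_true(all(a$h3 >= 0 & a$h3 <= 1))
  expect_true(all(a$f_sum >= 0 & a$f_sum <= 3))
})

test_that("the uncoupled network shows the canonical excitability split", {
  traj <- reduced_traj(0, duration = 250000)
  cyc <- detect_cycles(traj)
  ev <- cyc$unit_events
  n_he <- sum(ev$unit == 1)
  n_me <- sum(ev$unit == 2)
  expect_gt(n_he, 0)
  expect_gt(n_me, 0)
  expect_gt(n_he, n_me)                    # HE bursts faster than ME
  expect_equal(sum(ev$unit == 3), 0)       # LE silent when uncoupled
})

test_that("cycle detection merges overlapping unit events into network events", {
  tm <- seq(0, 1000, by = 10)
  mk <- function(lo, hi) as.numeric(tm >= lo & tm <= hi) * 0.5
  traj <- tibble::tibble(time = tm,
                         v1 = 0, v2 = 0, v3 = 0,
                         h1 = 0.5, h2 = 0.5, h3 = 0.5,
                         f1 = mk(100, 200) + mk(600, 700),
                         f2 = mk(150, 250),
                         f3 = mk(620, 680),
                         f_sum = 0)
  cyc <- detect_cycles(traj)
  ne <- cyc$network_events
  expect_equal(nrow(ne), 2)
  expect_equal(ne$class, c("SA", "LA"))    # only the second involves unit 3
  expect_equal(ne$units[[1]], c(1L, 2L))
  expect_equal(ne$units[[2]], c(1L, 3L))
})

test_that("halving the integration step leaves the regime and period intact", {
  t1 <- simulate_reduced(w = 3, duration = 150000, dt = 0.5, discard = 50000)
  t2 <- simulate_reduced(w = 3, duration = 150000, dt = 0.25, discard = 50000)
  r1 <- reduced_regime(t1)
  r2 <- reduced_regime(t2)
  expect_equal(r1$n_per_la, r2$n_per_la)
  per <- function(tr) {
    on <- detect_cycles(tr)$unit_events
    mean(diff(sort(on$onset[on$unit == 3])))
  }
  expect_lt(abs(per(t1) - per(t2)) / per(t2), 0.01)
})

test_that("RK4 agrees with an adaptive reference on the coupled system", {
  skip_if_not_installed("deSolve")
  p <- reduced_params()
  rhs <- function(t, y, parms) {
    d <- reduced_derivatives(y[1:3], y[4:6], w = parms, params = p)
    list(c(d$dv, d$dh))
  }
  ref <- deSolve::lsoda(c(rep(-60, 3), rep(0.6, 3)), seq(0, 100000, by = 10),
                        rhs, 2, rtol = 1e-9, atol = 1e-9)
  traj <- simulate_reduced(w = 2, duration = 100000, record_every = 20)
  idx <- match(traj$time, ref[, 1])
  expect_lt(max(abs(traj$v1 - ref[idx, 2])), 0.5)   # mV, over 100 s of MMO
  expect_lt(max(abs(traj$h3 - ref[idx, 7])), 1e-3)
})

test_that("a transient drop in excitability abolishes LA cycles", {
  # scaling all leak reversals by 1.08 makes them 8% more negative; the HE
  # unit (to -58.9 mV) stays inside the bursting window while the LE unit
  # drops too far below its activation threshold to be recruited
  traj <- simulate_reduced(w = 1.7, duration = 140000, discard = 20000,
                           perturb = list(t_on = 60000, t_off = 140000,
                                          e_l_scale = 1.08))
  cyc <- detect_cycles(traj)
  ev <- cyc$unit_events
  in_win <- ev$onset >= 75000          # allow a settling margin
  expect_true(any(ev$unit == 3 & !in_win))      # LA cycles present before
  expect_equal(sum(ev$unit == 3 & in_win), 0)   # none during the perturbation
  expect_gt(sum(ev$unit == 1 & in_win), 0)      # HE keeps bursting, slowly
})

test_that("weight scans collect per-unit onset-to-onset periods", {
  sc <- scan_weights(c(0, 2), duration = 150000, discard = 50000)
  expect_true(all(c("w", "unit", "onset", "period") %in% names(sc)))
  # uncoupled HE period equals the single-unit intrinsic period
  he0 <- sc$period[sc$w == 0 & sc$unit == 1]
  expect_gt(length(he0), 3)
  expect_lt(sd(he0, na.rm = TRUE) / mean(he0, na.rm = TRUE), 0.01)
  expect_equal(sum(sc$unit == 3 & sc$w == 0), 0)
  expect_gt(sum(sc$unit == 3 & sc$w == 2), 0)
})
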