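test_that("drive pressure is a square wave between PEEP and PEEP + Pinsp", {
  s <- vent_settings(25, 5, 15, 2)
  expect_equal(drive_pressure(s, t = 0.5), 30)
  expect_equal(drive_pressure(s, t = 2.0), 5)
  expect_equal(drive_pressure(s, t = c(0, 1.33, 1.34, 3.99)),
               c(30, 30, 5, 5))
  # times fold into the period
  expect_equal(drive_pressure(s, t = 4.5), 30)
  s0 <- vent_settings(0, 5, 15, 2)
  expect_equal(drive_pressure(s0, t = seq(0, 3.9, by = 0.5)),
               rep(5, 8))
})

test_that("phase dynamics have the expected time constants and structure", {
  # Bench inspiration: slow (lung) and fast (tubing) modes.
  pd <- phase_dynamics(bench_lung1(), bench_circuit(), "insp")
  expect_equal(pd$n, 2L)
  expect_equal(max(pd$time_constants), 1.4182, tolerance = 1e-4)
  expect_equal(pd$r_series, 22)

  # Restrictor resistance adds in series on the ventilator side.
  pd_r <- phase_dynamics(bench_lung1(), bench_circuit(12), "insp")
  expect_equal(pd_r$r_series, 34)
  pd_r_exp <- phase_dynamics(bench_lung1(), bench_circuit(12), "exp")
  expect_equal(pd_r_exp$r_series, 22)

  # c_v = 0 collapses to one state with tau = (Rv + R) C = 1.36 s.
  pd0 <- phase_dynamics(bench_lung1(), circuit_params(22, 0), "insp")
  expect_equal(pd0$n, 1L)
  expect_equal(pd0$time_constants, (22 + 12) * 0.04)

  # Slow eigen-time-constant cross-checked by numerical integration:
  # with zero drive amplitude both phases share the same dynamics, and
  # after the fast tubing mode dies out the cycle-to-cycle residual
  # decays as exp(-period / tau_slow).
  tr <- simulate_transient(bench_lung1(), bench_circuit(),
                           vent_settings(0, 5, 15, 2),
                           initial_state = c(5, 15), n_cycles = 40)
  ratio <- tr$residuals[4] / tr$residuals[3]
  expect_equal(-4 / log(ratio), 1.4182, tolerance = 1e-3)
})

test_that("degenerate resistance combinations are rejected as ill-posed", {
  expect_error(
    phase_dynamics(lung_params(0, 0.04), circuit_params(22, 0.004), "insp"),
    class = "ventrc_ill_posed"
  )
  expect_error(
    phase_dynamics(lung_params(0, 0.04), circuit_params(0, 0), "insp"),
    class = "ventrc_ill_posed"
  )
  # r = 0 is fine without tubing compliance as long as Rs > 0
  pd <- phase_dynamics(lung_params(0, 0.04), circuit_params(22, 0), "insp")
  expect_equal(pd$time_constants, 22 * 0.04)
})

test_that("cyclic steady state reproduces the bench tidal volumes", {
  sol1 <- cyclic_steady_state(bench_lung1(), bench_circuit(),
                              bench_settings(25))
  expect_equal(sol1$vt, 0.541, tolerance = 0.02)
  sol2 <- cyclic_steady_state(bench_lung2(), bench_circuit(),
                              bench_settings(25))
  expect_equal(sol2$vt, 0.509, tolerance = 0.02)
})

test_that("zero drive amplitude gives zero tidal volume and flat pressures", {
  sol <- cyclic_steady_state(bench_lung1(), bench_circuit(),
                             vent_settings(0, 5, 15, 2))
  expect_equal(sol$vt, 0)
  expect_equal(range(sol$waveforms$p_lung_cmH2O), c(5, 5))
  expect_equal(range(sol$waveforms$p_tube_cmH2O), c(5, 5))
})

test_that("the c_v = 0 limit equals the first-order closed form", {
  s <- bench_settings(25)
  fo <- first_order_vt(bench_lung1(), 22, 22, s)
  sol <- cyclic_steady_state(bench_lung1(), circuit_params(22, 0), s)
  expect_equal(sol$vt, fo, tolerance = 1e-9)
  # frozen closed-form value: tau = 1.36 s both phases
  expect_equal(fo, 0.5668219, tolerance = 1e-6)

  # with an inspiratory restrictor the series resistances differ per phase
  fo_r <- first_order_vt(bench_lung1(), 34, 22, s)
  sol_r <- cyclic_steady_state(bench_lung1(),
                               circuit_params(22, 0, r_restrictor_insp = 12),
                               s)
  expect_equal(sol_r$vt, fo_r, tolerance = 1e-9)
})

test_that("first-order closed form has the right limits", {
  expect_equal(first_order_vt(bench_lung1(), 22, 22, vent_settings(0, 5)), 0)
  # long inspiration and expiration: full equilibration, vt -> Pinsp * C
  slow <- vent_settings(25, 5, rr = 0.06, ie_e = 1)
  expect_equal(first_order_vt(bench_lung1(), 22, 22, slow), 25 * 0.04,
               tolerance = 1e-6)
})

test_that("waveforms are periodic and conserve volume over a cycle", {
  withr::with_seed(42, {
    for (k in 1:5) {
      ps <- draw_param_set()
      sol <- cyclic_steady_state(ps$lung, ps$circuit, ps$settings,
                                 samples_per_cycle = 4000)
      wf <- sol$waveforms
      n <- nrow(wf)
      # state at t = 0 equals state at t = period
      expect_lt(max(abs(wf$p_tube_cmH2O[1] - wf$p_tube_cmH2O[n]),
                    abs(wf$p_lung_cmH2O[1] - wf$p_lung_cmH2O[n])), 1e-9)
      # net volume through the patient airway vanishes over a cycle
      expect_lt(abs(pracma::trapz(wf$time_s, wf$q_patient_Lps)), 1e-4)
      # so does the net volume through the series resistance; q_vent
      # jumps with the drive at the switch, so integrate per phase with
      # the inspiration-side limit appended at the switch time
      insp <- wf[wf$phase == "insp", ]
      expi <- wf[wf$phase == "exp", ]
      rs_i <- ps$circuit$r_v + ps$circuit$r_restrictor_insp
      p_i <- ps$settings$peep + ps$settings$pinsp
      q_switch <- (p_i - expi$p_tube_cmH2O[1]) / rs_i
      qv_int <-
        pracma::trapz(c(insp$time_s, expi$time_s[1]),
                      c(insp$q_vent_Lps, q_switch)) +
        pracma::trapz(expi$time_s, expi$q_vent_Lps)
      expect_lt(abs(qv_int), 1e-4)
      # bounds: 0 <= vt <= pinsp * c
      expect_gte(sol$vt, 0)
      expect_lte(sol$vt, ps$settings$pinsp * ps$lung$c + 1e-12)
    }
  })
})

test_that("tidal volume equals the integral of positive patient flow", {
  sol <- cyclic_steady_state(bench_lung1(), bench_circuit(),
                             bench_settings(25), samples_per_cycle = 20000)
  expect_equal(sol$vt, sol$vt_flow_integral, tolerance = 1e-6)
})

test_that("tidal volume responds monotonically to restriction and compliance", {
  s <- bench_settings(25)
  vt_r <- vapply(seq(0, 100, length.out = 12), function(r) {
    cyclic_steady_state(bench_lung1(), bench_circuit(r), s,
                        samples_per_cycle = 400)$vt
  }, numeric(1))
  expect_true(all(diff(vt_r) < 0))

  vt_c <- vapply(seq(0.01, 0.06, length.out = 8), function(cc) {
    cyclic_steady_state(lung_params(12, cc), bench_circuit(), s,
                        samples_per_cycle = 400)$vt
  }, numeric(1))
  expect_true(all(diff(vt_c) > 0))
})

test_that("time-marching oracle agrees with the closed-form cyclic solution", {
  tr <- simulate_transient(bench_lung1(), bench_circuit(), bench_settings(25),
                           n_cycles = 20, dt = 1e-3)
  sol <- cyclic_steady_state(bench_lung1(), bench_circuit(),
                             bench_settings(25))
  expect_lt(abs(tr$vt - sol$vt), 1e-4)
  expect_true(tr$converged)

  # starting at the cyclic solution's state, the first cycle is already
  # periodic to within the integrator's own accuracy
  tr0 <- simulate_transient(bench_lung1(), bench_circuit(),
                            bench_settings(25), initial_state = sol$x0,
                            n_cycles = 5, tol = 1e-12)
  expect_lt(tr0$residuals[1], 1e-5)
})

test_that("the integrator guards its step size and reports non-convergence", {
  expect_error(
    simulate_transient(bench_lung1(), bench_circuit(), bench_settings(25),
                       dt = 0.5),
    class = "ventrc_invalid_parameter"
  )
  err <- tryCatch(
    simulate_transient(bench_lung1(), bench_circuit(), bench_settings(25),
                       initial_state = c(100, 100), n_cycles = 1),
    condition = function(e) e
  )
  expect_s3_class(err, "ventrc_convergence_error")
  expect_true(is.numeric(err$residual) && err$residual > 0)
})

test_that("samples_per_cycle below 100 is refused", {
  expect_error(
    cyclic_steady_state(bench_lung1(), bench_circuit(), bench_settings(25),
                        samples_per_cycle = 50),
    class = "ventrc_invalid_parameter"
  )
})

test_that("cycle_solution supports tidy, glance and autoplot", {
  sol <- cyclic_steady_state(bench_lung1(), bench_circuit(),
                             bench_settings(25), samples_per_cycle = 200)
  expect_s3_class(tidy(sol), "tbl_df")
  g <- glance(sol)
  expect_equal(g$vt_L, sol$vt)
  expect_equal(g$period_s, 4)
  expect_s3_class(autoplot(sol), "ggplot")
})
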