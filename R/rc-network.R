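#' Ventilator drive pressure (ideal square wave)
#'
#' In pressure-control mode the ventilator switches the circuit driving
#' pressure between `peep + pinsp` (inspiration) and `peep` (expiration)
#' as fast as it can; the model idealises this as an instantaneous square
#' wave.  Times are folded into the breath period, so any `t >= 0` is
#' accepted.
#'
#' @param settings A [vent_settings()] object.
#' @param timing A [phase_timing()] object (defaults to
#'   `phase_timing(settings)`).
#' @param t Time(s) in seconds; vectorised.
#' @return Drive pressure(s) in cmH2O.
#' @examples
#' s <- vent_settings(25, 5, 15, 2)
#' drive_pressure(s, t = c(0.5, 2.0))  # 30 during insp, 5 during exp
#' @export
drive_pressure <- function(settings, timing = phase_timing(settings), t) {
  stopifnot(inherits(settings, "vent_settings"),
            inherits(timing, "phase_timing"))
  tm <- t %% timing$period
  ifelse(tm < timing$t_insp, settings$peep + settings$pinsp, settings$peep)
}

# Internal: the affine state-space system for one breath phase -----------
#
# Two-state form (c_v > 0, series resistance Rs > 0), x = (p_tube, p_lung):
#   c_v dp_tube/dt = (P - p_tube)/Rs - (p_tube - p_lung)/r
#   c   dp_lung/dt = (p_tube - p_lung)/r
# One-state form (c_v = 0, or Rs = 0 which pins p_tube to the drive):
#   (Rs + r) c dp_lung/dt = P - p_lung
# Both have equilibrium p_tube = p_lung = P for constant drive P.
phase_system <- function(lung, circuit, phase = c("insp", "exp")) {
  phase <- match.arg(phase)
  lp <- phase_lung(lung, phase)
  rs <- phase_series_resistance(circuit, phase)
  cv <- circuit$c_v
  if (cv > 0 && rs > 0) {
    if (lp$r <= 0) {
      stop_ventrc(
        "Patient resistance must be > 0 when tubing compliance is present.",
        "ventrc_ill_posed"
      )
    }
    a <- rbind(
      c(-(1 / rs + 1 / lp$r) / cv, 1 / (lp$r * cv)),
      c(1 / (lp$r * lp$c), -1 / (lp$r * lp$c))
    )
    lam <- eigen(a, only.values = TRUE)$values
    sys <- list(n = 2L, a = a, b_unit = c(1 / (rs * cv), 0),
                time_constants = sort(-1 / Re(lam)))
  } else {
    if (rs + lp$r <= 0) {
      stop_ventrc(
        "Ill-posed phase: series resistance and patient resistance are both zero.",
        "ventrc_ill_posed"
      )
    }
    tau <- (rs + lp$r) * lp$c
    sys <- list(n = 1L, a = matrix(-1 / tau), b_unit = 1 / tau,
                time_constants = tau)
  }
  c(sys, list(phase = phase, r_series = rs, r_patient = lp$r,
              c_patient = lp$c, c_tube = cv))
}

#' Affine phase dynamics of the RC network
#'
#' Returns the constant-coefficient affine system `dx/dt = A x + b_unit * P`
#' governing one breath phase, where `P` is the (constant) drive pressure
#' for that phase.  With tubing compliance `c_v > 0` the state is
#' `x = (p_tube, p_lung)`; with `c_v = 0` (or zero series resistance,
#' which pins the tubing node to the drive) the network collapses to the
#' single state `p_lung` with time constant `(Rs + r) c`.  The phase
#' equilibrium is `p_tube = p_lung = P` in either case.
#'
#' @param lung A [lung_params()] object.
#' @param circuit A [circuit_params()] object.
#' @param phase `"insp"` or `"exp"`; selects the per-phase series
#'   resistance (tubing plus that phase's restrictor) and any per-phase
#'   lung parameter overrides.
#' @return An object of class `phase_dynamics`: a list with `a` (state
#'   matrix), `b_unit` (input vector multiplying the drive pressure),
#'   `n` (number of states), `time_constants` (seconds, ascending),
#'   `r_series`, `r_patient`, `c_patient`, `c_tube` and `phase`.
#' @examples
#' pd <- phase_dynamics(lung_params(12, 0.040),
#'                      circuit_params(22, 0.004), "insp")
#' pd$time_constants  # fast tubing mode, slow lung mode
#' @export
phase_dynamics <- function(lung, circuit, phase = c("insp", "exp")) {
  stopifnot(inherits(lung, "lung_params"), inherits(circuit, "circuit_params"))
  sys <- phase_system(lung, circuit, match.arg(phase))
  structure(sys, class = "phase_dynamics")
}

#' @export
print.phase_dynamics <- function(x, ...) {
  cat(sprintf(
    "<phase_dynamics> %s phase, %d state(s), time constant(s): %s s\n",
    x$phase, x$n, paste(signif(x$time_constants, 4), collapse = ", ")
  ))
  invisible(x)
}

# Internal: matrix exponential of the phase state matrix over time t.
# The 2x2 RC state matrices have real, almost always distinct
# eigenvalues, for which the eigendecomposition route is exact to
# machine precision; a scaled Taylor series covers the (near-)defective
# corner case.
phase_propagator <- function(sys, t) {
  if (sys$n == 1L) {
    return(matrix(exp(sys$a[1L] * t)))
  }
  m <- sys$a * t
  ev <- eigen(m)
  gap <- abs(ev$values[1] - ev$values[2])
  if (gap > 1e-7 * max(1, abs(ev$values[1]))) {
    return(Re(ev$vectors %*% diag(exp(ev$values)) %*% solve(ev$vectors)))
  }
  s <- max(0L, as.integer(ceiling(log2(max(1, norm(m, "F"))))) + 4L)
  ms <- m / 2^s
  out <- diag(2)
  term <- diag(2)
  for (k in 1:16) {
    term <- term %*% ms / k
    out <- out + term
  }
  for (k in seq_len(s)) out <- out %*% out
  out
}

# Internal: state at elapsed time t within a phase, from start state x0
# under constant drive P.  x(t) = x_eq + expm(A t) (x0 - x_eq).
phase_state <- function(sys, x0, p_drive, t) {
  xeq <- rep(p_drive, sys$n)
  as.vector(xeq + phase_propagator(sys, t) %*% (x0 - xeq))
}

# Internal: derived channels from a matrix of states (rows = times).
phase_channels <- function(sys, states, p_drive) {
  if (sys$n == 1L) {
    p_lung <- states[, 1L]
    q <- (p_drive - p_lung) / (sys$r_series + sys$r_patient)
    tibble::tibble(
      p_tube_cmH2O = p_drive - sys$r_series * q,
      p_lung_cmH2O = p_lung,
      q_patient_Lps = q,
      q_vent_Lps = q
    )
  } else {
    tibble::tibble(
      p_tube_cmH2O = states[, 1L],
      p_lung_cmH2O = states[, 2L],
      q_patient_Lps = (states[, 1L] - states[, 2L]) / sys$r_patient,
      q_vent_Lps = (p_drive - states[, 1L]) / sys$r_series
    )
  }
}

# Internal: sample one phase on a uniform grid by recursive exact
# propagation (one matrix exponential per phase).  Returns states at
# k * t_len / n_steps for k = 0..n_steps as a (n_steps + 1) x n matrix.
phase_grid_states <- function(sys, x0, p_drive, t_len, n_steps) {
  e_dt <- phase_propagator(sys, t_len / n_steps)
  xeq <- rep(p_drive, sys$n)
  out <- matrix(NA_real_, n_steps + 1L, sys$n)
  x <- x0
  out[1L, ] <- x
  for (k in seq_len(n_steps)) {
    x <- as.vector(xeq + e_dt %*% (x - xeq))
    out[k + 1L, ] <- x
  }
  out
}

# Internal: lung-pressure extrema within a phase.  Interior extrema occur
# where patient flow crosses zero (only possible in the two-state system,
# just after a switch while the tubing node is on the far side of the
# lung pressure); they are located by bisection on the exact trajectory.
phase_lung_extrema <- function(sys, x0, p_drive, t_len, grid_times, states) {
  p_lung <- states[, sys$n]
  vals <- c(p_lung[1L], p_lung[length(p_lung)])
  if (sys$n == 2L) {
    q <- (states[, 1L] - states[, 2L]) / sys$r_patient
    sgn <- sign(q)
    flips <- which(sgn[-length(sgn)] * sgn[-1L] < 0)
    q_at <- function(t) {
      x <- phase_state(sys, x0, p_drive, t)
      (x[1L] - x[2L]) / sys$r_patient
    }
    for (i in flips) {
      root <- uniroot(q_at, lower = grid_times[i], upper = grid_times[i + 1L],
                      tol = 1e-12)$root
      vals <- c(vals, phase_state(sys, x0, p_drive, root)[2L])
    }
  }
  vals
}

#' Exact cyclic steady state of the ventilated RC network
#'
#' Solves the two-phase switched affine system for its unique periodic
#' (breath-to-breath repeating) solution: the state is propagated through
#' each phase with a matrix exponential, and the cyclic boundary condition
#' `x(0) = x(period)` is solved as a linear fixed point.  No time-marching
#' is involved.
#'
#' Tidal volume is the inspiratory-phase compliance times the peak-to-peak
#' lung pressure over the cycle.  The lung-pressure extrema are refined
#' beyond the sampling grid by root-finding on the patient flow (the lung
#' keeps filling briefly after the switch to expiration while the tubing
#' node pressure still exceeds the lung pressure).
#'
#' @param lung A [lung_params()] object.
#' @param circuit A [circuit_params()] object.
#' @param settings A [vent_settings()] object.
#' @param samples_per_cycle Number of waveform samples over one period
#'   (>= 100; default 1000).
#' @return An object of class `cycle_solution` with components:
#'   `waveforms` (a tibble with columns `time_s`, `phase`,
#'   `p_vent_cmH2O`, `p_tube_cmH2O`, `p_lung_cmH2O`, `q_patient_Lps`,
#'   `q_vent_Lps`; first and last rows are one period apart and carry the
#'   same state), `vt` (tidal volume, L), `vt_flow_integral` (trapezoidal
#'   integral of positive patient flow, L, for cross-checking), `x0`
#'   (cycle-start state), `p_lung_range`, and the input parameter objects.
#' @examples
#' sol <- cyclic_steady_state(
#'   lung_params(12, 0.040), circuit_params(22, 0.004),
#'   vent_settings(25, 5, 15, 2)
#' )
#' sol$vt
#' @export
cyclic_steady_state <- function(lung, circuit, settings,
                                samples_per_cycle = 1000) {
  stopifnot(inherits(lung, "lung_params"),
            inherits(circuit, "circuit_params"),
            inherits(settings, "vent_settings"))
  if (!is.numeric(samples_per_cycle) || samples_per_cycle < 100) {
    stop_ventrc("`samples_per_cycle` must be at least 100.",
                "ventrc_invalid_parameter")
  }
  samples_per_cycle <- as.integer(samples_per_cycle)

  timing <- phase_timing(settings)
  sys_i <- phase_system(lung, circuit, "insp")
  sys_e <- phase_system(lung, circuit, "exp")
  if (sys_i$n != sys_e$n) {
    # Can only differ if a phase-dependent restrictor drives Rs to zero
    # with c_v > 0 in one phase; not a physically meaningful circuit.
    stop_ventrc("Phases reduce to different state dimensions.",
                "ventrc_ill_posed")
  }
  n <- sys_i$n
  p_i <- settings$peep + settings$pinsp
  p_e <- settings$peep

  e_i <- phase_propagator(sys_i, timing$t_insp)
  e_e <- phase_propagator(sys_e, timing$t_exp)
  xeq_i <- rep(p_i, n)
  xeq_e <- rep(p_e, n)

  # x(0) = xeq_e + Ee (xeq_i + Ei (x0 - xeq_i) - xeq_e)
  m_cycle <- e_e %*% e_i
  rhs <- xeq_e + as.vector(e_e %*% (xeq_i - e_i %*% xeq_i - xeq_e))
  x0 <- tryCatch(
    as.vector(solve(diag(n) - m_cycle, rhs)),
    error = function(e) {
      stop_ventrc("Singular cycle map; cannot solve for the periodic state.",
                  "ventrc_numerical_error", parent = e)
    }
  )

  n_i <- max(2L, as.integer(round(samples_per_cycle * timing$t_insp /
                                    timing$period)))
  n_e <- max(2L, samples_per_cycle - n_i)

  st_i <- phase_grid_states(sys_i, x0, p_i, timing$t_insp, n_i)
  x_switch <- st_i[n_i + 1L, ]
  st_e <- phase_grid_states(sys_e, x_switch, p_e, timing$t_exp, n_e)

  t_i <- seq(0, timing$t_insp, length.out = n_i + 1L)
  t_e <- timing$t_insp + seq(0, timing$t_exp, length.out = n_e + 1L)

  wf_i <- phase_channels(sys_i, st_i[seq_len(n_i), , drop = FALSE], p_i)
  wf_e <- phase_channels(sys_e, st_e, p_e)
  waveforms <- dplyr::bind_rows(
    dplyr::mutate(wf_i, time_s = t_i[seq_len(n_i)], phase = "insp",
                  p_vent_cmH2O = p_i, .before = 1),
    dplyr::mutate(wf_e, time_s = t_e, phase = "exp",
                  p_vent_cmH2O = p_e, .before = 1)
  )
  waveforms <- waveforms[, c("time_s", "phase", "p_vent_cmH2O",
                             "p_tube_cmH2O", "p_lung_cmH2O",
                             "q_patient_Lps", "q_vent_Lps")]

  pl_ext <- c(
    phase_lung_extrema(sys_i, x0, p_i, timing$t_insp, t_i, st_i),
    phase_lung_extrema(sys_e, x_switch, p_e, timing$t_exp, t_e - timing$t_insp,
                       st_e)
  )
  p_lung_range <- range(pl_ext)
  vt <- max(0, sys_i$c_patient * diff(p_lung_range))

  q <- waveforms$q_patient_Lps
  vt_flow <- pracma::trapz(waveforms$time_s, pmax(q, 0))

  structure(
    list(
      waveforms = waveforms, vt = vt, vt_flow_integral = vt_flow,
      x0 = x0, p_lung_range = p_lung_range, timing = timing,
      settings = settings, lung = lung, circuit = circuit,
      samples_per_cycle = samples_per_cycle
    ),
    class = "cycle_solution"
  )
}

#' @export
print.cycle_solution <- function(x, ...) {
  cat(sprintf(
    paste0("<cycle_solution> VT %.4f L; lung pressure %.2f-%.2f cmH2O; ",
           "period %.3g s (%d samples)\n"),
    x$vt, x$p_lung_range[1], x$p_lung_range[2], x$timing$period,
    x$samples_per_cycle
  ))
  invisible(x)
}

#' @rdname cyclic_steady_state
#' @param x A `cycle_solution`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cycle_solution <- function(x, ...) x$waveforms

#' @rdname cyclic_steady_state
#' @exportS3Method generics::glance
glance.cycle_solution <- function(x, ...) {
  tibble::tibble(
    vt_L = x$vt,
    p_lung_min_cmH2O = x$p_lung_range[1],
    p_lung_max_cmH2O = x$p_lung_range[2],
    period_s = x$timing$period,
    t_insp_s = x$timing$t_insp,
    samples_per_cycle = x$samples_per_cycle
  )
}

#' Closed-form tidal volume of the single-compliance network
#'
#' Analytic tidal volume of the first-order limit (no tubing compliance):
#' the lung charges towards `peep + pinsp` with time constant
#' `tau_i = (Rs_insp + r) c` and discharges towards `peep` with
#' `tau_e = (Rs_exp + r) c`.  The periodic peak-to-peak lung pressure is
#' `pinsp (1 - ei)(1 - ee) / (1 - ei ee)` with `ei = exp(-t_insp/tau_i)`,
#' `ee = exp(-t_exp/tau_e)`, and tidal volume is that times `c`.  Used as
#' an analytic cross-check of [cyclic_steady_state()] in the `c_v = 0`
#' limit.
#'
#' @param lung A [lung_params()] object.
#' @param series_resistance_insp,series_resistance_exp Series resistance
#'   outside the patient for each phase, cmH2O/(L/s).
#' @param settings A [vent_settings()] object.
#' @return Tidal volume in litres.
#' @examples
#' first_order_vt(lung_params(12, 0.040), 22, 22, vent_settings(25, 5, 15, 2))
#' @export
first_order_vt <- function(lung, series_resistance_insp,
                           series_resistance_exp, settings) {
  stopifnot(inherits(lung, "lung_params"), inherits(settings, "vent_settings"))
  rs_i <- check_number(series_resistance_insp, "series_resistance_insp",
                       lower = 0)
  rs_e <- check_number(series_resistance_exp, "series_resistance_exp",
                       lower = 0)
  timing <- phase_timing(settings)
  li <- phase_lung(lung, "insp")
  le <- phase_lung(lung, "exp")
  ei <- exp(-timing$t_insp / ((rs_i + li$r) * li$c))
  ee <- exp(-timing$t_exp / ((rs_e + le$r) * le$c))
  settings$pinsp * li$c * (1 - ei) * (1 - ee) / (1 - ei * ee)
}
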