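# Time-marching oracle for the switched RC network.
#
# Classical fixed-step RK4.  For a constant-coefficient affine system the
# RK4 update x -> x + h/6 (k1 + 2 k2 + 2 k3 + k4) is itself an affine map
# of the state, so the per-step map is obtained by running the RK4 stage
# arithmetic on the origin and on each basis vector, and then applied
# step by step.  This is numerically identical to naive stepping but lets
# the periodic-convergence loop run at matrix-map cost, and it shares no
# code with the matrix-exponential route in cyclic_steady_state().
rk4_affine_map <- function(a, b, h) {
  f <- function(x) as.vector(a %*% x) + b
  step1 <- function(x) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n <- nrow(a)
  m0 <- step1(numeric(n))
  cols <- vapply(seq_len(n), function(j) {
    e <- numeric(n)
    e[j] <- 1
    step1(e) - m0
  }, numeric(n))
  list(m = matrix(cols, n, n), v = m0)
}

# Compose an affine map (m, v) with itself n_steps times.
compose_affine <- function(map, n_steps) {
  n <- nrow(map$m)
  acc_m <- diag(n)
  acc_v <- numeric(n)
  for (k in seq_len(n_steps)) {
    acc_v <- as.vector(map$m %*% acc_v) + map$v
    acc_m <- map$m %*% acc_m
  }
  list(m = acc_m, v = acc_v)
}

#' Time-marching simulation of the switched RC network
#'
#' Fixed-step fourth-order Runge-Kutta integration of the two-phase
#' switched system from an arbitrary initial state, used as an
#' independent numerical oracle for [cyclic_steady_state()].  Steps are
#' aligned to the phase switching times (the step length is shortened
#' within each phase so that an integer number of steps spans it).  The
#' breath-to-breath change of the cycle-start state is monitored; once it
#' falls below `tol` the solution is taken as periodic and the final
#' cycle is traced out.
#'
#' @inheritParams cyclic_steady_state
#' @param initial_state Starting state (length 1 or 2 depending on the
#'   network order; see [phase_dynamics()]).  Default: all states at
#'   `peep`.
#' @param n_cycles Maximum number of breath cycles to integrate.
#' @param dt Requested integration step, seconds.  Must not exceed one
#'   tenth of the fastest phase time constant (accuracy/stability guard).
#' @param tol Convergence tolerance on the per-cycle change of the
#'   cycle-start state, cmH2O.
#' @return An object of class `transient_solution`: a list with
#'   `waveforms` (final-cycle tibble with the same channel columns as
#'   [cyclic_steady_state()]), `vt` (final-cycle tidal volume, L),
#'   `x_cycle_start`, `residuals` (per-cycle state change, cmH2O),
#'   `cycles_run`, and `converged`.
#' @examples
#' tr <- simulate_transient(
#'   lung_params(12, 0.040), circuit_params(22, 0.004),
#'   vent_settings(25, 5, 15, 2), n_cycles = 20
#' )
#' tr$vt
#' @export
simulate_transient <- function(lung, circuit, settings, initial_state = NULL,
                               n_cycles = 40, dt = 1e-3, tol = 1e-9) {
  stopifnot(inherits(lung, "lung_params"),
            inherits(circuit, "circuit_params"),
            inherits(settings, "vent_settings"))
  timing <- phase_timing(settings)
  sys_i <- phase_system(lung, circuit, "insp")
  sys_e <- phase_system(lung, circuit, "exp")
  if (sys_i$n != sys_e$n) {
    stop_ventrc("Phases reduce to different state dimensions.",
                "ventrc_ill_posed")
  }
  n <- sys_i$n

  tau_fast <- min(sys_i$time_constants, sys_e$time_constants)
  if (dt > tau_fast / 10) {
    stop_ventrc(sprintf(
      "`dt` = %g s is too large: it must be at most a tenth of the fastest phase time constant (%g s).",
      dt, tau_fast
    ), "ventrc_invalid_parameter")
  }

  x0 <- if (is.null(initial_state)) rep(settings$peep, n) else {
    stopifnot(is.numeric(initial_state), length(initial_state) == n)
    as.double(initial_state)
  }

  p_i <- settings$peep + settings$pinsp
  p_e <- settings$peep
  steps_i <- max(1L, as.integer(ceiling(timing$t_insp / dt)))
  steps_e <- max(1L, as.integer(ceiling(timing$t_exp / dt)))
  h_i <- timing$t_insp / steps_i
  h_e <- timing$t_exp / steps_e

  step_i <- rk4_affine_map(sys_i$a, sys_i$b_unit * p_i, h_i)
  step_e <- rk4_affine_map(sys_e$a, sys_e$b_unit * p_e, h_e)
  map_i <- compose_affine(step_i, steps_i)
  map_e <- compose_affine(step_e, steps_e)
  cyc_m <- map_e$m %*% map_i$m
  cyc_v <- as.vector(map_e$m %*% map_i$v) + map_e$v

  x <- x0
  residuals <- numeric(0)
  converged <- FALSE
  for (k in seq_len(n_cycles)) {
    x_new <- as.vector(cyc_m %*% x) + cyc_v
    residuals[k] <- max(abs(x_new - x))
    x <- x_new
    if (residuals[k] <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_ventrc(sprintf(
      "Cycle-to-cycle state change still %.3g cmH2O after %d cycles (tolerance %g).",
      residuals[length(residuals)], n_cycles, tol
    ), "ventrc_convergence_error", residual = residuals[length(residuals)])
  }

  # Trace the final (periodic) cycle step by step.
  trace_phase <- function(map_step, x_start, n_steps) {
    out <- matrix(NA_real_, n_steps + 1L, n)
    out[1L, ] <- x_start
    xx <- x_start
    for (k in seq_len(n_steps)) {
      xx <- as.vector(map_step$m %*% xx) + map_step$v
      out[k + 1L, ] <- xx
    }
    out
  }
  st_i <- trace_phase(step_i, x, steps_i)
  st_e <- trace_phase(step_e, st_i[steps_i + 1L, ], steps_e)

  t_i <- seq(0, timing$t_insp, length.out = steps_i + 1L)
  t_e <- timing$t_insp + seq(0, timing$t_exp, length.out = steps_e + 1L)
  wf_i <- phase_channels(sys_i, st_i[seq_len(steps_i), , drop = FALSE], p_i)
  wf_e <- phase_channels(sys_e, st_e, p_e)
  waveforms <- dplyr::bind_rows(
    dplyr::mutate(wf_i, time_s = t_i[seq_len(steps_i)], phase = "insp",
                  p_vent_cmH2O = p_i, .before = 1),
    dplyr::mutate(wf_e, time_s = t_e, phase = "exp",
                  p_vent_cmH2O = p_e, .before = 1)
  )
  waveforms <- waveforms[, c("time_s", "phase", "p_vent_cmH2O",
                             "p_tube_cmH2O", "p_lung_cmH2O",
                             "q_patient_Lps", "q_vent_Lps")]

  vt <- max(0, sys_i$c_patient * diff(range(waveforms$p_lung_cmH2O)))

  structure(
    list(
      waveforms = waveforms, vt = vt, x_cycle_start = x,
      residuals = residuals, cycles_run = length(residuals),
      converged = converged, dt = dt, h = c(insp = h_i, exp = h_e)
    ),
    class = "transient_solution"
  )
}

#' @export
print.transient_solution <- function(x, ...) {
  cat(sprintf(
    "<transient_solution> VT %.4f L after %d cycle(s); final residual %.2g cmH2O\n",
    x$vt, x$cycles_run, x$residuals[length(x$residuals)]
  ))
  invisible(x)
}
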