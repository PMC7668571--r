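#' Ventilator control-panel settings
#'
#' Bundles the four settings exposed by a ventilator in pressure-control
#' mode.  In this mode the machine drives the circuit pressure as a square
#' wave: `peep + pinsp` during inspiration, `peep` during expiration, with
#' transitions as fast as the machine allows.
#'
#' @param pinsp Inspiratory pressure **in excess of PEEP** (cmH2O, >= 0).
#' @param peep Positive end-expiratory pressure (cmH2O, >= 0).
#' @param rr Respiratory rate (breaths per minute, > 0).
#' @param ie_e Expiratory side of the I:E ratio expressed as `1:E`; e.g.
#'   `ie_e = 2` means I:E = 1:2.  Must be > 0.
#'
#' @return An object of class `vent_settings`.
#' @examples
#' vent_settings(pinsp = 25, peep = 5, rr = 15, ie_e = 2)
#' @export
vent_settings <- function(pinsp, peep = 5, rr = 15, ie_e = 2) {
  out <- list(
    pinsp = check_number(pinsp, "pinsp", lower = 0),
    peep = check_number(peep, "peep", lower = 0),
    rr = check_number(rr, "rr", lower = 0, allow_zero_lower = FALSE),
    ie_e = check_number(ie_e, "ie_e", lower = 0, allow_zero_lower = FALSE)
  )
  structure(out, class = "vent_settings")
}

#' @export
print.vent_settings <- function(x, ...) {
  cat(sprintf(
    "<vent_settings> Pinsp %g + PEEP %g cmH2O, RR %g /min, I:E 1:%g\n",
    x$pinsp, x$peep, x$rr, x$ie_e
  ))
  invisible(x)
}

#' Breath phase timing derived from ventilator settings
#'
#' Splits the breath period `60 / rr` into inspiration and expiration
#' according to the I:E ratio `1:E`.
#'
#' @param settings A [vent_settings()] object.
#' @return An object of class `phase_timing` with fields `t_insp`, `t_exp`
#'   and `period`, all in seconds.
#' @examples
#' phase_timing(vent_settings(25, 5, rr = 15, ie_e = 2))
#' @export
phase_timing <- function(settings) {
  stopifnot(inherits(settings, "vent_settings"))
  period <- 60 / settings$rr
  t_insp <- period / (1 + settings$ie_e)
  structure(
    list(t_insp = t_insp, t_exp = period - t_insp, period = period),
    class = "phase_timing"
  )
}

#' @export
print.phase_timing <- function(x, ...) {
  cat(sprintf(
    "<phase_timing> period %.4g s (insp %.4g s, exp %.4g s)\n",
    x$period, x$t_insp, x$t_exp
  ))
  invisible(x)
}

#' Patient airway resistance and lung compliance
#'
#' Linear single-compartment description of a patient: airway resistance
#' `r` and lung compliance `c`.  Either may differ between breath phases
#' via the `*_insp` / `*_exp` overrides (a ventilated patient can present
#' different impedance during filling and emptying).
#'
#' @param r Airway resistance, cmH2O/(L/s), >= 0.
#' @param c Lung compliance, L/cmH2O, > 0.
#' @param r_insp,r_exp Optional per-phase resistance overrides.
#' @param c_insp,c_exp Optional per-phase compliance overrides.
#' @return An object of class `lung_params`.
#' @examples
#' lung_params(r = 12, c = 0.040)
#' @export
lung_params <- function(r, c, r_insp = NULL, r_exp = NULL,
                        c_insp = NULL, c_exp = NULL) {
  r <- check_number(r, "r", lower = 0)
  c <- check_number(c, "c", lower = 0, allow_zero_lower = FALSE)
  opt <- function(x, name, strict = FALSE) {
    if (is.null(x)) NULL else check_number(x, name, lower = 0,
                                           allow_zero_lower = !strict)
  }
  structure(
    list(
      r = r, c = c,
      r_insp = opt(r_insp, "r_insp"), r_exp = opt(r_exp, "r_exp"),
      c_insp = opt(c_insp, "c_insp", strict = TRUE),
      c_exp = opt(c_exp, "c_exp", strict = TRUE)
    ),
    class = "lung_params"
  )
}

#' @export
print.lung_params <- function(x, ...) {
  cat(sprintf("<lung_params> R %g cmH2O/(L/s), C %g L/cmH2O\n", x$r, x$c))
  invisible(x)
}

#' Ventilator tubing and restrictor parameters
#'
#' Lumped description of everything between the ventilator and the patient
#' airway: series tubing resistance `r_v`, tubing compliance `c_v` (gas
#' stored by tube distension and compression), and any deliberately added
#' flow-restrictor resistance, which may act in one phase only.  A
#' restrictor placed in the inspiratory limb of a circle system (the usual
#' arrangement for dual-patient ventilation) is only in the flow path
#' during inspiration, so `r_restrictor_exp` defaults to 0.
#'
#' `c_v = 0` selects the single-compliance limit in which the network
#' collapses to one state (patient compliance behind the total series
#' resistance).
#'
#' @param r_v Tubing resistance, cmH2O/(L/s), >= 0.
#' @param c_v Tubing compliance, L/cmH2O, >= 0.
#' @param r_restrictor_insp Added inspiratory restrictor resistance,
#'   cmH2O/(L/s), >= 0.
#' @param r_restrictor_exp Added expiratory restrictor resistance,
#'   cmH2O/(L/s), >= 0.
#' @return An object of class `circuit_params`.
#' @examples
#' circuit_params(r_v = 22, c_v = 0.004)
#' circuit_params(r_v = 22, c_v = 0.004, r_restrictor_insp = 12)
#' @export
circuit_params <- function(r_v, c_v, r_restrictor_insp = 0,
                           r_restrictor_exp = 0) {
  structure(
    list(
      r_v = check_number(r_v, "r_v", lower = 0),
      c_v = check_number(c_v, "c_v", lower = 0),
      r_restrictor_insp = check_number(r_restrictor_insp,
                                       "r_restrictor_insp", lower = 0),
      r_restrictor_exp = check_number(r_restrictor_exp,
                                      "r_restrictor_exp", lower = 0)
    ),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(
    "<circuit_params> Rv %g, Cv %g; restrictor insp %g / exp %g\n",
    x$r_v, x$c_v, x$r_restrictor_insp, x$r_restrictor_exp
  ))
  invisible(x)
}

# Per-phase effective parameter resolution -------------------------------

phase_lung <- function(lung, phase) {
  if (phase == "insp") {
    list(r = lung$r_insp %||% lung$r, c = lung$c_insp %||% lung$c)
  } else {
    list(r = lung$r_exp %||% lung$r, c = lung$c_exp %||% lung$c)
  }
}

phase_series_resistance <- function(circuit, phase) {
  circuit$r_v +
    if (phase == "insp") circuit$r_restrictor_insp else circuit$r_restrictor_exp
}
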