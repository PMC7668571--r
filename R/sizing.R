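#' Tidal volume as a function of added inspiratory restriction
#'
#' Evaluates the cyclic steady state at each candidate inspiratory
#' restrictor resistance.  The typical dual-patient use case: the shared
#' ventilator must run at a higher driving pressure than one of the
#' patients needs, and an inspiratory restrictor brings that patient's
#' tidal volume back down.  Tidal volume is non-increasing in the added
#' resistance.
#'
#' Any restrictor already present in `circuit` is replaced by the grid
#' value (the grid is the total added inspiratory restriction).
#'
#' @param lung A [lung_params()] object.
#' @param circuit A [circuit_params()] object.
#' @param settings A [vent_settings()] object.
#' @param r_grid Numeric vector of candidate restrictor resistances,
#'   cmH2O/(L/s), all >= 0.
#' @param samples_per_cycle Passed to [cyclic_steady_state()].
#' @return A tibble (class `vt_curve`) with columns `r_restrictor` and
#'   `vt_L`.
#' @examples
#' vt_vs_restriction(
#'   lung_params(12, 0.040), circuit_params(22, 0.004),
#'   vent_settings(25, 5, 15, 2), r_grid = c(0, 12, 33)
#' )
#' @export
vt_vs_restriction <- function(lung, circuit, settings, r_grid,
                              samples_per_cycle = 1000) {
  stopifnot(is.numeric(r_grid), length(r_grid) >= 1, all(is.finite(r_grid)))
  if (any(r_grid < 0)) {
    stop_ventrc("Restrictor resistances must be >= 0.",
                "ventrc_invalid_parameter")
  }
  vt <- vapply(r_grid, function(r) {
    circ <- circuit_params(circuit$r_v, circuit$c_v,
                           r_restrictor_insp = r,
                           r_restrictor_exp = circuit$r_restrictor_exp)
    cyclic_steady_state(lung, circ, settings, samples_per_cycle)$vt
  }, numeric(1))
  out <- tibble::tibble(r_restrictor = as.double(r_grid), vt_L = vt)
  class(out) <- c("vt_curve", class(out))
  out
}

#' Inspiratory restrictor resistance required for a target tidal volume
#'
#' Inverts the monotone map from added inspiratory restriction to tidal
#' volume by bisection.  The bracket starts at `[0, 50]` cmH2O/(L/s) and
#' its upper end is doubled until it straddles the target (up to
#' `r_max`).  Restriction can only reduce tidal volume, so a target above
#' the unrestricted volume is reported as infeasible rather than clamped.
#'
#' @inheritParams vt_vs_restriction
#' @param target_vt Target tidal volume, L (> 0).
#' @param tolerance Convergence tolerance on tidal volume, L.  The
#'   tolerance is expressed in litres because the clinically meaningful
#'   quantity is the delivered volume, not the resistance.
#' @param r_max Cap on the bracket expansion, cmH2O/(L/s).
#' @return An object of class `sizing_result` with fields `r_restrictor`,
#'   `achieved_vt`, `target_vt`, `unrestricted_vt`, `iterations` and
#'   `bracket` (the initial bracketing interval).
#' @examples
#' fit <- required_restriction(
#'   0.45, lung_params(12, 0.040), circuit_params(22, 0.004),
#'   vent_settings(25, 5, 15, 2)
#' )
#' fit$r_restrictor
#' @export
required_restriction <- function(target_vt, lung, circuit, settings,
                                 tolerance = 1e-4, r_max = 1000,
                                 samples_per_cycle = 1000) {
  target_vt <- check_number(target_vt, "target_vt", lower = 0,
                            allow_zero_lower = FALSE)
  tolerance <- check_number(tolerance, "tolerance", lower = 0,
                            allow_zero_lower = FALSE)

  vt_at <- function(r) {
    circ <- circuit_params(circuit$r_v, circuit$c_v,
                           r_restrictor_insp = r,
                           r_restrictor_exp = circuit$r_restrictor_exp)
    cyclic_steady_state(lung, circ, settings, samples_per_cycle)$vt
  }

  vt0 <- vt_at(0)
  iterations <- 0L
  if (target_vt > vt0 + tolerance) {
    stop_ventrc(sprintf(
      "Target tidal volume %.4f L exceeds the unrestricted tidal volume %.4f L; added restriction can only reduce volume.",
      target_vt, vt0
    ), "ventrc_infeasible_target", unrestricted_vt = vt0)
  }
  if (abs(vt0 - target_vt) <= tolerance) {
    result <- list(r_restrictor = 0, achieved_vt = vt0,
                   target_vt = target_vt, unrestricted_vt = vt0,
                   iterations = iterations, bracket = c(0, 0))
    return(structure(result, class = "sizing_result"))
  }

  lo <- 0
  hi <- 50
  vt_hi <- vt_at(hi)
  iterations <- iterations + 1L
  while (vt_hi > target_vt && hi < r_max) {
    lo <- hi
    hi <- min(2 * hi, r_max)
    vt_hi <- vt_at(hi)
    iterations <- iterations + 1L
  }
  if (vt_hi > target_vt) {
    stop_ventrc(sprintf(
      "Target tidal volume %.4f L not reachable with restriction up to %g cmH2O/(L/s) (volume there is %.4f L).",
      target_vt, r_max, vt_hi
    ), "ventrc_bracket_exhausted", r_max = r_max, vt_at_cap = vt_hi)
  }
  bracket <- c(lo, hi)

  r_mid <- NA_real_
  vt_mid <- NA_real_
  for (k in seq_len(200L)) {
    r_mid <- (lo + hi) / 2
    vt_mid <- vt_at(r_mid)
    iterations <- iterations + 1L
    if (abs(vt_mid - target_vt) <= tolerance) break
    if (vt_mid > target_vt) lo <- r_mid else hi <- r_mid
  }
  if (abs(vt_mid - target_vt) > tolerance) {
    stop_ventrc("Bisection failed to meet the volume tolerance.",
                "ventrc_convergence_error")
  }

  structure(
    list(r_restrictor = r_mid, achieved_vt = vt_mid, target_vt = target_vt,
         unrestricted_vt = vt0, iterations = iterations, bracket = bracket),
    class = "sizing_result"
  )
}

#' @export
print.sizing_result <- function(x, ...) {
  cat(sprintf(
    paste0("<sizing_result> restrictor %.2f cmH2O/(L/s) -> VT %.4f L ",
           "(target %.4f L; unrestricted %.4f L; %d solver calls)\n"),
    x$r_restrictor, x$achieved_vt, x$target_vt, x$unrestricted_vt,
    x$iterations
  ))
  invisible(x)
}

#' @rdname required_restriction
#' @param x A `sizing_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sizing_result <- function(x, ...) {
  tibble::tibble(
    r_restrictor = x$r_restrictor,
    achieved_vt_L = x$achieved_vt,
    target_vt_L = x$target_vt,
    unrestricted_vt_L = x$unrestricted_vt
  )
}

#' @rdname required_restriction
#' @exportS3Method generics::glance
glance.sizing_result <- function(x, ...) {
  tibble::tibble(
    r_restrictor = x$r_restrictor,
    achieved_vt_L = x$achieved_vt,
    target_vt_L = x$target_vt,
    unrestricted_vt_L = x$unrestricted_vt,
    vt_error_L = x$achieved_vt - x$target_vt,
    iterations = x$iterations,
    bracket_lo = x$bracket[1],
    bracket_hi = x$bracket[2]
  )
}
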