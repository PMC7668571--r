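#' Benchtop validation cases for the dual-ventilation circuit
#'
#' The fixture table for the five benchtop validation tests of a shared
#' ventilator circuit driving two dissimilar test lungs, with an added
#' inspiratory restrictor on the Lung 1 branch in some tests.  Measured
#' tidal volumes (mean and standard deviation over 15 recorded breaths,
#' obtained by integrating the measured flows) are stored as constants;
#' predictions are always recomputed by [run_validation()].
#'
#' Common conditions: PEEP 5 cmH2O, RR 15 /min, I:E 1:2; tubing
#' Rv = 22 cmH2O/(L/s), Cv = 0.004 L/cmH2O; Lung 1 R = 12, C = 0.040;
#' Lung 2 R = 10, C = 0.030.  Tests 1-3 use Pinsp 25 with no restrictor,
#' a non-return valve (12 cmH2O/(L/s)) and a small orifice restrictor
#' (33 cmH2O/(L/s)) on the Lung 1 branch; tests 4-5 repeat the first two
#' at Pinsp 15.  The Lung 2 branch is never restricted.
#'
#' @return A tibble with one row per test/lung combination (10 rows):
#'   `test`, `lung`, `pinsp`, `restrictor`, `r_restrictor`, `r`, `c`,
#'   `measured_vt_L`, `measured_sd_L`.
#' @export
validation_cases <- function() {
  # Measured tidal volumes: benchtop reference values for the five
  # dual-lung validation experiments (mean over 15 breaths, with stdev).
  lung1 <- tibble::tibble(
    test = 1:5,
    lung = "Lung 1",
    pinsp = c(25, 25, 25, 15, 15),
    restrictor = c("none", "non-return valve", "small orifice restrictor",
                   "none", "non-return valve"),
    r_restrictor = c(0, 12, 33, 0, 12),
    r = 12, c = 0.040,
    measured_vt_L = c(0.554, 0.433, 0.357, 0.306, 0.245),
    measured_sd_L = c(0.001, 0.002, 0.004, 0.007, 0.005)
  )
  lung2 <- tibble::tibble(
    test = 1:5,
    lung = "Lung 2",
    pinsp = c(25, 25, 25, 15, 15),
    restrictor = "none",
    r_restrictor = 0,
    r = 10, c = 0.030,
    measured_vt_L = c(0.498, 0.515, 0.522, 0.282, 0.299),
    measured_sd_L = c(0.005, 0.004, 0.001, 0.006, 0.006)
  )
  dplyr::bind_rows(lung1, lung2)
}

#' Validate model predictions against the benchtop measurements
#'
#' Computes the cyclic-steady-state tidal volume prediction for each of
#' the ten validation cases ([validation_cases()]), the per-case
#' percentage deviation `100 (measured - predicted) / predicted`, and the
#' mean/min/max absolute deviation across all cases.  Fully
#' deterministic.
#'
#' @param cases A tibble in the format of [validation_cases()].
#' @param samples_per_cycle Passed to [cyclic_steady_state()].
#' @return A tibble of class `validation_report`: the cases plus
#'   `predicted_vt_L` and `deviation_pct`, with the summary statistics
#'   available through [glance()].
#' @examples
#' \donttest{
#' rep <- run_validation()
#' glance(rep)
#' }
#' @export
run_validation <- function(cases = validation_cases(),
                           samples_per_cycle = 1000) {
  circuit_base <- circuit_params(r_v = 22, c_v = 0.004)
  predicted <- purrr::pmap_dbl(
    cases[, c("pinsp", "r_restrictor", "r", "c")],
    function(pinsp, r_restrictor, r, c) {
      cyclic_steady_state(
        lung_params(r = r, c = c),
        circuit_params(circuit_base$r_v, circuit_base$c_v,
                       r_restrictor_insp = r_restrictor),
        vent_settings(pinsp = pinsp, peep = 5, rr = 15, ie_e = 2),
        samples_per_cycle = samples_per_cycle
      )$vt
    }
  )
  out <- dplyr::mutate(
    cases,
    predicted_vt_L = predicted,
    deviation_pct = 100 * (.data$measured_vt_L - predicted) / predicted
  )
  out <- out[, c("test", "lung", "pinsp", "restrictor", "r_restrictor",
                 "predicted_vt_L", "measured_vt_L", "measured_sd_L",
                 "deviation_pct")]
  class(out) <- c("validation_report", class(out))
  out
}

#' @rdname run_validation
#' @param x A `validation_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  dev <- abs(x$deviation_pct)
  tibble::tibble(
    mean_abs_deviation_pct = mean(dev),
    min_abs_deviation_pct = min(dev),
    max_abs_deviation_pct = max(dev),
    max_abs_error_L = max(abs(x$measured_vt_L - x$predicted_vt_L)),
    n_cases = nrow(x)
  )
}

#' @export
print.validation_report <- function(x, ...) {
  NextMethod()
  g <- glance(x)
  cat(sprintf(
    "Absolute deviation: mean %.1f%%, min %.1f%%, max %.1f%% over %d cases\n",
    g$mean_abs_deviation_pct, g$min_abs_deviation_pct,
    g$max_abs_deviation_pct, g$n_cases
  ))
  invisible(x)
}

#' Measured tidal-volume reductions due to added restriction
#'
#' For each restricted validation case, the percentage reduction of the
#' measured tidal volume relative to the unrestricted case at the same
#' Pinsp for the same lung, rounded to the nearest integer percent.
#'
#' @param cases A tibble in the format of [validation_cases()].
#' @return A tibble with `lung`, `test`, `reference_test`, `restrictor`
#'   and `reduction_pct`.
#' @examples
#' vt_reductions()
#' @export
vt_reductions <- function(cases = validation_cases()) {
  restricted <- dplyr::filter(cases, .data$r_restrictor > 0)
  purrr::pmap_dfr(
    restricted[, c("lung", "test", "pinsp", "restrictor", "measured_vt_L")],
    function(lung, test, pinsp, restrictor, measured_vt_L) {
      ref <- dplyr::filter(cases, .data$lung == !!lung,
                           .data$pinsp == !!pinsp, .data$r_restrictor == 0)
      tibble::tibble(
        lung = lung, test = test, reference_test = ref$test[1],
        restrictor = restrictor,
        reduction_pct = round(100 * (1 - measured_vt_L / ref$measured_vt_L[1]))
      )
    }
  )
}
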