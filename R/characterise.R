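#' Mean of two co-registered flowmeter readings
#'
#' Component pressure drops are measured between two flowmeters; the flow
#' through the component is taken as the arithmetic mean of the two
#' readings, which cancels first-order storage effects between the
#' meters.
#'
#' @param q_a,q_b Flow readings, L/s (vectorised, equal length).
#' @return Mean flow, L/s.
#' @examples
#' mean_flow(0.5, 0.7)
#' @export
mean_flow <- function(q_a, q_b) {
  stopifnot(is.numeric(q_a), is.numeric(q_b), length(q_a) == length(q_b))
  (q_a + q_b) / 2
}

# Internal: iteratively reweighted least squares with Tukey bi-square
# weights.  Tuning constant 4.685 (95% Gaussian efficiency), residual
# scale = median absolute residual / 0.6745.  A perfect fit (zero scale)
# short-circuits to the unweighted solution, so robust and non-robust
# fits coincide exactly on noise-free data.
irls_bisquare <- function(x, y, tuning = 4.685, maxit = 100, tol = 1e-8) {
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    stop_ventrc("Rank-deficient design: flow values do not span the model.",
                "ventrc_rank_deficient")
  }
  beta <- qr.coef(qr_x, y)
  w <- rep(1, length(y))
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    r <- y - as.vector(x %*% beta)
    s <- median(abs(r)) / 0.6745
    if (s < 1e-10 * max(1, median(abs(y)))) {
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < ncol(x)) {
      stop_ventrc("Bi-square weighting rejected too many points to fit.",
                  "ventrc_convergence_error")
    }
    fit <- stats::lm.wfit(x, y, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta_new)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged) {
    stop_ventrc(sprintf(
      "Bi-square IRLS did not converge within %d iterations.", maxit
    ), "ventrc_convergence_error")
  }
  list(beta = beta, weights = w, iterations = iter)
}

#' Robust pressure-drop versus flow characterisation of a component
#'
#' Fits the pressure drop across a circuit component (restrictor,
#' non-return valve, tube segment) as a polynomial in the mean flow:
#' `dp = k2 q^2 + k1 q + k0`.  The quadratic term represents turbulent
#' (orifice) losses and the linear term laminar losses.  Setting `k2 = 0`
#' gives the linear model, and additionally `k0 = 0` the proportional
#' model, in which `k1` is the component's resistance -- the only form
#' the dynamic network model can accommodate.
#'
#' Fitting is by iteratively reweighted least squares with Tukey
#' bi-square weights (tuning constant 4.685) for outlier rejection, or
#' ordinary least squares with `robust = FALSE`.  Samples from both
#' breath phases are pooled; expiratory (negative) flows are used as-is.
#'
#' For the no-intercept (proportional) model `r_squared` is computed
#' against the uncentred sum of squares; the centred value is also
#' reported as `r_squared_centred`.
#'
#' @param data A data frame of co-registered samples.
#' @param model `"quadratic"`, `"linear"` or `"proportional"`.
#' @param robust Use bi-square IRLS (default) or plain least squares.
#' @param flow,dp Columns of `data` holding mean flow (L/s) and pressure
#'   drop (cmH2O); tidy-evaluated, defaults `q_mean_Lps`, `dp_cmH2O`.
#' @return An object of class `restrictor_fit` with coefficients `k2`,
#'   `k1`, `k0`, goodness of fit, 95% confidence intervals from the
#'   final weighted fit, the bi-square weights, and the data with fitted
#'   values.
#' @examples
#' d <- tibble::tibble(q_mean_Lps = seq(0, 1, 0.05),
#'                     dp_cmH2O = 12 * q_mean_Lps)
#' fit_restrictor(d, "proportional")
#' @export
fit_restrictor <- function(data, model = c("quadratic", "linear",
                                           "proportional"),
                           robust = TRUE, flow = q_mean_Lps,
                           dp = dp_cmH2O) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data))
  q <- rlang::eval_tidy(rlang::enquo(flow), data)
  y <- rlang::eval_tidy(rlang::enquo(dp), data)
  if (!is.numeric(q) || !is.numeric(y) || length(q) != length(y)) {
    stop_ventrc("Flow and pressure-drop columns must be numeric and equal length.",
                "ventrc_invalid_parameter")
  }
  keep <- is.finite(q) & is.finite(y)
  q <- q[keep]
  y <- y[keep]
  n <- length(q)
  if (n < 3) {
    stop_ventrc("At least 3 samples are required.", "ventrc_invalid_parameter")
  }
  if (sd(q) == 0) {
    stop_ventrc("Degenerate design: all flow values are equal.",
                "ventrc_rank_deficient")
  }

  x <- switch(model,
    proportional = cbind(k1 = q),
    linear = cbind(k1 = q, k0 = rep(1, n)),
    quadratic = cbind(k2 = q^2, k1 = q, k0 = rep(1, n))
  )

  if (robust) {
    sol <- irls_bisquare(x, y)
  } else {
    qr_x <- qr(x)
    if (qr_x$rank < ncol(x)) {
      stop_ventrc("Rank-deficient design: flow values do not span the model.",
                  "ventrc_rank_deficient")
    }
    sol <- list(beta = qr.coef(qr_x, y), weights = rep(1, n), iterations = 0L)
  }
  beta <- sol$beta
  w <- sol$weights

  fitted <- as.vector(x %*% beta)
  res <- y - fitted
  p <- ncol(x)
  df <- n - p
  rss_w <- sum(w * res^2)
  sigma <- sqrt(rss_w / df)
  xtwx <- crossprod(x * sqrt(w))
  se <- sqrt(diag(sigma^2 * solve(xtwx)))
  tcrit <- qt(0.975, df)
  ci <- tibble::tibble(
    term = colnames(x),
    estimate = as.double(beta),
    std.error = as.double(se),
    conf.low = as.double(beta - tcrit * se),
    conf.high = as.double(beta + tcrit * se)
  )

  rss <- sum(res^2)
  r2_unc <- 1 - rss / sum(y^2)
  r2_cen <- 1 - rss / sum((y - mean(y))^2)
  r_squared <- if (model == "proportional") r2_unc else r2_cen

  coef_of <- function(term) {
    if (term %in% names(beta)) unname(beta[term]) else 0
  }

  structure(
    list(
      model_kind = model,
      k2 = coef_of("k2"), k1 = coef_of("k1"), k0 = coef_of("k0"),
      r_squared = r_squared, r_squared_centred = r2_cen,
      r_squared_uncentred = r2_unc,
      ci_95 = ci, n_samples = n, robust = robust, sigma = sigma,
      iterations = sol$iterations,
      data = tibble::tibble(q_mean_Lps = q, dp_cmH2O = y,
                            fitted = fitted, weight = w)
    ),
    class = "restrictor_fit"
  )
}

#' @export
print.restrictor_fit <- function(x, ...) {
  cat(sprintf(
    "<restrictor_fit> %s%s fit of %d samples\n  dp = %s%.4g q%s  (R^2 = %.4f)\n",
    if (x$robust) "robust " else "", x$model_kind, x$n_samples,
    if (x$model_kind == "quadratic") sprintf("%.4g q^2 + ", x$k2) else "",
    x$k1,
    if (x$model_kind != "proportional") sprintf(" + %.4g", x$k0) else "",
    x$r_squared
  ))
  invisible(x)
}

#' @rdname fit_restrictor
#' @param x A `restrictor_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.restrictor_fit <- function(x, ...) x$ci_95

#' @rdname fit_restrictor
#' @exportS3Method generics::glance
glance.restrictor_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_kind,
    r.squared = x$r_squared,
    r.squared.centred = x$r_squared_centred,
    sigma = x$sigma,
    nobs = x$n_samples,
    iterations = x$iterations,
    robust = x$robust
  )
}

# Internal: indices at which a signal crosses upward through a threshold,
# clustered so that each breath contributes one index.
detect_cycle_starts <- function(sig, thr) {
  n <- length(sig)
  up <- which(sig[-n] <= thr & sig[-1] > thr) + 1L
  if (length(up) <= 1L) return(up)
  gap <- median(diff(up))
  keep <- c(TRUE, diff(up) > gap / 2)
  up[keep]
}

# Internal: per-breath linear detrending of a running volume integral.
# The true net volume over each breath is zero at steady state, so any
# breath-to-breath change in the integral at breath starts is
# integration drift; it is removed by subtracting the piecewise-linear
# interpolant through the integral's values at the breath-start anchors.
detrend_volume <- function(v, t, anchors) {
  if (length(anchors) >= 2L) {
    v - approx(t[anchors], v[anchors], xout = t, rule = 2)$y
  } else {
    v - (lm(v ~ t)$fitted.values)
  }
}

# Internal: resolve time step and running volume from a waveform-style
# data frame.
resolve_waveform_inputs <- function(data, flow_q, pressure_q, dt) {
  q <- rlang::eval_tidy(flow_q, data)
  p <- rlang::eval_tidy(pressure_q, data)
  if (!is.numeric(q) || !is.numeric(p) || length(q) != length(p)) {
    stop_ventrc("Flow and pressure columns must be numeric and equal length.",
                "ventrc_invalid_parameter")
  }
  if ("time_s" %in% names(data)) {
    t <- data$time_s
  } else {
    if (is.null(dt)) {
      stop_ventrc("Provide `dt` or a `time_s` column.",
                  "ventrc_invalid_parameter")
    }
    t <- (seq_along(q) - 1) * dt
  }
  v <- if ("volume_L" %in% names(data)) {
    data$volume_L
  } else {
    pracma::cumtrapz(t, q)[, 1]
  }
  list(t = t, q = q, p = p, v = v)
}

#' Estimate patient resistance and compliance from waveform recordings
#'
#' Single-compartment pressure-balance regression: the airway pressure of
#' a linear one-compartment patient satisfies
#' `p(t) = baseline + r q(t) + V(t) / c`, where `V` is the lung volume
#' above baseline.  `V` is taken from a `volume_L` column when the
#' recording has one (flow analysers export integrated volume), otherwise
#' it is computed as the running trapezoidal integral of flow.  The
#' volume regressor is linearly detrended per breath (anchored at
#' detected breath starts) to remove integration drift before the least
#' squares fit.
#'
#' @param data A data frame holding co-registered, uniformly sampled
#'   series covering at least 3 full breaths: columns `time_s` (or supply
#'   `dt`), flow, pressure, and optionally `volume_L`.
#' @param flow,pressure Columns holding flow (L/s) and airway pressure
#'   (cmH2O); tidy-evaluated, defaults `flow_Lps`, `pressure_cmH2O`.
#' @param dt Sample interval in seconds, used only when `data` has no
#'   `time_s` column.
#' @return An object of class `lung_estimate` with fields `r`
#'   (cmH2O/(L/s)), `c` (L/cmH2O), `baseline` (cmH2O), `residual_rms`
#'   (cmH2O), `n_breaths` and `nobs`.
#' @examples
#' rec <- generate_synthetic(
#'   lung_params(12, 0.040), circuit_params(22, 0.004),
#'   vent_settings(25, 5, 15, 2), n_breaths = 5,
#'   noise_sd = c(flow = 0, pressure = 0, volume = 0), seed = 1
#' )$a
#' estimate_lung_rc(rec)
#' @export
estimate_lung_rc <- function(data, flow = flow_Lps, pressure = pressure_cmH2O,
                             dt = NULL) {
  stopifnot(is.data.frame(data))
  inp <- resolve_waveform_inputs(data, rlang::enquo(flow),
                                 rlang::enquo(pressure), dt)
  if (sd(inp$q) == 0) {
    stop_ventrc("Flow has no variation; resistance is not identifiable.",
                "ventrc_rank_deficient")
  }

  starts <- detect_cycle_starts(inp$q, 0.1 * max(abs(inp$q)))
  v <- detrend_volume(inp$v, inp$t, starts)
  if (sd(v) == 0) {
    stop_ventrc("Volume regressor has no variation.", "ventrc_rank_deficient")
  }

  x <- cbind(intercept = 1, q = inp$q, v = v)
  qr_x <- qr(x)
  if (qr_x$rank < 3L) {
    stop_ventrc("Collinear regressors; cannot separate R and C.",
                "ventrc_rank_deficient")
  }
  beta <- qr.coef(qr_x, inp$p)
  if (beta[["v"]] <= 0) {
    stop_ventrc("Estimated compliance is not positive; recording does not match a passive RC compartment.",
                "ventrc_estimation_error")
  }
  res <- inp$p - as.vector(x %*% beta)

  structure(
    list(
      r = unname(beta[["q"]]), c = 1 / beta[["v"]],
      baseline = unname(beta[["intercept"]]),
      residual_rms = sqrt(mean(res^2)),
      n_breaths = max(0L, length(starts) - 1L), nobs = length(inp$p)
    ),
    class = "lung_estimate"
  )
}

#' @export
print.lung_estimate <- function(x, ...) {
  cat(sprintf(
    "<lung_estimate> R %.3f cmH2O/(L/s), C %.5f L/cmH2O (baseline %.2f cmH2O, residual RMS %.3g cmH2O, %d obs)\n",
    x$r, x$c, x$baseline, x$residual_rms, x$nobs
  ))
  invisible(x)
}

#' @rdname estimate_lung_rc
#' @param x A `lung_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lung_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("r", "c", "baseline"),
    estimate = c(x$r, x$c, x$baseline)
  )
}

#' @rdname estimate_lung_rc
#' @exportS3Method generics::glance
glance.lung_estimate <- function(x, ...) {
  tibble::tibble(
    r = x$r, c = x$c, baseline = x$baseline,
    residual_rms = x$residual_rms, n_breaths = x$n_breaths, nobs = x$nobs
  )
}

#' Estimate tubing compliance from a blocked-line recording
#'
#' With the patient end blocked, all delivered gas is stored in the
#' tubing, so the compliance is the slope of per-breath delivered volume
#' against per-breath pressure swing.  Breaths are segmented on upward
#' crossings of the mid-range pressure; per breath, the delivered volume
#' is the within-breath range of the volume channel (or of the integrated
#' flow) and the pressure swing is the within-breath pressure range.  The
#' slope is the through-origin regression `sum(dv * dp) / sum(dp^2)`.
#'
#' @inheritParams estimate_lung_rc
#' @param min_dp Reliability floor on the mean per-breath pressure swing,
#'   cmH2O; below it the estimate is refused.
#' @return An object of class `tube_compliance_estimate` with fields
#'   `c_v` (L/cmH2O), `n_breaths` and `breaths` (per-breath tibble of
#'   `dp_cmH2O` and `dv_L`).
#' @export
estimate_tube_compliance <- function(data, flow = flow_Lps,
                                     pressure = pressure_cmH2O, dt = NULL,
                                     min_dp = 1) {
  stopifnot(is.data.frame(data))
  inp <- resolve_waveform_inputs(data, rlang::enquo(flow),
                                 rlang::enquo(pressure), dt)

  p_mid <- (max(inp$p) + min(inp$p)) / 2
  starts <- detect_cycle_starts(inp$p, p_mid)
  bounds <- if (length(starts) >= 2L) {
    cbind(head(starts, -1L), tail(starts, -1L))
  } else {
    cbind(1L, length(inp$p))
  }

  breaths <- purrr::map_dfr(seq_len(nrow(bounds)), function(i) {
    idx <- bounds[i, 1L]:bounds[i, 2L]
    tibble::tibble(
      dp_cmH2O = max(inp$p[idx]) - min(inp$p[idx]),
      dv_L = max(inp$v[idx]) - min(inp$v[idx])
    )
  })

  if (mean(breaths$dp_cmH2O) < min_dp) {
    stop_ventrc(sprintf(
      "Mean per-breath pressure swing %.3g cmH2O is below the reliability floor (%g cmH2O).",
      mean(breaths$dp_cmH2O), min_dp
    ), "ventrc_estimation_error")
  }
  c_v <- sum(breaths$dv_L * breaths$dp_cmH2O) / sum(breaths$dp_cmH2O^2)

  structure(
    list(c_v = c_v, n_breaths = nrow(breaths), breaths = breaths),
    class = "tube_compliance_estimate"
  )
}

#' @export
print.tube_compliance_estimate <- function(x, ...) {
  cat(sprintf("<tube_compliance_estimate> Cv %.5f L/cmH2O from %d breath(s)\n",
              x$c_v, x$n_breaths))
  invisible(x)
}

#' @rdname estimate_tube_compliance
#' @param x A `tube_compliance_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.tube_compliance_estimate <- function(x, ...) {
  tibble::tibble(c_v = x$c_v, n_breaths = x$n_breaths)
}
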