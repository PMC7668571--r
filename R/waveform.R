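#' Waveform records
#'
#' A waveform record is a tibble of uniformly sampled channels with a
#' `time_s` column, carrying its sample rate (Hz) and a source label as
#' attributes.  Recognised channel names are `flow_Lps`,
#' `pressure_cmH2O` and `volume_L`; unknown columns are preserved.
#'
#' @param data A data frame with a numeric `time_s` column and at least
#'   one channel.
#' @param source Optional source label (e.g. which logger produced it).
#' @return A tibble of class `waveform_record` with attributes
#'   `sample_rate` and `source`.
#' @export
as_waveform <- function(data, source = NULL) {
  stopifnot(is.data.frame(data))
  if (!"time_s" %in% names(data)) {
    stop_ventrc("Waveform data must have a `time_s` column.",
                "ventrc_format_error")
  }
  t <- data$time_s
  if (length(t) < 2L || !is.numeric(t)) {
    stop_ventrc("Waveform needs at least two numeric time samples.",
                "ventrc_format_error")
  }
  dts <- diff(t)
  dt <- median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 0.01 * dt)) {
    stop_ventrc("Non-uniform sampling: time steps deviate by more than 1% (gap or jitter).",
                "ventrc_format_error")
  }
  out <- tibble::as_tibble(data)
  class(out) <- c("waveform_record", setdiff(class(out), "waveform_record"))
  attr(out, "sample_rate") <- 1 / dt
  attr(out, "source") <- source
  out
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %g Hz%s\n", attr(x, "sample_rate"),
              if (!is.null(attr(x, "source"))) {
                paste0(", source: ", attr(x, "source"))
              } else ""))
  NextMethod()
}

#' Sample rate of a waveform record
#' @param record A `waveform_record`.
#' @return Sample rate in Hz.
#' @export
sample_rate <- function(record) {
  attr(record, "sample_rate") %||% (1 / median(diff(record$time_s)))
}

#' Read and write waveform logs
#'
#' Waveform logs are plain comma-separated text with a header row, a
#' `time_s` column and named channels (`flow_Lps`, `pressure_cmH2O`,
#' `volume_L`, plus anything else, which is preserved).  Values are
#' written with full round-trip precision, so `read_waveform(write_waveform(x))`
#' reproduces `x` exactly.  Column order in the file is irrelevant.
#'
#' @param path File path.
#' @param source Optional source label attached to the record.
#' @return `read_waveform()` returns a [as_waveform()] record;
#'   `write_waveform()` returns `path` invisibly.
#' @export
read_waveform <- function(path, source = NULL) {
  if (!file.exists(path)) {
    stop_ventrc(sprintf("Waveform file not found: %s", path),
                "ventrc_format_error")
  }
  # base strtod parsing is correctly rounded, so values written with
  # shortest round-trip precision read back bit-identical
  data <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  as_waveform(data, source = source %||% basename(path))
}

#' @rdname read_waveform
#' @param record A data frame or `waveform_record`.
#' @export
write_waveform <- function(record, path) {
  stopifnot(is.data.frame(record))
  readr::write_csv(record, path, progress = FALSE)
  invisible(path)
}

#' Co-register two waveform records by cross-correlation
#'
#' Two loggers recording the same experiment start at slightly different
#' times.  The inter-logger lag is estimated as the integer-sample shift
#' maximising the cross-correlation of a shared channel, and both records
#' are trimmed to their overlap on a common clock (record `a`'s).
#' A positive lag means `b`'s channels are delayed relative to `a`'s
#' (`b(t) = a(t - lag)`).
#'
#' @param rec_a,rec_b Waveform records with equal sample rates sharing
#'   `channel`.
#' @param channel Name of the channel to align on.
#' @param max_lag_s Half-width of the lag search window, seconds.
#' @return A list with `a` and `b` (trimmed, aligned records), `lag_s`,
#'   `lag_samples` and `correlation` (the correlation at the chosen lag).
#' @export
coregister <- function(rec_a, rec_b, channel = "pressure_cmH2O",
                       max_lag_s = 10) {
  stopifnot(is.data.frame(rec_a), is.data.frame(rec_b))
  if (!channel %in% names(rec_a) || !channel %in% names(rec_b)) {
    stop_ventrc(sprintf("Channel `%s` must be present in both records.",
                        channel), "ventrc_alignment_error")
  }
  fs_a <- sample_rate(rec_a)
  fs_b <- sample_rate(rec_b)
  if (abs(fs_a - fs_b) > 1e-6 * fs_a) {
    stop_ventrc("Records must share a sample rate.", "ventrc_alignment_error")
  }
  a <- rec_a[[channel]]
  b <- rec_b[[channel]]
  if (min(length(a), length(b)) < 5 * fs_a) {
    stop_ventrc("Overlapping duration must be at least 5 s.",
                "ventrc_alignment_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_ventrc("Alignment impossible: channel has zero variance.",
                "ventrc_alignment_error")
  }

  a0 <- a - mean(a)
  b0 <- b - mean(b)
  k_max <- min(as.integer(round(max_lag_s * fs_a)),
               length(a0) - 2L, length(b0) - 2L)
  lags <- -k_max:k_max
  score <- vapply(lags, function(k) {
    # b[i] pairs with a[i - k]
    ia <- max(1L, 1L - k):min(length(a0), length(b0) - k)
    ib <- ia + k
    sa <- a0[ia]
    sb <- b0[ib]
    denom <- sqrt(sum(sa^2) * sum(sb^2))
    if (denom == 0) -Inf else sum(sa * sb) / denom
  }, numeric(1))
  k <- lags[which.max(score)]

  ia <- max(1L, 1L - k):min(nrow(rec_a), nrow(rec_b) - k)
  ib <- ia + k
  a_out <- rec_a[ia, , drop = FALSE]
  b_out <- rec_b[ib, , drop = FALSE]
  b_out$time_s <- a_out$time_s
  list(
    a = as_waveform(a_out, source = attr(rec_a, "source")),
    b = as_waveform(b_out, source = attr(rec_b, "source")),
    lag_s = k / fs_a, lag_samples = k, correlation = max(score)
  )
}

# Internal: continuous-time evaluation of the steady-cycle channels at
# arbitrary times (folded into the period).  Used by the generator so
# that sample times need not coincide with a solver grid.
steady_signal_fun <- function(lung, circuit, settings) {
  timing <- phase_timing(settings)
  sys_i <- phase_system(lung, circuit, "insp")
  sys_e <- phase_system(lung, circuit, "exp")
  p_i <- settings$peep + settings$pinsp
  p_e <- settings$peep
  sol <- cyclic_steady_state(lung, circuit, settings, samples_per_cycle = 400)
  x0 <- sol$x0
  x_switch <- phase_state(sys_i, x0, p_i, timing$t_insp)
  p_lung_min <- sol$p_lung_range[1]

  function(t) {
    tm <- t %% timing$period
    states <- matrix(NA_real_, length(tm), sys_i$n)
    in_insp <- tm < timing$t_insp
    for (i in seq_along(tm)) {
      states[i, ] <- if (in_insp[i]) {
        phase_state(sys_i, x0, p_i, tm[i])
      } else {
        phase_state(sys_e, x_switch, p_e, tm[i] - timing$t_insp)
      }
    }
    ch <- matrix(NA_real_, length(tm), 3,
                 dimnames = list(NULL, c("flow_Lps", "pressure_cmH2O",
                                         "volume_L")))
    for (ph in c(TRUE, FALSE)) {
      idx <- which(in_insp == ph)
      if (length(idx) == 0) next
      sys <- if (ph) sys_i else sys_e
      p_drive <- if (ph) p_i else p_e
      cc <- phase_channels(sys, states[idx, , drop = FALSE], p_drive)
      ch[idx, "flow_Lps"] <- cc$q_patient_Lps
      ch[idx, "pressure_cmH2O"] <- cc$p_tube_cmH2O
      ch[idx, "volume_L"] <- sys$c_patient * (cc$p_lung_cmH2O - p_lung_min)
    }
    ch
  }
}

# Internal: blocked-line steady cycle (patient end occluded): all flow is
# stored in the tubing compliance, a first-order system with time
# constant Rs * c_v per phase.
blocked_signal_fun <- function(circuit, settings) {
  timing <- phase_timing(settings)
  p_i <- settings$peep + settings$pinsp
  p_e <- settings$peep
  rs_i <- phase_series_resistance(circuit, "insp")
  rs_e <- phase_series_resistance(circuit, "exp")
  cv <- circuit$c_v
  if (cv == 0) {
    # Rigid line: pressure follows the drive, nothing is stored.
    return(function(t) {
      p <- drive_pressure(settings, timing, t)
      cbind(flow_Lps = 0 * t, pressure_cmH2O = p, volume_L = 0 * t)
    })
  }
  if (rs_i <= 0 || rs_e <= 0) {
    stop_ventrc("Blocked-line generation needs positive series resistance.",
                "ventrc_ill_posed")
  }
  ei <- exp(-timing$t_insp / (rs_i * cv))
  ee <- exp(-timing$t_exp / (rs_e * cv))
  # Cyclic boundary: x0 = Pe + ee * (xs - Pe), xs = Pi + ei * (x0 - Pi)
  x0 <- (p_e * (1 - ee) + ee * p_i * (1 - ei)) / (1 - ei * ee)
  xs <- p_i + ei * (x0 - p_i)

  function(t) {
    tm <- t %% timing$period
    insp <- tm < timing$t_insp
    p <- ifelse(insp,
                p_i + (x0 - p_i) * exp(-tm / (rs_i * cv)),
                p_e + (xs - p_e) * exp(-(tm - timing$t_insp) / (rs_e * cv)))
    q <- ifelse(insp, (p_i - p) / rs_i, (p_e - p) / rs_e)
    cbind(flow_Lps = q, pressure_cmH2O = p, volume_L = cv * (p - x0))
  }
}

#' Generate a synthetic pair of waveform recordings
#'
#' Samples the steady-cycle waveforms of the RC network at a logger's
#' rate over a number of breaths, adds independent Gaussian noise per
#' channel, and produces a second logger copy whose channels are delayed
#' by `logger_offset` seconds -- emulating two flow analysers logging the
#' same experiment on separate, unsynchronised computers.  Channels are
#' `flow_Lps` (patient airway flow, or line flow when `blocked`),
#' `pressure_cmH2O` (tubing-node pressure) and `volume_L` (integrated
#' volume above the cycle minimum).
#'
#' With `blocked = TRUE` the patient end is occluded (the tube-compliance
#' characterisation set-up) and the underlying dynamics are first order
#' in the tubing state.
#'
#' Defaults mirror the characterisation experiments: 50 Hz logging and 15
#' recorded breaths.
#'
#' @inheritParams cyclic_steady_state
#' @param n_breaths Number of breaths to record.
#' @param sample_rate Logging rate, Hz.
#' @param noise_sd Named numeric vector of per-channel noise standard
#'   deviations (`flow` L/s, `pressure` cmH2O, `volume` L); unnamed
#'   entries are not accepted.  Defaults are typical instrument noise.
#' @param logger_offset Delay of logger `b` relative to logger `a`,
#'   seconds.
#' @param seed Integer seed; the output is reproducible for a fixed seed.
#' @param blocked Generate a blocked-line (tube-only) recording.
#' @return A list with waveform records `a` and `b`, the generating
#'   tidal volume `vt` (NA when `blocked`), and `period`.
#' @export
generate_synthetic <- function(lung, circuit, settings, n_breaths = 15,
                               sample_rate = 50,
                               noise_sd = c(flow = 0.01, pressure = 0.1,
                                            volume = 0.001),
                               logger_offset = 0, seed = NULL,
                               blocked = FALSE) {
  stopifnot(inherits(circuit, "circuit_params"),
            inherits(settings, "vent_settings"))
  defaults <- c(flow = 0.01, pressure = 0.1, volume = 0.001)
  if (length(noise_sd) > 0 &&
      (is.null(names(noise_sd)) ||
       !all(names(noise_sd) %in% names(defaults)))) {
    stop_ventrc("`noise_sd` entries must be named flow/pressure/volume.",
                "ventrc_invalid_parameter")
  }
  nsd <- defaults
  nsd[names(noise_sd)] <- noise_sd
  if (any(nsd < 0)) {
    stop_ventrc("Noise standard deviations must be >= 0.",
                "ventrc_invalid_parameter")
  }

  timing <- phase_timing(settings)
  if (blocked) {
    sig <- blocked_signal_fun(circuit, settings)
    vt <- NA_real_
  } else {
    stopifnot(inherits(lung, "lung_params"))
    sig <- steady_signal_fun(lung, circuit, settings)
    vt <- cyclic_steady_state(lung, circuit, settings)$vt
  }

  n_samp <- as.integer(floor(n_breaths * timing$period * sample_rate)) + 1L
  t <- (seq_len(n_samp) - 1L) / sample_rate

  make_record <- function(times_true, label) {
    ch <- sig(times_true)
    noise <- cbind(
      flow_Lps = stats::rnorm(n_samp, 0, nsd[["flow"]]),
      pressure_cmH2O = stats::rnorm(n_samp, 0, nsd[["pressure"]]),
      volume_L = stats::rnorm(n_samp, 0, nsd[["volume"]])
    )
    as_waveform(
      tibble::tibble(
        time_s = t,
        flow_Lps = ch[, "flow_Lps"] + noise[, "flow_Lps"],
        pressure_cmH2O = ch[, "pressure_cmH2O"] + noise[, "pressure_cmH2O"],
        volume_L = ch[, "volume_L"] + noise[, "volume_L"]
      ),
      source = label
    )
  }

  build <- function() {
    list(
      a = make_record(t, "logger_a"),
      b = make_record(t - logger_offset, "logger_b"),
      vt = vt, period = timing$period
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
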