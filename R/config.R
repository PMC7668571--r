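#' Read a flat key-value configuration file
#'
#' Parses a plain-text configuration of the form `key = value`, one pair
#' per line, with `#` comments and blank lines ignored.  Recognised keys
#' (all values numeric, package units):
#'
#' * `pinsp`, `peep`, `rr`, `ie_e` — ventilator settings (see
#'   [vent_settings()]); `ie_e` is the E of I:E = 1:E.
#' * `r_v`, `c_v` — tubing resistance and compliance.
#' * `r_lung`, `c_lung` — patient resistance and compliance.
#' * `r_restrictor_insp`, `r_restrictor_exp` — optional added restrictor
#'   resistance per phase (default 0).
#'
#' @param path Path to the configuration file.
#' @return A list with components `settings` ([vent_settings()]),
#'   `lung` ([lung_params()]) and `circuit` ([circuit_params()]).
#' @seealso [write_vent_config()]
#' @export
read_vent_config <- function(path) {
  if (!file.exists(path)) {
    stop_ventrc(sprintf("Config file not found: %s", path),
                "ventrc_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)$",
                                  lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop_ventrc(
      sprintf("Malformed config line(s): %s",
              paste(sQuote(lines[bad]), collapse = ", ")),
      "ventrc_config_error"
    )
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 3L)))

  required <- c("pinsp", "peep", "rr", "ie_e", "r_v", "c_v", "r_lung", "c_lung")
  optional <- c("r_restrictor_insp", "r_restrictor_exp")
  unknown <- setdiff(keys, c(required, optional))
  if (length(unknown) > 0) {
    stop_ventrc(sprintf("Unknown config key(s): %s",
                        paste(unknown, collapse = ", ")),
                "ventrc_config_error")
  }
  if (anyDuplicated(keys)) {
    stop_ventrc("Duplicate config keys.", "ventrc_config_error")
  }
  missing <- setdiff(required, keys)
  if (length(missing) > 0) {
    stop_ventrc(sprintf("Missing config key(s): %s",
                        paste(missing, collapse = ", ")),
                "ventrc_config_error")
  }
  if (anyNA(vals)) {
    stop_ventrc(sprintf("Non-numeric value for key(s): %s",
                        paste(keys[is.na(vals)], collapse = ", ")),
                "ventrc_config_error")
  }
  v <- as.list(setNames(vals, keys))

  list(
    settings = vent_settings(v$pinsp, v$peep, v$rr, v$ie_e),
    lung = lung_params(r = v$r_lung, c = v$c_lung),
    circuit = circuit_params(
      r_v = v$r_v, c_v = v$c_v,
      r_restrictor_insp = v$r_restrictor_insp %||% 0,
      r_restrictor_exp = v$r_restrictor_exp %||% 0
    )
  )
}

#' Write a flat key-value configuration file
#'
#' Inverse of [read_vent_config()]; the written file reads back to
#' identical parameter objects.
#'
#' @param settings,lung,circuit Parameter objects (see [vent_settings()],
#'   [lung_params()], [circuit_params()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vent_config <- function(settings, lung, circuit, path) {
  stopifnot(inherits(settings, "vent_settings"),
            inherits(lung, "lung_params"),
            inherits(circuit, "circuit_params"))
  vals <- c(
    pinsp = settings$pinsp, peep = settings$peep, rr = settings$rr,
    ie_e = settings$ie_e, r_v = circuit$r_v, c_v = circuit$c_v,
    r_lung = lung$r, c_lung = lung$c,
    r_restrictor_insp = circuit$r_restrictor_insp,
    r_restrictor_exp = circuit$r_restrictor_exp
  )
  writeLines(sprintf("%s = %.15g", names(vals), vals), path)
  invisible(path)
}
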