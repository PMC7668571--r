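# Bench-top reference configuration used across tests: the dual-lung
# shared-ventilator validation set-up.

bench_settings <- function(pinsp = 25) {
  vent_settings(pinsp = pinsp, peep = 5, rr = 15, ie_e = 2)
}

bench_lung1 <- function() lung_params(r = 12, c = 0.040)
bench_lung2 <- function() lung_params(r = 10, c = 0.030)

bench_circuit <- function(r_restrictor_insp = 0) {
  circuit_params(r_v = 22, c_v = 0.004,
                 r_restrictor_insp = r_restrictor_insp)
}

# A random-but-physiological parameter draw (call inside withr::with_seed).
draw_param_set <- function() {
  list(
    lung = lung_params(r = runif(1, 5, 25), c = runif(1, 0.02, 0.05)),
    circuit = circuit_params(
      r_v = runif(1, 10, 30), c_v = runif(1, 0.002, 0.006),
      r_restrictor_insp = runif(1, 0, 30)
    ),
    settings = vent_settings(
      pinsp = runif(1, 10, 30), peep = runif(1, 0, 8),
      rr = runif(1, 10, 20), ie_e = runif(1, 1, 3)
    )
  )
}

bench_config_file <- function(path = tempfile(fileext = ".cfg"),
                              pinsp = 25, r_restrictor_insp = 0) {
  write_vent_config(bench_settings(pinsp), bench_lung1(),
                    bench_circuit(r_restrictor_insp), path)
  path
}
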