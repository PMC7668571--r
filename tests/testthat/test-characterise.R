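test_that("mean flow averages the two flowmeter readings", {
  expect_equal(mean_flow(0.5, 0.7), 0.6)
  q <- c(-0.3, 0, 1.2)
  expect_equal(mean_flow(q, q), q)
  expect_equal(mean_flow(0.5, -0.5), 0)
})

test_that("noise-free proportional data is fitted exactly", {
  d <- tibble::tibble(q_mean_Lps = seq(0, 1, by = 0.05),
                      dp_cmH2O = 12 * q_mean_Lps)
  fit <- fit_restrictor(d, "proportional")
  expect_equal(fit$k1, 12, tolerance = 1e-10)
  expect_equal(fit$k2, 0)
  expect_equal(fit$k0, 0)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("robust and plain fits coincide on outlier-free data", {
  q <- seq(-1, 1, by = 0.05)
  truth <- list(
    quadratic = 96.8 * q^2 + 6.1 * q + 0.5,
    linear = 9.1 * q + 1.1,
    proportional = 12 * q
  )
  for (model in names(truth)) {
    d <- tibble::tibble(q_mean_Lps = q, dp_cmH2O = truth[[model]])
    rob <- fit_restrictor(d, model, robust = TRUE)
    ols <- fit_restrictor(d, model, robust = FALSE)
    expect_lt(max(abs(c(rob$k2 - ols$k2, rob$k1 - ols$k1, rob$k0 - ols$k0))),
              1e-8)
  }
})

test_that("the converged proportional slope satisfies its weighted normal equation", {
  withr::with_seed(7, {
    q <- runif(300, 0, 1.2)
    dp <- 12 * q + rnorm(300, 0, 0.3)
    dp[1:20] <- dp[1:20] + 15  # gross outliers
  })
  fit <- fit_restrictor(tibble::tibble(q_mean_Lps = q, dp_cmH2O = dp),
                        "proportional", robust = TRUE)
  w <- fit$data$weight
  closed_form <- sum(w * q * dp) / sum(w * q^2)
  expect_equal(fit$k1, closed_form, tolerance = 1e-6)
})

test_that("quadratic coefficients are recovered within their confidence intervals", {
  # Monte-Carlo parameter recovery: truth near the characterised small
  # orifice restrictor, Gaussian noise sd 0.2 cmH2O, n = 500.
  k2_true <- 96.8
  k1_true <- 6.1
  n_rep <- 100
  hits <- withr::with_seed(2024, {
    vapply(seq_len(n_rep), function(i) {
      q <- runif(500, 0, 1.1)
      dp <- k2_true * q^2 + k1_true * q + rnorm(500, 0, 0.2)
      fit <- fit_restrictor(tibble::tibble(q_mean_Lps = q, dp_cmH2O = dp),
                            "quadratic")
      ci <- fit$ci_95
      in_ci <- function(term, truth) {
        row <- ci[ci$term == term, ]
        row$conf.low <= truth && truth <= row$conf.high
      }
      in_ci("k2", k2_true) && in_ci("k1", k1_true)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
})

test_that("bi-square weighting resists gross outliers", {
  withr::with_seed(11, {
    q <- runif(200, 0.1, 1.2)
    dp <- 12 * q + rnorm(200, 0, 0.1)
    out_idx <- sample(200, 20)
    dp[out_idx] <- dp[out_idx] + 20
  })
  d <- tibble::tibble(q_mean_Lps = q, dp_cmH2O = dp)
  rob <- fit_restrictor(d, "proportional", robust = TRUE)
  ols <- fit_restrictor(d, "proportional", robust = FALSE)
  dev_rob <- abs(rob$k1 - 12)
  dev_ols <- abs(ols$k1 - 12)
  expect_gt(dev_ols, 1)            # outliers visibly bias plain LS
  expect_lt(dev_rob, dev_ols / 5)  # bi-square removes almost all of it
  expect_lt(mean(rob$data$weight[out_idx]), 0.05)
})

test_that("bi-square IRLS agrees with an independent robust fitter", {
  skip_if_not_installed("MASS")
  withr::with_seed(13, {
    q <- runif(300, 0, 1.2)
    dp <- 9.1 * q + 1.1 + rnorm(300, 0, 0.2)
    dp[1:15] <- dp[1:15] + 10
  })
  fit <- fit_restrictor(tibble::tibble(q_mean_Lps = q, dp_cmH2O = dp),
                        "linear", robust = TRUE)
  ref <- MASS::rlm(dp ~ q, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(fit$k1, unname(coef(ref)["q"]), tolerance = 0.02)
  expect_equal(fit$k0, unname(coef(ref)["(Intercept)"]), tolerance = 0.05)
})

test_that("degenerate restrictor inputs are rejected", {
  expect_error(
    fit_restrictor(tibble::tibble(q_mean_Lps = c(1, 2), dp_cmH2O = c(1, 2)),
                   "proportional"),
    class = "ventrc_invalid_parameter"
  )
  expect_error(
    fit_restrictor(tibble::tibble(q_mean_Lps = rep(1, 10),
                                  dp_cmH2O = rnorm(10)), "linear"),
    class = "ventrc_rank_deficient"
  )
})

test_that("lung R and C are recovered exactly from noise-free waveforms", {
  rec <- generate_synthetic(
    bench_lung1(), bench_circuit(), bench_settings(25), n_breaths = 5,
    noise_sd = c(flow = 0, pressure = 0, volume = 0), seed = 1
  )$a
  est <- estimate_lung_rc(rec)
  expect_equal(est$r, 12, tolerance = 1e-6)
  expect_equal(est$c, 0.040, tolerance = 1e-6)
  expect_lt(est$residual_rms, 1e-9)
})

test_that("lung R and C are recovered from noisy 50 Hz recordings", {
  rec <- generate_synthetic(
    bench_lung1(), bench_circuit(), bench_settings(25), n_breaths = 15,
    noise_sd = c(flow = 0.01, pressure = 0.1, volume = 0.001), seed = 21
  )$a
  # force the flow-integration path (no volume channel)
  rec$volume_L <- NULL
  est <- estimate_lung_rc(rec)
  expect_lt(abs(est$r - 12), 0.5)
  expect_lt(abs(est$c - 0.040), 0.002)
  g <- glance(est)
  expect_gte(g$n_breaths, 3)
})

test_that("degenerate lung recordings are rejected", {
  flat <- tibble::tibble(time_s = seq(0, 10, by = 0.02))
  flat$flow_Lps <- 0
  flat$pressure_cmH2O <- 10
  expect_error(estimate_lung_rc(flat), class = "ventrc_rank_deficient")
})

test_that("tube compliance is recovered from blocked-line recordings", {
  bl <- generate_synthetic(
    bench_lung1(), bench_circuit(), bench_settings(25), n_breaths = 15,
    seed = 5, blocked = TRUE
  )$a
  est <- estimate_tube_compliance(bl)
  expect_equal(est$c_v, 0.004, tolerance = 0.05)
  expect_gte(est$n_breaths, 10)
})

test_that("a rigid blocked line yields zero compliance", {
  bl <- generate_synthetic(
    bench_lung1(), circuit_params(22, 0), bench_settings(25), n_breaths = 5,
    noise_sd = c(flow = 0, pressure = 0, volume = 0), seed = 6,
    blocked = TRUE
  )$a
  est <- estimate_tube_compliance(bl)
  expect_equal(est$c_v, 0)
})

test_that("tiny pressure swings are refused as unreliable", {
  bl <- generate_synthetic(
    bench_lung1(), bench_circuit(), vent_settings(0.4, 5, 15, 2),
    n_breaths = 5, noise_sd = c(flow = 0, pressure = 0, volume = 0),
    seed = 7, blocked = TRUE
  )$a
  expect_error(estimate_tube_compliance(bl),
               class = "ventrc_estimation_error")
})

test_that("generate -> estimate -> re-simulate closes the loop on tidal volume", {
  rec <- generate_synthetic(
    bench_lung1(), bench_circuit(), bench_settings(25), n_breaths = 15,
    seed = 33
  )
  est <- estimate_lung_rc(rec$a)
  resim <- cyclic_steady_state(lung_params(r = est$r, c = est$c),
                               bench_circuit(), bench_settings(25))
  expect_lt(abs(resim$vt - rec$vt) / rec$vt, 0.01)
})
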