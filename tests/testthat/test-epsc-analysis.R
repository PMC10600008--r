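test_that("component measurement: baselines, peaks and the 35-ms read-out", {
  flat <- sweep_trace(seq(0, 0.5, by = 5e-5), numeric(10001), -70, 0.05, 1.5)
  expect_equal(measure_component(flat, "AMPA", "peak")$amplitude, 0)

  sw <- gen_epsc_sweep(-70, ampa_amp = 130, nmda_amp = 0, noise_sd = 0)
  expect_equal(measure_component(sw, "AMPA", "peak")$amplitude, 130,
               tolerance = 1e-3)  # sampled-grid peak, no interpolation

  # a DC offset is removed by pre-stimulus baseline subtraction
  sw_dc <- sw; sw_dc$current <- sw$current + 25
  expect_equal(measure_component(sw_dc, "AMPA", "peak")$amplitude, 130,
               tolerance = 1e-3)

  # method/holding pairing is enforced
  expect_error(measure_component(sw, "NMDA", "t35"),
               class = "habtrap_invalid_measurement")
  plus40 <- gen_epsc_sweep(40, ampa_amp = 100, nmda_amp = 40, noise_sd = 0)
  expect_error(measure_component(plus40, "AMPA", "peak"),
               class = "habtrap_invalid_measurement")

  # AMPAR contamination of the 35-ms value stays below 1% for decay <= 5 ms
  for (td in c(3, 5)) {
    k <- default_epsc_kinetics(); k$tau_decay_a <- td
    mix <- gen_epsc_sweep(40, ampa_amp = 130, nmda_amp = 40, kinetics = k,
                          noise_sd = 0)
    pure <- gen_epsc_sweep(40, ampa_amp = 0, nmda_amp = 40, kinetics = k,
                           noise_sd = 0)
    a <- measure_component(mix, "NMDA", "t35")$amplitude
    b <- measure_component(pure, "NMDA", "t35")$amplitude
    expect_lt(abs(a - b) / b, 0.01)
  }
})

test_that("NMDA/AMPA ratio recovers the configured value", {
  nm <- gen_epsc_sweep(40, ampa_amp = 0, nmda_amp = 50, noise_sd = 0)
  am <- gen_epsc_sweep(-70, ampa_amp = 50 / 0.638, nmda_amp = 0, noise_sd = 0)
  # equal measured amplitudes give ratio 1 by construction
  r_am <- measure_component(am, "AMPA", "peak")$amplitude
  nm2 <- gen_epsc_sweep(40, ampa_amp = 0, nmda_amp = 50, noise_sd = 0)
  expect_equal(nmda_ampa_ratio(nm2, am),
               measure_component(nm2, "NMDA", "t35")$amplitude / r_am)

  # configured ratio 0.30: NMDA t35 amplitude = 0.30 * AMPA peak
  k <- default_epsc_kinetics()
  tr <- k$tau_rise_n / 1000; td <- k$tau_decay_n / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  w35 <- (exp(-0.035 / td) - exp(-0.035 / tr)) /
    (exp(-tpk / td) - exp(-tpk / tr))
  ampa_peak <- 130
  nmda_amp <- 0.30 * ampa_peak / w35
  nm3 <- gen_epsc_sweep(40, ampa_amp = ampa_peak, nmda_amp = nmda_amp,
                        noise_sd = 0)
  am3 <- gen_epsc_sweep(-70, ampa_amp = ampa_peak, nmda_amp = 0, noise_sd = 0)
  expect_equal(nmda_ampa_ratio(nm3, am3), 0.30, tolerance = 0.01)

  # zero NMDA component
  nm0 <- gen_epsc_sweep(40, ampa_amp = 130, nmda_amp = 0, noise_sd = 0)
  expect_lt(nmda_ampa_ratio(nm0, am3), 0.01)

  expect_error(nmda_ampa_ratio(nm3, gen_epsc_sweep(-70, 0, 0)),
               class = "habtrap_undefined_ratio")
})

test_that("input-output curve and >10 pA prevalence", {
  m0 <- data.frame(neuron_id = rep(1:5, each = 2),
                   intensity_mA = rep(c(0.25, 1.5), 5), amplitude_pA = 0)
  expect_equal(build_io_curve(m0)$prevalence, 0)

  # deterministic 69/100 construction
  amps <- c(rep(30, 69), rep(5, 31))
  m1 <- data.frame(neuron_id = 1:100, intensity_mA = 1.5, amplitude_pA = amps)
  io1 <- build_io_curve(m1)
  expect_equal(io1$prevalence, 0.69)
  expect_equal(io1$n_neurons, 100L)

  # monotone amplitudes produce a monotone curve
  iv <- seq(0.25, 1.5, by = 0.25)
  m2 <- data.frame(neuron_id = 1, intensity_mA = iv, amplitude_pA = iv * 40)
  io2 <- build_io_curve(m2, prevalence_threshold = NULL)
  expect_equal(io2$intensities, iv)
  expect_true(all(diff(io2$mean_amplitude) > 0))

  expect_error(build_io_curve(data.frame(neuron_id = 1, intensity_mA = 0.25,
                                         amplitude_pA = 10)),
               "reference intensity")
})

test_that("washout normalization and its idempotence", {
  ep <- list(baseline = c(0, 300), wash_in = c(300, 900),
             washout = c(900, 3900))
  tt <- seq(0, 3890, by = 10)
  const <- washout_normalize(tt, rep(80, length(tt)), ep)
  expect_true(all(const$normalized_amplitude == 1))

  raw <- ifelse(tt < 300, 100, ifelse(tt < 900, 20, 60))
  ws <- washout_normalize(tt, raw, ep)
  expect_equal(sort(unique(ws$normalized_amplitude)), c(0.2, 0.6, 1))
  expect_equal(mean(ws$normalized_amplitude[tt < 300]), 1, tolerance = 1e-9)

  twice <- washout_normalize(ws$pulse_times, ws$normalized_amplitude, ep)
  expect_equal(twice$normalized_amplitude, ws$normalized_amplitude)

  expect_error(washout_normalize(tt, raw - 100, ep),
               class = "habtrap_normalization_error")
})

test_that("maximal blockade, late blockade and recovery", {
  ep <- list(baseline = c(0, 300), wash_in = c(300, 900),
             washout = c(900, 3900))
  tt <- seq(0, 3900, by = 10)

  flat <- washout_series(tt, rep(1, length(tt)), ep)
  br0 <- blockade_recovery(flat)
  expect_equal(br0$max_blockade, 0)
  expect_equal(br0$recovery, 0)

  # step series: 0.2 in the first 20 min after wash-in, 0.6 at 50-60 min
  rel <- (tt - 300) / 60
  amp <- ifelse(rel < 0, 1, ifelse(rel < 20, 0.2, 0.6))
  br <- blockade_recovery(washout_series(tt, amp, ep))
  expect_equal(br$max_blockade, 80)
  expect_equal(br$blockade_50_60, 40)
  expect_equal(br$recovery, 40)

  # recovery is never negative for a series that only recovers
  mono <- ifelse(rel < 0, 1, pmin(1, 0.2 + pmax(rel, 0) * 0.01))
  expect_gte(blockade_recovery(washout_series(tt, mono, ep))$recovery, 0)

  # vehicle-like noise keeps blockade within the noise bound
  set.seed(8)
  noise <- 1 + rnorm(length(tt), 0, 0.02)
  expect_lt(abs(blockade_recovery(washout_series(tt, noise, ep))$max_blockade),
            3 * 2)  # 3 x noise sd, in percent

  expect_error(blockade_recovery(washout_series(seq(0, 1200, 10),
                                                rep(1, 121), ep)),
               "too short")
})

test_that("recovery never exceeds maximal blockade on simulated series", {
  for (p in c("ketamine", "memantine")) {
    br <- blockade_recovery(run_washout_experiment(build_model(p), 100))
    expect_lte(br$recovery, br$max_blockade)
    expect_gte(br$max_blockade, max(br$bin_blockade) - 1e-12)
  }
})

test_that("blockade-recovery regression matches lm and recovers signs", {
  x <- c(50, 60, 70, 80, 90)
  y <- 2 + 0.5 * x
  fit <- blockade_recovery_regression(x, y)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.5)

  # zero covariance: slope 0, R^2 0
  x2 <- c(1, 1, 2, 2); y2 <- c(0, 4, 0, 4)
  fit2 <- blockade_recovery_regression(x2, y2)
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$r_squared, 0)

  # agreement with the standard least-squares fit
  set.seed(13)
  x3 <- runif(20, 40, 95)
  y3 <- 60 - 0.6 * x3 + rnorm(20, 0, 5)
  fit3 <- blockade_recovery_regression(x3, y3)
  lmfit <- lm(y3 ~ x3)
  expect_equal(fit3$slope, unname(coef(lmfit)[2L]), tolerance = 1e-6)
  expect_equal(fit3$intercept, unname(coef(lmfit)[1L]), tolerance = 1e-6)
  expect_equal(fit3$r_squared, summary(lmfit)$r.squared, tolerance = 1e-6)
  expect_lt(fit3$slope, 0)

  expect_error(blockade_recovery_regression(rep(1, 5), 1:5),
               class = "habtrap_degenerate_regression")
})
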