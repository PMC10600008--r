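test_that("generators are deterministic given a seed", {
  expect_identical(gen_tonic_train(5, 60, seed = 9)$spikes,
                   gen_tonic_train(5, 60, seed = 9)$spikes)
  expect_identical(gen_bursting_train(10, duration = 60, seed = 9)$spikes,
                   gen_bursting_train(10, duration = 60, seed = 9)$spikes)
  expect_identical(gen_pk_series(16, 13, 0:6 * 10, noise_cv = 0.2, seed = 9),
                   gen_pk_series(16, 13, 0:6 * 10, noise_cv = 0.2, seed = 9))
  s1 <- gen_epsc_sweep(40, 100, 30, noise_sd = 3, seed = 9)
  s2 <- gen_epsc_sweep(40, 100, 30, noise_sd = 3, seed = 9)
  expect_identical(s1$current, s2$current)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(2)
  set.seed(123); invisible(gen_tonic_train(5, 10, seed = 1)); b <- runif(2)
  expect_identical(a, b)
})

test_that("tonic train: rate, refractoriness and degenerate cases", {
  expect_length(gen_tonic_train(0, 180, seed = 1)$spikes, 0L)
  expect_error(gen_tonic_train(-1, 10, seed = 1), "outside")
  expect_error(gen_tonic_train(5, 0, seed = 1), "outside")

  tr <- gen_tonic_train(5, 180, seed = 2)
  expect_lt(abs(length(tr$spikes) - 900), 3 * sqrt(900))
  expect_true(all(diff(tr$spikes) >= 0.002))

  # a 25-ms refractory period leaves no ISI short enough to open a burst
  tr2 <- gen_tonic_train(5, 180, seed = 3, refractory = 0.025)
  expect_equal(nrow(detect_bursts(tr2)), 0L)
})

test_that("bursting train respects its preconditions and structure", {
  expect_error(gen_bursting_train(10, isi0 = 25), "onset criterion")
  expect_error(gen_bursting_train(10, spikes_per_burst = 12, isi0 = 15,
                                  isi_growth = 1.3), "50 ms")
  # zero burst rate degenerates to pure background
  tr <- gen_bursting_train(0, background_rate = 3, duration = 60, seed = 4)
  expect_gt(length(tr$spikes), 0)
  expect_equal(nrow(detect_bursts(tr)), 0L)

  # background does not corrupt burst spike counts
  tr2 <- gen_bursting_train(10, spikes_per_burst = 4, background_rate = 2,
                            duration = 120, seed = 5)
  b <- detect_bursts(tr2)
  expect_true(all(b$n_spikes == 4L))
})

test_that("synthetic eEPSC sweeps have the designed component structure", {
  flat <- gen_epsc_sweep(40, 0, 0, noise_sd = 0)
  expect_true(all(flat$current == 0))

  # 35-ms read-out isolates the NMDAR component to closed-form accuracy
  sw <- gen_epsc_sweep(40, ampa_amp = 130, nmda_amp = 40, noise_sd = 0)
  got <- measure_component(sw, "NMDA", "t35")$amplitude
  k <- default_epsc_kinetics()
  tr <- k$tau_rise_n / 1000; td <- k$tau_decay_n / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  want <- 40 * (exp(-0.035 / td) - exp(-0.035 / tr)) /
    (exp(-tpk / td) - exp(-tpk / tr))
  expect_lt(abs(got - want) / want, 0.005)

  # physiological magnesium suppresses the NMDAR component at -70 mV
  sw2 <- gen_epsc_sweep(-70, ampa_amp = 130, nmda_amp = 40, noise_sd = 0,
                        mg_mode = "physiological")
  expect_equal(measure_component(sw2, "AMPA", "peak")$amplitude, 130,
               tolerance = 1e-3)
  late <- sw2$current[sw2$time > sw2$stim_onset + 0.030]
  expect_lt(max(abs(late)), 0.1)  # no slow component left

  # magnesium-free mode keeps it
  sw3 <- gen_epsc_sweep(-70, ampa_amp = 0, nmda_amp = 40, noise_sd = 0,
                        mg_mode = "free")
  expect_gt(max(abs(sw3$current)), 35)

  expect_error(gen_epsc_sweep(40, 10, 10, sampling_rate = 500), "sampling_rate")
})

test_that("concentration decay series follows the closed form", {
  p <- gen_pk_series(16, 13, c(0, 13, 60), noise_cv = 0)
  expect_equal(p$concentrations[1L], 16)
  expect_equal(p$concentrations[2L], 8)
  expect_equal(p$concentrations[3L], 16 * 2^(-60 / 13))
  expect_error(gen_pk_series(0, 13, 0:3), "outside")
})

test_that("session generator: structure, suppression and basal mixture", {
  expect_length(gen_session(0, seed = 1), 0L)

  # full suppression: inhibited units emit no post-injection bursts
  sess <- gen_session(12, frac_inhibited = 0.5, inhibition_factor = 0,
                      seed = 21)
  inh <- attr(sess, "inhibited")
  expect_equal(sum(inh), 6L)
  for (s in sess[inh]) {
    post <- window_train(s$train, s$injection_time, s$train$t_stop)
    expect_equal(burst_metrics(post)$bursting_spike_frequency, 0)
  }

  # the high-mode mass puts about 27% of units above the 2-Hz cutoff
  sess2 <- gen_session(97, seed = 22)
  basal <- attr(sess2, "basal_freq")
  expect_lt(abs(sum(basal > 2) - 26), 3 * sqrt(97 * 0.27 * 0.73))

  # no-effect cohort: the z criterion flags at most a small minority
  sess3 <- gen_session(60, frac_inhibited = 0, seed = 23)
  cls <- classify_units(sess3)$classification
  expect_gte(mean(cls == "unchanged"), 0.9)
})

test_that("washout generator delegates to the model and layers noise", {
  ket <- build_model("ketamine")
  veh <- gen_washout_dataset(ket, 0, noise_sd = 0, seed = 1)
  expect_true(all(abs(veh$normalized_amplitude - 1) < 1e-9))

  clean <- gen_washout_dataset(ket, 100, noise_sd = 0, seed = 1)
  pred <- run_washout_experiment(ket, 100)
  expect_equal(clean$normalized_amplitude, pred$normalized_amplitude)

  noisy <- gen_washout_dataset(ket, 100, noise_sd = 0.05, seed = 1)
  expect_false(identical(noisy$normalized_amplitude, pred$normalized_amplitude))
  expect_lt(max(abs(noisy$normalized_amplitude - pred$normalized_amplitude)),
            0.05 * 5)

  mem <- gen_washout_dataset(build_model("memantine"), 100, noise_sd = 0,
                             seed = 1)
  expect_lt(blockade_recovery(mem)$blockade_50_60,
            blockade_recovery(clean)$blockade_50_60)
})
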