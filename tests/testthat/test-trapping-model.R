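test_that("model construction and drug presets", {
  ket <- build_model("ketamine")
  expect_equal(ket$Kd, 0.8)
  expect_equal(ket$koff0, log(2) / 9)

  expect_equal(receptor_model(kon = 1, koff0 = 1)$Kd, 1)

  mem <- build_model("memantine")
  expect_equal(mem$Kd, 0.8)  # similar affinity ...
  expect_gte(mem$koff0 / ket$koff0, 10)  # ... but faster off-rate

  expect_error(receptor_model(kon = -1, koff0 = 1), "outside")
  expect_error(receptor_model(kon = 0, koff0 = 1), "outside")
})

test_that("steady-state occupancy follows the binding isotherm", {
  ket <- build_model("ketamine")
  expect_equal(equilibrium_occupancy(ket, 0), 0)
  expect_equal(equilibrium_occupancy(ket, 0.8), 0.5, tolerance = 1e-9)
  expect_equal(equilibrium_occupancy(ket, 3 * 0.8), 0.75, tolerance = 1e-9)

  # numeric stationary solution vs the analytic isotherm across the range
  cc <- c(0.05, 0.2, 0.8, 2, 10, 100)
  expect_equal(equilibrium_occupancy(ket, cc), cc / (cc + ket$Kd),
               tolerance = 1e-9)

  # half-occupancy concentration equals the dissociation constant
  expect_equal(half_occupancy_conc(ket), 0.8, tolerance = 1e-9)
})

test_that("master-equation integration matches a fine-step oracle", {
  m <- receptor_model(kon = 0.1, koff0 = 0.08, alpha = 50, beta_drive = 100,
                      mg_open_scale = 0.5, depol_factor = 3)
  p0 <- c(C = 0.4, O = 0.1, OB = 0.2, CB = 0.3)
  cases <- list(
    list(in_event = TRUE, in_depol = FALSE, conc = 5, t = 0.05),
    list(in_event = FALSE, in_depol = FALSE, conc = 0, t = 0.05),
    list(in_event = TRUE, in_depol = TRUE, conc = 1.5, t = 0.05))
  for (cs in cases) {
    ev <- if (cs$in_event) data.frame(time = 0, duration = cs$t)
          else data.frame(time = numeric(), duration = numeric())
    dp <- if (cs$in_depol) data.frame(start = 0, end = cs$t)
          else data.frame(start = numeric(), end = numeric())
    pr <- stim_protocol(events = ev, depol = dp, conc = cs$conc)
    sim <- simulate_trapping(m, pr, t_end = cs$t, p0 = p0)
    got <- as.numeric(sim[nrow(sim), c("C", "O", "OB", "CB")])
    want <- oracle_propagate(oracle_Q(m, cs$conc, cs$in_event, cs$in_depol),
                             p0, cs$t)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("probability is conserved and occupancies stay in [0, 1]", {
  sim <- attr(run_washout_experiment(build_model("ketamine"), 100), "sim")
  tot <- sim$C + sim$O + sim$OB + sim$CB
  expect_lt(max(abs(tot - 1)), 1e-9)
  expect_true(all(sim$C >= 0 & sim$O >= 0 & sim$OB >= 0 & sim$CB >= 0))
  expect_true(all(sim$blocked <= 1 + 1e-12))
})

test_that("trapping conserves the blocked fraction without channel opening", {
  m <- build_model("ketamine", spont_event_rate = 0)
  pr <- stim_protocol(conc = 0)
  sim <- simulate_trapping(m, pr, t_end = 3600,
                           p0 = c(C = 0, O = 0, OB = 0, CB = 1),
                           sample_times = c(60, 600, 1800))
  expect_equal(sim$blocked, rep(1, nrow(sim)), tolerance = 1e-12)
})

test_that("frequent openings at zero concentration unblock monotonically", {
  m <- build_model("ketamine")
  pr <- stim_protocol(events = data.frame(time = seq(0, 59.9, by = 0.1),
                                          duration = 0.002),
                      conc = 0)
  sim <- simulate_trapping(m, pr, t_end = 60,
                           p0 = c(C = 0, O = 0, OB = 0, CB = 1))
  expect_true(all(diff(sim$blocked) <= 1e-12))
  expect_lt(sim$blocked[nrow(sim)], sim$blocked[1L])
})

test_that("ambient concentration drives the blocked fraction bidirectionally", {
  # from half-blocked, a 3-min 40-Hz train at 0.23 uM (below Kd) unbinds,
  # the same train at 6 uM (above Kd) binds more
  m <- build_model("ketamine", mg_open_scale = 0.2)
  ev <- data.frame(time = seq(0, 180, by = 0.025), duration = 0.002)
  p0 <- c(C = 0.5, O = 0, OB = 0, CB = 0.5)
  lo <- simulate_trapping(m, stim_protocol(events = ev, conc = 0.23), 180, p0 = p0)
  hi <- simulate_trapping(m, stim_protocol(events = ev, conc = 6), 180, p0 = p0)
  expect_lt(lo$blocked[nrow(lo)], 0.5)
  expect_gt(hi$blocked[nrow(hi)], 0.5)
})

test_that("the apparent in vivo off-rate is orders of magnitude slower than in solution", {
  # with only spontaneous openings, the blocked fraction has lost less than
  # half after 100x the 13-s in-solution dissociation time
  m <- build_model("ketamine")
  sim <- simulate_trapping(m, stim_protocol(conc = 0), t_end = 1300,
                           p0 = c(C = 0, O = 0, OB = 0, CB = 1))
  expect_gt(sim$blocked[nrow(sim)], 0.5)
})

test_that("apparent IC50: isotherm limit and magnesium shift", {
  ket <- build_model("ketamine")
  cc <- c(0.05, 0.2, 0.8, 3, 10, 40)
  eq <- dose_inhibition_ic50(ket, cc, mode = "equilibrium")
  expect_equal(eq$ic50, ket$Kd, tolerance = 1e-6)
  expect_true(all(diff(eq$inhibition) > 0))

  mg <- build_model("ketamine", mg_open_scale = 0.2)
  tr <- dose_inhibition_ic50(mg, c(0.5, 2, 5, 20, 80, 300))
  expect_gt(tr$ic50, ket$Kd)
  expect_true(all(diff(tr$inhibition) >= 0))

  expect_error(dose_inhibition_ic50(ket, c(1e-6, 2e-6, 5e-6, 1e-5, 2e-5),
                                    mode = "equilibrium"),
               class = "habtrap_out_of_range")
  expect_error(dose_inhibition_ic50(ket, c(1, 2)), "at least 5")
})

test_that("explicit Euler integration agrees with exact stepping and checks stability", {
  m <- receptor_model(kon = 0.1, koff0 = 0.08, alpha = 20, beta_drive = 40)
  pr <- stim_protocol(events = data.frame(time = c(0.5, 2), duration = 0.05),
                      conc = 2)
  a <- simulate_trapping(m, pr, t_end = 3)
  b <- simulate_trapping(m, pr, t_end = 3, method = "euler", dt = 1e-4)
  expect_equal(b$blocked, a$blocked, tolerance = 1e-3)
  expect_error(simulate_trapping(m, pr, t_end = 3, method = "euler", dt = 0.5),
               class = "habtrap_stability_error")
})

test_that("kick-off protocol builder produces the paired-stimulation schedule", {
  kp <- make_kickoff_protocol()
  expect_equal(nrow(kp$events), 30L)  # 2 sessions x 5 pairings x 3 pulses
  expect_equal(nrow(kp$depol), 10L)
  expect_true(all(kp$depol$end - kp$depol$start == 3))
  # pulses at 1 Hz within each 3-s pairing
  expect_equal(kp$events$time[1:3], c(0, 1, 2))

  pre <- make_kickoff_protocol(depol = "absent")
  expect_equal(pre$events, kp$events)
  expect_equal(nrow(pre$depol), 0L)

  expect_equal(nrow(make_kickoff_protocol(n_sessions = 0)$events), 0L)
})

test_that("washout: persistence, drug contrast and activity-dependent release", {
  ket <- build_model("ketamine")
  veh <- run_washout_experiment(ket, 0)
  expect_true(all(abs(veh$normalized_amplitude - 1) < 1e-9))

  # residual blockade at 50-60 min: ketamine (trapped) >> memantine
  wk <- blockade_recovery(run_washout_experiment(ket, 100))
  wm <- blockade_recovery(run_washout_experiment(build_model("memantine"), 100))
  expect_gt(wk$blockade_50_60, wm$blockade_50_60)
  expect_gt(wk$blockade_50_60, 50)   # most of the block persists
  expect_lt(wm$blockade_50_60, wk$max_blockade / 2)

  # kick-off releases trapped drug; presynaptic stimulation alone barely does
  mg <- build_model("ketamine", mg_open_scale = 0.2)
  none <- blockade_recovery(run_washout_experiment(mg, 100))$blockade_50_60
  kick <- blockade_recovery(run_washout_experiment(mg, 100,
                                                   kickoff = "paired"))$blockade_50_60
  pre <- blockade_recovery(run_washout_experiment(mg, 100,
                                                  kickoff = "absent"))$blockade_50_60
  expect_lt(kick, pre)
  expect_lt(pre, none + 1e-9)
  expect_lt(none - pre, 0.35 * (none - kick))
})

test_that("single-channel Gillespie mode is reproducible and well-formed", {
  m <- build_model("ketamine")
  pr <- stim_protocol(events = data.frame(time = seq(0, 59, by = 1),
                                          duration = 0.002),
                      conc = 10)
  g1 <- simulate_gillespie(m, pr, t_end = 60, seed = 5)
  g2 <- simulate_gillespie(m, pr, t_end = 60, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(g1$state %in% c("C", "O", "OB", "CB")))
  expect_true(all(diff(g1$time) >= 0))
})
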