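# build a session whose 100-s-bin bursting-spike counts are prescribed
# exactly: each bin holds short two- or three-spike bursts (ISIs 10/15 ms)
# well separated from each other and from bin edges
make_counted_session <- function(base_counts, post_counts,
                                 injection = 600, post_offset = 1200) {
  burst_at <- function(t, k) {
    if (k == 2L) c(t, t + 0.010) else c(t, t + 0.010, t + 0.025)
  }
  fill_bin <- function(count, t0) {
    if (count == 0) return(numeric(0))
    sizes <- if (count %% 2 == 1) c(3L, rep(2L, (count - 3L) / 2L))
             else rep(2L, count / 2L)
    starts <- t0 + 0.1 + (seq_along(sizes) - 1L) * 0.5
    unlist(mapply(burst_at, starts, sizes, SIMPLIFY = FALSE))
  }
  base_start <- injection - length(base_counts) * 100
  spikes <- c(
    unlist(mapply(fill_bin, base_counts,
                  base_start + (seq_along(base_counts) - 1L) * 100)),
    unlist(mapply(fill_bin, post_counts,
                  injection + post_offset + (seq_along(post_counts) - 1L) * 100)))
  tr <- spike_train(sort(spikes), 0, injection + post_offset +
                      length(post_counts) * 100, unit_id = "u1")
  session_recording(tr, injection,
                    epochs = list(baseline = c(0, injection),
                                  post = c(injection, tr$t_stop)))
}

test_that("z-score formula and boundary-inclusive classification", {
  # baseline bins {1, 2, 3} Hz (mu 2, sigma 1), post mean 0.33 -> z = -1.67
  s <- make_counted_session(c(100, 200, 300), c(33, 33, 33))
  zr <- unit_zscore(s, baseline_window = c(-300, 0), post_window = c(1200, 1500))
  expect_equal(zr$baseline_bins, c(1, 2, 3))
  expect_equal(zr$mu, 2)
  expect_equal(zr$sigma, 1)
  expect_equal(zr$xbar, 0.33)
  expect_equal(zr$z, -1.67)
  expect_equal(zr$classification, "inhibited")

  # post equal to the baseline mean -> z = 0, unchanged
  s2 <- make_counted_session(c(100, 200, 300), c(200, 200, 200))
  zr2 <- unit_zscore(s2, baseline_window = c(-300, 0), post_window = c(1200, 1500))
  expect_equal(zr2$z, 0)
  expect_equal(zr2$classification, "unchanged")

  # symmetric excitation flags the other tail
  s3 <- make_counted_session(c(100, 200, 300), c(370, 370, 370))
  zr3 <- unit_zscore(s3, baseline_window = c(-300, 0), post_window = c(1200, 1500))
  expect_equal(zr3$classification, "excited")

  # constant baseline: sigma 0 is unclassifiable, not silently zero
  s4 <- make_counted_session(c(200, 200, 200), c(100, 100, 100))
  expect_error(unit_zscore(s4, baseline_window = c(-300, 0),
                           post_window = c(1200, 1500)),
               class = "habtrap_degenerate_baseline")
})

test_that("z is invariant to affine rescaling of the binned metric", {
  s <- make_counted_session(c(100, 150, 300), c(60, 90, 120))
  zr <- unit_zscore(s, baseline_window = c(-300, 0), post_window = c(1200, 1500))
  z_of <- function(b, p) (mean(p) - mean(b)) / sd(b)
  for (a in c(0, -3)) for (k in c(1, 2.5)) {
    expect_equal(z_of(a + k * zr$baseline_bins, a + k * zr$post_bins), zr$z)
  }
})

test_that("null cohort: at most 5% flagged per tail", {
  sess <- gen_session(1000, frac_inhibited = 0, seed = 4242)
  cls <- classify_units(sess)$classification
  expect_lte(mean(cls == "inhibited"), 0.05)
  expect_lte(mean(cls == "excited"), 0.05)
  expect_lt(1 - stats::pnorm(1.67), 0.05)  # threshold/significance consistency
})

test_that("classification is monotone in suppression strength", {
  frac_flagged <- function(factor) {
    mean(unlist(lapply(1:3, function(sd0) {
      sess <- gen_session(60, frac_inhibited = 0.4, inhibition_factor = factor,
                          seed = 1000 + sd0)
      classify_units(sess)$classification == "inhibited"
    })))
  }
  f <- vapply(c(1, 0.3, 0), frac_flagged, numeric(1L))
  expect_true(all(diff(f) >= 0))
  expect_gt(f[3L], f[1L])
})

test_that("basal 2-Hz split bookkeeping", {
  expect_equal(basal_split(rep(0, 10))$n_high, 0L)

  basal <- c(rep(3, 26), rep(1, 71))
  sp <- basal_split(basal)
  expect_equal(sp$n_high, 26L)
  expect_equal(sp$n_low, 71L)
  expect_equal(sp$frac_high, 26 / 97)
  expect_equal(round(100 * sp$frac_high), 27)

  # the boundary value goes to the low group ("larger than 2 Hz")
  expect_equal(basal_split(c(2, 2.001))$n_high, 1L)

  # inhibition confined to the high mode lands mostly in the > 2 Hz group
  sess <- gen_session(80, frac_inhibited = 0.25, inhibition_factor = 0.05,
                      inhibit_high_only = TRUE, seed = 31)
  u <- classify_units(sess)
  sp2 <- basal_split(u$basal_freq, u$classification == "inhibited")
  expect_gt(sp2$inhibited_share_high, 0.5)
})

test_that("percentage-blockade formulas", {
  pb <- percent_blockade_group(39.09, 17.58)
  expect_equal(pb$group_mean, 100 * (39.09 - 17.58) / 39.09)
  expect_equal(round(pb$group_mean, 1), 55)

  expect_equal(percent_blockade_group(c(10, 10), 10)$percent_blockade, 0)
  expect_equal(percent_blockade_group(c(10, 10), 0)$percent_blockade, 100)
  expect_error(percent_blockade_group(c(-1, 1), 5),
               class = "habtrap_undefined_blockade")

  expect_equal(percent_blockade_timecourse(4, 1), 75)
  expect_equal(percent_blockade_timecourse(4, 4), 0)
  expect_equal(percent_blockade_timecourse(4, 8), -100)
  expect_error(percent_blockade_timecourse(0, 1),
               class = "habtrap_undefined_blockade")
})
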