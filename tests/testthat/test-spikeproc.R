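test_that("PSTH rates, baseline and spike-mass conservation", {
  ev <- data.frame(onset_s = seq(0, by = 0.25, length.out = 45))
  none <- data.frame(unit_id = character(0), spike_time_s = numeric(0))
  p0 <- compute_psth(none, ev)
  expect_true(all(p0$rate == 0))
  expect_equal(p0$baseline_mean, 0)

  # one spike at +7.5 ms on each trial -> 200 Hz in the [5,10) ms bin
  one <- data.frame(unit_id = "u", spike_time_s = ev$onset_s + 0.0075)
  p1 <- compute_psth(one, ev, bin_width = 0.005)
  hit <- which(p1$bin_mid > 0.005 & p1$bin_mid < 0.01)
  expect_equal(p1$rate[hit], 200)
  expect_equal(sum(p1$rate[-hit]), 0)

  # halving resolution conserves total spike mass
  spikes <- data.frame(unit_id = "u",
                       spike_time_s = rep(ev$onset_s, 3) +
                         runif(135, 0, 0.1))
  p5 <- compute_psth(spikes, ev, bin_width = 0.005)
  p10 <- compute_psth(spikes, ev, bin_width = 0.01)
  mass <- function(p) sum(p$rate * diff(p$bin_edges)) * p$n_trials
  expect_equal(mass(p5), mass(p10))
  expect_equal(mass(p5), 135)
  expect_equal(length(p10$rate), ceiling(length(p5$rate) / 2))
  expect_error(compute_psth(none, ev[0, , drop = FALSE]), "at least one")
})

test_that("extremum finding applies the strict 3-SD rule", {
  flat <- fake_psth(rep(5, 30), baseline_mean = 5, baseline_sd = 1)
  ex <- find_response_extrema(flat)
  expect_equal(nrow(ex$peaks), 0)
  expect_equal(nrow(ex$troughs), 0)

  r <- rep(2, 30); r[10] <- 20
  ex1 <- find_response_extrema(fake_psth(r, baseline_mean = 2,
                                         baseline_sd = 0.5))
  expect_equal(nrow(ex1$peaks), 1)
  expect_equal(ex1$peaks$rate, 20)

  # a peak exactly at baseline_mean + 3 SD is excluded (strict inequality)
  r2 <- rep(2, 30); r2[10] <- 2 + 3 * 0.5
  ex2 <- find_response_extrema(fake_psth(r2, baseline_mean = 2,
                                         baseline_sd = 0.5))
  expect_equal(nrow(ex2$peaks), 0)

  # trough threshold floors at zero: when baseline - 3 SD is negative no
  # nonnegative rate can qualify
  r3 <- rep(0.5, 30); r3[12] <- 0
  ex3 <- find_response_extrema(fake_psth(r3, baseline_mean = 0.5,
                                         baseline_sd = 0.2))
  expect_equal(nrow(ex3$troughs), 0)
  r4 <- rep(10, 30); r4[12] <- 1
  ex4 <- find_response_extrema(fake_psth(r4, baseline_mean = 10,
                                         baseline_sd = 1))
  expect_equal(nrow(ex4$troughs), 1)

  # plateaus report their leftmost bin
  r5 <- rep(1, 30); r5[8:10] <- 15
  ex5 <- find_response_extrema(fake_psth(r5, baseline_mean = 1,
                                         baseline_sd = 0.5))
  expect_equal(nrow(ex5$peaks), 1)
  expect_equal(ex5$peaks$time, fake_psth(r5)$bin_mid[8])
})

test_that("profile taxonomy recovers every class on noise-free extrema", {
  mk <- function(rate, base = 1, sd = 0.2) {
    classify_response_profile(
      find_response_extrema(fake_psth(rate, baseline_mean = base,
                                      baseline_sd = sd)))
  }
  base <- rep(1, 20)                      # 5 ms bins spanning 0-100 ms
  onset <- base; onset[2] <- 30           # single max at 7.5 ms
  expect_equal(mk(onset)$label, "onset")
  expect_true(mk(onset)$sound_responsive)
  sustained <- base; sustained[6] <- 30   # single max at 27.5 ms
  expect_equal(mk(sustained)$label, "sustained")
  ei <- rep(5, 20); ei[4] <- 40; ei[8] <- 0.1
  expect_equal(mk(ei, base = 5, sd = 1)$label, "E-I")
  ie <- rep(5, 20); ie[3] <- 0.1; ie[8] <- 40
  expect_equal(mk(ie, base = 5, sd = 1)$label, "I-E")
  biph <- base; biph[2] <- 30; biph[7] <- 25
  expect_equal(mk(biph)$label, "biphasic")
  mixed <- base; mixed[2] <- 30; mixed[5] <- 25; mixed[9] <- 28
  expect_equal(mk(mixed)$label, "mixed")
  # combination labels for offset-window responses
  both <- base; both[2] <- 30; both[14] <- 25
  expect_equal(mk(both)$label, "onset/offset")
  # exclusions: offset-only, inhibited-only, unresponsive
  off <- base; off[14] <- 30
  expect_equal(mk(off)$label, "offset")
  expect_false(mk(off)$sound_responsive)
  inh <- rep(8, 20); inh[5] <- 0.5
  expect_equal(mk(inh, base = 8, sd = 1)$label, "inhibited")
  expect_false(mk(inh, base = 8, sd = 1)$sound_responsive)
  expect_equal(mk(base)$label, "unresponsive")
  expect_false(mk(base)$sound_responsive)
})

test_that("trial firing rate uses a half-open window", {
  ev <- data.frame(onset_s = c(0, 1))
  sp <- data.frame(unit_id = "u",
                   spike_time_s = c(0.02, 0.05, 0.09, 1.0, 1.1))
  expect_equal(trial_firing_rate(sp, ev, c(0, 0.1)), c(30, 10))
  # spike exactly at window end is excluded
  sp2 <- data.frame(unit_id = "u", spike_time_s = 0.1)
  expect_equal(trial_firing_rate(sp2, ev, c(0, 0.1)), c(0, 0))
  expect_equal(trial_firing_rate(sp2, ev, c(0.1, 0.2)), c(10, 0))
  none <- data.frame(unit_id = character(0), spike_time_s = numeric(0))
  expect_equal(trial_firing_rate(none, ev, c(0, 0.1)), c(0, 0))
  expect_error(trial_firing_rate(sp, ev, c(0.1, 0.1)), "positive")
})

test_that("laser screen flags only infragranular units suppressed in both", {
  # Table-style example: silence 11 -> 4.1 Hz is ~63% reduction
  res <- laser_suppression_screen(rep(11, 20), rep(4.1, 20),
                                  rep(18, 20), rep(9.6, 20))
  expect_equal(res$reduction_silence_pct, (11 - 4.1) / 11 * 100,
               tolerance = 1e-9)
  expect_gt(res$reduction_silence_pct, 30)
  expect_true(res$putative_cc)

  none <- laser_suppression_screen(rep(10, 5), rep(10, 5),
                                   rep(12, 5), rep(12, 5))
  expect_equal(none$reduction_silence_pct, 0)
  expect_false(none$putative_cc)

  # both reductions must clear 30%
  onesided <- laser_suppression_screen(rep(10, 5), rep(7.1, 5),
                                       rep(10, 5), rep(5, 5))
  expect_lt(onesided$reduction_silence_pct, 30)
  expect_false(onesided$putative_cc)
  expect_false(laser_suppression_screen(rep(10, 5), rep(5, 5),
                                        rep(10, 5), rep(5, 5),
                                        infragranular = FALSE)$putative_cc)
  und <- laser_suppression_screen(rep(0, 5), rep(0, 5),
                                  rep(10, 5), rep(5, 5))
  expect_true(und$undefined)
  expect_false(und$putative_cc)
})

test_that("raising laser-on rates never flags an unflagged unit", {
  off_s <- rep(10, 10); off_t <- rep(20, 10)
  on_s <- seq(3, 12, length.out = 10)
  flags <- vapply(seq(3, 25, by = 1), function(on_t_mean) {
    laser_suppression_screen(off_s, on_s, off_t,
                             rep(on_t_mean, 10))$putative_cc
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))  # monotone non-increasing
})
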