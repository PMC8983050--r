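test_that("context labelling yields the designed trial counts", {
  spec <- default_spec(seed = 5)
  pair <- make_oddball_pair(spec)
  casc <- make_cascade(f1 = spec$f1)
  ms <- make_many_standards(casc, seed = 2)
  tt <- label_contexts(pair, casc, ms)
  for (f in c(spec$f1, spec$f2)) {
    sub <- tt[tt$freq_hz == f, ]
    cnt <- table(sub$context, sub$condition)
    expect_equal(cnt["last_standard", "baseline"], 45)
    expect_equal(cnt["deviant", "baseline"], 45)
    expect_equal(cnt["cascade", "baseline"], 45)
    # laser deviants and laser standards are block-matched
    expect_equal(cnt["deviant", "laser"], cnt["last_standard", "laser"])
    expect_equal(cnt["many_standards", "baseline"] +
                   cnt["many_standards", "laser"], 90)
  }
  # a cascade missing an oddball frequency is rejected
  bad <- make_cascade(f1 = spec$f1 * 3)
  expect_error(label_contexts(pair, bad), "both oddball frequencies")
})

test_that("context rates recover generating rates and partition laser trials", {
  spec <- default_spec(seed = 6)
  pair <- make_oddball_pair(spec)
  casc <- make_cascade(f1 = spec$f1)
  tt <- label_contexts(pair, casc)
  gt <- recovery_unit("u", c(standard = 5, deviant = 10, cascade = 5),
                      gain = c(standard = 3, deviant = 3, cascade = 3))
  spikes <- list(seq_a = simulate_unit(gt, pair$seq_a, seed = 1),
                 seq_b = simulate_unit(gt, pair$seq_b, seed = 2),
                 cascade = simulate_unit(gt, casc, seed = 3))
  cr <- compute_context_rates(spikes, tt, window = c(0, 0.05))
  base <- cr$rates[cr$rates$condition == "baseline", ]
  se <- function(r, n) sqrt(r / (0.05 * n))
  for (i in seq_len(nrow(base))) {
    expect_lt(abs(base$fr_stan[i] - 5), 3 * se(5, 45))
    expect_lt(abs(base$fr_dev[i] - 10), 3 * se(10, 45))
    expect_lt(abs(base$fr_casc[i] - 5), 3 * se(5, 45))
  }
  expect_true(all(base$n_stan == 45 & base$n_dev == 45 & base$n_casc == 45))
  # laser trials (gain 3) never leak into baseline means
  las <- cr$rates[cr$rates$condition == "laser", ]
  expect_gt(mean(las$fr_stan), 2 * mean(base$fr_stan))
  zero <- list(seq_a = data.frame(unit_id = character(0), spike_time_s = numeric(0)),
               seq_b = data.frame(unit_id = character(0), spike_time_s = numeric(0)),
               cascade = data.frame(unit_id = character(0),
                                    spike_time_s = numeric(0)))
  cr0 <- compute_context_rates(zero, tt, window = c(0, 0.05))
  expect_true(all(cr0$rates$fr_stan == 0))
})

test_that("index decomposition matches hand-computed triples", {
  flat <- compute_indices(5, 5, 5)
  expect_equal(unlist(flat[1, c("iMM", "iPE", "iRS")]),
               c(iMM = 0, iPE = 0, iRS = 0))
  a <- compute_indices(fr_stan = 5, fr_casc = 5, fr_dev = 10)
  expect_equal(a$norm_N, sqrt(150))
  expect_equal(a$iPE, 5 / sqrt(150), tolerance = 1e-12)   # ~ 0.4082
  expect_equal(a$iRS, 0)
  expect_equal(a$iMM, a$iPE)
  b <- compute_indices(fr_stan = 10, fr_casc = 5, fr_dev = 0)
  expect_equal(b$iPE, -5 / sqrt(125), tolerance = 1e-12)  # ~ -0.4472
  expect_equal(b$iRS, -5 / sqrt(125), tolerance = 1e-12)
  expect_equal(b$iMM, -10 / sqrt(125), tolerance = 1e-12) # ~ -0.8944
  z <- compute_indices(0, 0, 0)
  expect_false(z$defined)
  expect_error(compute_indices(-1, 2, 3), "nonnegative")
})

test_that("index identity, bounds and scale invariance hold on random triples", {
  set.seed(42)
  r <- matrix(runif(3000, 0, 100), ncol = 3)
  idx <- compute_indices(r[, 1], r[, 2], r[, 3])
  expect_true(all(abs(idx$iMM - (idx$iPE + idx$iRS)) < 1e-12))
  expect_true(all(abs(idx$iMM) <= 1 & abs(idx$iPE) <= 1 &
                    abs(idx$iRS) <= 1))
  scaled <- compute_indices(7.3 * r[, 1], 7.3 * r[, 2], 7.3 * r[, 3])
  expect_equal(scaled$iMM, idx$iMM, tolerance = 1e-12)
  expect_equal(scaled$iPE, idx$iPE, tolerance = 1e-12)
  # bound attained when two of three rates vanish
  expect_equal(abs(compute_indices(0, 0, 8)$iMM), 1)
})

test_that("unit classification agrees with the rank-sum oracle", {
  expect_equal(classify_unit(rep(5, 45), rep(5, 45))$adapting_class,
               "nonadapting")
  expect_equal(classify_unit(rep(5, 45), rep(5, 45))$p_value, 1)

  set.seed(7)
  stan <- rpois(45, 5); dev <- rpois(45, 20)
  res <- classify_unit(stan, dev)
  expect_equal(res$adapting_class, "adapting")
  expect_gt(res$direction, 0)
  oracle <- suppressWarnings(wilcox.test(dev, stan, exact = FALSE,
                                         correct = TRUE))$p.value
  expect_equal(res$p_value, oracle)
  flipped <- classify_unit(dev, stan)
  expect_equal(flipped$adapting_class, "facilitating")
  expect_lt(flipped$direction, 0)
  # a unit classified adapting always has iMM > 0 on the same trials
  expect_gt(compute_indices(mean(stan), mean(c(stan, dev)),
                            mean(dev))$iMM, 0)
  expect_error(classify_unit(1, c(1, 2)), "2 trials")
})

test_that("per-context laser deltas carry sign and antisymmetry", {
  rates <- data.frame(
    freq_hz = c(1000, 1000), condition = c("baseline", "laser"),
    fr_stan = c(10, 13), fr_casc = c(10, 10), fr_dev = c(20, 15))
  cr <- structure(list(rates = rates, trials = NULL),
                  class = "context_rates")
  d <- fr_change_by_context(cr)
  expect_equal(d$delta_hz[d$context == "standard"], 3)
  expect_equal(d$delta_hz[d$context == "cascade"], 0)
  expect_equal(d$delta_hz[d$context == "deviant"], -5)
  # swapping condition labels flips every delta
  sw <- rates; sw$condition <- rev(sw$condition)
  d2 <- fr_change_by_context(structure(list(rates = sw),
                                       class = "context_rates"))
  expect_equal(d2$delta_hz, -d$delta_hz)
  expect_error(fr_change_by_context(structure(
    list(rates = rates[1, ]), class = "context_rates")), "laser")
})

test_that("standards-by-position profile detects repetition ramps", {
  spec <- default_spec(seed = 9)
  pair <- make_oddball_pair(spec)
  ev <- pair$seq_a$events
  # flat generating rate: contrast ~ 0 within its own standard error
  gt <- recovery_unit("u", c(standard = 30, deviant = 30, cascade = 30))
  st <- simulate_unit(gt, pair$seq_a, seed = 3)
  flat <- standards_by_position(st, pair$seq_a, window = c(0, 0.05))
  expect_true(all(is.finite(flat$position_means)))
  se_contrast <- sd(flat$pairs$last_before - flat$pairs$first_after) /
    sqrt(nrow(flat$pairs))
  expect_lt(abs(flat$contrast), 3 * se_contrast)
  expect_gt(flat$n_blocks_used, 0)

  # constructed ramp: rate grows with position in block -> last > first
  set.seed(11)
  ramp_spikes <- unlist(lapply(seq_len(nrow(ev)), function(i) {
    lam <- 0.5 + 0.4 * ev$pos_in_block[i]
    ev$onset_s[i] + runif(rpois(1, lam), 0, 0.05)
  }))
  st2 <- data.frame(unit_id = "u", spike_time_s = sort(ramp_spikes))
  ramp <- standards_by_position(st2, pair$seq_a, window = c(0, 0.05))
  expect_gt(ramp$contrast, 0)
  expect_gt(mean(ramp$pairs$last_before), mean(ramp$pairs$first_after))
  # position means rise towards the deviant
  expect_gt(ramp$position_means[["-1"]], ramp$position_means[["+1"]])
})

test_that("cascade vs many-standards contrast behaves under the null", {
  x <- c(10, 12, 9, 14, 11, 13, 10, 12)
  same <- compare_cascade_many_standards(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, 0)
  set.seed(3)
  casc <- rnorm(60, 20, 3); ms <- casc * 2
  strong <- compare_cascade_many_standards(casc, ms)
  expect_lt(strong$p_value, 1e-6)
  expect_lt(strong$direction, 0)
  expect_error(compare_cascade_many_standards(1:5, 1:4), "paired")
})
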