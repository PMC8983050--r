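test_that("frequency-response-function stimulus matches the design", {
  s <- make_frf_sequence(seed = 11)
  ev <- s$events
  expect_equal(nrow(ev), 1000)                      # 50 freqs x 20 reps
  expect_equal(length(unique(ev$freq_hz)), 50)
  expect_true(all(table(ev$freq_hz) == 20))
  expect_equal(range(ev$freq_hz), c(1000, 70000))
  expect_true(all(ev$level_db == 70))
  expect_true(all(ev$context == "frf"))
  # presentation rate: 50 ms tone + 200 ms ISI = 4 Hz
  expect_equal(unique(diff(ev$onset_s)), 0.25, tolerance = 1e-12)
  expect_identical(ev, make_frf_sequence(seed = 11)$events)
  expect_false(identical(ev$freq_hz, make_frf_sequence(seed = 12)$events$freq_hz))
})

test_that("frf endpoint case and validation errors", {
  s <- make_frf_sequence(n_freqs = 2, f_lo = 1000, f_hi = 2000, n_reps = 1)
  expect_equal(sort(s$events$freq_hz), c(1000, 2000))
  expect_error(make_frf_sequence(f_lo = -1), "positive")
  expect_error(make_frf_sequence(n_freqs = 1), "n_freqs")
})

test_that("tuning stimulus is a full factorial grid", {
  s <- make_tuning_sequence(seed = 2)
  expect_equal(nrow(s$events), 2000)                # 50 x 8 x 5
  expect_equal(sort(unique(s$events$level_db)), seq(35, 70, by = 5))
  s2 <- make_tuning_sequence(n_freqs = 3, levels = c(40, 60), n_reps = 4)
  expect_equal(nrow(s2$events), 24)
  cell <- table(s2$events$freq_hz, s2$events$level_db)
  expect_true(all(cell == 4))
  s3 <- make_tuning_sequence(n_freqs = 2, f_lo = 1000, f_hi = 2000,
                             levels = 70, n_reps = 1)
  expect_equal(nrow(s3$events), 2)
  expect_error(make_tuning_sequence(levels = numeric(0)), "nonempty")
  expect_error(make_tuning_sequence(levels = c(50, 40)), "increasing")
})

test_that("block allocation hits the printed totals and balance", {
  blocks <- allocate_block_counts(default_spec())
  expect_equal(nrow(blocks), 135)
  expect_equal(sum(blocks$n_standards), 1115)
  expect_equal(sum(blocks$n_standards + 1), 1250)
  sums <- tapply(blocks$n_standards, blocks$laser_condition, sum)
  expect_lte(diff(range(sums)), 1)
  for (cond in unique(blocks$laser_condition)) {
    n <- blocks$n_standards[blocks$laser_condition == cond]
    expect_true(all(n >= 3 & n <= 17))
    expect_true(all(c(3, 17) %in% n))               # endpoints everywhere
  }
  # conditions rotate deviant-laser -> standard-laser -> no-laser
  expect_equal(blocks$laser_condition[1:6],
               rep(c("deviant_laser", "standard_laser", "no_laser"), 2))
})

test_that("block allocation forced and exhaustively-checked cases", {
  sp <- oddball_spec(blocks_per_condition = 1, standards_range = c(3, 3),
                     total_tones = 12)
  b <- allocate_block_counts(sp)
  expect_equal(b$n_standards, rep(3L, 3))

  # 2 blocks/condition in [3,5], 30 tones: 24 standards over 6 blocks with
  # both endpoints per condition forces the multiset {3,5} in each condition
  # (exhaustive check below)
  sp2 <- oddball_spec(blocks_per_condition = 2, standards_range = c(3, 5),
                      total_tones = 30)
  b2 <- allocate_block_counts(sp2)
  expect_equal(sum(b2$n_standards), 24)
  sums <- tapply(b2$n_standards, b2$laser_condition, sum)
  expect_true(all(sums == 8))
  admissible <- list()
  for (x in 3:5) for (y in x:5) {
    if (x + y == 8 && 3 %in% c(x, y) && 5 %in% c(x, y)) {
      admissible <- c(admissible, list(c(x, y)))
    }
  }
  expect_equal(admissible, list(c(3, 5)))
  for (cond in unique(b2$laser_condition)) {
    expect_equal(sort(b2$n_standards[b2$laser_condition == cond]), c(3L, 5L))
  }
})

test_that("infeasible totals raise an error naming the feasible interval", {
  sp <- oddball_spec(blocks_per_condition = 2, standards_range = c(3, 5),
                     total_tones = 100)
  expect_error(allocate_block_counts(sp), "\\[24, 36\\]")
})

test_that("oddball pair is frozen, swapped and laser-paired", {
  spec <- default_spec(seed = 21)
  pair <- make_oddball_pair(spec)
  a <- pair$seq_a$events; b <- pair$seq_b$events
  expect_equal(nrow(a), 1250)
  expect_equal(nrow(b), 1250)
  # frequency swap f1 <-> f2 reproduces the partner sequence exactly
  swapped <- a
  swapped$freq_hz <- ifelse(abs(a$freq_hz - spec$f1) < 1e-9,
                            spec$f2, spec$f1)
  expect_identical(swapped, b)
  # one laser deviant per deviant-laser block, one laser last-standard per
  # standard-laser block, nothing else
  expect_equal(sum(a$laser), 2 * spec$blocks_per_condition)
  laser_ctx <- table(a$context[a$laser])
  expect_equal(as.integer(laser_ctx[c("deviant", "last_standard")]),
               c(45L, 45L))
  expect_true(all(a$laser_dur_s[a$laser] == 0.1))
  expect_true(all(a$laser_onset_s == 0))
  # every block ends with its single deviant, preceded by a last_standard
  per_block <- split(a$context, a$block)
  expect_true(all(vapply(per_block, function(x)
    x[length(x)] == "deviant" && sum(x == "deviant") == 1 &&
      x[length(x) - 1] == "last_standard", logical(1))))
  # determinism
  expect_identical(a, make_oddball_pair(spec)$seq_a$events)
})

test_that("validate_sequence reports run lengths and degenerate input", {
  v <- validate_sequence(make_oddball_pair(default_spec())$seq_a)
  expect_length(v$violations, 0)
  expect_equal(range(v$run_lengths), c(3, 17))
  expect_equal(v$n_deviants, 135)
  expect_equal(v$standard_fraction, 1115 / 1250)
  empty <- structure(list(kind = "oddball",
                          events = data.frame(), spec = NULL, seed = 1),
                     class = "stim_sequence")
  ve <- validate_sequence(empty)
  expect_true(ve$degenerate)
  expect_equal(ve$n_events, 0)
})

test_that("cascade is evenly log-spaced with adjacent oddball tones", {
  casc <- make_cascade(f1 = 10000)
  ev <- casc$events
  freqs <- sort(unique(ev$freq_hz))
  expect_length(freqs, 10)
  expect_equal(diff(log2(freqs)), rep(0.5, 9), tolerance = 1e-9)
  expect_equal(max(freqs) / min(freqs), 2^4.5, tolerance = 1e-9)
  # oddball pair occupies adjacent positions
  expect_true(all(abs(casc$spec$oddball_freqs -
                        c(10000, 10000 * 2^0.5)) < 1e-9))
  # within-cycle order is monotone; descending reverses it
  cyc <- ev$freq_hz[ev$block == 0]
  expect_true(all(diff(cyc) > 0))
  desc <- make_cascade(f1 = 10000, direction = "descending")
  expect_equal(desc$events$freq_hz[desc$events$block == 0], rev(cyc))
  expect_equal(sort(unique(desc$events$freq_hz)), freqs)
  # laser on oddball tones in alternate cycles: 45 + 45 trials per frequency
  for (f in casc$spec$oddball_freqs) {
    sel <- abs(ev$freq_hz - f) < 1e-9
    expect_equal(sum(ev$laser[sel]), 45)
    expect_equal(sum(!ev$laser[sel]), 45)
  }
  expect_equal(nrow(make_cascade(n_tones = 2, oddball_pair_position = 1,
                                 n_cycles = 1)$events), 2)
  expect_error(make_cascade(oddball_pair_position = 10), "inside the set")
})

test_that("many-standards shuffle removes adjacent repeats, keeps multisets", {
  casc <- make_cascade(f1 = 8000, n_cycles = 10)
  ms <- make_many_standards(casc, seed = 7)
  expect_equal(validate_sequence(ms)$adjacent_repeats, 0)
  expect_true(all(ms$events$context == "many_standards"))
  # per-cycle frequency multiset conserved
  for (b in unique(casc$events$block)) {
    expect_equal(sort(ms$events$freq_hz[ms$events$block == b]),
                 sort(casc$events$freq_hz[casc$events$block == b]))
  }
  # timing grid untouched
  expect_equal(ms$events$onset_s, casc$events$onset_s)
  expect_identical(ms$events, make_many_standards(casc, seed = 7)$events)
  # two frequencies, one cycle: only the 2 alternations are valid
  two <- make_cascade(f1 = 8000, n_tones = 2, oddball_pair_position = 1,
                      n_cycles = 1)
  perm <- make_many_standards(two, seed = 1)$events$freq_hz
  expect_true(length(unique(perm)) == 2)
  one <- two
  one$events$freq_hz <- 8000
  expect_error(make_many_standards(one), "2 distinct")
})

test_that("event tables round-trip through delimited text", {
  s <- make_cascade(f1 = 10000, n_cycles = 2)
  path <- tempfile(fileext = ".tsv")
  write_events(s, path)
  back <- read_events(path)
  expect_equal(back$freq_hz, s$events$freq_hz)
  expect_equal(back$onset_s, s$events$onset_s)
  expect_equal(back$laser, s$events$laser)
})
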