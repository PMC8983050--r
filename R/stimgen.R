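# Stimulus sequence generators: frequency-response function, tuning curve,
# frozen oddball pair with laser pairings, cascade, and many-standards.
# Sequences are S3 objects holding an event table (one row per tone).

EVENT_COLS <- c("onset_s", "freq_hz", "level_db", "duration_s", "ramp_s",
                "context", "block", "pos_in_block", "laser", "laser_onset_s",
                "laser_dur_s")

new_stim_sequence <- function(kind, events, spec, seed) {
  stopifnot(is.data.frame(events))
  structure(list(kind = kind, events = events, spec = spec, seed = seed),
            class = "stim_sequence")
}

#' @export
print.stim_sequence <- function(x, ...) {
  cat(sprintf("<stim_sequence: %s, %d events, %d laser, seed %s>\n",
              x$kind, nrow(x$events), sum(x$events$laser),
              format(x$seed)))
  invisible(x)
}

# Assemble the event table; onsets on a fixed grid of duration + isi.
build_events <- function(freq_hz, context, block, pos_in_block, laser,
                         level_db, duration_s, ramp_s, isi_s, laser_dur_s) {
  n <- length(freq_hz)
  onset <- (seq_len(n) - 1) * (duration_s + isi_s)
  data.frame(
    onset_s = onset,
    freq_hz = freq_hz,
    level_db = rep_len(level_db, n),
    duration_s = duration_s,
    ramp_s = ramp_s,
    context = context,
    block = block,
    pos_in_block = pos_in_block,
    laser = laser,
    laser_onset_s = 0,
    laser_dur_s = ifelse(laser, laser_dur_s, 0),
    stringsAsFactors = FALSE
  )
}

#' Oddball sequence specification
#'
#' Parameters of the frozen two-tone oddball design: a common standard and a
#' rare deviant separated by half an octave, presented 90:10, divided into
#' deviant-terminated blocks whose number of preceding standards varies over
#' `standards_range`, with laser pairings rotated across blocks
#' (deviant-laser, last-standard-laser, no laser).
#'
#' Defaults are the published design: 50 ms tones with 1 ms ramps, 200 ms
#' inter-stimulus interval (4 Hz presentation), 100 ms laser coincident with
#' tone onset, 45 blocks per laser condition, 3-17 preceding standards, and
#' 1250 tones per sequence.
#'
#' @param f1 Frequency of the first oddball tone (Hz).
#' @param f2 Frequency of the second tone (Hz); must be half an octave above
#'   `f1`.
#' @param standard_fraction Nominal standard probability (0.9 for 90:10).
#' @param blocks_per_condition Number of blocks per laser condition.
#' @param standards_range Integer interval `c(min, max)` of preceding
#'   standards per block.
#' @param total_tones Total number of tone events per sequence.
#' @param tone_duration,isi,ramp Tone duration, inter-stimulus interval and
#'   on/off ramp, seconds.
#' @param level Tone level, dB SPL.
#' @param laser_duration Laser pulse duration, seconds.
#' @param seed Integer seed freezing the block pattern.
#' @return An object of class `oddball_spec`.
#' @export
oddball_spec <- function(f1 = 10000, f2 = f1 * 2^0.5,
                         standard_fraction = 0.9,
                         blocks_per_condition = 45,
                         standards_range = c(3L, 17L),
                         total_tones = 1250,
                         tone_duration = 0.05, isi = 0.2, ramp = 0.001,
                         level = 70, laser_duration = 0.1, seed = 1L) {
  if (f1 <= 0 || f2 <= 0) stop("frequencies must be positive")
  if (abs(f2 / f1 - 2^0.5) > 1e-9) {
    stop("f2 must lie half an octave (factor 2^0.5) above f1")
  }
  standards_range <- as.integer(standards_range)
  if (length(standards_range) != 2 ||
      standards_range[1] > standards_range[2] || standards_range[1] < 0) {
    stop("standards_range must be an ordered nonnegative integer interval")
  }
  if (blocks_per_condition < 1) stop("blocks_per_condition must be >= 1")
  structure(list(f1 = f1, f2 = f2, standard_fraction = standard_fraction,
                 blocks_per_condition = as.integer(blocks_per_condition),
                 standards_range = standards_range,
                 total_tones = as.integer(total_tones),
                 tone_duration = tone_duration, isi = isi, ramp = ramp,
                 level = level, laser_duration = laser_duration,
                 seed = as.integer(seed)),
            class = "oddball_spec")
}

#' Frequency-response-function stimulus
#'
#' A pseudo-random sequence of `n_freqs` log-spaced pure tones spanning
#' `[f_lo, f_hi]`, each repeated `n_reps` times at a single level. Defaults
#' reproduce the published search stimulus: 50 tones, 1-70 kHz, 20
#' repetitions at 70 dB SPL.
#'
#' @param n_freqs Number of distinct frequencies (>= 2).
#' @param f_lo,f_hi Frequency range, Hz.
#' @param n_reps Repetitions per frequency.
#' @param level Level, dB SPL.
#' @param tone_duration,isi,ramp Timing parameters, seconds.
#' @param seed Integer seed for the presentation order.
#' @return A `stim_sequence` whose events are all labelled `"frf"`.
#' @export
make_frf_sequence <- function(n_freqs = 50, f_lo = 1000, f_hi = 70000,
                              n_reps = 20, level = 70,
                              tone_duration = 0.05, isi = 0.2, ramp = 0.001,
                              seed = 1L) {
  if (f_lo <= 0 || f_hi <= 0) stop("frequencies must be positive")
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (n_freqs < 2 || n_reps < 1) stop("n_freqs >= 2 and n_reps >= 1 required")
  freqs <- 2^seq(log2(f_lo), log2(f_hi), length.out = n_freqs)
  order <- with_seed(seed, sample(rep(freqs, n_reps)))
  ev <- build_events(order, "frf", 0L, seq_along(order) - 1L, FALSE,
                     level, tone_duration, ramp, isi, 0)
  new_stim_sequence("frf", ev,
                    list(n_freqs = n_freqs, f_lo = f_lo, f_hi = f_hi,
                         n_reps = n_reps, level = level), seed)
}

#' Tuning-curve stimulus
#'
#' Full factorial frequency-by-level grid in pseudo-random order. Defaults:
#' 50 frequencies, eight levels 35-70 dB SPL in 5 dB steps, five repetitions.
#'
#' @inheritParams make_frf_sequence
#' @param levels Strictly increasing vector of levels, dB SPL.
#' @return A `stim_sequence` with events labelled `"tuning"`.
#' @export
make_tuning_sequence <- function(n_freqs = 50, f_lo = 1000, f_hi = 70000,
                                 levels = seq(35, 70, by = 5), n_reps = 5,
                                 tone_duration = 0.05, isi = 0.2,
                                 ramp = 0.001, seed = 1L) {
  if (length(levels) == 0) stop("levels must be nonempty")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (f_lo <= 0 || f_lo >= f_hi) stop("need 0 < f_lo < f_hi")
  freqs <- 2^seq(log2(f_lo), log2(f_hi), length.out = n_freqs)
  grid <- expand.grid(freq = freqs, level = levels)
  grid <- grid[rep(seq_len(nrow(grid)), n_reps), ]
  perm <- with_seed(seed, sample(nrow(grid)))
  grid <- grid[perm, ]
  ev <- build_events(grid$freq, "tuning", 0L, seq_len(nrow(grid)) - 1L,
                     FALSE, grid$level, tone_duration, ramp, isi, 0)
  new_stim_sequence("tuning", ev,
                    list(n_freqs = n_freqs, levels = levels,
                         n_reps = n_reps), seed)
}

# Build one condition's multiset of preceding-standard counts. Preferred
# construction: one block at every count in [lo, hi] (full coverage), the
# remaining blocks filled as uniformly as the sum budget allows. When the
# block budget or the sum makes that infeasible, fall back to cycling the
# range and walking the sum to the target by unit steps, protecting one
# copy of each endpoint.
condition_counts <- function(n_blocks, lo, hi, target_sum) {
  vals <- seq(lo, hi)
  if (n_blocks >= length(vals)) {
    m <- n_blocks - length(vals)
    budget <- target_sum - sum(vals)
    if ((m == 0 && budget == 0) ||
        (m > 0 && budget >= m * lo && budget <= m * hi)) {
      fill <- if (m > 0) {
        v <- budget %/% m
        rem <- budget - v * m
        c(rep(v + 1L, rem), rep(v, m - rem))
      } else integer(0)
      return(as.integer(c(vals, fill)))
    }
  }
  counts <- rep_len(vals, n_blocks)
  if (n_blocks >= 2) {          # guarantee both endpoints
    counts[1] <- lo
    counts[2] <- hi
  }
  protected <- if (n_blocks >= 2) c(1L, 2L) else integer(0)
  excess <- sum(counts) - target_sum
  idx <- setdiff(order(counts, decreasing = TRUE), protected)
  while (excess > 0) {
    moved <- FALSE
    for (i in idx) {
      if (excess == 0) break
      if (counts[i] > lo) {
        counts[i] <- counts[i] - 1L
        excess <- excess - 1L
        moved <- TRUE
      }
    }
    if (!moved) stop("internal: cannot reach target sum")
  }
  idx <- setdiff(order(counts), protected)
  while (excess < 0) {
    moved <- FALSE
    for (i in idx) {
      if (excess == 0) break
      if (counts[i] < hi) {
        counts[i] <- counts[i] + 1L
        excess <- excess + 1L
        moved <- TRUE
      }
    }
    if (!moved) stop("internal: cannot reach target sum")
  }
  counts
}

#' Allocate per-block standard counts across the three laser conditions
#'
#' Balances the number of preceding standards over the deviant-laser,
#' standard-laser and no-laser conditions: every block's count lies in
#' `standards_range`, the grand total of tones (standards + one deviant per
#' block) equals `total_tones` exactly, per-condition standard sums differ by
#' at most one, and both range endpoints occur in every condition. Block
#' order within a condition is shuffled under the spec seed, and conditions
#' rotate deviant-laser, standard-laser, no-laser.
#'
#' @param spec An [oddball_spec()].
#' @param total_tones Total tone count; defaults to `spec$total_tones`.
#' @return A data.frame with one row per block: `block`, `laser_condition`
#'   (`"deviant_laser"`, `"standard_laser"`, `"no_laser"`), and
#'   `n_standards`.
#' @export
allocate_block_counts <- function(spec, total_tones = spec$total_tones) {
  B <- spec$blocks_per_condition
  lo <- spec$standards_range[1]
  hi <- spec$standards_range[2]
  n_blocks <- 3L * B
  total_standards <- total_tones - n_blocks
  feas <- c(n_blocks * (lo + 1L), n_blocks * (hi + 1L))
  if (total_tones < feas[1] || total_tones > feas[2]) {
    stop(sprintf(
      "total_tones = %d infeasible: with %d blocks and %d-%d standards the feasible total is [%d, %d]",
      total_tones, n_blocks, lo, hi, feas[1], feas[2]))
  }
  # per-condition sums as equal as the integer split allows
  base <- total_standards %/% 3L
  sums <- base + c(rep(1L, total_standards %% 3L),
                   rep(0L, 3L - total_standards %% 3L))
  conditions <- c("deviant_laser", "standard_laser", "no_laser")
  per_cond <- lapply(seq_len(3), function(k) {
    counts <- condition_counts(B, lo, hi, sums[k])
    counts[with_seed(spec$seed + k, sample.int(length(counts)))]
  })
  data.frame(
    block = seq_len(n_blocks) - 1L,
    laser_condition = rep(conditions, B),
    n_standards = as.integer(unlist(lapply(seq_len(B), function(b) {
      vapply(1:3, function(k) per_cond[[k]][b], integer(1))
    }))),
    stringsAsFactors = FALSE
  )
}

oddball_events_for <- function(spec, blocks, standard_hz, deviant_hz) {
  per_block <- lapply(seq_len(nrow(blocks)), function(i) {
    n <- blocks$n_standards[i]
    cond <- blocks$laser_condition[i]
    context <- c(rep("standard", n - 1L), "last_standard", "deviant")
    laser <- rep(FALSE, n + 1L)
    if (cond == "deviant_laser") laser[n + 1L] <- TRUE
    if (cond == "standard_laser") laser[n] <- TRUE
    data.frame(
      freq_hz = c(rep(standard_hz, n), deviant_hz),
      context = context,
      block = blocks$block[i],
      pos_in_block = seq_len(n + 1L) - 1L,
      laser = laser,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, per_block)
  build_events(ev$freq_hz, ev$context, ev$block, ev$pos_in_block, ev$laser,
               spec$level, spec$tone_duration, spec$ramp, spec$isi,
               spec$laser_duration)
}

#' Frozen oddball sequence pair
#'
#' Generates the two frozen oddball sequences of the design: identical block
#' structure, timing and laser pattern, with the standard and deviant
#' frequency roles exchanged between the two. In deviant-laser blocks only
#' the deviant carries the laser; in standard-laser blocks only the final
#' standard before the deviant does; the final standard of every block is
#' labelled `last_standard`.
#'
#' @param spec An [oddball_spec()].
#' @return A list of two `stim_sequence` objects, `seq_a` (standard = `f1`)
#'   and `seq_b` (standard = `f2`), sharing a `blocks` allocation stored in
#'   each sequence's spec.
#' @export
make_oddball_pair <- function(spec) {
  blocks <- allocate_block_counts(spec)
  spec$blocks <- blocks
  a <- new_stim_sequence("oddball",
                         oddball_events_for(spec, blocks, spec$f1, spec$f2),
                         spec, spec$seed)
  b <- new_stim_sequence("oddball",
                         oddball_events_for(spec, blocks, spec$f2, spec$f1),
                         spec, spec$seed)
  list(seq_a = a, seq_b = b)
}

#' Cascade control sequence
#'
#' A regular monotone sweep of `n_tones` evenly log-spaced pure tones
#' (default 10 tones at half-octave separation), repeated for `n_cycles`
#' cycles. The two oddball frequencies occupy adjacent positions
#' (`oddball_pair_position`, `+1`). Each tone is as rare as an oddball
#' deviant (1/`n_tones`) but fully predictable. Under
#' `laser_scheme = "alternate_cycles"` the two oddball-frequency tones carry
#' the laser on every second cycle, giving equal numbers of laser and
#' baseline cascade trials per oddball frequency (45 each at the default 90
#' cycles, mirroring the oddball design).
#'
#' @param f1 Lower oddball frequency, Hz (anchors the sweep).
#' @param n_tones Tones per cycle.
#' @param octave_step Log2 spacing between adjacent tones, octaves.
#' @param direction `"ascending"` or `"descending"` within-cycle order.
#' @param n_cycles Number of sweep cycles.
#' @param oddball_pair_position 1-based position of `f1` within the
#'   ascending set; the half-octave partner sits one position above.
#' @param laser_scheme `"alternate_cycles"` or `"none"`.
#' @param tone_duration,isi,ramp,level,laser_duration As in [oddball_spec()].
#' @return A `stim_sequence` with events labelled `"cascade"`.
#' @export
make_cascade <- function(f1 = 10000, n_tones = 10, octave_step = 0.5,
                         direction = c("ascending", "descending"),
                         n_cycles = 90, oddball_pair_position = 5,
                         laser_scheme = c("alternate_cycles", "none"),
                         tone_duration = 0.05, isi = 0.2, ramp = 0.001,
                         level = 70, laser_duration = 0.1) {
  direction <- match.arg(direction)
  laser_scheme <- match.arg(laser_scheme)
  if (n_tones < 2) stop("n_tones must be >= 2")
  p <- as.integer(oddball_pair_position)
  if (p < 1 || p + 1L > n_tones) {
    stop("oddball_pair_position must leave both oddball tones inside the set")
  }
  freqs <- f1 * 2^(octave_step * (seq_len(n_tones) - p))
  oddball_freqs <- freqs[c(p, p + 1L)]
  cycle <- if (direction == "ascending") freqs else rev(freqs)
  all_freq <- rep(cycle, n_cycles)
  cyc_idx <- rep(seq_len(n_cycles), each = n_tones)
  laser <- rep(FALSE, length(all_freq))
  if (laser_scheme == "alternate_cycles") {
    laser <- (cyc_idx %% 2L == 0L) & (all_freq %in% oddball_freqs)
  }
  ev <- build_events(all_freq, "cascade", cyc_idx - 1L,
                     rep(seq_len(n_tones) - 1L, n_cycles), laser,
                     level, tone_duration, ramp, isi, laser_duration)
  new_stim_sequence("cascade", ev,
                    list(f1 = f1, n_tones = n_tones,
                         octave_step = octave_step, direction = direction,
                         n_cycles = n_cycles,
                         oddball_pair_position = p,
                         oddball_freqs = oddball_freqs,
                         laser_scheme = laser_scheme), NA_integer_)
}

# Fisher-Yates with adjacent-repeat rejection and a local-swap repair pass.
shuffle_no_adjacent <- function(values, prev_last, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    perm <- sample(values)
    bad <- which(c(perm[1] == prev_last, diff(perm) == 0))
    if (length(bad) == 0) return(perm)
    # repair: swap each offending element with a later compatible position
    ok <- TRUE
    for (i in bad) {
      fixed <- FALSE
      for (j in seq_along(perm)) {
        if (j == i) next
        cand <- perm
        cand[c(i, j)] <- cand[c(j, i)]
        full <- c(prev_last, cand)
        if (!any(diff(full) == 0)) { perm <- cand; fixed <- TRUE; break }
      }
      if (!fixed) { ok <- FALSE; break }
    }
    if (ok && !any(c(perm[1] == prev_last, diff(perm) == 0))) return(perm)
  }
  stop("could not shuffle without adjacent frequency repeats")
}

#' Many-standards control sequence
#'
#' Shuffles a cascade sequence cycle by cycle so that no two consecutive
#' tones anywhere in the output share a frequency, removing the cascade's
#' global predictability while conserving each cycle's frequency multiset.
#'
#' @param cascade A cascade `stim_sequence`.
#' @param seed Integer seed for the shuffle.
#' @return A `stim_sequence` with events labelled `"many_standards"`.
#' @export
make_many_standards <- function(cascade, seed = 1L) {
  ev <- cascade$events
  if (length(unique(ev$freq_hz)) < 2) {
    stop("many-standards shuffle needs >= 2 distinct frequencies")
  }
  out <- with_seed(seed, {
    prev <- NA_real_
    pieces <- lapply(split(seq_len(nrow(ev)), ev$block), function(rows) {
      perm_freq <- shuffle_no_adjacent(ev$freq_hz[rows], prev)
      prev <<- perm_freq[length(perm_freq)]
      # carry each tone's laser pairing with its frequency
      rows[match_multiset(ev$freq_hz[rows], perm_freq)]
    })
    unlist(pieces, use.names = FALSE)
  })
  new_ev <- ev[out, ]
  new_ev$context <- "many_standards"
  new_ev$onset_s <- ev$onset_s          # keep the fixed presentation grid
  new_ev$pos_in_block <- ev$pos_in_block
  new_ev$block <- ev$block
  rownames(new_ev) <- NULL
  new_stim_sequence("many_standards", new_ev,
                    c(cascade$spec, list(shuffle_seed = seed)), seed)
}

# indices mapping values onto a target ordering of the same multiset
match_multiset <- function(values, target) {
  pool <- seq_along(values)
  vapply(target, function(v) {
    hit <- pool[values[pool] == v][1]
    pool <<- setdiff(pool, hit)
    hit
  }, integer(1))
}

#' Validate a stimulus sequence
#'
#' Summarises an event table and checks the design constraints: strictly
#' increasing onsets on the fixed grid, deviant-terminated blocks, standard
#' run lengths, adjacent frequency repeats (for many-standards), and laser
#' counts per condition.
#'
#' @param seq A `stim_sequence`.
#' @return A list of class `stim_validation` with counts and a character
#'   vector `violations` (empty when the sequence is consistent).
#' @export
validate_sequence <- function(seq) {
  ev <- seq$events
  v <- character(0)
  if (nrow(ev) == 0) {
    return(structure(list(n_events = 0L, n_deviants = 0L,
                          standard_fraction = NA_real_,
                          run_lengths = integer(0), laser_counts = integer(0),
                          adjacent_repeats = 0L, degenerate = TRUE,
                          violations = "empty sequence"),
                     class = "stim_validation"))
  }
  if (any(diff(ev$onset_s) <= 0)) v <- c(v, "onsets not strictly increasing")
  step <- ev$duration_s[1] + if (!is.null(seq$spec$isi)) seq$spec$isi else NA
  if (!is.na(step) && any(abs(diff(ev$onset_s) - step) > 1e-9)) {
    v <- c(v, "inter-onset interval off the duration + isi grid")
  }
  is_std <- ev$context %in% c("standard", "last_standard")
  n_dev <- sum(ev$context == "deviant")
  run_lengths <- integer(0)
  if (seq$kind == "oddball") {
    per_block <- split(ev$context, ev$block)
    ends_dev <- vapply(per_block, function(x) x[length(x)] == "deviant" &&
                         sum(x == "deviant") == 1L, logical(1))
    if (!all(ends_dev)) v <- c(v, "block not terminated by a single deviant")
    run_lengths <- vapply(per_block, function(x) sum(x != "deviant"),
                          integer(1))
  }
  adj <- sum(diff(ev$freq_hz) == 0)
  if (seq$kind == "many_standards" && adj > 0) {
    v <- c(v, sprintf("%d adjacent same-frequency pairs", adj))
  }
  if (any(ev$laser & ev$laser_dur_s <= 0)) {
    v <- c(v, "laser event with nonpositive duration")
  }
  laser_counts <- table(ev$context[ev$laser])
  structure(list(
    n_events = nrow(ev),
    n_deviants = n_dev,
    standard_fraction = sum(is_std) / nrow(ev),
    run_lengths = unname(run_lengths),
    laser_counts = laser_counts,
    adjacent_repeats = adj,
    degenerate = FALSE,
    violations = v
  ), class = "stim_validation")
}

#' Write / read stimulus event tables
#'
#' Event tables round-trip as UTF-8 tab-separated text with a header row.
#'
#' @param seq A `stim_sequence` (or bare event data.frame) to write.
#' @param path File path.
#' @return `read_events()` returns the event data.frame.
#' @export
write_events <- function(seq, path) {
  ev <- if (inherits(seq, "stim_sequence")) seq$events else seq
  utils::write.table(ev[, intersect(EVENT_COLS, names(ev))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
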