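# Context labelling, context firing rates, the iMM/iPE/iRS decomposition,
# adapting/facilitating classification, and the laser-change and
# standards-by-position analyses.

freq_match <- function(a, b, tol = 1e-6) abs(a / b - 1) < tol

# laser condition of each event's block, from the spec's block allocation
block_condition <- function(seq) {
  blocks <- seq$spec$blocks
  blocks$laser_condition[match(seq$events$block, blocks$block)]
}

#' Label analyzable trials with context and laser condition
#'
#' Builds the trial table feeding the index analysis. Each oddball frequency
#' is analyzed separately: it appears as the (last) standard in one sequence
#' of the frozen pair and as the deviant in the other. Baseline trials are
#' trial-matched to the laser design: baseline last-standard and deviant
#' trials come from no-laser blocks only (45 each at the default design),
#' laser trials from the standard-laser / deviant-laser blocks; cascade and
#' many-standards trials split by their own laser flag.
#'
#' @param oddball_pair Result of [make_oddball_pair()].
#' @param cascade A cascade `stim_sequence` containing both oddball
#'   frequencies.
#' @param many_standards Optional many-standards `stim_sequence`.
#' @return data.frame with columns `source` (`"seq_a"`, `"seq_b"`,
#'   `"cascade"`, `"many_standards"`), `onset_s`, `freq_hz`, `context`
#'   (`last_standard`, `deviant`, `cascade`, `many_standards`), `condition`
#'   (`baseline`, `laser`).
#' @export
label_contexts <- function(oddball_pair, cascade, many_standards = NULL) {
  spec <- oddball_pair$seq_a$spec
  freqs <- c(spec$f1, spec$f2)
  if (!all(vapply(freqs, function(f)
    any(freq_match(cascade$events$freq_hz, f)), logical(1)))) {
    stop("cascade sequence does not contain both oddball frequencies")
  }
  odd_rows <- function(seq, name) {
    ev <- seq$events
    cond <- block_condition(seq)
    keep_ls <- ev$context == "last_standard" &
      cond %in% c("no_laser", "standard_laser")
    keep_dev <- ev$context == "deviant" &
      cond %in% c("no_laser", "deviant_laser")
    keep <- keep_ls | keep_dev
    data.frame(source = name, onset_s = ev$onset_s[keep],
               freq_hz = ev$freq_hz[keep],
               context = ev$context[keep],
               condition = ifelse(cond[keep] == "no_laser",
                                  "baseline", "laser"),
               stringsAsFactors = FALSE)
  }
  casc_rows <- function(seq, name, context) {
    ev <- seq$events
    keep <- freq_match(ev$freq_hz, spec$f1) | freq_match(ev$freq_hz, spec$f2)
    data.frame(source = name, onset_s = ev$onset_s[keep],
               freq_hz = ev$freq_hz[keep], context = context,
               condition = ifelse(ev$laser[keep], "laser", "baseline"),
               stringsAsFactors = FALSE)
  }
  out <- rbind(odd_rows(oddball_pair$seq_a, "seq_a"),
               odd_rows(oddball_pair$seq_b, "seq_b"),
               casc_rows(cascade, "cascade", "cascade"))
  if (!is.null(many_standards)) {
    out <- rbind(out, casc_rows(many_standards, "many_standards",
                                "many_standards"))
  }
  # snap frequencies of the pair onto canonical values
  out$freq_hz <- ifelse(freq_match(out$freq_hz, spec$f1), spec$f1, spec$f2)
  for (f in freqs) {
    have <- unique(out$context[out$freq_hz == f & out$condition == "baseline"])
    need <- c("last_standard", "deviant", "cascade")
    if (!all(need %in% have)) {
      stop(sprintf("frequency %.0f Hz is missing baseline context(s): %s",
                   f, paste(setdiff(need, have), collapse = ", ")))
    }
  }
  out
}

#' Per-unit context firing rates
#'
#' Computes the trial-by-trial firing rate for every labelled trial and the
#' per-(frequency, condition) context means: `fr_stan` (last-standard
#' trials), `fr_casc`, `fr_dev`, and `fr_ms` when many-standards trials are
#' present. Baseline means use only no-laser trials.
#'
#' @param spikes Named list of `spike_train`s keyed by the `source` values
#'   of `trial_table` (a single `spike_train` is recycled to all sources).
#' @param trial_table Output of [label_contexts()].
#' @param window Response window relative to tone onset, seconds; default
#'   0-100 ms (tone + offset windows), `c(0, 0.05)` restricts to the tone
#'   window.
#' @return A list of class `context_rates`: `$rates` (wide data.frame, one
#'   row per frequency x condition) and `$trials` (the trial table with a
#'   `rate` column).
#' @export
compute_context_rates <- function(spikes, trial_table, window = c(0, 0.1)) {
  if (inherits(spikes, "spike_train") || is.data.frame(spikes)) {
    spikes <- stats::setNames(
      rep(list(spikes), length(unique(trial_table$source))),
      unique(trial_table$source))
  }
  tt <- trial_table
  tt$rate <- NA_real_
  for (src in unique(tt$source)) {
    sel <- tt$source == src
    if (is.null(spikes[[src]])) {
      stop(sprintf("no spike train supplied for source '%s'", src))
    }
    tt$rate[sel] <- trial_firing_rate(
      spikes[[src]], data.frame(onset_s = tt$onset_s[sel]), window)
  }
  ctx_col <- c(last_standard = "fr_stan", cascade = "fr_casc",
               deviant = "fr_dev", many_standards = "fr_ms")
  combos <- unique(tt[, c("freq_hz", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- tt[tt$freq_hz == combos$freq_hz[i] &
                tt$condition == combos$condition[i], ]
    out <- data.frame(freq_hz = combos$freq_hz[i],
                      condition = combos$condition[i],
                      fr_stan = NA_real_, fr_casc = NA_real_,
                      fr_dev = NA_real_, fr_ms = NA_real_,
                      n_stan = 0L, n_casc = 0L, n_dev = 0L, n_ms = 0L,
                      stringsAsFactors = FALSE)
    for (ctx in names(ctx_col)) {
      r <- sub$rate[sub$context == ctx]
      if (length(r)) {
        out[[ctx_col[ctx]]] <- mean(r)
        out[[sub("fr_", "n_", ctx_col[ctx])]] <- length(r)
      }
    }
    out
  })
  structure(list(rates = do.call(rbind, rows), trials = tt),
            class = "context_rates")
}

#' Mismatch, prediction-error and repetition-suppression indices
#'
#' Normalizes the three context firing rates by their Euclidean norm
#' `N = sqrt(fr_dev^2 + fr_casc^2 + fr_stan^2)` and returns
#' `iPE = (fr_dev - fr_casc)/N`, `iRS = (fr_casc - fr_stan)/N` and
#' `iMM = (fr_dev - fr_stan)/N`, so that `iMM = iPE + iRS` identically.
#' Positive iPE signals prediction error (negative: negative prediction
#' error); positive iRS signals repetition suppression (negative: repetition
#' enhancement); iMM equals the classical SSA index. All-zero rate triples
#' are undefined (`defined = FALSE`) and excluded downstream.
#'
#' @param fr_stan,fr_casc,fr_dev Context firing rates, Hz (vectorized).
#' @return data.frame of class `index_set` with columns `iMM`, `iPE`,
#'   `iRS`, `norm_N`, `defined`.
#' @export
compute_indices <- function(fr_stan, fr_casc, fr_dev) {
  if (any(c(fr_stan, fr_casc, fr_dev) < 0, na.rm = TRUE)) {
    stop("context rates must be nonnegative")
  }
  n <- sqrt(fr_dev^2 + fr_casc^2 + fr_stan^2)
  defined <- is.finite(n) & n > 0
  safe_n <- ifelse(defined, n, NA_real_)
  structure(data.frame(
    iMM = (fr_dev - fr_stan) / safe_n,
    iPE = (fr_dev - fr_casc) / safe_n,
    iRS = (fr_casc - fr_stan) / safe_n,
    norm_N = n, defined = defined),
    class = c("index_set", "data.frame"))
}

#' Classify a unit as adapting, facilitating or nonadapting
#'
#' Wilcoxon rank-sum test between the trial-by-trial firing rates to the
#' standard and the deviant on the baseline trials: `adapting` when the
#' deviant response is significantly larger, `facilitating` when the
#' standard response is significantly larger, else `nonadapting`. Exact
#' enumeration for samples of 10 or fewer without ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param trial_rates_standard,trial_rates_deviant Trial rates, Hz.
#' @param alpha Significance level (default 0.05).
#' @return List of class `unit_classification`: `adapting_class`,
#'   `p_value`, `direction`.
#' @export
classify_unit <- function(trial_rates_standard, trial_rates_deviant,
                          alpha = 0.05) {
  x <- trial_rates_deviant
  y <- trial_rates_standard
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 trials per context")
  }
  direction <- sign(mean(x) - mean(y))
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else {
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  }
  cls <- if (!is.na(p) && p < alpha && direction > 0) "adapting"
         else if (!is.na(p) && p < alpha && direction < 0) "facilitating"
         else "nonadapting"
  structure(list(adapting_class = cls, p_value = p, direction = direction),
            class = "unit_classification")
}

#' Per-context firing-rate change under laser
#'
#' Laser-minus-baseline change in the mean firing rate to the standard,
#' cascade and deviant contexts, per frequency.
#'
#' @param cr A [compute_context_rates()] result containing both conditions.
#' @return data.frame with `freq_hz`, `context`, `delta_hz`.
#' @export
fr_change_by_context <- function(cr) {
  r <- cr$rates
  if (!all(c("baseline", "laser") %in% r$condition)) {
    stop("both baseline and laser conditions are required")
  }
  base <- r[r$condition == "baseline", ]
  las <- r[r$condition == "laser", ]
  las <- las[match(base$freq_hz, las$freq_hz), ]
  ctx <- c(fr_stan = "standard", fr_casc = "cascade", fr_dev = "deviant")
  do.call(rbind, lapply(names(ctx), function(col) {
    data.frame(freq_hz = base$freq_hz, context = ctx[[col]],
               delta_hz = las[[col]] - base[[col]],
               stringsAsFactors = FALSE)
  }))
}

#' Standard responses by position around the deviant
#'
#' Mean firing rate to the three standards immediately before the deviant
#' (positions -3, -2, -1; no-laser blocks only, so the last standard is
#' laser-free) and the first three standards of the following block
#' (positions +1, +2, +3), plus the paired last-before vs first-after
#' contrast used to demonstrate true repetition enhancement.
#'
#' @param spikes A `spike_train` recorded against `oddball_seq`.
#' @param oddball_seq One sequence of an oddball pair.
#' @param window Response window, seconds.
#' @return List of class `position_profile`: `position_means` (named, Hz),
#'   `pairs` (per-block last-before / first-after rates),
#'   `contrast` (mean difference, Hz), `n_blocks_used`, `n_blocks_skipped`.
#' @export
standards_by_position <- function(spikes, oddball_seq, window = c(0, 0.1)) {
  ev <- oddball_seq$events
  cond <- block_condition(oddball_seq)
  rates <- trial_firing_rate(spikes, ev, window)
  blocks <- sort(unique(ev$block))
  pos_vals <- vector("list", 6)
  names(pos_vals) <- c("-3", "-2", "-1", "+1", "+2", "+3")
  pairs <- NULL
  skipped <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    rows <- which(ev$block == b)
    if (cond[rows[1]] != "no_laser") next
    n_std <- length(rows) - 1L     # block = standards then one deviant
    if (n_std < 3) { skipped <- skipped + 1L; next }
    before <- rows[(n_std - 2):n_std]
    pos_vals[["-3"]] <- c(pos_vals[["-3"]], rates[before[1]])
    pos_vals[["-2"]] <- c(pos_vals[["-2"]], rates[before[2]])
    pos_vals[["-1"]] <- c(pos_vals[["-1"]], rates[before[3]])
    if (bi < length(blocks)) {
      nxt <- which(ev$block == blocks[bi + 1])
      n_nxt <- length(nxt) - 1L
      if (n_nxt >= 3) {
        after <- nxt[1:3]
        pos_vals[["+1"]] <- c(pos_vals[["+1"]], rates[after[1]])
        pos_vals[["+2"]] <- c(pos_vals[["+2"]], rates[after[2]])
        pos_vals[["+3"]] <- c(pos_vals[["+3"]], rates[after[3]])
        pairs <- rbind(pairs, data.frame(block = b,
                                         last_before = rates[before[3]],
                                         first_after = rates[after[1]]))
      }
    }
  }
  structure(list(
    position_means = vapply(pos_vals, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)),
    pairs = pairs,
    contrast = if (!is.null(pairs))
      mean(pairs$last_before - pairs$first_after) else NA_real_,
    n_blocks_used = if (!is.null(pairs)) nrow(pairs) else 0L,
    n_blocks_skipped = skipped),
    class = "position_profile")
}

#' Compare cascade and many-standards responses
#'
#' Paired per-unit contrast between firing rates in the cascade and
#' many-standards contexts, dispatched through [dispatch_test()].
#'
#' @param fr_casc,fr_ms Per-unit mean rates (Hz), paired.
#' @return A `stat_result` (see [dispatch_test()]) with an added
#'   `direction` element, the sign of the mean cascade-minus-many-standards
#'   difference.
#' @export
compare_cascade_many_standards <- function(fr_casc, fr_ms) {
  if (length(fr_casc) != length(fr_ms)) stop("inputs must be paired")
  res <- dispatch_test(fr_casc, fr_ms, paired = TRUE,
                       comparison_name = "cascade vs many standards")
  res$direction <- sign(mean(fr_casc - fr_ms))
  res
}
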