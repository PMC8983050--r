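# Event-aligned spike processing: PSTHs, response-profile classification,
# trial firing rates, and the laser-suppression screen for putative
# cortico-collicular units.

#' Peristimulus time histogram
#'
#' Trial-aligned spike histogram in Hz. The baseline mean and SD are taken
#' from the bins covering the 50 ms before tone onset.
#'
#' @param spikes A `spike_train` (data.frame with `spike_time_s`).
#' @param events Event table (or `stim_sequence`); one trial per row.
#' @param bin_width Bin width, seconds (default 5 ms).
#' @param window Peri-onset window, seconds.
#' @return A list of class `psth`: `bin_edges`, `bin_mid`, `rate` (Hz),
#'   `n_trials`, `baseline_mean`, `baseline_sd`.
#' @export
compute_psth <- function(spikes, events, bin_width = 0.005,
                         window = c(-0.05, 0.1)) {
  ev <- if (inherits(events, "stim_sequence")) events$events else events
  if (nrow(ev) == 0) stop("compute_psth needs at least one event")
  if (bin_width <= 0) stop("bin_width must be positive")
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  st <- spikes$spike_time_s
  # align every spike to every trial it falls into (trials do not overlap
  # at the design ISI, so findInterval on onsets is enough)
  rel <- unlist(lapply(ev$onset_s, function(o) {
    r <- st[st >= o + window[1] & st < o + window[2]] - o
    r
  }))
  counts <- if (length(rel)) {
    tabulate(findInterval(rel, edges, rightmost.closed = FALSE,
                          left.open = FALSE),
             nbins = length(edges) - 1L)
  } else rep(0L, length(edges) - 1L)
  widths <- diff(edges)
  rate <- counts / (nrow(ev) * widths)
  base_bins <- which(edges[-length(edges)] >= -0.05 &
                       edges[-1] <= 0 + 1e-12)
  structure(list(bin_edges = edges,
                 bin_mid = edges[-length(edges)] + widths / 2,
                 rate = rate, n_trials = nrow(ev),
                 baseline_mean = if (length(base_bins))
                   mean(rate[base_bins]) else 0,
                 baseline_sd = if (length(base_bins) > 1)
                   stats::sd(rate[base_bins]) else 0),
            class = "psth")
}

# local extrema with plateau -> leftmost bin; strict neighbour comparison
local_extrema <- function(y) {
  n <- length(y)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  run <- rle(y)
  starts <- cumsum(c(1L, run$lengths[-length(run$lengths)]))
  k <- length(run$values)
  is_max <- is_min <- rep(FALSE, k)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (run$values[j] > run$values[j - 1] &&
          run$values[j] > run$values[j + 1]) is_max[j] <- TRUE
      if (run$values[j] < run$values[j - 1] &&
          run$values[j] < run$values[j + 1]) is_min[j] <- TRUE
    }
  }
  list(max = starts[is_max], min = starts[is_min])
}

#' Find significant response extrema in a PSTH
#'
#' Local maxima must exceed `baseline_mean + 3 * baseline_sd` strictly, and
#' local minima must fall strictly below `baseline_mean - 3 * baseline_sd`
#' (floored at 0). The baseline SD is floored at 1e-6 Hz so a silent
#' baseline does not make every bin significant. Plateaus report their
#' leftmost bin.
#'
#' @param psth A [compute_psth()] result.
#' @param n_sd Threshold in baseline SDs (default 3).
#' @return List with data.frames `peaks` and `troughs` (`time`, `rate`).
#' @export
find_response_extrema <- function(psth, n_sd = 3) {
  sd0 <- max(psth$baseline_sd, 1e-6)
  hi <- psth$baseline_mean + n_sd * sd0
  lo <- max(psth$baseline_mean - n_sd * sd0, 0)
  ex <- local_extrema(psth$rate)
  pk <- ex$max[psth$rate[ex$max] > hi]
  tr <- ex$min[psth$rate[ex$min] < lo]
  list(peaks = data.frame(time = psth$bin_mid[pk], rate = psth$rate[pk]),
       troughs = data.frame(time = psth$bin_mid[tr],
                            rate = psth$rate[tr]))
}

#' Classify the temporal response profile of a unit
#'
#' Applies the peak-based taxonomy over a tone window (0-50 ms) and an
#' offset window (50-100 ms): `onset` (single tone-window maximum in the
#' first 10 ms), `sustained` (single maximum after 10 ms), `E-I` / `I-E`
#' (one maximum and one minimum, ordered), `biphasic` (two maxima), `mixed`
#' (more than two extrema). Offset-window responses are appended
#' (`"onset/offset"`, `".../inhibited offset"`). Units with no extrema are
#' `unresponsive`; units with only minima are `inhibited`; units with only
#' offset-window responses are `offset`. A unit is `sound_responsive` (and
#' eligible for index analysis) only if it has at least one maximum in the
#' tone window.
#'
#' @param extrema Output of [find_response_extrema()].
#' @param tone_window,offset_window Window bounds, seconds.
#' @param onset_cutoff Latest peak time still counted as onset, seconds.
#' @return A list of class `response_profile`: `label`, `sound_responsive`,
#'   `peak_times`, `trough_times`.
#' @export
classify_response_profile <- function(extrema, tone_window = c(0, 0.05),
                                      offset_window = c(0.05, 0.1),
                                      onset_cutoff = 0.01) {
  pt <- extrema$peaks$time
  tt <- extrema$troughs$time
  in_win <- function(x, w) x >= w[1] & x < w[2]
  tone_pk <- pt[in_win(pt, tone_window)]
  tone_tr <- tt[in_win(tt, tone_window)]
  off_pk <- pt[in_win(pt, offset_window)]
  off_tr <- tt[in_win(tt, offset_window)]
  n_pk <- length(tone_pk); n_tr <- length(tone_tr)
  sound_responsive <- n_pk >= 1
  label <-
    if (n_pk + n_tr + length(off_pk) + length(off_tr) == 0) "unresponsive"
    else if (n_pk == 0 && n_tr >= 1) "inhibited"
    else if (n_pk == 0) "offset"
    else if (n_pk == 1 && n_tr == 1) {
      if (tone_pk[1] < tone_tr[1]) "E-I" else "I-E"
    }
    else if (n_pk == 1 && n_tr == 0) {
      if (tone_pk[1] < onset_cutoff) "onset" else "sustained"
    }
    else if (n_pk == 2 && n_tr == 0) "biphasic"
    else "mixed"
  if (sound_responsive) {
    if (length(off_pk)) label <- paste0(label, "/offset")
    if (length(off_tr)) label <- paste0(label, "/inhibited offset")
  }
  structure(list(label = label, sound_responsive = sound_responsive,
                 peak_times = pt, trough_times = tt),
            class = "response_profile")
}

#' Profile a set of units against an event table
#'
#' Convenience wrapper: PSTH, extrema and profile label per unit.
#'
#' @param spike_list Named list of `spike_train`s.
#' @param events Event table or `stim_sequence`.
#' @param bin_width PSTH bin width, seconds.
#' @return data.frame with `unit_id`, `label`, `sound_responsive`,
#'   `n_peaks`, `n_troughs`.
#' @export
profile_units <- function(spike_list, events, bin_width = 0.005) {
  rows <- lapply(names(spike_list), function(id) {
    p <- compute_psth(spike_list[[id]], events, bin_width = bin_width)
    pr <- classify_response_profile(find_response_extrema(p))
    data.frame(unit_id = id, label = pr$label,
               sound_responsive = pr$sound_responsive,
               n_peaks = length(pr$peak_times),
               n_troughs = length(pr$trough_times),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trial firing rate
#'
#' Spike count in the half-open window `[onset + window[1], onset +
#' window[2])`, divided by the window length, for each event.
#'
#' @param spikes A `spike_train`.
#' @param events Event table (or `stim_sequence`).
#' @param window Window relative to tone onset, seconds.
#' @return Numeric vector of rates (Hz), one per event.
#' @export
trial_firing_rate <- function(spikes, events, window = c(0, 0.1)) {
  ev <- if (inherits(events, "stim_sequence")) events$events else events
  len <- window[2] - window[1]
  if (len <= 0) stop("window length must be positive")
  st <- sort(spikes$spike_time_s)
  lo <- findInterval(ev$onset_s + window[1], st, left.open = TRUE)
  hi <- findInterval(ev$onset_s + window[2], st, left.open = TRUE)
  (hi - lo) / len
}

#' Screen for laser-suppressed (putative cortico-collicular) units
#'
#' A unit passes the screen when it is infragranular and shows at least a
#' 30 percent laser-induced reduction in firing in both silence (baseline
#' activity) and during tone presentation, with reduction computed as
#' `(mean_off - mean_on) / mean_off * 100`.
#'
#' @param rates_silence_off,rates_silence_on Trial rates (Hz) in silence,
#'   laser off / on.
#' @param rates_tone_off,rates_tone_on Trial rates during tones.
#' @param infragranular Logical metadata flag for the unit's layer.
#' @param min_reduction Threshold, percent (default 30).
#' @return List of class `cc_screen`: `reduction_silence_pct`,
#'   `reduction_tone_pct`, `putative_cc`, `undefined`.
#' @export
laser_suppression_screen <- function(rates_silence_off, rates_silence_on,
                                     rates_tone_off, rates_tone_on,
                                     infragranular = TRUE,
                                     min_reduction = 30) {
  pct <- function(off, on) {
    m <- mean(off)
    if (m == 0) return(NA_real_)
    (m - mean(on)) / m * 100
  }
  rs <- pct(rates_silence_off, rates_silence_on)
  rt <- pct(rates_tone_off, rates_tone_on)
  undefined <- is.na(rs) || is.na(rt)
  structure(list(reduction_silence_pct = rs, reduction_tone_pct = rt,
                 putative_cc = !undefined && infragranular &&
                   rs >= min_reduction && rt >= min_reduction,
                 undefined = undefined),
            class = "cc_screen")
}
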