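# Synthetic recordings: Poisson spike trains with known ground truth for
# every downstream stage (context rates, temporal profiles, frequency
# tuning, tonotopy, laser modulation).

# temporal response kernels, seconds from tone onset
PROFILE_KERNELS <- list(
  onset     = rbind(c(0.000, 0.010)),
  sustained = rbind(c(0.000, 0.050)),
  offset    = rbind(c(0.050, 0.100)),
  inhibited = rbind(c(0.000, 0.050)),   # rate below baseline inside
  biphasic  = rbind(c(0.000, 0.010), c(0.030, 0.040)),
  mixed     = rbind(c(0.000, 0.010), c(0.020, 0.030), c(0.050, 0.060))
)

#' Ground truth for one synthetic unit
#'
#' Holds the generating quantities whose downstream estimates are the
#' context firing rates (standard, deviant, cascade), the temporal response
#' profile, the Gaussian (in log2 frequency) tuning curve, and the
#' multiplicative laser gains.
#'
#' @param unit_id Unit identifier.
#' @param depth Recording depth, micrometres.
#' @param best_frequency Tuning-curve centre, Hz.
#' @param tuning_bandwidth Gaussian tuning sigma, octaves.
#' @param baseline_rate Spontaneous rate, Hz.
#' @param context_rates Named numeric `c(standard=, deviant=, cascade=)`,
#'   driven rate (Hz) at best frequency within the response kernel.
#' @param laser_gain Named multiplicative gains per context; 1 = no effect.
#' @param profile Temporal kernel label, one of
#'   `names(oddpred:::PROFILE_KERNELS)`.
#' @param adapting_class Intended label, `"adapting"`, `"facilitating"` or
#'   `"nonadapting"`.
#' @return An object of class `unit_ground_truth`.
#' @export
unit_ground_truth <- function(unit_id, depth = 1000, best_frequency = 10000,
                              tuning_bandwidth = 0.5, baseline_rate = 2,
                              context_rates = c(standard = 10, deviant = 20,
                                                cascade = 14),
                              laser_gain = c(standard = 1, deviant = 1,
                                             cascade = 1),
                              profile = "sustained",
                              adapting_class = "adapting") {
  stopifnot(profile %in% names(PROFILE_KERNELS))
  req <- c("standard", "deviant", "cascade")
  if (!all(req %in% names(context_rates))) {
    stop("context_rates must name standard, deviant and cascade")
  }
  if (any(context_rates < 0) || baseline_rate < 0) {
    stop("rates must be nonnegative")
  }
  if (any(laser_gain < 0)) stop("laser_gain must be nonnegative")
  if (tuning_bandwidth <= 0) stop("tuning_bandwidth must be positive")
  structure(list(unit_id = unit_id, depth = depth,
                 best_frequency = best_frequency,
                 tuning_bandwidth = tuning_bandwidth,
                 baseline_rate = baseline_rate,
                 context_rates = context_rates[req],
                 laser_gain = laser_gain[req],
                 profile = profile, adapting_class = adapting_class),
            class = "unit_ground_truth")
}

# map event context labels onto the three generating contexts; generic tone
# stimuli (frf / tuning) are driven at the neutral cascade-context rate
generating_context <- function(context) {
  out <- rep("cascade", length(context))
  out[context %in% c("standard", "last_standard")] <- "standard"
  out[context == "deviant"] <- "deviant"
  out
}

#' Simulate a spike train for one unit
#'
#' Per trial the spike count within each response-kernel interval is Poisson
#' with mean `driven_rate * interval_length`, where
#' `driven_rate = context_rate * tuning_factor * laser_gain` (laser trials
#' only); spike times are uniform within the interval. Spontaneous spikes at
#' `baseline_rate` fill the rest of the peri-tone window. Inhibited-profile
#' units instead drop their rate below baseline inside the kernel. Negative
#' effective rates are clipped to zero and counted.
#'
#' @param gt A [unit_ground_truth()].
#' @param seq A `stim_sequence` (or bare event table).
#' @param window Peri-onset simulation window, seconds, e.g. `c(-0.05, 0.15)`.
#' @param seed Integer seed; same seed, same spikes.
#' @return A `spike_train`: data.frame with `unit_id` and `spike_time_s`
#'   (absolute, sorted), with attributes `n_clipped` and `window`.
#' @export
simulate_unit <- function(gt, seq, window = c(-0.05, 0.15), seed = 1L) {
  ev <- if (inherits(seq, "stim_sequence")) seq$events else seq
  tun <- tuning_factor(ev$freq_hz, gt$best_frequency, gt$tuning_bandwidth)
  ctx <- generating_context(ev$context)
  rate <- unname(gt$context_rates[ctx]) * tun
  gain <- ifelse(ev$laser, unname(gt$laser_gain[ctx]), 1)
  rate <- rate * gain
  n_clipped <- sum(rate < 0)
  rate[rate < 0] <- 0
  kern <- PROFILE_KERNELS[[gt$profile]]
  inhibited <- gt$profile == "inhibited"
  win_len <- diff(window)
  spikes <- with_seed(seed, {
    out <- vector("list", nrow(kern) + 1L)
    for (k in seq_len(nrow(kern))) {
      lo <- kern[k, 1]; hi <- kern[k, 2]
      lam <- if (inhibited) pmax(0, gt$baseline_rate - rate) * (hi - lo)
             else rate * (hi - lo)
      counts <- stats::rpois(length(lam), lam)
      out[[k]] <- rep(ev$onset_s, counts) +
        stats::runif(sum(counts), lo, hi)
    }
    # baseline spikes over the whole window, thinned inside the kernels
    counts <- stats::rpois(nrow(ev), gt$baseline_rate * win_len)
    rel <- stats::runif(sum(counts), window[1], window[2])
    inside <- rep(FALSE, length(rel))
    for (k in seq_len(nrow(kern))) {
      inside <- inside | (rel >= kern[k, 1] & rel < kern[k, 2])
    }
    out[[nrow(kern) + 1L]] <- (rep(ev$onset_s, counts) + rel)[!inside]
    sort(unlist(out))
  })
  structure(data.frame(unit_id = rep(gt$unit_id, length(spikes)),
                       spike_time_s = spikes),
            class = c("spike_train", "data.frame"),
            n_clipped = n_clipped, window = window)
}

# Gaussian tuning in log2 frequency
tuning_factor <- function(freq_hz, bf_hz, sigma_oct) {
  exp(-(log2(freq_hz / bf_hz))^2 / (2 * sigma_oct^2))
}

#' Specification of a synthetic recording-site population
#'
#' Central sites carry a tonotopic gradient (best frequency monotone in
#' depth, narrow tuning); shell sites have disordered best frequencies and
#' broad tuning. Unit classes (adapting / facilitating / nonadapting) are
#' assigned per `class_mix`; adapting units respond twice as strongly to the
#' deviant as to the standard (`rate_ratio`), facilitating units the
#' reverse, with the cascade rate at the geometric mean.
#'
#' @param site_type `"central"` or `"shell"`.
#' @param n_units Units per site.
#' @param depth_range Probe depth span, micrometres.
#' @param tonotopy_slope Octaves per micrometre (central); ignored for shell.
#' @param tuning_bandwidth Gaussian tuning sigma, octaves; defaults 0.3
#'   (central) or 1.5 (shell).
#' @param bf_jitter SD of log2-BF jitter around the gradient, octaves.
#' @param class_mix Proportions `c(adapting, facilitating, nonadapting)`.
#' @param rate_range Uniform range of the standard-context rate, Hz.
#' @param rate_ratio Deviant/standard rate ratio for adapting units.
#' @param baseline_rate Spontaneous rate, Hz.
#' @param profile Temporal kernel for all units (mix configurable per unit
#'   via [unit_ground_truth()]).
#' @param anchor_freq Frequency at the probe midpoint, Hz.
#' @param seed Integer seed.
#' @return An object of class `site_population_spec`.
#' @export
site_population_spec <- function(site_type = c("central", "shell"),
                                 n_units = 12,
                                 depth_range = c(400, 2000),
                                 tonotopy_slope = 0.0025,
                                 tuning_bandwidth = NULL,
                                 bf_jitter = 0.1,
                                 class_mix = c(adapting = 0.25,
                                               facilitating = 0.1,
                                               nonadapting = 0.65),
                                 rate_range = c(10, 50),
                                 rate_ratio = 2,
                                 baseline_rate = 2,
                                 profile = "sustained",
                                 anchor_freq = 10000,
                                 seed = 1L) {
  site_type <- match.arg(site_type)
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (n_units < 1) stop("n_units must be >= 1")
  if (is.null(tuning_bandwidth)) {
    tuning_bandwidth <- if (site_type == "central") 0.3 else 1.5
  }
  structure(list(site_type = site_type, n_units = as.integer(n_units),
                 depth_range = depth_range,
                 tonotopy_slope = if (site_type == "central") tonotopy_slope
                                  else 0,
                 tuning_bandwidth = tuning_bandwidth,
                 bf_jitter = bf_jitter, class_mix = class_mix,
                 rate_range = rate_range, rate_ratio = rate_ratio,
                 baseline_rate = baseline_rate, profile = profile,
                 anchor_freq = anchor_freq, seed = as.integer(seed)),
            class = "site_population_spec")
}

# context-rate triple for one unit of a given class
class_rates <- function(class, standard_rate, ratio) {
  switch(class,
    adapting = c(standard = standard_rate,
                 deviant = standard_rate * ratio,
                 cascade = standard_rate * sqrt(ratio)),
    facilitating = c(standard = standard_rate * ratio,
                     deviant = standard_rate,
                     cascade = standard_rate * sqrt(ratio)),
    nonadapting = c(standard = standard_rate, deviant = standard_rate,
                    cascade = standard_rate))
}

#' Generate a population of ground-truth units for one recording site
#'
#' @param spec A [site_population_spec()].
#' @param laser_gain Named gains applied to every unit (scenario hook);
#'   default no laser effect.
#' @return A list of [unit_ground_truth()] objects (one per unit), with the
#'   spec attached as attribute `"spec"`.
#' @export
make_population <- function(spec, laser_gain = c(standard = 1, deviant = 1,
                                                 cascade = 1)) {
  n <- spec$n_units
  with_seed(spec$seed, {
    depths <- seq(spec$depth_range[1], spec$depth_range[2], length.out = n)
    mid <- mean(spec$depth_range)
    if (spec$site_type == "central") {
      lbf <- log2(spec$anchor_freq) + spec$tonotopy_slope * (depths - mid) +
        stats::rnorm(n, 0, spec$bf_jitter)
    } else {
      lbf <- log2(spec$anchor_freq) + stats::runif(n, -3, 3)
    }
    n_class <- stats::setNames(
      diff(round(cumsum(c(0, spec$class_mix)) * n)),
      names(spec$class_mix))
    classes <- sample(rep(names(n_class), n_class))
    std_rate <- stats::runif(n, spec$rate_range[1], spec$rate_range[2])
    units <- lapply(seq_len(n), function(i) {
      unit_ground_truth(
        unit_id = sprintf("%s_u%02d", spec$site_type, i),
        depth = depths[i], best_frequency = 2^lbf[i],
        tuning_bandwidth = spec$tuning_bandwidth,
        baseline_rate = spec$baseline_rate,
        context_rates = class_rates(classes[i], std_rate[i],
                                    spec$rate_ratio),
        laser_gain = laser_gain,
        profile = spec$profile, adapting_class = classes[i])
    })
    attr(units, "spec") <- spec
    units
  })
}

#' Analytic indices from generating rates
#'
#' The recovery oracle: applies the mismatch / prediction-error /
#' repetition-suppression decomposition directly to a unit's generating
#' context rates (with laser gains applied when `laser = TRUE`), bypassing
#' simulation entirely.
#'
#' @param gt A [unit_ground_truth()].
#' @param laser Apply the unit's laser gains?
#' @return An `index_set` as returned by [compute_indices()].
#' @export
expected_indices <- function(gt, laser = FALSE) {
  r <- gt$context_rates
  if (laser) r <- r * gt$laser_gain
  compute_indices(fr_stan = r[["standard"]], fr_casc = r[["cascade"]],
                  fr_dev = r[["deviant"]])
}
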