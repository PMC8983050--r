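# Shared fixtures: small designs and a hand-built PSTH constructor.

default_spec <- function(seed = 3L) oddball_spec(seed = seed)

small_spec <- function(seed = 3L) {
  oddball_spec(blocks_per_condition = 5, standards_range = c(3, 7),
               total_tones = 90, seed = seed)
}

# a PSTH object with prescribed bin rates and baseline moments
fake_psth <- function(rate, bin_width = 0.005, t0 = 0,
                      baseline_mean = 0, baseline_sd = 1) {
  edges <- t0 + bin_width * (0:length(rate))
  structure(list(bin_edges = edges,
                 bin_mid = edges[-length(edges)] + bin_width / 2,
                 rate = rate, n_trials = 1,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "psth")
}

# flat-tuning unit centred between the oddball pair
recovery_unit <- function(id, rates, baseline = 0, profile = "sustained",
                          gain = c(standard = 1, deviant = 1, cascade = 1)) {
  unit_ground_truth(unit_id = id, best_frequency = 10000 * 2^0.25,
                    tuning_bandwidth = 4, baseline_rate = baseline,
                    context_rates = rates, laser_gain = gain,
                    profile = profile)
}
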