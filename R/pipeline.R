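# End-to-end orchestration: stimulus generation, synthetic recordings,
# per-unit index analysis, population summaries, and the canned
# experiments (parameter recovery, type-I error, site-label recovery,
# laser-inactivation scenario).

#' Simulate one unit against a set of stimulus sequences
#'
#' @param gt A [unit_ground_truth()].
#' @param seqs Named list of `stim_sequence`s (e.g. `seq_a`, `seq_b`,
#'   `cascade`, `many_standards`).
#' @param seed Integer; per-sequence child seeds are derived from it.
#' @return Named list of `spike_train`s.
#' @export
simulate_unit_set <- function(gt, seqs, seed = 1L) {
  out <- lapply(seq_along(seqs), function(k) {
    simulate_unit(gt, seqs[[k]], seed = child_seed(seed, k))
  })
  stats::setNames(out, names(seqs))
}

#' Per-unit, per-frequency index table
#'
#' Runs the full context-rate and index analysis for every unit: trial
#' firing rates, context means per laser condition, the iMM/iPE/iRS
#' decomposition, and the adapting/facilitating classification on the
#' baseline last-standard vs deviant trials. Each unit yields up to two
#' rows per condition, one per oddball frequency.
#'
#' @param spike_sets Named list (by unit id) of named spike-train lists as
#'   returned by [simulate_unit_set()].
#' @param trial_table Output of [label_contexts()].
#' @param window Response window, seconds.
#' @param alpha Classification significance level.
#' @return data.frame with columns `unit_id`, `freq_hz`, `condition`,
#'   `fr_stan`, `fr_casc`, `fr_dev`, `iMM`, `iPE`, `iRS`, `norm_N`,
#'   `defined`, `class`, `p_class`.
#' @export
analyze_units <- function(spike_sets, trial_table, window = c(0, 0.1),
                          alpha = 0.05) {
  rows <- lapply(names(spike_sets), function(uid) {
    cr <- compute_context_rates(spike_sets[[uid]], trial_table, window)
    r <- cr$rates
    tr <- cr$trials
    idx <- compute_indices(r$fr_stan, r$fr_casc, r$fr_dev)
    cls <- lapply(r$freq_hz, function(f) {
      base <- tr[tr$freq_hz == f & tr$condition == "baseline", ]
      classify_unit(base$rate[base$context == "last_standard"],
                    base$rate[base$context == "deviant"], alpha = alpha)
    })
    data.frame(unit_id = uid, freq_hz = r$freq_hz,
               condition = r$condition,
               fr_stan = r$fr_stan, fr_casc = r$fr_casc,
               fr_dev = r$fr_dev,
               iMM = idx$iMM, iPE = idx$iPE, iRS = idx$iRS,
               norm_N = idx$norm_N, defined = idx$defined,
               class = vapply(cls, `[[`, character(1), "adapting_class"),
               p_class = vapply(cls, `[[`, numeric(1), "p_value"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# paired OFF/ON index contrasts per adapting class, plus per-context
# firing-rate changes, dispatched through statrep
summarize_laser_effects <- function(index_table, alpha = 0.05) {
  it <- index_table[index_table$defined, ]
  key <- paste(it$unit_id, it$freq_hz)
  off <- it[it$condition == "baseline", ]
  on <- it[it$condition == "laser", ]
  on <- on[match(paste(off$unit_id, off$freq_hz),
                 paste(on$unit_id, on$freq_hz)), ]
  ok <- !is.na(on$unit_id)
  off <- off[ok, ]; on <- on[ok, ]
  results <- list()
  deltas <- list()
  for (cl in unique(off$class)) {
    sel <- off$class == cl
    if (sum(sel) < 3) next
    for (m in c("iMM", "iPE", "iRS")) {
      results[[paste(m, cl, "laser OFF vs ON")]] <-
        dispatch_test(off[[m]][sel], on[[m]][sel], paired = TRUE,
                      comparison_name = paste(m, cl, "(laser OFF vs ON)"))
    }
    for (ctx in c("fr_stan", "fr_casc", "fr_dev")) {
      d <- on[[ctx]][sel] - off[[ctx]][sel]
      nm <- c(fr_stan = "standard", fr_casc = "cascade",
              fr_dev = "deviant")[[ctx]]
      deltas[[paste(nm, cl)]] <- d
      results[[paste("FR change", nm, cl)]] <-
        dispatch_test(d, comparison_name = paste("FR change", nm, cl))
    }
  }
  list(stats = results, deltas = deltas, off = off, on = on)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param scenario `"baseline"` (no laser effect) or `"inactivation"`
#'   (class-dependent laser gains emulating cortico-collicular
#'   suppression).
#' @param seed Master seed; every stage derives child seeds from it.
#' @param oddball An [oddball_spec()].
#' @param populations List of [site_population_spec()]s.
#' @param window Analysis window, seconds.
#' @param alpha Significance level.
#' @param laser_gains Named list by class of named gain vectors; used when
#'   `scenario = "inactivation"`.
#' @param out_dir Output directory (created).
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = c("inactivation", "baseline"),
                       seed = 1L,
                       oddball = oddball_spec(seed = seed),
                       populations = list(
                         site_population_spec("central", seed = seed),
                         site_population_spec("shell",
                                              seed = seed + 1L)),
                       window = c(0, 0.05), alpha = 0.05,
                       laser_gains = list(
                         adapting = c(standard = 1.3, deviant = 0.75,
                                      cascade = 1),
                         facilitating = c(standard = 0.75, deviant = 1.3,
                                          cascade = 1),
                         nonadapting = c(standard = 0.85, deviant = 1,
                                         cascade = 1)),
                       out_dir = tempfile("oddpred_run_")) {
  structure(list(scenario = match.arg(scenario), seed = as.integer(seed),
                 oddball = oddball, populations = populations,
                 window = window, alpha = alpha,
                 laser_gains = laser_gains, out_dir = out_dir),
            class = "run_config")
}

# override each unit's laser gains according to its ground-truth class
apply_laser_scenario <- function(units, gains_by_class) {
  lapply(units, function(u) {
    g <- gains_by_class[[u$adapting_class]]
    if (!is.null(g)) u$laser_gain <- g[names(u$context_rates)]
    u
  })
}

#' Run the full pipeline end to end
#'
#' Generates the frozen oddball pair, cascade and many-standards sequences,
#' simulates every population unit against them, computes response
#' profiles, the per-unit index table, recording-site features and labels,
#' and the population-level statistical report; writes all tables and a
#' JSON manifest under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return List of class `run_result`: `index_table`, `profiles`,
#'   `site_table`, `summary`, `ground_truth`, `manifest`, `out_dir`.
#' @export
run_end_to_end <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("stim", "profiles", "indices", "sites", "report")) {
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  }
  ob <- config$oddball
  pair <- make_oddball_pair(ob)
  casc <- make_cascade(f1 = ob$f1, tone_duration = ob$tone_duration,
                       isi = ob$isi, level = ob$level,
                       laser_duration = ob$laser_duration)
  ms <- make_many_standards(casc, seed = child_seed(config$seed, 99))
  frf <- make_frf_sequence(seed = child_seed(config$seed, 98))
  seqs <- list(seq_a = pair$seq_a, seq_b = pair$seq_b, cascade = casc,
               many_standards = ms)
  for (nm in names(seqs)) {
    write_events(seqs[[nm]], file.path(config$out_dir, "stim",
                                       paste0(nm, ".tsv")))
  }
  trial_table <- label_contexts(pair, casc, ms)

  units <- list(); site_of <- character(0)
  for (pi in seq_along(config$populations)) {
    pop <- make_population(config$populations[[pi]])
    names(pop) <- paste0("s", pi, "_", vapply(pop, `[[`, character(1),
                                              "unit_id"))
    for (i in seq_along(pop)) pop[[i]]$unit_id <- names(pop)[i]
    units <- c(units, pop)
    site_of <- c(site_of, rep(paste0("site", pi), length(pop)))
  }
  names(site_of) <- names(units)
  if (config$scenario == "inactivation") {
    units <- apply_laser_scenario(units, config$laser_gains)
  }

  spike_sets <- lapply(seq_along(units), function(i) {
    simulate_unit_set(units[[i]], seqs, seed = child_seed(config$seed, i))
  })
  names(spike_sets) <- names(units)

  # response profiles from the oddball responses (both contexts combined)
  prof <- profile_units(lapply(spike_sets, `[[`, "seq_a"), pair$seq_a)
  utils::write.table(prof, file.path(config$out_dir, "profiles",
                                     "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  index_table <- analyze_units(spike_sets, trial_table,
                               window = config$window,
                               alpha = config$alpha)
  # exclusion rule: only sound-responsive units enter the index table
  responsive <- prof$unit_id[prof$sound_responsive]
  index_table <- index_table[index_table$unit_id %in% responsive, ]
  utils::write.table(index_table,
                     file.path(config$out_dir, "indices",
                               "index_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # site features from simulated frequency-response functions
  tuning <- do.call(rbind, lapply(names(units), function(uid) {
    tr <- simulate_unit(units[[uid]], frf,
                        seed = child_seed(config$seed,
                                          10000 + match(uid, names(units))))
    rates <- trial_firing_rate(tr, frf$events, window = c(0, 0.05))
    agg <- tapply(rates, frf$events$freq_hz, mean)
    data.frame(site_id = site_of[[uid]], unit_id = uid,
               depth_um = units[[uid]]$depth,
               freq_hz = as.numeric(names(agg)), rate_hz = as.numeric(agg),
               stringsAsFactors = FALSE)
  }))
  site_table <- cluster_sites(site_features(tuning),
                              seed = child_seed(config$seed, 7))
  utils::write.table(site_table,
                     file.path(config$out_dir, "sites", "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  eff <- summarize_laser_effects(index_table, alpha = config$alpha)
  summary_df <- build_summary_table(eff$stats,
                                    path = file.path(config$out_dir,
                                                     "report",
                                                     "summary.tsv"))
  manifest <- list(
    package = "oddpred",
    version = as.character(utils::packageVersion("oddpred")),
    scenario = config$scenario, seed = config$seed,
    config_hash = config_hash(config),
    n_units = length(units),
    rows = list(index_table = nrow(index_table),
                profiles = nrow(prof), sites = nrow(site_table),
                summary = nrow(summary_df)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(index_table = index_table, profiles = prof,
                 site_table = site_table, summary = summary_df,
                 laser_effects = eff, ground_truth = units,
                 manifest = manifest, out_dir = config$out_dir),
            class = "run_result")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Parameter-recovery experiment
#'
#' Simulates units whose generating context rates are drawn uniformly over
#' `rate_range` (independently per context, covering the index range), runs
#' the complete stimulus/simulation/analysis pipeline at the design's 45
#' baseline trials per context, and reports the bias and mean absolute
#' error of the recovered iMM, iPE and iRS against the analytic
#' [expected_indices()] oracle. A second set of units with a fixed
#' `rate_ratio` deviant/standard effect yields the class-recovery
#' confusion matrix.
#'
#' @param n_units Units for the index-recovery set.
#' @param n_class_units Units for the class-recovery set (half adapting,
#'   half facilitating).
#' @param rate_range Uniform range of generating rates, Hz.
#' @param rate_ratio Effect size for the class-recovery set.
#' @param window Analysis window, seconds (0-50 ms tone window by
#'   default: the synthetic kernels confine driven spikes to the tone).
#' @param oddball Oddball design; trials per context scale with
#'   `blocks_per_condition`.
#' @param cascade_cycles Cascade cycles; baseline cascade trials per
#'   frequency are half of this.
#' @param seed Integer seed.
#' @return List of class `recovery_report`: `mae` and `bias` (named by
#'   index), `per_unit` (estimated vs true indices), `confusion`
#'   (table), `class_recovery_rate`.
#' @export
recovery_experiment <- function(n_units = 200, n_class_units = 100,
                                rate_range = c(10, 50), rate_ratio = 2,
                                window = c(0, 0.05),
                                oddball = oddball_spec(seed = seed),
                                cascade_cycles = 90,
                                seed = 1L) {
  if (n_units < 10) stop("n_units must be >= 10")
  pair <- make_oddball_pair(oddball)
  casc <- make_cascade(f1 = oddball$f1, n_cycles = cascade_cycles,
                       tone_duration = oddball$tone_duration,
                       isi = oddball$isi, level = oddball$level,
                       laser_duration = oddball$laser_duration)
  trial_table <- label_contexts(pair, casc)
  seqs <- list(seq_a = pair$seq_a, seq_b = pair$seq_b, cascade = casc)
  bf <- sqrt(oddball$f1 * oddball$f2)    # flat tuning across the pair

  make_units <- function(n, classed, seed0) {
    with_seed(seed0, lapply(seq_len(n), function(i) {
      if (classed) {
        cls <- if (i <= n / 2) "adapting" else "facilitating"
        rates <- class_rates(cls, stats::runif(1, rate_range[1],
                                               rate_range[2]), rate_ratio)
      } else {
        cls <- "free"
        rates <- c(standard = stats::runif(1, rate_range[1], rate_range[2]),
                   deviant = stats::runif(1, rate_range[1], rate_range[2]),
                   cascade = stats::runif(1, rate_range[1], rate_range[2]))
      }
      unit_ground_truth(unit_id = sprintf("%s%03d",
                                          if (classed) "c" else "r", i),
                        best_frequency = bf, tuning_bandwidth = 4,
                        baseline_rate = 2, context_rates = rates,
                        adapting_class = cls)
    }))
  }

  run_set <- function(units, seed0) {
    sets <- lapply(seq_along(units), function(i) {
      simulate_unit_set(units[[i]], seqs, seed = child_seed(seed0, i))
    })
    names(sets) <- vapply(units, `[[`, character(1), "unit_id")
    analyze_units(sets, trial_table, window = window)
  }

  units_r <- make_units(n_units, classed = FALSE, child_seed(seed, 1))
  tab_r <- run_set(units_r, child_seed(seed, 2))
  truth <- do.call(rbind, lapply(units_r, function(u) {
    ei <- expected_indices(u)
    data.frame(unit_id = u$unit_id, iMM_true = ei$iMM, iPE_true = ei$iPE,
               iRS_true = ei$iRS, stringsAsFactors = FALSE)
  }))
  per_unit <- merge(tab_r[tab_r$condition == "baseline", ], truth,
                    by = "unit_id")
  err <- cbind(iMM = per_unit$iMM - per_unit$iMM_true,
               iPE = per_unit$iPE - per_unit$iPE_true,
               iRS = per_unit$iRS - per_unit$iRS_true)
  units_c <- make_units(n_class_units, classed = TRUE, child_seed(seed, 3))
  tab_c <- run_set(units_c, child_seed(seed, 4))
  tab_c <- tab_c[tab_c$condition == "baseline", ]
  intended <- vapply(units_c, `[[`, character(1), "adapting_class")
  names(intended) <- vapply(units_c, `[[`, character(1), "unit_id")
  confusion <- table(intended = intended[tab_c$unit_id],
                     estimated = tab_c$class)
  structure(list(
    mae = colMeans(abs(err)), bias = colMeans(err), per_unit = per_unit,
    confusion = confusion,
    class_recovery_rate =
      mean(intended[tab_c$unit_id] == tab_c$class)),
    class = "recovery_report")
}

#' Type-I error of the adapting/facilitating classification
#'
#' Simulates pairs of equal-rate Poisson trial sets (the null) and reports
#' the fraction of units classified as anything but nonadapting.
#'
#' @param n_sim Number of simulated null units.
#' @param n_trials Trials per context.
#' @param rate Common generating rate, Hz.
#' @param window_len Response-window length, seconds.
#' @param alpha Classification level.
#' @param seed Integer seed.
#' @return List: `false_positive_rate`, `n_sim`, `alpha`.
#' @export
type1_experiment <- function(n_sim = 2000, n_trials = 45, rate = 10,
                             window_len = 0.05, alpha = 0.05, seed = 1L) {
  fp <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      a <- stats::rpois(n_trials, rate * window_len) / window_len
      b <- stats::rpois(n_trials, rate * window_len) / window_len
      classify_unit(a, b, alpha = alpha)$adapting_class != "nonadapting"
    }, logical(1))
  })
  list(false_positive_rate = mean(fp), n_sim = n_sim, alpha = alpha)
}

#' Recording-site label recovery
#'
#' For each seed, builds central and shell populations at the default
#' separations, simulates their frequency-response-function responses,
#' extracts site features and clusters them, then scores the fraction of
#' sites whose k-means label matches the generating site type.
#'
#' @param n_seeds Number of independent replicates.
#' @param n_sites_per_type Central and shell sites per replicate.
#' @param n_units Units per site.
#' @param seed Master seed.
#' @return List: `recovery_rate`, `per_seed` (fraction correct per
#'   replicate).
#' @export
site_recovery_experiment <- function(n_seeds = 100, n_sites_per_type = 2,
                                     n_units = 12, seed = 1L) {
  frf <- make_frf_sequence(seed = seed)
  per_seed <- vapply(seq_len(n_seeds), function(s) {
    tuning <- NULL
    truth <- character(0)
    for (ty in c("central", "shell")) {
      for (k in seq_len(n_sites_per_type)) {
        sid <- paste0(ty, k)
        spec <- site_population_spec(ty, n_units = n_units,
                                     seed = child_seed(seed, s * 100 +
                                                         k * 10 +
                                                         (ty == "shell")))
        pop <- make_population(spec)
        rows <- lapply(seq_along(pop), function(i) {
          tr <- simulate_unit(pop[[i]], frf,
                              seed = child_seed(seed, s * 1000 + k * 50 +
                                                  i + (ty == "shell") *
                                                  25000))
          rates <- trial_firing_rate(tr, frf$events, window = c(0, 0.05))
          agg <- tapply(rates, frf$events$freq_hz, mean)
          data.frame(site_id = sid,
                     unit_id = paste0(sid, "_", pop[[i]]$unit_id),
                     depth_um = pop[[i]]$depth,
                     freq_hz = as.numeric(names(agg)),
                     rate_hz = as.numeric(agg), stringsAsFactors = FALSE)
        })
        tuning <- rbind(tuning, do.call(rbind, rows))
        truth[sid] <- ty
      }
    }
    labelled <- cluster_sites(site_features(tuning),
                              seed = child_seed(seed, s))
    mean(labelled$cluster_label == truth[labelled$site_id])
  }, numeric(1))
  list(recovery_rate = mean(per_seed), per_seed = per_seed)
}

#' Laser-inactivation scenario experiment
#'
#' The package's emulation of the cortico-collicular inactivation findings:
#' a population of adapting units whose laser gains raise the standard
#' response and lower the deviant response, run through the complete
#' pipeline. Reports the population signs: change in mean iPE of
#' estimated-adapting units under laser, and the per-context firing-rate
#' changes.
#'
#' @param n_units Number of adapting ground-truth units.
#' @param gains Named laser gains applied to every unit.
#' @param window Analysis window, seconds.
#' @param seed Integer seed.
#' @return List of class `laser_scenario`: `index_table`,
#'   `mean_iPE_off`, `mean_iPE_on`, `delta_standard`, `delta_deviant`,
#'   `delta_cascade` (population means, Hz, adapting units),
#'   `frac_iPE_reduced`, `frac_delta_std_pos`, `frac_delta_dev_neg`.
#' @export
laser_scenario_experiment <- function(n_units = 60,
                                      gains = c(standard = 1.3,
                                                deviant = 0.75,
                                                cascade = 1),
                                      window = c(0, 0.05), seed = 1L) {
  ob <- oddball_spec(seed = seed)
  pair <- make_oddball_pair(ob)
  casc <- make_cascade(f1 = ob$f1)
  trial_table <- label_contexts(pair, casc)
  seqs <- list(seq_a = pair$seq_a, seq_b = pair$seq_b, cascade = casc)
  bf <- sqrt(ob$f1 * ob$f2)
  units <- with_seed(seed, lapply(seq_len(n_units), function(i) {
    unit_ground_truth(unit_id = sprintf("a%03d", i), best_frequency = bf,
                      tuning_bandwidth = 4, baseline_rate = 2,
                      context_rates = class_rates(
                        "adapting", stats::runif(1, 10, 50), 2),
                      laser_gain = gains, adapting_class = "adapting")
  }))
  sets <- lapply(seq_along(units), function(i) {
    simulate_unit_set(units[[i]], seqs, seed = child_seed(seed, i + 500))
  })
  names(sets) <- vapply(units, `[[`, character(1), "unit_id")
  it <- analyze_units(sets, trial_table, window = window)
  ad <- it[it$class == "adapting" & it$condition == "baseline", ]
  on <- it[it$condition == "laser", ]
  on <- on[match(paste(ad$unit_id, ad$freq_hz),
                 paste(on$unit_id, on$freq_hz)), ]
  structure(list(
    index_table = it,
    n_adapting_rows = nrow(ad),
    mean_iPE_off = mean(ad$iPE), mean_iPE_on = mean(on$iPE),
    delta_standard = mean(on$fr_stan - ad$fr_stan),
    delta_cascade = mean(on$fr_casc - ad$fr_casc),
    delta_deviant = mean(on$fr_dev - ad$fr_dev),
    frac_iPE_reduced = mean(on$iPE < ad$iPE),
    frac_delta_std_pos = mean(on$fr_stan > ad$fr_stan),
    frac_delta_dev_neg = mean(on$fr_dev < ad$fr_dev)),
    class = "laser_scenario")
}
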