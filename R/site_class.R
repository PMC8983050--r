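# Recording-site parsing: best frequency, tuning sparseness, robust
# best-frequency-vs-depth fit, and k-means assignment of recordings to
# central nucleus vs shell locations.

#' Best frequency of a tuning curve
#'
#' The frequency evoking the maximal tone-window rate; ties resolve to the
#' lower frequency. All-zero tuning is undefined and the unit is excluded
#' from the tonotopy fit.
#'
#' @param rates Per-frequency mean rates, Hz.
#' @param freqs Frequencies, Hz (same length).
#' @return Best frequency (Hz), or `NA` when undefined.
#' @export
best_frequency <- function(rates, freqs) {
  if (length(rates) < 2 || length(rates) != length(freqs)) {
    stop("need >= 2 matched rates and frequencies")
  }
  if (all(rates == 0)) return(NA_real_)
  o <- order(freqs)
  freqs <- freqs[o]; rates <- rates[o]
  freqs[which.max(rates)]       # first max = lowest frequency on ties
}

#' Lifetime (Rolls-Tovee) sparseness
#'
#' `S = (1 - (mean r)^2 / mean(r^2)) / (1 - 1/n)`, in `[0, 1]`: 0 for a
#' flat response profile (broad tuning), 1 when a single frequency drives
#' all the response (sharp tuning). Invariant to positive rescaling.
#'
#' @param rates Nonnegative per-frequency rates, Hz.
#' @return Sparseness in `[0, 1]`, or `NA` for an all-zero profile.
#' @export
sparseness <- function(rates) {
  n <- length(rates)
  if (n < 2) stop("need >= 2 responses")
  if (any(rates < 0)) stop("responses must be nonnegative")
  if (all(rates == 0)) return(NA_real_)
  s <- (1 - mean(rates)^2 / mean(rates^2)) / (1 - 1 / n)
  min(max(s, 0), 1)
}

#' Robust fit of best frequency against depth
#'
#' Iteratively reweighted least squares with bisquare weights
#' (`MASS::rlm`) of `log2(BF)` on depth; the returned R-squared is computed
#' on the robust weights, so isolated outliers barely dilute it. Clamped to
#' `[0, 1]`.
#'
#' @param depth Depths, micrometres.
#' @param bf Best frequencies, Hz (`NA` rows dropped).
#' @return List: `r_squared`, `slope` (octaves per micrometre), `n`,
#'   `classifiable` (`FALSE` when fewer than 3 usable units).
#' @export
bf_depth_fit <- function(depth, bf) {
  ok <- is.finite(depth) & is.finite(bf) & bf > 0
  depth <- depth[ok]; y <- log2(bf[ok])
  if (length(y) < 3) {
    return(list(r_squared = NA_real_, slope = NA_real_, n = length(y),
                classifiable = FALSE))
  }
  if (stats::sd(y) == 0 || stats::sd(depth) == 0) {
    return(list(r_squared = if (stats::sd(y) == 0) 1 else 0, slope = 0,
                n = length(y), classifiable = TRUE))
  }
  fit <- MASS::rlm(y ~ depth, psi = MASS::psi.bisquare, maxit = 100)
  w <- fit$w
  res <- stats::residuals(fit)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * res^2) / sum(w * (y - ybar)^2)
  list(r_squared = min(max(r2, 0), 1),
       slope = unname(stats::coef(fit)[2]), n = length(y),
       classifiable = TRUE)
}

#' Per-recording site features
#'
#' Computes each site's tonotopy R-squared (robust fit of log2 best
#' frequency on depth) and mean tuning sparseness from per-unit tuning
#' responses.
#'
#' @param tuning data.frame with columns `site_id`, `unit_id`, `depth_um`,
#'   `freq_hz`, `rate_hz` (one row per unit x frequency).
#' @return data.frame of class `site_features`: `site_id`, `r_squared`,
#'   `mean_sparseness`, `n_units`, `classifiable`.
#' @export
site_features <- function(tuning) {
  rows <- lapply(split(tuning, tuning$site_id), function(ts) {
    per_unit <- split(ts, ts$unit_id)
    bf <- vapply(per_unit, function(u)
      best_frequency(u$rate_hz, u$freq_hz), numeric(1))
    sp <- vapply(per_unit, function(u) sparseness(u$rate_hz), numeric(1))
    depth <- vapply(per_unit, function(u) u$depth_um[1], numeric(1))
    fit <- bf_depth_fit(depth, bf)
    data.frame(site_id = ts$site_id[1], r_squared = fit$r_squared,
               mean_sparseness = mean(sp, na.rm = TRUE),
               n_units = length(per_unit),
               classifiable = fit$classifiable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("site_features", "data.frame")
  out
}

#' Cluster recording sites into central and shell groups
#'
#' k-means with two groups on the z-scored (R-squared, mean sparseness)
#' pairs; 50 restarts under a fixed seed, best inertia kept. The cluster
#' with the higher mean sparseness is labelled `central` (sharp tuning,
#' strong tonotopy), the other `shell`. Degenerate inputs (all sites
#' identical) are labelled `unclassifiable`.
#'
#' @param features A [site_features()] data.frame (or any data.frame with
#'   `r_squared` and `mean_sparseness`).
#' @param seed Integer seed for the restarts.
#' @return `features` with an added `cluster_label` column.
#' @export
cluster_sites <- function(features, seed = 1L) {
  f <- features
  if (nrow(f) < 2) stop("need at least 2 sites to cluster")
  usable <- if ("classifiable" %in% names(f)) f$classifiable &
    is.finite(f$r_squared) & is.finite(f$mean_sparseness)
    else is.finite(f$r_squared) & is.finite(f$mean_sparseness)
  x <- as.matrix(f[usable, c("r_squared", "mean_sparseness")])
  f$cluster_label <- "unclassifiable"
  if (sum(usable) < 2 || nrow(unique(x)) < 2) return(f)
  z <- scale(x)
  z[, apply(x, 2, stats::sd) == 0] <- 0      # constant feature -> no weight
  if (nrow(z) == 2) {                        # exactly two sites: trivial split
    km <- list(cluster = c(1L, 2L))
  } else {
    km <- with_seed(seed, stats::kmeans(z, centers = 2, nstart = 50))
  }
  sp_mean <- tapply(x[, "mean_sparseness"], km$cluster, mean)
  central_cl <- as.integer(names(sp_mean)[which.max(sp_mean)])
  f$cluster_label[usable] <- ifelse(km$cluster == central_cl,
                                    "central", "shell")
  f
}
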