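# Data-evaluation statistics: ERP grand averages, P300 window amplitude,
# split-half SNR at Pz, score-versus-cycle regression, and the normality /
# one-sample t tests used to assess decoder accuracy.

#' Grand-average ERP per condition
#'
#' Mean over kept trials of each condition; rejected trials are excluded.
#'
#' @param epochs a baseline-corrected `epoch_set`.
#' @param conditions conditions to average (default: all present).
#' @return object of class `erp_result`: `waveforms` (named list of
#'   channels x time matrices), `n_trials`, `times_ms`, `channel_labels`.
#' @export
grand_average <- function(epochs, conditions = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(conditions)) conditions <- unique(epochs$labels)
  waveforms <- list(); n_trials <- integer(0)
  for (cond in conditions) {
    idx <- epochs$kept & epochs$labels == cond
    if (!any(idx)) stop("no kept trials for condition: ", cond)
    waveforms[[cond]] <- apply(epochs$data[idx, , , drop = FALSE],
                               c(2, 3), mean)
    n_trials[cond] <- sum(idx)
  }
  structure(list(waveforms = waveforms, n_trials = n_trials,
                 times_ms = epochs$times_ms,
                 channel_labels = epochs$channel_labels),
            class = "erp_result")
}

#' Mean ERP amplitude in a window
#'
#' Mean of the grand-average waveform over a channel set and time window
#' (default 300-550 ms, the P300-like window for smoking cues).
#'
#' @param erp an [grand_average()] result.
#' @param channels channel labels (default `"Pz"`).
#' @param window_ms numeric length-2 window, half-open.
#' @return named numeric, one mean amplitude (uV) per condition.
#' @export
p300_amplitude <- function(erp, channels = "Pz",
                           window_ms = c(300, 550)) {
  stopifnot(inherits(erp, "erp_result"))
  cidx <- match(channels, erp$channel_labels)
  if (anyNA(cidx)) stop("unknown channel(s): ",
                        paste(channels[is.na(cidx)], collapse = ", "))
  tidx <- which(erp$times_ms >= window_ms[1] & erp$times_ms < window_ms[2])
  if (!length(tidx)) stop("window contains no samples")
  vapply(erp$waveforms,
         function(w) mean(w[cidx, tidx, drop = FALSE]), numeric(1))
}

#' Split-half signal-to-noise ratio at Pz
#'
#' SNR = P_signal / P_noise with P_signal the mean squared amplitude of
#' the all-trial average waveform at Pz over the analysis window and
#' P_noise the mean squared amplitude of (odd-trial average minus
#' even-trial average)/2 over the same window: the split-half difference
#' cancels the stimulus-locked signal and estimates the residual noise of
#' the trial average.
#'
#' @param epochs an `epoch_set` (kept trials are used).
#' @param channel channel to assess (default `"Pz"`).
#' @param window_ms analysis window (default 0-1000 ms).
#' @return unitless SNR; `Inf` (with a warning) when the split-half noise
#'   power is exactly zero.
#' @export
snr_pz <- function(epochs, channel = "Pz", window_ms = c(0, 1000)) {
  stopifnot(inherits(epochs, "epoch_set"))
  cidx <- match(channel, epochs$channel_labels)
  if (is.na(cidx)) stop("channel not present: ", channel)
  keep <- which(epochs$kept)
  if (length(keep) < 4) stop("need at least 4 kept trials")
  tidx <- which(epochs$times_ms >= window_ms[1] &
                epochs$times_ms < window_ms[2])
  X <- epochs$data[keep, cidx, tidx, drop = TRUE]
  X <- matrix(X, nrow = length(keep))
  avg <- colMeans(X)
  odd <- colMeans(X[seq(1, nrow(X), by = 2), , drop = FALSE])
  even <- colMeans(X[seq(2, nrow(X), by = 2), , drop = FALSE])
  p_signal <- mean(avg ^ 2)
  p_noise <- mean(((odd - even) / 2) ^ 2)
  if (p_noise == 0) {
    warning("zero split-half noise power; returning Inf")
    return(Inf)
  }
  p_signal / p_noise
}

#' Score-versus-cycle regression across sessions
#'
#' Pools per-cycle mean displayed scores across the given traces and
#' regresses them on the cycle index: Pearson correlation with two-tailed
#' p, OLS slope and its 95% confidence interval.
#'
#' @param traces a `feedback_trace` or a list of them.
#' @return list with `pearson_r`, `p`, `slope`, `ci` (length-2), `n`,
#'   and `undefined = TRUE` (with NA statistics) when the scores are
#'   constant.
#' @export
score_cycle_regression <- function(traces) {
  if (inherits(traces, "data.frame")) traces <- list(traces)
  cm <- do.call(rbind, lapply(traces, cycle_means))
  if (length(unique(cm$cycle)) < 2)
    stop("need at least 2 distinct cycle indices")
  if (stats::sd(cm$mean_displayed) == 0)
    return(list(pearson_r = NA_real_, p = NA_real_, slope = NA_real_,
                ci = c(NA_real_, NA_real_), n = nrow(cm),
                undefined = TRUE))
  ct <- stats::cor.test(cm$cycle, cm$mean_displayed)
  fit <- stats::lm(mean_displayed ~ cycle, data = cm)
  # suppress the "essentially perfect fit" note on exactly linear input
  ci <- suppressWarnings(stats::confint(fit)["cycle", ])
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)["cycle"]),
       ci = unname(ci), n = nrow(cm), undefined = FALSE)
}

#' Normality and against-chance tests
#'
#' Kolmogorov-Smirnov test of the values against a normal distribution
#' with the sample mean and SD (parameters estimated from the data — the
#' Lilliefors caveat applies: the reported p is conservative in the
#' direction of not rejecting), and a two-tailed one-sample t test against
#' the chance level.
#'
#' @param values numeric vector (n >= 3), e.g. per-subject accuracies.
#' @param chance value to test the mean against (default 0.5).
#' @return list with `ks_normality_p`, `one_sample_t` (list `t`, `p`,
#'   `df`, `mean`).
#' @export
distribution_tests <- function(values, chance = 0.5) {
  if (length(values) < 3) stop("need at least 3 values")
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values),
                   sd = stats::sd(values)))
  if (stats::sd(values) == 0) {
    tt <- list(t = 0, p = 1, df = length(values) - 1, mean = mean(values))
  } else {
    t0 <- stats::t.test(values, mu = chance)
    tt <- list(t = unname(t0$statistic), p = t0$p.value,
               df = unname(t0$parameter), mean = mean(values))
  }
  list(ks_normality_p = ks$p.value, one_sample_t = tt)
}

#' Topography export
#'
#' Channel-value table of a grand-average waveform sampled every
#' `step_ms` over a window (default 0-1000 ms in 200 ms steps), for
#' external rendering.
#'
#' @param erp an [grand_average()] result.
#' @param condition condition to export.
#' @param window_ms window bounds.
#' @param step_ms sampling step.
#' @return data.frame: one row per channel, one column per time point.
#' @export
topography_table <- function(erp, condition, window_ms = c(0, 1000),
                             step_ms = 200) {
  stopifnot(inherits(erp, "erp_result"))
  w <- erp$waveforms[[condition]]
  if (is.null(w)) stop("no such condition: ", condition)
  pts <- seq(window_ms[1], window_ms[2], by = step_ms)
  idx <- vapply(pts, function(p) which.min(abs(erp$times_ms - p)), 1L)
  out <- as.data.frame(w[, idx, drop = FALSE])
  names(out) <- paste0("t", pts, "ms")
  cbind(data.frame(channel = erp$channel_labels), out)
}

#' Family-wise error rate of the feature selection under the null
#'
#' Repeatedly generates two trial ensembles from the identical Gaussian
#' noise model, runs pointwise permutation testing plus cluster-mass
#' correction, and reports the fraction of datasets yielding at least one
#' significant cluster.  With valid family-wise error control this
#' fraction stays at or below the nominal level.
#'
#' @param n_datasets number of null simulations.
#' @param n_trials trials per condition.
#' @param n_channels,n_time map size (channels use the montage's first
#'   `n_channels` scalp labels for adjacency).
#' @param n_perm permutations per dataset.
#' @param alpha nominal level (pointwise and cluster-level).
#' @param seed RNG seed.
#' @return list with `fwer` (fraction), `hits` (logical per dataset),
#'   `upper95` (one-sided 95% binomial upper bound), `alpha`.
#' @export
fwer_simulation <- function(n_datasets = 500, n_trials = 40,
                            n_channels = 10, n_time = 50, n_perm = 1000,
                            alpha = 0.05, seed = 1) {
  labels <- model60_labels()[seq_len(n_channels)]
  adjacency <- montage_adjacency(labels)
  hits <- logical(n_datasets)
  for (i in seq_len(n_datasets)) {
    sim <- withr::with_seed(seed + i, list(
      a = array(stats::rnorm(n_trials * n_channels * n_time),
                dim = c(n_trials, n_channels, n_time)),
      b = array(stats::rnorm(n_trials * n_channels * n_time),
                dim = c(n_trials, n_channels, n_time))))
    map <- pointwise_permutation(sim$a, sim$b, n_perm = n_perm,
                                 alpha = alpha, seed = seed + i,
                                 channel_labels = labels)
    cfs <- cluster_mass(map, adjacency, alpha = alpha)
    hits[i] <- any(vapply(cfs$clusters, function(cl) cl$keep, TRUE))
  }
  fwer <- mean(hits)
  upper95 <- stats::binom.test(sum(hits), n_datasets,
                               alternative = "less")$conf.int[2]
  list(fwer = fwer, hits = hits, upper95 = upper95, alpha = alpha,
       n_datasets = n_datasets)
}
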