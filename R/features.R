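# Offline feature selection: pointwise two-sample permutation statistics on
# amplitude and Morlet band power, corrected by the maximum cluster-level
# mass statistic, then per-trial feature assembly.

#' The five analysis frequency bands
#'
#' alpha 8-13 Hz, low beta 14-20 Hz, high beta 21-30 Hz, low gamma
#' 31-48 Hz, high gamma 52-80 Hz (the 49-51 Hz gap skips line noise).
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
band_set <- function() {
  b <- data.frame(name = c("alpha", "low_beta", "high_beta",
                           "low_gamma", "high_gamma"),
                  low = c(8, 14, 21, 31, 52),
                  high = c(13, 20, 30, 48, 80),
                  stringsAsFactors = FALSE)
  stopifnot(all(b$low < b$high))
  b
}

morlet_wavelet <- function(freq, fs, n_cycles = 7) {
  sd_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sd_t * fs)
  t <- seq(-half, half) / fs
  w <- exp(2i * pi * freq * t) * exp(-t ^ 2 / (2 * sd_t ^ 2))
  w / (sum(abs(w)) / 2)   # unit amplitude response at `freq`
}

# Memoized wavelet spectra: the online loop transforms one window every
# update and the wavelet FFT never changes.
.wavelet_cache <- new.env(parent = emptyenv())

wavelet_fft <- function(w, nfft, key = NULL) {
  if (is.null(key)) return(stats::fft(c(w, rep(0, nfft - length(w)))))
  hit <- .wavelet_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- stats::fft(c(w, rep(0, nfft - length(w))))
  .wavelet_cache[[key]] <- val
  val
}

# Complex Morlet transform of a time x channels matrix at one frequency,
# "same" alignment.
morlet_conv <- function(X, w, nfft, key = NULL) {
  n <- nrow(X)
  half <- (length(w) - 1) / 2
  Wf <- wavelet_fft(w, nfft, key)
  Xf <- stats::mvfft(rbind(X, matrix(0, nfft - n, ncol(X))))
  Y <- stats::mvfft(Xf * Wf, inverse = TRUE) / nfft
  Y[(half + 1):(half + n), , drop = FALSE]
}

#' Morlet-wavelet band power of epochs
#'
#' Power at each band's center frequency (complex Morlet, `n_cycles`
#' cycles), squared magnitude, decimated in time by `decim`.
#'
#' @param epochs an `epoch_set` (or a channels x samples matrix for a
#'   single online window).
#' @param bands a [band_set()]-style data.frame.
#' @param n_cycles wavelet width in cycles.
#' @param decim keep every `decim`-th time sample.
#' @param fs sampling rate (required only for matrix input).
#' @return object of class `band_power_set`: `power`
#'   (trials x channels x bands x time array), `times_ms`, `band_names`,
#'   `channel_labels`.
#' @export
band_power <- function(epochs, bands = band_set(), n_cycles = 7, decim = 5,
                       fs = NULL) {
  single <- is.matrix(epochs)
  if (single) {
    if (is.null(fs)) stop("fs is required for matrix input")
    arr <- array(epochs, dim = c(1, nrow(epochs), ncol(epochs)))
    times_ms <- (seq_len(ncol(epochs)) - 1) / fs * 1000
    ch_labels <- rownames(epochs)
  } else {
    stopifnot(inherits(epochs, "epoch_set"))
    arr <- epochs$data
    times_ms <- epochs$times_ms
    ch_labels <- epochs$channel_labels
    fs <- epochs$sampling_rate
  }
  if (any(bands$high >= fs / 2))
    stop("band edge at or above the Nyquist frequency")
  n_t <- dim(arr)[3]
  if (n_t / fs < 1 / min(bands$low))
    stop("epochs shorter than one cycle of the lowest band edge")
  centers <- (bands$low + bands$high) / 2
  ws <- lapply(centers, morlet_wavelet, fs = fs, n_cycles = n_cycles)
  nfft <- stats::nextn(n_t + max(lengths(ws)) - 1, 2)
  keep <- seq(1, n_t, by = decim)
  n_tr <- dim(arr)[1]; n_ch <- dim(arr)[2]
  out <- array(NA_real_, dim = c(n_tr, n_ch, nrow(bands), length(keep)))
  for (i in seq_len(n_tr)) {
    X <- t(arr[i, , , drop = TRUE])
    if (n_ch == 1) X <- matrix(arr[i, 1, ], ncol = 1)
    for (b in seq_len(nrow(bands))) {
      key <- sprintf("%g|%g|%d|%d", centers[b], fs, n_cycles, nfft)
      Y <- morlet_conv(X, ws[[b]], nfft, key)
      out[i, , b, ] <- t(Mod(Y[keep, , drop = FALSE]) ^ 2)
    }
  }
  structure(list(power = out, times_ms = times_ms[keep],
                 band_names = bands$name, channel_labels = ch_labels,
                 sampling_rate = fs, decim = decim, n_cycles = n_cycles),
            class = "band_power_set")
}

# Permutation group assignments: n_perm x n 0/1 indicator matrix for group
# 1 membership (row 1 = the observed labeling), or exhaustive enumeration.
perm_indicators <- function(n1, n2, n_perm, seed, exact) {
  n <- n1 + n2
  if (exact) {
    sets <- utils::combn(n, n1)
    G <- matrix(0, ncol(sets), n)
    for (j in seq_len(ncol(sets))) G[j, sets[, j]] <- 1
    # put the observed labeling (first n1) in row 1
    obs <- which(apply(G[, seq_len(n1), drop = FALSE] == 1, 1, all))[1]
    G[c(1, obs), ] <- G[c(obs, 1), ]
    return(G)
  }
  G <- matrix(0, n_perm, n)
  G[1, seq_len(n1)] <- 1
  withr::with_seed(seed, for (j in seq(2, length.out = n_perm - 1))
    G[j, sample.int(n, n1)] <- 1)
  G
}

# t and p matrices (perms x points) for two-sample Welch t statistics under
# label permutation.  X: n x P data (group 1 = first n1 rows as observed).
perm_t_matrix <- function(X, n1, n_perm, seed, exact) {
  n <- nrow(X); n2 <- n - n1
  G <- perm_indicators(n1, n2, n_perm, seed, exact)
  m <- nrow(G)
  S_all <- colSums(X); Q_all <- colSums(X ^ 2)
  S1 <- G %*% X
  Q1 <- G %*% (X ^ 2)
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, S_all, "+") / n2
  v1 <- (Q1 - n1 * m1 ^ 2) / (n1 - 1)
  v2 <- (sweep(-Q1, 2, Q_all, "+") - n2 * m2 ^ 2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  bad <- !(se2 > 1e-30)            # zero/negative-roundoff variance, NaN
  se2[bad] <- Inf
  Tm <- (m1 - m2) / sqrt(se2)
  Tm[bad] <- 0                     # degenerate points: t = 0 (p becomes 1)
  # fraction of perms with |t| >= this one, per point (column); |t| is
  # rounded to 10 significant digits so exact ties (e.g. a labeling and
  # its complement, which share |t| up to float roundoff) rank together
  r <- matrixStats::colRanks(signif(abs(Tm), 10), ties.method = "min",
                             preserveShape = TRUE)
  Pm <- (m - r + 1) / m
  list(t = Tm, p = Pm, n_perm_used = m)
}

#' Pointwise permutation test between two trial ensembles
#'
#' Two-sample Welch t statistic at every (channel, time) point; p-values
#' from the label-permutation null (the observed labeling is included in
#' the permutation set, so the smallest attainable p is `1/n_perm`).  When
#' `exact = TRUE` (or the number of distinct label splits is at most
#' `n_perm`) all splits are enumerated and the p-values are exact.
#'
#' @param smoking,neutral trials x channels x time arrays (same channel and
#'   time axes).
#' @param n_perm number of permutations (including the observed labeling).
#' @param alpha two-tailed pointwise significance level for `sig_mask`.
#' @param seed RNG seed for the permutation draw.
#' @param exact force (or forbid) exhaustive enumeration; default:
#'   enumerate when `choose(n, n1) <= n_perm`.
#' @param domain label stored in the result (`"amplitude"` or
#'   `"band:<name>"`).
#' @param channel_labels,times_ms optional axis annotation.
#' @return object of class `stat_map` with `t`, `p`, `sig_mask`
#'   (channels x time), the inputs needed to replay the permutation null,
#'   and axis metadata.
#' @export
pointwise_permutation <- function(smoking, neutral, n_perm = 1000,
                                  alpha = 0.05, seed = 1, exact = NULL,
                                  domain = "amplitude",
                                  channel_labels = NULL, times_ms = NULL) {
  stopifnot(length(dim(smoking)) == 3, length(dim(neutral)) == 3,
            all(dim(smoking)[2:3] == dim(neutral)[2:3]))
  n1 <- dim(smoking)[1]; n2 <- dim(neutral)[1]
  if (n1 < 2 || n2 < 2) stop("need at least 2 trials per condition")
  n_ch <- dim(smoking)[2]; n_time <- dim(smoking)[3]
  X <- rbind(matrix(smoking, n1, n_ch * n_time),
             matrix(neutral, n2, n_ch * n_time))
  if (is.null(exact)) exact <- choose(n1 + n2, n1) <= n_perm
  res <- perm_t_matrix(X, n1, n_perm, seed, exact)
  tmap <- matrix(res$t[1, ], n_ch, n_time)
  pmap <- matrix(res$p[1, ], n_ch, n_time)
  cache <- if (length(res$t) <= 2.5e7) res else NULL
  structure(list(domain = domain, t = tmap, p = pmap,
                 sig_mask = pmap < alpha, alpha = alpha,
                 n_perm = res$n_perm_used, seed = seed, exact = exact,
                 X = X, n1 = n1, null_cache = cache,
                 channel_labels = channel_labels,
                 times_ms = times_ms),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s: %d x %d points, %d flagged at alpha=%g (%d perms%s)\n",
              x$domain, nrow(x$t), ncol(x$t), sum(x$sig_mask), x$alpha,
              x$n_perm, if (x$exact) ", exact" else ""))
  invisible(x)
}

adjacency_to_list <- function(adjacency, n_ch) {
  if (is.null(adjacency)) return(lapply(seq_len(n_ch), function(i) integer(0)))
  stopifnot(is.matrix(adjacency), nrow(adjacency) == n_ch)
  lapply(seq_len(n_ch), function(i) which(adjacency[i, ]))
}

#' Cluster-mass correction of a pointwise statistic map
#'
#' Connected components of the suprathreshold mask (time-adjacent samples
#' within a channel; channel neighbors at the same sample; only same-sign
#' points join a cluster), with mass = sum of the t statistic over members.
#' The corrected p of a cluster is the fraction of permutations whose
#' maximum absolute cluster mass (over both signs, under the identical
#' thresholding rule) reaches the cluster's absolute mass — the standard
#' maximum-statistic family-wise error control.
#'
#' @param map a [pointwise_permutation()] result.
#' @param adjacency logical channel adjacency matrix
#'   (e.g. [montage_adjacency()]); `NULL` for no channel neighbors.
#' @param n_perm,seed permutation replay parameters; default: those of
#'   `map` (the same label shuffles are regenerated, so observed and null
#'   statistics come from one permutation set).
#' @param alpha cluster-level significance level.
#' @return object of class `cluster_feature_set`: `clusters` (list with
#'   `domain`, `sign`, `members` data.frame, `mass`, `corrected_p`,
#'   `keep`), `alpha`, `null_max_mass` (the permutation null), axis
#'   metadata.  An empty suprathreshold mask yields zero clusters.
#' @export
cluster_mass <- function(map, adjacency = NULL, n_perm = map$n_perm,
                         alpha = 0.05, seed = map$seed) {
  stopifnot(inherits(map, "stat_map"))
  n_ch <- nrow(map$t); n_time <- ncol(map$t)
  adj <- adjacency_to_list(adjacency, n_ch)
  res <- if (!is.null(map$null_cache) && n_perm == map$n_perm &&
             seed == map$seed) map$null_cache
         else perm_t_matrix(map$X, map$n1, n_perm, seed, map$exact)
  null_max <- cpp_perm_max_masses(res$t, res$p, n_ch, n_time, adj,
                                  map$alpha)
  found <- cpp_find_clusters(map$t, map$sig_mask, adj)
  clusters <- list()
  if (length(found$mass)) {
    for (ci in seq_along(found$mass)) {
      mem <- which(found$labels == ci, arr.ind = TRUE)
      members <- data.frame(channel = mem[, 1], time = mem[, 2])
      if (!is.null(map$channel_labels))
        members$channel_label <- map$channel_labels[members$channel]
      if (!is.null(map$times_ms))
        members$time_ms <- map$times_ms[members$time]
      mass <- found$mass[ci]
      corrected_p <- mean(null_max >= abs(mass))
      clusters[[ci]] <- list(
        domain = map$domain,
        sign = if (mass > 0) "smoking>neutral" else "smoking<neutral",
        members = members, mass = mass, corrected_p = corrected_p,
        keep = corrected_p < alpha)
    }
  }
  structure(list(clusters = clusters, alpha = alpha,
                 null_max_mass = null_max,
                 n_ch = n_ch, n_time = n_time,
                 domain = map$domain,
                 channel_labels = map$channel_labels,
                 times_ms = map$times_ms),
            class = "cluster_feature_set")
}

#' @export
print.cluster_feature_set <- function(x, ...) {
  ks <- vapply(x$clusters, function(cl) cl$keep, TRUE)
  cat(sprintf("<cluster_feature_set> %d cluster(s), %d significant at alpha=%g\n",
              length(x$clusters), sum(ks), x$alpha))
  for (cl in x$clusters[ks])
    cat(sprintf("  %s %s: %d points, mass %.1f, p=%.4g\n", cl$domain,
                cl$sign, nrow(cl$members), cl$mass, cl$corrected_p))
  invisible(x)
}

#' Retained clusters of one or more feature sets
#'
#' Concatenates the clusters with `corrected_p < alpha` from the given
#' `cluster_feature_set` objects into one feature recipe.
#'
#' @param ... `cluster_feature_set` objects.
#' @return a `cluster_feature_set` containing only significant clusters.
#' @export
significant_clusters <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "cluster_feature_set"))
    sets <- sets[[1]]
  clusters <- list()
  for (s in sets) {
    stopifnot(inherits(s, "cluster_feature_set"))
    for (cl in s$clusters) if (cl$keep) clusters[[length(clusters) + 1]] <- cl
  }
  structure(list(clusters = clusters, alpha = sets[[1]]$alpha,
                 null_max_mass = NULL, domain = "mixed"),
            class = "cluster_feature_set")
}

#' Run the full offline feature selection
#'
#' Pointwise permutation testing plus cluster-mass correction on the
#' time-domain amplitude map and on each band-power map (bands cluster
#' only within themselves), returning the combined set of significant
#' clusters.
#'
#' @param epochs a baseline-corrected, artifact-flagged `epoch_set`
#'   containing smoking and neutral trials (only `kept` trials are used).
#' @param bands a [band_set()].
#' @param adjacency channel adjacency; default from the montage.
#' @param n_perm,alpha,seed permutation parameters.
#' @param decim,n_cycles band-power parameters.
#' @param domains which domains to search.
#' @param band_power_set optional precomputed [band_power()] of `epochs`
#'   (same trial order; trials are subset alongside the epochs), to avoid
#'   recomputing the wavelet transform, e.g. inside cross-validation
#'   folds.
#' @return a `cluster_feature_set` of significant clusters (possibly
#'   empty).
#' @export
select_features <- function(epochs, bands = band_set(), adjacency = NULL,
                            n_perm = 1000, alpha = 0.05, seed = 1,
                            decim = 5, n_cycles = 7,
                            domains = c("amplitude", "bands"),
                            band_power_set = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- epochs$kept & epochs$labels %in% c("smoking", "neutral")
  ep <- subset_epochs(epochs, keep)
  if (!is.null(band_power_set)) {
    stopifnot(dim(band_power_set$power)[1] == length(epochs$labels))
    band_power_set$power <-
      band_power_set$power[keep, , , , drop = FALSE]
  }
  is_smoking <- ep$labels == "smoking"
  if (is.null(adjacency))
    adjacency <- montage_adjacency(ep$channel_labels)
  sets <- list()
  if ("amplitude" %in% domains) {
    map <- pointwise_permutation(
      ep$data[is_smoking, , , drop = FALSE],
      ep$data[!is_smoking, , , drop = FALSE],
      n_perm = n_perm, alpha = alpha, seed = seed,
      domain = "amplitude",
      channel_labels = ep$channel_labels, times_ms = ep$times_ms)
    sets[[length(sets) + 1]] <- cluster_mass(map, adjacency,
                                             alpha = alpha)
  }
  if ("bands" %in% domains) {
    bp <- if (!is.null(band_power_set)) band_power_set
          else band_power(ep, bands, n_cycles = n_cycles, decim = decim)
    for (b in seq_len(nrow(bands))) {
      map <- pointwise_permutation(
        bp$power[is_smoking, , b, , drop = TRUE],
        bp$power[!is_smoking, , b, , drop = TRUE],
        n_perm = n_perm, alpha = alpha, seed = seed + b,
        domain = paste0("band:", bands$name[b]),
        channel_labels = ep$channel_labels, times_ms = bp$times_ms)
      sets[[length(sets) + 1]] <- cluster_mass(map, adjacency,
                                               alpha = alpha)
    }
  }
  significant_clusters(sets)
}

#' Assemble per-trial feature vectors from a cluster recipe
#'
#' One value per cluster per trial: the mean of the cluster's domain
#' quantity (baseline-corrected amplitude, or Morlet band power) over the
#' cluster members.  For a single online 1-s window (channels x samples
#' matrix) the window is mean-centered per channel, its timebase is taken
#' as the 0-1000 ms post-stimulus period, and cluster members with
#' pre-stimulus times are dropped.
#'
#' @param x an `epoch_set` or a channels x samples matrix (one window).
#' @param featset a `cluster_feature_set` (significant clusters only, see
#'   [significant_clusters()]).
#' @param bands band definitions used for band-domain clusters.
#' @param fs sampling rate (matrix input only).
#' @param band_power_set optional precomputed [band_power()] of `x`
#'   (epoch input), to avoid recomputation.
#' @param n_cycles,decim band-power parameters (must match the selection).
#' @return numeric matrix, trials x clusters (a 1-row matrix for window
#'   input).
#' @export
assemble_features <- function(x, featset, bands = band_set(), fs = NULL,
                              band_power_set = NULL, n_cycles = 7,
                              decim = 5) {
  stopifnot(inherits(featset, "cluster_feature_set"))
  if (!length(featset$clusters))
    stop("no discriminative features - cannot build decoder")
  band_domains <- grepl("^band:", vapply(featset$clusters,
                                         function(cl) cl$domain, ""))
  if (is.matrix(x)) {
    if (is.null(fs)) stop("fs is required for window input")
    x <- x - rowMeans(x)                     # per-channel mean centering
    bp <- NULL; bp_chan <- NULL
    if (any(band_domains)) {
      # only the bands and channels the recipe references
      need <- unique(sub("^band:", "",
        vapply(featset$clusters[band_domains],
               function(cl) cl$domain, "")))
      bp_chan <- sort(unique(unlist(lapply(
        featset$clusters[band_domains], function(cl) cl$members$channel))))
      bp <- band_power(x[bp_chan, , drop = FALSE],
                       bands[bands$name %in% need, , drop = FALSE],
                       n_cycles = n_cycles, decim = decim, fs = fs)
    }
    out <- matrix(NA_real_, 1, length(featset$clusters))
    for (ci in seq_along(featset$clusters)) {
      cl <- featset$clusters[[ci]]
      mem <- cl$members
      tms <- if (!is.null(mem$time_ms)) mem$time_ms else
        stop("cluster members lack time_ms; cannot map onto a window")
      mem <- mem[tms >= 0, , drop = FALSE]
      if (!nrow(mem)) { out[1, ci] <- 0; next }
      if (grepl("^band:", cl$domain)) {
        b <- match(sub("^band:", "", cl$domain), bp$band_names)
        tidx <- vapply(mem$time_ms,
                       function(tm) which.min(abs(bp$times_ms - tm)), 1L)
        cidx <- match(mem$channel, bp_chan)
        vals <- bp$power[cbind(1, cidx, b, tidx)]
      } else {
        sidx <- pmin(ncol(x), round(mem$time_ms / 1000 * fs) + 1)
        vals <- x[cbind(mem$channel, sidx)]
      }
      out[1, ci] <- mean(vals)
    }
    return(out)
  }
  stopifnot(inherits(x, "epoch_set"))
  n_tr <- dim(x$data)[1]
  bp <- band_power_set
  if (any(band_domains) && is.null(bp))
    bp <- band_power(x, bands, n_cycles = n_cycles, decim = decim)
  out <- matrix(NA_real_, n_tr, length(featset$clusters))
  for (ci in seq_along(featset$clusters)) {
    cl <- featset$clusters[[ci]]
    mem <- cl$members
    if (grepl("^band:", cl$domain)) {
      b <- match(sub("^band:", "", cl$domain), bp$band_names)
      vals <- vapply(seq_len(nrow(mem)), function(k)
        bp$power[, mem$channel[k], b, mem$time[k]], numeric(n_tr))
    } else {
      vals <- vapply(seq_len(nrow(mem)), function(k)
        x$data[, mem$channel[k], mem$time[k]], numeric(n_tr))
    }
    vals <- matrix(vals, nrow = n_tr)
    out[, ci] <- rowMeans(vals)
  }
  out
}
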