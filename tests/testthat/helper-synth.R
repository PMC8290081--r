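# Shared fixtures, built in code.  Expensive objects (a full offline
# pipeline) are built once per test run and cached in an environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A compact 16-channel world: the planted effect channels plus EOG.
# Same planted effects as the default spec; inter-block rest shortened to
# keep recordings small (rest carries no analyzed data).
compact_spec <- function(seed = 33, ...) {
  simulation_spec(
    channels = c("Fp1", "Fp2", "Fz", "FCz", "Cz", "CP1", "CPz", "CP2",
                 "Pz", "P3", "P4", "POz", "O1", "Oz", "VEOG", "HEOG"),
    erp_effect = list(channels = c("CP1", "CPz", "CP2", "Pz"),
                      window_ms = c(300, 550), amplitude_uv = 5),
    band_effects = list(list(band = "alpha",
                             channels = c("P3", "Pz", "P4", "POz",
                                          "O1", "Oz"),
                             power_ratio = 1.5, base_amplitude_uv = 4)),
    rest_s = 2, seed = seed, ...)
}

# Build epoch_set objects directly (no epoching) for feature/decoder unit
# tests: n_s smoking + n_n neutral trials of white noise, with an optional
# additive shift on given (channel, time) cells of the smoking trials.
make_test_epochs <- function(n_s = 20, n_n = 20, n_ch = 6, n_t = 30,
                             shift = 0, shift_ch = NULL, shift_t = NULL,
                             fs = 250, seed = 1) {
  labs <- model60_labels()[seq_len(n_ch)]
  withr::with_seed(seed, {
    arr <- array(stats::rnorm((n_s + n_n) * n_ch * n_t),
                 c(n_s + n_n, n_ch, n_t))
  })
  if (shift != 0 && length(shift_ch) && length(shift_t))
    arr[seq_len(n_s), shift_ch, shift_t] <-
      arr[seq_len(n_s), shift_ch, shift_t] + shift
  structure(list(data = arr,
                 times_ms = (seq_len(n_t) - 1) / fs * 1000,
                 labels = rep(c("smoking", "neutral"), c(n_s, n_n)),
                 kept = rep(TRUE, n_s + n_n),
                 channel_labels = labs, sampling_rate = fs),
            class = "epoch_set")
}

# Compact-world offline pipeline: recording -> preprocess -> epochs ->
# feature selection -> calibrated decoder.  Cached.
compact_pipeline <- function() {
  fixture("compact_pipeline", function() {
    spec <- compact_spec()
    sch <- make_schedule(spec, spec$seed)
    rec <- generate_recording(spec, sch)
    rec <- remove_blinks_rls(highpass(rec, 0.5, "offline"))
    labs <- intersect(spec$channels, model60_labels())
    ep <- reject_epochs(epoch(extract_channels(rec, labs),
                              codes = c("smoking", "neutral")))
    ep <- subset_epochs(ep, ep$kept)
    adjacency <- montage_adjacency(labs)
    featset <- select_features(ep, adjacency = adjacency, seed = 5)
    feats <- assemble_features(ep, featset)
    decoder <- train_decoder(feats, ep$labels, seed = 1,
                             featset = featset)
    list(spec = spec, schedule = sch, epochs = ep, featset = featset,
         features = feats, decoder = decoder, adjacency = adjacency,
         model_labels = labs)
  })
}

# Independent R flood-fill oracle: connected components of same-sign
# suprathreshold points (time neighbors within channel, channel neighbors
# at same time), BFS, unrelated to the C++ implementation.
oracle_clusters <- function(tmap, mask, adjacency) {
  n_ch <- nrow(tmap); n_t <- ncol(tmap)
  labels <- matrix(0L, n_ch, n_t)
  masses <- numeric(0)
  nid <- 0L
  for (c0 in seq_len(n_ch)) for (t0 in seq_len(n_t)) {
    if (!mask[c0, t0] || labels[c0, t0]) next
    nid <- nid + 1L
    pos <- tmap[c0, t0] > 0
    queue <- list(c(c0, t0)); labels[c0, t0] <- nid
    mass <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      mass <- mass + tmap[cur[1], cur[2]]
      nbrs <- list(c(cur[1], cur[2] - 1), c(cur[1], cur[2] + 1))
      for (c2 in which(adjacency[cur[1], ]))
        nbrs <- c(nbrs, list(c(c2, cur[2])))
      for (nb in nbrs) {
        if (nb[2] < 1 || nb[2] > n_t) next
        if (mask[nb[1], nb[2]] && !labels[nb[1], nb[2]] &&
            (tmap[nb[1], nb[2]] > 0) == pos) {
          labels[nb[1], nb[2]] <- nid
          queue <- c(queue, list(nb))
        }
      }
    }
    masses <- c(masses, mass)
  }
  list(labels = labels, mass = masses)
}
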