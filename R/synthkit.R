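# Synthetic cue-reactivity EEG: a stated world standing in for human data.
# Smoking trials carry a planted centro-parietal P300-like deflection
# (boxcar over 300-550 ms) and a stronger posterior alpha oscillation;
# background is 1/f Gaussian noise; blinks propagate from VEOG to anterior
# scalp channels.  A virtual subject converts displayed feedback into the
# amplitude of the planted smoking pattern, closing the loop.

#' Simulation specification
#'
#' Describes the synthetic world: montage, sampling rate, planted
#' condition effects, background noise, and blink artifacts.  Defaults
#' emulate a 250 Hz, 64-channel (62 scalp + VEOG + HEOG) cue-reactivity
#' recording with a 5 uV P300-like smoking effect against 10 uV 1/f noise
#' and a posterior alpha power ratio of 1.5 between smoking and neutral
#' trials.
#'
#' @param channels channel labels; default the full [standard_montage()].
#' @param sampling_rate Hz.
#' @param erp_effect list with `channels`, `window_ms` (inside 0..1000) and
#'   `amplitude_uv`: a boxcar deflection added to smoking trials.
#' @param band_effects list of lists with `band`, `channels`,
#'   `power_ratio` (smoking/neutral, > 0) and `base_amplitude_uv` (RMS-like
#'   amplitude of the neutral-trial oscillation).
#' @param noise list with `exponent` (1/f^exponent power spectrum) and
#'   `amplitude_uv` (per-channel SD).
#' @param blink list with `rate_per_min`, `amplitude_uv` (at VEOG) and
#'   optional `propagation` (named scalp gains; default decays
#'   anterior to posterior).
#' @param stimulus_s,iti_s,rest_s trial timing: stimulus duration,
#'   inter-trial interval, inter-block rest (seconds).  The protocol never
#'   fixes stimulus/ITI durations, so these are configurable with 1 s + 1 s
#'   defaults.
#' @param seed integer driving every random element of generation.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(channels = standard_montage()$label,
                            sampling_rate = 250,
                            erp_effect = list(
                              channels = c("CP1", "CPz", "CP2",
                                           "P1", "Pz", "P2", "POz"),
                              window_ms = c(300, 550),
                              amplitude_uv = 5),
                            band_effects = list(list(
                              band = "alpha",
                              channels = c("P3", "Pz", "P4", "PO3", "POz",
                                           "PO4", "O1", "Oz", "O2"),
                              power_ratio = 1.5,
                              base_amplitude_uv = 4)),
                            noise = list(exponent = 1, amplitude_uv = 10),
                            blink = list(rate_per_min = 15,
                                         amplitude_uv = 150,
                                         propagation = NULL),
                            stimulus_s = 1, iti_s = 1, rest_s = 90,
                            seed = 1) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  w <- erp_effect$window_ms
  if (w[1] < 0 || w[2] > 1000 || w[1] >= w[2])
    stop("erp window must lie within 0..1000 ms")
  for (be in band_effects)
    if (be$power_ratio <= 0) stop("band power_ratio must be > 0")
  if (is.null(blink$propagation))
    blink$propagation <- default_blink_propagation(channels)
  if (!all(is.finite(blink$propagation)))
    stop("blink propagation gains must be finite")
  structure(list(channels = channels, sampling_rate = sampling_rate,
                 erp_effect = erp_effect, band_effects = band_effects,
                 noise = noise, blink = blink,
                 stimulus_s = stimulus_s, iti_s = iti_s, rest_s = rest_s,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Default blink propagation gains
#'
#' Scalp gain of the VEOG blink template, decaying anterior to posterior
#' (cubic in normalized anterior position); zero for EOG channels
#' themselves (VEOG receives the full template, HEOG a fixed 0.1).
#'
#' @param channels channel labels.
#' @return named numeric vector of gains in `[0, 1)`.
#' @export
default_blink_propagation <- function(channels) {
  m <- standard_montage(channels)
  g <- 0.5 * pmax(0, (m$y + 0.95) / 2) ^ 3
  g[m$kind == "eog"] <- 0
  names(g) <- m$label
  g
}

band_center <- function(band_name, bands = band_set()) {
  i <- match(band_name, bands$name)
  if (is.na(i)) stop("unknown band: ", band_name)
  (bands$low[i] + bands$high[i]) / 2
}

#' Build the block-design task schedule
#'
#' Six 55-trial blocks in the fixed pseudo-randomized condition order
#' neutral, smoking, smoking, neutral, smoking, neutral.  In each block 50
#' trials carry the block condition and 5 attention-catch animal trials sit
#' at seed-determined random positions.  Onsets advance by
#' `stimulus_s + iti_s` within a block, with `rest_s` between blocks and a
#' 2 s lead-in.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer; animal-trial placement depends only on this.
#' @return object of class `task_schedule`: `trials` data.frame
#'   (`block`, `trial`, `code`, `condition`, `onset_sample`), `blocks`
#'   data.frame, and timing parameters.
#' @export
make_schedule <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  block_cond <- c("neutral", "smoking", "smoking",
                  "neutral", "smoking", "neutral")
  fs <- spec$sampling_rate
  step <- round((spec$stimulus_s + spec$iti_s) * fs)
  rest <- round(spec$rest_s * fs)
  lead <- 2 * fs
  animal_pos <- withr::with_seed(seed,
    lapply(seq_along(block_cond), function(b) sort(sample.int(55, 5))))
  rows <- list()
  cursor <- lead
  for (b in seq_along(block_cond)) {
    code <- rep(block_cond[b], 55)
    code[animal_pos[[b]]] <- "animal"
    onset <- cursor + (seq_len(55) - 1) * step
    rows[[b]] <- data.frame(block = b, trial = seq_len(55), code = code,
                            condition = block_cond[b],
                            onset_sample = onset,
                            stringsAsFactors = FALSE)
    cursor <- cursor + 55 * step + rest
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 blocks = data.frame(block = seq_along(block_cond),
                                     condition = block_cond,
                                     stringsAsFactors = FALSE),
                 stimulus_s = spec$stimulus_s, iti_s = spec$iti_s,
                 rest_s = spec$rest_s, sampling_rate = fs, seed = seed),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> %d blocks (%s), %d trials\n",
              nrow(x$blocks), paste(substr(x$blocks$condition, 1, 1),
                                    collapse = ""),
              nrow(x$trials)))
  invisible(x)
}

# 1/f^exponent Gaussian noise, unit SD per channel, via spectral shaping.
# Returns an n_ch x n matrix.
one_over_f_noise <- function(n, exponent, n_ch = 1) {
  nfft <- stats::nextn(n, 2)
  f <- c(1, seq_len(nfft / 2), rev(seq_len(nfft / 2 - 1)))  # avoid f = 0
  shape <- f ^ (-exponent / 2)
  spec <- matrix(stats::rnorm(nfft * n_ch) + 1i * stats::rnorm(nfft * n_ch),
                 nfft, n_ch) * shape
  x <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  t(x) / matrixStats::colSds(x)
}

raised_cosine <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' The planted smoking-condition pattern
#'
#' Deterministic channels x samples template over one post-stimulus
#' window: the ERP boxcar on its channels plus phase-zero band
#' oscillations at the smoking-condition amplitude.  A virtual subject's
#' window is `craving_state * template + noise`.
#'
#' @param spec a [simulation_spec()].
#' @param n_samples window length in samples.
#' @return numeric matrix, channels x `n_samples` (uV).
#' @export
smoking_template <- function(spec, n_samples) {
  fs <- spec$sampling_rate
  tpl <- matrix(0, length(spec$channels), n_samples,
                dimnames = list(spec$channels, NULL))
  e <- spec$erp_effect
  i0 <- floor(e$window_ms[1] / 1000 * fs) + 1
  i1 <- min(n_samples, ceiling(e$window_ms[2] / 1000 * fs))
  ch <- intersect(e$channels, spec$channels)
  tpl[ch, i0:i1] <- tpl[ch, i0:i1] + e$amplitude_uv
  tt <- (seq_len(n_samples) - 1) / fs
  for (be in spec$band_effects) {
    fc <- band_center(be$band)
    amp <- be$base_amplitude_uv * sqrt(be$power_ratio) * sqrt(2)
    ch <- intersect(be$channels, spec$channels)
    tpl[ch, ] <- tpl[ch, ] +
      matrix(amp * sin(2 * pi * fc * tt), length(ch), n_samples,
             byrow = TRUE)
  }
  tpl
}

#' Generate a synthetic continuous recording
#'
#' Renders a schedule into continuous EEG: 1/f background noise on every
#' channel, the planted ERP boxcar added to smoking trials, band-limited
#' oscillations (random phase per trial) whose amplitude differs between
#' conditions according to the configured power ratio, and raised-cosine
#' blink transients on VEOG propagated to anterior scalp channels.  Fully
#' deterministic given `(spec, schedule)` (randomness comes from
#' `spec$seed`).
#'
#' @param spec a [simulation_spec()].
#' @param schedule a [make_schedule()] result.
#' @param duration_s optional total duration; an error is raised if the
#'   schedule (plus a full 1 s post-stimulus window) does not fit.
#' @return a [raw_recording()] with events
#'   (`sample` = onset, `code`, `condition`).
#' @export
generate_recording <- function(spec, schedule, duration_s = NULL) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(schedule, "task_schedule"))
  fs <- spec$sampling_rate
  need <- max(schedule$trials$onset_sample) + fs + 2 * fs
  n <- if (is.null(duration_s)) need else round(duration_s * fs)
  if (n < need)
    stop("schedule overruns the recording: need at least ",
         ceiling(need / fs), " s")
  n_ch <- length(spec$channels)
  withr::with_seed(spec$seed, {
    data <- one_over_f_noise(n, spec$noise$exponent, n_ch) *
            spec$noise$amplitude_uv
    dimnames(data) <- list(spec$channels, NULL)

    # condition effects, one post-stimulus second per trial
    nwin <- fs
    tt <- (seq_len(nwin) - 1) / fs
    e <- spec$erp_effect
    i0 <- floor(e$window_ms[1] / 1000 * fs) + 1
    i1 <- min(nwin, ceiling(e$window_ms[2] / 1000 * fs))
    erp_ch <- match(intersect(e$channels, spec$channels), spec$channels)
    for (k in seq_len(nrow(schedule$trials))) {
      tr <- schedule$trials[k, ]
      s <- tr$onset_sample
      if (tr$code == "smoking" && length(erp_ch))
        data[erp_ch, (s + i0):(s + i1)] <-
          data[erp_ch, (s + i0):(s + i1)] + e$amplitude_uv
      for (be in spec$band_effects) {
        fc <- band_center(be$band)
        amp <- be$base_amplitude_uv * sqrt(2)
        if (tr$code == "smoking") amp <- amp * sqrt(be$power_ratio)
        if (tr$code == "animal") amp <- 0   # catch trials: no planted bands
        if (amp == 0) next
        bch <- match(intersect(be$channels, spec$channels), spec$channels)
        phase <- stats::runif(1, 0, 2 * pi)
        osc <- amp * sin(2 * pi * fc * tt + phase)
        data[bch, (s + 1):(s + nwin)] <-
          data[bch, (s + 1):(s + nwin)] +
          matrix(osc, length(bch), nwin, byrow = TRUE)
      }
    }

    # blinks
    if (spec$blink$rate_per_min > 0 && spec$blink$amplitude_uv != 0) {
      n_blink <- stats::rpois(1, spec$blink$rate_per_min * n / fs / 60)
      if (n_blink > 0) {
        tpl <- raised_cosine(round(0.4 * fs)) * spec$blink$amplitude_uv
        onsets <- sort(sample.int(n - length(tpl), n_blink))
        gains <- spec$blink$propagation[spec$channels]
        veog <- which(spec$channels == "VEOG")
        heog <- which(spec$channels == "HEOG")
        for (o in onsets) {
          idx <- o + seq_along(tpl)
          data[, idx] <- data[, idx] + outer(gains, tpl)
          if (length(veog)) data[veog, idx] <- data[veog, idx] + tpl
          if (length(heog)) data[heog, idx] <- data[heog, idx] + 0.1 * tpl
        }
      }
    }
  })
  ev <- data.frame(sample = schedule$trials$onset_sample,
                   code = schedule$trials$code,
                   condition = schedule$trials$condition,
                   stringsAsFactors = FALSE)
  raw_recording(data, fs, spec$channels, events = ev)
}

#' Create a virtual subject
#'
#' Latent-state model of a trainee: `craving_state` in `[0, 1]` scales the
#' planted smoking pattern in every emitted window.  Displayed pictures
#' push the state up or down through `reactivity_gain` (high-craving
#' pictures increase it); a drop in the displayed score reduces the state
#' by `learning_rate` (successful downregulation is consolidated); Gaussian
#' state noise is added; the state is clipped to `[0, 1]`.
#'
#' @param craving_state initial latent state in `[0, 1]`.
#' @param reactivity_gain state change per unit of (picture level - 6)/5.
#' @param learning_rate state decrement applied when the displayed score
#'   fell at the previous update (>= 0).
#' @param state_noise_sd SD of the per-update state noise.
#' @param seed integer seeding the subject's private RNG stream.
#' @return object of class `virtual_subject`.
#' @export
virtual_subject <- function(craving_state = 0.8, reactivity_gain = 0.01,
                            learning_rate = 0.03, state_noise_sd = 0.02,
                            seed = 1) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(craving_state = clip01(craving_state),
                 reactivity_gain = reactivity_gain,
                 learning_rate = learning_rate,
                 state_noise_sd = state_noise_sd,
                 seed = as.integer(seed),
                 rng = rng_new(seed)),
            class = "virtual_subject")
}

#' Advance a virtual subject by one feedback update
#'
#' @param subject a [virtual_subject()].
#' @param picture_level displayed picture level, 1..11.
#' @param displayed_score_delta change of the displayed score at the last
#'   update (negative = the score fell).
#' @return the updated `virtual_subject`.
#' @export
virtual_subject_step <- function(subject, picture_level,
                                 displayed_score_delta = 0) {
  stopifnot(inherits(subject, "virtual_subject"))
  if (picture_level < 1 || picture_level > 11)
    stop("picture_level must be in 1..11")
  drive <- subject$reactivity_gain * (picture_level - 6) / 5
  decay <- if (displayed_score_delta < 0) subject$learning_rate else 0
  noise <- 0
  if (subject$state_noise_sd > 0) {
    d <- rng_draw(subject$rng,
                  function() stats::rnorm(1, 0, subject$state_noise_sd))
    noise <- d$value
    subject$rng <- d$state
  }
  subject$craving_state <- clip01(subject$craving_state + drive - decay +
                                  noise)
  subject
}

#' Emit one real-time EEG window from a virtual subject
#'
#' The window is `craving_state` times the planted smoking-pattern
#' template (deterministic given the spec) plus 1/f noise and occasional
#' blinks drawn from the subject's private RNG stream.
#'
#' @param subject a [virtual_subject()].
#' @param spec a [simulation_spec()].
#' @param duration_s window length in seconds (default 1).
#' @param template optional precomputed [smoking_template()] for this spec
#'   and window length (a per-session cache; recomputed when `NULL`).
#' @return list with `data` (channels x samples matrix, uV) and `subject`
#'   (with advanced RNG state).
#' @export
emit_window <- function(subject, spec, duration_s = 1, template = NULL) {
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(spec, "simulation_spec"))
  fs <- spec$sampling_rate
  n <- round(duration_s * fs)
  tpl <- if (is.null(template)) smoking_template(spec, n) else template
  win <- subject$craving_state * tpl
  if (spec$noise$amplitude_uv > 0 || spec$blink$rate_per_min > 0) {
    d <- rng_draw(subject$rng, function() {
      noise <- matrix(0, nrow(tpl), n)
      if (spec$noise$amplitude_uv > 0)
        noise <- one_over_f_noise(n, spec$noise$exponent, nrow(tpl)) *
                 spec$noise$amplitude_uv
      if (spec$blink$rate_per_min > 0 && spec$blink$amplitude_uv != 0) {
        nb <- stats::rpois(1, spec$blink$rate_per_min * duration_s / 60)
        if (nb > 0) {
          btpl <- raised_cosine(round(0.4 * fs)) * spec$blink$amplitude_uv
          gains <- spec$blink$propagation[spec$channels]
          veog <- which(spec$channels == "VEOG")
          heog <- which(spec$channels == "HEOG")
          for (b in seq_len(nb)) {
            o <- sample.int(n, 1) - 1           # may truncate at the edge
            idx <- o + seq_len(min(length(btpl), n - o))
            seg <- btpl[seq_along(idx)]
            noise[, idx] <- noise[, idx] + outer(gains, seg)
            if (length(veog)) noise[veog, idx] <- noise[veog, idx] + seg
            if (length(heog)) noise[heog, idx] <- noise[heog, idx] + 0.1 * seg
          }
        }
      }
      noise
    })
    win <- win + d$value
    subject$rng <- d$state
  }
  dimnames(win) <- list(spec$channels, NULL)
  list(data = win, subject = subject)
}
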