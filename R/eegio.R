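# Core containers: continuous recordings and epoch sets.

#' Construct a continuous EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channel_labels character vector, one unique label per row of
#'   `data`.
#' @param channel_kinds optional character vector (`"scalp"`, `"mastoid"`,
#'   `"eog"`); inferred from the standard label table when `NULL`
#'   (labels containing "EOG" become `"eog"`, M1/M2 `"mastoid"`, the rest
#'   `"scalp"`).
#' @param events data.frame with columns `sample` (0-based index into the
#'   recording), `code` (character or integer stimulus code) and optionally
#'   `condition`; sorted by onset.
#' @param montage montage name (currently `"standard"`) or a data.frame of
#'   per-channel positions as returned by [standard_montage()].
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(data, sampling_rate, channel_labels,
                          channel_kinds = NULL,
                          events = NULL, montage = "standard") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data))
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must equal nrow(data)")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (is.null(channel_kinds)) channel_kinds <- infer_channel_kinds(channel_labels)
  if (is.null(events))
    events <- data.frame(sample = integer(0), code = character(0),
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "code") %in% names(events)))
    stop("events must have columns 'sample' and 'code'")
  if (nrow(events)) {
    if (is.unsorted(events$sample)) events <- events[order(events$sample), ]
    if (any(events$sample < 0 | events$sample >= ncol(data)))
      stop("event sample indices out of recording bounds")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels),
                 channel_kinds = channel_kinds,
                 events = events, montage = montage),
            class = "raw_recording")
}

#' Infer channel kinds from labels
#'
#' @param labels character vector of channel labels.
#' @return character vector: `"eog"` for labels containing "EOG"
#'   (case-insensitive), `"mastoid"` for M1/M2, `"scalp"` otherwise.
#' @export
infer_channel_kinds <- function(labels) {
  kinds <- rep("scalp", length(labels))
  kinds[grepl("EOG", labels, ignore.case = TRUE)] <- "eog"
  kinds[toupper(labels) %in% c("M1", "M2")] <- "mastoid"
  kinds
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Select channels from a recording
#'
#' `policy = "model60"` keeps exactly the 60 modeling channels (the
#' standard cap minus CB1/CB2, mastoids and EOG), in montage order; a
#' character vector keeps those labels in the requested order.
#'
#' @param rec a [raw_recording()].
#' @param policy `"model60"` or a character vector of labels.
#' @return a `raw_recording` with the selected channels.
#' @export
extract_channels <- function(rec, policy = "model60") {
  stopifnot(inherits(rec, "raw_recording"))
  want <- if (identical(policy, "model60")) model60_labels() else as.character(policy)
  missing <- setdiff(want, rec$channel_labels)
  if (length(missing))
    stop("required channel(s) absent from recording: ",
         paste(missing, collapse = ", "))
  idx <- match(want, rec$channel_labels)
  raw_recording(rec$data[idx, , drop = FALSE], rec$sampling_rate,
                rec$channel_labels[idx], rec$channel_kinds[idx],
                rec$events, rec$montage)
}

#' Cut a recording into baseline-corrected epochs
#'
#' Extracts one epoch per selected event on a half-open window
#' `[window_ms[1], window_ms[2])` relative to event onset (0-based sample
#' indexing at the source rate: at 250 Hz the default window has exactly
#' 300 samples).  The per-trial, per-channel mean over the baseline
#' interval is subtracted.  Events whose window extends past either edge of
#' the recording are dropped with a warning; the drop count is available as
#' `attr(, "n_dropped")`.
#'
#' @param rec a [raw_recording()].
#' @param codes event codes to epoch around (matched against
#'   `events$code`); `NULL` selects all events.
#' @param window_ms numeric length-2, epoch window in ms relative to onset.
#' @param baseline_ms numeric length-2 inside `window_ms`, interval whose
#'   mean is subtracted; `NULL` disables baseline correction.
#' @return object of class `epoch_set`: list with `data`
#'   (trials x channels x time array), `times_ms`, `labels` (the condition
#'   per kept trial, from `events$condition` when present, else the code),
#'   `kept` (logical, all `TRUE` here; see [reject_epochs()]),
#'   `channel_labels`, `sampling_rate`.
#' @export
epoch <- function(rec, codes = NULL, window_ms = c(-200, 1000),
                  baseline_ms = c(-200, 0)) {
  stopifnot(inherits(rec, "raw_recording"))
  ev <- rec$events
  if (!is.null(codes)) ev <- ev[ev$code %in% codes, , drop = FALSE]
  if (!nrow(ev)) stop("no matching events to epoch")
  fs <- rec$sampling_rate
  s0 <- round(window_ms[1] / 1000 * fs)
  s1 <- round(window_ms[2] / 1000 * fs)   # half-open: samples s0 .. s1-1
  n_t <- s1 - s0
  ok <- ev$sample + s0 >= 0 & ev$sample + s1 <= ncol(rec$data)
  n_dropped <- sum(!ok)
  if (n_dropped)
    warning(sprintf("%d event(s) too close to the recording edge were dropped",
                    n_dropped))
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stop("all epochs fall outside the recording")
  n_ch <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(nrow(ev), n_ch, n_t))
  for (i in seq_len(nrow(ev))) {
    a <- ev$sample[i] + s0
    arr[i, , ] <- rec$data[, (a + 1):(a + n_t), drop = FALSE]
  }
  times_ms <- (s0 + seq_len(n_t) - 1) / fs * 1000
  if (!is.null(baseline_ms)) {
    bidx <- which(times_ms >= baseline_ms[1] & times_ms < baseline_ms[2])
    if (!length(bidx)) stop("baseline interval contains no samples")
    bl <- apply(arr[, , bidx, drop = FALSE], c(1, 2), mean)
    arr <- arr - array(bl, dim = dim(arr))  # recycles over time (3rd dim last)
  }
  labels <- if ("condition" %in% names(ev)) as.character(ev$condition)
            else as.character(ev$code)
  out <- structure(list(data = arr, times_ms = times_ms, labels = labels,
                        kept = rep(TRUE, nrow(ev)),
                        channel_labels = rec$channel_labels,
                        sampling_rate = fs),
                   class = "epoch_set")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%g..%g ms), %d kept\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms), sum(x$kept)))
  if (length(x$labels)) print(table(condition = x$labels))
  invisible(x)
}

#' Subset an epoch set by trial index
#'
#' @param epochs an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return an `epoch_set` with the selected trials.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  epochs$kept <- epochs$kept[idx]
  epochs
}
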