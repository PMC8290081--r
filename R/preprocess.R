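# Cleaning chain: high-pass filtering (see filters.R), recursive
# least-squares regression of the EOG reference channels out of the scalp,
# and amplitude-threshold epoch rejection.

#' RLS blink-removal configuration
#'
#' @param forgetting_factor exponential forgetting factor in (0, 1];
#'   0.9999 tracks slowly varying blink propagation.
#' @param init_regularization initial inverse-correlation scale
#'   (P0 = I / init_regularization); must be > 0.
#' @param reference_channels EOG channel labels regressed out jointly.
#' @return object of class `rls_config`.
#' @export
rls_config <- function(forgetting_factor = 0.9999,
                       init_regularization = 0.01,
                       reference_channels = c("VEOG", "HEOG")) {
  if (forgetting_factor <= 0 || forgetting_factor > 1)
    stop("forgetting_factor must be in (0, 1]")
  if (init_regularization <= 0) stop("init_regularization must be > 0")
  structure(list(forgetting_factor = forgetting_factor,
                 init_regularization = init_regularization,
                 reference_channels = reference_channels),
            class = "rls_config")
}

#' Remove ocular artifacts by recursive least squares
#'
#' Adaptive linear regression of the EOG reference channels out of every
#' non-reference channel, sample by sample (the classic RLS EOG filter).
#' Reference channels pass through unchanged.  Returns the cleaned
#' recording; final filter state (weights `W`, inverse correlation `P`) is
#' attached as `attr(, "rls_state")` so streamed use can continue where a
#' previous call stopped.
#'
#' @param rec a [raw_recording()].
#' @param cfg an [rls_config()].
#' @param state optional state from a previous call (streaming).
#' @return cleaned `raw_recording`.
#' @export
remove_blinks_rls <- function(rec, cfg = rls_config(), state = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  refs <- cfg$reference_channels
  missing <- setdiff(refs, rec$channel_labels)
  if (length(missing))
    stop("missing RLS reference channel(s): ",
         paste(missing, collapse = ", "))
  ridx <- match(refs, rec$channel_labels)
  U <- rec$data[ridx, , drop = FALSE]
  Y <- rec$data[-ridx, , drop = FALSE]
  nr <- length(ridx)
  if (is.null(state))
    state <- list(P = diag(nr) / cfg$init_regularization,
                  W = matrix(0, nr, nrow(Y)))
  res <- cpp_rls(Y, U, cfg$forgetting_factor, state$P, state$W)
  out <- rec
  out$data[-ridx, ] <- res$cleaned
  attr(out, "rls_state") <- list(P = res$P, W = res$W)
  out
}

#' Flag epochs exceeding an absolute amplitude threshold
#'
#' Sets `kept = FALSE` for every trial in which any channel's absolute
#' (post-baseline) amplitude exceeds the threshold.  Data are retained;
#' rejection is flag-based and idempotent.  The default 100 uV follows the
#' conventional artifact bound for baseline-corrected scalp EEG.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts.
#' @return the `epoch_set` with updated `kept` flags;
#'   `attr(, "n_rejected")` counts newly rejected trials.
#' @export
reject_epochs <- function(epochs, threshold_uv = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  mx <- apply(abs(epochs$data), 1, max)
  bad <- mx > threshold_uv
  newly <- sum(bad & epochs$kept)
  epochs$kept <- epochs$kept & !bad
  attr(epochs, "n_rejected") <- newly
  epochs
}

#' Streaming online preprocessor
#'
#' Bundles the causal high-pass filter and the RLS blink filter with
#' persistent state, mirroring the offline chain for 1-s real-time
#' windows.  `$process(window)` takes and returns a channels x samples
#' matrix (all recording channels, row names = labels).
#'
#' @param channel_labels labels of the incoming windows, in order.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz high-pass cutoff.
#' @param rls an [rls_config()], or `NULL` to skip blink removal.
#' @return environment with `$process(window)`.
#' @export
online_preprocessor <- function(channel_labels, fs, cutoff_hz = 0.5,
                                rls = rls_config()) {
  hp <- online_highpass(cutoff_hz, fs, length(channel_labels))
  ridx <- NULL
  rls_state <- NULL
  if (!is.null(rls)) {
    missing <- setdiff(rls$reference_channels, channel_labels)
    if (length(missing))
      stop("missing RLS reference channel(s): ",
           paste(missing, collapse = ", "))
    ridx <- match(rls$reference_channels, channel_labels)
    nr <- length(ridx)
    rls_state <- list(P = diag(nr) / rls$init_regularization,
                      W = matrix(0, nr, length(channel_labels) - nr))
  }
  env <- new.env()
  env$process <- function(window) {
    stopifnot(nrow(window) == length(channel_labels))
    y <- hp$process(window)
    if (!is.null(rls)) {
      res <- cpp_rls(y[-ridx, , drop = FALSE], y[ridx, , drop = FALSE],
                     rls$forgetting_factor, rls_state$P, rls_state$W)
      rls_state <<- list(P = res$P, W = res$W)
      y[-ridx, ] <- res$cleaned
    }
    rownames(y) <- channel_labels
    y
  }
  env
}
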