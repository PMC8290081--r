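# Filter design and application.  Offline cleaning uses a zero-phase
# windowed-sinc FIR high-pass; the real-time path uses a causal 4th-order
# Butterworth whose state is carried across streamed windows.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth filter coefficients
#'
#' Digital Butterworth design by bilinear transform of the analog
#' prototype, matching the conventional (SciPy/Matlab) formulation.
#'
#' @param n filter order.
#' @param cutoff_hz -3 dB cutoff in Hz.
#' @param fs sampling rate in Hz.
#' @param type `"high"` or `"low"`.
#' @return list with numerator `b` and denominator `a` (a, normalized so
#'   `a[1] == 1`).
#' @export
butter_design <- function(n, cutoff_hz, fs, type = c("high", "low")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie strictly inside (0, Nyquist)")
  W <- cutoff_hz / (fs / 2)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles, |p| = 1
  warped <- 4 * tan(pi * W / 2)                   # fs_internal = 2
  if (type == "low") {
    p <- p * warped
    z <- complex(0)
    gain <- warped ^ n
  } else {
    p <- warped / p
    z <- rep(0 + 0i, n)
    gain <- 1
  }
  fs2 <- 4                                        # 2 * fs_internal
  pd <- (fs2 + p) / (fs2 - p)
  zd <- if (length(z)) (fs2 + z) / (fs2 - z) else complex(0)
  zd <- c(zd, rep(-1 + 0i, n - length(zd)))
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Windowed-sinc FIR high-pass kernel
#'
#' Hamming-windowed sinc low-pass, spectrally inverted.  Kernel length is
#' chosen from the transition width by the standard Hamming rule
#' (about 3.3 / normalized transition), forced odd so the kernel is
#' symmetric and the filter exactly zero-phase.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param transition_hz transition band width in Hz.
#' @return numeric vector of odd length (the impulse response).
#' @export
fir_highpass_kernel <- function(cutoff_hz, fs, transition_hz = 0.5) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie strictly inside (0, Nyquist)")
  L <- ceiling(3.3 / (transition_hz / fs))
  if (L %% 2 == 0) L <- L + 1
  m <- (L - 1) / 2
  t <- seq(-m, m)
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc_(2 * fc * t)
  w <- 0.54 + 0.46 * cos(pi * t / m)
  h <- h * w
  h <- h / sum(h)              # unit DC gain for the low-pass
  hp <- -h
  hp[m + 1] <- hp[m + 1] + 1   # spectral inversion: delta - lowpass
  hp
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# FFT convolution, "same" alignment for an odd symmetric kernel, with
# reflection padding so edges see plausible data rather than zeros.
fft_filter_same <- function(x, h) {
  L <- length(h); m <- (L - 1) / 2; n <- length(x)
  pad <- min(m, n - 1)
  xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
  nfft <- stats::nextn(length(xp) + L - 1, 2)
  Y <- stats::fft(c(xp, rep(0, nfft - length(xp)))) *
       stats::fft(c(h, rep(0, nfft - L)))
  y <- Re(stats::fft(Y, inverse = TRUE)) / nfft
  y[(pad + m + 1):(pad + m + n)]
}

#' Stateful causal IIR filter over channel x sample matrices
#'
#' Applies the filter along rows with direct-form II transposed updates,
#' returning the final state so consecutive windows of a stream can be
#' filtered with no boundary discontinuity.
#'
#' @param b,a coefficient vectors (`a[1]` must be 1 after normalization).
#' @param x channels x samples matrix.
#' @param zi channels x order state matrix, or `NULL` for zero state.
#' @return list `y` (filtered matrix) and `zf` (final state).
#' @export
iir_filter <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  order <- max(length(a), length(b)) - 1
  if (is.null(zi)) zi <- matrix(0, nrow(x), order)
  res <- cpp_iir_df2t(as.numeric(b), as.numeric(a), x, as.matrix(zi))
  dimnames(res$y) <- dimnames(x)
  res
}

#' High-pass filter a recording
#'
#' `mode = "offline"` applies a zero-phase windowed-sinc FIR (no phase
#' distortion, suitable for ERP analysis).  `mode = "online"` applies a
#' causal 4th-order Butterworth in a single forward pass, the same filter
#' the streaming path uses, so offline reproductions of online sessions
#' match.
#'
#' @param rec a [raw_recording()].
#' @param cutoff_hz cutoff frequency (default 0.5 Hz).
#' @param mode `"offline"` (zero-phase) or `"online"` (causal).
#' @param transition_hz FIR transition band width (offline mode).
#' @return filtered `raw_recording`.
#' @export
highpass <- function(rec, cutoff_hz = 0.5, mode = c("offline", "online"),
                     transition_hz = 0.5) {
  stopifnot(inherits(rec, "raw_recording"))
  mode <- match.arg(mode)
  if (cutoff_hz >= rec$sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  if (mode == "offline") {
    h <- fir_highpass_kernel(cutoff_hz, rec$sampling_rate, transition_hz)
    if (length(h) >= 2 * ncol(rec$data))
      stop("recording too short for the FIR kernel; widen transition_hz")
    rec$data <- t(apply(rec$data, 1, fft_filter_same, h = h))
  } else {
    d <- butter_design(4, cutoff_hz, rec$sampling_rate, "high")
    rec$data <- iir_filter(d$b, d$a, rec$data)$y
  }
  rec
}

#' Streaming high-pass filter object
#'
#' Returns a stateful processor for 1-s real-time windows.  Calling
#' `$process(window)` filters a channels x samples matrix and keeps the
#' filter state, so a stream of consecutive windows is filtered identically
#' to the concatenated signal.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param n_channels number of channels in each window.
#' @return environment with `$process(window)` and `$reset()`.
#' @export
online_highpass <- function(cutoff_hz, fs, n_channels) {
  d <- butter_design(4, cutoff_hz, fs, "high")
  state <- matrix(0, n_channels, 4)
  env <- new.env()
  env$process <- function(window) {
    res <- iir_filter(d$b, d$a, window, state)
    state <<- res$zf
    res$y
  }
  env$reset <- function() state <<- matrix(0, n_channels, 4)
  env
}
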