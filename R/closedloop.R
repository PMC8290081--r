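# Real-time neurofeedback engine: every 2 s protocol update acquires one
# second of EEG, preprocesses it online, scores it with the personalized
# decoder, smooths the score over the last three points, and maps the
# displayed score onto one of 11 pictures ordered by craving level.  The
# engine runs on a virtual clock; timestamps in the trace reflect protocol
# time, not wall time.

#' Session configuration
#'
#' @param n_cycles training cycles per session (default 8).
#' @param trials_per_cycle score updates per cycle (default 40, i.e. 80 s).
#' @param update_period_s seconds per update: 1 s acquisition + 1 s
#'   classification/display (default 2).
#' @param inter_cycle_rest_s rating/rest seconds between cycles
#'   (default 60).
#' @param picture_levels number of feedback pictures (default 11).
#' @param smooth_on smooth over the `"raw"` scores (default) or over the
#'   previously `"displayed"` values.
#' @param smoothing_reset reset the first-two-points rule per `"cycle"`
#'   (default: the feedback line is redrawn after every rating screen, so
#'   each cycle starts with the two fixed 0.5 points; this also keeps the
#'   display-initialization anchors from biasing per-cycle score means)
#'   or per `"session"`.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_cycles = 8, trials_per_cycle = 40,
                           update_period_s = 2, inter_cycle_rest_s = 60,
                           picture_levels = 11,
                           smooth_on = c("raw", "displayed"),
                           smoothing_reset = c("cycle", "session")) {
  stopifnot(n_cycles > 0, trials_per_cycle > 0, update_period_s > 0,
            inter_cycle_rest_s >= 0, picture_levels > 0)
  structure(list(n_cycles = n_cycles, trials_per_cycle = trials_per_cycle,
                 update_period_s = update_period_s,
                 inter_cycle_rest_s = inter_cycle_rest_s,
                 picture_levels = picture_levels,
                 smooth_on = match.arg(smooth_on),
                 smoothing_reset = match.arg(smoothing_reset)),
            class = "session_config")
}

#' Three-point feedback smoothing
#'
#' The displayed value at update n is the mean of the raw scores at
#' updates n, n-1, n-2; the first two updates are fixed at 0.5 (no
#' previous points to average).
#'
#' @param raw_history numeric vector of raw scores up to and including the
#'   current update.
#' @return the displayed score for the last update.
#' @export
smooth_score <- function(raw_history) {
  n <- length(raw_history)
  if (n <= 2) return(0.5)
  mean(raw_history[(n - 2):n])
}

#' Smooth a whole raw-score sequence
#' @param raws numeric vector of raw scores.
#' @return displayed scores, same length.
#' @export
smooth_trace <- function(raws) {
  vapply(seq_along(raws), function(n) smooth_score(raws[seq_len(n)]),
         numeric(1))
}

#' Map a displayed score onto a picture level
#'
#' Monotone non-decreasing step map onto 11 levels: uniform bins of width
#' 1/11 on `[0, 1]`, right edge closed (score 1 is level 11).  Out-of-range
#' scores are clipped with a warning.
#'
#' @param score displayed score(s) in `[0, 1]`.
#' @param levels number of picture levels.
#' @return integer level(s) in `1..levels`.
#' @export
picture_for <- function(score, levels = 11) {
  if (any(score < 0 | score > 1)) {
    warning("score outside [0, 1]; clipping")
    score <- clip01(score)
  }
  pmin(as.integer(floor(score * levels)) + 1L, as.integer(levels))
}

#' Window source backed by a virtual subject
#'
#' Closes the loop: at each request the displayed picture level and the
#' last displayed-score change are fed into [virtual_subject_step()], and
#' the advanced subject emits the next 1-s window.
#'
#' @param subject a [virtual_subject()].
#' @param spec the [simulation_spec()] the decoder was trained on.
#' @return object of class `virtual_source`.
#' @export
virtual_source <- function(subject, spec) {
  structure(list(subject = subject, spec = spec,
                 template = smoking_template(spec, spec$sampling_rate)),
            class = c("virtual_source", "window_source"))
}

#' Window source replaying a continuous recording
#'
#' Serves consecutive non-overlapping 1-s windows; raises an error when
#' the recording is exhausted.
#'
#' @param rec a [raw_recording()].
#' @return object of class `replay_source`.
#' @export
replay_source <- function(rec) {
  structure(list(rec = rec, cursor = 0),
            class = c("replay_source", "window_source"))
}

#' Draw the next window from a source
#' @param source a window source.
#' @param picture_level current picture level shown to the subject.
#' @param displayed_delta last change in the displayed score.
#' @param duration_s window length.
#' @return list with `data` (channels x samples) and the updated `source`.
#' @export
source_next <- function(source, picture_level, displayed_delta,
                        duration_s = 1) UseMethod("source_next")

#' @export
source_next.virtual_source <- function(source, picture_level,
                                       displayed_delta, duration_s = 1) {
  source$subject <- virtual_subject_step(source$subject, picture_level,
                                         displayed_delta)
  tpl <- if (round(duration_s * source$spec$sampling_rate) ==
             ncol(source$template)) source$template else NULL
  out <- emit_window(source$subject, source$spec, duration_s,
                     template = tpl)
  source$subject <- out$subject
  list(data = out$data, source = source)
}

#' @export
source_next.replay_source <- function(source, picture_level,
                                      displayed_delta, duration_s = 1) {
  fs <- source$rec$sampling_rate
  n <- round(duration_s * fs)
  if (source$cursor + n > ncol(source$rec$data))
    stop("window source exhausted")
  win <- source$rec$data[, (source$cursor + 1):(source$cursor + n),
                         drop = FALSE]
  source$cursor <- source$cursor + n
  list(data = win, source = source)
}

run_loop_updates <- function(decoder, source, cfg, preproc, n_updates,
                             cycle_idx, t0, history) {
  fs <- attr(preproc, "fs")
  rows <- vector("list", n_updates)
  for (u in seq_len(n_updates)) {
    last_level <- if (length(history$levels))
      history$levels[length(history$levels)] else 6L
    delta <- if (length(history$displayed) >= 2) {
      nd <- length(history$displayed)
      history$displayed[nd] - history$displayed[nd - 1]
    } else 0
    nx <- tryCatch(
      source_next(source, last_level, delta),
      error = function(e) e)
    if (inherits(nx, "error")) {
      out <- list(rows = do.call(rbind, rows[seq_len(u - 1)]),
                  source = source, history = history, error = nx)
      return(out)
    }
    source <- nx$source
    win <- preproc$process(nx$data)
    midx <- match(attr(preproc, "model_labels"), rownames(win))
    feats <- assemble_features(win[midx, , drop = FALSE],
                               decoder$featset, decoder$bands, fs = fs)
    raw <- unname(score_decoder(decoder, feats))
    basis <- if (cfg$smooth_on == "raw") c(history$raws, raw)
             else c(history$displayed, raw)
    displayed <- smooth_score(basis)
    level <- picture_for(displayed, cfg$picture_levels)
    history$raws <- c(history$raws, raw)
    history$displayed <- c(history$displayed, displayed)
    history$levels <- c(history$levels, level)
    rows[[u]] <- data.frame(cycle = cycle_idx, trial = u,
                            t_s = t0 + (u - 1) * cfg$update_period_s,
                            raw_score = raw, displayed_score = displayed,
                            picture_level = level)
  }
  list(rows = do.call(rbind, rows), source = source, history = history,
       error = NULL)
}

make_session_preproc <- function(decoder, source, cutoff_hz = 0.5,
                                 rls = rls_config()) {
  labels <- if (inherits(source, "virtual_source")) source$spec$channels
            else source$rec$channel_labels
  fs <- if (inherits(source, "virtual_source"))
    source$spec$sampling_rate else source$rec$sampling_rate
  if (!all(rls$reference_channels %in% labels)) rls <- NULL
  pp <- online_preprocessor(labels, fs, cutoff_hz, rls)
  attr(pp, "fs") <- fs
  attr(pp, "model_labels") <- intersect(labels, model60_labels())
  pp
}

#' Run one neurofeedback cycle
#'
#' Exactly `trials_per_cycle` updates: acquire a 1-s window, preprocess it
#' online (causal high-pass + RLS), assemble the decoder's cluster
#' features, score, smooth, map to a picture, and feed the picture back to
#' the source (closing the loop for virtual subjects).  Source exhaustion
#' raises an error carrying the partial trace in
#' `attr(condition, "partial_trace")`.
#'
#' @param decoder a [train_decoder()] result carrying its `featset`.
#' @param source a [virtual_source()] or [replay_source()].
#' @param cfg a [session_config()].
#' @param preproc optional streaming preprocessor (created fresh when
#'   `NULL`).
#' @return `feedback_trace` data.frame fragment (one row per update) with
#'   the updated `source` in `attr(, "source")`.
#' @export
run_cycle <- function(decoder, source, cfg = session_config(),
                      preproc = NULL) {
  stopifnot(inherits(decoder, "trained_decoder"))
  if (is.null(decoder$featset))
    stop("decoder carries no feature recipe (featset)")
  if (is.null(preproc)) preproc <- make_session_preproc(decoder, source)
  res <- run_loop_updates(decoder, source, cfg, preproc,
                          cfg$trials_per_cycle, 1L, 0,
                          list(raws = numeric(0), displayed = numeric(0),
                               levels = integer(0)))
  if (!is.null(res$error)) {
    cond <- simpleError(paste0("cycle aborted: ",
                               conditionMessage(res$error)))
    attr(cond, "partial_trace") <- res$rows
    stop(cond)
  }
  out <- res$rows
  class(out) <- c("feedback_trace", "data.frame")
  attr(out, "source") <- res$source
  out
}

#' Run a full neurofeedback session
#'
#' `n_cycles` cycles with `inter_cycle_rest_s` gaps in the virtual
#' timeline.  The three-point smoothing history resets per cycle (or per
#' session, by config); the first two updates after a reset display 0.5.
#'
#' @inheritParams run_cycle
#' @return `feedback_trace` data.frame, one row per update (columns
#'   `cycle`, `trial`, `t_s`, `raw_score`, `displayed_score`,
#'   `picture_level`), with the final `source` in `attr(, "source")`.
#' @export
run_session <- function(decoder, source, cfg = session_config()) {
  stopifnot(inherits(decoder, "trained_decoder"))
  if (is.null(decoder$featset))
    stop("decoder carries no feature recipe (featset)")
  preproc <- make_session_preproc(decoder, source)
  cycle_span <- cfg$trials_per_cycle * cfg$update_period_s +
    cfg$inter_cycle_rest_s
  history <- list(raws = numeric(0), displayed = numeric(0),
                  levels = integer(0))
  traces <- vector("list", cfg$n_cycles)
  for (cy in seq_len(cfg$n_cycles)) {
    if (cfg$smoothing_reset == "cycle")
      history <- list(raws = numeric(0), displayed = numeric(0),
                      levels = integer(0))
    res <- run_loop_updates(decoder, source, cfg, preproc,
                            cfg$trials_per_cycle, cy,
                            (cy - 1) * cycle_span, history)
    if (!is.null(res$error)) {
      cond <- simpleError(paste0("session aborted in cycle ", cy, ": ",
                                 conditionMessage(res$error)))
      attr(cond, "partial_trace") <-
        rbind(do.call(rbind, traces[seq_len(cy - 1)]), res$rows)
      stop(cond)
    }
    traces[[cy]] <- res$rows
    source <- res$source
    history <- res$history
  }
  out <- do.call(rbind, traces)
  class(out) <- c("feedback_trace", "data.frame")
  attr(out, "source") <- source
  out
}

#' Per-cycle mean displayed score of a trace
#' @param trace a `feedback_trace`.
#' @return data.frame with `cycle` and `mean_displayed`.
#' @export
cycle_means <- function(trace) {
  agg <- stats::aggregate(displayed_score ~ cycle, data = trace, FUN = mean)
  names(agg) <- c("cycle", "mean_displayed")
  agg
}

#' Write a feedback trace as CSV
#' @param trace a `feedback_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a feedback trace CSV
#' @param path CSV written by [write_trace()].
#' @return a `feedback_trace` data.frame.
#' @export
read_trace <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("feedback_trace", "data.frame")
  out
}
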