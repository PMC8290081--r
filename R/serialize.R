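# Portable on-disk forms: simulation specs and schedules as YAML, feature
# recipes and decoders as JSON (clusters stored as channel-label + ms
# lists so a decoder artifact is human-inspectable).

#' Write / read a simulation spec as YAML
#' @param spec a [simulation_spec()].
#' @param path file path.
#' @return `path` invisibly / the spec.
#' @export
write_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  x <- unclass(spec)
  x$blink$propagation <- as.list(x$blink$propagation)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  prop <- x$blink$propagation
  blink <- x$blink
  blink$propagation <- if (is.null(prop)) NULL else
    stats::setNames(as.numeric(unlist(prop)), names(prop))
  simulation_spec(channels = unlist(x$channels),
                  sampling_rate = x$sampling_rate,
                  erp_effect = list(
                    channels = unlist(x$erp_effect$channels),
                    window_ms = unlist(x$erp_effect$window_ms),
                    amplitude_uv = x$erp_effect$amplitude_uv),
                  band_effects = lapply(x$band_effects, function(be)
                    list(band = be$band, channels = unlist(be$channels),
                         power_ratio = be$power_ratio,
                         base_amplitude_uv = be$base_amplitude_uv)),
                  noise = x$noise, blink = blink,
                  stimulus_s = x$stimulus_s, iti_s = x$iti_s,
                  rest_s = x$rest_s, seed = x$seed)
}

#' Write / read a task schedule as YAML
#' @param schedule a [make_schedule()] result.
#' @param path file path.
#' @return `path` invisibly / the schedule.
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  x <- unclass(schedule)
  x$trials <- as.list(x$trials)
  x$blocks <- as.list(x$blocks)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(trials = as.data.frame(lapply(x$trials, unlist),
                                        stringsAsFactors = FALSE),
                 blocks = as.data.frame(lapply(x$blocks, unlist),
                                        stringsAsFactors = FALSE),
                 stimulus_s = x$stimulus_s, iti_s = x$iti_s,
                 rest_s = x$rest_s, sampling_rate = x$sampling_rate,
                 seed = x$seed),
            class = "task_schedule")
}

featset_to_list <- function(featset) {
  list(alpha = featset$alpha,
       clusters = lapply(featset$clusters, function(cl) list(
         domain = cl$domain, sign = cl$sign, mass = cl$mass,
         corrected_p = cl$corrected_p, keep = cl$keep,
         channel = cl$members$channel,
         time = cl$members$time,
         channel_label = cl$members$channel_label,
         time_ms = cl$members$time_ms)))
}

featset_from_list <- function(x) {
  clusters <- lapply(x$clusters, function(cl) {
    members <- data.frame(channel = as.integer(unlist(cl$channel)),
                          time = as.integer(unlist(cl$time)))
    if (!is.null(cl$channel_label))
      members$channel_label <- as.character(unlist(cl$channel_label))
    if (!is.null(cl$time_ms))
      members$time_ms <- as.numeric(unlist(cl$time_ms))
    list(domain = cl$domain, sign = cl$sign, members = members,
         mass = cl$mass, corrected_p = cl$corrected_p, keep = cl$keep)
  })
  structure(list(clusters = clusters, alpha = x$alpha,
                 null_max_mass = NULL, domain = "mixed"),
            class = "cluster_feature_set")
}

#' Write / read a cluster feature set as JSON
#' @param featset a `cluster_feature_set`.
#' @param path file path.
#' @return `path` invisibly / the feature set.
#' @export
write_featset_json <- function(featset, path) {
  stopifnot(inherits(featset, "cluster_feature_set"))
  jsonlite::write_json(featset_to_list(featset), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_featset_json
#' @export
read_featset_json <- function(path) {
  featset_from_list(jsonlite::read_json(path))
}

#' Write / read a trained decoder as JSON
#'
#' The artifact carries the full feature recipe (clusters, bands),
#' standardization, SVM weights and Platt calibration, so a session can be
#' replayed from the file alone.
#'
#' @param decoder a [train_decoder()] result.
#' @param path file path.
#' @return `path` invisibly / the decoder.
#' @export
write_decoder_json <- function(decoder, path) {
  stopifnot(inherits(decoder, "trained_decoder"))
  x <- list(w = decoder$w, b = decoder$b, mu = decoder$mu,
            sd = decoder$sd, platt = as.list(decoder$platt),
            classes = decoder$classes, positive = decoder$positive,
            C = decoder$C, cv_accuracy = decoder$cv_accuracy,
            bands = as.list(decoder$bands),
            featset = if (is.null(decoder$featset)) NULL else
              featset_to_list(decoder$featset))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_decoder_json
#' @export
read_decoder_json <- function(path) {
  x <- jsonlite::read_json(path)
  num <- function(v) as.numeric(unlist(v))
  structure(list(w = num(x$w), b = num(x$b), mu = num(x$mu),
                 sd = num(x$sd),
                 platt = c(A = num(x$platt$A), B = num(x$platt$B)),
                 classes = as.character(unlist(x$classes)),
                 positive = x$positive, C = num(x$C),
                 cv_accuracy = if (is.null(x$cv_accuracy)) NA_real_
                               else num(x$cv_accuracy),
                 featset = if (is.null(x$featset)) NULL else
                   featset_from_list(x$featset),
                 bands = as.data.frame(lapply(x$bands, unlist),
                                       stringsAsFactors = FALSE)),
            class = "trained_decoder")
}
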