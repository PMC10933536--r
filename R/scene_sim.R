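# Synthetic multi-tag acoustic scenes with full ground truth: whale tracks
# with dive cycles, bout-structured call production with conspecific
# responses, distance-dependent received levels under geometric spreading,
# and optional waveform rendering.

#' Simulation configuration
#'
#' Defines a synthetic deployment of a small, fully tagged group of whales,
#' separated from any other whales, in which every call is audible at short
#' range. All randomness flows from `seed`.
#'
#' @param n_whales group size (default 2; pairs and trios are typical)
#' @param duration scene duration, seconds
#' @param tag_offset acoustic distance from a tag to its own whale's sound
#'   source, metres (default 1)
#' @param spacing_mean typical inter-whale horizontal distance, metres
#' @param spacing_model `"fixed"` (static geometry) or `"ou_wander"`
#'   (Ornstein-Uhlenbeck wander around the anchor positions)
#' @param source_level_mean,source_level_sd call source level distribution,
#'   dB re 1 uPa at 1 m. Defaults (155, 6) are simulator choices for
#'   moderate-level baleen whale social calls, not measured values.
#' @param noise_level broadband background level, dB re 1 uPa
#' @param detect_snr detectability threshold, dB: a call registers on a tag
#'   only when its received level exceeds the noise floor by this margin
#' @param spreading_coeff geometric spreading coefficient `k` in
#'   `k*log10(r)` transmission loss (default 20, spherical)
#' @param bout_p,bout_lambda_fast,bout_lambda_slow weight and rates (1/s) of
#'   the two-process exponential-mixture inter-call-interval process
#' @param response_prob probability a whale answers a conspecific call
#' @param response_latency_mean mean response latency, seconds (exponential)
#' @param call_dur_mean,call_dur_sd call duration distribution, seconds
#' @param dive_depth_max maximum dive depth, metres (defaults to 45 m,
#'   typical of feeding-ground dives of 30-60 m)
#' @param dive_cycle_s dive cycle period, seconds
#' @param track_rate track sampling rate, Hz (default 5, the decimated
#'   sensor rate)
#' @param fs audio sampling rate for waveform rendering, Hz (default 96000)
#' @param sweep frequency sweep of the rendered calls, Hz (default
#'   c(300, 800))
#' @param sensitivity hydrophone sensitivity used in rendering, dB re 1 V/uPa
#' @param seed integer RNG seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_whales = 2, duration = 3600, tag_offset = 1,
                       spacing_mean = 100, spacing_model = c("fixed", "ou_wander"),
                       source_level_mean = 155, source_level_sd = 6,
                       noise_level = 95, detect_snr = 10, spreading_coeff = 20,
                       bout_p = 0.75, bout_lambda_fast = 0.5,
                       bout_lambda_slow = 0.01, response_prob = 0.5,
                       response_latency_mean = 20, call_dur_mean = 1,
                       call_dur_sd = 0.3, dive_depth_max = 45,
                       dive_cycle_s = 300, track_rate = 5, fs = 96000,
                       sweep = c(300, 800), sensitivity = -171, seed = 1) {
  spacing_model <- match.arg(spacing_model)
  if (!is_count(n_whales) || n_whales < 1) fc_stop("n_whales must be >= 1", "invalid_config")
  if (!is_scalar(duration) || duration < 0) fc_stop("duration must be >= 0", "invalid_config")
  if (bout_lambda_fast <= bout_lambda_slow)
    fc_stop("bout_lambda_fast must exceed bout_lambda_slow", "invalid_config")
  if (bout_p <= 0 || bout_p >= 1) fc_stop("bout_p must be in (0, 1)", "invalid_config")
  if (any(c(bout_lambda_fast, bout_lambda_slow, track_rate, dive_cycle_s) <= 0))
    fc_stop("rates and periods must be positive", "invalid_config")
  if (tag_offset >= spacing_mean)
    fc_stop("tag_offset must be smaller than spacing_mean", "invalid_config")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Scene configuration: %d whales, %.0f s, spacing %.0f m (%s), seed %d\n",
    "  SL ~ N(%.0f, %.0f) dB, noise %.0f dB, detect SNR %.0f dB, k = %.0f\n",
    "  ICI mixture p = %.2f, lambda_fast = %.3g, lambda_slow = %.3g /s\n"),
    x$n_whales, x$duration, x$spacing_mean, x$spacing_model, x$seed,
    x$source_level_mean, x$source_level_sd, x$noise_level, x$detect_snr,
    x$spreading_coeff, x$bout_p, x$bout_lambda_fast, x$bout_lambda_slow))
  invisible(x)
}

whale_ids <- function(n) sprintf("whale%d", seq_len(n))
tag_ids <- function(n) sprintf("tag%d", seq_len(n))

# anchor positions: pair on a segment, trio (or more) on a regular polygon,
# with nearest-neighbour spacing equal to spacing_mean
anchor_positions <- function(n, spacing) {
  if (n == 1) return(cbind(x = 0, y = 0))
  if (n == 2) return(cbind(x = c(0, spacing), y = c(0, 0)))
  r <- spacing / (2 * sin(pi / n))
  a <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = r * cos(a), y = r * sin(a))
}

#' Simulate whale tracks
#'
#' Generates per-whale horizontal positions and depth profiles at the track
#' sampling rate. Depth follows repeated dive cycles between the surface
#' (< 2 m) and a per-cycle maximum drawn between 60 and 100% of
#' `dive_depth_max`; horizontal positions are static (`fixed`) or wander
#' around group anchors (`ou_wander`).
#'
#' @param config a [sim_config()]
#' @return data frame: `whale_id`, `time`, `x`, `y`, `depth`
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration <= 0) fc_stop("duration must be positive", "invalid_config")
  set.seed(config$seed)
  dt <- 1 / config$track_rate
  times <- seq(0, config$duration, by = dt)
  anchors <- anchor_positions(config$n_whales, config$spacing_mean)
  out <- vector("list", config$n_whales)
  for (w in seq_len(config$n_whales)) {
    if (config$spacing_model == "fixed") {
      x <- rep(anchors[w, 1], length(times))
      y <- rep(anchors[w, 2], length(times))
    } else {
      # OU wander around the anchor; sd scales with group spacing but stays
      # small enough to preserve the separation ordering
      theta <- 0.02; sig <- 0.03 * config$spacing_mean
      x <- y <- numeric(length(times))
      x[1] <- anchors[w, 1]; y[1] <- anchors[w, 2]
      ex <- rnorm(length(times) - 1); ey <- rnorm(length(times) - 1)
      for (i in seq_along(times)[-1]) {
        x[i] <- x[i - 1] + theta * (anchors[w, 1] - x[i - 1]) * dt +
          sig * sqrt(dt) * ex[i - 1]
        y[i] <- y[i - 1] + theta * (anchors[w, 2] - y[i - 1]) * dt +
          sig * sqrt(dt) * ey[i - 1]
      }
    }
    # dive cycles: 20% surface phase near 0.5 m, then a smooth excursion
    phase0 <- runif(1) * config$dive_cycle_s
    n_cycles <- ceiling((config$duration + phase0) / config$dive_cycle_s) + 1L
    cycle_max <- runif(n_cycles, 0.6, 1) * config$dive_depth_max
    u <- ((times + phase0) %% config$dive_cycle_s) / config$dive_cycle_s
    cyc <- floor((times + phase0) / config$dive_cycle_s) + 1L
    surface_frac <- 0.2
    depth <- ifelse(u < surface_frac, 0.5,
                    cycle_max[cyc] *
                      sin(pi * (u - surface_frac) / (1 - surface_frac))^2)
    out[[w]] <- data.frame(whale_id = whale_ids(config$n_whales)[w],
                           time = times, x = x, y = y, depth = depth,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

track_lookup <- function(tracks, whale, t) {
  tw <- tracks[tracks$whale_id == whale, ]
  c(x = approx(tw$time, tw$x, t, rule = 2)$y,
    y = approx(tw$time, tw$y, t, rule = 2)$y,
    depth = approx(tw$time, tw$depth, t, rule = 2)$y)
}

#' Simulate call event times
#'
#' Each whale produces spontaneous calls as a renewal process whose
#' inter-call intervals follow the two-process exponential mixture
#' `p * Exp(lambda_fast) + (1 - p) * Exp(lambda_slow)`. Additionally, on
#' hearing a conspecific's spontaneous call, each other whale answers with
#' probability `response_prob` after an exponential latency (responses do
#' not themselves trigger responses). Calls carry durations, source levels
#' and emission depths; the generating process is recorded per call.
#'
#' @param config a [sim_config()]
#' @param tracks tracks from [simulate_tracks()] (for emission depths)
#' @return data frame: `call_id`, `whale_id`, `t_emit`, `duration`,
#'   `source_level`, `emit_depth`, `process` (`"bout"` or `"response"`)
#' @export
simulate_call_times <- function(config, tracks = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- whale_ids(config$n_whales)
  spont <- list()
  for (w in seq_len(config$n_whales)) {
    t <- 0; times <- numeric(0)
    repeat {
      ici <- rici_mixture(1, config$bout_p, config$bout_lambda_fast,
                          config$bout_lambda_slow)
      t <- t + ici
      if (t > config$duration) break
      times <- c(times, t)
    }
    if (length(times))
      spont[[length(spont) + 1L]] <- data.frame(
        whale_id = ids[w], t_emit = times, process = "bout",
        stringsAsFactors = FALSE)
  }
  calls <- if (length(spont)) do.call(rbind, spont) else
    data.frame(whale_id = character(0), t_emit = numeric(0),
               process = character(0), stringsAsFactors = FALSE)

  if (config$response_prob > 0 && nrow(calls) > 0 && config$n_whales > 1) {
    resp <- list()
    ord <- order(calls$t_emit)
    for (i in ord) {
      for (w in setdiff(ids, calls$whale_id[i])) {
        if (runif(1) < config$response_prob) {
          t_r <- calls$t_emit[i] + rexp(1, 1 / config$response_latency_mean)
          if (t_r <= config$duration)
            resp[[length(resp) + 1L]] <- data.frame(
              whale_id = w, t_emit = t_r, process = "response",
              stringsAsFactors = FALSE)
        }
      }
    }
    if (length(resp)) calls <- rbind(calls, do.call(rbind, resp))
  }
  if (nrow(calls) == 0) {
    return(data.frame(call_id = integer(0), whale_id = character(0),
                      t_emit = numeric(0), duration = numeric(0),
                      source_level = numeric(0), emit_depth = numeric(0),
                      process = character(0), stringsAsFactors = FALSE))
  }
  calls <- calls[order(calls$t_emit), ]
  calls$call_id <- seq_len(nrow(calls))
  calls$duration <- pmax(0.1, rnorm(nrow(calls), config$call_dur_mean,
                                    config$call_dur_sd))
  calls$source_level <- rnorm(nrow(calls), config$source_level_mean,
                              config$source_level_sd)
  calls$emit_depth <- if (!is.null(tracks)) {
    vapply(seq_len(nrow(calls)), function(i)
      unname(track_lookup(tracks, calls$whale_id[i], calls$t_emit[i])["depth"]),
      numeric(1))
  } else NA_real_
  rownames(calls) <- NULL
  calls[, c("call_id", "whale_id", "t_emit", "duration", "source_level",
            "emit_depth", "process")]
}

# Hann-windowed linear FM sweep, unit peak before windowing
sweep_waveform <- function(duration, fs, f0, f1) {
  n <- max(8L, round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * duration) * t^2)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  sin(phase) * w
}

# rms of a unit sweep as seen by the measurement chain (condition to 12 kHz,
# 500 Hz high-pass, 90% energy window); used to calibrate rendered levels so
# that measured RL equals target RL
measured_rms_unit_sweep <- function(duration, fs, f0, f1) {
  u <- sweep_waveform(duration, fs, f0, f1)
  rec <- tag_recording(u, fs, sensitivity = 0)
  seg <- condition_segment(rec, 0, length(u) / fs)
  win <- energy_window_90(seg)
  x <- seg$samples[win[1]:win[2]]
  sqrt(mean(x^2))
}

#' Render a scene onto its tags
#'
#' Computes, for every call and tag, the observed received level under
#' geometric spreading, `RL = SL - k * log10(max(r, 1))`, with `r` the
#' 3-D source-receiver distance at emission (a whale's own tag sits at
#' `tag_offset`). A detection is emitted on a tag iff
#' `RL - noise_level >= detect_snr`. In waveform mode each call is rendered
#' as a Hann-windowed FM sweep calibrated so that the received-level
#' measurement chain recovers the target RL, summed into Gaussian background
#' noise whose rms sits at `noise_level`.
#'
#' @param config a [sim_config()]
#' @param tracks tracks from [simulate_tracks()]
#' @param calls call events from [simulate_call_times()]
#' @param waveform render per-tag audio? (default FALSE: detection-level
#'   output only)
#' @return object of class `scene`: list with `config`, `tracks`, `calls`
#'   (truth), `rl_table` (call x tag observed RLs and detectability),
#'   `detections` (per-tag annotation table with truth `true_call_id` links) and,
#'   in waveform mode, `audio` (named list of [tag_recording()] objects)
#' @export
render_scene <- function(config, tracks, calls, waveform = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (waveform && config$fs < 2 * max(config$sweep))
    fc_stop(sprintf("fs = %g Hz cannot represent a sweep to %g Hz",
                    config$fs, max(config$sweep)), "aliasing")
  set.seed(config$seed + 2L)
  wids <- whale_ids(config$n_whales)
  tids <- tag_ids(config$n_whales)

  rl_rows <- list(); det_rows <- list()
  det_counter <- 0L
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      src_w <- calls$whale_id[i]
      src <- track_lookup(tracks, src_w, calls$t_emit[i])
      for (j in seq_len(config$n_whales)) {
        if (wids[j] == src_w) {
          r <- config$tag_offset
        } else {
          rcv <- track_lookup(tracks, wids[j], calls$t_emit[i])
          r <- sqrt(sum((src - rcv)^2))
        }
        rl <- calls$source_level[i] -
          config$spreading_coeff * log10(max(r, 1))
        detected <- (rl - config$noise_level) >= config$detect_snr
        rl_rows[[length(rl_rows) + 1L]] <- data.frame(
          call_id = calls$call_id[i], tag_id = tids[j], whale_id = wids[j],
          distance_m = r, rl_db = rl, detected = detected,
          stringsAsFactors = FALSE)
        if (detected) {
          det_counter <- det_counter + 1L
          det_rows[[length(det_rows) + 1L]] <- data.frame(
            detection_id = sprintf("%s_d%04d", tids[j], det_counter),
            tag_id = tids[j], whale_id = wids[j],
            t_start = calls$t_emit[i],
            t_end = calls$t_emit[i] + calls$duration[i],
            f_low = config$sweep[1], f_high = config$sweep[2],
            noise_flag = FALSE, true_call_id = calls$call_id[i], rl_db = rl,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_rl <- data.frame(call_id = integer(0), tag_id = character(0),
                         whale_id = character(0), distance_m = numeric(0),
                         rl_db = numeric(0), detected = logical(0))
  empty_det <- data.frame(detection_id = character(0), tag_id = character(0),
                          whale_id = character(0), t_start = numeric(0),
                          t_end = numeric(0), f_low = numeric(0),
                          f_high = numeric(0), noise_flag = logical(0),
                          true_call_id = integer(0), rl_db = numeric(0))
  rl_table <- if (length(rl_rows)) do.call(rbind, rl_rows) else empty_rl
  detections <- if (length(det_rows)) do.call(rbind, det_rows) else empty_det

  audio <- NULL
  if (waveform) {
    fs <- config$fs
    n <- as.integer(ceiling(config$duration * fs))
    noise_rms <- 10^((config$noise_level + config$sensitivity) / 20)
    audio <- setNames(vector("list", config$n_whales), tids)
    # one calibration per call (duration-dependent), reused across tags
    unit_rms <- if (nrow(calls)) vapply(
      calls$duration, measured_rms_unit_sweep, numeric(1),
      fs = fs, f0 = config$sweep[1], f1 = config$sweep[2]) else numeric(0)
    for (j in seq_len(config$n_whales)) {
      x <- rnorm(n) * noise_rms
      audible <- rl_table[rl_table$tag_id == tids[j] & rl_table$detected, ,
                          drop = FALSE]
      for (k in seq_len(nrow(audible))) {
        ci <- match(audible$call_id[k], calls$call_id)
        u <- sweep_waveform(calls$duration[ci], fs, config$sweep[1],
                            config$sweep[2])
        target_rms <- 10^((audible$rl_db[k] + config$sensitivity) / 20)
        i0 <- as.integer(round(calls$t_emit[ci] * fs)) + 1L
        if (i0 > n) next
        idx <- i0:min(n, i0 + length(u) - 1L)
        x[idx] <- x[idx] + u[seq_along(idx)] * (target_rms / unit_rms[ci])
      }
      audio[[j]] <- tag_recording(x, fs, tag_id = tids[j], whale_id = wids[j],
                                  start_time = 0,
                                  sensitivity = config$sensitivity)
    }
  }
  structure(list(config = config, tracks = tracks, calls = calls,
                 rl_table = rl_table, detections = detections, audio = audio),
            class = "scene")
}

#' Simulate a complete scene
#'
#' Convenience wrapper: [simulate_tracks()], [simulate_call_times()],
#' [render_scene()].
#'
#' @param config a [sim_config()]
#' @param waveform render per-tag audio?
#' @return a `scene` (see [render_scene()])
#' @export
simulate_scene <- function(config, waveform = FALSE) {
  tracks <- simulate_tracks(config)
  calls <- simulate_call_times(config, tracks)
  render_scene(config, tracks, calls, waveform = waveform)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulated scene: %d whales, %.0f s, %d calls, %d detections%s\n"),
    x$config$n_whales, x$config$duration, nrow(x$calls), nrow(x$detections),
    if (!is.null(x$audio)) sprintf(", audio at %g Hz", x$config$fs) else ""))
  invisible(x)
}
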