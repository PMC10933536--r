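# End-to-end orchestration: manifest in, unique-call table, per-whale and
# group summaries, bout and exchange tables, call-depth table and run report
# out. Also writes simulated scenes to disk and packages canonical fixtures.

#' Pipeline run configuration
#'
#' @param delta_db minimum RL margin for a clear focal assignment, dB
#' @param start_tolerance cross-tag matching start tolerance, s
#' @param min_overlap_frac cross-tag matching minimum span-overlap fraction
#' @param surface_threshold surface depth, m
#' @param horizon vocal-exchange integration horizon, s
#' @param bec_min_n minimum pooled intervals for the bout-model fit
#' @param bec fixed bout-end criterion, s; when `NULL` (default) the
#'   criterion is fitted from the pooled intervals
#' @param seed RNG seed recorded in outputs
#' @return list of class `run_config`
#' @export
run_config <- function(delta_db = 3, start_tolerance = 0.5,
                       min_overlap_frac = 0.3, surface_threshold = 2,
                       horizon = 100, bec_min_n = 30, bec = NULL, seed = 1) {
  stopifnot(delta_db > 0, start_tolerance > 0, min_overlap_frac > 0,
            surface_threshold > 0, horizon > 0)
  structure(list(delta_db = delta_db, start_tolerance = start_tolerance,
                 min_overlap_frac = min_overlap_frac,
                 surface_threshold = surface_threshold, horizon = horizon,
                 bec_min_n = bec_min_n, bec = bec, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline on a tagged group
#'
#' Reads every tag's detections (and audio and depth records when present),
#' measures received levels, matches detections across tags into unique
#' calls, assigns callers, and computes per-whale call rates, silence,
#' bout and vocal-exchange statistics and call depths. Deterministic given
#' inputs and seed.
#'
#' @param manifest a `group_manifest` (see [read_manifest()])
#' @param config a [run_config()]
#' @param out_dir optional output directory; when given, all result tables
#'   and a plain-text run report are written there
#' @param allow_silent_tags permit tags that have audio but no selection
#'   table (default FALSE: fatal)
#' @return list of class `pipeline_result`: `detections`, `calls`,
#'   `assignment_summary`, `per_whale`, `group_summary`, `bout_model`
#'   (or NULL), `bouts`, `exchange`, `call_depths`, `dives`, `report`
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL,
                         allow_silent_tags = FALSE) {
  stopifnot(inherits(manifest, "group_manifest"))
  period <- analysis_period(manifest$period$t_start, manifest$period$t_end,
                            group_id = manifest$group_id)
  log_lines <- character(0)
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  # --- ingest ---------------------------------------------------------------
  det_list <- list(); audio <- list(); depth_by_whale <- list()
  whale_of_tag <- character(0)
  for (t in manifest$tags) {
    if (abs(t$clock_offset) > 60)
      fc_stop(sprintf("tag %s clock offset %.1f s exceeds 60 s; refusing alignment",
                      t$tag_id, t$clock_offset), "alignment")
    whale_of_tag[t$tag_id] <- t$whale_id
    has_audio <- !is.null(t$wav)
    if (is.null(t$selections)) {
      if (has_audio && !allow_silent_tags)
        fc_stop(sprintf("tag %s has audio but no selection table", t$tag_id),
                "missing_selections")
      note("tag %s: no selection table", t$tag_id)
    } else {
      d <- read_selection_table(t$selections, tag_id = t$tag_id,
                                clock_offset = t$clock_offset)
      inside <- d$t_start >= period$t_start & d$t_end <= period$t_end
      if (any(!inside))
        note("tag %s: dropped %d detection(s) outside the analysis period",
             t$tag_id, sum(!inside))
      d <- d[inside, , drop = FALSE]
      d$whale_id <- rep(t$whale_id, nrow(d))
      det_list[[t$tag_id]] <- d
    }
    if (has_audio) {
      w <- read_wav(t$wav)
      audio[[t$tag_id]] <- tag_recording(
        w$samples, w$fs, tag_id = t$tag_id, whale_id = t$whale_id,
        start_time = t$clock_offset, sensitivity = t$sensitivity)
    }
    if (!is.null(t$depth))
      depth_by_whale[[t$whale_id]] <-
        read_depth_csv(t$depth, tag_id = t$tag_id, clock_offset = t$clock_offset)
  }
  detections <- if (length(det_list)) do.call(rbind, det_list) else
    data.frame(detection_id = character(0), tag_id = character(0),
               t_start = numeric(0), t_end = numeric(0), f_low = numeric(0),
               f_high = numeric(0), noise_flag = logical(0),
               whale_id = character(0))
  rownames(detections) <- NULL
  note("detections in: %d", nrow(detections))

  # --- received levels ------------------------------------------------------
  if (nrow(detections)) {
    if (length(audio)) {
      rl <- do.call(rbind, lapply(names(audio), function(tid) {
        dd <- detections[detections$tag_id == tid, , drop = FALSE]
        measure_rl_table(audio[[tid]], dd)
      }))
      detections$rl_db <- rl$rl_db[match(detections$detection_id, rl$detection_id)]
      detections$rl_valid <- rl$valid[match(detections$detection_id, rl$detection_id)]
    } else if (!is.null(detections$rl_db)) {
      detections$rl_valid <- !is.na(detections$rl_db) & !detections$noise_flag
      note("no audio: using selection-table RL column")
    } else {
      detections$rl_db <- NA_real_
      detections$rl_valid <- FALSE
      note("no audio and no RL column: all RLs invalid")
    }
  } else {
    detections$rl_db <- numeric(0); detections$rl_valid <- logical(0)
  }

  # --- caller assignment ----------------------------------------------------
  matched <- match_across_tags(detections,
                               start_tolerance = config$start_tolerance,
                               min_overlap_frac = config$min_overlap_frac)
  asg <- assign_callers(matched, delta_db = config$delta_db)
  detections <- asg$detections
  calls <- asg$calls
  summ <- rl_difference_stats(calls, detections)
  note("unique calls: %d (focal %d, indeterminate %d; %d multi-tag)",
       summ$n_calls, summ$n_assigned, summ$n_indeterminate, summ$n_multi_tag)

  # --- per-whale vocal statistics -------------------------------------------
  whales <- unname(whale_of_tag)
  focal <- calls[!is.na(calls$focal_whale), , drop = FALSE]
  icis_by_whale <- lapply(setNames(whales, whales), function(w)
    suppressWarnings(ici_series(focal$t_start[focal$focal_whale == w])))
  pooled_icis <- unlist(icis_by_whale, use.names = FALSE)

  bm <- NULL
  bec <- config$bec
  if (is.null(bec)) {
    bm <- tryCatch(fit_bout_model(pooled_icis, min_n = config$bec_min_n),
                   focalcall_error = function(e) {
                     note("bout model not fitted: %s", conditionMessage(e))
                     NULL
                   })
    bec <- if (!is.null(bm)) bm$bec else NA_real_
  }

  per_whale <- do.call(rbind, lapply(whales, function(w) {
    tw <- focal$t_start[focal$focal_whale == w]
    b <- if (!is.na(bec)) segment_bouts(tw, bec, period) else
      list(bouts = NULL, summary = list(n_bouts = NA, bout_rate = NA,
                                        mean_calls_per_bout = NA,
                                        frac_in_bouts = NA))
    data.frame(whale_id = w, n_focal = length(tw),
               call_rate = call_rate(length(tw), period),
               n_bouts = b$summary$n_bouts, bout_rate = b$summary$bout_rate,
               mean_calls_per_bout = b$summary$mean_calls_per_bout,
               frac_in_bouts = b$summary$frac_in_bouts,
               stringsAsFactors = FALSE)
  }))
  bouts <- if (!is.na(bec)) {
    do.call(rbind, lapply(whales, function(w) {
      b <- segment_bouts(focal$t_start[focal$focal_whale == w], bec)$bouts
      if (nrow(b)) cbind(whale_id = w, b) else NULL
    }))
  } else NULL

  sil <- silence_stats(detections, period)
  group_summary <- list(
    group_id = manifest$group_id,
    duration_h = period$duration_s / 3600,
    n_focal = nrow(focal),
    group_call_rate = call_rate(nrow(focal), period),
    proportion_silent = sil$proportion_silent,
    longest_silence_s = sil$longest_silence_s,
    bec_s = bec)

  exch <- tryCatch({
    x <- inter_individual_icis(
      data.frame(whale_id = focal$focal_whale, t_start = focal$t_start))
    exchange_auc(x, horizon = config$horizon)
  }, focalcall_insufficient_data = function(e) {
    note("exchange analysis skipped: %s", conditionMessage(e))
    NULL
  })

  depths <- NULL; dives <- NULL
  if (length(depth_by_whale) && nrow(focal)) {
    fc <- data.frame(whale_id = focal$focal_whale, t_start = focal$t_start,
                     call_id = focal$call_id, stringsAsFactors = FALSE)
    depths <- suppressWarnings(
      call_depth_summary(fc, depth_by_whale,
                         surface_threshold = config$surface_threshold))
    dives <- do.call(rbind, lapply(depth_by_whale, find_dives,
                                   surface_threshold = config$surface_threshold))
    rownames(dives) <- NULL
  }

  report <- c(
    sprintf("group: %s", manifest$group_id),
    sprintf("analysis period: [%.2f, %.2f] s (%.2f h)", period$t_start,
            period$t_end, period$duration_s / 3600),
    sprintf("seed: %d", config$seed),
    sprintf("parameters: delta_db=%g start_tolerance=%g min_overlap_frac=%g surface_threshold=%g horizon=%g",
            config$delta_db, config$start_tolerance, config$min_overlap_frac,
            config$surface_threshold, config$horizon),
    log_lines)

  res <- structure(list(detections = detections, calls = calls,
                        assignment_summary = summ, per_whale = per_whale,
                        group_summary = group_summary, bout_model = bm,
                        bouts = bouts, exchange = exch, call_depths = depths,
                        dives = dives, report = report),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$assignment_summary; g <- x$group_summary
  cat(sprintf(paste0(
    "Pipeline result for group %s (%.2f h)\n",
    "  %d unique calls: %d assigned (%s%%), %d indeterminate, %d multi-tag\n",
    "  group call rate %.1f calls/h; %.0f%% silent; longest silence %.0f s\n",
    "  BEC %s s\n"),
    g$group_id, g$duration_h, s$n_calls, s$n_assigned,
    ifelse(is.na(s$pct_assigned), "-", s$pct_assigned), s$n_indeterminate,
    s$n_multi_tag, g$group_call_rate, 100 * g$proportion_silent,
    g$longest_silence_s,
    ifelse(is.na(g$bec_s), "not fitted", sprintf("%.2f", g$bec_s))))
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(res$detections, "detections.csv")
  wcsv(res$calls, "unique_calls.csv")
  wcsv(res$per_whale, "per_whale_summary.csv")
  wcsv(res$bouts, "bouts.csv")
  wcsv(res$dives, "dives.csv")
  if (!is.null(res$call_depths)) wcsv(res$call_depths$calls, "call_depths.csv")
  utils::write.csv(as.data.frame(res$group_summary),
                   file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  if (!is.null(res$exchange))
    utils::write.csv(as.data.frame(res$exchange),
                     file.path(out_dir, "exchange_summary.csv"), row.names = FALSE)
  writeLines(res$report, file.path(out_dir, "run_report.txt"))
  invisible(out_dir)
}

#' Write a simulated scene to disk as a tagged-group deployment
#'
#' Emits, per tag: a Raven-style selection table (with the simulator's
#' observed RLs), a 5 Hz depth CSV and, for waveform scenes, a WAV file;
#' plus a truth CSV and a YAML group manifest covering the full scene
#' duration.
#'
#' @param scene a `scene` from [simulate_scene()]
#' @param out_dir output directory
#' @return path to the manifest, invisibly
#' @export
write_scene <- function(scene, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scene$config
  tids <- tag_ids(cfg$n_whales); wids <- whale_ids(cfg$n_whales)
  tags <- vector("list", cfg$n_whales)
  for (j in seq_len(cfg$n_whales)) {
    sel <- file.path(out_dir, sprintf("%s_selections.txt", tids[j]))
    dd <- scene$detections[scene$detections$tag_id == tids[j], , drop = FALSE]
    write_selection_table(dd, sel)
    dep <- file.path(out_dir, sprintf("%s_depth.csv", tids[j]))
    tw <- scene$tracks[scene$tracks$whale_id == wids[j], ]
    write_depth_csv(depth_series(tw$time, tw$depth, tag_id = tids[j]), dep)
    wav <- NULL
    if (!is.null(scene$audio)) {
      wav <- file.path(out_dir, sprintf("%s.wav", tids[j]))
      write_wav(scene$audio[[tids[j]]]$samples, cfg$fs, wav,
                bit_depth = "float32")
    }
    tags[[j]] <- list(tag_id = tids[j], whale_id = wids[j],
                      selections = basename(sel), depth = basename(dep),
                      wav = if (!is.null(wav)) basename(wav),
                      sensitivity = cfg$sensitivity, clock_offset = 0)
  }
  utils::write.csv(scene$calls, file.path(out_dir, "truth_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$rl_table, file.path(out_dir, "truth_rl.csv"),
                   row.names = FALSE)
  man <- list(group_id = sprintf("sim_seed%d", cfg$seed), tags = tags,
              period = list(t_start = 0, t_end = cfg$duration))
  path <- file.path(out_dir, "manifest.yaml")
  write_manifest(man, path)
  invisible(path)
}

#' Generate the canonical packaged test scenes
#'
#' Three small fixtures with ground truth: (a) a 2-whale detection-level
#' scene, (b) a 3-whale waveform scene in which calls register on all three
#' tags, (c) a two-process mixture inter-call-interval dataset of 1000
#' intervals for bout-criterion testing. Regenerates byte-identically from
#' the same seed.
#'
#' @param seed integer seed
#' @param out_dir output directory (three subdirectories are created)
#' @return named list of fixture directories/files, invisibly
#' @export
make_fixtures <- function(seed = 1, out_dir = tempfile("fixtures")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir_a <- file.path(out_dir, "scene_detection_2whale")
  sc_a <- simulate_scene(sim_config(n_whales = 2, duration = 1800,
                                    spacing_mean = 100, seed = seed))
  write_scene(sc_a, dir_a)

  dir_b <- file.path(out_dir, "scene_waveform_3whale")
  sc_b <- simulate_scene(sim_config(n_whales = 3, duration = 120,
                                    spacing_mean = 50, fs = 24000,
                                    bout_p = 0.5, bout_lambda_fast = 0.3,
                                    bout_lambda_slow = 0.03,
                                    call_dur_mean = 0.7, call_dur_sd = 0.15,
                                    response_prob = 0.3,
                                    seed = seed + 1L),
                         waveform = TRUE)
  write_scene(sc_b, dir_b)

  ici_file <- file.path(out_dir, "ici_mixture.csv")
  set.seed(seed + 2L)
  ici <- rici_mixture(1000, 0.75, 0.5, 0.01)
  utils::write.csv(data.frame(ici_s = ici), ici_file, row.names = FALSE)

  invisible(list(scene_detection = dir_a, scene_waveform = dir_b,
                 ici_mixture = ici_file))
}
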