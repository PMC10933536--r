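# File formats: Raven-style selection tables (tab-separated), depth CSVs,
# group manifests (YAML), truth tables.

sel_required <- c("Begin Time (s)", "End Time (s)")

#' Read a Raven-style selection table
#'
#' Tab-separated annotation table with one row per detected call. Required
#' columns: `Begin Time (s)`, `End Time (s)`. Optional columns parsed when
#' present: `Selection` (detection id), `Low Freq (Hz)`, `High Freq (Hz)`,
#' `Noise Flag`, `RL (dB)` (simulator-provided received level for
#' detection-level scenes).
#'
#' @param path file path
#' @param tag_id tag the table belongs to
#' @param clock_offset seconds added to the file-relative times to place them
#'   on the scene clock
#' @return data frame of detections: `detection_id`, `tag_id`, `t_start`,
#'   `t_end`, `f_low`, `f_high`, `noise_flag` (and `rl_db` when present)
#' @export
read_selection_table <- function(path, tag_id = "tag1", clock_offset = 0) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in sel_required) {
    if (!col %in% names(raw))
      fc_stop(sprintf("selection table %s is missing required column '%s'",
                      path, col), "format")
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad))
      fc_stop(sprintf("non-numeric '%s' in %s at data row %d (line %d)",
                      col, path, bad[1], bad[1] + 1L), "row")
    v
  }
  n <- nrow(raw)
  if (n == 0) {
    out <- data.frame(detection_id = character(0), tag_id = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      f_low = numeric(0), f_high = numeric(0),
                      noise_flag = logical(0), stringsAsFactors = FALSE)
    if ("RL (dB)" %in% names(raw)) out$rl_db <- numeric(0)
    return(out)
  }
  out <- data.frame(
    detection_id = if ("Selection" %in% names(raw))
      paste0(tag_id, "_s", raw$Selection) else sprintf("%s_s%d", tag_id, seq_len(n)),
    tag_id = rep(tag_id, n),
    t_start = num("Begin Time (s)") + clock_offset,
    t_end = num("End Time (s)") + clock_offset,
    f_low = if ("Low Freq (Hz)" %in% names(raw)) num("Low Freq (Hz)") else
      rep(NA_real_, n),
    f_high = if ("High Freq (Hz)" %in% names(raw)) num("High Freq (Hz)") else
      rep(NA_real_, n),
    noise_flag = if ("Noise Flag" %in% names(raw))
      as.logical(raw[["Noise Flag"]]) %in% TRUE else rep(FALSE, n),
    stringsAsFactors = FALSE)
  if ("RL (dB)" %in% names(raw)) out$rl_db <- num("RL (dB)")
  if (n && any(out$t_end <= out$t_start))
    fc_stop(sprintf("non-positive detection span in %s", path), "format")
  out
}

#' Write a Raven-style selection table
#'
#' @param detections data frame with `t_start`, `t_end` and optionally
#'   `f_low`, `f_high`, `noise_flag`, `rl_db`
#' @param path output path
#' @param clock_offset seconds subtracted to convert scene-clock times back
#'   to file-relative times
#' @return `path`, invisibly
#' @export
write_selection_table <- function(detections, path, clock_offset = 0) {
  n <- nrow(detections)
  out <- data.frame(
    Selection = seq_len(n),
    `Begin Time (s)` = sprintf("%.6f", detections$t_start - clock_offset),
    `End Time (s)` = sprintf("%.6f", detections$t_end - clock_offset),
    `Low Freq (Hz)` = if (!is.null(detections$f_low)) detections$f_low else NA,
    `High Freq (Hz)` = if (!is.null(detections$f_high)) detections$f_high else NA,
    `Noise Flag` = if (!is.null(detections$noise_flag))
      as.integer(detections$noise_flag) else 0L,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(detections$rl_db)) out$`RL (dB)` <- sprintf("%.4f", detections$rl_db)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth CSV (`time_s`, `depth_m`)
#'
#' @param path file path
#' @param tag_id tag identifier
#' @param clock_offset seconds added to file-relative times
#' @return a [depth_series()]
#' @export
read_depth_csv <- function(path, tag_id = "tag1", clock_offset = 0) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "depth_m") %in% names(d)))
    fc_stop(sprintf("depth CSV %s must have columns time_s, depth_m", path),
            "format")
  depth_series(d$time_s + clock_offset, d$depth_m, tag_id = tag_id)
}

#' Write a depth CSV
#' @param series a [depth_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_depth_csv <- function(series, path) {
  utils::write.csv(data.frame(time_s = series$times, depth_m = series$depths),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a group manifest (YAML)
#'
#' The manifest names the group, its analysis period and, per tag: the tag
#' and whale ids, file paths (selection table, depth CSV, optional WAV),
#' hydrophone sensitivity and clock offset.
#'
#' @param path YAML file path
#' @return list of class `group_manifest`
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  validate_manifest(m, dirname(path))
}

validate_manifest <- function(m, base_dir = ".") {
  if (is.null(m$group_id) || is.null(m$tags) || length(m$tags) < 1)
    fc_stop("manifest needs group_id and at least one tag entry", "manifest")
  tag_ids <- vapply(m$tags, function(t) t$tag_id, character(1))
  whale_ids <- vapply(m$tags, function(t) t$whale_id, character(1))
  if (anyDuplicated(tag_ids) || anyDuplicated(whale_ids))
    fc_stop("tag and whale ids must be unique", "manifest")
  if (is.null(m$period) || m$period$t_end <= m$period$t_start)
    fc_stop("manifest needs a positive analysis period", "manifest")
  for (i in seq_along(m$tags)) {
    t <- m$tags[[i]]
    if (is.null(t$sensitivity)) m$tags[[i]]$sensitivity <- -171
    if (is.null(t$clock_offset)) m$tags[[i]]$clock_offset <- 0
    for (f in c("selections", "depth", "wav")) {
      if (!is.null(t[[f]]) && !file.exists(t[[f]])) {
        cand <- file.path(base_dir, t[[f]])
        if (file.exists(cand)) m$tags[[i]][[f]] <- cand
      }
    }
  }
  structure(m, class = "group_manifest")
}

#' Write a group manifest (YAML)
#' @param manifest a `group_manifest` (or compatible list)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
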