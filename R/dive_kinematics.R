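# Depth at call time, dive segmentation and call-depth summaries from the
# tag pressure record (5 Hz decimated series).

#' Construct a depth series
#'
#' @param times sample times, seconds (strictly increasing; 5 Hz typical)
#' @param depths depths in metres, positive down. Small negative values
#'   (surface sensor noise, >= -0.5 m) are tolerated and clamped to 0 for
#'   classification.
#' @param tag_id tag identifier
#' @return object of class `depth_series`
#' @export
depth_series <- function(times, depths, tag_id = "tag1") {
  times <- as.numeric(times); depths <- as.numeric(depths)
  if (length(times) != length(depths) || length(times) == 0)
    fc_stop("times and depths must be equal-length, non-empty", "invalid_input")
  if (any(diff(times) <= 0)) fc_stop("times must be strictly increasing", "invalid_input")
  if (any(depths < -0.5)) fc_stop("depths below -0.5 m are not physical", "invalid_input")
  structure(list(times = times, depths = depths, tag_id = tag_id),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("Depth series '%s': %d samples over %.1f s, max depth %.1f m\n",
              x$tag_id, length(x$times), diff(range(x$times)), max(x$depths)))
  invisible(x)
}

#' Depth at a given time
#'
#' Linear interpolation between the bracketing pressure samples.
#'
#' @param series a [depth_series()]
#' @param t time(s), seconds; must lie within the series span
#' @return depth(s) in metres
#' @export
depth_at <- function(series, t) {
  stopifnot(inherits(series, "depth_series"))
  rng <- range(series$times)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9))
    fc_stop(sprintf("time outside depth record [%.2f, %.2f]", rng[1], rng[2]),
            "out_of_range")
  approx(series$times, series$depths, xout = t, rule = 1)$y
}

#' Segment a depth series into dives
#'
#' A dive is a maximal run of samples at or below `surface_threshold` depth
#' (i.e. depth >= threshold) lasting at least `min_duration` seconds.
#'
#' @param series a [depth_series()]
#' @param surface_threshold surface depth threshold, metres (default 2)
#' @param min_duration minimum dive duration, seconds (default 10; rejects
#'   sensor blips)
#' @return data frame: `tag_id`, `t_start`, `t_end`, `max_depth`
#' @export
find_dives <- function(series, surface_threshold = 2, min_duration = 10) {
  stopifnot(inherits(series, "depth_series"))
  d <- pmax(series$depths, 0)
  under <- d >= surface_threshold
  r <- rle(under)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    if (series$times[i1] - series$times[i0] < min_duration) return(NULL)
    data.frame(tag_id = series$tag_id, t_start = series$times[i0],
               t_end = series$times[i1], max_depth = max(d[i0:i1]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(tag_id = character(0), t_start = numeric(0),
                      t_end = numeric(0), max_depth = numeric(0)))
  do.call(rbind, rows)
}

#' Call-depth summary
#'
#' Interpolates the depth of each call at its start time, classifies surface
#' calls (depth below `surface_threshold`) and summarizes call depths pooled
#' and per individual, together with each individual's maximum dive depth.
#' Calls outside their tag's depth record are excluded with a warning.
#'
#' @param calls data frame with `whale_id`, `t_start` (focal calls)
#' @param depth_by_whale named list of [depth_series()], one per whale
#' @param surface_threshold surface depth, metres (default 2)
#' @return list with `calls` (input plus `depth_m`, `surface`), `pooled`
#'   (`n_calls`, `n_surface`, `frac_surface`, `min_depth`, `mean_depth`,
#'   `max_depth`) and `per_whale` data frame (adds `max_dive_depth`)
#' @export
call_depth_summary <- function(calls, depth_by_whale, surface_threshold = 2) {
  calls$depth_m <- NA_real_
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ds <- depth_by_whale[[calls$whale_id[i]]]
    if (is.null(ds)) { keep[i] <- FALSE; next }
    d <- tryCatch(depth_at(ds, calls$t_start[i]),
                  focalcall_out_of_range = function(e) NA_real_)
    if (is.na(d)) keep[i] <- FALSE else calls$depth_m[i] <- max(d, 0)
  }
  if (any(!keep))
    warning(sprintf("%d call(s) outside their depth record excluded", sum(!keep)))
  calls <- calls[keep, , drop = FALSE]
  calls$surface <- calls$depth_m < surface_threshold

  pooled <- list(
    n_calls = nrow(calls),
    n_surface = sum(calls$surface),
    frac_surface = if (nrow(calls)) mean(calls$surface) else NA_real_,
    min_depth = if (nrow(calls)) min(calls$depth_m) else NA_real_,
    mean_depth = if (nrow(calls)) mean(calls$depth_m) else NA_real_,
    max_depth = if (nrow(calls)) max(calls$depth_m) else NA_real_)

  per_whale <- do.call(rbind, lapply(names(depth_by_whale), function(w) {
    cw <- calls[calls$whale_id == w, , drop = FALSE]
    dv <- find_dives(depth_by_whale[[w]], surface_threshold)
    data.frame(whale_id = w, n_calls = nrow(cw), n_surface = sum(cw$surface),
               mean_depth = if (nrow(cw)) mean(cw$depth_m) else NA_real_,
               max_call_depth = if (nrow(cw)) max(cw$depth_m) else NA_real_,
               max_dive_depth = if (nrow(dv)) max(dv$max_depth) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, pooled = pooled, per_whale = per_whale)
}
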