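# Cross-tag matching of detections into unique calls and focal/non-focal/
# indeterminate assignment by relative received level.

#' Match detections of the same call across tags
#'
#' Two detections on different tags are linked when their start times differ
#' by at most `start_tolerance` and their spans overlap by at least
#' `min_overlap_frac` of the shorter span. Unique calls are the single-linkage
#' connected components of the link graph, with the constraint that a call
#' never contains two detections from the same tag: links are added strongest
#' first (smallest start-time difference) and any link whose addition would
#' merge two same-tag detections is cut.
#'
#' @param detections data frame with columns `detection_id`, `tag_id`,
#'   `t_start`, `t_end` (and optionally `noise_flag`, `f_low`, `f_high`)
#' @param start_tolerance maximum start-time difference, seconds. The default
#'   0.5 s covers the <= 0.33 s acoustic propagation delay across a group
#'   spread over 500 m plus annotation jitter.
#' @param min_overlap_frac minimum span overlap as a fraction of the shorter
#'   span (default 0.3)
#' @return the input data frame with a `call_id` column added; attribute
#'   `cut_links` counts links cut by the same-tag rule, `band_disjoint`
#'   counts linked pairs whose frequency bands do not intersect
#' @export
match_across_tags <- function(detections, start_tolerance = 0.5,
                              min_overlap_frac = 0.3) {
  n <- nrow(detections)
  if (n == 0) {
    detections$call_id <- integer(0)
    return(detections)
  }
  stopifnot(all(c("detection_id", "tag_id", "t_start", "t_end") %in% names(detections)))
  ts <- detections$t_start; te <- detections$t_end; tg <- detections$tag_id

  # candidate links: different tags, starts within tolerance, enough overlap
  ord <- order(ts)
  links <- list()
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      dt <- ts[j] - ts[i]
      if (dt > start_tolerance) break
      if (tg[i] == tg[j]) next
      ov <- min(te[i], te[j]) - max(ts[i], ts[j])
      if (ov >= min_overlap_frac * min(te[i] - ts[i], te[j] - ts[j]))
        links[[length(links) + 1L]] <- c(i, j, dt)
    }
  }

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  comp_tags <- lapply(seq_len(n), function(i) tg[i])
  cut <- 0L
  if (length(links)) {
    lm <- do.call(rbind, links)
    lm <- lm[order(lm[, 3]), , drop = FALSE]   # strongest (smallest dt) first
    for (r in seq_len(nrow(lm))) {
      ri <- find(as.integer(lm[r, 1])); rj <- find(as.integer(lm[r, 2]))
      if (ri == rj) next
      if (length(intersect(comp_tags[[ri]], comp_tags[[rj]])) > 0) {
        cut <- cut + 1L                       # would duplicate a tag: cut link
        next
      }
      parent[rj] <- ri
      comp_tags[[ri]] <- c(comp_tags[[ri]], comp_tags[[rj]])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  first_start <- vapply(split(ts, roots), min, numeric(1))
  call_id <- match(roots, as.integer(names(sort(first_start))))
  detections$call_id <- call_id

  band_disjoint <- 0L
  if (all(c("f_low", "f_high") %in% names(detections)) && length(links)) {
    for (r in seq_along(links)) {
      i <- links[[r]][1]; j <- links[[r]][2]
      if (call_id[i] == call_id[j] &&
          (detections$f_low[i] > detections$f_high[j] ||
           detections$f_low[j] > detections$f_high[i]))
        band_disjoint <- band_disjoint + 1L
    }
  }
  attr(detections, "cut_links") <- cut
  attr(detections, "band_disjoint") <- band_disjoint
  detections
}

#' Assign a caller to one unique call
#'
#' Applies the relative received-level rules to the member detections of one
#' unique call:
#' \itemize{
#'   \item a call detected on a single tag is focal on that tag;
#'   \item on multiple tags, the tag with the highest valid RL is focal if it
#'     exceeds the second-highest by at least `delta_db`; the rest are
#'     non-focal; otherwise every member is indeterminate;
#'   \item if all members but one are masked by noise (noise flag set), the
#'     unmasked tag is focal regardless of RLs;
#'   \item calls whose RLs are all invalid (and not resolved by the masked-tag
#'     rule) are indeterminate.
#' }
#'
#' @param cluster data frame of one call's member detections with columns
#'   `tag_id`, `rl_db`, `rl_valid` and optionally `noise_flag`
#' @param delta_db minimum RL margin (dB) for a "clear difference"; default 3
#' @return `cluster` with an `assignment` column
#'   (`focal`/`non_focal`/`indeterminate`); attributes `focal_tag` and
#'   `rl_difference` (focal RL minus loudest valid non-focal RL, dB)
#' @export
assign_caller <- function(cluster, delta_db = 3) {
  m <- nrow(cluster)
  if (is.null(m) || m == 0) fc_stop("empty call cluster", "invalid_input")
  if (is.null(cluster$noise_flag)) cluster$noise_flag <- FALSE
  rl <- ifelse(cluster$rl_valid %in% TRUE, cluster$rl_db, NA_real_)

  label <- function(focal_idx) {
    cluster$assignment <- ifelse(seq_len(m) == focal_idx, "focal", "non_focal")
    attr(cluster, "focal_tag") <- cluster$tag_id[focal_idx]
    nf <- rl[-focal_idx]
    attr(cluster, "rl_difference") <-
      if (any(!is.na(nf)) && !is.na(rl[focal_idx]))
        rl[focal_idx] - max(nf, na.rm = TRUE) else NA_real_
    cluster
  }

  if (m == 1L) return(label(1L))

  flagged <- cluster$noise_flag %in% TRUE
  if (sum(!flagged) == 1L) return(label(which(!flagged)))

  valid_idx <- which(!is.na(rl))
  if (length(valid_idx) >= 2L) {
    o <- valid_idx[order(rl[valid_idx], decreasing = TRUE)]
    if (rl[o[1L]] - rl[o[2L]] >= delta_db) return(label(o[1L]))
  }
  cluster$assignment <- rep("indeterminate", m)
  attr(cluster, "focal_tag") <- NA_character_
  attr(cluster, "rl_difference") <- NA_real_
  cluster
}

#' Assign callers to every unique call in a detection table
#'
#' @param detections data frame with `call_id`, `tag_id`, `rl_db`, `rl_valid`
#'   (from [match_across_tags()] joined with RL measurements)
#' @param delta_db RL margin passed to [assign_caller()]
#' @return list with `detections` (input plus `assignment`) and `calls` (one
#'   row per unique call: `call_id`, `n_tags`, `multi_tag`, `focal_tag`,
#'   `focal_whale` when whale ids are present, `masked`, `rl_difference`)
#' @export
assign_callers <- function(detections, delta_db = 3) {
  stopifnot("call_id" %in% names(detections))
  if (nrow(detections) == 0) {
    detections$assignment <- character(0)
    return(list(detections = detections,
                calls = data.frame(call_id = integer(0), n_tags = integer(0),
                                   multi_tag = logical(0), focal_tag = character(0),
                                   focal_whale = character(0), masked = logical(0),
                                   rl_difference = numeric(0), t_start = numeric(0))))
  }
  if (is.null(detections$noise_flag)) detections$noise_flag <- FALSE
  ids <- sort(unique(detections$call_id))
  detections$assignment <- NA_character_
  calls <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- which(detections$call_id == ids[k])
    cl <- assign_caller(detections[rows, , drop = FALSE], delta_db = delta_db)
    detections$assignment[rows] <- cl$assignment
    focal_tag <- attr(cl, "focal_tag")
    calls[[k]] <- data.frame(
      call_id = ids[k], n_tags = length(rows), multi_tag = length(rows) > 1L,
      focal_tag = focal_tag,
      focal_whale = if (!is.null(detections$whale_id) && !is.na(focal_tag))
        detections$whale_id[rows][match(focal_tag, detections$tag_id[rows])]
      else NA_character_,
      masked = length(rows) > 1L && sum(!(cl$noise_flag %in% TRUE)) == 1L,
      rl_difference = attr(cl, "rl_difference"),
      t_start = min(detections$t_start[rows]),
      stringsAsFactors = FALSE)
  }
  list(detections = detections, calls = do.call(rbind, calls))
}

#' Summary statistics of caller assignment and cross-tag RL differences
#'
#' Counts calls by outcome and summarizes the difference in RL of the same
#' call recorded across multiple tags (focal RL minus loudest valid non-focal
#' RL), computed only over calls with a focal tag and at least one valid
#' non-focal RL. Percentages are rounded to the integer, the precision at
#' which such results are conventionally reported.
#'
#' @param calls calls table from [assign_callers()]
#' @param detections labelled detections table from [assign_callers()]
#' @return list of counts and statistics; see Details
#' @export
rl_difference_stats <- function(calls, detections = NULL) {
  n_calls <- nrow(calls)
  if (n_calls == 0) {
    return(list(n_calls = 0L, n_assigned = 0L, n_indeterminate = 0L,
                pct_assigned = NA_real_, n_multi_tag = 0L, pct_multi_tag = NA_real_,
                n_nonfocal_detections = 0L, mean_rl_difference = NA_real_,
                sd_rl_difference = NA_real_, n_rl_pairs = 0L))
  }
  assigned <- !is.na(calls$focal_tag)
  d <- calls$rl_difference[assigned & !is.na(calls$rl_difference)]
  n_nonfocal <- if (!is.null(detections))
    sum(detections$assignment == "non_focal", na.rm = TRUE)
  else sum(assigned & calls$multi_tag)  # lower bound without the table
  list(
    n_calls = n_calls,
    n_assigned = sum(assigned),
    n_indeterminate = sum(!assigned),
    pct_assigned = round(100 * sum(assigned) / n_calls),
    n_multi_tag = sum(calls$multi_tag),
    pct_multi_tag = round(100 * sum(calls$multi_tag) / n_calls),
    n_nonfocal_detections = n_nonfocal,
    mean_rl_difference = if (length(d)) mean(d) else NA_real_,
    sd_rl_difference = if (length(d) > 1) stats::sd(d) else NA_real_,
    n_rl_pairs = length(d))
}
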