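det_row <- function(id, tag, t0, t1, noise = FALSE, rl = NA_real_, whale = NA_character_) {
  data.frame(detection_id = id, tag_id = tag, t_start = t0, t_end = t1,
             noise_flag = noise, rl_db = rl, rl_valid = !is.na(rl) & !noise,
             whale_id = whale, stringsAsFactors = FALSE)
}

test_that("cross-tag matching links by start tolerance and span overlap", {
  d <- rbind(det_row("a1", "A", 10.00, 10.80), det_row("b1", "B", 10.10, 10.90))
  m <- match_across_tags(d, 0.5, 0.3)
  expect_equal(length(unique(m$call_id)), 1L)

  d2 <- rbind(det_row("a1", "A", 10.0, 10.5), det_row("b1", "B", 11.0, 11.5))
  m2 <- match_across_tags(d2, 0.5, 0.3)
  expect_equal(length(unique(m2$call_id)), 2L)

  # chain linkage across three tags
  d3 <- rbind(det_row("a1", "A", 10.0, 10.6), det_row("b1", "B", 10.4, 11.0),
              det_row("c1", "C", 10.8, 11.4))
  m3 <- match_across_tags(d3, 0.5, 0.3)
  expect_equal(length(unique(m3$call_id)), 1L)
  expect_equal(unname(oracle_components(d3, 0.5, 0.3)), c(1L, 1L, 1L))
})

test_that("matching agrees with brute-force connected components and never
          merges same-tag detections", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    d <- do.call(rbind, lapply(seq_len(n), function(i) {
      t0 <- runif(1, 0, 30)
      det_row(sprintf("d%d", i), sample(c("A", "B", "C"), 1), t0,
              t0 + runif(1, 0.3, 1.2))
    }))
    m <- match_across_tags(d, 0.5, 0.3)
    # never two same-tag detections in one call
    for (cid in unique(m$call_id)) {
      expect_false(anyDuplicated(m$tag_id[m$call_id == cid]) > 0)
    }
    # where the brute-force components are already same-tag-free, the
    # clustering must match them exactly
    comp <- oracle_components(d, 0.5, 0.3)
    clean <- !vapply(comp, function(cc)
      anyDuplicated(d$tag_id[comp == cc]) > 0, logical(1))
    if (any(clean)) {
      sub <- which(clean)
      expect_equal(length(unique(m$call_id[sub])), length(unique(comp[sub])))
      for (cc in unique(comp[sub])) {
        ids <- m$call_id[comp == cc]
        expect_equal(length(unique(ids)), 1L)
      }
    }
  }
})

test_that("caller assignment follows the relative received-level rules", {
  # clear RL gap at the observed mean focal/non-focal levels
  cl <- rbind(det_row("a", "A", 0, 1, rl = 129), det_row("b", "B", 0, 1, rl = 122))
  r <- assign_caller(cl, delta_db = 3)
  expect_equal(attr(r, "focal_tag"), "A")
  expect_equal(r$assignment, c("focal", "non_focal"))
  expect_equal(attr(r, "rl_difference"), 7)

  # no clear difference -> indeterminate on both
  cl2 <- rbind(det_row("a", "A", 0, 1, rl = 125), det_row("b", "B", 0, 1, rl = 124))
  r2 <- assign_caller(cl2, delta_db = 3)
  expect_equal(r2$assignment, c("indeterminate", "indeterminate"))
  expect_true(is.na(attr(r2, "focal_tag")))

  # masked-tag rule beats the RL comparison
  cl3 <- rbind(det_row("a", "A", 0, 1, rl = 126),
               det_row("b", "B", 0, 1, noise = TRUE))
  r3 <- assign_caller(cl3, delta_db = 3)
  expect_equal(attr(r3, "focal_tag"), "A")

  # singleton rule
  r4 <- assign_caller(det_row("a", "A", 0, 1, rl = 110))
  expect_equal(attr(r4, "focal_tag"), "A")

  # all RLs invalid and unflagged -> indeterminate
  cl5 <- rbind(det_row("a", "A", 0, 1), det_row("b", "B", 0, 1))
  expect_true(all(assign_caller(cl5)$assignment == "indeterminate"))

  expect_error(assign_caller(det_row("x", "A", 0, 1)[0, ]),
               class = "focalcall_invalid_input")
})

test_that("labels partition every cluster with at most one focal tag", {
  set.seed(7)
  for (rep in 1:50) {
    k <- sample(1:3, 1)
    cl <- do.call(rbind, lapply(seq_len(k), function(i)
      det_row(sprintf("d%d", i), LETTERS[i], 0, 1,
              noise = runif(1) < 0.2,
              rl = if (runif(1) < 0.8) runif(1, 110, 140) else NA_real_)))
    r <- assign_caller(cl, delta_db = 3)
    expect_equal(sum(r$assignment == "focal") <= 1, TRUE)
    expect_equal(nrow(r), sum(r$assignment %in%
                                c("focal", "non_focal", "indeterminate")))
    if (any(r$assignment == "indeterminate"))
      expect_true(all(r$assignment == "indeterminate"))
  }
})

test_that("assignment summary counts partition the call set", {
  d <- rbind(
    det_row("a1", "A", 0, 1, rl = 130, whale = "w1"),
    det_row("b1", "B", 0.05, 1.05, rl = 115, whale = "w2"),
    det_row("a2", "A", 10, 11, rl = 125, whale = "w1"),
    det_row("b2", "B", 20, 21, rl = 124.5, whale = "w2"),
    det_row("a3", "A", 20.02, 21.02, rl = 124, whale = "w1"))
  m <- match_across_tags(d)
  asg <- assign_callers(m)
  s <- rl_difference_stats(asg$calls, asg$detections)
  expect_equal(s$n_calls, 3L)
  expect_equal(s$n_assigned, 2L)
  expect_equal(s$n_indeterminate, 1L)
  expect_equal(s$n_multi_tag, 2L)
  expect_equal(s$n_nonfocal_detections, 1L)
  expect_equal(s$mean_rl_difference, 15)
  expect_equal(s$n_assigned + s$n_indeterminate, s$n_calls)
})

test_that("simulated scenes at wide spacing are assigned to the true caller", {
  for (spacing in c(50, 100)) {
    sc <- simulate_scene(sim_config(n_whales = 2, duration = 1200,
                                    spacing_mean = spacing, seed = 21))
    d <- sc$detections
    d$rl_valid <- TRUE
    m <- match_across_tags(d)
    asg <- assign_callers(m, delta_db = 3)
    truth <- sc$calls$whale_id[match(
      vapply(asg$calls$call_id, function(cid)
        m$true_call_id[m$call_id == cid][1], integer(1)), sc$calls$call_id)]
    expect_true(all(!is.na(asg$calls$focal_whale)))
    expect_true(all(asg$calls$focal_whale == truth))
  }
})

test_that("assignment accuracy does not increase as whales converge", {
  # shallow dives keep the 3-D separation close to the horizontal spacing
  accs <- vapply(c(50, 10, 5, 2), function(spacing) {
    sc <- simulate_scene(sim_config(n_whales = 2, duration = 1200,
                                    spacing_mean = spacing,
                                    spacing_model = "ou_wander",
                                    dive_depth_max = 0.6, seed = 33))
    d <- sc$detections
    d$rl_valid <- TRUE
    m <- match_across_tags(d)
    asg <- assign_callers(m, delta_db = 3)
    truth <- sc$calls$whale_id[match(
      vapply(asg$calls$call_id, function(cid)
        m$true_call_id[m$call_id == cid][1], integer(1)), sc$calls$call_id)]
    mean(!is.na(asg$calls$focal_whale) & asg$calls$focal_whale == truth)
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
  expect_equal(accs[1], 1)

  # near contact the geometric gap falls under delta_db: everything indeterminate
  sc <- simulate_scene(sim_config(n_whales = 2, duration = 1200,
                                  spacing_mean = 1.2, dive_depth_max = 0.6,
                                  seed = 33))
  d <- sc$detections; d$rl_valid <- TRUE
  asg <- assign_callers(match_across_tags(d), delta_db = 3)
  multi <- asg$calls$multi_tag
  expect_true(all(is.na(asg$calls$focal_whale[multi])))
})
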