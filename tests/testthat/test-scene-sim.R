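test_that("config invariants are enforced", {
  expect_error(sim_config(n_whales = 0), class = "focalcall_invalid_config")
  expect_error(sim_config(bout_lambda_fast = 0.01, bout_lambda_slow = 0.5),
               class = "focalcall_invalid_config")
  expect_error(sim_config(bout_p = 1.2), class = "focalcall_invalid_config")
  expect_error(sim_config(tag_offset = 100, spacing_mean = 50),
               class = "focalcall_invalid_config")
  expect_error(simulate_tracks(sim_config(duration = 0)),
               class = "focalcall_invalid_config")
})

test_that("tracks respect depth bounds, spacing and seeding", {
  cfg <- sim_config(n_whales = 2, duration = 600, dive_depth_max = 45,
                    spacing_mean = 100, spacing_model = "fixed", seed = 4)
  tr <- simulate_tracks(cfg)
  expect_true(all(tr$depth >= 0 & tr$depth <= 45))
  expect_equal(sort(unique(tr$whale_id)), c("whale1", "whale2"))
  # track sampled at 5 Hz
  t1 <- tr$time[tr$whale_id == "whale1"]
  expect_equal(unique(round(diff(t1), 9)), 0.2)
  # each whale surfaces (< 2 m) and dives within each cycle
  for (w in unique(tr$whale_id)) {
    d <- tr$depth[tr$whale_id == w]
    expect_true(any(d < 2))
    expect_true(any(d > 10))
  }
  # fixed geometry: horizontal separation is exactly the spacing everywhere
  w1 <- tr[tr$whale_id == "whale1", ]; w2 <- tr[tr$whale_id == "whale2", ]
  expect_true(all(abs(sqrt((w1$x - w2$x)^2 + (w1$y - w2$y)^2) - 100) < 1e-9))

  # seeded reproducibility, and different seeds differ
  cfg_ou <- sim_config(n_whales = 2, duration = 300,
                       spacing_model = "ou_wander", seed = 4)
  a <- simulate_tracks(cfg_ou)
  b <- simulate_tracks(cfg_ou)
  expect_identical(a, b)
  cfg_ou2 <- sim_config(n_whales = 2, duration = 300,
                        spacing_model = "ou_wander", seed = 5)
  expect_false(isTRUE(all.equal(a$x, simulate_tracks(cfg_ou2)$x)))
})

test_that("call times follow the two-process mixture", {
  # closed-form mixture mean: p/lf + (1-p)/ls = 0.75*2 + 0.25*100 = 26.5 s
  cfg <- sim_config(n_whales = 1, duration = 30000, bout_p = 0.75,
                    bout_lambda_fast = 0.5, bout_lambda_slow = 0.01,
                    response_prob = 0, seed = 10)
  calls <- simulate_call_times(cfg)
  ici <- ici_series(calls$t_emit)
  expect_gt(length(ici), 700)
  mix_mean <- 26.5
  mix_sd <- sqrt(0.75 * 2 / 0.5^2 + 0.25 * 2 / 0.01^2 - mix_mean^2)
  expect_lt(abs(mean(ici) - mix_mean), 3 * mix_sd / sqrt(length(ici)))

  # durations and source levels drawn, truth recorded
  expect_true(all(calls$duration > 0))
  expect_true(all(calls$process %in% c("bout", "response")))
  expect_true(all(calls$process == "bout"))  # no responses requested

  # degenerate input
  cfg0 <- sim_config(duration = 0)
  expect_equal(nrow(simulate_call_times(cfg0)), 0L)
})

test_that("without responses the two whales' call processes show no cross-clustering", {
  cfg <- sim_config(n_whales = 2, duration = 20000, response_prob = 0, seed = 14)
  calls <- simulate_call_times(cfg)
  x <- inter_individual_icis(calls[, c("whale_id", "t_emit")] |>
                               setNames(c("whale_id", "t_start")))
  obs <- mean(x <= 30)
  # null distribution by circularly shifting whale2's calls
  t2 <- calls$t_emit[calls$whale_id == "whale2"]
  t1 <- calls$t_emit[calls$whale_id == "whale1"]
  set.seed(1)
  null <- vapply(1:40, function(k) {
    shift <- runif(1, 1000, 19000)
    sh <- data.frame(
      whale_id = c(rep("whale1", length(t1)), rep("whale2", length(t2))),
      t_start = c(t1, (t2 + shift) %% 20000))
    mean(inter_individual_icis(sh) <= 30)
  }, numeric(1))
  expect_lt(abs(obs - mean(null)), 4 * stats::sd(null) + 0.02)

  # with responses enabled, short cross-whale intervals are enriched
  cfg_r <- sim_config(n_whales = 2, duration = 20000, response_prob = 0.6,
                      response_latency_mean = 10, seed = 14)
  calls_r <- simulate_call_times(cfg_r)
  xr <- inter_individual_icis(calls_r[, c("whale_id", "t_emit")] |>
                                setNames(c("whale_id", "t_start")))
  expect_gt(mean(xr <= 30), obs)
})

test_that("received levels follow geometric spreading and the detectability rule", {
  cfg <- sim_config(n_whales = 2, duration = 10, spacing_mean = 100,
                    dive_depth_max = 0.6, source_level_sd = 0,
                    source_level_mean = 155, noise_level = 95,
                    detect_snr = 10, seed = 2)
  tracks <- simulate_tracks(cfg)
  calls <- data.frame(call_id = 1L, whale_id = "whale1", t_emit = 5,
                      duration = 1, source_level = 155, emit_depth = 0.5,
                      process = "bout")
  sc <- render_scene(cfg, tracks, calls)
  own <- sc$rl_table[sc$rl_table$tag_id == "tag1", ]
  other <- sc$rl_table[sc$rl_table$tag_id == "tag2", ]
  # r = 1 m -> RL = SL; r ~ 100 m -> SL - 40
  expect_equal(own$rl_db, 155)
  expect_equal(other$rl_db, 155 - 20 * log10(other$distance_m), tolerance = 1e-9)
  expect_lt(abs(other$rl_db - 115), 0.5)
  expect_true(all(sc$rl_table$detected))

  # below-threshold levels produce no detection: RL 104 vs floor 95 + snr 10
  calls2 <- calls; calls2$source_level <- 104 + 20 * log10(other$distance_m)
  sc2 <- render_scene(cfg, tracks, calls2)
  expect_false(sc2$rl_table$detected[sc2$rl_table$tag_id == "tag2"])
  expect_false("tag2" %in% sc2$detections$tag_id)
})

test_that("the true caller's own tag always receives the call loudest", {
  for (seed in 1:3) {
    sc <- simulate_scene(sim_config(n_whales = 3, duration = 600,
                                    spacing_mean = 50, seed = seed))
    for (cid in sc$calls$call_id) {
      rl <- sc$rl_table[sc$rl_table$call_id == cid, ]
      own <- rl$whale_id == sc$calls$whale_id[sc$calls$call_id == cid]
      expect_true(rl$rl_db[own] > max(rl$rl_db[!own]))
    }
  }
})

test_that("scenes regenerate identically from the same seed", {
  cfg <- sim_config(n_whales = 2, duration = 300, seed = 123)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$rl_table, s2$rl_table)
  expect_identical(s1$detections, s2$detections)

  cfgw <- sparse_waveform_config(seed = 6, duration = 30, fs = 24000)
  w1 <- simulate_scene(cfgw, waveform = TRUE)
  w2 <- simulate_scene(cfgw, waveform = TRUE)
  expect_identical(w1$audio[["tag1"]]$samples, w2$audio[["tag1"]]$samples)
})

test_that("waveform rendering refuses an aliasing sample rate", {
  cfg <- sim_config(n_whales = 2, duration = 10, fs = 1000, seed = 1)
  tracks <- simulate_tracks(cfg)
  calls <- simulate_call_times(cfg, tracks)
  expect_error(render_scene(cfg, tracks, calls, waveform = TRUE),
               class = "focalcall_aliasing")
})

test_that("a mixture fit to simulated intervals recovers the generating rates", {
  cfg <- sim_config(n_whales = 1, duration = 1e9, seed = 42)
  set.seed(cfg$seed)
  ici <- rici_mixture(2000, cfg$bout_p, cfg$bout_lambda_fast, cfg$bout_lambda_slow)
  bm <- fit_bout_model(ici)
  expect_lt(abs(bm$lambda_fast - cfg$bout_lambda_fast) / cfg$bout_lambda_fast, 0.2)
  expect_lt(abs(bm$lambda_slow - cfg$bout_lambda_slow) / cfg$bout_lambda_slow, 0.2)
})
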