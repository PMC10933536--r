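test_that("call rates reproduce tabulated rates at 1-decimal rounding", {
  # self-consistent published rows: (n calls, duration min) -> calls/h
  rows <- list(list(20, 88, 13.6), list(3, 160, 1.1), list(8, 147, 3.3),
               list(12, 147, 4.9), list(46, 31, 89.0), list(15, 31, 29.0),
               list(6, 17, 21.2))
  for (r in rows) {
    expect_equal(call_rate(r[[1]], r[[2]] * 60), r[[3]])
  }
  expect_equal(call_rate(0, analysis_period(0, 5000)), 0)
  expect_error(call_rate(5, 0), class = "focalcall_invalid_period")
  expect_error(call_rate(-1, 100), class = "focalcall_invalid_input")
})

test_that("silence is the complement of the union of detection spans", {
  p <- analysis_period(0, 100)
  s0 <- silence_stats(data.frame(t_start = numeric(0), t_end = numeric(0)), p)
  expect_equal(s0$proportion_silent, 1)
  expect_equal(s0$longest_silence_s, 100)

  s1 <- silence_stats(data.frame(t_start = 10, t_end = 12), p)
  expect_equal(s1$proportion_silent, 0.98)
  expect_equal(s1$longest_silence_s, 88)

  # abutting spans merge into one occupied block
  s2 <- silence_stats(data.frame(t_start = c(10, 12), t_end = c(12, 14)), p)
  expect_equal(s2$total_silence_s, 96)
  expect_equal(s2$longest_silence_s, 86)

  # random instances against a discretization oracle
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    t0 <- runif(n, 0, 90)
    d <- data.frame(t_start = round(t0, 2), t_end = round(t0 + runif(n, 0.5, 15), 2))
    got <- silence_stats(d, p)
    want <- oracle_silence(d, 0, 100)
    expect_equal(got$proportion_silent, want$proportion_silent, tolerance = 0.01)
    expect_equal(got$longest_silence_s, want$longest_silence_s, tolerance = 0.5)
  }
})

test_that("inter-call intervals are start-to-start differences", {
  expect_equal(ici_series(c(0, 1.5, 3.0, 60)), c(1.5, 1.5, 57))
  expect_equal(ici_series(42), numeric(0))
  expect_equal(ici_series(numeric(0)), numeric(0))
  expect_warning(ii <- ici_series(c(0, 5, 5, 9)), "zero")
  expect_equal(ii, c(5, 4))
})

test_that("bout model recovers two-process mixture parameters", {
  set.seed(2024)
  ici <- rici_mixture(1000, 0.75, 0.5, 0.01)
  bm <- fit_bout_model(ici)
  true_bec <- bec_from_params(0.75, 0.5, 0.01)
  expect_equal(true_bec, log(150) / 0.49, tolerance = 1e-12)
  expect_lt(abs(bm$bec - true_bec) / true_bec, 0.15)
  expect_lt(abs(bm$lambda_fast - 0.5) / 0.5, 0.2)
  expect_lt(abs(bm$lambda_slow - 0.01) / 0.01, 0.2)
  expect_true(bm$converged)
  expect_gt(bm$p, 0); expect_lt(bm$p, 1)
  expect_gt(bm$lambda_fast, bm$lambda_slow)

  # the EM optimum matches an independent direct likelihood maximization
  direct <- oracle_mixture_mle(ici)
  expect_equal(bm$loglik, direct$loglik, tolerance = 1e-4)
  expect_equal(bm$lambda_fast, direct$lambda_fast, tolerance = 0.02)
  expect_equal(bm$lambda_slow, direct$lambda_slow, tolerance = 0.02)

  # order invariance
  bm2 <- fit_bout_model(sample(ici))
  expect_equal(coef(bm2), coef(bm), tolerance = 1e-6)
})

test_that("bout model rejects degenerate and insufficient input", {
  set.seed(5)
  expect_error(fit_bout_model(rexp(800, 0.2)),
               class = "focalcall_degenerate_mixture")
  expect_error(fit_bout_model(rici_mixture(10, 0.7, 0.5, 0.01)),
               class = "focalcall_insufficient_data")
})

test_that("bout model methods are coherent", {
  set.seed(9)
  bm <- fit_bout_model(rici_mixture(800, 0.7, 0.6, 0.02))
  expect_named(coef(bm), c("p", "lambda_fast", "lambda_slow"))
  expect_equal(attr(logLik(bm), "df"), 3L)
  expect_output(print(bm), "bout-end criterion")
  expect_output(print(summary(bm)), "BEC")
  # density integrates to ~1 and survival decreases
  tt <- seq(0, 2000, by = 0.05)
  dens <- predict(bm, tt, type = "density")
  expect_equal(sum(dens) * 0.05, 1, tolerance = 0.02)
  surv <- predict(bm, c(0, 1, 10, 100), type = "survival")
  expect_true(all(diff(surv) < 0))
  expect_equal(surv[1], 1)
  sim <- simulate(bm, nsim = 500, seed = 1)
  expect_length(sim, 500)
  expect_true(all(sim > 0))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(bm); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})

test_that("bout segmentation applies the criterion and conserves call counts", {
  # criterion of 2.2 s, the dataset-wide value reported for this species
  b <- segment_bouts(c(0, 1.5, 3.0, 60, 61, 200), 2.2, period = 3600)
  expect_equal(b$summary$n_bouts, 2L)
  expect_equal(b$bouts$n_calls, c(3L, 2L))
  expect_equal(b$summary$mean_calls_per_bout, 2.5)
  expect_equal(b$summary$frac_in_bouts, 5 / 6)
  expect_equal(b$summary$bout_rate, 2)

  # tabulated bout-rate rows: (n bouts, duration min) -> bouts/h
  rows <- list(list(3, 88, 2.0), list(1, 160, 0.4), list(2, 147, 0.8),
               list(3, 147, 1.2), list(7, 31, 13.5), list(2, 31, 3.9),
               list(17, 227, 4.5))
  for (r in rows) {
    times <- if (r[[1]] > 0) as.vector(outer(c(0, 1), (1:r[[1]]) * 1000, "+")) else 100
    b <- segment_bouts(times, bec = 2.2, period = r[[2]] * 60)
    expect_equal(b$summary$n_bouts, r[[1]])
    expect_equal(b$summary$bout_rate, r[[3]])
  }

  none <- segment_bouts(c(0, 10, 20, 30), 2.2)
  expect_equal(none$summary$n_bouts, 0L)
  expect_equal(none$summary$frac_in_bouts, 0)

  expect_error(segment_bouts(1:5, bec = 0), class = "focalcall_invalid_input")
})

test_that("bout segmentation matches a brute-force scan on random call sets", {
  set.seed(77)
  for (rep in 1:1000) {
    n <- sample(0:25, 1)
    times <- sort(runif(n, 0, 300))
    bec <- runif(1, 0.5, 30)
    got <- segment_bouts(times, bec)
    want <- oracle_bouts(times, bec)
    expect_identical(got$summary$n_bouts, want$n_bouts)
    expect_identical(got$bouts$n_calls, want$sizes)
    # conservation: calls in bouts + singleton calls = all calls
    in_bouts <- sum(got$bouts$n_calls)
    expect_equal(in_bouts + (n - in_bouts), n)
    if (nrow(got$bouts)) {
      # every within-bout interval is below the criterion
      for (k in seq_len(nrow(got$bouts))) {
        idx <- got$bouts$first_call[k]:got$bouts$last_call[k]
        expect_true(all(diff(times[idx]) < bec))
      }
    }
  }
})

test_that("cross-individual intervals pair each call with the next other-whale call", {
  calls <- data.frame(whale_id = rep(c("A", "B"), each = 3),
                      t_start = c(0, 100, 200, 50, 150, 250))
  expect_equal(sort(inter_individual_icis(calls)), rep(50, 5))

  expect_equal(inter_individual_icis(
    data.frame(whale_id = c("A", "B"), t_start = c(0, 30))), 30)

  expect_error(inter_individual_icis(
    data.frame(whale_id = "A", t_start = c(0, 5))),
    class = "focalcall_insufficient_data")

  set.seed(88)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    calls <- data.frame(whale_id = sample(c("A", "B", "C"), n, replace = TRUE),
                        t_start = round(runif(n, 0, 500), 3))
    if (length(unique(calls$whale_id)) < 2) next
    expect_equal(sort(inter_individual_icis(calls)), oracle_cross_icis(calls))
  }
})

test_that("exchange probability: kernel estimate agrees with the empirical fraction", {
  expect_equal(exchange_auc(rep(50, 20))$proportion_empirical, 1)
  expect_equal(exchange_auc(rep(150, 20), horizon = 100)$proportion_empirical, 0)
  expect_error(exchange_auc(1:5), class = "focalcall_insufficient_data")

  set.seed(3)
  x <- runif(2000, 0, 200)
  a <- exchange_auc(x, horizon = 100)
  expect_lt(abs(a$proportion_empirical - 0.5), 0.03)
  expect_lt(abs(a$auc_kde - a$proportion_empirical), 0.05)

  # mixture-like interval data at moderate n
  set.seed(4)
  y <- rici_mixture(500, 0.6, 0.2, 0.005)
  ay <- exchange_auc(y, horizon = 100)
  expect_lt(abs(ay$auc_kde - ay$proportion_empirical), 0.05)
})
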