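# Independent brute-force oracles used to check the package's operators.

# bout segmentation by literal rule application: walk the sorted times and
# start a new bout whenever the gap reaches the criterion
oracle_bouts <- function(times, bec) {
  times <- sort(times)
  n <- length(times)
  if (n < 2) return(list(n_bouts = 0L, sizes = integer(0)))
  sizes <- integer(0)
  run <- 1L
  for (i in 2:n) {
    if (times[i] - times[i - 1] < bec) {
      run <- run + 1L
    } else {
      if (run >= 2L) sizes <- c(sizes, run)
      run <- 1L
    }
  }
  if (run >= 2L) sizes <- c(sizes, run)
  list(n_bouts = length(sizes), sizes = sizes)
}

# silence by fine time discretization of the analysis period
oracle_silence <- function(detections, t0, t1, dt = 0.01) {
  grid <- seq(t0, t1 - dt, by = dt) + dt / 2
  occupied <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(detections))) {
    occupied <- occupied |
      (grid >= detections$t_start[i] & grid < detections$t_end[i])
  }
  r <- rle(!occupied)
  longest <- if (any(r$values)) max(r$lengths[r$values]) * dt else 0
  list(proportion_silent = mean(!occupied), longest_silence_s = longest)
}

# cross-individual intervals by double loop over the merged timeline
oracle_cross_icis <- function(calls) {
  out <- numeric(0)
  for (i in seq_len(nrow(calls))) {
    later <- calls$t_start > calls$t_start[i] & calls$whale_id != calls$whale_id[i]
    if (any(later)) out <- c(out, min(calls$t_start[later]) - calls$t_start[i])
  }
  sort(out)
}

# connected components of the pairwise link graph by repeated expansion
oracle_components <- function(detections, tol, frac) {
  n <- nrow(detections)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || detections$tag_id[i] == detections$tag_id[j]) next
    dt <- abs(detections$t_start[i] - detections$t_start[j])
    ov <- min(detections$t_end[i], detections$t_end[j]) -
      max(detections$t_start[i], detections$t_start[j])
    shorter <- min(detections$t_end[i] - detections$t_start[i],
                   detections$t_end[j] - detections$t_start[j])
    if (dt <= tol && ov >= frac * shorter) linked[i, j] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (linked[i, j] && comp[i] != comp[j]) {
        comp[pmax(comp[i], comp[j]) == comp] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# direct maximum-likelihood fit of the two-exponential mixture via optim,
# independent of the package's EM route
oracle_mixture_mle <- function(x, init = c(0.5, 1 / stats::median(x),
                                           1 / mean(x))) {
  nll <- function(par) {
    p <- stats::plogis(par[1]); lf <- exp(par[2]); ls <- exp(par[3])
    -sum(log(p * lf * exp(-lf * x) + (1 - p) * ls * exp(-ls * x)))
  }
  fit <- stats::optim(c(stats::qlogis(init[1]), log(init[2]), log(init[3])),
                      nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  p <- stats::plogis(fit$par[1]); lf <- exp(fit$par[2]); ls <- exp(fit$par[3])
  if (lf < ls) { tmp <- lf; lf <- ls; ls <- tmp; p <- 1 - p }
  list(p = p, lambda_fast = lf, lambda_slow = ls, loglik = -fit$value)
}

# a quiet, sparse waveform scene for round-trip level checks
sparse_waveform_config <- function(seed, duration = 300, noise_level = 20,
                                   fs = 96000) {
  sim_config(n_whales = 2, duration = duration, spacing_mean = 100,
             fs = fs, noise_level = noise_level, detect_snr = 5,
             bout_p = 0.3, bout_lambda_fast = 0.3, bout_lambda_slow = 0.05,
             call_dur_mean = 0.8, call_dur_sd = 0.15, response_prob = 0,
             seed = seed)
}
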