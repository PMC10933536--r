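# Call rates, silence, inter-call intervals, the two-process exponential
# mixture bout model (MLE via EM, broken-stick initialisation), bout
# segmentation and inter-individual vocal-exchange timing.

#' Define an analysis period
#'
#' The window over which a group's acoustic behaviour is analysed, typically
#' starting when the last tag in the group was deployed.
#'
#' @param t_start,t_end period bounds, seconds on the scene clock
#' @param group_id optional group identifier
#' @param whales optional character vector of member whale ids
#' @return object of class `analysis_period`
#' @export
analysis_period <- function(t_start, t_end, group_id = NA_character_, whales = NULL) {
  if (!is_scalar(t_start) || !is_scalar(t_end) || t_end <= t_start)
    fc_stop("analysis period must have t_end > t_start", "invalid_period")
  structure(list(t_start = t_start, t_end = t_end, group_id = group_id,
                 whales = whales, duration_s = t_end - t_start),
            class = "analysis_period")
}

period_hours <- function(period) {
  if (inherits(period, "analysis_period")) return(period$duration_s / 3600)
  if (is_scalar(period) && period > 0) return(period / 3600)
  fc_stop("period must be an analysis_period or a positive duration in seconds",
          "invalid_period")
}

#' Raw call rate in calls per hour
#'
#' @param n_focal number of focal calls
#' @param period an [analysis_period()] or a duration in seconds
#' @param digits rounding of the reported rate (default 1 decimal, the
#'   precision at which call rates are conventionally tabulated)
#' @return calls per hour
#' @export
call_rate <- function(n_focal, period, digits = 1) {
  if (!is_count(n_focal)) fc_stop("n_focal must be a non-negative count", "invalid_input")
  round(n_focal / period_hours(period), digits)
}

#' Silence statistics over an analysis period
#'
#' Silence is the complement, within the period, of the union of all
#' detection spans across every tag in the group (abutting or overlapping
#' spans merge).
#'
#' @param detections data frame with `t_start`, `t_end` (all tags pooled)
#' @param period an [analysis_period()]
#' @return list: `proportion_silent`, `longest_silence_s`, `total_silence_s`
#' @export
silence_stats <- function(detections, period) {
  stopifnot(inherits(period, "analysis_period"))
  dur <- period$duration_s
  if (is.null(detections) || nrow(detections) == 0) {
    return(list(proportion_silent = 1, longest_silence_s = dur, total_silence_s = dur))
  }
  s <- pmax(detections$t_start, period$t_start)
  e <- pmin(detections$t_end, period$t_end)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0) {
    return(list(proportion_silent = 1, longest_silence_s = dur, total_silence_s = dur))
  }
  o <- order(s)
  s <- s[o]; e <- e[o]
  # merge the union of occupied spans
  ms <- s[1]; me <- e[1]; gaps <- numeric(0); occupied <- 0
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      occupied <- occupied + (me - ms)
      gaps <- c(gaps, s[i] - me)
      ms <- s[i]; me <- e[i]
    }
  }
  occupied <- occupied + (me - ms)
  gaps <- c(s[1] - period$t_start, gaps, period$t_end - me)
  list(proportion_silent = (dur - occupied) / dur,
       longest_silence_s = max(gaps),
       total_silence_s = dur - occupied)
}

#' Inter-call intervals of one individual
#'
#' Start-to-start intervals between successive calls of the same individual.
#' Duplicate start times produce zero intervals, which are dropped with a
#' warning.
#'
#' @param times call start times, seconds (sorted or not)
#' @return numeric vector of intervals (length `n - 1`, empty for `n <= 1`)
#' @export
ici_series <- function(times) {
  times <- sort(as.numeric(times))
  if (length(times) <= 1L) return(numeric(0))
  ici <- diff(times)
  if (any(ici == 0)) {
    warning(sprintf("%d zero inter-call interval(s) dropped (duplicate start times)",
                    sum(ici == 0)))
    ici <- ici[ici > 0]
  }
  ici
}

# ---- two-process exponential mixture bout model -----------------------------

mixture_loglik <- function(par, x) {
  p <- par[1]; lf <- par[2]; ls <- par[3]
  sum(log(p * lf * exp(-lf * x) + (1 - p) * ls * exp(-ls * x)))
}

# broken-stick initialisation: two-segment least-squares fit to the
# log-frequency histogram of log-transformed intervals
broken_stick_init <- function(x) {
  lx <- log(x)
  nb <- max(8L, min(30L, floor(sqrt(length(x)))))
  h <- graphics::hist(lx, breaks = nb, plot = FALSE)
  mids <- h$mids[h$counts > 0]
  lc <- log(h$counts[h$counts > 0])
  best <- NULL; best_sse <- Inf
  if (length(mids) >= 4L) {
    for (k in 2L:(length(mids) - 2L)) {
      sse <- 0
      for (side in list(1:k, (k + 1):length(mids))) {
        if (length(side) >= 2L) {
          f <- stats::lm.fit(cbind(1, mids[side]), lc[side])
          sse <- sse + sum(f$residuals^2)
        }
      }
      if (sse < best_sse) { best_sse <- sse; best <- mids[k] }
    }
  }
  thr <- if (is.null(best)) stats::median(lx) else best
  fast <- x[lx <= thr]; slow <- x[lx > thr]
  if (length(fast) < 2L || length(slow) < 2L) {
    fast <- x[x <= stats::median(x)]; slow <- x[x > stats::median(x)]
  }
  c(p = length(fast) / length(x), lambda_fast = 1 / mean(fast),
    lambda_slow = 1 / mean(slow))
}

#' Fit the two-process exponential mixture bout model
#'
#' Models inter-call intervals as a mixture of a fast within-bout Poisson
#' process and a slow between-bout process,
#' \deqn{f(t) = p\,\lambda_f e^{-\lambda_f t} + (1-p)\,\lambda_s e^{-\lambda_s t},}
#' fitted by maximum likelihood on the raw intervals (EM iterations,
#' initialised from a broken-stick fit to the log-frequency histogram of the
#' log-transformed intervals). The bout-end criterion (BEC) is the interval at
#' which the two weighted component densities cross:
#' \deqn{\mathrm{BEC} = \frac{\log\left(p \lambda_f / ((1-p)\lambda_s)\right)}
#'   {\lambda_f - \lambda_s}.}
#'
#' @param icis inter-call intervals, seconds (pooled across individuals for a
#'   dataset-wide criterion)
#' @param min_n minimum number of intervals (default 30)
#' @param max_iter EM iteration cap
#' @param tol relative log-likelihood convergence tolerance (default 1e-8)
#' @param min_ratio minimum `lambda_fast / lambda_slow` below which the fit is
#'   declared degenerate (default 1.5)
#' @return object of class `bout_model` with elements `p`, `lambda_fast`,
#'   `lambda_slow`, `bec`, `loglik`, `n`, `iterations`, `converged`
#' @export
fit_bout_model <- function(icis, min_n = 30, max_iter = 5000, tol = 1e-8,
                           min_ratio = 1.5) {
  x <- as.numeric(icis)
  x <- x[is.finite(x) & x > 0]
  if (length(x) < min_n)
    fc_stop(sprintf("need at least %d positive intervals, got %d", min_n, length(x)),
            "insufficient_data")
  init <- broken_stick_init(x)
  p <- min(max(init[1], 0.05), 0.95)
  lf <- init[2]; ls <- init[3]
  if (lf < ls) { tmp <- lf; lf <- ls; ls <- tmp; p <- 1 - p }

  ll_old <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    df <- p * lf * exp(-lf * x)
    ds <- (1 - p) * ls * exp(-ls * x)
    tot <- df + ds
    r <- df / tot                       # responsibility of the fast process
    p <- mean(r)
    lf <- sum(r) / sum(r * x)
    ls <- sum(1 - r) / sum((1 - r) * x)
    if (lf < ls) { tmp <- lf; lf <- ls; ls <- tmp; p <- 1 - p }
    ll <- mixture_loglik(c(p, lf, ls), x)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!is.finite(lf) || !is.finite(ls) || lf / ls < min_ratio)
    fc_stop(sprintf(
      "degenerate mixture: lambda_fast/lambda_slow = %.3g < %.3g (single-process data?)",
      lf / ls, min_ratio), "degenerate_mixture")

  bec <- log(p * lf / ((1 - p) * ls)) / (lf - ls)
  structure(list(p = unname(p), lambda_fast = unname(lf), lambda_slow = unname(ls),
                 bec = unname(bec), loglik = unname(ll_old), n = length(x),
                 iterations = it, converged = converged, icis = x),
            class = "bout_model")
}

#' @export
print.bout_model <- function(x, ...) {
  cat("Two-process exponential mixture bout model\n")
  cat(sprintf("  n = %d intervals, log-likelihood = %.2f%s\n", x$n, x$loglik,
              if (!x$converged) " (not converged)" else ""))
  cat(sprintf("  p (fast)      = %.3f\n", x$p))
  cat(sprintf("  lambda_fast   = %.4g /s  (mean within-bout ICI %.2f s)\n",
              x$lambda_fast, 1 / x$lambda_fast))
  cat(sprintf("  lambda_slow   = %.4g /s  (mean between-bout ICI %.1f s)\n",
              x$lambda_slow, 1 / x$lambda_slow))
  cat(sprintf("  bout-end criterion = %.2f s\n", x$bec))
  invisible(x)
}

#' @export
summary.bout_model <- function(object, ...) {
  out <- c(object[c("p", "lambda_fast", "lambda_slow", "bec", "loglik", "n",
                    "iterations", "converged")],
           list(mean_ici_fast = 1 / object$lambda_fast,
                mean_ici_slow = 1 / object$lambda_slow,
                frac_below_bec = mean(object$icis < object$bec)))
  class(out) <- "summary.bout_model"
  out
}

#' @export
print.summary.bout_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Bout model summary (n = %d)\n",
    "  mixture: p = %.3f, lambda_fast = %.4g /s, lambda_slow = %.4g /s\n",
    "  mean ICI within bouts %.2f s, between bouts %.1f s\n",
    "  BEC = %.2f s; %.0f%% of intervals fall below it\n",
    "  log-likelihood %.2f after %d EM iterations\n"),
    x$n, x$p, x$lambda_fast, x$lambda_slow, x$mean_ici_fast, x$mean_ici_slow,
    x$bec, 100 * x$frac_below_bec, x$loglik, x$iterations))
  invisible(x)
}

#' @export
coef.bout_model <- function(object, ...) {
  c(p = object$p, lambda_fast = object$lambda_fast, lambda_slow = object$lambda_slow)
}

#' @export
logLik.bout_model <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' Mixture density or survival function of a fitted bout model
#'
#' @param object a [fit_bout_model()] fit
#' @param newdata intervals (s) at which to evaluate; defaults to the fitted
#'   intervals
#' @param type `"density"` (default) or `"survival"`
#' @param ... unused
#' @return numeric vector
#' @export
predict.bout_model <- function(object, newdata = NULL,
                               type = c("density", "survival"), ...) {
  type <- match.arg(type)
  t <- if (is.null(newdata)) object$icis else as.numeric(newdata)
  p <- object$p; lf <- object$lambda_fast; ls <- object$lambda_slow
  if (type == "density") p * lf * exp(-lf * t) + (1 - p) * ls * exp(-ls * t)
  else p * exp(-lf * t) + (1 - p) * exp(-ls * t)
}

#' Simulate intervals from a fitted bout model
#'
#' @param object a [fit_bout_model()] fit
#' @param nsim number of intervals
#' @param seed optional RNG seed
#' @param ... unused
#' @return numeric vector of simulated intervals (s)
#' @export
simulate.bout_model <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rici_mixture(nsim, object$p, object$lambda_fast, object$lambda_slow)
}

#' Draw intervals from a two-process exponential mixture
#'
#' @param n number of intervals
#' @param p fast-process weight
#' @param lambda_fast,lambda_slow process rates, 1/s
#' @return numeric vector of intervals (s)
#' @export
rici_mixture <- function(n, p, lambda_fast, lambda_slow) {
  fast <- runif(n) < p
  ifelse(fast, rexp(n, lambda_fast), rexp(n, lambda_slow))
}

#' Closed-form bout-end criterion of a two-process mixture
#'
#' @param p fast-process weight
#' @param lambda_fast,lambda_slow process rates, 1/s
#' @return the interval (s) at which the weighted component densities cross
#' @export
bec_from_params <- function(p, lambda_fast, lambda_slow) {
  log(p * lambda_fast / ((1 - p) * lambda_slow)) / (lambda_fast - lambda_slow)
}

#' Log-survivorship plot of intervals with the fitted mixture
#'
#' @param x a [fit_bout_model()] fit
#' @param ... passed to [graphics::plot()]
#' @export
plot.bout_model <- function(x, ...) {
  s <- sort(x$icis)
  surv <- 1 - (seq_along(s) - 0.5) / length(s)
  graphics::plot(s, log(surv), type = "s", xlab = "inter-call interval (s)",
                 ylab = "log survivorship", ...)
  graphics::lines(s, log(predict(x, s, type = "survival")), col = 2, lwd = 2)
  graphics::abline(v = x$bec, lty = 2)
  graphics::legend("topright", legend = c("empirical", "fitted mixture",
                                          sprintf("BEC = %.2f s", x$bec)),
                   col = c(1, 2, 1), lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

# ---- bout segmentation ------------------------------------------------------

#' Segment one individual's calls into bouts
#'
#' A bout is a maximal run of two or more consecutive calls, each separated
#' from the previous by a start-to-start interval strictly below the bout-end
#' criterion.
#'
#' @param times call start times (s) of one individual
#' @param bec bout-end criterion, seconds
#' @param period optional [analysis_period()] (or duration, s) for the bout
#'   rate
#' @param digits rounding of the reported bout rate (default 1 decimal)
#' @return list with `bouts` (data frame: `bout_id`, `t_start`, `t_end`,
#'   `n_calls`, `first_call`, `last_call` as indices into the sorted times)
#'   and `summary` (`n_calls`, `n_bouts`, `bout_rate`, `mean_calls_per_bout`,
#'   `frac_in_bouts`)
#' @export
segment_bouts <- function(times, bec, period = NULL, digits = 1) {
  if (!is_scalar(bec) || bec <= 0) fc_stop("bec must be positive", "invalid_input")
  times <- sort(as.numeric(times))
  n <- length(times)
  empty <- data.frame(bout_id = integer(0), t_start = numeric(0), t_end = numeric(0),
                      n_calls = integer(0), first_call = integer(0),
                      last_call = integer(0))
  if (n < 2L) {
    return(list(bouts = empty, summary = bout_summary(n, empty, period, digits)))
  }
  in_run <- diff(times) < bec
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  bouts <- if (length(idx)) {
    do.call(rbind, lapply(seq_along(idx), function(k) {
      i0 <- starts[idx[k]]          # first interval of the run
      i1 <- ends[idx[k]]            # last interval of the run
      data.frame(bout_id = k, t_start = times[i0], t_end = times[i1 + 1L],
                 n_calls = i1 - i0 + 2L, first_call = i0, last_call = i1 + 1L)
    }))
  } else empty
  list(bouts = bouts, summary = bout_summary(n, bouts, period, digits))
}

bout_summary <- function(n_calls, bouts, period, digits) {
  nb <- nrow(bouts)
  list(n_calls = n_calls,
       n_bouts = nb,
       bout_rate = if (!is.null(period)) round(nb / period_hours(period), digits)
       else NA_real_,
       mean_calls_per_bout = if (nb) mean(bouts$n_calls) else 0,
       frac_in_bouts = if (n_calls) sum(bouts$n_calls) / n_calls else NA_real_)
}

# ---- inter-individual exchange timing ---------------------------------------

#' Inter-individual inter-call intervals
#'
#' For every call, the interval to the next strictly later call produced by a
#' different individual (one interval per call when such a successor exists).
#'
#' @param calls data frame with `whale_id` and `t_start`
#' @return numeric vector of cross-individual intervals (s)
#' @export
inter_individual_icis <- function(calls) {
  stopifnot(all(c("whale_id", "t_start") %in% names(calls)))
  vocal <- unique(calls$whale_id)
  if (length(vocal) < 2L)
    fc_stop("need calls from at least 2 individuals", "insufficient_data")
  o <- order(calls$t_start)
  t <- calls$t_start[o]; w <- calls$whale_id[o]
  n <- length(t)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && (w[j] == w[i] || t[j] <= t[i])) j <- j + 1L
    if (j <= n) out <- c(out, t[j] - t[i])
  }
  # last call may still have a successor among earlier-indexed ties: none by
  # construction (t sorted), so nothing to add
  out
}

#' Vocal-exchange probability within a horizon
#'
#' Estimates the probability that a call is answered by a different
#' individual within `horizon` seconds, two ways: the trapezoidal integral
#' over `[0, horizon]` of a Gaussian kernel density (Silverman bandwidth,
#' reflected at zero to correct boundary bias) of the cross-individual
#' intervals, and the empirical fraction of intervals at or below the
#' horizon.
#'
#' @param cross_icis cross-individual intervals from [inter_individual_icis()]
#' @param horizon integration horizon, seconds (default 100)
#' @param n_grid density grid resolution
#' @return list: `auc_kde`, `proportion_empirical`, `horizon`, `n`
#' @export
exchange_auc <- function(cross_icis, horizon = 100, n_grid = 1024) {
  x <- as.numeric(cross_icis)
  x <- x[is.finite(x) & x >= 0]
  if (length(x) < 10L)
    fc_stop(sprintf("need at least 10 intervals, got %d", length(x)),
            "insufficient_data")
  h <- bw.nrd0(x)
  grid <- seq(0, horizon, length.out = n_grid)
  f <- vapply(grid, function(g) {
    mean(dnorm((g - x) / h) + dnorm((g + x) / h)) / h   # reflection at zero
  }, numeric(1))
  list(auc_kde = trapz(grid, f),
       proportion_empirical = mean(x <= horizon),
       horizon = horizon, n = length(x))
}
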