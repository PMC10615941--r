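#' Response caution of the LBA
#'
#' Caution is the threshold minus the mean start point, `b - A/2`; it plays
#' the role boundary separation plays in the diffusion model.
#'
#' @param A start-point range upper bound (> 0).
#' @param b response threshold (> A).
#' @return `b - A/2`.
#' @export
compute_caution <- function(A, b) {
  if (any(b <= A) || any(A <= 0))
    stop("need b > A > 0", call. = FALSE)
  b - A / 2
}

# finishing-time pdf/cdf of a single LBA accumulator: start ~ U(0, A),
# drift ~ N(v, s), threshold b. As t -> Inf the cdf tends to P(drift > 0);
# negative-drift draws never finish.
lba_pdf_acc <- function(t, v, A, b, s) {
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  if (A < 1e-10) { # degenerate start point: T = b / drift
    out[pos] <- (b / tt^2) * dnorm((b / tt - v) / s) / s
  } else {
    z1 <- (b - A - tt * v) / (tt * s)
    z2 <- (b - tt * v) / (tt * s)
    out[pos] <- (-v * pnorm(z1) + s * dnorm(z1) +
                  v * pnorm(z2) - s * dnorm(z2)) / A
  }
  pmax(out, 0)
}

lba_cdf_acc <- function(t, v, A, b, s) {
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  if (A < 1e-10) {
    out[pos] <- pnorm((v - b / tt) / s)
  } else {
    z1 <- (b - A - tt * v) / (tt * s)
    z2 <- (b - tt * v) / (tt * s)
    out[pos] <- 1 + ((b - A - tt * v) / A) * pnorm(z1) -
      ((b - tt * v) / A) * pnorm(z2) +
      (tt * s / A) * dnorm(z1) - (tt * s / A) * dnorm(z2)
  }
  pmin(pmax(out, 0), 1)
}

#' Simulate two-choice trials from the linear ballistic accumulator
#'
#' Two independent accumulators race: the correct one with mean drift `v`,
#' the error one with mean drift `1 - v`, both with trial-to-trial drift SD
#' `s`, uniform start points on `(0, A)`, and threshold `b`. The winner's
#' finishing time plus `t0` is the RT. Trials on which neither accumulator
#' draws a positive drift are redrawn.
#'
#' @param v mean drift of the correct accumulator.
#' @param A start-point range (> 0; `A = 0` is allowed and pins all start
#'   points to 0).
#' @param b threshold (> A).
#' @param t0 non-decision time (s).
#' @param n_trials number of trials.
#' @param s trial-to-trial drift SD.
#' @param seed optional integer seed.
#' @param participant,condition label columns stamped on the output.
#' @return Trial table as in [simulate_ddm_trials()].
#' @export
simulate_lba_trials <- function(v, A, b, t0, n_trials, s = 0.3, seed = NULL,
                                participant = 1L, condition = "easy") {
  stopifnot(b > A, A >= 0, t0 >= 0, n_trials >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_trials == 0)
    return(data.frame(participant = integer(0), condition = character(0),
                      rt = numeric(0), response = integer(0)))
  rt <- numeric(n_trials); resp <- integer(n_trials)
  need <- seq_len(n_trials)
  guard <- 0L
  while (length(need) > 0 && guard < 1000L) {
    m <- length(need)
    u1 <- runif(m, 0, max(A, 0)); u2 <- runif(m, 0, max(A, 0))
    d1 <- rnorm(m, v, s); d2 <- rnorm(m, 1 - v, s)
    t1 <- ifelse(d1 > 0, (b - u1) / d1, Inf)
    t2 <- ifelse(d2 > 0, (b - u2) / d2, Inf)
    ok <- is.finite(pmin(t1, t2))
    rt[need[ok]] <- pmin(t1, t2)[ok] + t0
    resp[need[ok]] <- as.integer(t1[ok] <= t2[ok])
    need <- need[!ok]
    guard <- guard + 1L
  }
  data.frame(participant = participant, condition = condition,
             rt = rt, response = resp, stringsAsFactors = FALSE)
}

#' LBA log-likelihood of a set of trials
#'
#' Per trial, the defective density of the observed response at decision
#' time `rt - t0` — the winning accumulator's finishing-time pdf times the
#' losing accumulator's survivor function — renormalized by the probability
#' that at least one drift is positive (matching the simulator's redraw
#' rule), floored at `dens_floor`, and summed on the log scale.
#'
#' @inheritParams simulate_lba_trials
#' @param rt response times (s).
#' @param response 1 = correct, 0 = error.
#' @param dens_floor per-trial density floor.
#' @return Log-likelihood in nats (0 for an empty trial set).
#' @export
lba_loglik <- function(rt, response, v, A, b, t0, s = 0.3,
                       dens_floor = 1e-10) {
  stopifnot(length(rt) == length(response))
  if (length(rt) == 0) return(0)
  dt <- rt - t0
  v_err <- 1 - v
  p_none <- pnorm(-v / s) * pnorm(-v_err / s) # both drifts non-positive
  dens <- ifelse(
    response == 1,
    lba_pdf_acc(dt, v, A, b, s) * (1 - lba_cdf_acc(dt, v_err, A, b, s)),
    lba_pdf_acc(dt, v_err, A, b, s) * (1 - lba_cdf_acc(dt, v, A, b, s)))
  dens <- dens / (1 - p_none)
  dens[dt <= 0] <- 0
  sum(log(pmax(dens, dens_floor)))
}

#' Starting values for the LBA search
#'
#' The standard heuristics: `t0` at 90% of the fastest response; mean
#' correct drift `v` at `0.5 + qnorm(p, 0, 0.3)` with `p` the proportion
#' correct clamped to `[1/(2n), 1 - 1/(2n)]`; `A` at twice the
#' inter-quartile range of all response times; `b` at `1.25 * A`.
#'
#' @inheritParams lba_loglik
#' @return List with `v`, `A`, `b`, `t0`.
#' @export
lba_start_heuristics <- function(rt, response) {
  n <- length(rt)
  p <- min(max(mean(response == 1), 1 / (2 * n)), 1 - 1 / (2 * n))
  A <- 2 * IQR(rt)
  list(v = 0.5 + qnorm(p, 0, 0.3), A = A, b = 1.25 * A, t0 = 0.9 * min(rt))
}

#' Maximum-likelihood fit of the LBA to one condition
#'
#' Quasi-Newton bounded minimization (via [stats::nlminb()]) of the negative
#' [lba_loglik()]. Starting values follow the standard heuristics: `t0` at
#' 90% of the fastest response; `v` at `0.5 + qnorm(p, 0, 0.3)` where `p` is
#' the proportion correct (clamped away from 0 and 1); `A` at twice the
#' inter-quartile range of the RTs; `b` at `1.25 * A`. The threshold is
#' parameterized as `b = A + delta`, `delta > 0`, so `b > A` always holds.
#' On failure the start is jittered and the fit retried.
#'
#' @inheritParams lba_loglik
#' @param n_restarts additional jittered starts tried if the first fit does
#'   not converge.
#' @return List with `v`, `A`, `b`, `t0`, `caution`, `loglik`, `converged`,
#'   `n_restarts_used`.
#' @export
fit_lba_ml <- function(rt, response, s = 0.3, n_restarts = 2,
                       dens_floor = 1e-10) {
  n <- length(rt)
  stopifnot(n >= 2)
  h <- lba_start_heuristics(rt, response)
  t0_start <- h$t0; v_start <- h$v; A_start <- h$A; b_start <- h$b

  lower <- c(v = 0.1, A = 0.01, delta = 0.001, t0 = 0)
  upper <- c(v = 10, A = 5, delta = 5, t0 = max(min(rt) - 0.001, 0.002))
  clamp <- function(p) pmin(pmax(p, lower + 1e-6), upper - 1e-6)
  start0 <- clamp(c(v = v_start, A = A_start,
                    delta = max(b_start - A_start, 0.01), t0 = t0_start))
  obj <- function(p) -lba_loglik(rt, response, p[1], p[2], p[2] + p[3], p[4],
                                 s, dens_floor)
  tries <- 0L; res <- NULL
  start <- start0
  repeat {
    cand <- tryCatch(nlminb(start, obj, lower = lower, upper = upper,
                            control = list(iter.max = 500, eval.max = 1000)),
                     error = function(e) NULL)
    ok <- !is.null(cand) && is.finite(cand$objective) &&
      cand$convergence == 0
    if (is.null(res) || (!is.null(cand) && is.finite(cand$objective) &&
                         cand$objective < res$objective)) res <- cand
    if (ok || tries >= n_restarts) break
    tries <- tries + 1L
    start <- clamp(start0 * runif(4, 0.8, 1.2))
  }
  if (is.null(res))
    return(list(v = NA, A = NA, b = NA, t0 = NA, caution = NA,
                loglik = NA_real_, converged = FALSE,
                n_restarts_used = tries))
  p <- res$par
  list(v = p[[1]], A = p[[2]], b = p[[2]] + p[[3]], t0 = p[[4]],
       caution = compute_caution(p[[2]], p[[2]] + p[[3]]),
       loglik = -res$objective,
       converged = res$convergence == 0 && is.finite(res$objective),
       n_restarts_used = tries)
}

#' Simulate trials for a whole LBA parameter population
#'
#' @param params parameter table with columns `participant`, `condition`,
#'   `v`, `A`, `b`, `t0` (e.g. from [sample_lba_uniform_population()]).
#' @param n_trials trials per participant per condition.
#' @param seed integer seed.
#' @inheritParams simulate_lba_trials
#' @return Trial table.
#' @export
simulate_lba_population <- function(params, n_trials, seed = 1L, s = 0.3) {
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    stream <- 1L + (row$condition == "hard")
    out[[i]] <- simulate_lba_trials(
      row$v, row$A, row$b, row$t0, n_trials, s = s,
      seed = child_seed(seed, row$participant, stream = stream),
      participant = row$participant, condition = row$condition)
  }
  do.call(rbind, out)
}

#' Fit the LBA to every participant-by-condition cell
#'
#' @inheritParams simulate_lba_population
#' @param trials trial table.
#' @return Data frame with `participant`, `condition`, `v`, `A`, `b`, `t0`,
#'   `caution`, `loglik`, `converged`.
#' @export
fit_lba_population <- function(trials, s = 0.3, n_restarts = 2) {
  ids <- sort(unique(trials$participant))
  out <- vector("list", 2L * length(ids))
  k <- 0L
  for (id in ids) {
    for (cc in c("easy", "hard")) {
      d <- trials[trials$participant == id & trials$condition == cc, ]
      f <- fit_lba_ml(d$rt, d$response, s = s, n_restarts = n_restarts)
      k <- k + 1L
      out[[k]] <- data.frame(participant = id, condition = cc, v = f$v,
                             A = f$A, b = f$b, t0 = f$t0,
                             caution = f$caution, loglik = f$loglik,
                             converged = f$converged,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
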