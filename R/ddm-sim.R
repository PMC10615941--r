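# density-implied CDF on a grid, used by the inverse-CDF sampler.
# tmax comes from the slowest spectral decay rate lambda1 = pi^2 s^2/(2 a^2)
# + v^2/(2 s^2): beyond ~30/lambda1 the surviving mass is negligible.
ddm_cdf_grid <- function(v, a, zr = 0.5, s = 1, n_grid = 8192L, eps = 1e-9) {
  lambda1 <- pi^2 * s^2 / (2 * a^2) + v^2 / (2 * s^2)
  tmax <- 30 / lambda1
  tt <- seq(0, tmax, length.out = n_grid)
  fu <- wiener_fpt_density(tt, v, a, zr, "upper", s, eps)
  fl <- wiener_fpt_density(tt, v, a, zr, "lower", s, eps)
  dt <- tt[2] - tt[1]
  cum <- function(f) c(0, cumsum((f[-1] + f[-length(f)]) / 2) * dt)
  list(t = tt, cdf_upper = cum(fu), cdf_lower = cum(fl))
}

#' Simulate two-choice trials from the diffusion model
#'
#' Draws decision times and boundary choices from the Wiener
#' first-passage-time distribution and adds the non-decision time. The
#' default method inverts the density-implied CDF on a fine grid (fast,
#' exact up to grid interpolation); `method = "euler"` integrates the
#' diffusion path directly by Euler–Maruyama with step `dt`.
#'
#' @param v,a,t0 DDM parameters (drift, boundary separation, non-decision
#'   time in seconds).
#' @param n_trials number of trials.
#' @param zr relative starting point.
#' @param s diffusion coefficient.
#' @param method `"inverse_cdf"` (default) or `"euler"`.
#' @param dt Euler step in seconds (used only by `"euler"`).
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param participant,condition label columns stamped on the output.
#' @return Data frame with columns `participant`, `condition`, `rt`
#'   (seconds), `response` (1 = correct/upper, 0 = error/lower).
#' @export
simulate_ddm_trials <- function(v, a, t0, n_trials, zr = 0.5, s = 1,
                                method = c("inverse_cdf", "euler"),
                                dt = 5e-4, seed = NULL,
                                participant = 1L, condition = "easy") {
  method <- match.arg(method)
  stopifnot(n_trials >= 0, a > 0, t0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_trials == 0) {
    return(data.frame(participant = integer(0), condition = character(0),
                      rt = numeric(0), response = integer(0)))
  }
  if (method == "euler") {
    m <- ddm_euler_cpp(n_trials, v / s, a / s, zr, dt, 1)
    dtimes <- m[, 1]
    resp <- as.integer(m[, 2])
  } else {
    g <- ddm_cdf_grid(v, a, zr, s)
    p_up_num <- g$cdf_upper[length(g$t)]
    p_lo_num <- g$cdf_lower[length(g$t)]
    p_up <- ddm_prob_upper(v, a, zr, s)
    u <- runif(n_trials)
    resp <- as.integer(u < p_up)
    q <- runif(n_trials)
    dtimes <- numeric(n_trials)
    inv <- function(cdf, q) { # invert on the strictly increasing part
      k <- c(TRUE, diff(cdf) > 0)
      approx(cdf[k], g$t[k], xout = q, rule = 2)$y
    }
    iu <- resp == 1L
    if (any(iu)) dtimes[iu] <- inv(g$cdf_upper / p_up_num, q[iu])
    if (any(!iu)) dtimes[!iu] <- inv(g$cdf_lower / p_lo_num, q[!iu])
  }
  data.frame(participant = participant, condition = condition,
             rt = dtimes + t0, response = resp, stringsAsFactors = FALSE)
}

#' Simulate trials for a whole parameter population
#'
#' Runs [simulate_ddm_trials()] for every participant-by-condition row of a
#' parameter table, with per-row child seeds derived from `seed`.
#'
#' @param params parameter table with columns `participant`, `condition`,
#'   `v`, `a`, `t0` (e.g. from [sample_uniform_population()]).
#' @param n_trials trials per participant per condition.
#' @param seed integer seed.
#' @inheritParams simulate_ddm_trials
#' @return Trial table (one row per trial).
#' @export
simulate_ddm_population <- function(params, n_trials, seed = 1L, zr = 0.5,
                                    s = 1, method = "inverse_cdf") {
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    stream <- 1L + (row$condition == "hard")
    out[[i]] <- simulate_ddm_trials(
      row$v, row$a, row$t0, n_trials, zr = zr, s = s, method = method,
      seed = child_seed(seed, row$participant, stream = stream),
      participant = row$participant, condition = row$condition)
  }
  do.call(rbind, out)
}
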