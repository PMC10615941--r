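#' Diffusion-model log-likelihood of a set of trials
#'
#' Sum over trials of the log defective first-passage density at the
#' observed decision time `rt - t0` and boundary. Densities are floored at
#' `dens_floor` so that misfit regions (including trials with `rt <= t0`)
#' contribute a large-but-finite penalty rather than `-Inf`, keeping
#' derivative-free optimizers stable.
#'
#' @param rt response times (s).
#' @param response 1 = correct/upper, 0 = error/lower.
#' @param v,a,t0 DDM parameters.
#' @param zr relative starting point.
#' @param s diffusion coefficient.
#' @param eps density series truncation error.
#' @param dens_floor per-trial density floor.
#' @return Log-likelihood in nats (0 for an empty trial set).
#' @export
ddm_loglik <- function(rt, response, v, a, t0, zr = 0.5, s = 1,
                       eps = 1e-7, dens_floor = 1e-10) {
  stopifnot(length(rt) == length(response), a > 0)
  if (length(rt) == 0) return(0)
  ddm_loglik_cpp(as.numeric(rt), as.integer(response), v / s, a / s, t0, zr,
                 eps, dens_floor)
}

ddm_default_bounds <- function(rt) {
  list(v = c(-10, 10), a = c(0.05, 5), t0 = c(0, max(min(rt) - 0.001, 0.002)))
}

# box-constrained simplex: optimize on the logit scale of each bounded
# parameter, so plain Nelder-Mead respects the bounds
to_theta <- function(p, lo, hi) qlogis(pmin(pmax((p - lo) / (hi - lo), 1e-6), 1 - 1e-6))
from_theta <- function(theta, lo, hi) lo + (hi - lo) * plogis(theta)

ez_start <- function(rt, response, s = 1) {
  st <- tryCatch(fit_ez_trials(rt, response, s = s), error = function(e) NULL)
  if (is.null(st) || !all(is.finite(unlist(st))))
    st <- list(v = 1, a = 1, t0 = 0.5 * min(rt))
  st
}

#' Maximum-likelihood fit of the diffusion model to one condition
#'
#' Maximizes [ddm_loglik()] over `(v, a, t0)` with `zr` fixed and all
#' variability parameters at zero, using a box-constrained simplex
#' (Nelder–Mead on logit-transformed parameters). Starting values come from
#' the EZ closed form on the data's behavioural summaries, plus jittered
#' restarts (10% multiplicative jitter); the best restart is returned.
#' Bounds: `v` in \[-10, 10\], `a` in \[0.05, 5\], `t0` in
#' \[0, min(rt) - 1 ms\].
#'
#' @inheritParams ddm_loglik
#' @param n_restarts number of additional jittered starts after the EZ start.
#' @param maxit simplex iteration cap per start.
#' @return List with `v`, `a`, `t0`, `loglik`, `converged`,
#'   `n_restarts_used`.
#' @export
fit_ddm_ml <- function(rt, response, zr = 0.5, s = 1, n_restarts = 2,
                       eps = 1e-7, dens_floor = 1e-10, maxit = 400) {
  stopifnot(length(rt) >= 2)
  b <- ddm_default_bounds(rt)
  lo <- c(b$v[1], b$a[1], b$t0[1]); hi <- c(b$v[2], b$a[2], b$t0[2])
  obj <- function(theta) {
    p <- from_theta(theta, lo, hi)
    -ddm_loglik_cpp(rt, as.integer(response), p[1] / s, p[2] / s, p[3], zr,
                    eps, dens_floor)
  }
  st <- ez_start(rt, response, s)
  p0 <- c(st$v, st$a, st$t0)
  starts <- list(p0)
  for (j in seq_len(n_restarts))
    starts[[j + 1]] <- p0 * runif(3, 0.9, 1.1)
  best <- NULL
  for (p in starts) {
    res <- optim(to_theta(p, lo, hi), obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || res$value < best$value) best <- res
  }
  pars <- from_theta(best$par, lo, hi)
  list(v = pars[1], a = pars[2], t0 = pars[3], loglik = -best$value,
       converged = best$convergence == 0 && is.finite(best$value),
       n_restarts_used = length(starts) - 1L)
}

#' Joint fit of both conditions with shared-parameter constraints
#'
#' Fits one participant's two-condition data under a sharing pattern:
#' parameters named in `share` take a single value across conditions
#' (estimated from the pooled likelihood), the rest vary freely. With
#' nothing shared, this reduces exactly to two independent
#' [fit_ddm_ml()] fits (likelihood separability).
#'
#' @param trials data frame with columns `condition` (`"easy"`/`"hard"`),
#'   `rt`, `response`, for a single participant.
#' @param share character vector among `"v"`, `"a"`, `"t0"` naming
#'   parameters constrained equal across conditions.
#' @param extra_starts optional list of length-6 numeric vectors
#'   `(v_easy, v_hard, a_easy, a_hard, t0_easy, t0_hard)` used as
#'   additional starting points (shared entries are averaged).
#' @inheritParams fit_ddm_ml
#' @return List with `params` (data frame: condition, v, a, t0), `loglik`,
#'   `n_free`, `converged`, `n_restarts_used`.
#' @export
fit_ddm_conditions <- function(trials, share = character(0),
                               extra_starts = list(), zr = 0.5, s = 1,
                               n_restarts = 2, eps = 1e-7,
                               dens_floor = 1e-10, maxit = 600) {
  stopifnot(all(c("condition", "rt", "response") %in% names(trials)),
            all(share %in% c("v", "a", "t0")))
  e <- trials[trials$condition == "easy", ]
  h <- trials[trials$condition == "hard", ]
  stopifnot(nrow(e) >= 2, nrow(h) >= 2)

  if (length(share) == 0) {
    fe <- fit_ddm_ml(e$rt, e$response, zr, s, n_restarts, eps, dens_floor)
    fh <- fit_ddm_ml(h$rt, h$response, zr, s, n_restarts, eps, dens_floor)
    return(list(
      params = data.frame(condition = c("easy", "hard"),
                          v = c(fe$v, fh$v), a = c(fe$a, fh$a),
                          t0 = c(fe$t0, fh$t0), stringsAsFactors = FALSE),
      loglik = fe$loglik + fh$loglik,
      loglik_by_condition = c(easy = fe$loglik, hard = fh$loglik),
      n_free = 6L,
      converged = fe$converged && fh$converged,
      n_restarts_used = fe$n_restarts_used + fh$n_restarts_used))
  }

  pars <- c("v", "a", "t0")
  shared <- pars %in% share
  # free-vector layout: one slot per shared parameter, two per free one
  slot_names <- unlist(lapply(pars, function(p)
    if (p %in% share) p else paste0(p, c("_easy", "_hard"))))
  n_free <- length(slot_names)

  be <- ddm_default_bounds(e$rt); bh <- ddm_default_bounds(h$rt)
  bounds_for <- function(nm) {
    p <- sub("_(easy|hard)$", "", nm)
    if (p != "t0") return(be[[p]])
    if (nm == "t0") c(0, min(be$t0[2], bh$t0[2]))
    else if (nm == "t0_easy") be$t0 else bh$t0
  }
  lo <- vapply(slot_names, function(nm) bounds_for(nm)[1], 0)
  hi <- vapply(slot_names, function(nm) bounds_for(nm)[2], 0)

  expand6 <- function(p) { # free vector -> (v_e, v_h, a_e, a_h, t0_e, t0_h)
    out <- numeric(6); k <- 1
    for (j in seq_along(pars)) {
      if (shared[j]) { out[2 * j - 1] <- out[2 * j] <- p[k]; k <- k + 1 }
      else { out[2 * j - 1] <- p[k]; out[2 * j] <- p[k + 1]; k <- k + 2 }
    }
    out
  }
  collapse6 <- function(q) { # full 6-vector -> free vector (averaging shared)
    out <- numeric(0)
    for (j in seq_along(pars)) {
      pair <- q[c(2 * j - 1, 2 * j)]
      out <- c(out, if (shared[j]) mean(pair) else pair)
    }
    out
  }
  ll6 <- function(q) {
    ddm_loglik_cpp(e$rt, as.integer(e$response), q[1] / s, q[3] / s, q[5],
                   zr, eps, dens_floor) +
      ddm_loglik_cpp(h$rt, as.integer(h$response), q[2] / s, q[4] / s, q[6],
                     zr, eps, dens_floor)
  }
  obj <- function(theta) -ll6(expand6(from_theta(theta, lo, hi)))

  ste <- ez_start(e$rt, e$response, s); sth <- ez_start(h$rt, h$response, s)
  q0 <- c(ste$v, sth$v, ste$a, sth$a, ste$t0, sth$t0)
  starts <- c(list(collapse6(q0)),
              lapply(extra_starts, collapse6),
              list(collapse6(q0) * runif(n_free, 0.9, 1.1)))
  starts <- lapply(starts, function(p) pmin(pmax(p, lo + 1e-6), hi - 1e-6))

  best_val <- Inf; best_par <- NULL; best_conv <- FALSE
  for (p in starts) {
    th0 <- to_theta(p, lo, hi)
    v0 <- obj(th0) # keep the raw start as a candidate too
    if (v0 < best_val) { best_val <- v0; best_par <- th0; best_conv <- FALSE }
    res <- optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
    if (res$value < best_val) {
      best_val <- res$value; best_par <- res$par
      best_conv <- res$convergence == 0
    }
  }
  q <- expand6(from_theta(best_par, lo, hi))
  ll_e <- ddm_loglik_cpp(e$rt, as.integer(e$response), q[1] / s, q[3] / s,
                         q[5], zr, eps, dens_floor)
  list(params = data.frame(condition = c("easy", "hard"),
                           v = q[1:2], a = q[3:4], t0 = q[5:6],
                           stringsAsFactors = FALSE),
       loglik = -best_val,
       loglik_by_condition = c(easy = ll_e, hard = -best_val - ll_e),
       n_free = as.integer(n_free),
       converged = best_conv && is.finite(best_val),
       n_restarts_used = length(starts) - 1L)
}

#' Fit every participant-by-condition cell of a trial table
#'
#' @param trials trial table with columns `participant`, `condition`, `rt`,
#'   `response`.
#' @param fitter `"ml"` (maximum likelihood, [fit_ddm_ml()]) or `"ez"`
#'   ([fit_ez_trials()]).
#' @param share sharing constraint passed to [fit_ddm_conditions()]
#'   (ML only).
#' @inheritParams fit_ddm_ml
#' @return Data frame with one row per participant-by-condition:
#'   `participant`, `condition`, `v`, `a`, `t0`, `loglik`, `converged`.
#' @export
fit_ddm_population <- function(trials, fitter = c("ml", "ez"),
                               share = character(0), zr = 0.5, s = 1,
                               n_restarts = 2) {
  fitter <- match.arg(fitter)
  ids <- sort(unique(trials$participant))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- trials[trials$participant == ids[k], ]
    if (fitter == "ez") {
      rows <- lapply(c("easy", "hard"), function(cc) {
        d <- tr[tr$condition == cc, ]
        f <- tryCatch(fit_ez_trials(d$rt, d$response, s = s),
                      error = function(e) list(v = NA, a = NA, t0 = NA))
        data.frame(participant = ids[k], condition = cc, v = f$v, a = f$a,
                   t0 = f$t0, loglik = NA_real_,
                   converged = all(is.finite(unlist(f))),
                   stringsAsFactors = FALSE)
      })
      out[[k]] <- do.call(rbind, rows)
    } else {
      f <- fit_ddm_conditions(tr, share = share, zr = zr, s = s,
                              n_restarts = n_restarts)
      out[[k]] <- data.frame(participant = ids[k], f$params,
                             loglik = unname(f$loglik_by_condition),
                             converged = f$converged,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
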