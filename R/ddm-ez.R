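#' EZ-diffusion closed-form estimator
#'
#' Method-of-moments inversion from three behavioural summaries — proportion
#' correct, variance of correct-response RTs, and mean of correct-response
#' RTs — to the three main DDM parameters, reported on the diffusion
#' coefficient `s` scale (default 1, matching the rest of the package).
#'
#' Proportions of exactly 0, 0.5, or 1 are edge-corrected before inversion
#' when the trial count `n` is supplied: 1 becomes `1 - 1/(2n)`, 0 becomes
#' `1/(2n)`, and 0.5 is nudged up by `1/(2n)`.
#'
#' @param pc proportion correct.
#' @param vrt variance of correct-response RTs (s^2).
#' @param mrt mean of correct-response RTs (s).
#' @param s diffusion coefficient of the reported parameters.
#' @param n number of trials behind `pc`, enabling the edge correction.
#' @return List with `v`, `a`, `t0`.
#' @export
fit_ez <- function(pc, vrt, mrt, s = 1, n = NULL) {
  if (!is.finite(vrt) || vrt <= 0) stop("vrt must be positive", call. = FALSE)
  if (pc %in% c(0, 0.5, 1)) {
    if (is.null(n))
      stop("pc of 0, 0.5 or 1 needs `n` for the edge correction", call. = FALSE)
    pc <- pc + c(`0` = 1, `0.5` = 1, `1` = -1)[[as.character(pc)]] / (2 * n)
  }
  if (pc <= 0 || pc >= 1) stop("pc must lie strictly in (0, 1)", call. = FALSE)
  # published closed form (conventional scaling), then reported at `s`
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  list(v = v, a = a, t0 = mrt - mdt)
}

#' Behavioural summaries for the EZ estimator
#'
#' @param rt vector of response times (s).
#' @param response 1 = correct, 0 = error.
#' @return List with `pc`, `vrt`, `mrt`, `n`.
#' @export
ez_summaries <- function(rt, response) {
  stopifnot(length(rt) == length(response))
  crt <- rt[response == 1]
  list(pc = mean(response == 1),
       vrt = if (length(crt) > 1) var(crt) else NA_real_,
       mrt = mean(crt), n = length(rt))
}

#' Fit the EZ-diffusion model to a set of trials
#'
#' @inheritParams ez_summaries
#' @inheritParams fit_ez
#' @return List with `v`, `a`, `t0`.
#' @export
fit_ez_trials <- function(rt, response, s = 1) {
  sm <- ez_summaries(rt, response)
  fit_ez(sm$pc, sm$vrt, sm$mrt, s = s, n = sm$n)
}
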