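#' Default generating ranges for the no-difference DDM population
#'
#' Uniform ranges for drift rate `v`, boundary separation `a`, and
#' non-decision time `t0` (seconds), on the diffusion-coefficient-1 scale.
#' @export
ddm_uniform_ranges <- function() {
  list(v = c(0, 4), a = c(0.5, 2), t0 = c(0.2, 0.5))
}

check_ranges <- function(ranges) {
  for (p in names(ranges)) {
    r <- ranges[[p]]
    if (length(r) != 2 || !is.numeric(r) || r[1] >= r[2])
      stop("invalid range for '", p, "': need numeric c(lo, hi) with lo < hi",
           call. = FALSE)
  }
  invisible(ranges)
}

new_parameter_table <- function(participant, condition, ...) {
  data.frame(participant = participant, condition = condition, ...,
             stringsAsFactors = FALSE)
}

#' Sample a no-difference parameter population
#'
#' Draws per-participant DDM parameters from independent uniform
#' distributions for the easy condition and copies them bit-identically into
#' the hard condition, so no participant has any true condition difference.
#'
#' @param n number of participants.
#' @param ranges named list of `c(lo, hi)` uniform ranges for `v`, `a`, `t0`.
#' @param seed integer seed; each participant consumes an independent child
#'   seed derived from it.
#' @return A data frame with columns `participant`, `condition`
#'   (`"easy"`/`"hard"`), `v`, `a`, `t0`; `2 * n` rows.
#' @export
sample_uniform_population <- function(n, ranges = ddm_uniform_ranges(),
                                      seed = 1L) {
  check_ranges(ranges)
  stopifnot(n >= 0)
  pars <- names(ranges)
  if (n == 0) {
    out <- new_parameter_table(integer(0), character(0))
    for (p in pars) out[[p]] <- numeric(0)
    return(out)
  }
  easy <- matrix(NA_real_, n, length(pars), dimnames = list(NULL, pars))
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i))
    for (p in pars) easy[i, p] <- runif(1, ranges[[p]][1], ranges[[p]][2])
  }
  out <- new_parameter_table(rep(seq_len(n), 2L),
                             rep(c("easy", "hard"), each = n))
  for (p in pars) out[[p]] <- c(easy[, p], easy[, p])
  out
}

#' Condition means and SDs for single-parameter manipulations
#'
#' Sampling values for the manipulated parameter when exactly one DDM
#' parameter differs between conditions: the parameter is drawn per
#' participant from a bivariate normal across conditions (correlation
#' `rho = 0.5` at the population level), with these condition means and SDs.
#'
#' @param parameter which parameter is manipulated: `"v"`, `"a"` or `"t0"`.
#' @param effect effect-size label: `"small"`, `"medium"` or `"large"`.
#' @return list with `mu_easy`, `mu_hard`, `sigma_easy`, `sigma_hard`.
#' @export
manipulation_spec <- function(parameter = c("v", "a", "t0"),
                              effect = c("small", "medium", "large")) {
  parameter <- match.arg(parameter)
  effect <- match.arg(effect)
  tab <- list(
    v  = list(sigma = 1,   mu_easy = c(small = 2.3, medium = 2.5, large = 2.8),
              mu_hard = c(small = 2.0, medium = 2.0, large = 2.0)),
    a  = list(sigma = 0.4, mu_easy = c(small = 1.25, medium = 1.25, large = 1.25),
              mu_hard = c(small = 1.37, medium = 1.45, large = 1.57)),
    t0 = list(sigma = 0.1, mu_easy = c(small = 0.350, medium = 0.350, large = 0.350),
              mu_hard = c(small = 0.385, medium = 0.400, large = 0.430))
  )[[parameter]]
  list(mu_easy = unname(tab$mu_easy[effect]),
       mu_hard = unname(tab$mu_hard[effect]),
       sigma_easy = tab$sigma, sigma_hard = tab$sigma)
}

# one positive bivariate-normal pair by rejection; whole draws are rejected
# (never truncated/clipped) so the correlation structure is preserved
rbvn_positive <- function(mu1, mu2, s1, s2, rho, max_attempts = 1000L) {
  for (k in seq_len(max_attempts)) {
    z1 <- rnorm(1); z2 <- rnorm(1)
    x1 <- mu1 + s1 * z1
    x2 <- mu2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
    if (x1 > 0 && x2 > 0) return(c(x1, x2))
  }
  stop("failed to draw a positive bivariate-normal pair within ",
       max_attempts, " attempts", call. = FALSE)
}

#' Sample a population with true condition differences
#'
#' Generates per-participant DDM parameters where one (or all three) main
#' parameters truly differ between conditions. Manipulated parameters are
#' drawn as a correlated pair across conditions (population correlation
#' `rho`), rejected and redrawn whole whenever a component is non-positive;
#' non-manipulated parameters are sampled uniformly for the easy condition
#' and copied bit-identically into the hard condition.
#'
#' @param n number of participants.
#' @param manipulated name of the manipulated parameter (ignored when
#'   `all_three = TRUE`).
#' @param effect effect-size label passed to [manipulation_spec()].
#' @param rho between-condition population correlation of each manipulated
#'   parameter.
#' @param all_three if `TRUE`, all of `v`, `a`, `t0` are manipulated
#'   (independently across parameters, each with correlation `rho` across
#'   conditions) at the given effect size.
#' @param ranges uniform ranges used for non-manipulated parameters.
#' @param seed integer seed.
#' @return A parameter table as in [sample_uniform_population()].
#' @export
sample_manipulated_population <- function(n, manipulated = c("v", "a", "t0"),
                                          effect = c("small", "medium", "large"),
                                          rho = 0.5, all_three = FALSE,
                                          ranges = ddm_uniform_ranges(),
                                          seed = 1L) {
  effect <- match.arg(effect)
  check_ranges(ranges)
  stopifnot(n >= 0, rho >= -1, rho <= 1)
  pars <- c("v", "a", "t0")
  which_manip <- if (all_three) pars else match.arg(manipulated)
  easy <- matrix(NA_real_, n, 3, dimnames = list(NULL, pars))
  hard <- easy
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i))
    for (p in pars) {
      if (p %in% which_manip) {
        ms <- manipulation_spec(p, effect)
        xy <- rbvn_positive(ms$mu_easy, ms$mu_hard, ms$sigma_easy,
                            ms$sigma_hard, rho)
        easy[i, p] <- xy[1]; hard[i, p] <- xy[2]
      } else {
        easy[i, p] <- runif(1, ranges[[p]][1], ranges[[p]][2])
        hard[i, p] <- easy[i, p]
      }
    }
  }
  out <- new_parameter_table(rep(seq_len(n), 2L),
                             rep(c("easy", "hard"), each = n))
  for (p in pars) out[[p]] <- c(easy[, p], hard[, p])
  out
}

#' Sample a population with truly correlated difference scores
#'
#' Easy-condition parameters are sampled as in
#' [sample_uniform_population()]. The hard condition keeps the same drift
#' rate, while boundary separation and non-decision time receive additive
#' difference scores drawn from a bivariate normal with mean zero, the given
#' SDs, and population correlation `rho_diff`. So both population mean
#' differences are zero, yet individual differences in `a` and `t0` changes
#' are truly correlated. Draws whose resulting hard-condition `a` or `t0`
#' would be non-positive are regenerated whole (bounded attempts).
#'
#' @param n number of participants.
#' @param rho_diff population correlation between the `a` and `t0`
#'   difference scores.
#' @param sd_a_diff,sd_t0_diff SDs of the two difference scores.
#' @param ranges easy-condition uniform ranges.
#' @param seed integer seed.
#' @return A parameter table as in [sample_uniform_population()].
#' @export
sample_diffcorr_population <- function(n, rho_diff, sd_a_diff = 0.1,
                                       sd_t0_diff = 0.05,
                                       ranges = ddm_uniform_ranges(),
                                       seed = 1L) {
  check_ranges(ranges)
  stopifnot(n >= 0, rho_diff >= -1, rho_diff <= 1,
            sd_a_diff > 0, sd_t0_diff > 0)
  easy <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("v", "a", "t0")))
  hard <- easy
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i))
    v <- runif(1, ranges$v[1], ranges$v[2])
    a <- runif(1, ranges$a[1], ranges$a[2])
    t0 <- runif(1, ranges$t0[1], ranges$t0[2])
    ok <- FALSE
    for (k in 1:1000) {
      z1 <- rnorm(1); z2 <- rnorm(1)
      a_diff <- sd_a_diff * z1
      t0_diff <- sd_t0_diff * (rho_diff * z1 + sqrt(1 - rho_diff^2) * z2)
      if (a + a_diff > 0 && t0 + t0_diff >= 0) { ok <- TRUE; break }
    }
    if (!ok) stop("could not generate positive hard-condition parameters for ",
                  "participant ", i, call. = FALSE)
    easy[i, ] <- c(v, a, t0)
    hard[i, ] <- c(v, a + a_diff, t0 + t0_diff)
  }
  out <- new_parameter_table(rep(seq_len(n), 2L),
                             rep(c("easy", "hard"), each = n))
  for (p in colnames(easy)) out[[p]] <- c(easy[, p], hard[, p])
  out
}

#' Sample a no-difference LBA parameter population
#'
#' Per-participant LBA parameters drawn from uniform ranges — mean correct
#' drift `v` in `[1, 4]`, start-point range `A` in `[0.5, 2]`, threshold `b`
#' in `[A + 0.001, 2]` (drawn after `A`), non-decision time `t0` in
#' `[0.2, 0.5]` s — with the hard condition a bit-identical copy of the easy
#' condition.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @return Data frame with columns `participant`, `condition`, `v`, `A`,
#'   `b`, `t0`.
#' @export
sample_lba_uniform_population <- function(n, seed = 1L) {
  stopifnot(n >= 0)
  easy <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("v", "A", "b", "t0")))
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, i))
    v <- runif(1, 1, 4)
    A <- runif(1, 0.5, 2)
    while (A + 0.001 >= 2) A <- runif(1, 0.5, 2) # keep the b interval non-empty
    b <- runif(1, A + 0.001, 2)
    t0 <- runif(1, 0.2, 0.5)
    easy[i, ] <- c(v, A, b, t0)
  }
  out <- new_parameter_table(rep(seq_len(n), 2L),
                             rep(c("easy", "hard"), each = n))
  for (p in colnames(easy)) out[[p]] <- c(easy[, p], easy[, p])
  out
}
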