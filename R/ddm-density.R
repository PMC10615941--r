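#' Wiener first-passage-time density
#'
#' Defective density of absorption at one boundary of a Wiener diffusion at
#' decision time `t` (seconds, excluding non-decision time). Evaluated by a
#' dual series expansion — a small-time reflection series and a large-time
#' spectral series — with an automatic per-`t` crossover rule, truncated to
#' absolute error `eps`. The upper boundary codes the correct response
#' throughout the package.
#'
#' Integrated over `t` in `(0, Inf)`, the upper and lower densities sum to 1;
#' each alone integrates to that boundary's choice probability
#' ([ddm_prob_upper()]).
#'
#' @param t decision time(s) in seconds; non-positive values return 0.
#' @param v drift rate.
#' @param a boundary separation (> 0).
#' @param zr relative starting point in (0, 1); 0.5 is unbiased.
#' @param bound `"upper"` (correct) or `"lower"` (error).
#' @param s diffusion coefficient (scaling constant, default 1).
#' @param eps absolute truncation error of the series.
#' @return Vector of densities (1/s), same length as `t`.
#' @export
wiener_fpt_density <- function(t, v, a, zr = 0.5, bound = c("upper", "lower"),
                               s = 1, eps = 1e-7) {
  bound <- match.arg(bound)
  stopifnot(a > 0, zr > 0, zr < 1, s > 0)
  # rescale to diffusion coefficient 1
  wiener_density_cpp(as.numeric(t), v / s, a / s, zr, bound == "upper", eps)
}

#' Probability of absorption at the upper (correct) boundary
#'
#' Closed-form choice probability of a Wiener diffusion with drift `v`,
#' separation `a`, relative start `zr` and diffusion coefficient `s`.
#'
#' @inheritParams wiener_fpt_density
#' @return Probability in \[0, 1\].
#' @export
ddm_prob_upper <- function(v, a, zr = 0.5, s = 1) {
  stopifnot(a > 0, zr > 0, zr < 1, s > 0)
  v <- v / s; a <- a / s
  z <- zr * a
  out <- ifelse(abs(v) < 1e-10, zr,
                (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a)))
  pmin(pmax(out, 0), 1)
}

# mean decision time, z = a/2 start (used in tests and EZ cross-checks):
# a/(2v) * tanh(v a / (2 s^2)); v -> 0 limit z(a - z)/s^2
ddm_mean_dt <- function(v, a, s = 1) {
  ifelse(abs(v) < 1e-8, (a / 2) * (a / 2) / s^2,
         a / (2 * v) * tanh(v * a / (2 * s^2)))
}
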