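# Independent reference implementations used only as test oracles.

# Wiener lower-bound first-passage density by brute-force reflection sum:
# a single series with a fixed, generous number of image terms, independent
# of the package's dual-series truncation logic.
oracle_wiener_lower <- function(t, v, a, w, kmax = 100) {
  sapply(t, function(tt) {
    if (tt <= 0) return(0)
    u <- tt / a^2
    k <- -kmax:kmax
    q <- w + 2 * k
    s <- sum(q * exp(-q^2 / (2 * u)))
    exp(-v * a * w - v^2 * tt / 2) / a^2 * s / sqrt(2 * pi * u^3)
  })
}

oracle_wiener <- function(t, v, a, w, bound) {
  if (bound == "upper") oracle_wiener_lower(t, -v, a, 1 - w)
  else oracle_wiener_lower(t, v, a, w)
}

# textbook Pearson correlation, written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# defective-density CDF of the correct response by quadrature
oracle_lba_cdf_correct <- function(tq, v, A, b, s) {
  v_err <- 1 - v
  pnone <- pnorm(-v / s) * pnorm(-v_err / s)
  f <- function(t)
    diffscoresim:::lba_pdf_acc(t, v, A, b, s) *
      (1 - diffscoresim:::lba_cdf_acc(t, v_err, A, b, s)) / (1 - pnone)
  sapply(tq, function(q) integrate(f, 0, q, rel.tol = 1e-8)$value)
}
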