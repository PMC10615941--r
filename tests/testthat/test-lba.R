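test_that("caution is b - A/2 and validates its inputs", {
  expect_equal(compute_caution(1.0, 1.5), 1.0)
  expect_equal(compute_caution(1e-9, 2), 2, tolerance = 1e-6)
  expect_error(compute_caution(1.5, 1.0), "b > A")
  p <- sample_lba_uniform_population(100, seed = 3)
  expect_equal(compute_caution(p$A, p$b), p$b - p$A / 2)
})

test_that("single-accumulator density normalizes with the never-finish mass", {
  for (g in list(c(2, 1, 1.5), c(1, 0.5, 1.9), c(-1, 1, 1.2))) {
    v <- g[1]; A <- g[2]; b <- g[3]; s <- 0.3
    i <- integrate(function(t) diffscoresim:::lba_pdf_acc(t, v, A, b, s),
                   0, Inf, rel.tol = 1e-9)$value
    expect_equal(i + pnorm(-v / s), 1, tolerance = 1e-6)
  }
})

test_that("defective densities of both responses jointly normalize", {
  v <- 2.2; A <- 1; b <- 1.6; s <- 0.3
  v_err <- 1 - v
  pnone <- pnorm(-v / s) * pnorm(-v_err / s)
  f <- function(t, w, l)
    diffscoresim:::lba_pdf_acc(t, w, A, b, s) *
      (1 - diffscoresim:::lba_cdf_acc(t, l, A, b, s))
  tot <- integrate(function(t) f(t, v, v_err), 0, Inf)$value +
    integrate(function(t) f(t, v_err, v), 0, Inf)$value
  expect_equal(tot / (1 - pnone), 1, tolerance = 1e-4)
})

test_that("simulated LBA data match the defective-density distribution", {
  v <- 2; A <- 1; b <- 1.5; t0 <- 0.3; s <- 0.3
  tr <- simulate_lba_trials(v, A, b, t0, 50000, s = s, seed = 19)
  # choice probability
  p_correct_num <- integrate(function(t)
    diffscoresim:::lba_pdf_acc(t, v, A, b, s) *
      (1 - diffscoresim:::lba_cdf_acc(t, 1 - v, A, b, s)) /
      (1 - pnorm(-v / s) * pnorm(-(1 - v) / s)), 0, Inf)$value
  expect_lt(abs(mean(tr$response) - p_correct_num), 3 * 0.5 / sqrt(50000))
  # RT distribution of correct responses (KS against quadrature CDF)
  dt <- sort(tr$rt[tr$response == 1] - t0)
  qs <- quantile(dt, seq(0.05, 0.95, 0.05))
  emp <- seq(0.05, 0.95, 0.05)
  theo <- oracle_lba_cdf_correct(qs, v, A, b, s) / p_correct_num
  expect_lt(max(abs(theo - emp)), 0.01)
})

test_that("accuracy increases with correct-accumulator drift", {
  acc <- sapply(1:4, function(v)
    mean(simulate_lba_trials(v, 1, 1.5, 0.3, 10000, seed = 100 + v)$response))
  expect_true(all(diff(acc) >= 0))
  expect_gt(mean(simulate_lba_trials(4, 0.5, 1.5, 0.3, 10000,
                                     seed = 9)$response), 0.95)
})

test_that("degenerate start-point range pins finishing times to b/drift", {
  # with A = 0 and the error accumulator effectively never positive,
  # b/(rt - t0) recovers the winning drift draws ~ N(v, s) | > 0
  v <- 4; b <- 1.5; t0 <- 0.3; s <- 0.3
  tr <- simulate_lba_trials(v, 0, b, t0, 20000, s = s, seed = 8)
  drifts <- b / (tr$rt - t0)
  expect_lt(abs(mean(drifts) - v), 3 * s / sqrt(20000) + 0.01)
  expect_lt(abs(sd(drifts) - s), 0.01)
})

test_that("LBA log-likelihood sums independently computed log densities", {
  rt <- c(0.6, 0.8, 0.55); resp <- c(1L, 0L, 1L)
  v <- 2; A <- 1; b <- 1.5; t0 <- 0.3; s <- 0.3
  pnone <- pnorm(-v / s) * pnorm(-(1 - v) / s)
  dens <- sapply(seq_along(rt), function(i) {
    w <- if (resp[i] == 1) v else 1 - v
    l <- if (resp[i] == 1) 1 - v else v
    diffscoresim:::lba_pdf_acc(rt[i] - t0, w, A, b, s) *
      (1 - diffscoresim:::lba_cdf_acc(rt[i] - t0, l, A, b, s)) / (1 - pnone)
  })
  expect_equal(lba_loglik(rt, resp, v, A, b, t0),
               sum(log(pmax(dens, 1e-10))))
  expect_equal(lba_loglik(numeric(0), integer(0), v, A, b, t0), 0)
  # rt at or below t0 contributes the floor
  expect_equal(lba_loglik(0.2, 1L, v, A, b, t0), log(1e-10))
})

test_that("starting heuristics follow the stated rules", {
  rt <- c(0.50, 0.7, 0.9, 1.1)
  h <- lba_start_heuristics(rt, c(1L, 1L, 0L, 1L))
  expect_equal(h$t0, 0.45)
  expect_equal(h$A, 2 * IQR(rt))
  expect_equal(h$b, 1.25 * h$A)
  expect_equal(h$v, 0.5 + qnorm(0.75, 0, 0.3))
})

test_that("LBA fitting recovers caution from a large sample", {
  tr <- simulate_lba_trials(2.5, 1, 1.5, 0.3, 10000, seed = 44)
  set.seed(5)
  f <- fit_lba_ml(tr$rt, tr$response)
  expect_true(f$converged)
  expect_lt(abs(f$caution - compute_caution(1, 1.5)) / 1, 0.10)
  expect_equal(f$caution, f$b - f$A / 2)
})
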