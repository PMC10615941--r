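test_that("log-likelihood is the term-by-term sum of log densities", {
  rt <- c(0.45, 0.6, 0.38, 0.9, 0.52)
  resp <- c(1L, 1L, 0L, 1L, 0L)
  v <- 1.2; a <- 1.1; t0 <- 0.2
  by_hand <- sum(log(pmax(
    sapply(seq_along(rt), function(i)
      oracle_wiener(rt[i] - t0, v, a, 0.5,
                    if (resp[i] == 1) "upper" else "lower")),
    1e-10)))
  expect_equal(ddm_loglik(rt, resp, v, a, t0), by_hand, tolerance = 1e-6)
  expect_equal(ddm_loglik(numeric(0), integer(0), v, a, t0), 0)
})

test_that("trials faster than t0 hit the density floor, not an error", {
  ll <- ddm_loglik(c(0.1, 0.6), c(1L, 1L), 2, 1, 0.3)
  expect_true(is.finite(ll))
  expect_equal(ll - ddm_loglik(0.6, 1L, 2, 1, 0.3), log(1e-10))
})

test_that("true parameters beat perturbed parameters on large samples", {
  tr <- simulate_ddm_trials(2, 1, 0.3, 10000, seed = 21)
  ll_true <- ddm_loglik(tr$rt, tr$response, 2, 1, 0.3)
  ll_pert <- ddm_loglik(tr$rt, tr$response, 2, 1.2, 0.3)
  expect_gt(ll_true, ll_pert)
})

test_that("ML recovers generating parameters from one large sample", {
  tr <- simulate_ddm_trials(2, 1, 0.3, 10000, seed = 22)
  set.seed(1)
  f <- fit_ddm_ml(tr$rt, tr$response)
  expect_true(f$converged)
  expect_lt(abs(f$v - 2) / 2, 0.05)
  expect_lt(abs(f$a - 1) / 1, 0.05)
  expect_lt(abs(f$t0 - 0.3) / 0.3, 0.05)
})

test_that("ML recovery is accurate across random parameter sets", {
  set.seed(33)
  errs <- replicate(12, {
    v <- runif(1, 0.5, 3.5); a <- runif(1, 0.6, 1.8); t0 <- runif(1, 0.2, 0.5)
    tr <- simulate_ddm_trials(v, a, t0, 3000,
                              seed = sample.int(1e6, 1))
    f <- fit_ddm_ml(tr$rt, tr$response)
    abs(c(f$v - v, f$a - a, f$t0 - t0)) / c(v, a, t0)
  })
  expect_lt(median(errs[1, ]), 0.03)
  expect_lt(median(errs[2, ]), 0.03)
  expect_lt(median(errs[3, ]), 0.03)
})

test_that("EZ inverts forward-simulated summaries and agrees with ML", {
  tr <- simulate_ddm_trials(2, 1, 0.3, 100000, seed = 23)
  ez <- fit_ez_trials(tr$rt, tr$response)
  expect_lt(abs(ez$v - 2) / 2, 0.05)
  expect_lt(abs(ez$a - 1) / 1, 0.05)
  expect_lt(abs(ez$t0 - 0.3) / 0.3, 0.05)
  set.seed(2)
  ml <- fit_ddm_ml(tr$rt[1:20000], tr$response[1:20000])
  expect_lt(abs(ez$v - ml$v) / ml$v, 0.1)
  expect_lt(abs(ez$a - ml$a) / ml$a, 0.1)
  expect_lt(abs(ez$t0 - ml$t0) / ml$t0, 0.1)
})

test_that("EZ edge-corrects degenerate accuracies and rejects bad variance", {
  f <- fit_ez(1, 0.02, 0.5, n = 500)
  g <- fit_ez(1 - 1 / 1000, 0.02, 0.5)
  expect_equal(f, g)
  expect_true(all(is.finite(unlist(f))))
  expect_error(fit_ez(0.8, -0.01, 0.5), "vrt")
  expect_error(fit_ez(0.5, 0.02, 0.5), "edge correction")
})

test_that("shared-parameter fits are properly nested", {
  tr <- rbind(
    simulate_ddm_trials(2, 1, 0.3, 400, seed = 41, condition = "easy"),
    simulate_ddm_trials(2, 1, 0.3, 400, seed = 42, condition = "hard"))
  set.seed(3)
  free <- fit_ddm_conditions(tr)
  set.seed(3)
  shared_v <- fit_ddm_conditions(tr, share = "v",
                                 extra_starts = list(
                                   with(free$params,
                                        c(v[1], v[2], a[1], a[2], t0[1], t0[2]))))
  set.seed(3)
  all_shared <- fit_ddm_conditions(tr, share = c("v", "a", "t0"))
  expect_equal(free$n_free, 6L)
  expect_equal(shared_v$n_free, 5L)
  expect_equal(all_shared$n_free, 3L)
  # constraint semantics: one drift value for both conditions
  expect_equal(shared_v$params$v[1], shared_v$params$v[2])
  # nested likelihood dominance
  expect_lte(all_shared$loglik, shared_v$loglik + 1e-6)
  expect_lte(shared_v$loglik, free$loglik + 1e-6)
})

test_that("unconstrained joint fitting separates into per-condition fits", {
  tr <- rbind(
    simulate_ddm_trials(1.5, 1.2, 0.25, 300, seed = 51, condition = "easy"),
    simulate_ddm_trials(1.5, 1.2, 0.25, 300, seed = 52, condition = "hard"))
  set.seed(4)
  joint <- fit_ddm_conditions(tr)
  e <- tr[tr$condition == "easy", ]
  set.seed(4)
  fe <- fit_ddm_ml(e$rt, e$response)
  expect_equal(joint$params$v[1], fe$v)
  expect_equal(joint$loglik_by_condition[["easy"]], fe$loglik)
})
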