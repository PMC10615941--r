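tiny <- function(...) study_config(n_participants = 5, n_trials = 60, ...)

test_that("study configuration validates and carries its settings", {
  cfg <- tiny("sim2", manipulated = "a", effect = "large", seed = 99)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$n_participants, 5L)
  expect_equal(cfg$manipulated, "a")
  expect_error(study_config("sim3"), "arg")
  expect_error(study_config(n_participants = 1), "n_participants")
})

test_that("a full study run is bit-reproducible under a fixed seed", {
  cfg <- tiny("sim1", seed = 7)
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(s1$fitted, s2$fitted)
  expect_identical(unclass(s1$corr), unclass(s2$corr))
  expect_identical(s1$key_correlation, s2$key_correlation)
  # a different seed gives different data
  s3 <- run_study(tiny("sim1", seed = 8))
  expect_false(identical(s1$fitted$a, s3$fitted$a))
})

test_that("study results contain coherent pieces", {
  s <- run_study(tiny("sim1", seed = 3, keep_trials = TRUE))
  expect_s3_class(s, "diffscore_study")
  expect_equal(nrow(s$fitted), 10) # 5 participants x 2 conditions
  expect_equal(nrow(s$trials), 5 * 2 * 60)
  expect_equal(dim(unclass(s$corr)), c(9, 9))
  expect_equal(s$key_pair, c("a_diff", "t0_diff"))
  expect_equal(s$key_correlation,
               unclass(s$corr)["a_diff", "t0_diff"])
  expect_true(all(c("mean_rt", "accuracy") %in% names(s$behaviour)))
  out <- capture.output(print(s))
  expect_true(any(grepl("a_diff", out)))
})

test_that("the EZ fitter variant runs the same pipeline", {
  s <- run_study(tiny("sim1", fitter = "ez", seed = 4))
  expect_true(all(s$fitted$converged))
  expect_equal(nrow(s$fitted), 10)
})

test_that("the constrained-drift study fits one drift per participant", {
  s <- run_study(tiny("constrained_v", seed = 5, keep_trials = TRUE))
  v <- tapply(s$fitted$v, s$fitted$participant, function(x) diff(range(x)))
  expect_true(all(v == 0))
  # the reported matrix collapses the shared drift to one column
  expect_equal(dim(unclass(s$corr)), c(7, 7))
  expect_true("v" %in% rownames(s$corr))
  expect_false("v_diff" %in% rownames(s$corr))
  # shared-v likelihood cannot beat the free fit on the same trials
  free <- fit_ddm_population(s$trials)
  ll_shared <- tapply(s$fitted$loglik, s$fitted$participant, sum)
  ll_free <- tapply(free$loglik, free$participant, sum)
  expect_true(all(ll_shared <= ll_free + 1e-6))
})

test_that("the LBA study reports the caution difference pair", {
  s <- run_study(tiny("sim4_lba", seed = 6))
  expect_equal(s$key_pair, c("caution_diff", "t0_diff"))
  expect_true(all(c("caution_easy", "caution_diff") %in% rownames(s$corr)))
})

test_that("the competition study returns the eight-model table", {
  s <- run_study(study_config("competition", n_participants = 3,
                              n_trials = 80, seed = 7))
  expect_s3_class(s$ic_table, "model_ic_table")
  expect_equal(nrow(s$ic_table), 8)
  expect_null(s$corr)
})

test_that("recovery correlations line up generating and fitted values", {
  s <- run_study(study_config("sim1", n_participants = 25, n_trials = 150,
                              seed = 8))
  r <- recovery_correlations(s)
  expect_equal(names(r), c("v_easy", "a_easy", "t0_easy",
                           "v_hard", "a_hard", "t0_hard"))
  expect_true(all(r > 0.8)) # loose sanity bound at this tiny scale
})

test_that("output files are written and the YAML round trip works", {
  dir <- tempfile("study_out")
  s <- run_study(study_config("sim1", n_participants = 4, n_trials = 50,
                              seed = 9, out_dir = dir, save_trials = TRUE))
  for (f in c("sim1_generating_params.csv", "sim1_behaviour.csv",
              "sim1_fitted_params.csv", "sim1_correlations.csv",
              "sim1_trials.csv", "sim1_correlations.png"))
    expect_true(file.exists(file.path(dir, f)))
  fit <- read.csv(file.path(dir, "sim1_fitted_params.csv"))
  expect_equal(nrow(fit), 8)
  expect_true(all(c("seed", "config_hash") %in% names(fit)))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("study: sim2", "n_participants: 5", "n_trials: 60",
               "manipulated: t0", "effect: medium", "seed: 11"), yml)
  cfg <- read_study_config(yml)
  expect_equal(cfg$study, "sim2")
  expect_equal(cfg$manipulated, "t0")
  expect_equal(cfg$seed, 11L)
  unlink(dir, recursive = TRUE); unlink(yml)
})
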