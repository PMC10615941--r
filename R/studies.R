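#' Configure a simulation study
#'
#' Assembles and validates the settings for one end-to-end study run. The
#' default participant and trial counts (1000 x 1000) are the full-scale
#' study conditions; desk-scale runs lower them via the arguments.
#'
#' @param study one of `"sim1"` (no true differences, DDM), `"sim2"` (one
#'   parameter truly differs), `"sim2_all"` (all three differ),
#'   `"sim4_lba"` (no true differences, LBA), `"sim5"` (truly correlated
#'   difference scores), `"constrained_v"` (no true differences, drift
#'   shared during fitting), `"competition"` (eight-model family on
#'   no-difference data).
#' @param n_participants,n_trials design size (trials are per condition).
#' @param fitter `"ml"` or `"ez"` (DDM studies only).
#' @param manipulated,effect for `"sim2"`/`"sim2_all"`: the manipulated
#'   parameter and effect-size label (see [manipulation_spec()]).
#' @param rho_diff for `"sim5"`: generating correlation between the `a` and
#'   `t0` difference scores.
#' @param seed integer seed governing every random stage.
#' @param out_dir optional directory; when set, [run_study()] writes CSV
#'   tables and a heatmap there.
#' @param save_trials also write the (large) trial table.
#' @param keep_trials also return the trial table in the result (memory
#'   permitting), e.g. to refit the same data with another estimator.
#' @param sim_method DDM simulator method (see [simulate_ddm_trials()]).
#' @param lba_s LBA trial-to-trial drift SD used for generation and
#'   fitting.
#' @return Object of class `study_config`.
#' @export
study_config <- function(study = c("sim1", "sim2", "sim2_all", "sim4_lba",
                                   "sim5", "constrained_v", "competition"),
                         n_participants = 1000L, n_trials = 1000L,
                         fitter = c("ml", "ez"), manipulated = "v",
                         effect = "small", rho_diff = -0.7, seed = 1L,
                         out_dir = NULL, save_trials = FALSE,
                         keep_trials = FALSE,
                         sim_method = "inverse_cdf", lba_s = 0.3) {
  study <- match.arg(study)
  fitter <- match.arg(fitter)
  stopifnot(n_participants >= 3, n_trials >= 2, is.numeric(seed))
  structure(list(study = study, n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), fitter = fitter,
                 manipulated = manipulated, effect = effect,
                 rho_diff = rho_diff, seed = as.integer(seed),
                 out_dir = out_dir, save_trials = isTRUE(save_trials),
                 keep_trials = isTRUE(keep_trials),
                 sim_method = sim_method, lba_s = lba_s),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [study_config()].
#' @return Object of class `study_config`.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

behaviour_summary <- function(trials) {
  do.call(rbind, lapply(split(trials, trials$condition), function(d)
    data.frame(condition = d$condition[1], mean_rt = mean(d$rt),
               sd_rt = sd(d$rt), accuracy = 100 * mean(d$response == 1),
               stringsAsFactors = FALSE)))
}

generate_population <- function(config) {
  n <- config$n_participants; seed <- config$seed
  switch(config$study,
         sim1 = ,
         constrained_v = ,
         competition = sample_uniform_population(n, seed = seed),
         sim2 = sample_manipulated_population(n, config$manipulated,
                                              config$effect, seed = seed),
         sim2_all = sample_manipulated_population(n, effect = config$effect,
                                                  all_three = TRUE,
                                                  seed = seed),
         sim4_lba = sample_lba_uniform_population(n, seed = seed),
         sim5 = sample_diffcorr_population(n, config$rho_diff, seed = seed))
}

#' Run a simulation study end to end
#'
#' Generates the parameter population for the configured design, simulates
#' the trials, fits the model (`ml` or `ez` for DDM studies; LBA for
#' `sim4_lba`; the eight-model family for `competition`), computes
#' difference scores and the parameter correlation matrix, and applies the
#' |z| > 2.5 outlier-filtered correlation to the key difference-score pair.
#' With `out_dir` set, all tables are written as CSV (stamped with the seed
#' and a config hash) plus a correlation heatmap.
#'
#' @param config a [study_config()] object.
#' @return Object of class `diffscore_study` with elements `config`,
#'   `generating` (parameter table), `fitted`, `behaviour`, `corr`,
#'   `key_correlation`, `key_correlation_filtered`, `n_unconverged`; for
#'   `"competition"`, `ic_table` instead of the correlation elements.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  gen <- generate_population(config)

  if (config$study == "sim4_lba") {
    trials <- simulate_lba_population(gen, config$n_trials,
                                      seed = config$seed, s = config$lba_s)
  } else {
    trials <- simulate_ddm_population(gen, config$n_trials,
                                      seed = config$seed,
                                      method = config$sim_method)
  }
  behaviour <- behaviour_summary(trials)
  set.seed(child_seed(config$seed, 0L, stream = 9L)) # fitting-stage RNG

  if (config$study == "competition") {
    ic <- fit_model_family(trials)
    res <- list(config = config, generating = gen, behaviour = behaviour,
                ic_table = ic,
                trials = if (config$keep_trials) trials,
                n_unconverged = attr(ic, "n_excluded"))
    class(res) <- "diffscore_study"
    write_study_outputs(res, trials)
    return(res)
  }

  if (config$study == "sim4_lba") {
    fits <- fit_lba_population(trials, s = config$lba_s)
    params <- c("caution", "v", "t0")
    fits_for_corr <- fits[, c("participant", "condition", "caution", "v",
                              "t0", "loglik", "converged")]
    key <- c("caution_diff", "t0_diff")
  } else if (config$study == "constrained_v") {
    fits <- fit_ddm_population(trials, fitter = "ml", share = "v")
    params <- c("a", "v", "t0")
    fits_for_corr <- fits
    key <- c("a_diff", "t0_diff")
  } else {
    fits <- fit_ddm_population(trials, fitter = config$fitter)
    params <- c("a", "v", "t0")
    fits_for_corr <- fits
    key <- c("a_diff", "t0_diff")
  }

  corr <- withCallingHandlers(
    correlation_matrix(fits_for_corr, params = params),
    warning = function(w) {
      # with drift shared, v_diff is identically zero by construction;
      # that expected zero-variance warning is noise here
      if (config$study == "constrained_v" &&
          identical(conditionMessage(w), paste0(
            "zero-variance column(s): v_diff; ",
            "their correlations are undefined (NA)")))
        invokeRestart("muffleWarning")
    })
  m <- parameter_matrix(fits_for_corr, params)
  keyr <- unclass(corr)[key[1], key[2]]
  keyf <- outlier_filtered_correlation(m[, key[1]], m[, key[2]])
  if (config$study == "constrained_v") {
    # with drift shared, the informative matrix is the 7-column one
    keep <- setdiff(colnames(corr), c("v_hard", "v_diff"))
    corr7 <- unclass(corr)[keep, keep]
    colnames(corr7)[colnames(corr7) == "v_easy"] <- "v"
    rownames(corr7)[rownames(corr7) == "v_easy"] <- "v"
    corr <- structure(corr7, n = attr(corr, "n"),
                      n_excluded = attr(corr, "n_excluded"),
                      class = c("diffscore_corr", "matrix"))
  }
  res <- list(config = config, generating = gen, fitted = fits,
              behaviour = behaviour, corr = corr,
              key_pair = key, key_correlation = keyr,
              key_correlation_filtered = keyf,
              trials = if (config$keep_trials) trials,
              n_unconverged = sum(!fits$converged))
  class(res) <- "diffscore_study"
  write_study_outputs(res, trials)
  res
}

#' Run the shared-drift (constrained v) study
#'
#' Convenience wrapper: no-difference generation as in the base design, but
#' the fit constrains drift rate to a single value across conditions while
#' `a` and `t0` stay free.
#'
#' @inheritParams run_study
#' @return As [run_study()].
#' @export
run_constrained_v_study <- function(config) {
  config$study <- "constrained_v"
  run_study(config)
}

#' Generating-vs-recovered correlations of a fitted study
#'
#' Pearson correlation between the data-generating parameter values and the
#' fitted estimates, per parameter per condition — the standard parameter
#' recovery readout.
#'
#' @param study a `diffscore_study` result with both `generating` and
#'   `fitted` tables.
#' @param params parameter columns to correlate.
#' @return Named vector of six correlations (`<param>_<condition>`).
#' @export
recovery_correlations <- function(study, params = c("v", "a", "t0")) {
  gen <- study$generating; fit <- study$fitted
  out <- c()
  for (cc in c("easy", "hard")) {
    g <- gen[gen$condition == cc, ]
    f <- fit[fit$condition == cc & fit$converged, ]
    g <- g[match(f$participant, g$participant), ]
    for (p in params)
      out[paste0(p, "_", cc)] <- cor(g[[p]], f[[p]])
  }
  out
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(config)[setdiff(names(config), "out_dir")], file = f)
  unname(tools::md5sum(f))
}

write_study_outputs <- function(res, trials) {
  dir <- res$config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- data.frame(seed = res$config$seed, config_hash = config_hash(res$config))
  pre <- file.path(dir, res$config$study)
  write.csv(cbind(res$generating, stamp), paste0(pre, "_generating_params.csv"),
            row.names = FALSE)
  write.csv(cbind(res$behaviour, stamp), paste0(pre, "_behaviour.csv"),
            row.names = FALSE)
  if (!is.null(res$fitted))
    write.csv(cbind(res$fitted, stamp), paste0(pre, "_fitted_params.csv"),
              row.names = FALSE)
  if (!is.null(res$corr)) {
    write.csv(data.frame(parameter = rownames(res$corr),
                         unclass(res$corr), check.names = FALSE),
              paste0(pre, "_correlations.csv"), row.names = FALSE)
    g <- plot_correlation_matrix(res$corr)
    ggplot2::ggsave(paste0(pre, "_correlations.png"), g,
                    width = 7, height = 6, dpi = 150)
  }
  if (!is.null(res$ic_table))
    write.csv(cbind(as.data.frame(res$ic_table), stamp),
              paste0(pre, "_model_competition.csv"), row.names = FALSE)
  if (res$config$save_trials)
    write.csv(trials, paste0(pre, "_trials.csv"), row.names = FALSE)
  invisible(NULL)
}

#' @export
print.diffscore_study <- function(x, ...) {
  cat("Study:", x$config$study, "| participants:",
      x$config$n_participants, "| trials/condition:", x$config$n_trials,
      "| seed:", x$config$seed, "\n")
  cat("\nBehaviour:\n"); print(x$behaviour, row.names = FALSE)
  if (!is.null(x$corr)) {
    cat("\n"); print(x$corr)
    cat("\nKey pair ", x$key_pair[1], " vs ", x$key_pair[2], ": r = ",
        round(x$key_correlation, 3), " (outlier-filtered r = ",
        round(x$key_correlation_filtered$r, 3), ", ",
        x$key_correlation_filtered$n_removed, " removed)\n", sep = "")
  }
  if (!is.null(x$ic_table)) { cat("\n"); print(x$ic_table) }
  if (isTRUE(x$n_unconverged > 0))
    cat("Unconverged fits:", x$n_unconverged, "\n")
  invisible(x)
}
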