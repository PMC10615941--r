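#' The eight-model sharing-pattern family
#'
#' Every combination of letting drift rate, boundary separation and
#' non-decision time vary (or not) across the two conditions. Model 1 holds
#' all three fixed across conditions (3 free parameters per participant);
#' Model 8 frees all three (6 free parameters).
#'
#' @return Data frame with columns `model`, `vary_v`, `vary_a`, `vary_t0`,
#'   `n_free`.
#' @export
enumerate_model_family <- function() {
  flags <- rbind(
    c(FALSE, FALSE, FALSE),
    c(TRUE,  FALSE, FALSE),
    c(FALSE, TRUE,  FALSE),
    c(FALSE, FALSE, TRUE),
    c(FALSE, TRUE,  TRUE),
    c(TRUE,  FALSE, TRUE),
    c(TRUE,  TRUE,  FALSE),
    c(TRUE,  TRUE,  TRUE))
  data.frame(model = 1:8, vary_v = flags[, 1], vary_a = flags[, 2],
             vary_t0 = flags[, 3], n_free = 3L + rowSums(flags))
}

#' Akaike weights from information-criterion values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = IC_i - min(IC)`; identical for AIC and BIC inputs. The
#' weights are invariant to adding any constant to all ICs. Non-finite ICs
#' are excluded (their weight is `NA`) with a warning.
#'
#' @param ic numeric vector of AIC or BIC values, one per model.
#' @return Vector of weights summing to 1 over the finite entries.
#' @export
akaike_weights <- function(ic) {
  stopifnot(length(ic) >= 1)
  fin <- is.finite(ic)
  if (!any(fin)) stop("no finite information-criterion values", call. = FALSE)
  if (!all(fin)) warning("non-finite IC values excluded from the weights")
  w <- rep(NA_real_, length(ic))
  d <- ic[fin] - min(ic[fin])
  w[fin] <- exp(-d / 2) / sum(exp(-d / 2))
  w
}

#' Fit the eight-model family and rank it by summed AIC/BIC
#'
#' Every model is fitted per participant under its sharing constraint
#' (shared parameters estimated from the single pooled two-condition
#' likelihood), then log-likelihood, `AIC = 2k - 2LL`, and
#' `BIC = k log(n) - 2LL` (with `n` the participant's total trial count
#' over both conditions) are summed across participants. Akaike weights
#' are computed from the summed AIC and summed BIC. A participant with any
#' unconverged model fit is excluded from every model's sums, keeping the
#' comparison balanced.
#'
#' To keep the family's nesting structure numerically honest, richer models
#' receive the solutions of the models nested inside them as extra starting
#' points, so a model's fitted likelihood never falls below that of a model
#' it nests.
#'
#' @param trials trial table (`participant`, `condition`, `rt`,
#'   `response`) with both conditions per participant.
#' @param zr,s DDM fixed settings.
#' @param per_participant if `TRUE`, also return the per-participant,
#'   per-model IC table (group-level selection remains the default
#'   reading).
#' @return Object of class `model_ic_table`: data frame with `model`,
#'   `vary_v`, `vary_a`, `vary_t0`, `n_free`, `LL`, `AIC`, `BIC`, `w_AIC`,
#'   `w_BIC`, `winner_AIC`, `winner_BIC`; attributes `n_participants`,
#'   `n_excluded`, and optionally `per_participant`.
#' @export
fit_model_family <- function(trials, zr = 0.5, s = 1,
                             per_participant = FALSE) {
  fam <- enumerate_model_family()
  ids <- sort(unique(trials$participant))
  share_of <- function(row)
    c("v", "a", "t0")[!c(row$vary_v, row$vary_a, row$vary_t0)]
  rows <- list(); excluded <- 0L
  for (id in ids) {
    tr <- trials[trials$participant == id, ]
    n_tr <- nrow(tr)
    sols <- vector("list", 8) # full 6-vector solutions, nested starts
    res <- vector("list", 8)
    ok <- TRUE
    for (m in 1:8) {
      row <- fam[m, ]
      share <- share_of(row)
      extra <- list()
      for (j in seq_len(m - 1)) { # solutions of models nested in model m
        nested <- all(!fam[j, 2:4] | unlist(row[2:4]))
        if (nested && !is.null(sols[[j]])) extra <- c(extra, list(sols[[j]]))
      }
      f <- fit_ddm_conditions(tr, share = share, extra_starts = extra,
                              zr = zr, s = s)
      q <- with(f$params, c(v[1], v[2], a[1], a[2], t0[1], t0[2]))
      sols[[m]] <- q
      res[[m]] <- data.frame(participant = id, model = m,
                             n_free = row$n_free, LL = f$loglik,
                             AIC = 2 * row$n_free - 2 * f$loglik,
                             BIC = row$n_free * log(n_tr) - 2 * f$loglik)
      if (!f$converged) ok <- FALSE
    }
    if (ok) rows <- c(rows, res) else excluded <- excluded + 1L
  }
  if (length(rows) == 0) stop("no participant converged under all models",
                              call. = FALSE)
  pp <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(1:8, function(m) {
    d <- pp[pp$model == m, ]
    data.frame(model = m, LL = sum(d$LL), AIC = sum(d$AIC),
               BIC = sum(d$BIC))
  }))
  out <- cbind(fam, agg[, c("LL", "AIC", "BIC")])
  out$w_AIC <- akaike_weights(out$AIC)
  out$w_BIC <- akaike_weights(out$BIC)
  out$winner_AIC <- seq_len(8) == which.min(out$AIC)
  out$winner_BIC <- seq_len(8) == which.min(out$BIC)
  structure(out, n_participants = length(ids) - excluded,
            n_excluded = excluded,
            per_participant = if (per_participant) pp else NULL,
            class = c("model_ic_table", "data.frame"))
}

#' @export
print.model_ic_table <- function(x, ...) {
  cat("Eight-model competition over", attr(x, "n_participants"),
      "participants")
  if (isTRUE(attr(x, "n_excluded") > 0))
    cat(" (", attr(x, "n_excluded"), " excluded)", sep = "")
  cat("\n")
  df <- as.data.frame(x)
  df$LL <- round(df$LL); df$AIC <- round(df$AIC); df$BIC <- round(df$BIC)
  df$w_AIC <- round(df$w_AIC, 3); df$w_BIC <- round(df$w_BIC, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
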