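#' Hard-minus-easy difference scores per participant
#'
#' Subtracts each participant's easy-condition estimate from the
#' hard-condition estimate, parameter by parameter. Participants missing a
#' condition, or with an unconverged fit in either condition, are dropped
#' listwise (with a message) before the subtraction.
#'
#' @param fits data frame with columns `participant`, `condition`, one
#'   column per parameter, and optionally `converged`.
#' @param params parameter columns to difference; default: every column
#'   other than `participant`, `condition`, `loglik`, `converged`.
#' @return Data frame with `participant` and one `<param>_diff` column per
#'   parameter; attribute `n_excluded` records the dropped participants.
#' @export
compute_diff_scores <- function(fits, params = NULL) {
  if (is.null(params))
    params <- setdiff(names(fits),
                      c("participant", "condition", "loglik", "converged"))
  keep <- fits
  if ("converged" %in% names(fits)) {
    bad <- unique(fits$participant[!fits$converged %in% TRUE])
    keep <- fits[!fits$participant %in% bad, ]
  } else bad <- c()
  e <- keep[keep$condition == "easy", c("participant", params)]
  h <- keep[keep$condition == "hard", c("participant", params)]
  both <- intersect(e$participant, h$participant)
  dropped <- length(unique(fits$participant)) - length(both)
  if (dropped > 0)
    message(dropped, " participant(s) excluded (unconverged or missing a condition)")
  e <- e[match(both, e$participant), ]
  h <- h[match(both, h$participant), ]
  out <- data.frame(participant = both)
  for (p in params) out[[paste0(p, "_diff")]] <- h[[p]] - e[[p]]
  attr(out, "n_excluded") <- dropped
  out
}

# wide per-participant matrix in the conventional column order:
# p1_easy, p1_hard, p2_easy, ..., p1_diff, p2_diff, ...
parameter_matrix <- function(fits, params) {
  diffs <- compute_diff_scores(fits, params)
  keep <- fits[fits$participant %in% diffs$participant, ]
  e <- keep[keep$condition == "easy", ]
  h <- keep[keep$condition == "hard", ]
  e <- e[match(diffs$participant, e$participant), ]
  h <- h[match(diffs$participant, h$participant), ]
  cols <- list()
  for (p in params) {
    cols[[paste0(p, "_easy")]] <- e[[p]]
    cols[[paste0(p, "_hard")]] <- h[[p]]
  }
  for (p in params) cols[[paste0(p, "_diff")]] <- diffs[[paste0(p, "_diff")]]
  m <- do.call(cbind, cols)
  rownames(m) <- diffs$participant
  attr(m, "n_excluded") <- attr(diffs, "n_excluded")
  m
}

#' Product-moment correlation matrix of fitted parameters and their
#' difference scores
#'
#' Builds the participant-level matrix of per-condition estimates plus
#' hard-minus-easy difference scores and returns its Pearson correlation
#' matrix. With the default DDM parameters this is the 9-column matrix
#' `a(easy), a(hard), v(easy), v(hard), t0(easy), t0(hard), a_diff, v_diff,
#' t0_diff`. Correlations involving a zero-variance column are reported as
#' `NA` (with a warning), never silently as 0.
#'
#' Correlation sizes of |0.1|, |0.3| and |0.5| are conventionally read as
#' small, medium and large effects; these thresholds are attached as the
#' `effect_sizes` attribute.
#'
#' @inheritParams compute_diff_scores
#' @param params parameters to include, in display order; default
#'   `c("a", "v", "t0")` (use `c("caution", "v", "t0")` for LBA fits).
#' @return Object of class `diffscore_corr`: the correlation matrix with
#'   attributes `n` (participants used) and `n_excluded`.
#' @export
correlation_matrix <- function(fits, params = c("a", "v", "t0")) {
  m <- parameter_matrix(fits, params)
  if (nrow(m) < 3) stop("need at least 3 participants", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; their correlations are undefined (NA)")
  r <- suppressWarnings(cor(m)) # cor warns on zero-variance; we NA them
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  structure(r, n = nrow(m), n_excluded = attr(m, "n_excluded"),
            effect_sizes = c(small = 0.1, medium = 0.3, large = 0.5),
            class = c("diffscore_corr", "matrix"))
}

#' @export
print.diffscore_corr <- function(x, digits = 3, ...) {
  cat("Parameter correlation matrix (n =", attr(x, "n"), "participants")
  if (isTRUE(attr(x, "n_excluded") > 0))
    cat(",", attr(x, "n_excluded"), "excluded")
  cat(")\n")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, digits))
  invisible(x)
}

#' Pearson correlation after |z| outlier removal
#'
#' Standardizes `x` and `y` (each within the pair being correlated), drops
#' every observation with `|z| > z_threshold` on either variable, and
#' recomputes the product-moment correlation on the remainder.
#'
#' @param x,y numeric vectors of equal length.
#' @param z_threshold absolute standardized-score cutoff.
#' @return List with `r`, `n_removed`, `n_used`.
#' @export
outlier_filtered_correlation <- function(x, y, z_threshold = 2.5) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  keep <- abs(zx) <= z_threshold & abs(zy) <= z_threshold
  if (!any(keep)) stop("all observations removed by the outlier filter",
                       call. = FALSE)
  list(r = cor(x[keep], y[keep]), n_removed = sum(!keep),
       n_used = sum(keep))
}

#' Heatmap of a difference-score correlation matrix
#'
#' Tile heatmap of a [correlation_matrix()] result with the
#' difference-score block outlined, so the correlation structure among
#' difference scores stands out against the per-condition block.
#'
#' @param x a `diffscore_corr` object.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(x) {
  labs <- colnames(x)
  df <- expand.grid(col = labs, row = labs, stringsAsFactors = FALSE)
  df$r <- as.vector(unclass(x))
  df$col <- factor(df$col, levels = labs)
  df$row <- factor(df$row, levels = rev(labs))
  n_diff <- sum(grepl("_diff$", labs))
  k <- length(labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::annotate("rect", xmin = k - n_diff + 0.5, xmax = k + 0.5,
                      ymin = 0.5, ymax = n_diff + 0.5, colour = "grey30",
                      fill = NA, linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
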