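# Value-by-unit count matrix: rows are distinct code values, columns units.
# Units with fewer than 2 codings carry no pairable information and are
# dropped here, matching the standard treatment of missing entries.
.code_counts <- function(codes) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 2L) stop("need at least 2 coders (matrix rows)")
  obs <- as.vector(codes)
  ok <- !is.na(obs)
  if (!any(ok)) stop("coding matrix contains no codes")
  vals <- sort(unique(obs[ok]))
  unit <- as.vector(col(codes))[ok]
  counts <- unclass(table(
    factor(match(obs[ok], vals), levels = seq_along(vals)),
    factor(unit, levels = seq_len(ncol(codes)))
  ))
  dimnames(counts) <- NULL
  keep <- colSums(counts) >= 2L
  if (!any(keep)) stop("no unit has at least 2 codings")
  list(counts = counts[, keep, drop = FALSE], values = vals)
}

# Alpha from a value-by-unit count matrix (columns already restricted to
# pairable units). Coincidence matrix C[c,k] = sum_u n_uc n_uk / (m_u - 1)
# off-diagonal and n_uc (n_uc - 1) / (m_u - 1) on it; alpha = 1 - Do/De.
.alpha_from_counts <- function(counts, values, metric) {
  m_u <- colSums(counts)
  w <- sweep(counts, 2L, m_u - 1, "/")
  coin <- counts %*% t(w)
  diag(coin) <- diag(coin) - rowSums(w)
  n_c <- rowSums(coin)
  n_tot <- sum(n_c)
  delta <- switch(metric,
    nominal = 1 - diag(length(values)),
    interval = outer(values, values, function(a, b) (a - b)^2)
  )
  d_obs <- sum(coin * delta)
  d_exp <- sum(outer(n_c, n_c) * delta) / (n_tot - 1)
  if (d_exp <= 0) {
    stop("expected disagreement is zero (a single code value across all ",
         "units); Krippendorff's alpha is undefined for this matrix")
  }
  1 - d_obs / d_exp
}

#' Krippendorff's alpha inter-rater reliability
#'
#' Chance-corrected agreement over a coder-by-unit matrix, computed from the
#' coincidence matrix as `1 - Do/De` (observed over expected disagreement).
#' Missing entries are allowed; units with fewer than two codings are
#' excluded. With the default nominal metric the statistic is invariant to
#' relabeling the code values.
#'
#' @param codes Matrix with one row per coder and one column per unit
#'   (here, a (participant, picture) pair); entries are the assigned codes,
#'   `NA` for not coded.
#' @param metric Disagreement metric: `"nominal"` (default; codes are
#'   unordered categories) or `"interval"` (squared difference).
#' @return The alpha value (a scalar, at most 1).
#' @details A matrix in which every coded entry carries one single value has
#'   zero expected disagreement; alpha is undefined there and an error is
#'   signalled rather than silently returning 1.
#' @examples
#' codes <- rbind(c(0, 1, 0, 1), c(0, 1, 0, 0))
#' krippendorff_alpha(codes)
#' @export
krippendorff_alpha <- function(codes, metric = c("nominal", "interval")) {
  metric <- match.arg(metric)
  cc <- .code_counts(codes)
  .alpha_from_counts(cc$counts, cc$values, metric)
}

#' Bootstrap confidence interval for Krippendorff's alpha
#'
#' Nonparametric bootstrap over units: columns of the coding matrix are
#' resampled with replacement, alpha recomputed for each replicate, and a
#' percentile interval ([percentile_ci()]) taken over the replicate alphas.
#' Replicates that are degenerate (a single code value, so alpha is
#' undefined) are skipped and counted.
#'
#' @inheritParams krippendorff_alpha
#' @param n_boot Number of bootstrap replicates (default 1000; fewer than
#'   100 triggers a warning and the interval cannot be formed).
#' @param level Interval level in (0, 1); default 0.95.
#' @param seed Optional integer seed for reproducible resampling.
#' @return An object of class `reliability_result`: a list with `alpha`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_degenerate`, `level`, `seed`, and
#'   `replicates` (the retained replicate alphas).
#' @examples
#' codes <- rbind(c(0, 1, 0, 1, 1, 0, 0, 1), c(0, 1, 0, 1, 0, 0, 0, 1))
#' bootstrap_alpha_ci(codes, n_boot = 200, seed = 1)
#' @export
bootstrap_alpha_ci <- function(codes, n_boot = 1000, level = 0.95,
                               seed = NULL, metric = c("nominal", "interval")) {
  metric <- match.arg(metric)
  if (n_boot < 100) {
    warning("n_boot < 100 gives an unstable interval")
  }
  alpha <- krippendorff_alpha(codes, metric)
  cc <- .code_counts(codes)
  n_units <- ncol(cc$counts)
  if (!is.null(seed)) set.seed(seed)
  reps <- rep(NA_real_, n_boot)
  n_degenerate <- 0L
  for (i in seq_len(n_boot)) {
    j <- sample.int(n_units, n_units, replace = TRUE)
    a_i <- tryCatch(
      .alpha_from_counts(cc$counts[, j, drop = FALSE], cc$values, metric),
      error = function(e) NA_real_
    )
    if (is.na(a_i)) n_degenerate <- n_degenerate + 1L else reps[i] <- a_i
  }
  reps <- reps[!is.na(reps)]
  if (length(reps) == 0L) {
    stop("all bootstrap replicates were degenerate; no interval available")
  }
  ci <- if (length(reps) >= 100L) {
    percentile_ci(reps, level = level)
  } else {
    # same type-7 percentile rule, tolerated below the usual replicate
    # minimum (already warned about above)
    tail <- (1 - level) / 2
    stats::quantile(reps, probs = c(tail, 1 - tail), type = 7,
                    names = FALSE)
  }
  structure(
    list(alpha = alpha, ci_low = ci[1L], ci_high = ci[2L],
         n_boot = as.integer(n_boot), n_degenerate = n_degenerate,
         level = level, seed = seed, replicates = reps),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, digits = 3, ...) {
  cat("Krippendorff's alpha = ", round(x$alpha, digits),
      ", ", 100 * x$level, "% CI [", round(x$ci_low, digits), ", ",
      round(x$ci_high, digits), "] (", x$n_boot, " bootstrap replicates, ",
      x$n_degenerate, " degenerate)\n", sep = "")
  invisible(x)
}
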