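#' Percentile confidence interval from replicate statistics
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`, using
#' linear interpolation between order statistics (the type-7 rule of
#' [stats::quantile()]), fixed so that reported intervals are reproducible.
#'
#' @param draws Numeric vector of replicate statistics (at least 100).
#' @param level Interval level in (0, 1); default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' percentile_ci(1:100, level = 0.90)
#' @export
percentile_ci <- function(draws, level = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L) {
    stop("need at least 100 draws for a percentile interval, got ",
         length(draws))
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)")
  }
  tail <- (1 - level) / 2
  stats::quantile(draws, probs = c(tail, 1 - tail), type = 7, names = FALSE)
}

#' Sobel test for an indirect effect
#'
#' First-order normal-theory test of the product of coefficients
#' `a * b`, used as an analytic cross-check on bootstrap inference:
#' `z = a b / sqrt(b^2 se_a^2 + a^2 se_b^2)`.
#'
#' @param a,b Path coefficient estimates.
#' @param se_a,se_b Their standard errors (must be positive).
#' @return List with `z` and two-sided `p` from the standard normal.
#' @examples
#' sobel(a = 1, se_a = 1, b = 1, se_b = 1) # z = 1/sqrt(2)
#' @export
sobel <- function(a, se_a, b, se_b) {
  if (!is.numeric(se_a) || !is.numeric(se_b) || se_a <= 0 || se_b <= 0) {
    stop("standard errors must be positive")
  }
  denom <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  z <- if (denom == 0) 0 else (a * b) / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Single-mediator mediation model with percentile-bootstrap inference
#'
#' Estimates the classic product-of-coefficients mediation model for one
#' mediator with optional covariates, the structure popularized as "Model 4":
#' \describe{
#'   \item{a}{from regressing the mediator `m` on `x` (+ covariates);}
#'   \item{b, c'}{from regressing the outcome `y` on `m` and `x`
#'     (+ covariates);}
#'   \item{c}{from regressing `y` on `x` (+ covariates);}
#'   \item{ab}{the indirect effect `a * b`.}
#' }
#' Covariates enter all three regressions. Because the three regressions
#' share the same sample and covariate set, the OLS identity
#' `c = c' + a*b` holds to machine precision. Inference is by case
#' resampling: whole rows are resampled with replacement, all regressions
#' refit, and percentile intervals taken over replicate statistics. A
#' replicate in which the resampled `x` is constant cannot identify the
#' paths and is redrawn (with the redraw count logged).
#'
#' @param x Numeric exposure codes (e.g. 0/1 condition); at least two
#'   distinct values.
#' @param m Numeric mediator values.
#' @param y Numeric outcome values.
#' @param covariates Optional numeric matrix or data.frame of covariate
#'   columns (no intercept), same number of rows as `length(x)`.
#' @param n_boot Number of bootstrap resamples (default 10000). `n_boot = 0`
#'   skips the bootstrap and returns `NA` intervals (useful in large
#'   simulation studies that only need point estimates).
#' @param level Confidence level for all intervals (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return An object of class `mediation_result`: a list with `paths` (a
#'   data.frame of estimate, se, t, p, ci_low, ci_high for a, b, c, c_prime,
#'   ab), `n`, `n_boot`, `level`, `seed`, `covariate_names`, `n_redraws`,
#'   and `boot` (the replicate matrix, `NULL` when `n_boot = 0`).
#' @examples
#' set.seed(1)
#' x <- rep(0:1, each = 40)
#' m <- 0.5 * x + rnorm(80)
#' y <- 0.6 * m + rnorm(80)
#' fit_model4(x, m, y, n_boot = 200, seed = 1)
#' @export
fit_model4 <- function(x, m, y, covariates = NULL, n_boot = 10000,
                       level = 0.95, seed = NULL) {
  x <- as.numeric(x)
  m <- as.numeric(m)
  y <- as.numeric(y)
  n <- length(x)
  if (length(m) != n || length(y) != n) {
    stop("`x`, `m`, `y` must have equal lengths")
  }
  if (anyNA(x) || anyNA(m) || anyNA(y)) {
    stop("missing values are not allowed; apply listwise deletion upstream")
  }
  if (length(unique(x)) < 2L) {
    stop("`x` must take at least 2 distinct values")
  }
  if (!is.numeric(n_boot) || n_boot < 0) stop("`n_boot` must be >= 0")
  n_boot <- as.integer(n_boot)

  cov_names <- character(0)
  cmat <- NULL
  if (!is.null(covariates)) {
    cmat <- as.matrix(covariates)
    if (nrow(cmat) != n) stop("covariates must have one row per observation")
    if (anyNA(cmat)) stop("missing covariate values; apply listwise deletion upstream")
    if (is.null(colnames(cmat))) {
      colnames(cmat) <- paste0("cov", seq_len(ncol(cmat)))
    }
    cov_names <- colnames(cmat)
  }

  x_m <- cbind(intercept = 1, x = x)
  x_y <- cbind(intercept = 1, m = m, x = x)
  x_c <- cbind(intercept = 1, x = x)
  if (!is.null(cmat)) {
    x_m <- cbind(x_m, cmat)
    x_y <- cbind(x_y, cmat)
    x_c <- cbind(x_c, cmat)
  }

  fit_m <- ols(x_m, m)
  fit_y <- ols(x_y, y)
  fit_c <- ols(x_c, y)

  est <- c(a = unname(fit_m$coefficients["x"]),
           b = unname(fit_y$coefficients["m"]),
           c = unname(fit_c$coefficients["x"]),
           c_prime = unname(fit_y$coefficients["x"]))
  est["ab"] <- est["a"] * est["b"]
  se <- c(a = unname(fit_m$se["x"]), b = unname(fit_y$se["m"]),
          c = unname(fit_c$se["x"]), c_prime = unname(fit_y$se["x"]),
          ab = NA_real_)
  tval <- c(a = unname(fit_m$t["x"]), b = unname(fit_y$t["m"]),
            c = unname(fit_c$t["x"]), c_prime = unname(fit_y$t["x"]),
            ab = NA_real_)
  pval <- c(a = unname(fit_m$p["x"]), b = unname(fit_y$p["m"]),
            c = unname(fit_c$p["x"]), c_prime = unname(fit_y$p["x"]),
            ab = NA_real_)

  boot <- NULL
  n_redraws <- 0L
  ci <- matrix(NA_real_, 2L, 5L,
               dimnames = list(c("low", "high"),
                               c("a", "b", "c", "c_prime", "ab")))
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, 5L,
                   dimnames = list(NULL, c("a", "b", "c", "c_prime", "ab")))
    for (i in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xi <- x[idx]
        if (any(xi != xi[1L])) break
        n_redraws <- n_redraws + 1L
      }
      cm <- stats::.lm.fit(x_m[idx, , drop = FALSE], m[idx])$coefficients
      cy <- stats::.lm.fit(x_y[idx, , drop = FALSE], y[idx])$coefficients
      cc <- stats::.lm.fit(x_c[idx, , drop = FALSE], y[idx])$coefficients
      boot[i, ] <- c(cm[2L], cy[2L], cc[2L], cy[3L], cm[2L] * cy[2L])
    }
    if (n_redraws > 0.1 * n_boot) {
      warning("more than 10% of bootstrap resamples had a degenerate ",
              "exposure and were redrawn (", n_redraws, " redraws)")
    }
    ci <- apply(boot, 2L, percentile_ci, level = level)
    rownames(ci) <- c("low", "high")
    se["ab"] <- stats::sd(boot[, "ab"])
  }

  paths <- data.frame(
    path = c("a", "b", "c", "c_prime", "ab"),
    estimate = unname(est),
    se = unname(se),
    t = unname(tval),
    p = unname(pval),
    ci_low = unname(ci["low", ]),
    ci_high = unname(ci["high", ]),
    stringsAsFactors = FALSE
  )
  structure(
    list(paths = paths, n = n, n_boot = n_boot, level = level,
         seed = seed, covariate_names = cov_names,
         n_redraws = n_redraws, boot = boot),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat("Single-mediator mediation model (N = ", x$n,
      ", bootstrap = ", x$n_boot, ")\n", sep = "")
  if (length(x$covariate_names)) {
    cat("Covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  }
  tab <- x$paths
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
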