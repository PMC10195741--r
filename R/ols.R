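#' Ordinary least squares on an explicit design matrix
#'
#' Minimal OLS fitter used by the mediation engine. The design matrix is
#' taken as-is (supply your own intercept column); coefficients are obtained
#' by QR decomposition and standard errors from the unbiased residual
#' variance estimator.
#'
#' @param design Numeric matrix, `n x p`, with named columns. Include an
#'   intercept column explicitly if one is wanted.
#' @param response Numeric vector of length `n`.
#' @return A list with components `coefficients`, `se`, `t`, `p` (named by
#'   design column), `sigma2` (unbiased residual variance), `df_residual`,
#'   `residuals`, and `fitted`.
#' @examples
#' x <- c(0, 0, 0, 1, 1, 1)
#' y <- 2 + 3 * x + c(-0.1, 0, 0.1, -0.1, 0, 0.1)
#' ols(cbind(intercept = 1, x = x), y)$coefficients
#' @export
ols <- function(design, response) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("V", seq_len(ncol(design)))
  }
  response <- as.numeric(response)
  n <- nrow(design)
  p <- ncol(design)
  if (length(response) != n) {
    stop("`response` must have one value per design row (", n, ")")
  }
  if (anyNA(design) || anyNA(response)) {
    stop("missing values are not allowed; apply listwise deletion upstream")
  }
  if (n <= p) {
    stop("need more observations (", n, ") than parameters (", p, ")")
  }
  qx <- qr(design)
  if (qx$rank < p) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, response)
  fitted <- drop(design %*% coefs)
  res <- response - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(design)
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coefficients = coefs, se = se, t = tval, p = pval,
       sigma2 = sigma2, df_residual = df, residuals = res, fitted = fitted)
}
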