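#' Z-score a vector of measurements
#'
#' Centers to mean 0 and scales to unit standard deviation, using the
#' sample (n - 1) denominator. Constant input has no defined z-scores and
#' raises an error rather than silently emitting zeros; missing values are
#' an error because participant exclusion is handled listwise upstream.
#'
#' @param values Numeric vector, length at least 2, with nonzero spread.
#' @return Numeric vector with mean 0 and standard deviation 1.
#' @examples
#' standardize(c(1, 2, 3)) # -1 0 1
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values to standardize")
  if (anyNA(values)) {
    stop("missing values are not allowed; apply listwise deletion upstream")
  }
  s <- stats::sd(values)
  if (s == 0) stop("cannot standardize a constant vector (zero spread)")
  (values - mean(values)) / s
}

#' Positive emotional memory bias composite
#'
#' Builds the summary score measuring a positive-over-negative tilt in
#' memory from two retrieval measures collected in the final week: false
#' alarms in recognition (a criterion/bias measure, preferred over hits)
#' and correct free-recall counts. Each of the four inputs is z-scored
#' across the included participants and the composite is
#' `(z_fa_pos - z_fa_neg) + (z_rec_pos - z_rec_neg)`, so false recognition
#' and recall contribute equally and the sample mean of the composite is
#' zero by construction.
#'
#' @param components Data frame with columns `participant_id`, `fa_pos`,
#'   `fa_neg` (false-alarm proportions for positive/negative lures) and
#'   `rec_pos`, `rec_neg` (correct recall counts), listwise-complete.
#' @return Data frame with `participant_id`, the four z-columns
#'   (`z_fa_pos`, `z_fa_neg`, `z_rec_pos`, `z_rec_neg`), and `bias`.
#' @examples
#' comp <- data.frame(participant_id = c("a", "b", "c", "d"),
#'                    fa_pos = c(.1, 0, .1, 0), fa_neg = c(0, .1, 0, .1),
#'                    rec_pos = c(3, 1, 3, 1), rec_neg = c(1, 3, 1, 3))
#' compute_bias_scores(comp)$bias
#' @export
compute_bias_scores <- function(components) {
  needed <- c("participant_id", "fa_pos", "fa_neg", "rec_pos", "rec_neg")
  missing_cols <- setdiff(needed, names(components))
  if (length(missing_cols)) {
    stop("`components` missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(components$participant_id)) {
    stop("duplicate participant_id in `components`")
  }
  raw <- components[c("fa_pos", "fa_neg", "rec_pos", "rec_neg")]
  if (anyNA(raw)) {
    stop("missing values are not allowed; intersect participants listwise ",
         "before scoring")
  }
  z <- lapply(names(raw), function(nm) {
    tryCatch(standardize(raw[[nm]]),
             error = function(e) {
               stop("column `", nm, "`: ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  names(z) <- paste0("z_", names(raw))
  out <- data.frame(participant_id = components$participant_id,
                    z, stringsAsFactors = FALSE)
  out$bias <- (out$z_fa_pos - out$z_fa_neg) +
    (out$z_rec_pos - out$z_rec_neg)
  out
}
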