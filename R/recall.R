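#' Reconcile two coders' recall codings
#'
#' Free-recall descriptions are matched to studied pictures by two
#' independent coders; each (participant, picture) unit gets a code of 0
#' (not recalled), 1 (recalled), or occasionally 2 (two descriptions
#' matched to the same picture). In the original procedure the coders
#' resolved discrepancies by discussion; this automated stand-in
#' enumerates every discrepancy and applies a deterministic resolution
#' rule, defaulting to `"max"` (favor "reported").
#'
#' @param coding_a,coding_b Data frames with columns `coder_id`, `week`,
#'   `participant_id`, `item_id`, `code` (0/1/2). The two codings must
#'   cover identical (participant_id, item_id) index sets for the same
#'   week.
#' @param rule Resolution rule for unequal codes: `"max"` (default),
#'   `"min"`, `"coder_a"`, or `"coder_b"`.
#' @return List with `discrepancies` (data frame of `participant_id`,
#'   `item_id`, `code_a`, `code_b`) and `merged` (a coding data frame with
#'   `coder_id = "merged"`).
#' @export
reconcile_coders <- function(coding_a, coding_b,
                             rule = c("max", "min", "coder_a", "coder_b")) {
  rule <- match.arg(rule)
  for (nm in c("participant_id", "item_id", "code", "week")) {
    if (!nm %in% names(coding_a) || !nm %in% names(coding_b)) {
      stop("codings must have column `", nm, "`")
    }
  }
  for (df in list(coding_a, coding_b)) {
    if (!all(df$code %in% 0:2)) {
      stop("codes must be 0, 1, or 2")
    }
  }
  if (length(unique(c(coding_a$week, coding_b$week))) != 1L) {
    stop("codings must refer to a single common week")
  }
  key_a <- paste(coding_a$participant_id, coding_a$item_id, sep = "\r")
  key_b <- paste(coding_b$participant_id, coding_b$item_id, sep = "\r")
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("duplicate (participant_id, item_id) keys within a coding")
  }
  only_a <- setdiff(key_a, key_b)
  only_b <- setdiff(key_b, key_a)
  if (length(only_a) || length(only_b)) {
    fmt <- function(k) paste(utils::head(gsub("\r", "/", k), 5L),
                             collapse = ", ")
    stop("coder index sets differ; missing from coder B: [", fmt(only_a),
         "]; missing from coder A: [", fmt(only_b), "]")
  }
  b_code <- coding_b$code[match(key_a, key_b)]
  differs <- coding_a$code != b_code
  discrepancies <- data.frame(
    participant_id = coding_a$participant_id[differs],
    item_id = coding_a$item_id[differs],
    code_a = coding_a$code[differs],
    code_b = b_code[differs],
    stringsAsFactors = FALSE
  )
  merged_code <- switch(rule,
    max = pmax(coding_a$code, b_code),
    min = pmin(coding_a$code, b_code),
    coder_a = coding_a$code,
    coder_b = b_code
  )
  merged <- data.frame(
    coder_id = "merged",
    week = coding_a$week,
    participant_id = coding_a$participant_id,
    item_id = coding_a$item_id,
    code = merged_code,
    stringsAsFactors = FALSE
  )
  list(discrepancies = discrepancies, merged = merged)
}

#' Tally correct recall counts by valence
#'
#' Sums a merged recall coding into per-participant counts of correctly
#' recalled pictures per valence, plus the count of recall descriptions
#' that matched no studied picture. The valence map assigns each coded
#' item either a picture valence or the sentinel valence `"incorrect"`
#' (for the unmatched-description slots).
#'
#' @param merged A recall coding data frame (e.g. the `merged` element of
#'   [reconcile_coders()]) with columns `participant_id`, `item_id`,
#'   `week`, `code`.
#' @param valence_map Data frame with columns `item_id` and `valence`
#'   (`neutral`/`positive`/`negative`/`incorrect`); every coded item must
#'   appear.
#' @return Data frame with one row per participant: `participant_id`,
#'   `week`, `correct_neutral`, `correct_positive`, `correct_negative`,
#'   `incorrect`.
#' @export
tally_recall <- function(merged, valence_map) {
  if (!all(c("item_id", "valence") %in% names(valence_map))) {
    stop("`valence_map` must have columns item_id and valence")
  }
  ok_val <- c(.VALENCES, "incorrect")
  if (!all(valence_map$valence %in% ok_val)) {
    stop("valence_map valences must be one of: ",
         paste(ok_val, collapse = ", "))
  }
  vmap <- valence_map$valence[match(merged$item_id, valence_map$item_id)]
  if (anyNA(vmap)) {
    stop("unmapped item(s): ",
         paste(utils::head(unique(merged$item_id[is.na(vmap)]), 5L),
               collapse = ", "))
  }
  if (!all(merged$code %in% 0:2)) stop("codes must be 0, 1, or 2")
  wk <- unique(merged$week)
  if (length(wk) != 1L) stop("`merged` must cover a single week")
  pid <- factor(merged$participant_id)
  vfac <- factor(vmap, levels = ok_val)
  sums <- stats::xtabs(merged$code ~ pid + vfac)
  data.frame(
    participant_id = levels(pid),
    week = wk,
    correct_neutral = as.vector(sums[, "neutral"]),
    correct_positive = as.vector(sums[, "positive"]),
    correct_negative = as.vector(sums[, "negative"]),
    incorrect = as.vector(sums[, "incorrect"]),
    stringsAsFactors = FALSE
  )
}

#' Coding data frame to coder-by-unit matrix
#'
#' Reshapes long recall codings (one or more coders, one week) into the
#' coder-by-unit matrix consumed by [krippendorff_alpha()]. Units are
#' (participant, picture) pairs.
#'
#' @param codings Data frame with columns `coder_id`, `week`,
#'   `participant_id`, `item_id`, `code`.
#' @return Numeric matrix, rows named by coder, columns by
#'   `participant/item`.
#' @export
coding_matrix <- function(codings) {
  coders <- sort(unique(codings$coder_id))
  if (length(coders) < 2L) stop("need at least 2 coders")
  if (length(unique(codings$week)) != 1L) {
    stop("`codings` must cover a single week")
  }
  unit <- paste(codings$participant_id, codings$item_id, sep = "/")
  units <- sort(unique(unit))
  mat <- matrix(NA_real_, length(coders), length(units),
                dimnames = list(coders, units))
  mat[cbind(match(codings$coder_id, coders), match(unit, units))] <-
    codings$code
  mat
}
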