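.VALENCES <- c("neutral", "positive", "negative")
.STATUSES <- c("old", "new")
.RESPONSES <- c("remember", "know", "new")
.CONDITIONS <- c("OscPlus", "OscMinus")
.AGE_GROUPS <- c("YA", "OA")

#' Signal-detection rates from trial-level recognition responses
#'
#' Converts Remember/Know/New responses to old and new pictures into
#' per-participant, per-valence recognition rates. An item counts as
#' "called old" when the response is `remember` or `know` (the standard
#' Remember/Know convention): hits are old items called old, false alarms
#' are new items called old, and corrected recognition is hits minus false
#' alarms. Remember- and Know-specific rates partition the overall rates.
#'
#' @param trials Data frame with columns `participant_id`, `item_id`,
#'   `valence` (`neutral`/`positive`/`negative`), `status` (`old`/`new`),
#'   and `response` (`remember`/`know`/`new`). `(participant_id, item_id)`
#'   pairs must be unique and every participant x valence x status cell
#'   non-empty.
#' @return Data frame with one row per participant x valence: `n_old`,
#'   `n_new`, `hit_rate`, `fa_rate`, `corrected_recognition`,
#'   `remember_hit_rate`, `know_hit_rate`, `remember_fa_rate`,
#'   `know_fa_rate`.
#' @export
compute_recognition_rates <- function(trials) {
  needed <- c("participant_id", "item_id", "valence", "status", "response")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("recognition trials missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(trials$response %in% .RESPONSES))
  if (length(bad)) {
    stop("unknown response label '", trials$response[bad[1L]],
         "' at row ", bad[1L], " (allowed: ",
         paste(.RESPONSES, collapse = ", "), ")")
  }
  bad <- which(!(trials$valence %in% .VALENCES))
  if (length(bad)) {
    stop("unknown valence label '", trials$valence[bad[1L]],
         "' at row ", bad[1L])
  }
  bad <- which(!(trials$status %in% .STATUSES))
  if (length(bad)) {
    stop("unknown status label '", trials$status[bad[1L]],
         "' at row ", bad[1L])
  }
  key <- paste(trials$participant_id, trials$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (participant_id, item_id) pair: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }

  pid <- factor(trials$participant_id)
  val <- factor(trials$valence, levels = .VALENCES)
  status <- factor(trials$status, levels = .STATUSES)
  n_cell <- table(pid, val, status)
  if (any(n_cell == 0L)) {
    z <- which(n_cell == 0L, arr.ind = TRUE)[1L, ]
    stop("empty cell: participant ", dimnames(n_cell)[[1L]][z[1L]],
         ", valence ", dimnames(n_cell)[[2L]][z[2L]],
         ", status ", dimnames(n_cell)[[3L]][z[3L]])
  }
  called_old <- trials$response != "new"
  rem <- trials$response == "remember"
  know <- trials$response == "know"
  tab <- function(v) stats::xtabs(v ~ pid + val + status)
  n_called <- tab(as.integer(called_old))
  n_rem <- tab(as.integer(rem))
  n_know <- tab(as.integer(know))

  n_old <- n_cell[, , "old"]
  n_new <- n_cell[, , "new"]
  out <- data.frame(
    participant_id = rep(levels(pid), times = length(.VALENCES)),
    valence = rep(.VALENCES, each = nlevels(pid)),
    n_old = as.vector(n_old),
    n_new = as.vector(n_new),
    hit_rate = as.vector(n_called[, , "old"] / n_old),
    fa_rate = as.vector(n_called[, , "new"] / n_new),
    remember_hit_rate = as.vector(n_rem[, , "old"] / n_old),
    know_hit_rate = as.vector(n_know[, , "old"] / n_old),
    remember_fa_rate = as.vector(n_rem[, , "new"] / n_new),
    know_fa_rate = as.vector(n_know[, , "new"] / n_new),
    stringsAsFactors = FALSE
  )
  out$corrected_recognition <- out$hit_rate - out$fa_rate
  out[order(out$participant_id, match(out$valence, .VALENCES)),
      c("participant_id", "valence", "n_old", "n_new", "hit_rate",
        "fa_rate", "corrected_recognition", "remember_hit_rate",
        "know_hit_rate", "remember_fa_rate", "know_fa_rate")]
}
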