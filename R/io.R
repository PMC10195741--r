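# Required columns per input table; the CSV schemas of the pipeline.
.SCHEMAS <- list(
  participants = c("participant_id", "condition", "age_group", "age",
                   "sex", "years_education"),
  recognition = c("participant_id", "item_id", "valence", "status",
                  "response"),
  recall_coding = c("coder_id", "week", "participant_id", "item_id",
                    "code"),
  connectivity = c("participant_id", "pre_beta", "post_beta"),
  covariates = c("participant_id", "mood_change", "rmssd_change",
                 "rmssd_baseline"),
  valence_map = c("item_id", "valence")
)

#' Validate pipeline input files against their schemas
#'
#' Checks each input CSV for presence, required columns, label enumerations
#' (condition, age group, valence, status, response, codes), and the
#' consistency of recall-coding index sets across coders within a week.
#' Failures are collected in the report rather than raised.
#'
#' @param paths Named character vector or list of file paths; recognised
#'   names are `participants`, `recognition`, `recall_coding`,
#'   `connectivity`, `covariates`, `valence_map`.
#' @return Data frame with one row per file: `file`, `path`, `pass`,
#'   `message` (first offending row/column for failures).
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  rows <- lapply(names(.SCHEMAS), function(nm) {
    path <- paths[[nm]]
    res <- list(file = nm, path = if (is.null(path)) NA_character_ else path,
                pass = FALSE, message = "")
    if (is.null(path)) {
      res$message <- "path not supplied"
      return(as.data.frame(res, stringsAsFactors = FALSE))
    }
    if (!file.exists(path)) {
      res$message <- "file does not exist"
      return(as.data.frame(res, stringsAsFactors = FALSE))
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.SCHEMAS[[nm]], names(tab))
    if (length(missing_cols)) {
      res$message <- paste0("missing column(s): ",
                            paste(missing_cols, collapse = ", "))
      return(as.data.frame(res, stringsAsFactors = FALSE))
    }
    msg <- .check_enums(nm, tab)
    if (is.null(msg)) {
      res$pass <- TRUE
    } else {
      res$message <- msg
    }
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.first_bad <- function(col, allowed, values) {
  bad <- which(!(values %in% allowed))
  if (!length(bad)) return(NULL)
  paste0("column `", col, "`: invalid value '", values[bad[1L]],
         "' at row ", bad[1L])
}

.check_enums <- function(nm, tab) {
  if (nm == "participants") {
    return(.first_bad("condition", .CONDITIONS, tab$condition) %||%
             .first_bad("age_group", .AGE_GROUPS, tab$age_group))
  }
  if (nm == "recognition") {
    return(.first_bad("valence", .VALENCES, tab$valence) %||%
             .first_bad("status", .STATUSES, tab$status) %||%
             .first_bad("response", .RESPONSES, tab$response))
  }
  if (nm == "recall_coding") {
    msg <- .first_bad("code", 0:2, tab$code)
    if (!is.null(msg)) return(msg)
    for (w in unique(tab$week)) {
      sub <- tab[tab$week == w, ]
      keys <- split(paste(sub$participant_id, sub$item_id, sep = "/"),
                    sub$coder_id)
      if (length(keys) < 2L) {
        return(paste0("week ", w, ": fewer than 2 coders"))
      }
      ref <- sort(keys[[1L]])
      for (cd in names(keys)[-1L]) {
        if (!identical(sort(keys[[cd]]), ref)) {
          diff <- c(setdiff(ref, keys[[cd]]), setdiff(keys[[cd]], ref))
          return(paste0("week ", w, ": coder index sets differ (e.g. ",
                        diff[1L], ")"))
        }
      }
    }
    return(NULL)
  }
  if (nm == "valence_map") {
    return(.first_bad("valence", c(.VALENCES, "incorrect"), tab$valence))
  }
  # connectivity / covariates: numeric, finite
  for (col in setdiff(.SCHEMAS[[nm]], "participant_id")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      return(paste0("column `", col, "` must be numeric"))
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      return(paste0("column `", col, "`: non-finite value at row ", bad[1L]))
    }
  }
  NULL
}
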