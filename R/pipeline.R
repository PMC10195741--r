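#' Pipeline configuration
#'
#' Bundles the input file paths, inference settings, and output directory
#' for [run_pipeline()].
#'
#' @param paths Named list/vector of input CSV paths (see
#'   [validate_inputs()] for the recognised names and schemas). A
#'   directory written by [write_cohort()] can be passed via `input_dir`
#'   instead.
#' @param input_dir Convenience: directory containing the standard file
#'   names; ignored when `paths` is given.
#' @param n_boot Bootstrap resamples for mediation (default 10000, at
#'   least 100).
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @param seed Integer seed controlling all resampling in the run.
#' @param covariates Optional mediation covariates, a subset of
#'   `c("mood_change", "rmssd_change")`. Pre-intervention connectivity is
#'   always controlled for; one additional mediation model is fitted per
#'   listed covariate (added singly), mirroring the usual robustness
#'   checks.
#' @param out_dir Output directory for the results bundle.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, input_dir = NULL, n_boot = 10000,
                            ci_level = 0.95, seed = 1L,
                            covariates = character(0), out_dir = "results") {
  if (is.null(paths)) {
    if (is.null(input_dir)) stop("supply `paths` or `input_dir`")
    paths <- stats::setNames(
      file.path(input_dir, paste0(names(.SCHEMAS), ".csv")),
      names(.SCHEMAS)
    )
  }
  paths <- as.list(paths)
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  if (ci_level <= 0 || ci_level >= 1) stop("`ci_level` must be in (0, 1)")
  bad <- setdiff(covariates, c("mood_change", "rmssd_change"))
  if (length(bad)) {
    stop("unknown mediation covariate(s): ", paste(bad, collapse = ", "))
  }
  missing_files <- names(.SCHEMAS)[!vapply(
    names(.SCHEMAS), function(nm) !is.null(paths[[nm]]) &&
      file.exists(paths[[nm]]), logical(1))]
  if (length(missing_files)) {
    stop("input file(s) missing: ", paste(missing_files, collapse = ", "))
  }
  structure(
    list(paths = paths, n_boot = as.integer(n_boot), ci_level = ci_level,
         seed = as.integer(seed), covariates = covariates,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# Participants with a complete 72-trial recognition set (every valence x
# status cell non-empty); others are excluded with a reason code.
.complete_recognition_ids <- function(trials) {
  tab <- table(trials$participant_id,
               factor(trials$valence, .VALENCES),
               factor(trials$status, .STATUSES))
  ok <- apply(tab > 0L, 1L, all)
  rownames(tab)[ok]
}

#' Run the full emotional-memory-bias pipeline
#'
#' Orchestrates all stages from CSV inputs (real or synthetic) to a results
#' bundle on disk: input validation, recognition scoring, dual-coder recall
#' reconciliation and reliability, the positive emotional memory bias
#' composite, the factorial ANOVAs (bias 2x2; recognition measures 2x2x3;
#' recall counts 2x2x3x2), and the mediation models (condition ->
#' post-intervention amygdala-mPFC connectivity -> bias, always controlling
#' for pre-intervention connectivity, optionally also for mood and RMSSD
#' change). Every stage logs the participants excluded and why; all
#' resampling is driven by the configured seed, so two runs with the same
#' config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `bias_scores`, `mediation` (one
#'   `mediation_result` per covariate set), `anova_tables`, `reliability`,
#'   and `manifest`. Writes `bias_scores.csv`, `mediation.json`,
#'   `anova_tables.csv`, `reliability.json`, and `manifest.json` to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config")
  }
  report <- validate_inputs(config$paths)
  if (!all(report$pass)) {
    bad <- report[!report$pass, ]
    stop("input validation failed: ", bad$file[1L], ": ", bad$message[1L])
  }
  rd <- function(nm) utils::read.csv(config$paths[[nm]],
                                     stringsAsFactors = FALSE)
  participants <- rd("participants")
  recognition <- rd("recognition")
  recall_coding <- rd("recall_coding")
  connectivity <- rd("connectivity")
  covariates <- rd("covariates")
  valence_map <- rd("valence_map")

  exclusions <- data.frame(participant_id = character(0),
                           stage = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  note_excluded <- function(ids, stage, reason) {
    if (!length(ids)) return()
    exclusions <<- rbind(exclusions, data.frame(
      participant_id = ids, stage = stage, reason = reason,
      stringsAsFactors = FALSE))
  }

  ## --- recognition scoring -------------------------------------------
  rec_ok <- .complete_recognition_ids(recognition)
  note_excluded(setdiff(participants$participant_id, rec_ok),
                "recognition", "incomplete_recognition_trials")
  rates <- compute_recognition_rates(
    recognition[recognition$participant_id %in% rec_ok, ])

  ## --- recall: reconcile, reliability, tally per week ----------------
  weeks <- sort(unique(recall_coding$week))
  reliability <- list()
  tallies <- list()
  for (i in seq_along(weeks)) {
    w <- weeks[i]
    sub <- recall_coding[recall_coding$week == w, ]
    coders <- sort(unique(sub$coder_id))
    rel <- bootstrap_alpha_ci(coding_matrix(sub), n_boot = 1000,
                              level = config$ci_level,
                              seed = config$seed + i)
    reliability[[paste0("week", w)]] <- rel
    merged <- reconcile_coders(sub[sub$coder_id == coders[1L], ],
                               sub[sub$coder_id == coders[2L], ])$merged
    tallies[[paste0("week", w)]] <- tally_recall(merged, valence_map)
  }

  ## --- bias composite (final-week false alarms + final-week recall) --
  wk_final <- paste0("week", max(weeks))
  tally_final <- tallies[[wk_final]]
  fa_wide <- stats::reshape(
    rates[c("participant_id", "valence", "fa_rate")],
    idvar = "participant_id", timevar = "valence", direction = "wide")
  comp <- merge(
    data.frame(participant_id = fa_wide$participant_id,
               fa_pos = fa_wide$fa_rate.positive,
               fa_neg = fa_wide$fa_rate.negative,
               stringsAsFactors = FALSE),
    data.frame(participant_id = tally_final$participant_id,
               rec_pos = tally_final$correct_positive,
               rec_neg = tally_final$correct_negative,
               stringsAsFactors = FALSE),
    by = "participant_id"
  )
  note_excluded(setdiff(rec_ok, comp$participant_id), "bias",
                "missing_final_week_recall")
  note_excluded(setdiff(tally_final$participant_id, comp$participant_id),
                "bias", "missing_recognition_rates")
  bias_scores <- compute_bias_scores(comp)

  ## --- ANOVAs ---------------------------------------------------------
  demo <- participants[c("participant_id", "condition", "age_group")]
  anova_tables <- list()
  add_anova <- function(label, tab) {
    tab <- as.data.frame(tab)
    tab <- cbind(analysis = label, tab, stringsAsFactors = FALSE)
    anova_tables[[length(anova_tables) + 1L]] <<- tab
  }
  bias_dat <- merge(bias_scores, demo, by = "participant_id")
  add_anova("bias_condition_age", fit_mixed_anova(
    bias_dat, dv = "bias", id = "participant_id",
    between = c("condition", "age_group")))
  rate_dat <- merge(rates, demo, by = "participant_id")
  for (measure in c("fa_rate", "hit_rate", "corrected_recognition")) {
    add_anova(paste0(measure, "_condition_age_valence"), fit_mixed_anova(
      rate_dat, dv = measure, id = "participant_id",
      between = c("condition", "age_group"), within = "valence"))
  }
  if (length(weeks) >= 2L) {
    long <- do.call(rbind, lapply(names(tallies), function(wk) {
      t_w <- tallies[[wk]]
      do.call(rbind, lapply(.VALENCES, function(v) {
        data.frame(participant_id = t_w$participant_id, week = wk,
                   valence = v,
                   count = t_w[[paste0("correct_", v)]],
                   stringsAsFactors = FALSE)
      }))
    }))
    in_all <- Reduce(intersect, lapply(tallies,
                                       function(t) t$participant_id))
    note_excluded(setdiff(unique(long$participant_id), in_all),
                  "recall_anova", "missing_a_recall_week")
    long <- merge(long[long$participant_id %in% in_all, ], demo,
                  by = "participant_id")
    add_anova("recall_condition_age_valence_week", fit_mixed_anova(
      long, dv = "count", id = "participant_id",
      between = c("condition", "age_group"),
      within = c("valence", "week")))
  }
  anova_out <- do.call(rbind, anova_tables)
  rownames(anova_out) <- NULL

  ## --- mediation ------------------------------------------------------
  med_dat <- merge(merge(merge(bias_scores[c("participant_id", "bias")],
                               demo, by = "participant_id"),
                         connectivity, by = "participant_id"),
                   covariates, by = "participant_id")
  note_excluded(setdiff(bias_scores$participant_id,
                        med_dat$participant_id),
                "mediation", "missing_connectivity_or_covariates")
  x <- as.numeric(med_dat$condition == "OscMinus")
  cov_sets <- c(list(character(0)), as.list(config$covariates))
  mediation <- list()
  for (j in seq_along(cov_sets)) {
    extra <- cov_sets[[j]]
    cmat <- as.matrix(med_dat[c("pre_beta", extra)])
    label <- paste(c("pre_beta", extra), collapse = "+")
    mediation[[label]] <- fit_model4(
      x = x, m = med_dat$post_beta, y = med_dat$bias, covariates = cmat,
      n_boot = config$n_boot, level = config$ci_level,
      seed = config$seed + 100L + j)
  }

  ## --- outputs --------------------------------------------------------
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)
  utils::write.csv(bias_scores, outp("bias_scores.csv"), row.names = FALSE)
  utils::write.csv(anova_out, outp("anova_tables.csv"), row.names = FALSE)
  med_json <- lapply(mediation, function(m) {
    list(paths = m$paths, n = m$n, n_boot = m$n_boot, level = m$level,
         seed = m$seed, covariate_names = m$covariate_names,
         n_redraws = m$n_redraws)
  })
  jsonlite::write_json(med_json, outp("mediation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  rel_json <- lapply(reliability, function(r) {
    list(alpha = r$alpha, ci_low = r$ci_low, ci_high = r$ci_high,
         n_boot = r$n_boot, n_degenerate = r$n_degenerate,
         level = r$level, seed = r$seed)
  })
  jsonlite::write_json(rel_json, outp("reliability.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config = list(paths = config$paths, n_boot = config$n_boot,
                  ci_level = config$ci_level, seed = config$seed,
                  covariates = config$covariates,
                  out_dir = config$out_dir),
    n = c(list(participants = nrow(participants),
               recognition = length(unique(rates$participant_id)),
               bias = nrow(bias_scores),
               mediation = mediation[[1L]]$n),
          stats::setNames(
            lapply(tallies, nrow),
            paste0("recall_", names(tallies)))),
    exclusions = exclusions
  )
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(bias_scores = bias_scores, mediation = mediation,
                 anova_tables = anova_out, reliability = reliability,
                 manifest = manifest))
}
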