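#' Specification for a synthetic biofeedback-trial cohort
#'
#' Collects the ground-truth parameters of the generative model used by
#' [generate_cohort()]. The design mirrors a two-arm randomized
#' biofeedback trial with two age groups: condition is coded
#' `OscPlus = 0`, `OscMinus = 1`, pre-intervention connectivity is
#' standard normal, post-intervention connectivity is
#' `rho_pre * pre + true_a * x + Normal(0, sigma_m)`, and a latent bias
#' score is `true_c_prime * x + true_b * post + Normal(0, sigma_y)`
#' (plus `oa_offset` for older adults). The latent drives valence-specific
#' memory behavior: hit/false-alarm probabilities are shifted by
#' `+/- bias_gain * latent` on the logit scale (positive valence up,
#' negative down) and expected recall counts by the same amount on the
#' log scale. On the latent (linear) outcome scale, the true indirect
#' effect of condition is exactly `true_a * true_b`.
#'
#' @param n_per_cell Participants per condition x age-group cell (>= 2).
#' @param true_a Condition -> post-connectivity path (beta units).
#' @param true_b Post-connectivity -> latent-bias path.
#' @param true_c_prime Direct condition -> latent-bias path.
#' @param rho_pre Pre/post connectivity autocorrelation in `[0, 1]`.
#' @param sigma_m,sigma_y Noise standard deviations (> 0) of the mediator
#'   and latent-outcome equations.
#' @param base_fa,base_hit Baseline false-alarm and hit probabilities per
#'   valence, in (0, 1); a scalar or a length-3 vector
#'   (neutral, positive, negative).
#' @param base_recall_rate Expected correct recall counts per valence at
#'   each test, a named length-2 vector `c(week4 =, week5 =)` with values
#'   in (0, 12).
#' @param bias_gain Scale mapping the latent bias to valence-probability
#'   shifts (>= 0).
#' @param coder_disagreement Probability in `[0, 1)` that the second coder
#'   records a different code for an item.
#' @param cov_mood_sd,cov_rmssd_sd Noise scales of the mood-change and
#'   RMSSD-change covariates (> 0).
#' @param oa_offset Additive latent-bias offset for older adults
#'   (default 0: no age truth).
#' @param incorrect_recall_rate Expected number of recall descriptions per
#'   participant per week that match no studied picture.
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_per_cell = 40,
                        true_a = -0.35,
                        true_b = 0.45,
                        true_c_prime = -0.28,
                        rho_pre = 0.5,
                        sigma_m = 0.85,
                        sigma_y = 1,
                        base_fa = 0.055,
                        base_hit = 0.86,
                        base_recall_rate = c(week4 = 4.0, week5 = 1.75),
                        bias_gain = 0.25,
                        coder_disagreement = 0.04,
                        cov_mood_sd = 1,
                        cov_rmssd_sd = 10,
                        oa_offset = 0,
                        incorrect_recall_rate = 2,
                        seed = 1L) {
  expand3 <- function(v, nm) {
    if (length(v) == 1L) v <- rep(v, 3L)
    if (length(v) != 3L) stop("`", nm, "` must have length 1 or 3")
    stats::setNames(as.numeric(v), .VALENCES)
  }
  base_fa <- expand3(base_fa, "base_fa")
  base_hit <- expand3(base_hit, "base_hit")
  if (length(base_recall_rate) != 2L) {
    stop("`base_recall_rate` must have length 2 (week4, week5)")
  }
  base_recall_rate <- stats::setNames(as.numeric(base_recall_rate),
                                      c("week4", "week5"))
  spec <- structure(
    list(n_per_cell = as.integer(n_per_cell), true_a = true_a,
         true_b = true_b, true_c_prime = true_c_prime, rho_pre = rho_pre,
         sigma_m = sigma_m, sigma_y = sigma_y, base_fa = base_fa,
         base_hit = base_hit, base_recall_rate = base_recall_rate,
         bias_gain = bias_gain, coder_disagreement = coder_disagreement,
         cov_mood_sd = cov_mood_sd, cov_rmssd_sd = cov_rmssd_sd,
         oa_offset = oa_offset,
         incorrect_recall_rate = incorrect_recall_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks every invariant of the generative parameters; the error message
#' names the offending field.
#'
#' @param spec A `cohort_spec` (or a plain list with the same fields).
#' @return The spec, invisibly, if valid.
#' @export
validate_cohort_spec <- function(spec) {
  fail <- function(field, why) {
    stop("invalid cohort spec: field `", field, "` ", why, call. = FALSE)
  }
  num1 <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  if (!is.numeric(spec$n_per_cell) || length(spec$n_per_cell) != 1L ||
      is.na(spec$n_per_cell) || spec$n_per_cell < 2) {
    fail("n_per_cell", "must be a single count >= 2")
  }
  for (f in c("true_a", "true_b", "true_c_prime", "oa_offset")) num1(f)
  if (num1("rho_pre") < 0 || spec$rho_pre > 1) {
    fail("rho_pre", "must be in [0, 1]")
  }
  if (num1("sigma_m") <= 0) fail("sigma_m", "must be > 0")
  if (num1("sigma_y") <= 0) fail("sigma_y", "must be > 0")
  for (f in c("base_fa", "base_hit")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 3L || any(v <= 0) || any(v >= 1)) {
      fail(f, "must be three probabilities in (0, 1)")
    }
  }
  v <- spec$base_recall_rate
  if (!is.numeric(v) || length(v) != 2L || any(v <= 0) || any(v > 12)) {
    fail("base_recall_rate", "must be two rates in (0, 12]")
  }
  if (num1("bias_gain") < 0) fail("bias_gain", "must be >= 0")
  if (num1("coder_disagreement") < 0 || spec$coder_disagreement >= 1) {
    fail("coder_disagreement", "must be in [0, 1)")
  }
  if (num1("cov_mood_sd") <= 0) fail("cov_mood_sd", "must be > 0")
  if (num1("cov_rmssd_sd") <= 0) fail("cov_rmssd_sd", "must be > 0")
  if (num1("incorrect_recall_rate") < 0) {
    fail("incorrect_recall_rate", "must be >= 0")
  }
  if (!is.numeric(spec$seed) || length(spec$seed) != 1L ||
      is.na(spec$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(spec)
}

# studied ("old") items are the week-4 viewing set; lures are "new"
.item_ids <- function(status) {
  unlist(lapply(.VALENCES, function(v) {
    sprintf("%s_%s_%02d", substr(v, 1, 3), status, 1:12)
  }))
}
.N_UNMATCHED <- 8L

#' Generate a synthetic biofeedback-trial cohort
#'
#' Draws a complete synthetic dataset -- participants, trial-level
#' recognition responses, dual-coder recall codings for both test weeks,
#' pre/post connectivity betas, and covariates -- from the generative model
#' described in [cohort_spec()]. Every participant has exactly 72
#' recognition trials (36 old, 36 new; 12 per valence per status). The
#' second coder's coding is the first coder's with each item code changed
#' with probability `coder_disagreement`; recalled-twice codes (2) occur
#' with a fixed small probability of 0.01 per recalled item.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list of data frames
#'   `participants`, `recognition_trials`, `recall_codings`,
#'   `connectivity`, `covariates`, `valence_map`, the ground-truth
#'   `latent` scores (with the week-specific true recall lambdas), and
#'   `truth` (the spec echoed back).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- 4L * spec$n_per_cell
  cells <- expand.grid(condition = .CONDITIONS, age_group = .AGE_GROUPS,
                       stringsAsFactors = FALSE)
  condition <- rep(cells$condition, each = spec$n_per_cell)
  age_group <- rep(cells$age_group, each = spec$n_per_cell)
  pid <- sprintf("P%04d", seq_len(n))
  x <- as.numeric(condition == "OscMinus")

  age <- ifelse(age_group == "YA", round(stats::runif(n, 18, 35)),
                round(stats::runif(n, 55, 80)))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  years_education <- pmin(pmax(round(stats::rnorm(n, 16, 2)), 12), 25)

  pre <- stats::rnorm(n)
  post <- spec$rho_pre * pre + spec$true_a * x +
    stats::rnorm(n, 0, spec$sigma_m)
  latent <- spec$true_c_prime * x + spec$true_b * post +
    spec$oa_offset * (age_group == "OA") +
    stats::rnorm(n, 0, spec$sigma_y)

  participants <- data.frame(
    participant_id = pid, condition = condition, age_group = age_group,
    age = age, sex = sex, years_education = years_education,
    stringsAsFactors = FALSE
  )

  # recognition trials (week 5 test): item-level Bernoulli draws whose
  # per-cell sums are the binomial counts over 12 items per cell
  sgn <- c(neutral = 0, positive = 1, negative = -1)
  old_items <- .item_ids("old")
  new_items <- .item_ids("new")
  rec <- data.frame(
    participant_id = rep(pid, each = 72L),
    item_id = rep(c(old_items, new_items), times = n),
    valence = rep(rep(.VALENCES, each = 12L), times = 2L * n),
    status = rep(rep(.STATUSES, each = 36L), times = n),
    stringsAsFactors = FALSE
  )
  lat_row <- rep(latent, each = 72L)
  shift <- spec$bias_gain * sgn[rec$valence] * lat_row
  base <- ifelse(rec$status == "old", spec$base_hit[rec$valence],
                 spec$base_fa[rec$valence])
  p_old_resp <- stats::plogis(stats::qlogis(base) + shift)
  called_old <- stats::rbinom(nrow(rec), 1L, p_old_resp) == 1L
  # Remember/Know split of "old" responses: recollection dominates hits,
  # familiarity dominates false alarms
  p_rem <- ifelse(rec$status == "old", 0.65, 1 / 3)
  remember <- called_old & stats::rbinom(nrow(rec), 1L, p_rem) == 1L
  rec$response <- ifelse(!called_old, "new",
                         ifelse(remember, "remember", "know"))

  # recall codings, weeks 4 and 5; units are the 36 studied items plus
  # sentinel slots for unmatched (incorrect) descriptions
  lam <- lapply(c(week4 = "week4", week5 = "week5"), function(w) {
    outer(latent, sgn[.VALENCES], function(l, s) {
      spec$base_recall_rate[w] * exp(spec$bias_gain * s * l)
    })
  })
  unmatched_items <- sprintf("unmatched_%02d", seq_len(.N_UNMATCHED))
  codings <- list()
  for (w in c(4L, 5L)) {
    lam_w <- lam[[paste0("week", w)]]
    counts <- matrix(pmin(stats::rpois(n * 3L, lam_w), 12L), n, 3L)
    # mark `count` randomly-chosen studied items per cell as recalled
    u <- stats::runif(n * 36L)
    cell_id <- rep(seq_len(n * 3L), each = 12L)
    rank_in_cell <- stats::ave(u, cell_id, FUN = rank)
    code <- as.integer(rank_in_cell <= rep(as.vector(t(counts)),
                                           each = 12L))
    two <- code == 1L & stats::runif(n * 36L) < 0.01
    code[two] <- 2L
    n_inc <- pmin(stats::rpois(n, spec$incorrect_recall_rate),
                  .N_UNMATCHED)
    inc_code <- as.integer(
      rep(seq_len(.N_UNMATCHED), times = n) <= rep(n_inc,
                                                   each = .N_UNMATCHED))
    coding_a <- data.frame(
      coder_id = "coder1", week = w,
      participant_id = c(rep(pid, each = 36L), rep(pid, each = .N_UNMATCHED)),
      item_id = c(rep(old_items, times = n), rep(unmatched_items, times = n)),
      code = c(code, inc_code),
      stringsAsFactors = FALSE
    )
    flip <- stats::runif(nrow(coding_a)) < spec$coder_disagreement
    code_b <- coding_a$code
    code_b[flip] <- ifelse(coding_a$code[flip] == 0L, 1L,
                           ifelse(coding_a$code[flip] == 1L, 0L, 1L))
    coding_b <- coding_a
    coding_b$coder_id <- "coder2"
    coding_b$code <- code_b
    codings[[length(codings) + 1L]] <- coding_a
    codings[[length(codings) + 1L]] <- coding_b
  }
  recall_codings <- do.call(rbind, codings)

  connectivity <- data.frame(participant_id = pid, pre_beta = pre,
                             post_beta = post, stringsAsFactors = FALSE)
  covariates <- data.frame(
    participant_id = pid,
    mood_change = stats::rnorm(n, 0, spec$cov_mood_sd),
    rmssd_change = stats::rnorm(n, 0, spec$cov_rmssd_sd),
    rmssd_baseline = pmax(stats::rnorm(n, 45, 15), 5),
    stringsAsFactors = FALSE
  )
  valence_map <- data.frame(
    item_id = c(old_items, unmatched_items),
    valence = c(rep(.VALENCES, each = 12L),
                rep("incorrect", .N_UNMATCHED)),
    stringsAsFactors = FALSE
  )
  structure(
    list(participants = participants, recognition_trials = rec,
         recall_codings = recall_codings, connectivity = connectivity,
         covariates = covariates, valence_map = valence_map,
         latent = data.frame(participant_id = pid, latent_bias = latent,
                             stringsAsFactors = FALSE),
         truth = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$participants)
  cat("Synthetic biofeedback-trial cohort: ", n, " participants (",
      x$truth$n_per_cell, " per condition x age cell), ",
      nrow(x$recognition_trials), " recognition trials, ",
      nrow(x$recall_codings), " recall coding rows\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes the pipeline input schemas (`participants.csv`,
#' `recognition.csv`, `recall_coding.csv`, `connectivity.csv`,
#' `covariates.csv`, `valence_map.csv`) plus a `truth.json` sidecar
#' echoing the generating [cohort_spec()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must be a synthetic_cohort")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    participants = "participants.csv", recognition = "recognition.csv",
    recall_coding = "recall_coding.csv", connectivity = "connectivity.csv",
    covariates = "covariates.csv", valence_map = "valence_map.csv"
  )
  tables <- list(cohort$participants, cohort$recognition_trials,
                 cohort$recall_codings, cohort$connectivity,
                 cohort$covariates, cohort$valence_map)
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  for (i in seq_along(paths)) {
    utils::write.csv(tables[[i]], paths[i], row.names = FALSE)
  }
  truth <- unclass(cohort$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, truth = file.path(dir, "truth.json")))
}
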