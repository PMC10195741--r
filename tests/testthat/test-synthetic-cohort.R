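test_that("identical specs generate identical cohorts", {
  s <- cohort_spec(n_per_cell = 6, seed = 123)
  expect_identical(generate_cohort(s), generate_cohort(s))
})

test_that("every participant has a balanced 72-trial recognition design", {
  coh <- generate_cohort(cohort_spec(n_per_cell = 5, seed = 2))
  tr <- coh$recognition_trials
  counts <- table(tr$participant_id, tr$valence, tr$status)
  expect_true(all(counts == 12))
  expect_equal(nrow(tr), nrow(coh$participants) * 72)
  key <- paste(tr$participant_id, tr$item_id)
  expect_false(anyDuplicated(key) > 0)
})

test_that("coders are identical when disagreement is zero and share index sets", {
  coh <- generate_cohort(cohort_spec(n_per_cell = 5, seed = 3,
                                     coder_disagreement = 0))
  for (w in c(4, 5)) {
    sub <- coh$recall_codings[coh$recall_codings$week == w, ]
    m <- coding_matrix(sub)
    expect_false(anyNA(m))
    expect_identical(m["coder1", ], m["coder2", ])
  }
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n_per_cell = 1), "n_per_cell")
  expect_error(cohort_spec(rho_pre = 1.4), "rho_pre")
  expect_error(cohort_spec(sigma_m = 0), "sigma_m")
  expect_error(cohort_spec(base_fa = 1.2), "base_fa")
  expect_error(cohort_spec(coder_disagreement = 1), "coder_disagreement")
  expect_error(cohort_spec(base_recall_rate = c(4, 13)),
               "base_recall_rate")
})

test_that("a null condition->connectivity path leaves them uncorrelated", {
  coh <- generate_cohort(cohort_spec(n_per_cell = 2000, true_a = 0,
                                     seed = 11))
  x <- as.numeric(coh$participants$condition == "OscMinus")
  expect_lt(abs(cor(x, coh$connectivity$post_beta)), 0.05)
})

test_that("with no bias gain, empirical false alarms track the base rate", {
  coh <- generate_cohort(cohort_spec(n_per_cell = 500, base_fa = 0.05,
                                     bias_gain = 0, seed = 21))
  tr <- coh$recognition_trials
  lure <- tr[tr$status == "new", ]
  fa <- tapply(lure$response != "new", lure$valence, mean)
  # binomial sampling bound: 2000 * 12 lures per valence; sd ~ 0.0014,
  # so [0.04, 0.06] is a > 7-sigma window around 0.05
  expect_true(all(fa > 0.04 & fa < 0.06))
})

test_that("the latent ground truth has the configured linear structure", {
  spec <- cohort_spec(n_per_cell = 3000, true_a = 0.5, true_b = 0.6,
                      true_c_prime = -0.2, seed = 31)
  coh <- generate_cohort(spec)
  x <- as.numeric(coh$participants$condition == "OscMinus")
  fit <- fit_model4(x, coh$connectivity$post_beta,
                    coh$latent$latent_bias,
                    covariates = cbind(pre = coh$connectivity$pre_beta),
                    n_boot = 0)
  est <- setNames(fit$paths$estimate, fit$paths$path)
  # n = 12000: estimates should sit close to the generating paths
  expect_equal(est[["a"]], 0.5, tolerance = 0.1)
  expect_equal(est[["b"]], 0.6, tolerance = 0.1)
  expect_equal(est[["ab"]], 0.3, tolerance = 0.1)
})

test_that("full behavioral pipeline recovers the sign of strong indirect effects", {
  # scoring -> bias composite -> mediation on the behavioral (logit/log)
  # outcome; the fitted ab is on the composite scale but its sign must
  # agree with true_a * true_b when the true indirect effect is strong
  n_rep <- 100
  hits <- 0
  for (i in seq_len(n_rep)) {
    spec <- cohort_spec(n_per_cell = 250, true_a = 0.7, true_b = 0.5,
                        true_c_prime = 0.1, seed = 5000 + i)
    coh <- generate_cohort(spec)
    rates <- compute_recognition_rates(coh$recognition_trials)
    wk5 <- coh$recall_codings[coh$recall_codings$week == 5, ]
    merged <- reconcile_coders(wk5[wk5$coder_id == "coder1", ],
                               wk5[wk5$coder_id == "coder2", ])$merged
    tally <- tally_recall(merged, coh$valence_map)
    fa <- rates[rates$valence == "positive", c("participant_id", "fa_rate")]
    names(fa)[2] <- "fa_pos"
    fa$fa_neg <- rates$fa_rate[rates$valence == "negative"]
    comp <- merge(fa, data.frame(
      participant_id = tally$participant_id,
      rec_pos = tally$correct_positive,
      rec_neg = tally$correct_negative), by = "participant_id")
    bias <- compute_bias_scores(comp)
    dat <- merge(merge(bias, coh$participants, by = "participant_id"),
                 coh$connectivity, by = "participant_id")
    fit <- fit_model4(as.numeric(dat$condition == "OscMinus"),
                      dat$post_beta, dat$bias,
                      covariates = cbind(pre = dat$pre_beta), n_boot = 0)
    ab <- fit$paths$estimate[fit$paths$path == "ab"]
    if (sign(ab) == sign(0.7 * 0.5)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
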