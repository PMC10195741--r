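make_2b3w_data <- function(seed = 3, n_per_group = 4) {
  set.seed(seed)
  d <- expand.grid(id = sprintf("s%02d", seq_len(2 * n_per_group)),
                   w = c("w1", "w2", "w3"), stringsAsFactors = FALSE)
  d$g <- rep(rep(c("g1", "g2"), each = n_per_group), times = 3)
  d$dv <- rnorm(nrow(d)) + as.numeric(factor(d$w)) / 2 +
    (d$g == "g2") * 0.8
  d
}

test_that("balanced 2x3 mixed ANOVA matches the cell-means oracle", {
  d <- make_2b3w_data()
  tab <- fit_mixed_anova(d, "dv", "id", between = "g", within = "w")
  o <- oracle_mixed_anova_1b1w(d$dv, d$id, d$g, d$w)
  get <- function(e, col) tab[tab$effect == e, col]
  expect_equal(get("g", "ss_effect"), o$ss[["g"]], tolerance = 1e-8)
  expect_equal(get("g", "ss_error"), o$ss[["err_b"]], tolerance = 1e-8)
  expect_equal(get("w", "ss_effect"), o$ss[["w"]], tolerance = 1e-8)
  expect_equal(get("g:w", "ss_effect"), o$ss[["gw"]], tolerance = 1e-8)
  expect_equal(get("w", "ss_error"), o$ss[["err_w"]], tolerance = 1e-8)
  expect_equal(get("g", "df_effect"), o$df[["g"]])
  expect_equal(get("g", "df_error"), o$df[["err_b"]])
  expect_equal(get("w", "df_effect"), o$df[["w"]])
  expect_equal(get("w", "df_error"), o$df[["err_w"]])
  f_g <- (o$ss[["g"]] / o$df[["g"]]) / (o$ss[["err_b"]] / o$df[["err_b"]])
  expect_equal(get("g", "F"), f_g, tolerance = 1e-8)
})

test_that("mixed ANOVA agrees with stats::aov error strata on balanced data", {
  d <- make_2b3w_data(seed = 19, n_per_group = 5)
  tab <- fit_mixed_anova(d, "dv", "id", between = "g", within = "w")
  av <- summary(stats::aov(dv ~ g * w + Error(id / w), data = d))
  b_strat <- av[["Error: id"]][[1]]
  w_strat <- av[["Error: id:w"]][[1]]
  expect_equal(tab[tab$effect == "g", "F"], b_strat["g", "F value"],
               tolerance = 1e-10)
  expect_equal(tab[tab$effect == "w", "F"], w_strat["w", "F value"],
               tolerance = 1e-10)
  expect_equal(tab[tab$effect == "g:w", "F"], w_strat["g:w", "F value"],
               tolerance = 1e-10)
})

test_that("adding a constant to the dv leaves all F statistics unchanged", {
  d <- make_2b3w_data(seed = 6)
  t1 <- fit_mixed_anova(d, "dv", "id", between = "g", within = "w")
  d$dv <- d$dv + 1000
  t2 <- fit_mixed_anova(d, "dv", "id", between = "g", within = "w")
  expect_equal(t1$F, t2$F, tolerance = 1e-7)
})

test_that("a constant dv yields zero effects with the degenerate flag", {
  d <- make_2b3w_data()
  d$dv <- 5
  tab <- fit_mixed_anova(d, "dv", "id", between = "g", within = "w")
  expect_true(all(tab$ss_effect == 0))
  expect_true(all(tab$F == 0))
  expect_true(all(tab$partial_eta_sq == 0))
  expect_true(attr(tab, "degenerate_error"))
})

test_that("permuting participant labels leaves the table unchanged", {
  d <- make_2b3w_data(seed = 10)
  t1 <- fit_mixed_anova(d, "dv", "id", between = "g", within = "w")
  relab <- setNames(sample(unique(d$id)), unique(d$id))
  d2 <- d
  d2$id <- unname(relab[d$id])
  t2 <- fit_mixed_anova(d2, "dv", "id", between = "g", within = "w")
  expect_equal(t1$ss_effect, t2$ss_effect, tolerance = 1e-10)
  expect_equal(t1$F, t2$F, tolerance = 1e-10)
})

test_that("four-factor mixed designs carry the expected error strata dfs", {
  set.seed(44)
  n <- c(7, 5, 6, 8) # unbalanced between cells
  subj <- data.frame(
    id = sprintf("u%02d", seq_len(sum(n))),
    cond = rep(c("A", "A", "B", "B"), n),
    age = rep(c("Y", "O", "Y", "O"), n), stringsAsFactors = FALSE)
  d <- merge(merge(subj, data.frame(v = c("neu", "pos", "neg"))),
             data.frame(t = c("t1", "t2")))
  d$dv <- rnorm(nrow(d)) + (d$v == "pos") * 0.5 + (d$t == "t2") * -1
  tab <- fit_mixed_anova(d, "dv", "id", between = c("cond", "age"),
                         within = c("v", "t"))
  ns <- sum(n)
  expect_setequal(
    tab$effect,
    c("cond", "age", "cond:age",
      "v", "cond:v", "age:v", "cond:age:v",
      "t", "cond:t", "age:t", "cond:age:t",
      "v:t", "cond:v:t", "age:v:t", "cond:age:v:t"))
  expect_equal(tab[tab$effect == "cond", "df_error"], ns - 4)
  expect_equal(tab[tab$effect == "v", "df_error"], (ns - 4) * 2)
  expect_equal(tab[tab$effect == "t", "df_error"], ns - 4)
  expect_equal(tab[tab$effect == "v:t", "df_error"], (ns - 4) * 2)
  expect_true(all(tab$ss_effect >= 0))
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
  # grand total within stratum: effect + error SS partition is additive
  expect_true(all(is.finite(tab$F)))
})

test_that("mixed ANOVA validates design completeness", {
  d <- make_2b3w_data()
  expect_error(fit_mixed_anova(d[-1, ], "dv", "id", between = "g",
                               within = "w"), "exactly one observation")
  d_bad <- d
  d_bad$g[d_bad$id == "s01" & d_bad$w == "w2"] <- "g2"
  expect_error(fit_mixed_anova(d_bad, "dv", "id", between = "g",
                               within = "w"), "varies within")
})

test_that("partial eta squared follows its closed form", {
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_equal(partial_eta_squared(5, 0), 1)
  expect_equal(partial_eta_squared(2, 6), 0.25)
  expect_error(partial_eta_squared(0, 0), "both")
  expect_error(partial_eta_squared(-1, 2), ">= 0")
})

test_that("two-sample t matches the textbook pooled formula", {
  a <- c(1.2, 0.8, 1.9, 2.4, 0.3)
  b <- c(2.2, 1.4, 3.0, 2.8, 1.1)
  r <- two_sample_t(a, b)
  o <- oracle_pooled_t(a, b)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$df, o$df)
  expect_equal(r$p, o$p, tolerance = 1e-12)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- two_sample_t(c(1, 2, 3), c(1001, 1002, 1003))
  expect_gt(abs(far$t), 100)
  expect_lt(far$p, 1e-6)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "variance")
  # Welch flag changes df on heteroscedastic input
  w <- two_sample_t(c(1, 2, 3, 4), c(10, 30, 50, 90), welch = TRUE)
  expect_lt(w$df, 6)
})
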