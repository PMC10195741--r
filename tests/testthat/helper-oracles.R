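# Independent oracles used to freeze expected values. Each is a deliberately
# naive implementation (explicit normal equations, direct summation, cell
# means) kept separate from the package's own code paths.

# OLS by explicit normal equations with matrix inversion.
oracle_ols <- function(X, y) {
  X <- as.matrix(X)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coefficients = drop(beta), se = sqrt(diag(xtx_inv) * sigma2))
}

# Krippendorff's alpha by direct double summation over the coincidence
# matrix (nominal metric). codes: coders x units matrix.
oracle_alpha_nominal <- function(codes) {
  vals <- sort(unique(as.vector(codes[!is.na(codes)])))
  k <- length(vals)
  coin <- matrix(0, k, k)
  for (u in seq_len(ncol(codes))) {
    cu <- codes[, u]
    cu <- cu[!is.na(cu)]
    m <- length(cu)
    if (m < 2) next
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        a <- match(cu[i], vals)
        b <- match(cu[j], vals)
        coin[a, b] <- coin[a, b] + 1 / (m - 1)
      }
    }
  }
  n_c <- rowSums(coin)
  n <- sum(n_c)
  d_o <- 0
  d_e <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      d_o <- d_o + coin[a, b]
      d_e <- d_e + n_c[a] * n_c[b] / (n - 1)
    }
  }
  1 - d_o / d_e
}

# z-scores by direct summation.
oracle_z <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  (x - m) / s
}

# Balanced one-between (g groups) x one-within (w levels) ANOVA by cell and
# marginal means; subjects must be equally many per group.
oracle_mixed_anova_1b1w <- function(dv, subject, group, wfac) {
  subject <- as.factor(subject)
  group <- as.factor(group)
  wfac <- as.factor(wfac)
  w <- nlevels(wfac)
  gm <- mean(dv)
  m_subj <- tapply(dv, subject, mean)
  subj_group <- tapply(as.character(group), subject, function(v) v[1])
  m_grp <- tapply(dv, group, mean)
  m_w <- tapply(dv, wfac, mean)
  m_gw <- tapply(dv, list(group, wfac), mean)
  n_g <- table(subj_group)[levels(group)]

  ss_subj <- w * sum((m_subj - gm)^2)
  ss_g <- w * sum(n_g * (m_grp - gm)^2)
  ss_err_b <- ss_subj - ss_g
  ss_w <- sum(table(wfac) * (m_w - gm)^2)
  ss_gw <- 0
  for (g in levels(group)) {
    for (lv in levels(wfac)) {
      ss_gw <- ss_gw + n_g[g] *
        (m_gw[g, lv] - m_grp[g] - m_w[lv] + gm)^2
    }
  }
  ss_err_w <- 0
  for (s in levels(subject)) {
    g <- subj_group[s]
    for (lv in levels(wfac)) {
      y <- dv[subject == s & wfac == lv]
      ss_err_w <- ss_err_w +
        (y - m_subj[s] - m_gw[g, lv] + m_grp[g])^2
    }
  }
  n_subj <- nlevels(subject)
  g_n <- nlevels(group)
  list(
    ss = c(g = unname(ss_g), err_b = unname(ss_err_b), w = unname(ss_w),
           gw = unname(ss_gw), err_w = unname(ss_err_w)),
    df = c(g = g_n - 1, err_b = n_subj - g_n, w = w - 1,
           gw = (g_n - 1) * (w - 1), err_w = (n_subj - g_n) * (w - 1))
  )
}

# Pooled-variance two-sample t by the textbook formula.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2, p = 2 * pt(-abs(tt), na + nb - 2))
}

# Brute-force recognition tally for one participant's trials.
oracle_recognition_tally <- function(trials, pid, v) {
  sub <- trials[trials$participant_id == pid & trials$valence == v, ]
  old <- sub[sub$status == "old", ]
  new <- sub[sub$status == "new", ]
  list(
    hit = sum(old$response %in% c("remember", "know")) / nrow(old),
    fa = sum(new$response %in% c("remember", "know")) / nrow(new),
    rem_hit = sum(old$response == "remember") / nrow(old),
    know_hit = sum(old$response == "know") / nrow(old),
    rem_fa = sum(new$response == "remember") / nrow(new),
    know_fa = sum(new$response == "know") / nrow(new)
  )
}

# A deterministic 72-trial recognition fixture with known per-cell counts.
make_recognition_fixture <- function(pid = "p1") {
  rows <- list()
  # per valence: old items -> 8 remember, 2 know, 2 new;
  # new items -> 1 remember, 2 know, 9 new
  for (v in c("neutral", "positive", "negative")) {
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pid,
      item_id = sprintf("%s_old_%02d", v, 1:12),
      valence = v, status = "old",
      response = c(rep("remember", 8), rep("know", 2), rep("new", 2)),
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = pid,
      item_id = sprintf("%s_new_%02d", v, 1:12),
      valence = v, status = "new",
      response = c("remember", rep("know", 2), rep("new", 9)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

make_coding <- function(codes, coder = "c1", week = 5,
                        pid = "p1") {
  data.frame(coder_id = coder, week = week, participant_id = pid,
             item_id = sprintf("it%02d", seq_along(codes)), code = codes,
             stringsAsFactors = FALSE)
}

# Fresh scratch directory under the session tempdir.
local_testdir <- function() {
  d <- tempfile("membias-test-")
  dir.create(d)
  d
}
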