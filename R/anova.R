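#' Partial eta-squared effect size
#'
#' `ss_effect / (ss_effect + ss_error)`, the proportion of effect-plus-error
#' variability attributable to the effect.
#'
#' @param ss_effect,ss_error Non-negative sums of squares (not both zero).
#' @return A proportion in `[0, 1]`.
#' @examples
#' partial_eta_squared(2, 6) # 0.25
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0) stop("sums of squares must be >= 0")
  if (ss_effect == 0 && ss_error == 0) {
    stop("ss_effect and ss_error cannot both be zero")
  }
  ss_effect / (ss_effect + ss_error)
}

#' Two-sample t test (pooled or Welch)
#'
#' Pooled-variance Student t with `df = n_a + n_b - 2` by default, matching
#' conventional reporting for balanced group contrasts; set `welch = TRUE`
#' for the unequal-variance version.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @param welch Use the Welch correction instead of pooling? Default FALSE.
#' @return List with `t`, `df`, and two-sided `p`.
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(group_a) + stats::var(group_b) == 0) {
    stop("zero pooled variance; t statistic undefined")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

# Orthonormal basis for a within factor with k levels: first column is the
# normalized constant, the rest span the contrast space.
.ortho_basis <- function(k) {
  q <- qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))
  list(const = q[, 1L, drop = FALSE], contrasts = q[, -1L, drop = FALSE])
}

# Residual sum of squares per column of a (possibly multi-column) response,
# under the model spanned by design columns `cols` of X.
.rss_cols <- function(x, cols, y) {
  if (length(cols) == 0L) return(colSums(y^2))
  colSums(qr.resid(qr(x[, cols, drop = FALSE]), y)^2)
}

#' Mixed-design factorial ANOVA with partial eta-squared
#'
#' Fits the classical univariate mixed-model ANOVA for up to two
#' between-subjects and two within-subjects factors, the workhorse design
#' of behavioral intervention studies (e.g. condition x age between, with
#' stimulus valence and/or test week within). The error term is
#' partitioned by within-subject stratum: between-subjects effects are
#' tested against subjects-within-groups error; each within effect (and
#' its crossings with between factors) against its own factor-by-subject
#' error. Each error stratum is isolated by projecting every subject's
#' responses onto an orthonormal contrast basis, and effects within a
#' stratum use Type III sums of squares from a sum-to-zero-coded
#' between-subjects model, so unbalanced group sizes are handled the way
#' mainstream commercial ANOVA software handles them. No sphericity
#' correction is applied.
#'
#' @param data Long-format data frame: one row per observation.
#' @param dv Name of the numeric dependent-variable column.
#' @param id Name of the participant identifier column.
#' @param between Character vector (0-2) of between-subjects factor
#'   columns.
#' @param within Character vector (0-2) of within-subjects factor columns.
#'   Every participant must have exactly one observation per combination
#'   of within-factor levels.
#' @return A data frame of class `anova_table` with one row per effect:
#'   `effect`, `ss_effect`, `df_effect`, `ss_error`, `df_error`, `F`, `p`,
#'   `partial_eta_sq`. If an error stratum has (numerically) zero error
#'   sum of squares the affected rows report `F = 0` (or `Inf`), `p = NA`
#'   and the table carries attribute `degenerate_error = TRUE`.
#' @export
fit_mixed_anova <- function(data, dv, id, between = character(0),
                            within = character(0)) {
  between <- as.character(between %||% character(0))
  within <- as.character(within %||% character(0))
  cols <- c(dv, id, between, within)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("data missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(between) > 2L || length(within) > 2L) {
    stop("at most 2 between- and 2 within-subjects factors are supported")
  }
  if (!is.numeric(data[[dv]])) stop("`", dv, "` must be numeric")
  if (anyNA(data[[dv]])) stop("missing dv values; exclude listwise upstream")

  sid <- factor(data[[id]])
  wfac <- lapply(within, function(f) factor(data[[f]]))
  names(wfac) <- within
  k_w <- vapply(wfac, nlevels, integer(1))

  # within-cell index, first factor slowest (matches kronecker() ordering)
  if (length(within) == 0L) {
    cell <- rep(1L, nrow(data))
    n_cells <- 1L
  } else if (length(within) == 1L) {
    cell <- as.integer(wfac[[1L]])
    n_cells <- k_w[1L]
  } else {
    cell <- (as.integer(wfac[[1L]]) - 1L) * k_w[2L] + as.integer(wfac[[2L]])
    n_cells <- k_w[1L] * k_w[2L]
  }
  counts <- table(sid, factor(cell, levels = seq_len(n_cells)))
  if (any(counts != 1L)) {
    offenders <- rownames(counts)[apply(counts != 1L, 1L, any)]
    stop("each participant needs exactly one observation per ",
         "within-factor cell; offending participant(s): ",
         paste(utils::head(offenders, 5L), collapse = ", "))
  }

  # subject-level between table (between factors must be constant per id)
  n_subj <- nlevels(sid)
  first <- match(levels(sid), sid)
  subj <- data.frame(row.names = seq_len(n_subj))
  for (f in between) {
    fv <- factor(data[[f]])
    if (any(tapply(as.integer(fv), sid,
                   function(v) length(unique(v))) != 1L)) {
      stop("between factor `", f, "` varies within a participant")
    }
    subj[[f]] <- fv[first]
  }
  if (length(between)) {
    cell_n <- table(subj)
    if (any(cell_n == 0L)) stop("empty between-subjects cell")
    if (any(cell_n < 2L)) {
      stop("need at least 2 participants per between-subjects cell")
    }
  }

  y_wide <- matrix(NA_real_, n_subj, n_cells)
  y_wide[cbind(as.integer(sid), cell)] <- data[[dv]]

  # between-subjects design, sum-to-zero coded, full factorial
  if (length(between)) {
    form <- stats::as.formula(paste("~", paste(between, collapse = "*")))
    contr <- stats::setNames(rep(list("contr.sum"), length(between)),
                             between)
    x_b <- stats::model.matrix(form, subj, contrasts.arg = contr)
    assign <- attr(x_b, "assign")
    term_labels <- attr(stats::terms(form), "term.labels")
  } else {
    x_b <- matrix(1, n_subj, 1L)
    assign <- 0L
    term_labels <- character(0)
  }
  p_b <- ncol(x_b)
  if (n_subj <= p_b) stop("too few participants for the between model")

  bases <- lapply(k_w, .ortho_basis)

  # strata: subsets of the within factors ("" = between stratum)
  strata <- list(character(0))
  if (length(within) >= 1L) strata <- c(strata, list(within[1L]))
  if (length(within) == 2L) {
    strata <- c(strata, list(within[2L]), list(within))
  }

  rows <- list()
  degenerate <- FALSE
  tol <- 1e-16 * max(1, sum(y_wide^2))
  qr_full <- qr(x_b)
  for (s in strata) {
    if (length(within) == 0L) {
      trans <- matrix(1, 1L, 1L)
    } else {
      parts <- lapply(within, function(f) {
        if (f %in% s) bases[[f]]$contrasts else bases[[f]]$const
      })
      trans <- if (length(parts) == 1L) parts[[1L]] else
        kronecker(parts[[1L]], parts[[2L]])
    }
    y_s <- y_wide %*% trans
    q_s <- ncol(y_s)
    rss_full <- colSums(qr.resid(qr_full, y_s)^2)
    ss_err <- sum(rss_full)
    df_err <- (n_subj - p_b) * q_s
    s_label <- paste(s, collapse = ":")

    terms_here <- if (length(s)) c(0L, seq_along(term_labels)) else
      seq_along(term_labels)
    for (a in terms_here) {
      keep <- which(assign != a)
      ss_eff <- sum(.rss_cols(x_b, keep, y_s)) - ss_err
      ss_eff <- max(ss_eff, 0)
      df_eff <- sum(assign == a) * q_s
      eff_name <- if (a == 0L) s_label else if (length(s) == 0L)
        term_labels[a] else paste(term_labels[a], s_label, sep = ":")
      if (ss_err <= tol) {
        degenerate <- TRUE
        if (ss_eff <= tol) {
          ss_eff <- 0
          f_val <- 0
          eta <- 0
        } else {
          f_val <- Inf
          eta <- 1
        }
        p_val <- NA_real_
      } else {
        f_val <- (ss_eff / df_eff) / (ss_err / df_err)
        p_val <- stats::pf(f_val, df_eff, df_err, lower.tail = FALSE)
        eta <- partial_eta_squared(ss_eff, ss_err)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff_name, ss_effect = ss_eff, df_effect = df_eff,
        ss_error = ss_err, df_error = df_err, F = f_val, p = p_val,
        partial_eta_sq = eta, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  attr(out, "degenerate_error") <- degenerate
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
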