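#' Fit a random-intercept linear mixed model
#'
#' The behavioral models share one structure: a per-path response (RA_path or
#' RT_path), one two-level fixed factor, and a random intercept for every
#' subject-by-dimensionality cell. The fixed factor is coded 1 for the
#' reference condition (early phase / Set 1 / exploration) and 0 for the
#' comparison, so the reported effect is reference minus comparison — a
#' negative RA effect means lower accuracy in the reference condition.
#' Fitting is by REML via `lmerTest`, with Satterthwaite degrees of freedom
#' for the Wald t test; if the Satterthwaite computation fails the normal
#' approximation is used and flagged in `df_method`.
#'
#' @param table Per-path data.frame with `subject` and `n_dims` columns.
#' @param response Response column name (`"RA_path"` or `"RT_path"`).
#' @param fixed_factor Column name of the two-level fixed factor.
#' @param reference_level Level coded 1 (effect = this level minus the other).
#' @return List of class `lmm_result`: `beta`, `se`, `t`, `df`, `p`,
#'   `random_variance`, `residual_variance`, `df_method`, `singular`,
#'   `n_obs`, `fit` (the underlying `lmerModLmerTest` object).
#' @export
fit_lmm <- function(table, response, fixed_factor, reference_level) {
  stopifnot(response %in% names(table), fixed_factor %in% names(table))
  lev <- unique(as.character(table[[fixed_factor]]))
  if (length(lev) < 2L) stop("fixed factor needs >= 2 levels, got ",
                             length(lev))
  d <- data.frame(
    y = table[[response]],
    x = as.numeric(as.character(table[[fixed_factor]]) ==
                     as.character(reference_level)),
    cell = interaction(table$subject, table$n_dims, drop = TRUE))
  if (nlevels(d$cell) < 2L) stop("need >= 2 subject x dimensionality cells")
  if (stats::var(d$y) == 0) {
    # constant response: no variance to model, effect is exactly zero
    return(structure(list(
      beta = 0, se = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
      random_variance = 0, residual_variance = 0, df_method = "degenerate",
      singular = TRUE, n_obs = nrow(d), fit = NULL), class = "lmm_result"))
  }
  fit <- suppressMessages(
    lmerTest::lmer(y ~ x + (1 | cell), data = d, REML = TRUE))
  co <- tryCatch(summary(fit)$coefficients,
                 error = function(e) NULL)
  df_method <- "satterthwaite"
  if (is.null(co) || !"df" %in% colnames(co) || !is.finite(co["x", "df"])) {
    # normal-approximation fallback
    co <- summary(fit, ddf = "lme4")$coefficients
    beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    tval <- beta / se
    df <- Inf
    p <- 2 * stats::pnorm(-abs(tval))
    df_method <- "normal"
  } else {
    beta <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    tval <- co["x", "t value"]; df <- co["x", "df"]
    p <- co["x", "Pr(>|t|)"]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    beta = unname(beta), se = unname(se), t = unname(tval), df = unname(df),
    p = unname(p),
    random_variance = vc$vcov[vc$grp == "cell"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    df_method = df_method, singular = lme4::isSingular(fit),
    n_obs = nrow(d), fit = fit), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("LMM fixed effect: beta = %.4f, SE = %.4f, t(%.1f) = %.3f, p = %.4g%s\n",
              x$beta, x$se, x$df, x$t, x$p,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' The three behavioral mixed models
#'
#' `lmm1` compares early vs late learning phases (restricted to labelled
#' paths); `lmm2` compares Set 1 vs Set 2 spaces; `lmm3` compares the
#' exploration vs exploitation stages. Each is fitted for both RA_path and
#' RT_path with a random intercept per subject-by-dimensionality cell, and
#' the effect is coded reference minus comparison (early / Set 1 /
#' exploration coded 1), so planted learning yields a negative RA effect.
#'
#' @param table Combined staged path table (see [staged_path_table()]); for
#'   `lmm1` a `phase` column is required, for `lmm3` a `stage` column.
#' @return Named list of `lmm_result` (`RA_path`, `RT_path`).
#' @export
lmm1 <- function(table) {
  if (!"phase" %in% names(table)) stop("table lacks a 'phase' column")
  t2 <- table[table$phase %in% c("early", "late"), ]
  list(RA_path = fit_lmm(t2, "RA_path", "phase", "early"),
       RT_path = fit_lmm(t2, "RT_path", "phase", "early"))
}

#' @rdname lmm1
#' @export
lmm2 <- function(table) {
  if (!"set_index" %in% names(table)) stop("table lacks a 'set_index' column")
  list(RA_path = fit_lmm(table, "RA_path", "set_index", "1"),
       RT_path = fit_lmm(table, "RT_path", "set_index", "1"))
}

#' @rdname lmm1
#' @export
lmm3 <- function(table) {
  if (!"stage" %in% names(table)) stop("table lacks a 'stage' column")
  list(RA_path = fit_lmm(table, "RA_path", "stage", "exploration"),
       RT_path = fit_lmm(table, "RT_path", "stage", "exploration"))
}

#' One-sample, paired and repeated-measures tests
#'
#' `t_one_sample` tests a vector against `mu0` (used for classifier accuracy
#' against the 0.25 chance baseline; the one-sided p for the directional
#' "greater" hypothesis is reported alongside the two-sided p).
#' `t_paired` compares two paired vectors (used for exploration vs
#' exploitation path counts). `rm_anova` is a one-way repeated-measures
#' ANOVA of a value over a within-subject factor (used for classifier
#' accuracy across the three dimensionalities).
#'
#' @param values Numeric vector.
#' @param mu0 Null mean.
#' @return List: `t`, `df`, `p` (two-sided), `p_greater` (one-sided),
#'   `mean`, `n`.
#' @export
t_one_sample <- function(values, mu0) {
  if (length(values) < 2L) stop("need n >= 2")
  if (stats::sd(values) == 0 && values[1L] == mu0) {
    # degenerate: every value equals the null mean
    return(list(t = 0, df = length(values) - 1L, p = 1, p_greater = 0.5,
                mean = mu0, n = length(values)))
  }
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       p_greater = stats::pt(unname(ht$statistic), unname(ht$parameter),
                             lower.tail = FALSE),
       mean = mean(values), n = length(values))
}

#' @rdname t_one_sample
#' @param a,b Paired numeric vectors of equal length.
#' @export
t_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  if (length(a) < 2L) stop("need n >= 2")
  if (all(a == b)) return(list(t = 0, df = length(a) - 1L, p = 1,
                               mean_diff = 0, n = length(a)))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = mean(a - b), n = length(a))
}

#' @rdname t_one_sample
#' @param value Numeric response, one per subject-condition observation.
#' @param subject Subject identifier per observation.
#' @param condition Within-subject factor per observation (complete grid).
#' @export
rm_anova <- function(value, subject, condition) {
  d <- data.frame(value = value, subject = factor(subject),
                  condition = factor(condition))
  if (any(table(d$subject, d$condition) != 1L))
    stop("rm_anova needs a complete subject x condition grid")
  fit <- stats::aov(value ~ condition + Error(subject / condition), data = d)
  tab <- summary(fit)[["Error: subject:condition"]][[1L]]
  list(F = tab["condition", "F value"],
       df1 = tab["condition", "Df"], df2 = tab["Residuals", "Df"],
       p = tab["condition", "Pr(>F)"])
}

#' Run the full behavioral statistics battery on a staged cohort
#'
#' Fits LMM1-3 for both responses, tests mean classifier accuracy against
#' the 0.25 chance level, compares exploration vs exploitation path counts
#' with a paired t test, and runs the repeated-measures ANOVA of accuracy
#' across dimensionalities.
#'
#' @param staged List of `staged_session` objects.
#' @return List: `lmm` (data.frame, one row per model x response),
#'   `accuracy_vs_chance`, `path_count_paired`, `accuracy_by_dim_anova`.
#' @export
stage_statistics <- function(staged) {
  tab <- staged_path_table(staged)
  models <- list(LMM1 = lmm1(tab), LMM2 = lmm2(tab), LMM3 = lmm3(tab))
  lmm_tab <- do.call(rbind, lapply(names(models), function(m) {
    do.call(rbind, lapply(names(models[[m]]), function(resp) {
      r <- models[[m]][[resp]]
      data.frame(model = m, response = resp, beta = r$beta, se = r$se,
                 t = r$t, df = r$df, p = r$p, singular = r$singular,
                 df_method = r$df_method, stringsAsFactors = FALSE)
    }))
  }))
  gs <- do.call(rbind, c(lapply(staged, `[[`, "group_summary"),
                         make.row.names = FALSE))
  acc_mean <- vapply(staged, function(s) mean(s$group_summary$mean_test_accuracy),
                     numeric(1L))
  n_explore <- vapply(staged, function(s) sum(s$paths$stage == "exploration"),
                      numeric(1L))
  n_exploit <- vapply(staged, function(s) sum(s$paths$stage == "exploitation"),
                      numeric(1L))
  list(
    lmm = lmm_tab,
    accuracy_vs_chance = t_one_sample(acc_mean, classifier_chance_level()),
    path_count_paired = t_paired(n_explore, n_exploit),
    accuracy_by_dim_anova = rm_anova(
      gs$mean_test_accuracy,
      rep(names(staged), each = 3L),
      gs$n_dims))
}
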