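# Inferential layer: Pearson correlations with t statistics, chi-square
# goodness of fit, and two-level nested linear mixed models with
# likelihood-ratio tests and pseudo-R^2.

#' Pearson correlation with t statistic
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with a two-sided p from the t
#' distribution on n - 2 degrees of freedom. Perfect correlation yields an
#' infinite t with p = 0.
#'
#' @param x,y numeric vectors; only complete pairs are used.
#' @return An object of class `corr_test` with `r`, `n`, `df`, `t`, `p`.
#' @export
pearson_with_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop_oe("need at least 3 complete pairs", class = "oe_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_oe("zero variance in input", class = "oe_degenerate_input")
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- if (abs(r) >= 1 - 1e-12) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(r = r, n = n, df = df, t = t, p = p), class = "corr_test")
}

#' @export
print.corr_test <- function(x, ...) {
  cat(sprintf("r = %.3f, t(%d) = %.3f, p = %.4f\n", x$r, x$df, x$t, x$p))
  invisible(x)
}

#' Chi-square goodness of fit against given probabilities
#'
#' `chi2 = sum (O - E)^2 / E` with `E = N * probs` and `df = k - 1`.
#'
#' @param observed non-negative count vector.
#' @param probs probability vector of the same length summing to 1.
#' @return An object of class `gof_result` with `chi2`, `df`, `p`,
#'   `observed`, `expected`.
#' @export
chisq_gof <- function(observed, probs) {
  if (length(observed) != length(probs))
    stop_oe("observed and probs lengths differ", class = "oe_validation_error")
  if (any(observed < 0) || sum(observed) <= 0)
    stop_oe("observed must be non-negative with positive total", class = "oe_validation_error")
  if (abs(sum(probs) - 1) > 1e-9)
    stop_oe("probs must sum to 1", class = "oe_validation_error")
  expected <- sum(observed) * probs
  if (any(expected == 0))
    stop_oe("zero expected count; drop structural-zero bins first",
            class = "oe_validation_error")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi^2(%d) = %.2f, p = %.4g\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Simple linear regression with standard errors and F
#'
#' @param x predictor; must not be constant.
#' @param y response.
#' @return List with `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `r_squared`, `f_statistic`, `n`.
#' @export
fit_simple_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop_oe("need at least 3 complete pairs", class = "oe_insufficient_data")
  if (stats::sd(x) == 0)
    stop_oe("constant predictor: degenerate design", class = "oe_degenerate_design")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       slope_se = sm$coefficients[2, 2], intercept_se = sm$coefficients[1, 2],
       r_squared = sm$r.squared,
       f_statistic = if (!is.null(sm$fstatistic)) unname(sm$fstatistic[1]) else NA_real_,
       n = length(x))
}

#' Two-level nested linear mixed model with LRT and pseudo-R^2
#'
#' Fits, by maximum likelihood, a model with random intercepts for the
#' experimental condition and for participants nested in condition. The full
#' fixed part is `condition + n_cues + condition:n_cues` with treatment
#' coding and `neutral` as the reference level; the null model is
#' intercept-only with the same random effects. The two are compared with a
#' likelihood-ratio test, and pseudo-R^2 (total) is the squared correlation
#' between fitted and observed values. Wald t statistics carry Satterthwaite
#' degrees of freedom.
#'
#' With only three condition levels the condition-level variance component is
#' weakly identified; it may legitimately be estimated as 0 (a singular but
#' valid fit) and is reported as such.
#'
#' @param rows analysis table with columns `participant`, `condition`,
#'   `n_cues` and the dependent variable; rows with NA in the dependent
#'   variable or `n_cues` are dropped listwise.
#' @param dv name of the dependent-variable column.
#' @return An object of class `effort_lmm`: `fixed` (coefficient table),
#'   `varcomp` (condition, participant, residual variances), `loglik_full`,
#'   `loglik_null`, `lrt_chi2`, `lrt_df`, `lrt_p`, `pseudo_r2_total`, and the
#'   underlying `model` / `null_model`.
#' @export
fit_lmm <- function(rows, dv) {
  if (!dv %in% names(rows))
    stop_oe("dependent variable ", dv, " not in table", class = "oe_validation_error")
  d <- rows[stats::complete.cases(rows[[dv]], rows$n_cues), ]
  d$condition <- stats::relevel(factor(d$condition, levels = CONDITIONS),
                                ref = "neutral")
  d$.y <- d[[dv]]
  if (length(unique(d$participant)) < 2 ||
      min(table(unique(d[c("participant", "condition")])$condition)) < 2)
    stop_oe("need at least 2 participants per condition", class = "oe_insufficient_data")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  full <- withCallingHandlers(
    lmerTest::lmer(.y ~ condition * n_cues + (1 | condition) +
                     (1 | condition:participant),
                   data = d, REML = FALSE, control = ctrl),
    message = function(m) invokeRestart("muffleMessage"))
  null <- withCallingHandlers(
    lmerTest::lmer(.y ~ 1 + (1 | condition) + (1 | condition:participant),
                   data = d, REML = FALSE, control = ctrl),
    message = function(m) invokeRestart("muffleMessage"))
  conv <- full@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code < 0)
    stop_oe("mixed model did not converge: ",
            paste(unlist(conv$messages), collapse = "; "),
            class = "oe_convergence_error")
  sm <- summary(full)
  co <- sm$coefficients
  fixed <- data.frame(name = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], df = co[, "df"],
                      t = co[, "t value"], p = co[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(full))
  varcomp <- c(
    condition = vc$vcov[vc$grp == "condition"],
    participant = vc$vcov[vc$grp == "condition:participant"],
    residual = vc$vcov[vc$grp == "Residual"])
  lrt <- stats::anova(null, full)
  pseudo_r2 <- stats::cor(stats::fitted(full), d$.y)^2
  structure(list(dv = dv, fixed = fixed, varcomp = varcomp,
                 loglik_full = as.numeric(stats::logLik(full)),
                 loglik_null = as.numeric(stats::logLik(null)),
                 lrt_chi2 = lrt$Chisq[2], lrt_df = as.integer(lrt$Df[2]),
                 lrt_p = lrt$`Pr(>Chisq)`[2],
                 pseudo_r2_total = pseudo_r2,
                 n_rows = nrow(d),
                 model = full, null_model = null),
            class = "effort_lmm")
}

#' @export
print.effort_lmm <- function(x, ...) {
  cat(sprintf("Nested LMM for %s (n = %d rows)\n", x$dv, x$n_rows))
  cat(sprintf("  LRT full vs null: chi^2(%d) = %.3f, p = %.4g; pseudo-R2 (total) = %.3f\n",
              x$lrt_df, x$lrt_chi2, x$lrt_p, x$pseudo_r2_total))
  cat(sprintf("  variance components: condition %.3f, participant %.3f, residual %.3f\n",
              x$varcomp[["condition"]], x$varcomp[["participant"]],
              x$varcomp[["residual"]]))
  f <- x$fixed
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-28s b = %9.3f  SE = %8.3f  t(%.1f) = %6.3f  p = %.4f\n",
                f$name[i], f$estimate[i], f$se[i], f$df[i], f$t[i], f$p[i]))
  invisible(x)
}

#' @export
coef.effort_lmm <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$name)
}

#' @export
summary.effort_lmm <- function(object, ...) summary(object$model, ...)
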