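#' Standardized regression coefficient
#'
#' Expresses an unstandardized slope in outcome standard deviations per
#' predictor standard deviation: `b1 * sd(x) / sd(y)`, with the SDs taken
#' over the analyzed rows. For OLS this equals the coefficient obtained by
#' refitting on z-scored variables.
#'
#' @param b1 Unstandardized slope.
#' @param sd_predictor,sd_outcome Sample SDs of predictor and outcome (> 0).
#' @return Dimensionless standardized beta.
#' @export
standardized_beta <- function(b1, sd_predictor, sd_outcome) {
  if (!is.finite(sd_predictor) || !is.finite(sd_outcome) ||
      sd_predictor <= 0 || sd_outcome <= 0)
    stop("degenerate-variable error: predictor and outcome SDs must be > 0",
         call. = FALSE)
  b1 * sd_predictor / sd_outcome
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`; may be negative for weak models
#' and is reported as-is.
#'
#' @param r2 Unadjusted R-squared in \[0, 1\].
#' @param n Number of observations.
#' @param p_predictors Number of predictors (excluding the intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p_predictors) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1)
    stop("`r2` must lie in [0, 1]", call. = FALSE)
  if (n <= p_predictors + 1)
    stop("argument error: need n > p_predictors + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p_predictors - 1)
}

#' Cohen's f effect size from adjusted R-squared
#'
#' `f = sqrt(R2 / (1 - R2))` evaluated on the adjusted R-squared; negative
#' adjusted values are clamped to 0 so the effect size stays real-valued on
#' null data.
#'
#' @param adj_r2 Adjusted R-squared (< 1).
#' @return Cohen's f (>= 0).
#' @export
cohens_f <- function(adj_r2) {
  if (!is.finite(adj_r2) || adj_r2 >= 1)
    stop("argument error: `adj_r2` must be finite and < 1", call. = FALSE)
  a <- max(adj_r2, 0)
  sqrt(a / (1 - a))
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha Family-wise level (0 < alpha <= 1).
#' @param m Number of tests in the family (>= 1).
#' @return Per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 4L) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  alpha / m
}

#' Fit one adjusted tract-region association model
#'
#' Ordinary least squares of regional SUVr on the log tract-WMH volume plus
#' covariates. Reports the unstandardized and standardized slope on the
#' log-WMH predictor, the two-sided t-test p-value, the 95% confidence
#' interval from the t distribution with `n - p - 1` df, the adjusted
#' R-squared of the full model and the Cohen's f effect size.
#'
#' @param data data.frame containing `outcome`, `predictor` and the covariate
#'   columns; rows with missing values in any used column are dropped
#'   (listwise deletion).
#' @param outcome,predictor Column names of the outcome (SUVr) and predictor
#'   (log WMH volume).
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level for the slope interval.
#' @return Object of class `association_result`: list with `b0`, `b1`,
#'   `covariate_coefs`, `std_beta`, `p_value`, `ci_low`, `ci_high`, `adj_r2`,
#'   `r2`, `cohens_f`, `n_used`, `degenerate_outcome`.
#' @export
fit_adjusted_model <- function(data, outcome, predictor,
                               covariates = c("age", "sex", "apoe_e4_count", "icv"),
                               conf_level = 0.95) {
  used <- c(outcome, predictor, covariates)
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop(sprintf("estimation error: missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  n <- nrow(df)
  p <- 1L + length(covariates)
  if (n <= p + 1L)
    stop(sprintf("estimation error: %d usable rows for %d predictors", n, p),
         call. = FALSE)
  y <- df[[outcome]]
  x <- df[[predictor]]
  if (stats::sd(y) == 0) {
    return(structure(list(
      b0 = mean(y), b1 = 0, covariate_coefs = stats::setNames(rep(0, length(covariates)), covariates),
      std_beta = 0, p_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      adj_r2 = NA_real_, r2 = NA_real_, cohens_f = NA_real_, n_used = n,
      degenerate_outcome = TRUE), class = "association_result"))
  }
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(fml, data = df)
  if (fit$rank < p + 1L)
    stop("estimation error: rank-deficient design (collinear predictors)",
         call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  b1 <- co[predictor, "Estimate"]
  ci <- stats::confint(fit, predictor, level = conf_level)
  ar2 <- sm$adj.r.squared
  structure(list(
    b0 = co["(Intercept)", "Estimate"],
    b1 = b1,
    covariate_coefs = stats::setNames(co[covariates, "Estimate"], covariates),
    std_beta = standardized_beta(b1, stats::sd(x), stats::sd(y)),
    p_value = co[predictor, "Pr(>|t|)"],
    ci_low = min(ci), ci_high = max(ci),
    adj_r2 = ar2, r2 = sm$r.squared,
    cohens_f = if (ar2 < 1) cohens_f(ar2) else Inf,
    n_used = n, degenerate_outcome = FALSE),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> b1 = %.4g, std beta = %.3f, p = %.4g, adj R2 = %.3f, f = %.3f, n = %d\n",
              x$b1, x$std_beta, x$p_value, x$adj_r2, x$cohens_f, x$n_used))
  invisible(x)
}

#' Fit the four tract-region association models
#'
#' For each tract-region pair, merges the per-tract log-WMH records, the
#' per-region SUVr records and the covariate table (keeping only rows flagged
#' `included` by the upstream zero-volume and SUVr-floor policies, then
#' listwise-deleting missing values), fits the adjusted model, and flags
#' significance at the Bonferroni threshold `alpha / family_size`. A pair
#' with too few usable rows is reported as not estimable (all-NA statistics)
#' with a warning; the other pairs are unaffected.
#'
#' @param suvr data.frame: `subject_id`, `region_name`, `suvr`, `included`.
#' @param tracts data.frame: `subject_id`, `tract_name`, `log_volume`,
#'   `included`.
#' @param covariates data.frame: `subject_id` plus covariate columns.
#' @param pairings data.frame with `tract`, `region` (default [dmn_pairings()]).
#' @param covariate_names Covariate columns used in every model.
#' @param alpha Family-wise significance level.
#' @return data.frame with one row per pair: `region`, `tract`, `b1`,
#'   `std_beta`, `p_value`, `adj_r2`, `ci_low`, `ci_high`, `cohens_f`,
#'   `n_used`, `significant`.
#' @export
run_family <- function(suvr, tracts, covariates, pairings = dmn_pairings(),
                       covariate_names = c("age", "sex", "apoe_e4_count", "icv"),
                       alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, nrow(pairings))
  rows <- lapply(seq_len(nrow(pairings)), function(i) {
    tr <- pairings$tract[i]; reg <- pairings$region[i]
    na_row <- data.frame(region = reg, tract = tr, b1 = NA_real_,
                         std_beta = NA_real_, p_value = NA_real_,
                         adj_r2 = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, cohens_f = NA_real_,
                         n_used = 0L, significant = NA,
                         stringsAsFactors = FALSE)
    ts <- tracts[tracts$tract_name == tr &
                   !is.na(tracts$included) & tracts$included,
                 c("subject_id", "log_volume")]
    ss <- suvr[suvr$region_name == reg &
                 !is.na(suvr$included) & suvr$included,
               c("subject_id", "suvr")]
    df <- merge(merge(ts, ss, by = "subject_id"), covariates, by = "subject_id")
    res <- tryCatch(
      fit_adjusted_model(df, outcome = "suvr", predictor = "log_volume",
                         covariates = covariate_names),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("pair %s -> %s not estimable: %s", tr, reg,
                      conditionMessage(res)), call. = FALSE)
      na_row$n_used <- nrow(df[stats::complete.cases(df), ])
      return(na_row)
    }
    data.frame(region = reg, tract = tr, b1 = res$b1, std_beta = res$std_beta,
               p_value = res$p_value, adj_r2 = res$adj_r2,
               ci_low = res$ci_low, ci_high = res$ci_high,
               cohens_f = res$cohens_f, n_used = res$n_used,
               significant = !is.na(res$p_value) && res$p_value < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "alpha") <- alpha
  out
}
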