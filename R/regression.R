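# Adjusted birth-weight models: OLS on continuous birth weight with tertile
# exposure factors, the a-priori covariate set, ethnicity stratification, and
# overall / trend / interaction tests.

#' The a-priori maternal covariate set
#'
#' Ten maternal factors adjusted for in every model: caffeine intake (>= 200
#' mg/day), education (5 levels), fasting and post-load glucose (continuous),
#' ethnicity, smoking (3 levels), parity (0/1/>=2), age (continuous), BMI
#' quartile and IMD deprivation quintile. The two infant factors (gestational
#' age as linear + quadratic, sex) are always added by [fit_bw_model()].
#'
#' @return character vector of covariate column names.
#' @export
bw_covariates <- function() {
  c("caffeine_ge200", "education", "fasting_glucose", "postload_glucose",
    "ethnicity", "smoking", "parity", "age", "bmi_quartile", "imd_quintile")
}

BW_CATEGORICAL <- c("caffeine_ge200", "education", "ethnicity", "smoking",
                    "parity", "bmi_quartile", "imd_quintile", "sex")

prepare_bw_data <- function(data, vars) {
  for (v in intersect(vars, BW_CATEGORICAL)) {
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])
  }
  data
}

#' Fit an adjusted birth-weight model
#'
#' Ordinary least squares regression of continuous birth weight on one or two
#' categorical exposure terms (reference = lowest category) adjusted for the
#' a-priori maternal covariates plus gestational age (linear and quadratic)
#' and infant sex. Ethnic-stratum models drop the ethnicity covariate. A crude
#' (exposure-only) fit is kept for comparison. Fitting is complete-case over
#' the model variables.
#'
#' @param data analysis data.frame; exposure columns must be factors (e.g.
#'   from [categorize()]).
#' @param exposure names of 1 or 2 exposure factor columns.
#' @param stratum `"total"`, or an ethnicity level to restrict to (the
#'   ethnicity covariate is then dropped).
#' @param covariates maternal covariate names (default [bw_covariates()]).
#' @param min_per_level minimum observations required per exposure level.
#' @return object of class `"bw_fit"`.
#' @export
fit_bw_model <- function(data, exposure, stratum = "total",
                         covariates = bw_covariates(), min_per_level = 20) {
  stopifnot(length(exposure) %in% 1:2)
  if (stratum != "total") {
    data <- data[data$ethnicity %in% stratum, , drop = FALSE]
    covariates <- setdiff(covariates, "ethnicity")
  }
  vars <- c("birth_weight_g", exposure, covariates, "gestational_age_wk", "sex")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- complete_case(data, vars)
  data <- prepare_bw_data(data, vars)
  for (e in exposure) {
    data[[e]] <- droplevels(data[[e]])
    tab <- table(data[[e]])
    if (any(tab < min_per_level)) {
      stop("fewer than ", min_per_level, " observations in level(s) of ", e,
           ": ", paste(names(tab)[tab < min_per_level], collapse = ", "))
    }
  }
  rhs_adj <- paste(c(exposure, covariates,
                     "gestational_age_wk", "I(gestational_age_wk^2)", "sex"),
                   collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("birth_weight_g ~", rhs_adj)),
                   data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  crude <- stats::lm(stats::as.formula(
    paste("birth_weight_g ~", paste(exposure, collapse = " + "))), data = data)
  structure(list(fit = fit, crude = crude, exposure = exposure,
                 stratum = stratum, covariates = covariates,
                 data = data, n = nrow(data)),
            class = "bw_fit")
}

# per-level effect rows for one exposure term from an lm fit
effect_rows <- function(fit, data, exposure, level = 0.95) {
  lev <- levels(data[[exposure]])
  cf <- stats::coef(fit)
  ci <- stats::confint(fit, level = level)
  out <- data.frame(exposure = exposure, level = lev,
                    estimate = 0, ci_lo = NA_real_, ci_hi = NA_real_,
                    n = as.integer(table(data[[exposure]])),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lev)[-1]) {
    term <- paste0(exposure, lev[i])
    out$estimate[i] <- cf[[term]]
    out$ci_lo[i] <- ci[term, 1]
    out$ci_hi[i] <- ci[term, 2]
  }
  out
}

#' Effect estimates from a birth-weight model
#'
#' @param object a `"bw_fit"`.
#' @param crude if TRUE, report the unadjusted (bivariate) fit.
#' @param level confidence level.
#' @param ... unused.
#' @return data.frame with one row per exposure level: mean birth-weight
#'   difference (g) vs the lowest category, t-based confidence interval, n.
#' @export
summary.bw_fit <- function(object, crude = FALSE, level = 0.95, ...) {
  fit <- if (crude) object$crude else object$fit
  do.call(rbind, lapply(object$exposure, function(e) {
    effect_rows(fit, object$data, e, level)
  }))
}

#' @export
print.bw_fit <- function(x, ...) {
  cat("Adjusted birth-weight model (stratum:", x$stratum, "), n =", x$n, "\n")
  cat("Exposure term(s):", paste(x$exposure, collapse = " + "), "\n")
  tab <- summary(x)
  tab$estimate <- round(tab$estimate, 1)
  tab$ci_lo <- round(tab$ci_lo, 1)
  tab$ci_hi <- round(tab$ci_hi, 1)
  print(tab, row.names = FALSE)
  for (e in x$exposure) {
    cat(sprintf("%s: p_overall = %.4g, p_trend = %.4g\n",
                e, test_overall(x, e), test_trend(x, e)))
  }
  invisible(x)
}

#' @export
coef.bw_fit <- function(object, ...) stats::coef(object$fit)

#' @export
confint.bw_fit <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) stats::confint(object$fit, level = level)
  else stats::confint(object$fit, parm, level = level)
}

#' F-test for the overall significance of an exposure term
#'
#' Compares the adjusted model with and without the categorical exposure
#' factor as a whole.
#'
#' @param object a `"bw_fit"`.
#' @param exposure which exposure term (default: the first).
#' @return two-sided p-value.
#' @export
test_overall <- function(object, exposure = object$exposure[1]) {
  reduced <- stats::update(
    object$fit, stats::as.formula(paste(". ~ . -", exposure)),
    data = object$data)
  stats::anova(reduced, object$fit)[2, "Pr(>F)"]
}

#' Test for linear trend across exposure categories
#'
#' Refits the model with the exposure categories coded 0, 1, 2, ... entered as
#' a continuous variable; returns the two-sided p-value of its slope.
#'
#' @inheritParams test_overall
#' @return two-sided p-value for trend.
#' @export
test_trend <- function(object, exposure = object$exposure[1]) {
  lev <- levels(object$data[[exposure]])
  if (length(lev) < 3) stop("trend test needs >= 3 exposure categories")
  data <- object$data
  code_var <- paste0(".trend_", exposure)
  data[[code_var]] <- as.numeric(data[[exposure]]) - 1
  fml <- stats::as.formula(paste(". ~ . -", exposure, "+", code_var))
  fit <- stats::update(object$fit, fml, data = data)
  summary(fit)$coefficients[code_var, "Pr(>|t|)"]
}

#' F-test for exposure-ethnicity interaction
#'
#' Adds exposure x ethnicity product terms to the total-population model and
#' tests them jointly. Undefined for stratified models.
#'
#' @inheritParams test_overall
#' @return joint F-test p-value over the interaction terms.
#' @export
test_interaction <- function(object, exposure = object$exposure[1]) {
  if (object$stratum != "total" || !"ethnicity" %in% object$covariates) {
    stop("interaction test requires the total-population model with ethnicity")
  }
  if (nlevels(factor(object$data$ethnicity)) < 2) {
    stop("single-ethnicity data; interaction undefined")
  }
  full <- stats::update(
    object$fit,
    stats::as.formula(paste(". ~ . +", exposure, ":ethnicity")),
    data = object$data)
  stats::anova(object$fit, full)[2, "Pr(>F)"]
}

#' Run the full tertile analysis over metrics, windows and strata
#'
#' For each exposure metric (or metric pair for joint models) and gestational
#' window, tertiles are cut on the analysis population, and adjusted models
#' are fitted for the total population and each requested ethnic stratum, with
#' overall and trend tests per exposure term and the ethnicity-interaction
#' test in the total model.
#'
#' @param exposure_table output of [compute_exposure()] (or any table with
#'   `pregnancy_id`, `window` and metric columns).
#' @param cohort eligible cohort records (one row per pregnancy) carrying the
#'   outcome and covariates.
#' @param metrics list of metric column names; an element of length 2 fits the
#'   joint two-exposure model.
#' @param windows gestational windows to analyse.
#' @param strata strata to fit (always includes `"total"` first).
#' @param covariates maternal covariates; append e.g. environmental tobacco
#'   smoke or questionnaire language for sensitivity analyses.
#' @return data.frame of effect estimates, one row per metric x window x
#'   stratum x exposure level, with `p_overall`, `p_trend`, `p_interaction`.
#' @export
run_analysis_suite <- function(exposure_table, cohort,
                               metrics = list("up_TTHM", "up_THMBr",
                                              "ing_HAA3",
                                              c("ing_DBP7", "sbs_TTHM"),
                                              "conc_DBP7"),
                               windows = c("whole", "T1", "T2", "T3"),
                               strata = c("total", "white_British",
                                          "Pakistani_origin"),
                               covariates = bw_covariates()) {
  avail <- setdiff(names(exposure_table), c("pregnancy_id", "window"))
  bad <- setdiff(unlist(metrics), avail)
  if (length(bad)) {
    stop("metric(s) not in exposure table: ", paste(bad, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  }
  out <- list()
  for (metric in metrics) {
    for (wl in intersect(windows, unique(exposure_table$window))) {
      ew <- exposure_table[exposure_table$window == wl,
                           c("pregnancy_id", metric), drop = FALSE]
      d <- merge(cohort, ew, by = "pregnancy_id")
      tert_cols <- paste0(metric, "_tert")
      for (j in seq_along(metric)) {
        d[[tert_cols[j]]] <- categorize(d[[metric[j]]], "tertile")
      }
      for (st in strata) {
        fit <- tryCatch(
          fit_bw_model(d, exposure = tert_cols, stratum = st,
                       covariates = covariates),
          error = function(e) e)
        if (inherits(fit, "error")) next
        tab <- summary(fit)
        crude_tab <- summary(fit, crude = TRUE)
        tab$crude_estimate <- crude_tab$estimate
        tab$crude_lo <- crude_tab$ci_lo
        tab$crude_hi <- crude_tab$ci_hi
        for (j in seq_along(metric)) {
          sel <- tab$exposure == tert_cols[j]
          tab$metric[sel] <- metric[j]
          tab$p_overall[sel] <- test_overall(fit, tert_cols[j])
          tab$p_trend[sel] <- test_trend(fit, tert_cols[j])
          tab$p_interaction[sel] <- if (st == "total") {
            test_interaction(fit, tert_cols[j])
          } else NA_real_
        }
        tab$window <- wl
        tab$stratum <- st
        tab$model <- paste(metric, collapse = "+")
        out[[length(out) + 1]] <- tab
      }
    }
  }
  if (!length(out)) stop("no model could be fitted")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("model", "metric", "window", "stratum", "level", "n",
        "crude_estimate", "crude_lo", "crude_hi",
        "estimate", "ci_lo", "ci_hi",
        "p_overall", "p_trend", "p_interaction")]
}
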