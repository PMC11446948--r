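PRE_COVARIATES <- list(
  sex = "M", age_band_pre = ">=70", bmi_band_pre = "<30",
  deprivation = "5", calendar_band_pre = "2010-2011")

POST_COVARIATES <- list(
  sex = "M", age_band_post = ">=70", bmi_band_post = "25-<30",
  deprivation = "5", calendar_band_post = "2013-2014",
  hba1c_band = "<43", pre_category = "rapid gain",
  peri_category = "rapid loss")

#' Pre-diagnosis BMI trajectory analysis
#'
#' Fits the pre-diagnosis trajectory model on all BMI observations between
#' 3 years and 6 months before diagnosis for the cohort individuals. The
#' base model has fixed intercept and time slope, random intercept and
#' slope per individual and spatial-power residual correlation, with one
#' studentised-residual outlier-removal pass (|t| > `outlier_threshold`)
#' and a single refit. Individual trajectories (fixed slope + BLUP slope
#' deviation, kg/m2/year) and their seven-level categories come from the
#' refitted base model.
#'
#' Covariate models are then fitted on the outlier-cleaned observations:
#' for each of sex, age band, BMI band, deprivation and calendar band (all
#' at the -3 year anchor), a univariable model adds the covariate main
#' effect and its interaction with time (the interaction coefficient is the
#' difference in annual BMI change versus the reference level); a single
#' multivariable model then includes every covariate with any significant
#' (p < `alpha`) univariable interaction plus the always-retained
#' confounders.
#'
#' @param cohort a [build_cohort()] result.
#' @param bundle the `emr_bundle` the cohort came from.
#' @param window inclusive pre-diagnosis time window, years.
#' @param outlier_threshold studentised-residual cut-off.
#' @param always_retain covariates forced into the multivariable model.
#' @param alpha significance level for multivariable inclusion.
#' @param covariates fit the univariable and multivariable covariate models
#'   (default); `FALSE` stops after the base model and trajectories.
#' @return list with `trajectories` (id, period, rate, category),
#'   `coefficients` (per-covariate slope differences, univariable and
#'   multivariable, with 95% CIs), `fit` (the refitted base model), and
#'   `data` (the cleaned observation rows).
#' @export
run_pre_analysis <- function(cohort, bundle, window = c(-3, -0.5),
                             outlier_threshold = 3,
                             always_retain = c("age_band_pre", "sex"),
                             alpha = 0.05, covariates = TRUE) {
  stopifnot(nrow(cohort) > 0)
  design <- longitudinal_rows(bundle, cohort, window)
  design <- merge_covariates(design, cohort, names(PRE_COVARIATES))

  fit <- lmm_refit_outliers(bmi ~ time, design, id = "id", time = "time",
                            threshold = outlier_threshold,
                            on_rank_deficient = "drop")
  traj <- lmm_trajectories(fit)
  traj <- data.frame(id = traj$id, period = "pre", rate = traj$rate,
                     category = categorize_rate(traj$rate))

  cleaned <- design[fit$kept_rows, , drop = FALSE]
  if (!covariates)
    return(list(trajectories = traj, coefficients = NULL, fit = fit,
                multivariable_fit = NULL, data = cleaned))
  cov_out <- covariate_models(cleaned, PRE_COVARIATES, base_rhs = "time",
                              always_retain = always_retain, alpha = alpha)

  list(trajectories = traj, coefficients = cov_out$table,
       fit = fit, multivariable_fit = cov_out$multi_fit, data = cleaned)
}

#' Post-diagnosis BMI trajectory analysis
#'
#' Fits the exposure-adjusted post-diagnosis trajectory model on the
#' [attach_exposures()] rows (BMI observations 1 to 5 years after
#' diagnosis). The base model has fixed intercept, time slope, and
#' time-varying treatment-regimen and HbA1c-change-category indicator
#' offsets (reference: untreated, no HbA1c change), random intercept and
#' slope, spatial-power residual correlation, and one outlier pass.
#' Regimen levels with fewer than `min_regimen_obs` observations are pooled
#' into `other` before fitting. Individual trajectories come from this
#' adjusted base model; the exposure table reports the regimen and HbA1c
#' category offsets in kg/m2 versus their references.
#'
#' Covariate models (sex, age band at diagnosis, BMI band at +1 year,
#' deprivation, calendar band, HbA1c band, and the pre- and peri-diagnosis
#' weight-change categories) add covariate-by-time interactions to the
#' adjusted base model, univariable then multivariable, on the cleaned
#' observations.
#'
#' @param cohort a [build_cohort()] result; if a `pre_category` column is
#'   present (added from [run_pre_analysis()] trajectories) it is modelled
#'   as a covariate.
#' @param design_post an [attach_exposures()] result.
#' @param min_regimen_obs pooling threshold for rare regimen levels.
#' @inheritParams run_pre_analysis
#' @return list with `trajectories`, `coefficients`, `exposures` (offset
#'   table), `fit`, and `data` (cleaned rows).
#' @export
run_post_analysis <- function(cohort, design_post, outlier_threshold = 3,
                              min_regimen_obs = 30,
                              always_retain = c("age_band_post", "sex"),
                              alpha = 0.05, covariates = TRUE) {
  stopifnot(nrow(cohort) > 0, nrow(design_post) > 0)
  covars <- POST_COVARIATES
  if (!("pre_category" %in% names(cohort))) covars$pre_category <- NULL
  design <- merge_covariates(design_post, cohort, names(covars))

  # pool rare regimens, set reference levels for the exposure factors
  tab <- table(design$regimen)
  rare <- names(tab)[tab < min_regimen_obs & names(tab) != "none"]
  design$regimen[design$regimen %in% rare] <- "other"
  design$regimen <- stats::relevel(factor(design$regimen), ref = "none")
  design$hba1c_cat <- factor(design$hba1c_cat,
                             levels = intersect(HBA1C_CATEGORIES,
                                                unique(design$hba1c_cat)))

  terms_rhs <- "time"
  if (nlevels(design$regimen) > 1) terms_rhs <- c(terms_rhs, "regimen")
  if (nlevels(design$hba1c_cat) > 1) terms_rhs <- c(terms_rhs, "hba1c_cat")
  base_rhs <- paste(terms_rhs, collapse = " + ")
  base_formula <- stats::as.formula(paste("bmi ~", base_rhs))

  fit <- lmm_refit_outliers(base_formula, design, id = "id", time = "time",
                            threshold = outlier_threshold,
                            on_rank_deficient = "drop")
  traj <- lmm_trajectories(fit)
  traj <- data.frame(id = traj$id, period = "post", rate = traj$rate,
                     category = categorize_rate(traj$rate))

  exposures <- exposure_table(fit, design)

  cleaned <- design[fit$kept_rows, , drop = FALSE]
  if (!covariates)
    return(list(trajectories = traj, coefficients = NULL,
                exposures = exposures, fit = fit,
                multivariable_fit = NULL, data = cleaned))
  cov_out <- covariate_models(cleaned, covars, base_rhs = base_rhs,
                              always_retain = always_retain, alpha = alpha)

  list(trajectories = traj, coefficients = cov_out$table,
       exposures = exposures, fit = fit,
       multivariable_fit = cov_out$multi_fit, data = cleaned)
}

# stack all BMI observations of the cohort ids inside a relative-time window
longitudinal_rows <- function(bundle, cohort, window) {
  demo <- bundle$demographics
  diag_by_id <- stats::setNames(demo$diagnosis_date, demo$id)
  obs <- bundle$bmi_obs[bundle$bmi_obs$id %in% cohort$id, , drop = FALSE]
  t_rel <- date_to_rel(obs$date, diag_by_id[obs$id])
  keep <- t_rel >= window[1] & t_rel <= window[2]
  out <- data.frame(id = obs$id[keep], time = t_rel[keep],
                    bmi = obs$bmi[keep], stringsAsFactors = FALSE)
  out[order(match(out$id, cohort$id), out$time), , drop = FALSE]
}

merge_covariates <- function(design, cohort, covars) {
  cols <- intersect(c("id", covars), names(cohort))
  out <- merge(design, as.data.frame(cohort)[, cols, drop = FALSE],
               by = "id", sort = FALSE)
  out[order(match(out$id, cohort$id), out$time), , drop = FALSE]
}

# univariable covariate-by-time models, then one multivariable model with
# the significant covariates and the forced confounders
covariate_models <- function(data, covars, base_rhs, always_retain, alpha,
                             id = "id", time = "time") {
  rows <- list(); significant <- character(0)
  for (cv in names(covars)) {
    x <- droplevels(factor(data[[cv]]))
    if (!(covars[[cv]] %in% levels(x))) {
      message("reference level '", covars[[cv]], "' absent for ", cv,
              "; using first observed level")
    } else {
      x <- stats::relevel(x, ref = covars[[cv]])
    }
    data[[cv]] <- x
    if (nlevels(x) < 2) next
    f <- stats::as.formula(paste("bmi ~", base_rhs, "+", cv, "+ time:", cv))
    ufit <- lmm_fit(f, data, id = id, time = time,
                    on_rank_deficient = "drop")
    co <- interaction_coefs(ufit, cv, levels(x))
    if (any(co$p_value < alpha, na.rm = TRUE))
      significant <- c(significant, cv)
    n_by_level <- tapply(data[[id]], x, function(v) length(unique(v)))
    rows[[cv]] <- data.frame(
      covariate = cv, level = levels(x),
      n = as.integer(n_by_level[levels(x)]),
      reference = levels(x) == levels(x)[1],
      est_uni = co$estimate, lo_uni = co$ci_lo, hi_uni = co$ci_hi,
      p_uni = co$p_value,
      est_multi = NA_real_, lo_multi = NA_real_, hi_multi = NA_real_,
      p_multi = NA_real_, row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  retained <- union(intersect(always_retain, names(covars)), significant)
  retained <- retained[vapply(retained,
                              function(cv) nlevels(droplevels(factor(data[[cv]]))) > 1,
                              logical(1))]
  multi_fit <- NULL
  if (length(retained) > 0) {
    f <- stats::as.formula(paste(
      "bmi ~", base_rhs, "+",
      paste(retained, collapse = " + "), "+",
      paste(paste0("time:", retained), collapse = " + ")))
    multi_fit <- lmm_fit(f, data, id = id, time = time,
                         on_rank_deficient = "drop")
    for (cv in retained) {
      co <- interaction_coefs(multi_fit, cv, levels(data[[cv]]))
      ix <- tab$covariate == cv
      tab$est_multi[ix] <- co$estimate
      tab$lo_multi[ix] <- co$ci_lo; tab$hi_multi[ix] <- co$ci_hi
      tab$p_multi[ix] <- co$p_value
    }
  }
  attr(tab, "retained") <- retained
  list(table = tab, multi_fit = multi_fit, retained = retained)
}

# pull the time-interaction coefficient for each non-reference level
interaction_coefs <- function(fit, cv, lvls) {
  beta <- fit$beta
  out <- data.frame(estimate = rep(NA_real_, length(lvls)),
                    ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_)
  for (j in seq_along(lvls)[-1]) {
    cand <- c(paste0("time:", cv, lvls[j]), paste0(cv, lvls[j], ":time"))
    k <- which(beta$term %in% cand)
    if (length(k) == 1) {
      out$estimate[j] <- beta$estimate[k]
      out$ci_lo[j] <- beta$ci_lo[k]; out$ci_hi[j] <- beta$ci_hi[k]
      out$p_value[j] <- beta$p_value[k]
    }
  }
  out
}

# regimen / HbA1c-category offsets (kg/m2 vs reference) from the base fit
exposure_table <- function(fit, design) {
  beta <- fit$beta
  rows <- list()
  for (vv in c("regimen", "hba1c_cat")) {
    if (!is.factor(design[[vv]]) || nlevels(design[[vv]]) < 2) next
    lv <- levels(design[[vv]])
    n_obs <- table(design[[vv]])
    for (j in seq_along(lv)) {
      k <- which(beta$term == paste0(vv, lv[j]))
      rows[[paste(vv, lv[j])]] <- data.frame(
        exposure = vv, level = lv[j], n_obs = as.integer(n_obs[lv[j]]),
        reference = j == 1,
        estimate = if (length(k) == 1) beta$estimate[k] else NA_real_,
        ci_lo = if (length(k) == 1) beta$ci_lo[k] else NA_real_,
        ci_hi = if (length(k) == 1) beta$ci_hi[k] else NA_real_,
        p_value = if (length(k) == 1) beta$p_value[k] else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise trajectory categories
#'
#' Counts and percentages of the seven weight-change categories, the
#' percentage of individuals gaining (rate > 0) and losing (rate < 0)
#' weight, and the median and interquartile range of the annual rates.
#'
#' @param estimates data frame with columns `rate` and `category` (e.g.
#'   `trajectories` from [run_pre_analysis()]).
#' @return list with `table` (category, n, pct), `pct_gaining`,
#'   `pct_losing`, `median_rate`, `q1_rate`, `q3_rate`, `n`.
#' @export
summarize_categories <- function(estimates) {
  stopifnot(nrow(estimates) > 0)
  cat_f <- factor(estimates$category, levels = WEIGHT_CATEGORIES)
  tab <- table(cat_f)
  n <- nrow(estimates)
  q <- stats::quantile(estimates$rate, c(0.25, 0.5, 0.75), names = FALSE)
  list(table = data.frame(category = names(tab), n = as.integer(tab),
                          pct = 100 * as.integer(tab) / n, row.names = NULL),
       pct_gaining = 100 * mean(estimates$rate > 0),
       pct_losing = 100 * mean(estimates$rate < 0),
       median_rate = q[2], q1_rate = q[1], q3_rate = q[3], n = n)
}
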