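#' @name bands
#' @title Fixed covariate banding rules
#' @description Deterministic banding of continuous covariates into the
#'   fixed, pre-specified cut-points used throughout the analysis (never
#'   data-driven quantiles): age `<50, 50-<60, 60-<70, >=70` years;
#'   pre-diagnosis BMI `<30, 30-<35, 35-<40, >=40` kg/m2; post-diagnosis
#'   BMI `25-<30, 30-<35, 35-<40, >=40`; HbA1c `<43, 43-<48, 48-<54, >=54`
#'   mmol/mol; calendar year at the -3 year anchor `<2006, 2006-2007,
#'   2008-2009, 2010-2011` and at diagnosis `2003-2008, 2009-2010,
#'   2011-2012, 2013-2014`.
#' @param x numeric vector (years, kg/m2, mmol/mol or calendar year).
#' @return factor with the band labels above.
NULL

band_cut <- function(x, breaks, labels) {
  cut(x, breaks = c(-Inf, breaks, Inf), labels = labels, right = FALSE)
}

#' @rdname bands
#' @export
band_age <- function(x)
  band_cut(x, c(50, 60, 70), c("<50", "50-<60", "60-<70", ">=70"))

#' @rdname bands
#' @export
band_bmi_pre <- function(x)
  band_cut(x, c(30, 35, 40), c("<30", "30-<35", "35-<40", ">=40"))

#' @rdname bands
#' @export
band_bmi_post <- function(x)
  band_cut(x, c(30, 35, 40), c("25-<30", "30-<35", "35-<40", ">=40"))

#' @rdname bands
#' @export
band_hba1c <- function(x)
  band_cut(x, c(43, 48, 54), c("<43", "43-<48", "48-<54", ">=54"))

#' @rdname bands
#' @export
band_calendar_pre <- function(x)
  band_cut(x, c(2006, 2008, 2010), c("<2006", "2006-2007", "2008-2009",
                                     "2010-2011"))

#' @rdname bands
#' @export
band_calendar_post <- function(x)
  band_cut(x, c(2009, 2011, 2013), c("2003-2008", "2009-2010", "2011-2012",
                                     "2013-2014"))

#' Seven-level weight-change categories
#'
#' Maps an annual BMI-change rate (kg/m2/year) to one of seven categories:
#' rapid loss (< -0.5), moderate loss \[-0.5, -0.3), slow loss
#' \[-0.3, -0.1), stable \[-0.1, 0.1\], slow gain (0.1, 0.3\], moderate gain
#' (0.3, 0.5\], rapid gain (> 0.5). "Stable" is closed on both sides; each
#' loss/gain band is half-open with the boundary belonging to the band
#' nearer zero, so every finite rate has exactly one category.
#'
#' @param rate numeric vector of rates, kg/m2/year; must be finite.
#' @return factor with levels from rapid loss to rapid gain.
#' @export
categorize_rate <- function(rate) {
  if (any(!is.finite(rate))) stop("rate must be finite")
  a <- abs(rate)
  mag <- ifelse(a <= 0.1, "stable",
         ifelse(a <= 0.3, "slow",
         ifelse(a <= 0.5, "moderate", "rapid")))
  out <- ifelse(mag == "stable", "stable",
                paste0(mag, ifelse(rate > 0, " gain", " loss")))
  factor(out, levels = WEIGHT_CATEGORIES)
}

WEIGHT_CATEGORIES <- c("rapid loss", "moderate loss", "slow loss", "stable",
                       "slow gain", "moderate gain", "rapid gain")

#' Select an anchor measurement within a time window
#'
#' Returns the observation inside the closed window `[window[1], window[2]]`
#' whose time is closest to `target`; if two observations are equidistant,
#' the earlier one wins. Returns `NULL` when no observation falls in the
#' window (absence is a value, not an error).
#'
#' @param times numeric times (years relative to diagnosis).
#' @param values measurement values at those times.
#' @param target target time, years.
#' @param window length-2 numeric, closed window bounds (lo < hi).
#' @return `list(time =, value =)` or `NULL`.
#' @export
select_anchor <- function(times, values, target, window) {
  stopifnot(length(window) == 2, window[1] < window[2],
            length(times) == length(values))
  in_win <- which(times >= window[1] & times <= window[2])
  if (length(in_win) == 0) return(NULL)
  d <- abs(times[in_win] - target)
  pick <- in_win[order(d, times[in_win])][1]
  list(time = times[pick], value = values[pick])
}

#' Peri-diagnosis weight-change rate
#'
#' The annualised BMI change across the peri-diagnosis period,
#' `(BMI_1 - BMI_-0.5) / (t_1 - t_-0.5)` in kg/m2 per year, computed from
#' the two anchor measurements flanking it.
#'
#' @param anchors a list with elements `bmi_m05` and `bmi_1`, each
#'   `list(time =, value =)` as returned by [select_anchor()].
#' @return rate in kg/m2/year.
#' @export
peri_change <- function(anchors) {
  a <- anchors$bmi_m05; b <- anchors$bmi_1
  if (is.null(a) || is.null(b)) stop("both peri anchors must be present")
  dt <- b$time - a$time
  if (dt == 0) stop("anchor times coincide; rate undefined")
  (b$value - a$value) / dt
}

ANCHOR_SPECS <- list(
  bmi_m3  = list(target = -3,   window = c(-3, -2)),
  bmi_m05 = list(target = -0.5, window = c(-1.5, -0.5)),
  bmi_1   = list(target = 1,    window = c(1, 2)),
  bmi_5   = list(target = 5,    window = c(4, 5)))

#' Build the analysis cohort from an EMR bundle
#'
#' Applies the eligibility rules in sequence and emits one record per
#' eligible individual: diagnosis within the configured calendar years,
#' age at diagnosis at least `min_age`, all four BMI anchor measurements
#' present (closest to -3 years in \[-3, -2\], to -0.5 in \[-1.5, -0.5\],
#' to +1 in \[1, 2\] and to +5 in \[4, 5\] years relative to diagnosis),
#' BMI at the +1 year anchor at least `min_bmi1` kg/m2, and at least one
#' HbA1c measurement in \[1, 2) years after diagnosis. Individuals dropped
#' at each sequential filter are counted in the exclusion log.
#'
#' Each record carries the anchors, the banded covariates for both the pre-
#' and post-diagnosis models, the HbA1c closest to 1 year in \[1, 2), and
#' the peri-diagnosis weight-change rate and category.
#'
#' @param bundle a validated `emr_bundle`.
#' @param diagnosis_years inclusive calendar-year eligibility range.
#' @param min_age minimum age at diagnosis, years.
#' @param min_bmi1 minimum BMI at the +1 year anchor, kg/m2.
#' @return data frame of class `bmi_cohort`, one row per eligible
#'   individual, with the exclusion log in `attr(, "exclusions")`.
#' @export
build_cohort <- function(bundle, diagnosis_years = c(2003, 2014),
                         min_age = 35, min_bmi1 = 25) {
  validate_bundle(bundle)
  demo <- bundle$demographics
  bmi_by_id <- split(bundle$bmi_obs, bundle$bmi_obs$id)
  hba_by_id <- split(bundle$hba1c_obs, bundle$hba1c_obs$id)

  filters <- c("diagnosis_year_out_of_range", "age_under_minimum",
               "missing_pre_diagnosis_anchors", "missing_post_diagnosis_anchors",
               "bmi_1_below_minimum", "no_hba1c_1_to_2_years")
  excl <- stats::setNames(integer(length(filters)), filters)
  records <- vector("list", nrow(demo))

  for (i in seq_len(nrow(demo))) {
    diag_date <- demo$diagnosis_date[i]
    diag_year <- as.integer(format(diag_date, "%Y"))
    if (diag_year < diagnosis_years[1] || diag_year > diagnosis_years[2]) {
      excl["diagnosis_year_out_of_range"] <- excl["diagnosis_year_out_of_range"] + 1L
      next
    }
    age_dx <- as.numeric(diag_date - demo$birth_date[i]) / DAYS_PER_YEAR
    if (age_dx < min_age) {
      excl["age_under_minimum"] <- excl["age_under_minimum"] + 1L
      next
    }
    obs <- bmi_by_id[[demo$id[i]]]
    t_obs <- if (is.null(obs)) numeric(0) else date_to_rel(obs$date, diag_date)
    v_obs <- if (is.null(obs)) numeric(0) else obs$bmi
    anchors <- lapply(ANCHOR_SPECS, function(sp)
      select_anchor(t_obs, v_obs, sp$target, sp$window))
    if (is.null(anchors$bmi_m3) || is.null(anchors$bmi_m05)) {
      excl["missing_pre_diagnosis_anchors"] <- excl["missing_pre_diagnosis_anchors"] + 1L
      next
    }
    if (is.null(anchors$bmi_1) || is.null(anchors$bmi_5)) {
      excl["missing_post_diagnosis_anchors"] <- excl["missing_post_diagnosis_anchors"] + 1L
      next
    }
    if (anchors$bmi_1$value < min_bmi1) {
      excl["bmi_1_below_minimum"] <- excl["bmi_1_below_minimum"] + 1L
      next
    }
    hob <- hba_by_id[[demo$id[i]]]
    t_h <- if (is.null(hob)) numeric(0) else date_to_rel(hob$date, diag_date)
    in_12 <- which(t_h >= 1 & t_h < 2)
    if (length(in_12) == 0) {
      excl["no_hba1c_1_to_2_years"] <- excl["no_hba1c_1_to_2_years"] + 1L
      next
    }
    pick <- in_12[order(abs(t_h[in_12] - 1), t_h[in_12])][1]
    hba1c_1y <- hob$hba1c[pick]

    t_m3_date <- diag_date + round(anchors$bmi_m3$time * DAYS_PER_YEAR)
    age_m3 <- as.numeric(t_m3_date - demo$birth_date[i]) / DAYS_PER_YEAR
    pc <- peri_change(anchors)
    records[[i]] <- data.frame(
      id = demo$id[i], sex = demo$sex[i],
      age_at_diagnosis = age_dx, age_at_bmi_m3 = age_m3,
      age_band_pre = band_age(age_m3), age_band_post = band_age(age_dx),
      deprivation = if (is.na(demo$deprivation_quintile[i])) "missing"
                    else as.character(demo$deprivation_quintile[i]),
      calendar_band_pre = band_calendar_pre(
        as.integer(format(t_m3_date, "%Y"))),
      calendar_band_post = band_calendar_post(diag_year),
      bmi_band_pre = band_bmi_pre(anchors$bmi_m3$value),
      bmi_band_post = band_bmi_post(anchors$bmi_1$value),
      hba1c_1y = hba1c_1y, hba1c_band = band_hba1c(hba1c_1y),
      t_m3 = anchors$bmi_m3$time, bmi_m3 = anchors$bmi_m3$value,
      t_m05 = anchors$bmi_m05$time, bmi_m05 = anchors$bmi_m05$value,
      t_1 = anchors$bmi_1$time, bmi_1 = anchors$bmi_1$value,
      t_5 = anchors$bmi_5$time, bmi_5 = anchors$bmi_5$value,
      peri_change = pc, peri_category = categorize_rate(pc),
      stringsAsFactors = FALSE)
  }

  cohort <- do.call(rbind, records[!vapply(records, is.null, TRUE)])
  if (is.null(cohort)) cohort <- data.frame()
  rownames(cohort) <- NULL
  cohort$deprivation <- factor(cohort$deprivation,
                               levels = c("1", "2", "3", "4", "5", "missing"))
  attr(cohort, "exclusions") <- data.frame(filter = filters,
                                           n_excluded = as.integer(excl),
                                           row.names = NULL)
  class(cohort) <- c("bmi_cohort", "data.frame")
  cohort
}
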