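#' Canonical treatment-regimen label
#'
#' Collapses a set of concurrently active drug classes to a single label.
#' Any set containing insulin is `insulin_any` regardless of co-therapy;
#' otherwise `none`, `mono:<class>`, `dual:<a>+<b>`, `triple:<a>+<b>+<c>`
#' with the class set sorted alphabetically so each combination has one
#' spelling, and `quad_plus` pools the rare regimens of four or more
#' non-insulin agents.
#'
#' @param classes character vector of active drug classes (possibly empty),
#'   drawn from metformin, sulfonylurea, thiazolidinedione, dpp4i, glp1ra,
#'   sglt2i, insulin.
#' @return a single label string.
#' @export
regimen_label <- function(classes) {
  classes <- unique(classes)
  bad <- setdiff(classes, DRUG_CLASSES)
  if (length(bad) > 0) stop("unknown drug class: ", paste(bad, collapse = ", "))
  if ("insulin" %in% classes) return("insulin_any")
  k <- length(classes)
  if (k == 0) return("none")
  if (k >= 4) return("quad_plus")
  pre <- c("mono", "dual", "triple")[k]
  paste0(pre, ":", paste(sort(classes), collapse = "+"))
}

#' Regimen active at a date
#'
#' Collects the drug classes whose dispensing episode
#' `[start_date, end_date + grace_days]` covers the date, and labels the set
#' with [regimen_label()]. The label is invariant to the row order of the
#' episodes.
#'
#' @param rx_episodes data frame with columns `drug_class`, `start_date`,
#'   `end_date` (one individual's episodes).
#' @param date a `Date`.
#' @param grace_days days of continued coverage after an episode's end date.
#' @return a regimen label string.
#' @export
regimen_at <- function(rx_episodes, date, grace_days = 0) {
  if (is.null(rx_episodes) || nrow(rx_episodes) == 0) return("none")
  active <- rx_episodes$drug_class[
    rx_episodes$start_date <= date &
    (rx_episodes$end_date + grace_days) >= date]
  regimen_label(active)
}

#' HbA1c percentage-change category
#'
#' Categorises the percentage change `100 * (current - baseline) / baseline`
#' relative to the baseline (the first HbA1c measurement after 1 year from
#' diagnosis): `no_change` (exactly 0), `dec_0_10` (>0 to <10% decrease),
#' `dec_ge10` (>=10% decrease), `inc_0_10` (>0 to <10% increase),
#' `inc_ge10` (>=10% increase). The +/-10% boundaries belong to the >=10%
#' categories.
#'
#' @param baseline baseline HbA1c, mmol/mol; must be positive.
#' @param current current HbA1c, mmol/mol (vectorised).
#' @return character vector of categories.
#' @export
hba1c_category <- function(baseline, current) {
  if (any(baseline <= 0)) stop("baseline HbA1c must be positive")
  p <- 100 * (current - baseline) / baseline
  ifelse(p == 0, "no_change",
  ifelse(p <= -10, "dec_ge10",
  ifelse(p < 0, "dec_0_10",
  ifelse(p >= 10, "inc_ge10", "inc_0_10"))))
}

HBA1C_CATEGORIES <- c("no_change", "dec_0_10", "dec_ge10", "inc_0_10",
                      "inc_ge10")

#' Attach time-varying exposures to post-diagnosis BMI observations
#'
#' For every BMI observation of every cohort individual with time in
#' `post_window` years after diagnosis, attaches the treatment regimen
#' active at the observation date and the HbA1c change category. The HbA1c
#' baseline is the first measurement at or after 1 year from diagnosis;
#' each BMI observation is paired with the most recent HbA1c at or before
#' its date, falling back to the nearest within `pairing_window_days`;
#' observations with no pairable HbA1c carry the reference category
#' `no_change` and are flagged.
#'
#' @param bundle a validated `emr_bundle`.
#' @param cohort a [build_cohort()] result.
#' @param grace_days passed to [regimen_at()].
#' @param pairing_window_days fallback pairing half-window, days.
#' @param post_window inclusive time window, years from diagnosis.
#' @return data frame (`design_post`): `id`, `date`, `time`, `bmi`,
#'   `regimen`, `hba1c_cat`, `hba1c_unpaired` flag.
#' @export
attach_exposures <- function(bundle, cohort, grace_days = 0,
                             pairing_window_days = 90,
                             post_window = c(1, 5)) {
  validate_bundle(bundle)
  stopifnot(nrow(cohort) > 0)
  demo <- bundle$demographics
  diag_by_id <- stats::setNames(demo$diagnosis_date, demo$id)
  bmi_by_id <- split(bundle$bmi_obs, bundle$bmi_obs$id)
  hba_by_id <- split(bundle$hba1c_obs, bundle$hba1c_obs$id)
  rx_by_id <- split(bundle$rx_episodes, bundle$rx_episodes$id)

  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$id[i]
    diag_date <- diag_by_id[[pid]]
    obs <- bmi_by_id[[pid]]
    t_obs <- date_to_rel(obs$date, diag_date)
    keep <- t_obs >= post_window[1] & t_obs <= post_window[2]
    if (!any(keep)) next
    obs <- obs[keep, , drop = FALSE]; t_obs <- t_obs[keep]

    hob <- hba_by_id[[pid]]
    t_h <- date_to_rel(hob$date, diag_date)
    base_idx <- which(t_h >= 1)
    if (length(base_idx) == 0)
      stop("individual ", pid, " has no baseline HbA1c after 1 year; ",
           "cohort eligibility should prevent this")
    baseline <- hob$hba1c[base_idx[order(t_h[base_idx])][1]]

    rx <- rx_by_id[[pid]]
    regimen <- vapply(obs$date, function(d)
      regimen_at(rx, d, grace_days), character(1))

    cat <- character(nrow(obs)); unpaired <- logical(nrow(obs))
    for (j in seq_len(nrow(obs))) {
      before <- which(hob$date <= obs$date[j])
      if (length(before) > 0) {
        k <- before[which.max(as.numeric(hob$date[before]))]
      } else {
        gap <- abs(as.numeric(hob$date - obs$date[j]))
        k <- if (min(gap) <= pairing_window_days) which.min(gap) else NA_integer_
      }
      if (is.na(k)) { cat[j] <- "no_change"; unpaired[j] <- TRUE }
      else cat[j] <- hba1c_category(baseline, hob$hba1c[k])
    }
    rows[[i]] <- data.frame(id = pid, date = obs$date, time = t_obs,
                            bmi = obs$bmi, regimen = regimen,
                            hba1c_cat = cat, hba1c_unpaired = unpaired,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
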