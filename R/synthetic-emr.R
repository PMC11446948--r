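#' Simulation configuration for the synthetic EMR generator
#'
#' Builds and validates the parameter set controlling [generate_bundle()].
#' Defaults describe a realistic type 2 diabetes primary-care population:
#' individuals diagnosed in 2003--2014 at a mean age of 65.6 (SD 10.1,
#' floored at 35) years, 43% female, deprivation quintile frequencies as
#' observed in Scottish registry populations, latent BMI one year after
#' diagnosis ~ N(33, 5.9) kg/m2 floored at 25, and piecewise-linear latent
#' BMI trajectories with distinct pre-diagnosis (mean +0.25, SD 0.51
#' kg/m2/year), peri-diagnosis (mean -0.23, SD 0.76) and post-diagnosis
#' (mean -0.14, SD 0.44) slopes. Drug-regimen and HbA1c-change offsets
#' default to plausible magnitudes for the respective drug classes
#' (e.g. metformin monotherapy -0.32 kg/m2, thiazolidinedione +1.22,
#' insulin +0.29; >=10% HbA1c decrease -0.43, >=10% increase +0.48).
#' Measurement error is serially correlated within individual with
#' correlation `resid_rho^gap` for a gap in years.
#'
#' @param n_individuals number of individuals to simulate.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   bundles.
#' @param diagnosis_year_range two calendar years, inclusive.
#' @param age_at_diagnosis_dist `c(mean, sd)` in years; draws below 35 are
#'   floored at 35.
#' @param sex_ratio proportion female.
#' @param deprivation_probs probabilities of quintiles 1 (most deprived) to
#'   5; must sum to 1.
#' @param deprivation_missing_prob probability the quintile is unrecorded.
#' @param baseline_bmi_dist `c(mean, sd)` of the latent BMI at +1 year,
#'   kg/m2, floored at 25.
#' @param slope_pre,slope_peri,slope_post `c(mean, sd)` of the latent
#'   piecewise slopes, kg/m2/year (pre: before -0.5 y; peri: -0.5 to +1 y;
#'   post: after +1 y relative to diagnosis).
#' @param covariate_slope_effects named list mapping an age band
#'   (`"<50"`, `"50-<60"`, `"60-<70"`, `">=70"`) to an additive
#'   pre-diagnosis slope effect, kg/m2/year; the band is taken at 2.75
#'   years before diagnosis, the middle of the pre-diagnosis anchor window
#'   where the analysis bands age.
#' @param drug_effects named list mapping a regimen label (see
#'   [regimen_at()]) to an additive BMI offset, kg/m2, applied while the
#'   regimen is active; unlisted labels contribute 0.
#' @param hba1c_effects named list mapping an HbA1c change category (see
#'   [hba1c_category()]) to an additive BMI offset, kg/m2.
#' @param resid_sd residual (measurement) SD, kg/m2.
#' @param resid_rho residual serial correlation per year gap, in `[0, 1)`.
#' @param visit_rate `c(pre, post)` expected BMI measurements per year
#'   before and after diagnosis (a Poisson visit process).
#' @param hba1c_rate expected HbA1c measurements per year after diagnosis.
#' @param missing_prob probability any scheduled measurement is dropped.
#' @param drug_start_prob probability an individual ever starts glucose
#'   lowering therapy within the study horizon.
#' @param hba1c_baseline_dist `c(mean, sd)` of HbA1c at diagnosis, mmol/mol.
#' @return a validated object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_individuals = 1000,
                       seed = 1L,
                       diagnosis_year_range = c(2003, 2014),
                       age_at_diagnosis_dist = c(65.6, 10.1),
                       sex_ratio = 0.43,
                       deprivation_probs = c(598, 626, 502, 465, 485) / 2676,
                       deprivation_missing_prob = 60 / 2736,
                       baseline_bmi_dist = c(33, 5.9),
                       slope_pre = c(0.25, 0.51),
                       slope_peri = c(-0.23, 0.76),
                       slope_post = c(-0.14, 0.44),
                       covariate_slope_effects = list(),
                       drug_effects = list(
                         "mono:metformin" = -0.32,
                         "mono:sulfonylurea" = 0.31,
                         "mono:thiazolidinedione" = 1.22,
                         "insulin_any" = 0.29,
                         "dual:metformin+sglt2i" = -1.04,
                         "dual:glp1ra+metformin" = -0.79,
                         "dual:dpp4i+metformin" = -0.39),
                       hba1c_effects = list(
                         dec_0_10 = -0.20, dec_ge10 = -0.43,
                         inc_0_10 = 0.20, inc_ge10 = 0.48),
                       resid_sd = 1.0,
                       resid_rho = 0.5,
                       visit_rate = c(pre = 1.2, post = 1.8),
                       hba1c_rate = 2.0,
                       missing_prob = 0.1,
                       drug_start_prob = 0.5,
                       hba1c_baseline_dist = c(55, 13)) {
  cfg <- list(n_individuals = as.integer(n_individuals), seed = as.integer(seed),
              diagnosis_year_range = diagnosis_year_range,
              age_at_diagnosis_dist = age_at_diagnosis_dist,
              sex_ratio = sex_ratio, deprivation_probs = deprivation_probs,
              deprivation_missing_prob = deprivation_missing_prob,
              baseline_bmi_dist = baseline_bmi_dist,
              slope_pre = slope_pre, slope_peri = slope_peri,
              slope_post = slope_post,
              covariate_slope_effects = covariate_slope_effects,
              drug_effects = drug_effects, hba1c_effects = hba1c_effects,
              resid_sd = resid_sd, resid_rho = resid_rho,
              visit_rate = visit_rate, hba1c_rate = hba1c_rate,
              missing_prob = missing_prob, drug_start_prob = drug_start_prob,
              hba1c_baseline_dist = hba1c_baseline_dist)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals <= 0) stop("n_individuals must be positive")
  if (abs(sum(cfg$deprivation_probs) - 1) > 1e-9)
    stop("deprivation_probs must sum to 1")
  probs <- c(cfg$deprivation_probs, cfg$deprivation_missing_prob,
             cfg$sex_ratio, cfg$missing_prob, cfg$drug_start_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$resid_sd <= 0) stop("resid_sd must be > 0")
  if (cfg$resid_rho < 0 || cfg$resid_rho >= 1)
    stop("resid_rho must lie in [0, 1)")
  if (any(cfg$visit_rate < 0) || cfg$hba1c_rate < 0)
    stop("visit rates must be non-negative")
  if (diff(cfg$diagnosis_year_range) < 0)
    stop("diagnosis_year_range must be increasing")
  invisible(cfg)
}

DRUG_CLASSES <- c("metformin", "sulfonylurea", "thiazolidinedione",
                  "dpp4i", "glp1ra", "sglt2i", "insulin")
# class mix for first-line / add-on therapy, metformin-dominant
DRUG_START_PROBS <- c(0.72, 0.10, 0.03, 0.06, 0.03, 0.04, 0.02)

DAYS_PER_YEAR <- 365.25

rel_to_date <- function(diagnosis_date, t_years) {
  diagnosis_date + round(t_years * DAYS_PER_YEAR)
}

date_to_rel <- function(date, diagnosis_date) {
  as.numeric(date - diagnosis_date) / DAYS_PER_YEAR
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic EMR bundle
#'
#' Simulates demographics, BMI observations, HbA1c observations and
#' prescribing episodes for `n_individuals`, together with a truth ledger
#' recording each individual's latent intercept and slopes and each
#' observation's active regimen, HbA1c change category and error term.
#'
#' Each individual carries a latent piecewise-linear BMI trajectory with
#' knots at -0.5 and +1 years relative to diagnosis. An observed BMI at time
#' t adds the active drug-regimen offset, the HbA1c-change-category offset
#' (both coded exactly as the analysis codes them: insulin-dominant regimen
#' labels; percentage change from the first HbA1c after 1 year, carried
#' forward from the most recent measurement) and serially correlated
#' Gaussian error with correlation `resid_rho^gap`. Observation times come
#' from Poisson visit processes over \[-3, 0\) and \[0, 5\] years, thinned
#' by `missing_prob`; HbA1c times from a Poisson process over \[0.2, 5\].
#' Drug therapy starts at a random time after diagnosis in treated
#' individuals and may be intensified (a second agent, or a switch to
#' insulin) later; episodes are emitted as explicit start/end dates.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `emr_bundle`: a list of data frames
#'   `demographics`, `bmi_obs`, `hba1c_obs`, `rx_episodes`, `truth`.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(cfg) {
  n <- cfg$n_individuals
  ids <- sprintf("P%05d", seq_len(n))

  yr0 <- cfg$diagnosis_year_range[1]; yr1 <- cfg$diagnosis_year_range[2]
  diag_date <- as.Date(sprintf("%d-01-01", yr0)) +
    floor(stats::runif(n) * (as.numeric(as.Date(sprintf("%d-12-31", yr1)) -
                                        as.Date(sprintf("%d-01-01", yr0))) + 1))
  age <- pmax(stats::rnorm(n, cfg$age_at_diagnosis_dist[1],
                           cfg$age_at_diagnosis_dist[2]), 35)
  birth_date <- diag_date - round(age * DAYS_PER_YEAR)
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "F", "M")
  dep <- sample(1:5, n, replace = TRUE, prob = cfg$deprivation_probs)
  dep[stats::runif(n) < cfg$deprivation_missing_prob] <- NA_integer_

  bmi1 <- pmax(stats::rnorm(n, cfg$baseline_bmi_dist[1],
                            cfg$baseline_bmi_dist[2]), 25)
  # slope effects attach to the age band at the middle of the pre-diagnosis
  # anchor window (~2.75 years before diagnosis), where the analysis bands age
  age_band <- band_age(age - 2.75)
  slope_adj <- unname(vapply(as.character(age_band), function(b) {
    v <- cfg$covariate_slope_effects[[b]]
    if (is.null(v)) 0 else v
  }, numeric(1)))
  s_pre <- stats::rnorm(n, cfg$slope_pre[1], cfg$slope_pre[2]) + slope_adj
  s_peri <- stats::rnorm(n, cfg$slope_peri[1], cfg$slope_peri[2])
  s_post <- stats::rnorm(n, cfg$slope_post[1], cfg$slope_post[2])

  demographics <- data.frame(
    id = ids, sex = sex,
    birth_date = birth_date, diagnosis_date = diag_date,
    deprivation_quintile = dep, stringsAsFactors = FALSE)

  bmi_rows <- vector("list", n); hba_rows <- vector("list", n)
  rx_rows <- vector("list", n); truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    # -- visit processes -------------------------------------------------
    t_bmi <- sort(c(sim_poisson_times(-3, 0, cfg$visit_rate[["pre"]]),
                    sim_poisson_times(0, 5, cfg$visit_rate[["post"]])))
    t_bmi <- t_bmi[stats::runif(length(t_bmi)) >= cfg$missing_prob]
    t_hba <- sort(sim_poisson_times(0.2, 5, cfg$hba1c_rate))
    t_hba <- t_hba[stats::runif(length(t_hba)) >= cfg$missing_prob]

    # -- prescribing episodes -------------------------------------------
    rx <- sim_rx_episodes(cfg)
    # -- HbA1c series: random walk from baseline, drifting down on drugs
    h0 <- max(stats::rnorm(1, cfg$hba1c_baseline_dist[1],
                           cfg$hba1c_baseline_dist[2]), 30)
    hvals <- numeric(length(t_hba))
    if (length(t_hba) > 0) {
      h <- h0
      t_prev <- 0
      for (k in seq_along(t_hba)) {
        dt <- t_hba[k] - t_prev
        on_drug <- nrow(rx) > 0 &&
          any(rx$start <= t_hba[k] & rx$end >= t_hba[k])
        drift <- if (on_drug) -1.5 else 0.8    # mmol/mol per year
        h <- max(h + drift * dt + stats::rnorm(1, 0, 2 * sqrt(dt)), 25)
        hvals[k] <- round(h, 1)   # the recorded value drives the BMI offset
        t_prev <- t_hba[k]
      }
    }

    # -- observed BMI ----------------------------------------------------
    latent <- latent_bmi(t_bmi, bmi1[i], s_pre[i], s_peri[i], s_post[i])
    regimen <- vapply(t_bmi, function(tt)
      regimen_label_at_rel(rx, tt), character(1))
    drug_off <- unname(vapply(regimen, function(r) {
      v <- cfg$drug_effects[[r]]; if (is.null(v)) 0 else v
    }, numeric(1)))
    hb_cat <- hba1c_cat_series(t_bmi, t_hba, hvals)
    hb_off <- unname(vapply(hb_cat, function(cc) {
      v <- cfg$hba1c_effects[[cc]]; if (is.null(v)) 0 else v
    }, numeric(1)))
    err <- sim_ar_errors(t_bmi, cfg$resid_sd, cfg$resid_rho)
    bmi_obs <- pmax(latent + drug_off + hb_off + err, 12)

    d_bmi <- rel_to_date(diag_date[i], t_bmi)
    keep <- !duplicated(d_bmi)          # one measurement per calendar day
    bmi_rows[[i]] <- data.frame(id = ids[i], date = d_bmi[keep],
                                bmi = round(bmi_obs[keep], 2))
    if (length(t_hba) > 0)
      hba_rows[[i]] <- data.frame(id = ids[i],
                                  date = rel_to_date(diag_date[i], t_hba),
                                  hba1c = hvals)
    if (nrow(rx) > 0)
      rx_rows[[i]] <- data.frame(id = ids[i], drug_class = rx$class,
                                 start_date = rel_to_date(diag_date[i], rx$start),
                                 end_date = rel_to_date(diag_date[i], rx$end))
    truth_rows[[i]] <- data.frame(
      id = ids[i], date = d_bmi[keep], time = t_bmi[keep],
      latent_bmi = latent[keep], regimen = regimen[keep],
      hba1c_category = hb_cat[keep], error = err[keep],
      intercept_1y = bmi1[i], slope_pre = s_pre[i],
      slope_peri = s_peri[i], slope_post = s_post[i])
  }

  bundle <- structure(list(
    demographics = demographics,
    bmi_obs = do.call(rbind, bmi_rows[!vapply(bmi_rows, is.null, TRUE)]),
    hba1c_obs = do.call(rbind, hba_rows[!vapply(hba_rows, is.null, TRUE)]),
    rx_episodes = do.call(rbind, rx_rows[!vapply(rx_rows, is.null, TRUE)]),
    truth = do.call(rbind, truth_rows)), class = "emr_bundle")
  for (nmi in names(bundle)) if (is.data.frame(bundle[[nmi]]))
    rownames(bundle[[nmi]]) <- NULL
  if (is.null(bundle$hba1c_obs))
    bundle$hba1c_obs <- data.frame(id = character(), date = as.Date(character()),
                                   hba1c = numeric())
  if (is.null(bundle$rx_episodes))
    bundle$rx_episodes <- data.frame(id = character(),
                                     drug_class = character(),
                                     start_date = as.Date(character()),
                                     end_date = as.Date(character()))
  validate_bundle(bundle)
  bundle
}

# latent piecewise-linear trajectory anchored at the +1 year value
latent_bmi <- function(t, bmi1, s_pre, s_peri, s_post) {
  b_m05 <- bmi1 - 1.5 * s_peri          # value at t = -0.5
  ifelse(t >= 1, bmi1 + s_post * (t - 1),
         ifelse(t >= -0.5, bmi1 - s_peri * (1 - t),
                b_m05 + s_pre * (t + 0.5)))
}

sim_poisson_times <- function(lo, hi, rate) {
  k <- stats::rpois(1, rate * (hi - lo))
  if (k == 0) return(numeric(0))
  stats::runif(k, lo, hi)
}

# serially correlated Gaussian errors, corr = rho^|gap| (times sorted)
sim_ar_errors <- function(t, sd, rho) {
  k <- length(t)
  if (k == 0) return(numeric(0))
  e <- numeric(k)
  e[1] <- stats::rnorm(1)
  if (k > 1) for (j in 2:k) {
    a <- rho^(t[j] - t[j - 1])
    e[j] <- a * e[j - 1] + stats::rnorm(1, 0, sqrt(1 - a^2))
  }
  sd * e
}

# episodes on the relative-years scale: start prob, then possible add-on or
# switch to insulin; everything runs to the end of the horizon
sim_rx_episodes <- function(cfg) {
  out <- data.frame(class = character(), start = numeric(), end = numeric())
  if (stats::runif(1) >= cfg$drug_start_prob) return(out)
  t1 <- stats::runif(1, 0, 3.5)
  c1 <- sample(DRUG_CLASSES, 1, prob = DRUG_START_PROBS)
  out <- rbind(out, data.frame(class = c1, start = t1, end = 5))
  if (c1 != "insulin" && stats::runif(1) < 0.35) {    # intensification
    t2 <- stats::runif(1, t1 + 0.5, 5)
    if (t2 < 5) {
      if (stats::runif(1) < 0.15) {
        out <- rbind(out, data.frame(class = "insulin", start = t2, end = 5))
      } else {
        c2 <- sample(setdiff(DRUG_CLASSES, c("insulin", c1)), 1)
        out <- rbind(out, data.frame(class = c2, start = t2, end = 5))
      }
    }
  }
  out
}

# regimen label from relative-time episodes (generation-side mirror of the
# date-based analysis coding)
regimen_label_at_rel <- function(rx, t) {
  if (nrow(rx) == 0) return("none")
  active <- rx$class[rx$start <= t & rx$end >= t]
  regimen_label(active)
}

# carry-forward HbA1c change category at each BMI time, mirroring the
# analysis coding: baseline = first HbA1c after 1 year; pair with the most
# recent measurement at or before the BMI time, falling back to the nearest
# within 90 days
hba1c_cat_series <- function(t_bmi, t_hba, hvals) {
  out <- rep("no_change", length(t_bmi))
  base_idx <- which(t_hba >= 1)
  if (length(base_idx) == 0) return(out)
  baseline <- hvals[base_idx[1]]
  for (j in seq_along(t_bmi)) {
    if (t_bmi[j] < 1) next
    prev <- which(t_hba <= t_bmi[j])
    if (length(prev) > 0) {
      out[j] <- hba1c_category(baseline, hvals[max(prev)])
    } else {
      gap <- abs(t_hba - t_bmi[j])
      if (min(gap) <= 90 / DAYS_PER_YEAR)
        out[j] <- hba1c_category(baseline, hvals[which.min(gap)])
    }
  }
  out
}

#' Validate an EMR bundle against its schema
#'
#' Checks referential integrity (every observation and prescribing id exists
#' in demographics), date ordering of prescribing episodes, and positivity
#' of BMI and HbA1c values. Violations raise an error naming the offending
#' table, column and rows.
#'
#' @param bundle an `emr_bundle` (from [generate_bundle()] or
#'   [read_bundle()]).
#' @return the bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  req <- list(
    demographics = c("id", "sex", "birth_date", "diagnosis_date",
                     "deprivation_quintile"),
    bmi_obs = c("id", "date", "bmi"),
    hba1c_obs = c("id", "date", "hba1c"),
    rx_episodes = c("id", "drug_class", "start_date", "end_date"))
  for (tb in names(req)) {
    if (!is.data.frame(bundle[[tb]]))
      stop("bundle table '", tb, "' missing")
    miss <- setdiff(req[[tb]], names(bundle[[tb]]))
    if (length(miss) > 0)
      stop("table '", tb, "' lacks columns: ", paste(miss, collapse = ", "))
  }
  ids <- bundle$demographics$id
  if (anyDuplicated(ids)) stop("duplicate ids in demographics")
  for (tb in c("bmi_obs", "hba1c_obs", "rx_episodes")) {
    bad <- which(!(bundle[[tb]]$id %in% ids))
    if (length(bad) > 0)
      stop("table '", tb, "': unknown ids at rows ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(bundle$rx_episodes$end_date < bundle$rx_episodes$start_date)
  if (length(bad) > 0)
    stop("table 'rx_episodes': end_date before start_date at rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad_cls <- which(!(bundle$rx_episodes$drug_class %in% DRUG_CLASSES))
  if (length(bad_cls) > 0)
    stop("table 'rx_episodes': unknown drug_class at rows ",
         paste(utils::head(bad_cls, 5), collapse = ", "))
  if (any(bundle$bmi_obs$bmi <= 0))
    stop("table 'bmi_obs': non-positive bmi values")
  if (nrow(bundle$hba1c_obs) > 0 && any(bundle$hba1c_obs$hba1c <= 0))
    stop("table 'hba1c_obs': non-positive hba1c values")
  invisible(bundle)
}

#' @export
print.emr_bundle <- function(x, ...) {
  cat("Synthetic EMR bundle:\n")
  cat(sprintf("  %d individuals, %d BMI obs, %d HbA1c obs, %d rx episodes%s\n",
              nrow(x$demographics), nrow(x$bmi_obs), nrow(x$hba1c_obs),
              nrow(x$rx_episodes),
              if (!is.null(x$truth)) ", truth ledger attached" else ""))
  invisible(x)
}

#' Write / read an EMR bundle as CSV files
#'
#' `write_bundle()` writes `demographics.csv`, `bmi_obs.csv`,
#' `hba1c_obs.csv`, `rx_episodes.csv` and (if present) `truth.csv` into a
#' directory; `read_bundle()` reads them back and re-validates. Dates are
#' ISO-8601; a missing deprivation quintile round-trips as an empty field.
#' The truth ledger is written for reference but never read by the analysis
#' functions.
#'
#' @param bundle an `emr_bundle`.
#' @param directory target/source directory.
#' @return `write_bundle()`: the file paths, invisibly. `read_bundle()`: an
#'   `emr_bundle` (without truth unless `truth = TRUE` and the file exists).
#' @export
write_bundle <- function(bundle, directory) {
  validate_bundle(bundle)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tb in c("demographics", "bmi_obs", "hba1c_obs", "rx_episodes", "truth")) {
    if (is.null(bundle[[tb]])) next
    f <- file.path(directory, paste0(tb, ".csv"))
    utils::write.csv(bundle[[tb]], f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname write_bundle
#' @param truth also read `truth.csv` if present.
#' @export
read_bundle <- function(directory, truth = FALSE) {
  rd <- function(f, dates) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop("missing bundle file: ", path)
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (d in dates) x[[d]] <- as.Date(x[[d]])
    x
  }
  bundle <- list(
    demographics = rd("demographics.csv", c("birth_date", "diagnosis_date")),
    bmi_obs = rd("bmi_obs.csv", "date"),
    hba1c_obs = rd("hba1c_obs.csv", "date"),
    rx_episodes = rd("rx_episodes.csv", c("start_date", "end_date")))
  if (!is.integer(bundle$demographics$deprivation_quintile))
    bundle$demographics$deprivation_quintile <-
      as.integer(bundle$demographics$deprivation_quintile)
  if (truth && file.exists(file.path(directory, "truth.csv")))
    bundle$truth <- utils::read.csv(file.path(directory, "truth.csv"),
                                    stringsAsFactors = FALSE)
  class(bundle) <- "emr_bundle"
  validate_bundle(bundle)
  bundle
}
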