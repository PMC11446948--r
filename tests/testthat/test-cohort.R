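test_that("anchor selection picks the in-window observation closest to the target", {
  t <- c(-2.9, -2.1); v <- c(31.0, 32.0)
  expect_equal(select_anchor(t, v, -3, c(-3, -2)),
               list(time = -2.9, value = 31.0))
  # nothing inside the window is a value, not an error
  expect_null(select_anchor(-1.9, 30.0, -3, c(-3, -2)))
  # window endpoints are closed
  expect_equal(select_anchor(c(-3, -2), c(30, 31), -3, c(-3, -2))$time, -3)
  expect_equal(select_anchor(-2, 31, -3, c(-3, -2))$time, -2)
  # equidistant pair inside the window: the earlier observation wins
  tie <- select_anchor(c(-2.4, -2.6), c(29, 28), -2.5, c(-3, -2))
  expect_equal(tie, list(time = -2.6, value = 28))
})

test_that("weight-change categorisation partitions the line with the stated boundaries", {
  expect_equal(as.character(categorize_rate(0.6)), "rapid gain")
  expect_equal(as.character(categorize_rate(0.0)), "stable")
  expect_equal(as.character(categorize_rate(-0.4)), "moderate loss")
  # boundary sweep: each boundary belongs to exactly one category
  sweep <- categorize_rate(c(-0.5, -0.3, -0.1, 0.1, 0.3, 0.5))
  expect_equal(as.character(sweep),
               c("moderate loss", "slow loss", "stable", "stable",
                 "slow gain", "moderate gain"))
  eps <- 1e-9
  expect_equal(as.character(categorize_rate(c(-0.5 - eps, 0.5 + eps))),
               c("rapid loss", "rapid gain"))
  # property: every finite rate gets exactly one of the seven levels, with
  # losses negative and gains positive
  set.seed(1)
  r <- stats::runif(500, -2, 2)
  cat <- categorize_rate(r)
  expect_false(anyNA(cat))
  expect_true(all(r[grepl("loss", cat)] < 0))
  expect_true(all(r[grepl("gain", cat)] > 0))
  expect_true(all(abs(r[cat == "stable"]) <= 0.1))
  expect_error(categorize_rate(NaN), "finite")
})

test_that("peri-diagnosis change is the anchored difference divided by elapsed time", {
  a <- list(bmi_m05 = list(time = -0.55, value = 32.0),
            bmi_1 = list(time = 1.20, value = 31.0))
  expect_equal(peri_change(a), -1.0 / 1.75, tolerance = 1e-12)
  a$bmi_1$value <- 32.0
  expect_equal(peri_change(a), 0.0)
  expect_equal(peri_change(list(bmi_m05 = list(time = -0.5, value = 30.0),
                                bmi_1 = list(time = 1.0, value = 31.5))), 1.0)
  expect_error(peri_change(list(bmi_m05 = list(time = 1, value = 30),
                                bmi_1 = list(time = 1, value = 31))),
               "undefined")
})

test_that("covariate bands use the fixed printed cut-points", {
  expect_equal(as.character(band_age(49.9)), "<50")
  expect_equal(as.character(band_age(c(50, 70))), c("50-<60", ">=70"))
  expect_equal(as.character(band_hba1c(c(54, 53.9, 42.9))),
               c(">=54", "48-<54", "<43"))
  expect_equal(as.character(band_bmi_post(25.0)), "25-<30")
  expect_equal(as.character(band_bmi_pre(c(29.9, 40))), c("<30", ">=40"))
  expect_equal(as.character(band_calendar_pre(c(2005, 2006, 2009, 2010))),
               c("<2006", "2006-2007", "2008-2009", "2010-2011"))
  expect_equal(as.character(band_calendar_post(c(2003, 2008, 2009, 2014))),
               c("2003-2008", "2003-2008", "2009-2010", "2013-2014"))
})

# ten hand-built individuals: 7 fully eligible, 3 failing only the BMI_1
# >= 25 rule
eligible_person <- function(id, bmi1 = 32, diag = as.Date("2010-06-15"),
                            age = 60) {
  list(id = id, diag = diag, age = age, sex = "F",
       bmi = data.frame(t = c(-2.8, -1.0, 1.2, 4.5),
                        v = c(bmi1 + 1, bmi1 + 0.5, bmi1, bmi1 - 0.5)),
       hba1c = data.frame(t = c(1.3, 2.5), v = c(50, 52)))
}

test_that("eligibility filters count exclusions sequentially and exactly", {
  people <- c(lapply(1:7, function(i) eligible_person(sprintf("A%02d", i))),
              lapply(8:10, function(i) eligible_person(sprintf("A%02d", i),
                                                       bmi1 = 23)))
  b <- toy_bundle(people)
  ch <- build_cohort(b)
  expect_equal(nrow(ch), 7L)
  ex <- attr(ch, "exclusions")
  expect_equal(ex$n_excluded[ex$filter == "bmi_1_below_minimum"], 3L)
  expect_equal(sum(ex$n_excluded) + nrow(ch), 10L)

  # an individual with no pre-diagnosis BMI lands in the pre-anchor filter
  p <- eligible_person("B01")
  p$bmi <- p$bmi[p$bmi$t > 0, ]
  ch2 <- build_cohort(toy_bundle(c(list(p), lapply(1:2, function(i)
    eligible_person(sprintf("C%02d", i))))))
  ex2 <- attr(ch2, "exclusions")
  expect_equal(ex2$n_excluded[ex2$filter == "missing_pre_diagnosis_anchors"], 1L)

  # age and diagnosis-year rules
  p_young <- eligible_person("D01", age = 30)
  p_early <- eligible_person("D02", diag = as.Date("2001-03-01"))
  p_no_hba <- eligible_person("D03"); p_no_hba$hba1c <- p_no_hba$hba1c[0, ]
  ch3 <- build_cohort(toy_bundle(list(p_young, p_early, p_no_hba,
                                      eligible_person("D04"))))
  ex3 <- attr(ch3, "exclusions")
  expect_equal(nrow(ch3), 1L)
  expect_equal(ex3$n_excluded[ex3$filter == "age_under_minimum"], 1L)
  expect_equal(ex3$n_excluded[ex3$filter == "diagnosis_year_out_of_range"], 1L)
  expect_equal(ex3$n_excluded[ex3$filter == "no_hba1c_1_to_2_years"], 1L)
})

test_that("the HbA1c eligibility window is [1, 2) years", {
  p_lo <- eligible_person("E01")
  p_lo$hba1c <- data.frame(t = 0.95, v = 50)   # just before the window
  p_hi <- eligible_person("E02")
  p_hi$hba1c <- data.frame(t = 2.05, v = 50)   # just after
  p_in <- eligible_person("E03")
  p_in$hba1c <- data.frame(t = 1.95, v = 50)   # inside
  ch <- build_cohort(toy_bundle(list(p_lo, p_hi, p_in)))
  expect_equal(ch$id, "E03")
})

test_that("included records carry complete bands and a finite peri rate", {
  b <- generate_bundle(sim_config(n_individuals = 300, seed = 21))
  ch <- build_cohort(b)
  expect_gt(nrow(ch), 20)
  band_cols <- c("age_band_pre", "age_band_post", "calendar_band_pre",
                 "calendar_band_post", "bmi_band_pre", "bmi_band_post",
                 "hba1c_band", "deprivation", "peri_category")
  for (cc in band_cols) expect_false(anyNA(ch[[cc]]), info = cc)
  expect_true(all(is.finite(ch$peri_change)))
  expect_true(all(ch$bmi_1 >= 25))
  expect_true(all(ch$t_m3 >= -3 & ch$t_m3 <= -2))
  expect_true(all(ch$t_m05 >= -1.5 & ch$t_m05 <= -0.5))
  expect_true(all(ch$t_1 >= 1 & ch$t_1 <= 2))
  expect_true(all(ch$t_5 >= 4 & ch$t_5 <= 5))
  expect_equal(as.character(ch$peri_category),
               as.character(categorize_rate(ch$peri_change)))
  # exclusion accounting holds on simulated data too
  expect_equal(nrow(ch) + sum(attr(ch, "exclusions")$n_excluded), 300L)
  # missing deprivation is a level of its own
  expect_true("missing" %in% levels(ch$deprivation))
})

test_that("an empty bundle yields an empty cohort with a complete log", {
  b <- toy_bundle(list(eligible_person("Z1")))
  b$demographics <- b$demographics[0, ]
  b$bmi_obs <- b$bmi_obs[0, ]; b$hba1c_obs <- b$hba1c_obs[0, ]
  ch <- build_cohort(b)
  expect_equal(nrow(ch), 0L)
  expect_equal(sum(attr(ch, "exclusions")$n_excluded), 0L)
})
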