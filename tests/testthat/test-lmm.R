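test_that("block-diagonal likelihood matches dense whole-cohort evaluation", {
  d <- sim_design(12, sigma = 0.8, rho = 0.4, mean_obs = 5, seed = 11)
  grid <- list(
    list(G = matrix(c(2, 0.1, 0.1, 0.09), 2), sigma2 = 0.7, rho = 0.45),
    list(G = matrix(c(1, 0, 0, 0.25), 2), sigma2 = 1.3, rho = 0),
    list(G = matrix(c(0.5, -0.05, -0.05, 0.04), 2), sigma2 = 0.2, rho = 0.9))
  for (g in grid) {
    for (reml in c(TRUE, FALSE)) {
      beta <- c(29, 0.25)
      ours <- lmm_loglik(y ~ time, d, id = "id", G = g$G, sigma2 = g$sigma2,
                         rho = g$rho, beta = beta, reml = reml)
      oracle <- dense_loglik(y ~ time, d, id = "id", G = g$G,
                             sigma2 = g$sigma2, rho = g$rho, beta = beta,
                             reml = reml)
      expect_equal(ours, oracle, tolerance = 1e-8)
    }
  }
})

test_that("with rho = 0 and G = 0 the likelihood is the iid Gaussian sum and GLS is OLS", {
  d <- sim_design(8, sd_int = 0, sd_slope = 0, sigma = 1, rho = 0, seed = 2)
  beta <- c(30, 0.2); sigma2 <- 1.21
  ll <- lmm_loglik(y ~ time, d, id = "id", G = matrix(0, 2, 2),
                   sigma2 = sigma2, rho = 0, beta = beta, reml = FALSE)
  mu <- beta[1] + beta[2] * d$time
  expect_equal(ll, sum(stats::dnorm(d$y, mu, sqrt(sigma2), log = TRUE)),
               tolerance = 1e-10)
  # profiled GLS coefficients collapse to ordinary least squares
  bl <- bmitraject:::lmm_blocks(y ~ time, d, "id", "time")
  acc <- bmitraject:::lmm_gls_pass(bl$blocks, matrix(0, 2, 2), 0, 2)
  ols <- stats::coef(stats::lm(y ~ time, d))
  expect_equal(unname(acc$beta), unname(ols), tolerance = 1e-10)
})

test_that("ML log-likelihood obeys Gaussian scale equivariance", {
  d <- sim_design(6, sigma = 1, rho = 0.3, seed = 3)
  G <- matrix(c(1.2, 0.1, 0.1, 0.09), 2); s2 <- 0.8; beta <- c(30, 0.2)
  ll1 <- lmm_loglik(y ~ time, d, id = "id", G = G, sigma2 = s2, rho = 0.3,
                    beta = beta, reml = FALSE)
  d2 <- d; d2$y <- 2 * d$y
  ll2 <- lmm_loglik(y ~ time, d2, id = "id", G = 4 * G, sigma2 = 4 * s2,
                    rho = 0.3, beta = 2 * beta, reml = FALSE)
  expect_equal(ll2, ll1 - nrow(d) * log(2), tolerance = 1e-8)
})

test_that("near-noiseless data recover the generating line", {
  d <- sim_design(30, beta = c(27, 0.4), sd_int = 0, sd_slope = 0,
                  sigma = 1e-4, rho = 0, seed = 4)
  fit <- lmm_fit(y ~ time, d, id = "id", covariance = "independent")
  expect_equal(fit$beta$estimate[fit$beta$term == "(Intercept)"], 27,
               tolerance = 1e-3)
  expect_equal(fit$beta$estimate[fit$beta$term == "time"], 0.4,
               tolerance = 1e-3)
})

test_that("independent-correlation estimates agree with lme4 on shared parameters", {
  skip_if_not_installed("lme4")
  d <- sim_design(80, sd_int = 1.5, sd_slope = 0.3, cor_is = -0.3,
                  sigma = 1, rho = 0, seed = 5)
  fit <- lmm_fit(y ~ time, d, id = "id", covariance = "independent")
  m <- lme4::lmer(y ~ time + (1 + time | id), data = d, REML = TRUE)
  expect_equal(unname(fit$beta$estimate), unname(lme4::fixef(m)),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(fit$G[1, 1], vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$G[2, 2], vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(m)),
               tolerance = 1e-6)
})

test_that("spatial-power fit agrees with an independent continuous-AR1 implementation", {
  skip_if_not_installed("nlme")
  d <- sim_design(100, sigma = 1, rho = 0.5, mean_obs = 7, seed = 6)
  fit <- lmm_fit(y ~ time, d, id = "id", covariance = "sp_pow")
  m <- nlme::lme(y ~ time, random = ~ time | id, data = d,
                 correlation = nlme::corCAR1(form = ~ time | id),
                 method = "REML",
                 control = nlme::lmeControl(opt = "optim", maxIter = 200))
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(m)),
               tolerance = 1e-5)
  expect_equal(fit$rho,
               as.numeric(stats::coef(m$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 0.02)
  expect_equal(fit$sigma2, m$sigma^2, tolerance = 0.02)
})

test_that("REML optimum is invariant to the optimiser start", {
  d <- sim_design(40, sigma = 1, rho = 0.4, seed = 7)
  f1 <- lmm_fit(y ~ time, d, id = "id",
                start = c(0.2, 0.1, -1.5, stats::qlogis(0.2)))
  f2 <- lmm_fit(y ~ time, d, id = "id",
                start = c(0.8, -0.2, -0.5, stats::qlogis(0.7)))
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-4)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-2)
})

test_that("rank-deficient fixed designs are reported by column name", {
  d <- sim_design(10, seed = 8)
  d$dup <- d$time   # exact copy of the time column
  expect_error(lmm_fit(y ~ time + dup, d, id = "id"), "dup")
  expect_message(fit <- lmm_fit(y ~ time + dup, d, id = "id",
                                on_rank_deficient = "drop"), "dup")
  expect_false("dup" %in% fit$beta$term)
})

test_that("studentised residuals match the dense marginal-moment oracle and flag gross outliers", {
  d <- sim_design(40, sigma = 1, rho = 0.4, seed = 9)
  hit <- 57L
  d$y[hit] <- d$y[hit] + 10   # displace one observation by ~10 sigma
  fit <- lmm_fit(y ~ time, d, id = "id")
  st <- lmm_studentized(fit)
  expect_equal(length(st), nrow(d))
  # oracle recomputation of the marginal sd at the fitted parameters
  sd_or <- dense_marginal_sd(d, id = "id", G = fit$G, sigma2 = fit$sigma2,
                             rho = fit$rho)
  ord <- order(match(d$id, unique(d$id)), d$time)
  X <- stats::model.matrix(y ~ time, d)
  r <- d$y - drop(X %*% fit$beta$estimate)
  st_or <- numeric(nrow(d)); st_or[ord] <- r[ord] / sd_or
  expect_equal(st, st_or, tolerance = 1e-8)
  expect_equal(which.max(abs(st)), hit)
})

test_that("outlier pass removes only flagged rows and an infinite threshold is a no-op", {
  d <- sim_design(40, sigma = 1, rho = 0.4, seed = 10)
  fit_inf <- lmm_refit_outliers(y ~ time, d, id = "id", threshold = Inf)
  fit_plain <- lmm_fit(y ~ time, d, id = "id")
  expect_identical(fit_inf$n_outliers_removed, 0L)
  expect_equal(fit_inf$beta$estimate, fit_plain$beta$estimate)
  expect_equal(fit_inf$reml_loglik, fit_plain$reml_loglik)

  # monotone rule: raising the threshold never removes more observations
  d$y[c(10, 80)] <- d$y[c(10, 80)] + 8
  removed <- vapply(c(2, 3, 4, Inf), function(th)
    lmm_refit_outliers(y ~ time, d, id = "id", threshold = th)$n_outliers_removed,
    integer(1))
  expect_true(all(diff(removed) <= 0))
  expect_true(removed[length(removed)] == 0L)
})

test_that("trajectories shrink subject slopes toward the population slope", {
  # centred time keeps the per-subject intercept and slope near-orthogonal,
  # so the BLUP slope sits between the subject OLS slope and the population
  # slope (up to the small residual intercept leakage)
  d <- sim_design(200, beta = c(30, 0.2), sd_int = 1, sd_slope = 0.4,
                  sigma = 0.8, rho = 0, mean_obs = 8, t_range = c(-2, 2),
                  seed = 12)
  fit <- lmm_fit(y ~ time, d, id = "id", covariance = "independent")
  tr <- lmm_trajectories(fit)
  b_time <- fit$beta$estimate[fit$beta$term == "time"]
  ols <- ols_slopes(d)
  ok <- !is.na(ols)
  lo <- pmin(ols[ok], b_time) - 0.05
  hi <- pmax(ols[ok], b_time) + 0.05
  rate <- tr$rate[match(names(ols)[ok], tr$id)]
  expect_true(mean(rate >= lo & rate <= hi) > 0.95)
  # shrinkage never inflates: the BLUP rate is no farther from the
  # population slope than the subject's own OLS slope is
  expect_true(mean(abs(rate - b_time) <= abs(ols[ok] - b_time) + 0.05) > 0.95)
  # estimated rates track the simulated truth
  truth <- vapply(split(d, d$id), function(x) x$true_slope[1], numeric(1))
  expect_gt(stats::cor(tr$rate, truth[tr$id], method = "spearman"), 0.8)
})

test_that("zero slope variance forces every trajectory to the fixed slope", {
  d <- sim_design(30, beta = c(30, 0.25), sd_int = 1, sd_slope = 0,
                  sigma = 0.5, rho = 0, seed = 13)
  # evaluate the BLUP formula at a parameter point with (numerically) zero
  # slope variance: every slope deviation must vanish
  bl <- bmitraject:::lmm_blocks(y ~ time, d, "id", "time")
  n <- nrow(bl$X_all); p <- ncol(bl$X_all)
  fin <- bmitraject:::lmm_finalize(c(0, 0, log(1e-8)), bl, n - p, n, p,
                                   est_rho = FALSE, reml = TRUE)
  expect_true(all(abs(fin$blups$slope_dev) < 1e-10))
  # and the fitted model on such data estimates a near-zero slope variance,
  # so the trajectory spread collapses onto the fixed slope
  fit <- lmm_fit(y ~ time, d, id = "id", covariance = "independent")
  tr <- lmm_trajectories(fit)
  b_time <- fit$beta$estimate[fit$beta$term == "time"]
  expect_lt(stats::sd(tr$rate - b_time), 0.05)
})

test_that("trajectories are refused for covariate-by-time interaction models", {
  d <- sim_design(20, seed = 14)
  d$grp <- factor(rep(c("a", "b"), length.out = nrow(d)))
  fit <- lmm_fit(y ~ time + grp + time:grp, d, id = "id",
                 covariance = "independent")
  expect_error(lmm_trajectories(fit), "interaction")
})

test_that("duplicate observation times are perturbed, not fatal", {
  d <- sim_design(10, seed = 15)
  d2 <- rbind(d, d[1, ])   # exact duplicate row
  bl <- bmitraject:::lmm_blocks(y ~ time, d2, "id", "time")
  expect_identical(bl$n_dup_perturbed, 1L)
  expect_silent(fit <- lmm_fit(y ~ time, d2, id = "id"))
  expect_true(fit$converged)
})
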