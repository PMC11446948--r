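#' Linear mixed models with spatial-power residual correlation
#'
#' `lmm_fit()` estimates, by restricted (or ordinary) maximum likelihood, a
#' Gaussian linear mixed-effects model with a per-individual random intercept
#' and random slope on time, and within-individual residual correlation of the
#' continuous-time spatial-power form \eqn{corr(e_s, e_t) = \rho^{|s-t|}}
#' (the continuous-time analogue of AR(1), as used for irregularly timed
#' longitudinal measurements).
#'
#' The marginal covariance for individual i with design rows at times
#' \eqn{t_{i1} \dots t_{in_i}} is \eqn{V_i = Z_i G Z_i' + \sigma^2 R_i} with
#' \eqn{Z_i = [1, t_i]}, G the 2x2 random-effect covariance and
#' \eqn{R_i[j,k] = \rho^{|t_{ij} - t_{ik}|}}. The likelihood is evaluated
#' block-diagonally, one individual at a time; the full-cohort covariance
#' matrix is never materialised. Fixed effects and the residual scale are
#' profiled out analytically, so the optimiser works over three (plus one for
#' \eqn{\rho}) unconstrained parameters: the log-Cholesky factors of
#' \eqn{G/\sigma^2} and the logit of \eqn{\rho}.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `bmi ~ time + age_band + age_band:time`. The time variable must appear
#'   as a main effect.
#' @param data data frame with one row per observation.
#' @param id name of the column identifying individuals.
#' @param time name of the numeric time column (years).
#' @param covariance `"sp_pow"` (spatial power, the default) or
#'   `"independent"` (\eqn{\rho} fixed at 0).
#' @param reml logical; REML (default) or ML.
#' @param max_iter optimiser iteration cap.
#' @param on_rank_deficient `"error"` (default) stops naming aliased fixed
#'   effect columns; `"drop"` removes them with a message.
#' @param start optional numeric starting vector on the unconstrained scale
#'   (advanced use; mainly for checking optimiser-path invariance).
#'
#' @return an object of class `lmm_fit`: a list with elements `beta`
#'   (coefficient table with SE, Wald 95% CI and p value), `G`, `sigma2`,
#'   `rho`, `blups` (per-individual intercept/slope deviations),
#'   `reml_loglik`, `n_obs_used`, `converged`, and internal components used
#'   by [lmm_studentized()] and [lmm_trajectories()].
#'
#' @examples
#' d <- expand.grid(id = 1:20, time = 0:4)
#' set.seed(1)
#' d$y <- 25 + 0.3 * d$time + rnorm(20)[d$id] + rnorm(nrow(d), sd = 0.5)
#' fit <- lmm_fit(y ~ time, d, id = "id", covariance = "independent")
#' fit$beta
#' @export
lmm_fit <- function(formula, data, id = "id", time = "time",
                    covariance = c("sp_pow", "independent"),
                    reml = TRUE, max_iter = 300,
                    on_rank_deficient = c("error", "drop"),
                    start = NULL) {
  covariance <- match.arg(covariance)
  on_rank_deficient <- match.arg(on_rank_deficient)
  blocks <- lmm_blocks(formula, data, id, time, on_rank_deficient)
  p <- ncol(blocks$X_all)
  n <- nrow(blocks$X_all)
  df <- if (reml) n - p else n
  if (length(blocks$blocks) < 2L)
    stop("need at least 2 individuals")
  if (df <= 0) stop("more fixed-effect columns than observations")

  est_rho <- covariance == "sp_pow"
  obj <- function(eta) lmm_prof_dev(eta, blocks, df, n, p, est_rho)

  starts <- if (is.null(start)) lmm_starts(blocks, est_rho) else list(start)
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(s, obj, control = list(iter.max = max_iter,
                                           rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (opt$convergence != 0) {
      # "false convergence" and friends: restart from the solution; accept
      # if the restart settles or the objective no longer moves
      for (k in 1:2) {
        re <- tryCatch(
          stats::nlminb(opt$par, obj, control = list(iter.max = max_iter,
                                                     rel.tol = 1e-10)),
          error = function(e) NULL)
        if (is.null(re) || !is.finite(re$objective)) break
        moved <- opt$objective - re$objective
        opt <- re
        if (re$convergence == 0 || moved < 1e-6 * (1 + abs(re$objective))) {
          opt$convergence <- 0L
          break
        }
      }
    }
    if (is.null(best) || opt$objective < best$objective - 1e-8) best <- opt
    if (opt$convergence == 0) {
      converged <- TRUE
      if (best$objective > opt$objective) best <- opt
      break
    }
  }
  if (is.null(best))
    stop("mixed-model optimisation failed from all starting values")
  if (!converged && best$convergence != 0) {
    cond <- structure(
      class = c("lmm_nonconvergence", "error", "condition"),
      list(message = paste0("mixed-model REML optimisation did not converge (",
                            best$message, "); best-so-far parameters attached"),
           call = sys.call(-1), best = best))
    stop(cond)
  }

  fin <- lmm_finalize(best$par, blocks, df, n, p, est_rho, reml)
  fin$converged <- TRUE
  fin$reml <- reml
  fin$covariance <- covariance
  fin$formula <- formula
  fin$id <- id
  fin$time <- time
  class(fin) <- "lmm_fit"
  fin
}

# Assemble per-individual blocks (X, y, Z, |dt| matrix) once, before
# optimisation. Duplicate observation times within an individual are
# perturbed by one day to keep the correlation matrix positive definite.
lmm_blocks <- function(formula, data, id, time, on_rank_deficient = "error") {
  stopifnot(is.data.frame(data), id %in% names(data), time %in% names(data))
  data <- droplevels(as.data.frame(data))
  tt <- stats::terms(formula, data = data)
  if (!(time %in% all.vars(formula)))
    stop("time variable '", time, "' must appear in the fixed-effect formula")
  mf <- stats::model.frame(tt, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(tt, mf)
  stopifnot(all(is.finite(data[[time]])), all(is.finite(y)))

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    if (on_rank_deficient == "error")
      stop("fixed-effect design is rank deficient; aliased columns: ",
           paste(bad, collapse = ", "))
    message("dropping aliased fixed-effect columns: ",
            paste(bad, collapse = ", "))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }

  ids <- data[[id]]
  tvec <- as.numeric(data[[time]])
  ord <- order(match(ids, unique(ids)), tvec)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; ids <- ids[ord]; tvec <- tvec[ord]

  n_dup <- 0L
  split_idx <- split(seq_along(ids), factor(ids, levels = unique(ids)))
  blocks <- lapply(split_idx, function(ix) {
    t_i <- tvec[ix]
    # nudge exact ties apart by one day so R_i stays invertible
    while (anyDuplicated(t_i)) {
      d <- which(duplicated(t_i))[1L]
      t_i[d] <- t_i[d] + 1 / 365.25
      n_dup <<- n_dup + 1L
    }
    Z <- cbind(1, t_i)
    list(X = X[ix, , drop = FALSE], y = y[ix], Z = Z,
         D = abs(outer(t_i, t_i, "-")), idx = ix, t = t_i)
  })
  list(blocks = blocks, X_all = X, y_all = y, ids = ids,
       id_levels = names(blocks), order = ord, n_dup_perturbed = n_dup,
       time_all = tvec, terms = tt)
}

# eta -> (G/sigma2, rho) on the natural scale
lmm_theta <- function(eta, est_rho) {
  L <- matrix(c(exp(eta[1]), eta[2], 0, exp(eta[3])), 2, 2)
  list(Gs = L %*% t(L), rho = if (est_rho) stats::plogis(eta[4]) else 0)
}

# Profiled -2 log (restricted) likelihood; beta and sigma2 concentrated out.
lmm_prof_dev <- function(eta, blocks, df, n, p, est_rho) {
  th <- lmm_theta(eta, est_rho)
  acc <- lmm_gls_pass(blocks$blocks, th$Gs, th$rho, p)
  if (!acc$ok) return(1e10)
  rss <- acc$yty - sum(acc$beta * acc$XtWy)
  if (rss <= 0) return(1e10)
  sigma2 <- rss / df
  dev <- df * log(2 * pi) + df * log(sigma2) + acc$logdet + df
  if (df != n) dev <- dev + acc$logdet_xtx   # REML: + log|X' V*^-1 X|
  if (!is.finite(dev)) return(1e10)
  dev
}

# One generalised-least-squares sweep over the individual blocks.
lmm_gls_pass <- function(blocks, Gs, rho, p) {
  XtWX <- matrix(0, p, p); XtWy <- numeric(p)
  yty <- 0; logdet <- 0
  for (b in blocks) {
    M <- b$Z %*% Gs %*% t(b$Z) + rho^b$D
    U <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(U))
      U <- tryCatch(chol(M + diag(1e-8, nrow(M))), error = function(e) NULL)
    if (is.null(U)) return(list(ok = FALSE))
    logdet <- logdet + 2 * sum(log(diag(U)))
    Xw <- backsolve(U, b$X, transpose = TRUE)
    yw <- backsolve(U, b$y, transpose = TRUE)
    XtWX <- XtWX + crossprod(Xw)
    XtWy <- XtWy + drop(crossprod(Xw, yw))
    yty <- yty + sum(yw^2)
  }
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  beta <- drop(chol2inv(ch) %*% XtWy)
  list(ok = TRUE, beta = beta, XtWX = XtWX, XtWy = XtWy, yty = yty,
       logdet = logdet, logdet_xtx = 2 * sum(log(diag(ch))), chol_xtwx = ch)
}

# Data-driven start (per-subject OLS variance decomposition) plus one
# conservative fallback used if the first fails to converge.
lmm_starts <- function(blocks, est_rho) {
  ints <- c(); slps <- c(); rv <- c()
  for (b in blocks$blocks) {
    if (nrow(b$X) >= 2 && stats::var(b$t) > 0) {
      f <- stats::lm.fit(b$Z, b$y)
      ints <- c(ints, f$coefficients[1]); slps <- c(slps, f$coefficients[2])
      if (nrow(b$X) >= 3) rv <- c(rv, sum(f$residuals^2) / (nrow(b$X) - 2))
    }
  }
  s2 <- max(mean(rv, na.rm = TRUE), 1e-4)
  if (!is.finite(s2)) s2 <- 1
  vi <- max(stats::var(ints) / s2, 1e-2)
  vs <- max(stats::var(slps) / s2 / 2, 1e-3)  # subject OLS overstates slope var
  if (!is.finite(vi)) vi <- 1; if (!is.finite(vs)) vs <- 0.1
  s1 <- c(0.5 * log(vi), 0, 0.5 * log(vs))
  s2_ <- c(0, 0, log(0.3))
  if (est_rho) { s1 <- c(s1, stats::qlogis(0.3)); s2_ <- c(s2_, stats::qlogis(0.5)) }
  list(s1, s2_)
}

lmm_finalize <- function(eta, blocks, df, n, p, est_rho, reml) {
  th <- lmm_theta(eta, est_rho)
  acc <- lmm_gls_pass(blocks$blocks, th$Gs, th$rho, p)
  rss <- acc$yty - sum(acc$beta * acc$XtWy)
  sigma2 <- rss / df
  vcov_beta <- sigma2 * chol2inv(acc$chol_xtwx)
  se <- sqrt(diag(vcov_beta))
  est <- acc$beta
  nm <- colnames(blocks$X_all)
  beta_tab <- data.frame(
    term = nm, estimate = est, se = se,
    ci_lo = est - stats::qnorm(0.975) * se,
    ci_hi = est + stats::qnorm(0.975) * se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    row.names = NULL)

  dev <- df * log(2 * pi) + df * log(sigma2) + acc$logdet + df
  if (reml) dev <- dev + acc$logdet_xtx

  # BLUPs and per-observation marginal moments
  blup <- matrix(0, length(blocks$blocks), 2)
  fitted_marg <- numeric(n); marg_var <- numeric(n); resid_marg <- numeric(n)
  for (k in seq_along(blocks$blocks)) {
    b <- blocks$blocks[[k]]
    M <- b$Z %*% th$Gs %*% t(b$Z) + th$rho^b$D
    mu <- drop(b$X %*% est)
    r <- b$y - mu
    blup[k, ] <- drop(th$Gs %*% t(b$Z) %*% solve(M, r))
    fitted_marg[b$idx] <- mu
    resid_marg[b$idx] <- r
    marg_var[b$idx] <- sigma2 * diag(M)
  }
  blups <- data.frame(id = blocks$id_levels,
                      intercept_dev = blup[, 1], slope_dev = blup[, 2],
                      row.names = NULL)

  list(beta = beta_tab, vcov_beta = vcov_beta,
       G = sigma2 * th$Gs, sigma2 = sigma2, rho = th$rho,
       blups = blups, reml_loglik = -0.5 * dev,
       n_obs_used = n, n_individuals = length(blocks$blocks),
       n_outliers_removed = 0L,
       eta = eta, blocks = blocks,
       fitted_marginal = fitted_marg, residual_marginal = resid_marg,
       marginal_var = marg_var)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (random intercept + slope,",
      if (x$covariance == "sp_pow") "spatial-power errors)" else "independent errors)",
      "\n")
  cat(sprintf("  %s, %d observations, %d individuals\n",
              if (x$reml) "REML" else "ML", x$n_obs_used, x$n_individuals))
  cat(sprintf("  sigma2 = %.4f, rho = %.4f, log-lik = %.2f\n",
              x$sigma2, x$rho, x$reml_loglik))
  cat("  G (random-effect covariance):\n")
  print(round(x$G, 5))
  cat("  Fixed effects:\n")
  print(x$beta, digits = 4)
  if (x$n_outliers_removed > 0)
    cat(sprintf("  (%d outlying observations removed before refit)\n",
                x$n_outliers_removed))
  invisible(x)
}

#' Marginal log-likelihood at fixed parameter values
#'
#' Evaluates the Gaussian (restricted) log-likelihood of the random
#' intercept/slope model with spatial-power errors at user-supplied parameter
#' values, block-diagonally by individual. Used for likelihood diagnostics
#' and for validating the block computation against dense-matrix evaluation.
#'
#' @inheritParams lmm_fit
#' @param G 2x2 random-effect covariance matrix (intercept, slope).
#' @param sigma2 residual variance.
#' @param rho correlation decay per unit time gap, in `[0, 1)`.
#' @param beta fixed-effect vector; required for ML, ignored under REML
#'   (where the fixed effects are profiled out by generalised least squares).
#' @return scalar log-likelihood.
#' @export
lmm_loglik <- function(formula, data, id = "id", time = "time",
                       G, sigma2, rho = 0, beta = NULL, reml = TRUE) {
  stopifnot(sigma2 > 0, rho >= 0, rho < 1,
            is.matrix(G), all(dim(G) == 2),
            isTRUE(all.equal(G, t(G))))
  bl <- lmm_blocks(formula, data, id, time)
  p <- ncol(bl$X_all); n <- nrow(bl$X_all)
  Gs <- G / sigma2
  acc <- lmm_gls_pass(bl$blocks, Gs, rho, p)
  if (!acc$ok) stop("singular marginal covariance")
  # acc quantities are on the V/sigma2 scale; rescale
  if (reml) {
    rss <- acc$yty - sum(acc$beta * acc$XtWy)
    dev <- (n - p) * log(2 * pi) + n * log(sigma2) + acc$logdet +
      (acc$logdet_xtx - p * log(sigma2)) + rss / sigma2
  } else {
    if (is.null(beta)) beta <- acc$beta
    rss <- 0
    for (b in bl$blocks) {
      M <- b$Z %*% Gs %*% t(b$Z) + rho^b$D
      r <- b$y - drop(b$X %*% beta)
      rss <- rss + drop(crossprod(r, solve(M, r)))
    }
    dev <- n * log(2 * pi) + n * log(sigma2) + acc$logdet + rss / sigma2
  }
  -0.5 * dev
}

#' Internally studentised marginal residuals
#'
#' Marginal residual (observation minus fixed-effect fit) divided by its
#' estimated marginal standard deviation, the square root of the diagonal of
#' the fitted \eqn{V_i = Z_i G Z_i' + \sigma^2 R_i}.
#'
#' @param fit an [lmm_fit()] object.
#' @return numeric vector, one value per observation, in the row order of the
#'   data supplied to `lmm_fit()`.
#' @export
lmm_studentized <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  # moments are stored on the reordered (by id, time) rows; map back
  r <- fit$residual_marginal / sqrt(fit$marginal_var)
  out <- numeric(length(r))
  out[fit$blocks$order] <- r
  out
}

#' Fit with one studentised-residual outlier-removal pass
#'
#' Fits the model, flags observations whose absolute internally studentised
#' residual exceeds `threshold` (default 3 SD), removes them, and refits
#' once. Individuals left with no observations are dropped and counted.
#'
#' @inheritParams lmm_fit
#' @param threshold studentised-residual cut-off; `Inf` disables removal.
#' @param ... passed to [lmm_fit()].
#' @return an `lmm_fit` object with `n_outliers_removed`,
#'   `n_individuals_dropped` and logical `kept_rows` (relative to the input
#'   data) recorded.
#' @export
lmm_refit_outliers <- function(formula, data, id = "id", time = "time",
                               threshold = 3, ...) {
  stopifnot(threshold > 0)
  fit1 <- lmm_fit(formula, data, id = id, time = time, ...)
  st <- lmm_studentized(fit1)
  keep <- abs(st) <= threshold
  n_rm <- sum(!keep)
  if (n_rm == 0L) {
    fit1$kept_rows <- keep
    fit1$n_individuals_dropped <- 0L
    return(fit1)
  }
  kept_data <- data[keep, , drop = FALSE]
  dropped_ids <- setdiff(unique(data[[id]]), unique(kept_data[[id]]))
  fit2 <- lmm_fit(formula, kept_data, id = id, time = time, ...)
  fit2$n_outliers_removed <- n_rm
  fit2$n_individuals_dropped <- length(dropped_ids)
  fit2$kept_rows <- keep
  fit2
}

#' Per-individual annual trajectory from a fitted model
#'
#' The individual rate of change is the population (fixed) time slope plus
#' the individual's BLUP slope deviation. This is only meaningful for base
#' models whose fixed part contains a single common time slope (an intercept,
#' time, and optionally time-constant exposure offsets); for models with
#' covariate-by-time interactions the population slope differs by covariate
#' level and the request is refused.
#'
#' @param fit an [lmm_fit()] object.
#' @return data frame with columns `id` and `rate` (response units per unit
#'   time, here kg/m2 per year).
#' @export
lmm_trajectories <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  lab <- attr(fit$blocks$terms, "term.labels")
  inter <- grep(":", lab, value = TRUE)
  inter_t <- inter[vapply(strsplit(inter, ":", fixed = TRUE),
                          function(v) fit$time %in% v, logical(1))]
  if (length(inter_t) > 0)
    stop("model contains covariate-by-time interactions (",
         paste(inter_t, collapse = ", "), "); individual trajectories are ",
         "defined only for a base model with a single common time slope - ",
         "refit without the interactions to derive trajectories")
  b_time <- fit$beta$estimate[fit$beta$term == fit$time]
  if (length(b_time) != 1L)
    stop("no '", fit$time, "' slope in the fixed effects")
  data.frame(id = fit$blups$id, rate = b_time + fit$blups$slope_dev,
             row.names = NULL)
}
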