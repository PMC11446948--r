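# Independent oracles and fixture builders shared across the test files.

# Dense whole-cohort evaluation of the Gaussian (restricted) log-likelihood:
# assembles the full n x n marginal covariance and uses generic determinant /
# solve calls. Deliberately independent of the package's block-diagonal path.
dense_loglik <- function(formula, data, id = "id", time = "time",
                         G, sigma2, rho = 0, beta = NULL, reml = TRUE) {
  data <- data[order(match(data[[id]], unique(data[[id]])), data[[time]]), ]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  V <- matrix(0, n, n)
  for (s in split(seq_len(n), factor(data[[id]], levels = unique(data[[id]])))) {
    t_i <- data[[time]][s]
    Z <- cbind(1, t_i)
    V[s, s] <- Z %*% G %*% t(Z) + sigma2 * rho^abs(outer(t_i, t_i, "-"))
  }
  Vi <- solve(V)
  ld_v <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (reml) {
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    -0.5 * ((n - p) * log(2 * pi) + ld_v +
            as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
            drop(t(r) %*% Vi %*% r))
  } else {
    if (is.null(beta)) stop("beta required for ML oracle")
    r <- y - X %*% beta
    -0.5 * (n * log(2 * pi) + ld_v + drop(t(r) %*% Vi %*% r))
  }
}

# Diagonal of the dense marginal covariance, for studentisation cross-checks.
dense_marginal_sd <- function(data, id = "id", time = "time", G, sigma2, rho) {
  data <- data[order(match(data[[id]], unique(data[[id]])), data[[time]]), ]
  out <- numeric(nrow(data))
  for (s in split(seq_len(nrow(data)),
                  factor(data[[id]], levels = unique(data[[id]])))) {
    t_i <- data[[time]][s]
    Z <- cbind(1, t_i)
    out[s] <- sqrt(diag(Z %*% G %*% t(Z)) + sigma2)
  }
  out
}

# Simulate a longitudinal design directly from the model the engine fits:
# random intercept/slope per subject, spatial-power errors. Independent of
# the EMR generator.
sim_design <- function(n_subj, beta = c(30, 0.2), sd_int = 1.5,
                       sd_slope = 0.3, cor_is = 0, sigma = 1, rho = 0.5,
                       t_range = c(0, 4), mean_obs = 7, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_subj)
  Gc <- matrix(c(sd_int^2, cor_is * sd_int * sd_slope,
                 cor_is * sd_int * sd_slope, sd_slope^2), 2)
  for (i in seq_len(n_subj)) {
    ni <- max(2, stats::rpois(1, mean_obs))
    t <- sort(stats::runif(ni, t_range[1], t_range[2]))
    b <- drop(crossprod(chol(Gc + diag(1e-12, 2)), stats::rnorm(2)))
    R <- rho^abs(outer(t, t, "-"))
    e <- drop(crossprod(chol(R), stats::rnorm(ni)))
    rows[[i]] <- data.frame(
      id = i, time = t,
      y = beta[1] + beta[2] * t + b[1] + b[2] * t + sigma * e,
      true_slope = beta[2] + b[2])
  }
  do.call(rbind, rows)
}

# Per-subject ordinary least-squares slopes (brute-force oracle).
ols_slopes <- function(data, id = "id", time = "time", resp = "y") {
  vapply(split(data, data[[id]]), function(d) {
    if (nrow(d) < 2 || stats::var(d[[time]]) == 0) return(NA_real_)
    stats::coef(stats::lm(d[[resp]] ~ d[[time]]))[2]
  }, numeric(1))
}

# Hand-built EMR bundle. `people` is a list of lists with fields:
#   id, diag (Date), age (years at diagnosis), sex, dep (NA allowed),
#   bmi = data.frame(t, v) at times relative to diagnosis (years),
#   hba1c = data.frame(t, v), rx = data.frame(class, start, end) (years).
toy_bundle <- function(people) {
  demo <- do.call(rbind, lapply(people, function(p) data.frame(
    id = p$id, sex = p$sex %||% "M",
    birth_date = p$diag - round((p$age %||% 60) * 365.25),
    diagnosis_date = p$diag,
    deprivation_quintile = if (is.null(p$dep)) 3L else p$dep,
    stringsAsFactors = FALSE)))
  grab <- function(field, cols) {
    rows <- lapply(people, function(p) {
      x <- p[[field]]
      if (is.null(x) || nrow(x) == 0) return(NULL)
      cbind(id = p$id, x)
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  bmi <- grab("bmi")
  bmi_obs <- if (is.null(bmi)) {
    data.frame(id = character(), date = as.Date(character()), bmi = numeric())
  } else {
    data.frame(id = bmi$id,
               date = demo$diagnosis_date[match(bmi$id, demo$id)] +
                 round(bmi$t * 365.25),
               bmi = bmi$v)
  }
  hb <- grab("hba1c")
  hba1c_obs <- if (is.null(hb)) {
    data.frame(id = character(), date = as.Date(character()),
               hba1c = numeric())
  } else {
    data.frame(id = hb$id,
               date = demo$diagnosis_date[match(hb$id, demo$id)] +
                 round(hb$t * 365.25),
               hba1c = hb$v)
  }
  rx <- grab("rx")
  rx_episodes <- if (is.null(rx)) {
    data.frame(id = character(), drug_class = character(),
               start_date = as.Date(character()),
               end_date = as.Date(character()))
  } else {
    dd <- demo$diagnosis_date[match(rx$id, demo$id)]
    data.frame(id = rx$id, drug_class = rx$class,
               start_date = dd + round(rx$start * 365.25),
               end_date = dd + round(rx$end * 365.25))
  }
  structure(list(demographics = demo, bmi_obs = bmi_obs,
                 hba1c_obs = hba1c_obs, rx_episodes = rx_episodes),
            class = "emr_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
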