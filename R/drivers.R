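#' Prepare the standardized covariate matrix for the driver models
#'
#' Applies the pipeline's transforms — log for tree height, log1p for slope
#' (slope may be 0), identity elsewhere; temperature and precipitation are
#' converted to percent anomalies against configured historical normals when
#' `normals` is given (the synthetic generator already produces anomalies) —
#' then z-standardizes every column. Transform metadata (tag, centre, scale,
#' raw mean) is retained so effects can be converted back to physical units.
#'
#' @param records data frame of tree records with the covariate columns.
#' @param vars covariate columns to use, in order.
#' @param log_vars,log1p_vars columns receiving log / log1p transforms.
#' @param normals optional named list: `dt_pct`/`dppt_pct` entries are
#'   absolute values to be converted to percent anomalies
#'   (`100 * (x - normal) / normal`).
#' @return object of class `covariate_matrix`: standardized matrix `X` plus
#'   `transform`, `center`, `scale`, `raw_mean` per column.
#' @export
prepare_covariates <- function(records,
                               vars = intersect(c("height", "cover_pct",
                                                  "vpd_max", "dt_pct",
                                                  "dppt_pct", "slope_pct",
                                                  "soil_awc"),
                                                names(records)),
                               log_vars = "height",
                               log1p_vars = "slope_pct",
                               normals = NULL) {
  if (!length(vars)) stop("no covariates found")
  raw <- as.matrix(records[vars])
  if (any(!is.finite(raw))) stop("covariates must be finite")
  if (!is.null(normals)) {
    for (v in intersect(names(normals), vars))
      raw[, v] <- 100 * (raw[, v] - normals[[v]]) / normals[[v]]
  }
  transform <- ifelse(vars %in% log_vars, "log",
                      ifelse(vars %in% log1p_vars, "log1p", "identity"))
  names(transform) <- vars
  tx <- raw
  for (j in seq_along(vars)) {
    if (transform[j] == "log") {
      if (any(raw[, j] <= 0)) stop(vars[j], ": log transform needs positive values")
      tx[, j] <- log(raw[, j])
    } else if (transform[j] == "log1p") {
      if (any(raw[, j] < 0)) stop(vars[j], ": log1p transform needs non-negative values")
      tx[, j] <- log1p(raw[, j])
    }
  }
  ctr <- colMeans(tx)
  scl <- apply(tx, 2, stats::sd)
  zero <- vars[scl == 0 | !is.finite(scl)]
  if (length(zero)) stop("zero-variance covariate column(s): ",
                         paste(zero, collapse = ", "))
  X <- sweep(sweep(tx, 2, ctr), 2, scl, "/")
  structure(list(X = X, vars = vars, transform = transform,
                 center = ctr, scale = scl, raw_mean = colMeans(raw)),
            class = "covariate_matrix")
}

#' Back-transform a standardized covariate value to its raw scale
#'
#' @param cm a `covariate_matrix`.
#' @param var column name.
#' @param z standardized value(s).
#' @return value(s) on the original physical scale.
#' @export
covariate_backtransform <- function(cm, var, z) {
  t <- z * cm$scale[[var]] + cm$center[[var]]
  switch(cm$transform[[var]], log = exp(t), log1p = expm1(t), t)
}

#' Drop covariates from a prepared matrix
#'
#' @param cm a `covariate_matrix`.
#' @param drop column names to remove.
#' @return a `covariate_matrix` without those columns.
#' @export
drop_covariates <- function(cm, drop) {
  keep <- setdiff(cm$vars, drop)
  structure(list(X = cm$X[, keep, drop = FALSE], vars = keep,
                 transform = cm$transform[keep], center = cm$center[keep],
                 scale = cm$scale[keep], raw_mean = cm$raw_mean[keep]),
            class = "covariate_matrix")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column `j` on all other
#' columns. Values at or above 2 are flagged (the collinearity screen);
#' perfect collinearity reports `Inf`.
#'
#' @param X numeric matrix or `covariate_matrix` (needs >= 2 columns and
#'   more rows than columns).
#' @return data frame: `variable`, `vif`, `flagged`.
#' @export
compute_vif <- function(X) {
  if (inherits(X, "covariate_matrix")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 columns")
  if (nrow(X) <= ncol(X)) stop("need more rows than columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = vif, flagged = vif >= 2,
             row.names = NULL)
}

#' Logistic regression of mortality status by IRLS
#'
#' Maximum-likelihood fit of a binary-outcome (dead/live) logistic model by
#' iteratively reweighted least squares: tolerance 1e-8 on the largest
#' coefficient change, at most `max_iter` iterations, standard errors from
#' the observed information. The log-likelihood trace is retained so
#' monotone convergence can be checked. Complete separation surfaces as a
#' non-convergence error naming the diverging variable.
#'
#' @param X `covariate_matrix` or plain numeric matrix (no intercept
#'   column; one is added).
#' @param y 0/1 (or logical) outcome, 1 = dead; both classes required.
#' @param max_iter,tol IRLS controls.
#' @return object of class `model_fit`: `coefficients`, `se`, `ci_lo`,
#'   `ci_hi` (estimate +/- 1.96 SE), `loglik`, `loglik_trace`, `n`,
#'   `converged`, `iterations`, `vcov`, `baseline_rate`, and the
#'   `covariates` metadata when a `covariate_matrix` was supplied.
#' @export
fit_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  cm <- if (inherits(X, "covariate_matrix")) X else NULL
  M <- if (is.null(cm)) as.matrix(X) else cm$X
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (all(y == 0) || all(y == 1)) stop("y must contain both classes")
  if (ncol(M) > 0 && is.null(colnames(M)))
    colnames(M) <- paste0("x", seq_len(ncol(M)))
  A <- cbind(`(intercept)` = 1, M)
  n <- nrow(A); p <- ncol(A)
  beta <- numeric(p)
  ll <- function(b) {
    eta <- drop(A %*% b)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  trace <- ll(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(A %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- stats::lm.fit(A * sw, z * sw)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) stop("IRLS produced non-finite coefficients (rank deficiency?)")
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    trace <- c(trace, ll(beta))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(beta[-1])) > 10) {
    worst <- colnames(M)[which.max(abs(beta[-1]))]
    stop("non-convergence with diverging coefficient (complete separation?): ",
         worst)
  }
  eta <- drop(A %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(A, A * w)
  vc <- solve(info)
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- colnames(A)
  structure(list(coefficients = beta, se = se,
                 ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n = n, converged = converged, iterations = it,
                 vcov = vc, baseline_rate = mean(y), covariates = cm,
                 family = "binomial"),
            class = "model_fit")
}

#' Default physical increments for effect reporting
#'
#' The per-increment scale of the headline effects: 10 m of height, 0.4 kPa
#' of maximum VPD, a 2.9\% temperature anomaly (0.4 C), a -4\% precipitation
#' anomaly (35 mm drier), 6.2 mm of available water storage, 17\% tree
#' cover, 5\% slope.
#'
#' @return named vector of increments in each covariate's physical unit.
#' @export
default_increments <- function() {
  c(height = 10, vpd_max = 0.4, dt_pct = 2.9, dppt_pct = -4,
    soil_awc = 6.2, cover_pct = 17, slope_pct = 5)
}

# standardized coefficient -> per-raw-unit coefficient, linearized at the
# raw mean for log/log1p columns
coef_per_raw_unit <- function(b_sd, cm, v) {
  b_t <- b_sd / cm$scale[[v]]
  switch(cm$transform[[v]],
         log = b_t / cm$raw_mean[[v]],
         log1p = b_t / (1 + cm$raw_mean[[v]]),
         b_t)
}

#' Odds ratios per standard deviation and per physical increment
#'
#' Exponentiates the standardized logistic coefficients (odds ratio per 1
#' SD) and rescales each to its covariate's physical increment. For log- and
#' log1p-transformed covariates the per-unit coefficient is linearized at
#' the covariate's raw mean, which is flagged in the output. The report
#' notes whether the odds ratio can be read as an approximate relative risk
#' (baseline mortality below 3\%).
#'
#' @param fit a converged `model_fit` from [fit_logistic()] carrying
#'   covariate metadata.
#' @param increments named physical increments; default
#'   [default_increments()]. Zero increments are an error.
#' @return data frame: `variable`, `or_sd`, `or_sd_lo`, `or_sd_hi`,
#'   `increment`, `or_increment`, `or_inc_lo`, `or_inc_hi`, `direction`,
#'   `linearized`, plus attributes `baseline_rate` and `rr_approx_valid`.
#' @export
odds_ratio_report <- function(fit, increments = default_increments()) {
  stopifnot(inherits(fit, "model_fit"))
  if (!fit$converged) stop("fit did not converge")
  cm <- fit$covariates
  if (is.null(cm)) stop("fit lacks covariate metadata; fit with a covariate_matrix")
  vars <- cm$vars
  if (any(increments[intersect(names(increments), vars)] == 0))
    stop("increments must be non-zero")
  rows <- lapply(vars, function(v) {
    b <- fit$coefficients[[v]]; s <- fit$se[[v]]
    inc <- if (v %in% names(increments)) increments[[v]] else cm$scale[[v]]
    if (inc == 0) stop("increments must be non-zero")
    b_raw <- coef_per_raw_unit(b, cm, v)
    s_raw <- abs(coef_per_raw_unit(s, cm, v))
    data.frame(variable = v,
               or_sd = exp(b), or_sd_lo = exp(b - 1.96 * s),
               or_sd_hi = exp(b + 1.96 * s),
               increment = inc,
               or_increment = exp(b_raw * inc),
               or_inc_lo = exp((b_raw - 1.96 * s_raw) * inc),
               or_inc_hi = exp((b_raw + 1.96 * s_raw) * inc),
               direction = ifelse(exp(b) > 1, "risk-increasing",
                                  ifelse(exp(b) < 1, "risk-decreasing",
                                         "neutral")),
               linearized = cm$transform[[v]] != "identity")
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_rate") <- fit$baseline_rate
  attr(out, "rr_approx_valid") <- fit$baseline_rate < 0.03
  out
}

#' Reduced logistic model substituting VPD for temperature and precipitation
#'
#' Drops the temperature and precipitation anomaly columns (which are nearly
#' collinear with maximum VPD) and refits, reporting odds ratios from the
#' reduced model.
#'
#' @param cm a `covariate_matrix` containing `vpd_max`.
#' @param y binary dead/live outcome.
#' @param drop columns to remove, default `c("dt_pct", "dppt_pct")`.
#' @param increments passed to [odds_ratio_report()].
#' @return list with `fit` (`model_fit`) and `odds_ratios`.
#' @export
fit_reduced_vpd <- function(cm, y, drop = c("dt_pct", "dppt_pct"),
                            increments = default_increments()) {
  stopifnot(inherits(cm, "covariate_matrix"))
  if (!"vpd_max" %in% cm$vars) stop("covariate matrix lacks vpd_max")
  red <- drop_covariates(cm, drop)
  fit <- fit_logistic(red, y)
  list(fit = fit, odds_ratios = odds_ratio_report(fit, increments))
}

#' Mortality rate in narrow multivariate bins
#'
#' Bins every covariate at the given widths and, per unique bin combination,
#' computes the mortality rate as dead / total / `lag_years` x 100
#' (\% yr^-1; with the default 2-year acquisition lag the rate cannot exceed
#' 50). Combinations with fewer than `n_min` trees are excluded and counted
#' in a message.
#'
#' @param data data frame of tree-level covariates (raw physical units).
#' @param dead logical (or 0/1) death indicator, same length.
#' @param bin_widths named positive bin widths; names select the covariates.
#' @param n_min minimum trees per bin, default 25.
#' @param lag_years acquisition time-lag divisor, default 2.
#' @return object of class `rate_bin_table`: data frame with one bin-centre
#'   column per covariate plus `n`, `n_dead`, `rate`; attribute
#'   `n_excluded_bins`.
#' @export
binned_rates <- function(data, dead, bin_widths, n_min = 25, lag_years = 2) {
  if (nrow(data) == 0) stop("empty record set")
  if (any(bin_widths <= 0)) stop("bin widths must be positive")
  vars <- names(bin_widths)
  stopifnot(all(vars %in% names(data)), length(dead) == nrow(data))
  dead <- as.logical(dead)
  centers <- lapply(vars, function(v)
    floor(data[[v]] / bin_widths[[v]]) * bin_widths[[v]] + bin_widths[[v]] / 2)
  names(centers) <- vars
  key <- do.call(paste, c(centers, sep = "\r"))
  agg <- data.frame(key = key, dead = as.numeric(dead))
  n <- tapply(agg$dead, agg$key, length)
  nd <- tapply(agg$dead, agg$key, sum)
  keys <- names(n)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  tab <- as.data.frame(apply(parts, 2, as.numeric))
  names(tab) <- vars
  tab$n <- as.integer(n)
  tab$n_dead <- as.integer(nd)
  tab$rate <- 100 * tab$n_dead / tab$n / lag_years
  drop <- tab$n < n_min
  n_excluded <- sum(drop)
  if (n_excluded > 0)
    message(sprintf("binned_rates: %d bin(s) with n < %d excluded",
                    n_excluded, n_min))
  tab <- tab[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_excluded_bins") <- n_excluded
  attr(tab, "lag_years") <- lag_years
  class(tab) <- c("rate_bin_table", "data.frame")
  tab
}

#' Weighted linear model of binned mortality rate
#'
#' Regresses the binned mortality rate on the bin-centre covariates,
#' transformed and standardized exactly as the tree-level logistic model
#' (the `covariate_matrix` supplies the transforms, centres and scales), by
#' weighted least squares with bin tree counts as weights. Coefficients are
#' also reported as rate changes (\% yr^-1) per physical increment.
#'
#' @param rate_table a `rate_bin_table`.
#' @param cm the tree-level `covariate_matrix` providing transform metadata
#'   (only its per-column metadata is used; rows need not match).
#' @param increments physical increments, default [default_increments()].
#' @return list: `fit` (`model_fit`, Gaussian), `rate_changes` data frame
#'   (`variable`, `increment`, `rate_change`, `lo`, `hi`).
#' @export
fit_rate_model <- function(rate_table, cm, increments = default_increments()) {
  vars <- intersect(cm$vars, names(rate_table))
  if (nrow(rate_table) < length(vars) + 2)
    stop("need at least p + 2 bins")
  tx <- as.matrix(rate_table[vars])
  for (v in vars) {
    tx[, v] <- switch(cm$transform[[v]], log = log(tx[, v]),
                      log1p = log1p(tx[, v]), tx[, v])
  }
  Z <- sweep(sweep(tx, 2, cm$center[vars]), 2, cm$scale[vars], "/")
  df <- data.frame(rate = rate_table$rate, Z, check.names = FALSE)
  lmfit <- stats::lm(rate ~ ., data = df, weights = rate_table$n)
  if (any(is.na(stats::coef(lmfit)))) stop("rank-deficient rate model")
  sm <- summary(lmfit)
  beta <- stats::coef(lmfit)
  se <- sm$coefficients[, "Std. Error"]
  fit <- structure(list(coefficients = beta, se = se,
                        ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                        loglik = as.numeric(stats::logLik(lmfit)),
                        n = nrow(df), converged = TRUE, iterations = 1L,
                        vcov = stats::vcov(lmfit),
                        baseline_rate = stats::weighted.mean(df$rate,
                                                             rate_table$n),
                        covariates = NULL, family = "gaussian",
                        r_squared = sm$r.squared),
                   class = "model_fit")
  rows <- lapply(vars, function(v) {
    b_raw <- coef_per_raw_unit(beta[[v]], cm, v)
    s_raw <- abs(coef_per_raw_unit(se[[v]], cm, v))
    inc <- if (v %in% names(increments)) increments[[v]] else cm$scale[[v]]
    data.frame(variable = v, increment = inc,
               rate_change = b_raw * inc,
               lo = (b_raw - 1.96 * s_raw) * inc,
               hi = (b_raw + 1.96 * s_raw) * inc)
  })
  list(fit = fit, rate_changes = do.call(rbind, rows))
}

#' Default covariate bin widths for the rate analysis
#'
#' Height 5 m, VPD 0.1 kPa, temperature and precipitation anomalies 2\%,
#' available water storage 5 mm, cover 10\%, slope 5\%.
#'
#' @return named vector of bin widths.
#' @export
default_bin_widths <- function() {
  c(height = 5, vpd_max = 0.1, dt_pct = 2, dppt_pct = 2,
    soil_awc = 5, cover_pct = 10, slope_pct = 5)
}
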