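test_that("covariate preparation standardizes, transforms and round-trips", {
  set.seed(3)
  rec <- data.frame(height = rlnorm(500, log(18), 0.5),
                    vpd_max = runif(500, 1.2, 2.6),
                    slope_pct = runif(500, 0, 40))
  cm <- prepare_covariates(rec)
  expect_equal(unname(colMeans(cm$X)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(cm$X, 2, sd)), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(cm$transform),
               c("log", "identity", "log1p"))
  # round-trip identity to 1e-10
  expect_equal(unname(covariate_backtransform(cm, "height", cm$X[7, "height"])),
               rec$height[7], tolerance = 1e-10)
  expect_equal(unname(covariate_backtransform(cm, "slope_pct", cm$X[7, "slope_pct"])),
               rec$slope_pct[7], tolerance = 1e-10)
  rec$flat <- 1
  expect_error(prepare_covariates(rec, vars = c("height", "flat")), "flat")
  # anomaly conversion against configured normals
  rec2 <- data.frame(height = rec$height, dt_pct = runif(500, 13, 15))
  cm2 <- prepare_covariates(rec2, normals = list(dt_pct = 14))
  expect_equal(cm2$raw_mean[["dt_pct"]],
               mean(100 * (rec2$dt_pct - 14) / 14))
})

test_that("VIFs equal the auxiliary-regression oracle and flag collinearity", {
  # exactly orthogonal, mean-centred columns -> VIF 1
  set.seed(11)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(compute_vif(X)$vif, rep(1, 3), tolerance = 1e-10)
  # duplicated column -> infinite, flagged
  X2 <- cbind(X, d = X[, 1])
  v2 <- compute_vif(X2)
  expect_true(is.infinite(v2$vif[v2$variable == "d"]))
  expect_true(all(v2$flagged[v2$variable %in% c("a", "d")]))
  # 3-column case vs explicit auxiliary regressions
  set.seed(13)
  Z <- matrix(rnorm(300), 100, 3)
  Z[, 3] <- Z[, 1] + 0.5 * Z[, 2] + rnorm(100, sd = 0.7)
  v3 <- compute_vif(Z)$vif
  oracle <- sapply(1:3, function(j)
    1 / (1 - summary(lm(Z[, j] ~ Z[, -j]))$r.squared))
  expect_equal(v3, oracle, tolerance = 1e-8)
})

test_that("IRLS logistic matches closed forms, glm, and a likelihood grid search", {
  # intercept-only: 30 dead of 100 -> logit(0.3)
  y <- rep(c(1, 0), times = c(30, 70))
  f0 <- fit_logistic(matrix(numeric(0), 100, 0), y)
  expect_equal(unname(f0$coefficients[1]), log(30 / 70), tolerance = 1e-8)

  # single binary predictor from a 2x2 table: OR = ad/bc = 2.25
  x <- rep(c(1, 0), each = 100)
  y2 <- c(rep(c(1, 0), times = c(20, 80)), rep(c(1, 0), times = c(10, 90)))
  f1 <- fit_logistic(cbind(tall = x), y2)
  expect_equal(exp(unname(f1$coefficients["tall"])), (20 * 90) / (80 * 10),
               tolerance = 1e-8)

  expect_error(fit_logistic(cbind(x = rnorm(50)), rep(0, 50)), "both classes")

  # random 3-covariate problem: agreement with glm (independent route)
  set.seed(17)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  yr <- rbinom(200, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0)))
  f2 <- fit_logistic(X, yr)
  g <- glm(yr ~ X, family = binomial)
  expect_equal(unname(f2$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f2$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-4)
  expect_true(f2$converged)
  # log-likelihood is monotone along the IRLS trace; final gradient ~ 0
  expect_true(all(diff(f2$loglik_trace) > -1e-8))
  mu <- plogis(cbind(1, X) %*% f2$coefficients)
  expect_lt(max(abs(crossprod(cbind(1, X), yr - mu))), 1e-6)

  # brute-force likelihood grid search on a 2-parameter problem, n <= 200
  set.seed(19)
  xg <- rnorm(150)
  yg <- rbinom(150, 1, plogis(-0.4 + 0.9 * xg))
  fg <- fit_logistic(cbind(x = xg), yg)
  ll <- function(b0, b1) {
    eta <- b0 + b1 * xg
    sum(yg * eta - log1p(exp(eta)))
  }
  grid_b0 <- seq(fg$coefficients[1] - 0.3, fg$coefficients[1] + 0.3, 1e-3)
  grid_b1 <- seq(fg$coefficients[2] - 0.3, fg$coefficients[2] + 0.3, 1e-3)
  best0 <- grid_b0[which.max(vapply(grid_b0, ll, numeric(1),
                                    b1 = fg$coefficients[2]))]
  best1 <- grid_b1[which.max(vapply(grid_b1, function(b) ll(fg$coefficients[1], b),
                                    numeric(1)))]
  expect_lt(abs(best0 - fg$coefficients[1]), 1e-3 + 1e-9)
  expect_lt(abs(best1 - fg$coefficients[2]), 1e-3 + 1e-9)

  # complete separation is reported against the offending variable
  xs <- c(rep(-1, 30), rep(1, 30))
  ys <- c(rep(0, 30), rep(1, 30))
  expect_error(fit_logistic(cbind(sep = xs), ys), "sep")
})

test_that("odds ratios rescale to physical increments correctly", {
  # a linear-scale coefficient of 0.0231 per m over 10 m -> e^0.231 = 1.26
  set.seed(23)
  rec <- data.frame(height = runif(4000, 5, 60))
  cmid <- prepare_covariates(rec, vars = "height", log_vars = character(0))
  b_sd <- 0.0231 * cmid$scale[["height"]]
  fit <- structure(list(coefficients = c(`(intercept)` = -2, height = b_sd),
                        se = c(`(intercept)` = 0.1, height = 0.001),
                        converged = TRUE, baseline_rate = 0.02,
                        covariates = cmid),
                   class = "model_fit")
  orr <- odds_ratio_report(fit, increments = c(height = 10))
  expect_equal(round(orr$or_increment, 2), 1.26)
  expect_equal(orr$or_sd, exp(b_sd))
  expect_equal(orr$direction, "risk-increasing")
  expect_true(attr(orr, "rr_approx_valid"))

  # zero coefficient -> OR exactly 1 for any increment; negative -> < 1
  fit$coefficients["height"] <- 0
  expect_equal(odds_ratio_report(fit, increments = c(height = 10))$or_increment, 1)
  fit$coefficients["height"] <- -0.5
  orr2 <- odds_ratio_report(fit, increments = c(height = 10))
  expect_lt(orr2$or_increment, 1)
  expect_equal(orr2$direction, "risk-decreasing")
  expect_error(odds_ratio_report(fit, increments = c(height = 0)), "non-zero")
})

test_that("the reduced VPD model concentrates the climate signal", {
  # temperature and precipitation carry real effects that VPD proxies; once
  # they are dropped, the reduced model's VPD coefficient absorbs them and
  # must exceed the full model's partial VPD coefficient
  hz <- hazard_model("logistic-status", b0 = qlogis(0.10) - 0.02312 * 20,
                     b_height = 0.02312,
                     b_env = c(vpd_max = 0.15, dt_pct = 0.10,
                               dppt_pct = -0.04))
  co <- simulate_tree_cohort(40000, hz, seed = 29)
  cm <- prepare_covariates(co)
  y <- co$dead
  full <- fit_logistic(cm, y)
  red <- fit_reduced_vpd(cm, y)
  expect_gt(red$fit$coefficients[["vpd_max"]], full$coefficients[["vpd_max"]])
  # reduced model passes the collinearity screen
  vif <- compute_vif(drop_covariates(cm, c("dt_pct", "dppt_pct")))
  expect_true(all(vif$vif < 2))
  # no-op: removing and re-adding nothing leaves the full fit unchanged
  expect_equal(fit_logistic(drop_covariates(cm, character(0)), y)$coefficients,
               full$coefficients)
})

test_that("binned mortality rates follow dead/total/2 with the 50% cap", {
  d <- data.frame(height = c(rep(7, 50), rep(12, 40), rep(22, 30)))
  dead <- c(rep(c(TRUE, FALSE), times = c(10, 40)),
            rep(TRUE, 40), rep(FALSE, 30))
  tab <- binned_rates(d, dead, c(height = 5))
  expect_equal(tab$rate[tab$height == 7.5], 10.0)   # (10/50)/2 * 100
  expect_equal(tab$rate[tab$height == 12.5], 50.0)  # fully dead bin: cap
  expect_equal(tab$rate[tab$height == 22.5], 0.0)
  expect_true(all(tab$rate <= 50))
  expect_error(binned_rates(d[0, , drop = FALSE], logical(0), c(height = 5)),
               "empty")
  # n_min exclusion is counted
  d2 <- rbind(d, data.frame(height = 40))
  tab2 <- suppressMessages(binned_rates(d2, c(dead, TRUE), c(height = 5)))
  expect_equal(attr(tab2, "n_excluded_bins"), 1L)
  expect_false(42.5 %in% tab2$height)
})

test_that("the weighted rate model solves the normal equations", {
  # noiseless linear synthetic table: coefficients recovered to 1e-8
  set.seed(31)
  rec <- data.frame(height = runif(2000, 5, 60), vpd_max = runif(2000, 1.2, 2.6))
  cm <- prepare_covariates(rec, log_vars = character(0))
  tab <- data.frame(height = rep(seq(7.5, 57.5, 5), each = 4),
                    vpd_max = rep(c(1.4, 1.8, 2.2, 2.6), 11))
  zh <- (tab$height - cm$center[["height"]]) / cm$scale[["height"]]
  zv <- (tab$vpd_max - cm$center[["vpd_max"]]) / cm$scale[["vpd_max"]]
  tab$rate <- 3 + 2 * zh + 1 * zv
  tab$n <- rep(c(50L, 80L, 120L, 60L), 11)
  tab$n_dead <- 0L
  class(tab) <- c("rate_bin_table", "data.frame")
  fit <- fit_rate_model(tab, cm)
  expect_equal(unname(fit$fit$coefficients), c(3, 2, 1), tolerance = 1e-8)

  # 3-row system equals hand-solved weighted normal equations
  t3 <- data.frame(height = c(10, 20, 30), rate = c(1, 4, 5),
                   n = c(10L, 20L, 5L), n_dead = 0L)
  class(t3) <- c("rate_bin_table", "data.frame")
  cm1 <- prepare_covariates(data.frame(height = runif(100, 5, 40)),
                            vars = "height", log_vars = character(0))
  f3 <- fit_rate_model(t3, cm1)
  z <- (t3$height - cm1$center[["height"]]) / cm1$scale[["height"]]
  A <- cbind(1, z); W <- diag(t3$n)
  beta_hand <- solve(t(A) %*% W %*% A, t(A) %*% W %*% t3$rate)
  expect_equal(unname(f3$fit$coefficients), unname(drop(beta_hand)),
               tolerance = 1e-10)

  # a zero-weight row leaves the fit unchanged
  t4 <- rbind(t3, data.frame(height = 35, rate = 99, n = 0L, n_dead = 0L))
  class(t4) <- c("rate_bin_table", "data.frame")
  f4 <- fit_rate_model(t4, cm1)
  expect_equal(f4$fit$coefficients, f3$fit$coefficients, tolerance = 1e-10)
})

test_that("simulated effect sizes are recovered within their 95% CIs (scaled replicates)", {
  # CI coverage of the natural-scale generator coefficients; run at a
  # reduced n and replicate count to stay inside the test budget
  hz <- hazard_model("logistic-status", b0 = qlogis(0.12) - 0.02312 * 20,
                     b_height = 0.02312, b_env = c(vpd_max = 0.2833))
  hits_h <- 0L; hits_v <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    co <- simulate_tree_cohort(30000, hz, seed = 1000 + r)
    cm <- prepare_covariates(co, vars = c("height", "vpd_max", "soil_awc"),
                             log_vars = character(0))
    f <- fit_logistic(cm, co$dead)
    ci_h <- c(f$ci_lo[["height"]], f$ci_hi[["height"]]) / cm$scale[["height"]]
    ci_v <- c(f$ci_lo[["vpd_max"]], f$ci_hi[["vpd_max"]]) / cm$scale[["vpd_max"]]
    hits_h <- hits_h + (0.02312 >= ci_h[1] && 0.02312 <= ci_h[2])
    hits_v <- hits_v + (0.2833 >= ci_v[1] && 0.2833 <= ci_v[2])
  }
  expect_gte(hits_h, 17L)
  expect_gte(hits_v, 17L)
})
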