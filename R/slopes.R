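#' Height-mortality slope within bins of an environmental gradient
#'
#' For each bin of the environmental variable, computes the mortality rate
#' per height bin (dead / total / `lag_years` x 100, as in [binned_rates()])
#' and fits rate against height-bin centre by least squares weighted by the
#' number of trees per height bin. The slope is the height-mortality
#' coefficient (\% yr^-1 per m) with its standard error and p-value from the
#' weighted fit. Environmental bins with fewer than 3 occupied height bins
#' are skipped with a message.
#'
#' @param data tree-level data frame with `height` and the environmental
#'   column.
#' @param dead logical death indicator over the analysis interval.
#' @param env_var environmental column name.
#' @param env_bin_edges bin edges; default 15 equal-width bins spanning the
#'   1st-99th percentile of the variable.
#' @param height_bin_width height bin width (m), default 5.
#' @param n_min minimum trees per height bin, default 25.
#' @param lag_years rate divisor, default 2 (the 2-year acquisition lag).
#' @return data frame of class `slope_estimates`: `env_var`, `bin_center`,
#'   `slope`, `sigma`, `p`, `n`, `n_height_bins`.
#' @export
per_bin_height_slopes <- function(data, dead, env_var, env_bin_edges = NULL,
                                  height_bin_width = 5, n_min = 25,
                                  lag_years = 2) {
  stopifnot(env_var %in% names(data), length(dead) == nrow(data))
  x <- data[[env_var]]
  if (is.null(env_bin_edges)) {
    q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
    env_bin_edges <- seq(q[1], q[2], length.out = 16)
  }
  edges <- sort(env_bin_edges)
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    sel <- if (i == length(edges) - 1) x >= lo & x <= hi else x >= lo & x < hi
    if (!any(sel)) { n_skipped <- n_skipped + 1L; next }
    tab <- suppressMessages(
      binned_rates(data[sel, , drop = FALSE], dead[sel],
                   c(height = height_bin_width), n_min = n_min,
                   lag_years = lag_years))
    if (nrow(tab) < 3) { n_skipped <- n_skipped + 1L; next }
    w <- wls_line(tab$height, tab$rate, tab$n)
    out[[length(out) + 1L]] <- data.frame(
      env_var = env_var, bin_center = (lo + hi) / 2,
      slope = w$slope, sigma = w$se_slope, p = w$p,
      n = sum(tab$n), n_height_bins = nrow(tab))
  }
  if (n_skipped > 0)
    message(sprintf("per_bin_height_slopes: %d env bin(s) skipped (< 3 occupied height bins)",
                    n_skipped))
  if (!length(out))
    stop("no environmental bin had >= 3 occupied height bins")
  res <- do.call(rbind, out)
  class(res) <- c("slope_estimates", "data.frame")
  res
}

# weighted least-squares line fit: slope, intercept, SE(slope), p-value.
# An exact fit (zero residual) reports sigma 0 and p 0 for a non-zero slope,
# p 1 for a zero slope.
wls_line <- function(x, y, w) {
  sw <- sum(w)
  xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) stop("degenerate x in weighted line fit")
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  k <- length(x)
  df <- k - 2
  s2 <- if (df > 0) sum(w * res^2) / df else 0
  se <- sqrt(s2 / sxx)
  p <- if (se == 0) {
    if (abs(slope) < 1e-12) 1 else 0
  } else 2 * stats::pt(-abs(slope / se), df)
  list(slope = slope, intercept = intercept, se_slope = se, p = p)
}

#' Meta-regression of height-mortality slopes on an environmental gradient
#'
#' Weighted least squares of the per-bin height-mortality slope on the
#' environmental bin centre, using only slopes significant at `alpha`.
#' Weights are inverse-variance `1/sigma^2` by default, with `1/sigma`
#' available (the alternative in the source analysis); zero sigmas receive a
#' large finite weight so exact slopes remain usable. The weighted R^2 is
#' `1 - SSE_w / SST_w` with the weighted mean in SST.
#'
#' @param slopes `slope_estimates` data frame.
#' @param weighting `"inv_var2"` (1/sigma^2) or `"inv_var"` (1/sigma).
#' @param alpha significance filter on the per-bin slope p-values.
#' @return object of class `gradient_fit`: `beta0`, `beta1`, `se_beta1`,
#'   `weighted_r2`, `weighting`, `alpha`, `n_used`, `n_filtered`, `points`.
#' @export
gradient_regression <- function(slopes, weighting = c("inv_var2", "inv_var"),
                                alpha = 0.05) {
  weighting <- match.arg(weighting)
  keep <- slopes$p < alpha
  if (sum(keep) < 3)
    stop(sprintf("only %d slope estimate(s) pass the significance filter (need >= 3)",
                 sum(keep)))
  s <- slopes[keep, , drop = FALSE]
  w <- if (weighting == "inv_var2") 1 / s$sigma^2 else 1 / s$sigma
  if (any(!is.finite(w))) {
    cap <- 1e12 * max(1, max(w[is.finite(w)], 0))
    w[!is.finite(w)] <- cap
  }
  x <- s$bin_center; y <- s$slope
  f <- wls_line(x, y, w)
  yb <- sum(w * y) / sum(w)
  sst <- sum(w * (y - yb)^2)
  sse <- sum(w * (y - f$intercept - f$slope * x)^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sse / sst))
  structure(list(beta0 = f$intercept, beta1 = f$slope,
                 se_beta1 = f$se_slope, weighted_r2 = r2,
                 weighting = weighting, alpha = alpha,
                 n_used = nrow(s), n_filtered = sum(!keep),
                 points = s),
            class = "gradient_fit")
}

#' Two-segment cover analysis of the height-mortality slope
#'
#' Fits independent gradient regressions below and above the cover
#' breakpoint (default 50\% tree cover). A side with fewer than 3
#' significant slopes is reported as unfittable rather than an error.
#'
#' @param slopes `slope_estimates` for the cover gradient.
#' @param breakpoint cover breakpoint (\%); bins at the breakpoint go below.
#' @param ... passed to [gradient_regression()].
#' @return list with `below`, `above` (each a `gradient_fit` or a string
#'   reason), and `breakpoint`.
#' @export
cover_piecewise <- function(slopes, breakpoint = 50, ...) {
  fit_side <- function(sel) {
    if (!any(sel)) return("no slope estimates on this side")
    tryCatch(gradient_regression(slopes[sel, , drop = FALSE], ...),
             error = function(e) conditionMessage(e))
  }
  list(below = fit_side(slopes$bin_center <= breakpoint),
       above = fit_side(slopes$bin_center > breakpoint),
       breakpoint = breakpoint)
}
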