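#' Simulate a tree cohort without rasters
#'
#' Record-level counterpart of [generate_landscape()] +
#' [simulate_mortality()] for large-n statistical experiments: draws tree
#' heights from the truncated log-normal, environmental covariates per tree
#' (VPD uniform over its range; temperature and precipitation anomalies
#' affine in VPD at the target correlations, using exactly orthogonalized
#' residuals; water storage, cover and slope independent), and a single
#' death indicator per tree over the analysis interval.
#'
#' For a `"logistic-status"` hazard the death draw is one Bernoulli with
#' probability `plogis(eta)`; for `"linear-rate"` the hazard value is a
#' mortality rate in \% yr^-1 and the interval death probability is
#' `rate * lag_years / 100`, clamped.
#'
#' @param n number of trees.
#' @param hazard a [hazard_model()].
#' @param seed RNG seed.
#' @param height_mu,height_sigma,height_range truncated log-normal height
#'   parameters (log scale; range in metres).
#' @param vpd_range uniform range of maximum VPD (kPa).
#' @param vpd_t_corr,vpd_ppt_corr target `cor(vpd, dt)` and `cor(vpd, -dppt)`.
#' @param dt_mean,dt_sd,dppt_mean,dppt_sd anomaly moments (\%).
#' @param awc_range,cover_range,slope_range uniform ranges for water storage
#'   (mm), cover (\%) and slope (\%).
#' @param lag_years interval length for `"linear-rate"` hazards.
#' @return data frame: `id`, `height`, `vpd_max`, `dt_pct`, `dppt_pct`,
#'   `soil_awc`, `cover_pct`, `slope_pct`, `dead` (logical).
#' @export
simulate_tree_cohort <- function(n, hazard, seed = 1L,
                                 height_mu = log(18), height_sigma = 0.55,
                                 height_range = c(5, 60),
                                 vpd_range = c(1.2, 2.6),
                                 vpd_t_corr = 0.98, vpd_ppt_corr = 0.96,
                                 dt_mean = 2.9, dt_sd = 1.6,
                                 dppt_mean = -4, dppt_sd = 4.5,
                                 awc_range = c(20, 80),
                                 cover_range = c(10, 90),
                                 slope_range = c(0, 40),
                                 lag_years = 2) {
  stopifnot(inherits(hazard, "hazard_model"), n >= 1)
  set.seed(seed)
  lo <- stats::plnorm(height_range[1], height_mu, height_sigma)
  hi <- stats::plnorm(height_range[2], height_mu, height_sigma)
  height <- stats::qlnorm(stats::runif(n, lo, hi), height_mu, height_sigma)
  vpd <- stats::runif(n, vpd_range[1], vpd_range[2])
  zv <- (vpd - mean(vpd)) / stats::sd(vpd)
  ortho <- function() {
    e <- stats::rnorm(n)
    e <- e - mean(e) - zv * (sum(e * zv) / sum(zv * zv))
    e / stats::sd(e)
  }
  dt <- dt_mean + dt_sd * (vpd_t_corr * zv +
                             sqrt(1 - vpd_t_corr^2) * ortho())
  dppt <- dppt_mean + dppt_sd * (-vpd_ppt_corr * zv +
                                   sqrt(1 - vpd_ppt_corr^2) * ortho())
  trees <- data.frame(
    id = seq_len(n), height = height, vpd_max = vpd, dt_pct = dt,
    dppt_pct = dppt,
    soil_awc = stats::runif(n, awc_range[1], awc_range[2]),
    cover_pct = stats::runif(n, cover_range[1], cover_range[2]),
    slope_pct = stats::runif(n, slope_range[1], slope_range[2]))
  p <- annual_death_prob(hazard, trees)
  if (hazard$form == "linear-rate")
    p <- pmin(pmax(p * lag_years, hazard$clamp_eps), 1 - hazard$clamp_eps)
  trees$dead <- stats::runif(n) < p
  trees
}
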