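#' Hazard model for the mortality process
#'
#' Defines the per-tree annual death process used by [simulate_mortality()].
#' Two forms are supported:
#' \describe{
#'   \item{`"logistic-status"`}{annual death probability
#'     `plogis(b0 + b_height * h + sum(b_env * env) + sum(b_interaction * h * env))`.}
#'   \item{`"linear-rate"`}{annual mortality rate in \% yr^-1,
#'     `b0 + b_height * h + sum(b_env * env) + sum(b_interaction * h * env)`,
#'     divided by 100 to give the annual death probability. The interaction
#'     term is the height-by-environment rate model
#'     `M = beta0 + beta1 * Z_TREE * Delta_ENV`: `b0` plays beta0 and the
#'     named `b_interaction` entries play beta1 for each gradient.}
#' }
#' Probabilities are clamped to `[clamp_eps, 1 - clamp_eps]`; death is
#' absorbing.
#'
#' @param form `"logistic-status"` or `"linear-rate"`.
#' @param b0 intercept (log-odds, or \% yr^-1 for `"linear-rate"`).
#' @param b_height coefficient per metre of tree height.
#' @param b_env named numeric vector, per environmental unit.
#' @param b_interaction named numeric vector, per (m x env-unit).
#' @param clamp_eps probability clamp; annual probabilities are kept inside
#'   `[clamp_eps, 1 - clamp_eps]`.
#' @return an object of class `hazard_model`.
#' @export
hazard_model <- function(form = c("logistic-status", "linear-rate"),
                         b0 = 0, b_height = 0,
                         b_env = numeric(0), b_interaction = numeric(0),
                         clamp_eps = 1e-6) {
  form <- match.arg(form)
  stopifnot(is.numeric(b0), length(b0) == 1,
            is.numeric(b_height), length(b_height) == 1,
            clamp_eps >= 0, clamp_eps < 0.5)
  if (length(b_env) && is.null(names(b_env)))
    stop("b_env must be a named vector (names are environmental variables)")
  if (length(b_interaction) && is.null(names(b_interaction)))
    stop("b_interaction must be a named vector")
  structure(list(form = form, b0 = b0, b_height = b_height,
                 b_env = b_env, b_interaction = b_interaction,
                 clamp_eps = clamp_eps),
            class = "hazard_model")
}

#' Default spectral library for synthetic 4-band imagery
#'
#' Class means emulate growing-season aerial orthoimagery digital numbers in
#' (red, green, blue, NIR): live canopy is NIR-bright and green, dead canopy
#' red-grey with collapsed NIR, shading halves brightness, background is bare
#' soil. Covariances are diagonal by default.
#'
#' @param sd per-band standard deviation (scalar), default 5.
#' @return named list with one `list(mean, cov)` per class.
#' @export
default_spectra <- function(sd = 5) {
  mk <- function(mu) list(mean = mu, cov = diag(sd^2, 4))
  list(
    sunlit_live = mk(c(60, 95, 50, 185)),
    shaded_live = mk(c(30, 48, 25, 95)),
    sunlit_dead = mk(c(145, 110, 80, 90)),
    shaded_dead = mk(c(72, 55, 40, 48)),
    background  = mk(c(110, 100, 90, 60))
  )
}

check_pd <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop(what, ": covariance must be a symmetric square matrix")
  ch <- try(chol(m), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop(what, ": covariance is not positive definite")
  invisible(TRUE)
}

#' Synthetic forest scenario
#'
#' Bundles every knob of the synthetic landscape: domain and grid, stand
#' structure (tree count, spacing, truncated log-normal heights, crown radius
#' per metre of height), environmental gradients with their VPD-temperature
#' and VPD-precipitation correlations, the mortality hazard, acquisition
#' years, spectral classes, sun azimuth, and the seed.
#'
#' Environmental gradients are supplied as `list(base, ramp_x, ramp_y,
#' noise_sd, range_px)`: a planar ramp across the domain plus smooth Gaussian
#' noise with correlation range `range_px` pixels. Temperature and
#' precipitation anomalies are not drawn independently: they are affine in
#' the realized VPD field (plus orthogonalized smooth noise), so their
#' correlations with VPD hit `vpd_t_corr` and `-vpd_ppt_corr` exactly.
#'
#' @param domain_size_m numeric length-2, domain width/height in metres.
#' @param resolution_m pixel size (m), default 0.6.
#' @param n_trees number of trees to place.
#' @param min_spacing_m minimum pairwise stem spacing (m).
#' @param height_lognormal_mu,height_lognormal_sigma log-scale parameters of
#'   the tree-height distribution.
#' @param height_range_m truncation range, must lie within `[5, 120]`.
#' @param crown_radius_coef crown radius per metre of height (m/m).
#' @param env named list of gradient specs (see Details); must contain
#'   `vpd_max` (kPa), `dt_pct` (\%), `dppt_pct` (\%), `soil_awc` (mm),
#'   `slope_pct` (\%).
#' @param vpd_t_corr,vpd_ppt_corr target `cor(VPD, T)` and `cor(VPD, -PPT)`.
#' @param hazard a [hazard_model()].
#' @param acquisition_years strictly increasing integer years.
#' @param spectral spectral library as from [default_spectra()].
#' @param sun_azimuth_deg solar azimuth, degrees clockwise from north.
#' @param cover_cell_m aggregation cell (m) for percent tree cover.
#' @param seed integer RNG seed.
#' @return an object of class `forest_scenario`.
#' @export
forest_scenario <- function(domain_size_m = c(240, 240),
                            resolution_m = 0.6,
                            n_trees = 400,
                            min_spacing_m = 4,
                            height_lognormal_mu = log(18),
                            height_lognormal_sigma = 0.55,
                            height_range_m = c(5, 60),
                            crown_radius_coef = 0.10,
                            env = default_env(),
                            vpd_t_corr = 0.98,
                            vpd_ppt_corr = 0.96,
                            hazard = hazard_model("logistic-status",
                                                  b0 = qlogis(0.02)),
                            acquisition_years = c(2009L, 2010L, 2012L,
                                                  2014L, 2016L),
                            spectral = default_spectra(),
                            sun_azimuth_deg = 180,
                            cover_cell_m = 60,
                            seed = 1L) {
  stopifnot(length(domain_size_m) == 2, all(domain_size_m > 0),
            resolution_m > 0, n_trees >= 0, min_spacing_m >= 0,
            length(height_range_m) == 2,
            height_range_m[1] >= 5, height_range_m[2] <= 120,
            height_range_m[1] < height_range_m[2],
            crown_radius_coef > 0)
  if (length(acquisition_years) < 2 || any(diff(acquisition_years) <= 0))
    stop("acquisition_years must be strictly increasing with >= 2 entries")
  need <- c("vpd_max", "dt_pct", "dppt_pct", "soil_awc", "slope_pct")
  if (!all(need %in% names(env)))
    stop("env must define: ", paste(need, collapse = ", "))
  if (!inherits(hazard, "hazard_model")) stop("hazard must be a hazard_model")
  for (cl in names(spectral)) check_pd(spectral[[cl]]$cov, cl)
  structure(list(
    domain_size_m = domain_size_m, resolution_m = resolution_m,
    n_trees = as.integer(n_trees), min_spacing_m = min_spacing_m,
    height_lognormal_mu = height_lognormal_mu,
    height_lognormal_sigma = height_lognormal_sigma,
    height_range_m = height_range_m, crown_radius_coef = crown_radius_coef,
    env = env, vpd_t_corr = vpd_t_corr, vpd_ppt_corr = vpd_ppt_corr,
    hazard = hazard, acquisition_years = as.integer(acquisition_years),
    spectral = spectral, sun_azimuth_deg = sun_azimuth_deg,
    cover_cell_m = cover_cell_m, seed = as.integer(seed)
  ), class = "forest_scenario")
}

#' @rdname forest_scenario
#' @export
default_env <- function() {
  list(
    # maximum growing-season VPD, kPa: west-east drying ramp
    vpd_max  = list(base = 1.2, ramp_x = 1.2, ramp_y = 0,   noise_sd = 0.12, range_px = 12),
    # max-temperature anomaly, % of historical normal (0.4 C ~ 2.9 %)
    dt_pct   = list(base = 2.9, sd = 1.6),
    # precipitation anomaly, % of historical normal (negative = drier)
    dppt_pct = list(base = -4,  sd = 4.5),
    # profile available water storage, mm
    soil_awc = list(base = 40, ramp_x = 0, ramp_y = 40, noise_sd = 10, range_px = 15),
    # terrain slope, %
    slope_pct = list(base = 18, ramp_x = 0, ramp_y = -8, noise_sd = 8, range_px = 8)
  )
}
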