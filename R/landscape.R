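#' Generate a synthetic forest landscape
#'
#' Places trees by sequential random inhibition (candidates closer than
#' `min_spacing_m` to an accepted tree are rejected), draws heights from a
#' truncated log-normal by inverse-CDF so the draw count is fixed, realizes
#' the environmental rasters, and samples every gradient at each stem. Crown
#' radius is `crown_radius_coef * height`. The whole landscape is a pure
#' function of `scenario$seed`.
#'
#' Temperature and precipitation anomaly fields are affine in the realized
#' VPD field with an orthogonalized smooth-noise residual, so the realized
#' correlations equal `vpd_t_corr` and `-vpd_ppt_corr` up to floating-point
#' error. Percent tree cover is computed from the rendered canopy height
#' model aggregated to `cover_cell_m` cells (pixels above 5 m) and sampled
#' back at each stem.
#'
#' @param scenario a [forest_scenario()].
#' @param max_attempts_per_tree rejection-sampling budget per requested tree.
#' @return an object of class `forest_landscape`: list with `trees` (data
#'   frame: id, x, y, height, crown_radius, death_year, env columns),
#'   `env_fields` (named raster list incl. `cover_pct`), `chm`, `scenario`,
#'   and `n_rejected_trees`.
#' @export
generate_landscape <- function(scenario, max_attempts_per_tree = 200L) {
  stopifnot(inherits(scenario, "forest_scenario"))
  sc <- scenario
  # feasibility: disc packing at ~54.8% efficiency for random sequential
  # adsorption of discs of radius min_spacing/2
  area <- prod(sc$domain_size_m)
  if (sc$min_spacing_m > 0 && sc$n_trees > 0) {
    n_max <- floor(0.548 * area / (pi * (sc$min_spacing_m / 2)^2))
    if (sc$n_trees > n_max)
      stop(sprintf(paste0(
        "requested density infeasible: %d trees at %.1f m spacing in ",
        "%.0f m^2; at most ~%d trees are achievable"),
        sc$n_trees, sc$min_spacing_m, area, n_max))
  }
  set.seed(sc$seed)
  W <- sc$domain_size_m[1]; H <- sc$domain_size_m[2]

  placed <- place_trees(sc$n_trees, W, H, sc$min_spacing_m,
                        max_attempts_per_tree)
  n <- nrow(placed)
  n_rejected <- sc$n_trees - n
  if (n_rejected > 0)
    warning(sprintf("placed %d of %d trees (spacing rejection)", n, sc$n_trees))

  # truncated log-normal heights by inverse CDF
  lo <- stats::plnorm(sc$height_range_m[1], sc$height_lognormal_mu,
                      sc$height_lognormal_sigma)
  hi <- stats::plnorm(sc$height_range_m[2], sc$height_lognormal_mu,
                      sc$height_lognormal_sigma)
  height <- stats::qlnorm(stats::runif(n, lo, hi), sc$height_lognormal_mu,
                          sc$height_lognormal_sigma)

  trees <- data.frame(id = seq_len(n), x = placed$x, y = placed$y,
                      height = height,
                      crown_radius = sc$crown_radius_coef * height,
                      death_year = rep(NA_integer_, n))

  env_fields <- build_env_fields(sc)
  chm <- render_chm_trees(trees, W, H, sc$resolution_m)
  env_fields$cover_pct <- crown_cover_fraction(chm, min_height = 5,
                                               cell_size = sc$cover_cell_m)

  for (v in names(env_fields)) {
    trees[[v]] <- if (n > 0) tm_sample_any(env_fields[[v]], trees$x, trees$y,
                                           W, H) else numeric(0)
  }

  structure(list(trees = trees, env_fields = env_fields, chm = chm,
                 scenario = sc, n_rejected_trees = n_rejected),
            class = "forest_landscape")
}

# sample possibly-coarse raster by proportional position (handles cover cells)
tm_sample_any <- function(r, x, y, W, H) {
  row <- pmin(pmax(ceiling(y / H * nrow(r)), 1L), nrow(r))
  col <- pmin(pmax(ceiling(x / W * ncol(r)), 1L), ncol(r))
  r[cbind(as.integer(row), as.integer(col))]
}

# sequential random inhibition with grid hashing for the spacing test
place_trees <- function(n_trees, W, H, min_spacing, max_attempts_per_tree) {
  if (n_trees == 0)
    return(data.frame(x = numeric(0), y = numeric(0)))
  if (min_spacing <= 0)
    return(data.frame(x = stats::runif(n_trees, 0, W),
                      y = stats::runif(n_trees, 0, H)))
  xs <- numeric(n_trees); ys <- numeric(n_trees)
  cell <- min_spacing
  ngx <- max(1L, ceiling(W / cell)); ngy <- max(1L, ceiling(H / cell))
  grid <- vector("list", ngx * ngy)
  gidx <- function(x, y) {
    gx <- pmin(pmax(ceiling(x / cell), 1L), ngx)
    gy <- pmin(pmax(ceiling(y / cell), 1L), ngy)
    (gy - 1L) * ngx + gx
  }
  k <- 0L
  budget <- n_trees * max_attempts_per_tree
  attempts <- 0L
  while (k < n_trees && attempts < budget) {
    attempts <- attempts + 1L
    x <- stats::runif(1, 0, W); y <- stats::runif(1, 0, H)
    ok <- TRUE
    if (min_spacing > 0 && k > 0L) {
      gx <- as.integer(pmin(pmax(ceiling(x / cell), 1L), ngx))
      gy <- as.integer(pmin(pmax(ceiling(y / cell), 1L), ngy))
      for (dy in -1:1) for (dx in -1:1) {
        cx <- gx + dx; cy <- gy + dy
        if (cx < 1L || cx > ngx || cy < 1L || cy > ngy) next
        for (j in grid[[(cy - 1L) * ngx + cx]]) {
          if ((xs[j] - x)^2 + (ys[j] - y)^2 < min_spacing^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) {
      k <- k + 1L
      xs[k] <- x; ys[k] <- y
      gi <- gidx(x, y)
      grid[[gi]] <- c(grid[[gi]], k)
    }
  }
  data.frame(x = xs[seq_len(k)], y = ys[seq_len(k)])
}

build_env_fields <- function(sc) {
  res <- sc$resolution_m
  nr <- max(1L, round(sc$domain_size_m[2] / res))
  nc <- max(1L, round(sc$domain_size_m[1] / res))
  ramp_field <- function(spec) {
    xg <- ((seq_len(nc) - 0.5) / nc)
    yg <- ((seq_len(nr) - 0.5) / nr)
    f <- spec$base + outer(yg, xg, function(y, x)
      spec$ramp_x * x + spec$ramp_y * y)
    if (isTRUE(spec$noise_sd > 0))
      f <- f + spec$noise_sd * smooth_field(nr, nc, spec$range_px)
    attr(f, "res") <- res
    f
  }
  vpd <- ramp_field(sc$env$vpd_max)
  zv <- (vpd - mean(vpd)) / stats::sd(vpd)

  # residual smooth fields, orthogonalized against standardized VPD so the
  # affine construction hits the target correlation exactly
  ortho_noise <- function() {
    e <- smooth_field(nr, nc, sc$env$vpd_max$range_px)
    e <- e - mean(e) - zv * (sum(e * zv) / sum(zv * zv))
    e / stats::sd(e)
  }
  mk_derived <- function(base, sd, r, sign = 1) {
    e <- ortho_noise()
    f <- base + sd * (sign * r * zv + sqrt(1 - r^2) * e)
    attr(f, "res") <- res
    f
  }
  dt   <- mk_derived(sc$env$dt_pct$base,  sc$env$dt_pct$sd,  sc$vpd_t_corr,  1)
  dppt <- mk_derived(sc$env$dppt_pct$base, sc$env$dppt_pct$sd, sc$vpd_ppt_corr, -1)
  awc <- ramp_field(sc$env$soil_awc)
  awc[awc < 0] <- 0
  slp <- ramp_field(sc$env$slope_pct)
  slp[slp < 0] <- 0
  list(vpd_max = vpd, dt_pct = dt, dppt_pct = dppt,
       soil_awc = awc, slope_pct = slp)
}

#' Simulate the mortality process over the acquisition span
#'
#' Runs the annual hazard for every tree from the first acquisition year
#' (all trees alive) through the last. Each year a living tree dies with its
#' own annual probability from the tree's height and local environment;
#' death is absorbing. `death_year` is the calendar year of death, so a tree
#' is observed dead at the first acquisition year `>=` its `death_year`.
#'
#' @param landscape a `forest_landscape`.
#' @param hazard optional [hazard_model()] overriding the scenario's.
#' @param seed optional seed (default derives from the scenario seed).
#' @return the landscape with `trees$death_year` filled (NA = survived).
#' @export
simulate_mortality <- function(landscape, hazard = NULL, seed = NULL) {
  stopifnot(inherits(landscape, "forest_landscape"))
  hz <- if (is.null(hazard)) landscape$scenario$hazard else hazard
  stopifnot(inherits(hz, "hazard_model"))
  trees <- landscape$trees
  yrs <- landscape$scenario$acquisition_years
  set.seed(if (is.null(seed)) landscape$scenario$seed + 1L else seed)
  p <- annual_death_prob(hz, trees)
  alive <- rep(TRUE, nrow(trees))
  death_year <- rep(NA_integer_, nrow(trees))
  for (yr in seq(yrs[1] + 1L, yrs[length(yrs)])) {
    die <- alive & (stats::runif(nrow(trees)) < p)
    death_year[die] <- yr
    alive[die] <- FALSE
  }
  landscape$trees$death_year <- death_year
  landscape
}

#' Annual death probability under a hazard model
#'
#' Evaluates the hazard for a tree table (columns `height` plus any
#' environmental variables named in the hazard). Out-of-range raw
#' probabilities are clamped to `[clamp_eps, 1 - clamp_eps]` with a warning
#' tally, never an error.
#'
#' @param hazard a [hazard_model()].
#' @param trees data frame with `height` and env columns.
#' @return numeric vector of annual death probabilities.
#' @export
annual_death_prob <- function(hazard, trees) {
  eta <- hazard$b0 + hazard$b_height * trees$height
  for (v in names(hazard$b_env)) {
    if (is.null(trees[[v]])) stop("hazard references missing variable: ", v)
    eta <- eta + hazard$b_env[[v]] * trees[[v]]
  }
  for (v in names(hazard$b_interaction)) {
    if (is.null(trees[[v]])) stop("hazard references missing variable: ", v)
    eta <- eta + hazard$b_interaction[[v]] * trees$height * trees[[v]]
  }
  p <- if (hazard$form == "logistic-status") stats::plogis(eta) else eta / 100
  n_out <- sum(p < 0 | p > 1)
  if (n_out > 0)
    warning(sprintf("%d annual probabilities outside [0,1] before clamping",
                    n_out))
  pmin(pmax(p, hazard$clamp_eps), 1 - hazard$clamp_eps)
}
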