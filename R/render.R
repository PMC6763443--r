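#' Render a canopy height model from conical crowns
#'
#' Every tree contributes the cone surface `h * (1 - d / r)` (apex height `h`,
#' crown radius `r`, horizontal distance `d` from the stem), floored at 0 and
#' evaluated at pixel centres; the raster is the pixel-wise maximum over
#' trees with background exactly 0.
#'
#' @param landscape a `forest_landscape` (or anything with a `trees` data
#'   frame holding `x`, `y`, `height`, `crown_radius`).
#' @param resolution_m pixel size; defaults to the scenario resolution.
#' @return CHM raster matrix (metres) with `res` attribute.
#' @export
render_chm <- function(landscape, resolution_m = NULL) {
  sc <- landscape$scenario
  res <- if (is.null(resolution_m)) sc$resolution_m else resolution_m
  render_chm_trees(landscape$trees, sc$domain_size_m[1], sc$domain_size_m[2],
                   res)
}

render_chm_trees <- function(trees, W, H, res) {
  nr <- max(1L, round(H / res)); nc <- max(1L, round(W / res))
  chm <- matrix(0, nr, nc)
  for (i in seq_len(nrow(trees))) {
    v <- cone_patch(trees$x[i], trees$y[i], trees$height[i],
                    trees$crown_radius[i], nr, nc, res)
    if (is.null(v)) next
    sub <- chm[v$rows, v$cols, drop = FALSE]
    chm[v$rows, v$cols] <- pmax(sub, v$vals)
  }
  attr(chm, "res") <- res
  chm
}

# cone surface of one tree over its bounding pixel block (NULL if off-grid)
cone_patch <- function(x, y, h, r, nr, nc, res) {
  c0 <- max(1L, floor((x - r) / res)); c1 <- min(nc, ceiling((x + r) / res) + 1L)
  r0 <- max(1L, floor((y - r) / res)); r1 <- min(nr, ceiling((y + r) / res) + 1L)
  c0 <- min(c0, nc); r0 <- min(r0, nr)
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  px <- (cols - 0.5) * res; py <- (rows - 0.5) * res
  d <- sqrt(outer((py - y)^2, (px - x)^2, `+`))
  vals <- h * (1 - d / r)
  vals[vals < 1e-9] <- 0   # snap the d ~ r boundary so the disc is symmetric
  list(rows = rows, cols = cols, vals = vals)
}

#' Render synthetic 4-band imagery and its truth class raster
#'
#' Each crown pixel (pixel whose maximal cone value over trees is positive)
#' is labeled by its owning tree's status in `year` (dead once
#' `death_year <= year`, absorbing) crossed with illumination: the half-crown
#' toward the sun azimuth is sunlit, the far half shaded. Pixels exactly on
#' the divide are split deterministically by the perpendicular coordinate so
#' the two halves differ by at most one pixel. Band values are drawn from
#' the class's 4-band Gaussian; a zero covariance yields the class mean
#' exactly.
#'
#' @param landscape a `forest_landscape` with simulated `death_year`.
#' @param year acquisition year to render.
#' @param spectral spectral library; defaults to the scenario's.
#' @param seed RNG seed for the spectral draw.
#' @param sun_azimuth_deg solar azimuth; defaults to the scenario's.
#' @return list with `bands` (nrow x ncol x 4 array), `truth` (integer class
#'   raster), and `classes` (code-to-name vector:
#'   sunlit_live, shaded_live, sunlit_dead, shaded_dead, background).
#' @export
render_imagery <- function(landscape, year, spectral = NULL, seed = NULL,
                           sun_azimuth_deg = NULL) {
  sc <- landscape$scenario
  if (is.null(spectral)) spectral <- sc$spectral
  if (is.null(sun_azimuth_deg)) sun_azimuth_deg <- sc$sun_azimuth_deg
  if (is.null(seed)) seed <- sc$seed + 17L * (year %% 1000L)
  trees <- landscape$trees
  res <- sc$resolution_m
  nr <- max(1L, round(sc$domain_size_m[2] / res))
  nc <- max(1L, round(sc$domain_size_m[1] / res))

  owner <- matrix(0L, nr, nc)
  best <- matrix(0, nr, nc)
  for (i in seq_len(nrow(trees))) {
    v <- cone_patch(trees$x[i], trees$y[i], trees$height[i],
                    trees$crown_radius[i], nr, nc, res)
    if (is.null(v)) next
    sub <- best[v$rows, v$cols, drop = FALSE]
    win <- v$vals > sub & v$vals > 0
    if (any(win)) {
      osub <- owner[v$rows, v$cols, drop = FALSE]
      osub[win] <- i
      sub[win] <- v$vals[win]
      owner[v$rows, v$cols] <- osub
      best[v$rows, v$cols] <- sub
    }
  }

  classes <- c("sunlit_live", "shaded_live", "sunlit_dead", "shaded_dead",
               "background")
  truth <- matrix(5L, nr, nc)
  crown_idx <- which(owner > 0)
  if (length(crown_idx)) {
    rows <- ((crown_idx - 1L) %% nr) + 1L
    cols <- ((crown_idx - 1L) %/% nr) + 1L
    px <- (cols - 0.5) * res; py <- (rows - 0.5) * res
    ow <- owner[crown_idx]
    dead <- !is.na(trees$death_year[ow]) & trees$death_year[ow] <= year
    az <- sun_azimuth_deg * pi / 180
    sdir <- c(sin(az), -cos(az))          # toward the sun, y increasing south
    sdir[abs(sdir) < 1e-12] <- 0
    dx <- px - trees$x[ow]; dy <- py - trees$y[ow]
    dot <- dx * sdir[1] + dy * sdir[2]
    perp <- dx * (-sdir[2]) + dy * sdir[1]
    # snap floating-point jitter so pixels on the divide are split evenly
    dot[abs(dot) < 1e-9] <- 0
    perp[abs(perp) < 1e-9] <- 0
    sunlit <- dot > 0 | (dot == 0 & perp >= 0)
    code <- ifelse(dead, ifelse(sunlit, 3L, 4L), ifelse(sunlit, 1L, 2L))
    truth[crown_idx] <- code
  }
  attr(truth, "res") <- res

  set.seed(seed)
  bands <- array(0, dim = c(nr, nc, 4))
  flat <- matrix(0, nr * nc, 4)
  for (k in seq_along(classes)) {
    idx <- which(truth == k)
    if (!length(idx)) next
    sp <- spectral[[classes[k]]]
    if (is.null(sp)) stop("spectral library lacks class: ", classes[k])
    if (all(sp$cov == 0)) {
      flat[idx, ] <- matrix(sp$mean, length(idx), 4, byrow = TRUE)
    } else {
      z <- matrix(stats::rnorm(length(idx) * 4), length(idx), 4)
      flat[idx, ] <- z %*% chol(sp$cov) +
        matrix(sp$mean, length(idx), 4, byrow = TRUE)
    }
  }
  for (b in 1:4) bands[, , b] <- matrix(flat[, b], nr, nc)
  attr(bands, "res") <- res
  list(bands = bands, truth = truth, classes = classes)
}
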