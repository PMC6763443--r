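# shared fixture builders; everything is generated in code at test time

# minimal landscape wrapper around a hand-written tree table
manual_landscape <- function(trees, W, H, res = 0.6,
                             years = c(2009L, 2010L, 2012L, 2014L, 2016L),
                             seed = 1L, ...) {
  sc <- forest_scenario(domain_size_m = c(W, H), resolution_m = res,
                        n_trees = 0L, acquisition_years = years,
                        seed = seed, ...)
  if (is.null(trees$crown_radius))
    trees$crown_radius <- 0.10 * trees$height
  if (is.null(trees$death_year))
    trees$death_year <- rep(NA_integer_, nrow(trees))
  if (is.null(trees$id)) trees$id <- seq_len(nrow(trees))
  structure(list(trees = trees, env_fields = list(), chm = NULL,
                 scenario = sc, n_rejected_trees = 0L),
            class = "forest_landscape")
}

# CHM from a tree table (thin wrapper over render_chm)
cone_chm <- function(trees, W, H, res = 0.6) {
  render_chm(manual_landscape(trees, W, H, res))
}

# regular grid of trees with given spacing, snapped to pixel centres
grid_trees <- function(spacing, W, H, height = 20, res = 0.6) {
  xs <- seq(spacing, W - spacing, by = spacing)
  ys <- seq(spacing, H - spacing, by = spacing)
  snap <- function(v) (round(v / res - 0.5) + 0.5) * res
  g <- expand.grid(x = snap(xs), y = snap(ys))
  g$height <- height
  g
}

# brute-force exhaustive variable-window local-maxima scan (independent of
# the C++ path): O(n_pixels * window) double loop in R
brute_treetops <- function(chm, min_height = 5, min_radius_m = 1.5,
                           radius_coef = 0.05) {
  res <- attr(chm, "res")
  nr <- nrow(chm); nc <- ncol(chm)
  hits <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    h <- chm[r, c]
    if (h < min_height) next
    rad <- max(min_radius_m, radius_coef * h) / res
    w <- floor(rad)
    ok <- TRUE
    for (dr in -w:w) for (dc in -w:w) {
      if (dr == 0 && dc == 0) next
      if (dr^2 + dc^2 > rad^2) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      o <- chm[rr, cc]
      if (o > h || (o == h && (rr < r || (rr == r && cc < c)))) ok <- FALSE
    }
    if (ok) hits <- rbind(hits, c(r, c))
  }
  hits
}

# direct Gaussian log-density (independent oracle for the MLC path)
brute_log_density <- function(x, mu, sigma, prior) {
  d <- length(mu)
  -0.5 * log(det(sigma)) - 0.5 * d * log(2 * pi) -
    0.5 * drop(t(x - mu) %*% solve(sigma) %*% (x - mu)) + log(prior)
}

# greedy one-to-one matching of detected to true apices by distance
match_tops <- function(det, truth, max_dist = 1.5) {
  if (nrow(det) == 0 || nrow(truth) == 0)
    return(list(tp = 0, fp = nrow(det), fn = nrow(truth)))
  d <- outer(seq_len(nrow(det)), seq_len(nrow(truth)), function(i, j)
    sqrt((det$x[i] - truth$x[j])^2 + (det$y[i] - truth$y[j])^2))
  tp <- 0
  used_d <- rep(FALSE, nrow(det)); used_t <- rep(FALSE, nrow(truth))
  repeat {
    d[used_d, ] <- Inf; d[, used_t] <- Inf
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (!is.finite(d[m])) break
    if (d[m] > max_dist) break
    tp <- tp + 1
    used_d[m[1]] <- TRUE; used_t[m[2]] <- TRUE
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(truth) - tp)
}

# map truth class codes (render order) onto a trained model's class codes
truth_as_model_codes <- function(truth, truth_classes, model) {
  matrix(match(truth_classes[truth], model$classes),
         nrow(truth), ncol(truth))
}
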