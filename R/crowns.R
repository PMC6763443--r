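#' Detect treetops as variable-window local maxima in a CHM
#'
#' Scans the canopy height model for pixels at least `min_height` tall that
#' strictly exceed every other pixel inside a circular moving window whose
#' radius grows with the candidate's height:
#' `max(min_radius_m, radius_coef * height)`. Among equal-valued pixels in a
#' window, the smallest `(row, col)` wins, so output is deterministic and
#' ordered row-major.
#'
#' @param chm CHM raster matrix (finite, non-negative) with `res` attribute.
#' @param min_height minimum treetop height (m); must be positive.
#' @param min_radius_m floor of the window radius (m).
#' @param radius_coef window radius per metre of candidate height.
#' @return data frame: `row`, `col` (1-based), `x`, `y` (m, pixel centres),
#'   `height` (m).
#' @export
detect_treetops <- function(chm, min_height = 5, min_radius_m = 1.5,
                            radius_coef = 0.05) {
  if (min_height <= 0) stop("min_height must be positive")
  if (any(!is.finite(chm)) || any(chm < 0))
    stop("chm must be finite and non-negative")
  res <- tm_res(chm)
  rc <- .detect_treetops_cpp(unclass(chm), min_height, res, min_radius_m,
                             radius_coef)
  ord <- order(rc[, 1], rc[, 2])
  rc <- rc[ord, , drop = FALSE]
  xy <- tm_cell_xy(rc[, 1], rc[, 2], res)
  data.frame(row = rc[, 1], col = rc[, 2], x = xy$x, y = xy$y,
             height = chm[rc])
}

#' Segment crowns by marker-based watershed on the inverted CHM
#'
#' Floods the above-threshold mask (`chm >= min_height`) from the treetop
#' markers in order of decreasing height (equivalently, watershed of the
#' inverted surface), 4-connected, with ties on the divide going to the
#' lower label. Above-threshold components that contain no marker get their
#' highest pixel promoted to an apex (counted in a warning). Crowns smaller
#' than `min_crown_px` pixels are merged into the neighbouring crown with
#' the highest CHM along the shared border; their apices are dropped.
#' Labels are renumbered 1..K in apex row-major order.
#'
#' @param chm CHM raster with `res` attribute.
#' @param treetops data frame from [detect_treetops()] (columns `row`,
#'   `col`); may have zero rows.
#' @param min_height segmentation floor (m).
#' @param min_crown_px minimum crown size in pixels.
#' @return an object of class `crown_map`: list with `labels` (integer
#'   raster, 0 = background), `crowns` (data frame: `id`, `apex_row`,
#'   `apex_col`, `x`, `y`, `max_height`, `pixel_count`, `area_m2`,
#'   `centroid_x`, `centroid_y`), `min_height`, `res`.
#' @export
segment_crowns <- function(chm, treetops, min_height = 5, min_crown_px = 3) {
  res <- tm_res(chm)
  mask <- chm >= min_height
  tt <- treetops
  if (nrow(tt) > 0) {
    bad <- which(!mask[cbind(tt$row, tt$col)])
    if (length(bad))
      stop("treetop markers on below-threshold pixels: ",
           paste(sprintf("(%d,%d)", tt$row[bad], tt$col[bad]), collapse = " "))
  }
  nr <- nrow(chm); nc <- ncol(chm)
  if (nrow(tt) == 0) {
    labels <- matrix(0L, nr, nc)
    attr(labels, "res") <- res
    return(structure(list(labels = labels,
                          crowns = empty_crown_df(),
                          min_height = min_height, res = res),
                     class = "crown_map"))
  }
  markers <- cbind(tt$row, tt$col)
  labels <- .watershed_cpp(unclass(chm), mask, markers)
  apex <- markers

  # orphan above-threshold components (no marker): promote their max pixel
  orphans <- which(mask & labels == 0L)
  if (length(orphans)) {
    comp <- flood_components(mask & labels == 0L)
    n_new <- max(comp$id)
    warning(sprintf("%d above-threshold component(s) without a detected top; apex promoted", n_new))
    for (k in seq_len(n_new)) {
      px <- comp$cells[comp$id_of_cell == k]
      hbest <- max(chm[px])
      best <- min(px[chm[px] == hbest])  # smallest linear index = row-major in-col first
      labels[px] <- nrow(apex) + k
      apex <- rbind(apex, c(((best - 1L) %% nr) + 1L, ((best - 1L) %/% nr) + 1L))
    }
  }

  # merge undersized crowns into the neighbour with highest shared-border CHM
  cnt <- tabulate(labels[labels > 0L], nbins = nrow(apex))
  small <- which(cnt > 0L & cnt < min_crown_px)
  for (k in small) {
    px <- which(labels == k)
    nb <- neighbour_cells(px, nr, nc)
    nb_lab <- labels[nb$cells]
    keep <- nb_lab > 0L & nb_lab != k
    if (!any(keep)) next
    cand <- nb_lab[keep]
    hts <- chm[nb$cells[keep]]
    tgt <- cand[which.max(hts)]
    labels[px] <- tgt
    apex[k, ] <- NA_integer_
  }

  alive <- which(!is.na(apex[, 1]) & tabulate(labels[labels > 0L],
                                              nbins = nrow(apex)) > 0L)
  ord <- alive[order(apex[alive, 1], apex[alive, 2])]
  remap <- integer(nrow(apex))
  remap[ord] <- seq_along(ord)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  apex <- apex[ord, , drop = FALSE]

  crowns <- crown_metrics(labels, chm, apex, res)
  attr(labels, "res") <- res
  structure(list(labels = labels, crowns = crowns,
                 min_height = min_height, res = res),
            class = "crown_map")
}

empty_crown_df <- function() {
  data.frame(id = integer(0), apex_row = integer(0), apex_col = integer(0),
             x = numeric(0), y = numeric(0), max_height = numeric(0),
             pixel_count = integer(0), area_m2 = numeric(0),
             centroid_x = numeric(0), centroid_y = numeric(0))
}

crown_metrics <- function(labels, chm, apex, res) {
  k <- nrow(apex)
  if (k == 0) return(empty_crown_df())
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  cnt <- tabulate(lab, nbins = k)
  cx <- as.numeric(rowsum((cols - 0.5) * res, lab)) / cnt
  cy <- as.numeric(rowsum((rows - 0.5) * res, lab)) / cnt
  xy <- tm_cell_xy(apex[, 1], apex[, 2], res)
  data.frame(id = seq_len(k), apex_row = apex[, 1], apex_col = apex[, 2],
             x = xy$x, y = xy$y, max_height = chm[apex],
             pixel_count = cnt, area_m2 = cnt * res^2,
             centroid_x = cx, centroid_y = cy)
}

# 4-connected component labelling of a logical matrix (iterative flood)
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  id_of_cell <- integer(length(cells))
  lab_m <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in cells) {
    if (lab_m[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab_m[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- rr + (cc - 1L) * nr
        if (mask[q] && lab_m[q] == 0L) { lab_m[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  id_of_cell <- lab_m[cells]
  list(cells = cells, id_of_cell = id_of_cell, id = seq_len(cur))
}

# 4-neighbours of a set of linear indices (deduplicated, in-grid)
neighbour_cells <- function(px, nr, nc) {
  r <- ((px - 1L) %% nr) + 1L; c <- ((px - 1L) %/% nr) + 1L
  rr <- c(r - 1L, r + 1L, r, r); cc <- c(c, c, c - 1L, c + 1L)
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  cells <- unique((rr[ok] + (cc[ok] - 1L) * nr))
  cells <- setdiff(cells, px)
  list(cells = cells)
}

#' Validate the structural invariants of a crown map
#'
#' Asserts that crown labels partition the above-threshold mask (every pixel
#' with `chm >= min_height` has exactly one positive label, background has
#' none), that each crown contains exactly one apex whose height equals the
#' crown maximum, and that every crown's pixel set is 4-connected.
#'
#' @param cm a `crown_map`.
#' @param chm the CHM it was built from.
#' @return `TRUE` invisibly; stops on the first violated invariant.
#' @export
validate_crown_map <- function(cm, chm) {
  mask <- chm >= cm$min_height
  if (any(mask & cm$labels == 0L)) stop("above-threshold pixel unlabeled")
  if (any(!mask & cm$labels != 0L)) stop("below-threshold pixel labeled")
  k <- nrow(cm$crowns)
  if (k > 0) {
    lab_at_apex <- cm$labels[cbind(cm$crowns$apex_row, cm$crowns$apex_col)]
    if (!identical(as.integer(lab_at_apex), cm$crowns$id))
      stop("apex not inside its own crown")
    for (i in seq_len(k)) {
      px <- which(cm$labels == i)
      if (abs(max(chm[px]) - cm$crowns$max_height[i]) > 1e-9)
        stop("crown max height != apex height for crown ", i)
      comp <- flood_components(cm$labels == i)
      if (max(comp$id) != 1L) stop("crown ", i, " not 4-connected")
    }
  }
  invisible(TRUE)
}

#' Percent canopy cover by aggregation of a classified CHM
#'
#' Aggregates `chm > min_height` to coarse cells of `cell_size` metres and
#' reports the percent of covered pixels per cell. `cell_size` must be an
#' integer multiple of the CHM resolution; a trailing partial cell uses the
#' pixels it has.
#'
#' @param chm CHM raster with `res` attribute.
#' @param min_height cover threshold (m), default 5.
#' @param cell_size aggregate cell size (m).
#' @return raster matrix of percent cover (0-100) with `res = cell_size`.
#' @export
crown_cover_fraction <- function(chm, min_height = 5, cell_size) {
  res <- tm_res(chm)
  f <- cell_size / res
  if (abs(f - round(f)) > 1e-6)
    stop("cell_size must be an integer multiple of the CHM resolution")
  f <- as.integer(round(f))
  nr <- nrow(chm); nc <- ncol(chm)
  cr <- ceiling(nr / f); cc <- ceiling(nc / f)
  rowi <- ((seq_len(nr) - 1L) %/% f) + 1L
  coli <- ((seq_len(nc) - 1L) %/% f) + 1L
  cell <- outer(rowi, coli, function(a, b) a + (b - 1L) * cr)
  cov <- chm > min_height
  pct <- 100 * as.numeric(rowsum(as.numeric(cov), as.vector(cell))) /
    as.numeric(rowsum(rep(1, length(cell)), as.vector(cell)))
  out <- matrix(pct, cr, cc)
  attr(out, "res") <- cell_size
  out
}
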