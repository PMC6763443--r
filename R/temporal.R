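#' Height class of a tree
#'
#' Small trees are 5-15 m, medium 15-30 m, large above 30 m. Bounds are
#' half-open (`[5,15)`, `[15,30)`, `[30,Inf)`) so the classes partition the
#' height axis. Heights below the 5 m analysis floor are an error.
#'
#' @param height tree height(s) in metres.
#' @return factor with levels `small`, `medium`, `large`.
#' @export
assign_height_class <- function(height) {
  if (any(height < 5)) stop("height below the 5 m analysis floor")
  cut(height, c(5, 15, 30, Inf), labels = c("small", "medium", "large"),
      right = FALSE)
}

#' Build per-tree records from per-year crown statuses
#'
#' Joins the fixed crown segmentation with each acquisition year's crown
#' status and samples every environmental raster at the crown centroid
#' (nearest pixel). Dead status is made absorbing: any dead-to-live flicker
#' from the classifier is coerced back to dead with a warning count.
#'
#' @param crown_map a `crown_map` (the fixed segmentation; `max_height` is
#'   the tree height Z used throughout).
#' @param statuses data frame with columns `id`, `year`, `status`
#'   (`"live"`/`"dead"`), covering every crown in every year.
#' @param env_fields named list of rasters (may differ in resolution); each
#'   is sampled proportionally over the same map extent.
#' @param domain_size_m map extent `c(W, H)` in metres; defaults to the
#'   crown-map extent.
#' @return data frame, one row per tree: `id`, `height`, `height_class`,
#'   one column per environmental variable, `status_<year>` columns, and
#'   `first_dead_year` (NA = survived). Attribute `years` carries the
#'   acquisition years.
#' @export
build_records <- function(crown_map, statuses, env_fields = list(),
                          domain_size_m = NULL) {
  crowns <- crown_map$crowns
  years <- sort(unique(statuses$year))
  if (length(years) < 2) stop("need at least two acquisition years")
  wide <- matrix(NA_character_, nrow(crowns), length(years),
                 dimnames = list(NULL, paste0("status_", years)))
  for (j in seq_along(years)) {
    sy <- statuses[statuses$year == years[j], ]
    m <- match(crowns$id, sy$id)
    if (any(is.na(m)))
      stop("crowns missing from year ", years[j], ": ",
           paste(utils::head(crowns$id[is.na(m)], 10), collapse = ", "))
    wide[, j] <- sy$status[m]
  }
  if (!all(wide %in% c("live", "dead"))) stop("statuses must be live/dead")

  # absorbing-state enforcement
  n_flick <- 0L
  for (j in seq_along(years)[-1]) {
    flick <- wide[, j] == "live" & wide[, j - 1] == "dead"
    n_flick <- n_flick + sum(flick)
    wide[flick, j] <- "dead"
  }
  if (n_flick > 0)
    warning(sprintf("%d dead-to-live flicker(s) coerced to dead", n_flick))

  first_dead <- apply(wide == "dead", 1, function(d)
    if (any(d)) years[which(d)[1]] else NA_integer_)

  rec <- data.frame(id = crowns$id, height = crowns$max_height,
                    height_class = assign_height_class(crowns$max_height))
  if (length(env_fields)) {
    W <- if (is.null(domain_size_m)) ncol(crown_map$labels) * crown_map$res else domain_size_m[1]
    H <- if (is.null(domain_size_m)) nrow(crown_map$labels) * crown_map$res else domain_size_m[2]
    for (v in names(env_fields))
      rec[[v]] <- tm_sample_any(env_fields[[v]], crowns$centroid_x,
                                crowns$centroid_y, W, H)
  }
  rec <- cbind(rec, as.data.frame(wide, stringsAsFactors = FALSE))
  rec$first_dead_year <- as.integer(first_dead)
  attr(rec, "years") <- years
  rec
}

#' Survivor-pool mortality summary by height group
#'
#' For each group and acquisition interval: susceptible trees are those
#' still alive at the interval start (dead trees are removed from later
#' intervals so rates are not inflated); percent mortality is newly dead
#' over susceptible x 100, and the rate divides by the interval length in
#' years. Cumulative mortality per year is all deaths so far over the
#' initial group size. Groups with no susceptible trees get `NA` rates
#' (flagged), not zero. 95\% CIs use the normal approximation to the
#' binomial on the interval proportion.
#'
#' @param records output of [build_records()] (or any data frame with
#'   `height`, `status_<year>` columns and a `years` attribute).
#' @param grouping `"class"` (small/medium/large) or `"bin"` (5 m bins
#'   labeled by lower edge).
#' @param bin_width bin width in metres when `grouping = "bin"`.
#' @return object of class `mortality_summary`: `intervals` and
#'   `cumulative` data frames.
#' @export
mortality_summary <- function(records, grouping = c("class", "bin"),
                              bin_width = 5) {
  grouping <- match.arg(grouping)
  years <- attr(records, "years")
  if (is.null(years)) {
    years <- as.integer(sub("status_", "", grep("^status_",
                                                names(records), value = TRUE)))
  }
  years <- sort(years)
  if (any(diff(years) <= 0)) stop("acquisition years must be increasing")
  grp <- if (grouping == "class") as.character(assign_height_class(records$height))
         else floor(records$height / bin_width) * bin_width
  status <- as.matrix(records[paste0("status_", years)])
  glev <- if (grouping == "class") c("small", "medium", "large")
          else sort(unique(grp))

  intervals <- list(); cumulative <- list()
  for (g in glev) {
    sel <- grp == g
    n0 <- sum(sel)
    for (j in seq_along(years)[-1]) {
      dy <- years[j] - years[j - 1]
      sus <- sel & status[, j - 1] == "live"
      newd <- sus & status[, j] == "dead"
      ns <- sum(sus); nd <- sum(newd)
      if (ns == 0) {
        pct <- NA_real_; rate <- NA_real_; lo <- NA_real_; hi <- NA_real_
      } else {
        p <- nd / ns
        pct <- 100 * p
        rate <- pct / dy
        se <- sqrt(p * (1 - p) / ns)
        lo <- 100 * max(0, p - 1.96 * se) / dy
        hi <- 100 * (p + 1.96 * se) / dy
      }
      intervals[[length(intervals) + 1L]] <- data.frame(
        group = as.character(g), year_start = years[j - 1],
        year_end = years[j], n_susceptible = ns, n_newly_dead = nd,
        percent = pct, rate = rate, rate_ci_lo = lo, rate_ci_hi = hi,
        undefined = ns == 0)
    }
    for (j in seq_along(years)) {
      ndc <- sum(sel & status[, j] == "dead")
      cumulative[[length(cumulative) + 1L]] <- data.frame(
        group = as.character(g), year = years[j], n_initial = n0,
        n_dead_cum = ndc,
        cumulative_pct = if (n0 == 0) NA_real_ else 100 * ndc / n0)
    }
  }
  structure(list(intervals = do.call(rbind, intervals),
                 cumulative = do.call(rbind, cumulative),
                 grouping = grouping, years = years),
            class = "mortality_summary")
}
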