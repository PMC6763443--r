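#' Train a Gaussian maximum-likelihood classifier
#'
#' Per-class sample mean and sample covariance (denominator n-1) over the
#' labeled band vectors; priors are equal unless given. Near-singular
#' covariances are ridge-regularized by `eps = 1e-6 * trace / n_bands` on
#' the diagonal, with a warning.
#'
#' @param pixels numeric matrix, one row per labeled pixel, one column per
#'   band.
#' @param labels class label per row (character or factor); every class
#'   needs at least 5 pixels and there must be at least 2 classes.
#' @param priors optional named prior probabilities; default equal.
#' @return object of class `mlc_model`: per class `mean`, `cov`, plus
#'   `priors` and `classes` (the class order used for code rasters).
#' @export
train_mlc <- function(pixels, labels, priors = NULL) {
  pixels <- as.matrix(pixels)
  labels <- as.character(labels)
  stopifnot(nrow(pixels) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  nb <- ncol(pixels)
  small <- classes[table(factor(labels, classes)) < 5]
  if (length(small))
    stop("classes with < 5 training pixels: ", paste(small, collapse = ", "))
  fits <- lapply(classes, function(cl) {
    x <- pixels[labels == cl, , drop = FALSE]
    mu <- colMeans(x)
    sg <- stats::cov(x)
    if (inherits(try(chol(sg), silent = TRUE), "try-error") ||
        rcond(sg) < 1e-10) {
      eps <- 1e-6 * sum(diag(sg)) / nb
      if (eps <= 0) eps <- 1e-6
      sg <- sg + diag(eps, nb)
      warning(sprintf("class '%s': covariance ridge-regularized (eps=%.3g)",
                      cl, eps))
    }
    list(mean = mu, cov = sg)
  })
  names(fits) <- classes
  if (is.null(priors)) {
    priors <- rep(1 / length(classes), length(classes))
    names(priors) <- classes
  } else {
    stopifnot(all(classes %in% names(priors)))
    priors <- priors[classes] / sum(priors[classes])
  }
  structure(list(fits = fits, priors = priors, classes = classes,
                 n_bands = nb), class = "mlc_model")
}

#' Classify imagery pixels by maximum likelihood
#'
#' Assigns each pixel the class maximizing the Gaussian log-density plus
#' log-prior. Ties go to the lowest class index. Pixels with any
#' non-finite band are assigned the `background` class when the model has
#' one (code 0 otherwise) and counted in a warning.
#'
#' @param imagery `nrow x ncol x bands` array (or `n x bands` matrix).
#' @param model an `mlc_model`.
#' @return integer class-code raster (codes index `model$classes`, attribute
#'   `classes` carries the names); a vector if `imagery` was a matrix.
#' @export
classify_pixels <- function(imagery, model) {
  stopifnot(inherits(model, "mlc_model"))
  is_arr <- length(dim(imagery)) == 3
  X <- if (is_arr) {
    d <- dim(imagery)
    matrix(imagery, d[1] * d[2], d[3])
  } else as.matrix(imagery)
  if (ncol(X) != model$n_bands)
    stop("band count mismatch: imagery has ", ncol(X), ", model expects ",
         model$n_bands)
  n <- nrow(X)
  bad <- !apply(is.finite(X), 1, all)
  scores <- matrix(-Inf, n, length(model$classes))
  okX <- X[!bad, , drop = FALSE]
  for (k in seq_along(model$classes)) {
    f <- model$fits[[k]]
    ch <- chol(f$cov)
    z <- forwardsolve(t(ch), t(okX) - f$mean)
    mahal <- colSums(z^2)
    scores[!bad, k] <- -sum(log(diag(ch))) - 0.5 * mahal +
      log(model$priors[k])
  }
  code <- max.col(scores, ties.method = "first")
  if (any(bad)) {
    bg <- match("background", model$classes)
    code[bad] <- if (is.na(bg)) 0L else bg
    warning(sprintf("%d pixel(s) with non-finite bands assigned background",
                    sum(bad)))
  }
  if (is_arr) {
    out <- matrix(as.integer(code), dim(imagery)[1], dim(imagery)[2])
    attr(out, "res") <- attr(imagery, "res")
  } else out <- as.integer(code)
  attr(out, "classes") <- model$classes
  out
}

#' Collapse a class raster to a binary dead raster
#'
#' Maps the dead classes to 1 and everything else (live, background,
#' unclassified) to 0.
#'
#' @param class_raster output of [classify_pixels()] (attribute `classes`),
#'   or any integer raster if `classes` is given.
#' @param dead_classes class names counted as dead.
#' @param classes optional code-to-name vector overriding the attribute.
#' @return binary 0/1 raster of the same shape.
#' @export
collapse_to_dead <- function(class_raster,
                             dead_classes = c("sunlit_dead", "shaded_dead"),
                             classes = NULL) {
  if (is.null(classes)) classes <- attr(class_raster, "classes")
  if (is.null(classes)) stop("no class names available")
  dead_codes <- which(classes %in% dead_classes)
  out <- (class_raster %in% dead_codes) + 0L
  dim(out) <- dim(class_raster)
  attr(out, "res") <- attr(class_raster, "res")
  out
}

#' Per-crown dead fraction
#'
#' The crown dieback fraction: mean of the binary dead raster over each
#' crown's pixels.
#'
#' @param crown_map a `crown_map`.
#' @param dead_raster aligned binary raster from [collapse_to_dead()].
#' @return data frame: `id`, `dead_fraction`.
#' @export
crown_dead_fraction <- function(crown_map, dead_raster) {
  if (!identical(dim(crown_map$labels), dim(dead_raster)))
    stop("crown map and dead raster shapes differ")
  k <- nrow(crown_map$crowns)
  if (k == 0) return(data.frame(id = integer(0), dead_fraction = numeric(0)))
  idx <- which(crown_map$labels > 0L)
  lab <- crown_map$labels[idx]
  cnt <- tabulate(lab, nbins = k)
  if (any(cnt == 0)) stop("crown with 0 pixels")
  dead <- as.numeric(rowsum(as.numeric(dead_raster[idx]), lab))
  data.frame(id = seq_len(k), dead_fraction = dead / cnt)
}

#' Classify crown status from its dieback fraction
#'
#' A crown is dead when its dead fraction strictly exceeds the threshold
#' (default 0.375, i.e. 37.5\% crown death); a fraction exactly at the
#' threshold is live.
#'
#' @param fraction dieback fraction(s) in `[0, 1]`.
#' @param threshold dieback threshold in `[0, 1]`.
#' @return character vector, `"dead"` or `"live"`.
#' @export
classify_crown_status <- function(fraction, threshold = 0.375) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction > threshold, "dead", "live")
}

#' Calibrate the crown-death threshold against validation labels
#'
#' Sweeps thresholds over a grid on `[0, 1]`, computing overall accuracy,
#' false-positive rate (live crowns called dead) and false-negative rate
#' (dead crowns called live) at each. The selected threshold maximizes
#' accuracy; near-ties (within 0.005 of the maximum) are broken by the
#' smallest `|FPR - FNR|` (the least biased choice), then by the smaller
#' threshold.
#'
#' @param fractions crown dieback fractions.
#' @param truth_labels true status per crown (`"dead"`/`"live"`, or logical
#'   dead).
#' @param grid_step threshold grid spacing, default 0.025.
#' @return object of class `threshold_curve`: `curve` data frame
#'   (`threshold`, `accuracy`, `fpr`, `fnr`, `bias`) and `selected`.
#' @export
calibrate_threshold <- function(fractions, truth_labels, grid_step = 0.025) {
  dead <- if (is.logical(truth_labels)) truth_labels else truth_labels == "dead"
  stopifnot(length(fractions) == length(dead))
  if (!any(dead) || all(dead))
    stop("need at least one true-dead and one true-live crown")
  grid <- seq(0, 1, by = grid_step)
  npos <- sum(dead); nneg <- sum(!dead)
  curve <- do.call(rbind, lapply(grid, function(t) {
    pred <- fractions > t
    data.frame(threshold = t,
               accuracy = mean(pred == dead),
               fpr = sum(pred & !dead) / nneg,
               fnr = sum(!pred & dead) / npos)
  }))
  curve$bias <- curve$fpr - curve$fnr
  amax <- max(curve$accuracy)
  cand <- which(curve$accuracy >= amax - 0.005)
  cand <- cand[order(abs(curve$bias[cand]), curve$threshold[cand])]
  structure(list(curve = curve, selected = curve$threshold[cand[1]],
                 accuracy = curve$accuracy[cand[1]]),
            class = "threshold_curve")
}
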