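test_that("MLC training reproduces hand-computed moments and handles degenerate classes", {
  # 10 listed vectors, two classes: moments equal the brute-force formulas
  xa <- matrix(c(1, 2, 0, 1,
                 2, 3, 1, 2,
                 0, 1, 1, 0,
                 1, 1, 2, 1,
                 2, 2, 1, 3), 5, 4, byrow = TRUE)
  xb <- xa + 10
  mod <- train_mlc(rbind(xa, xb), rep(c("a", "b"), each = 5))
  expect_equal(mod$fits$a$mean, colMeans(xa))
  expect_equal(mod$fits$a$cov, crossprod(sweep(xa, 2, colMeans(xa))) / 4)
  expect_equal(unname(mod$priors), c(0.5, 0.5))

  # identical pixels in one class: ridge-regularized covariance, exact mean
  xc <- matrix(5, 6, 4)
  expect_warning(mod2 <- train_mlc(rbind(xa, xc),
                                   rep(c("a", "c"), times = c(5, 6))),
                 "ridge")
  expect_equal(mod2$fits$c$mean, rep(5, 4))
  expect_true(all(diag(mod2$fits$c$cov) > 0))

  expect_error(train_mlc(xa, rep("a", 5)), "2 classes")
  expect_error(train_mlc(rbind(xa, xb[1:3, ]),
                         c(rep("a", 5), rep("b", 3))), "< 5")

  # well-separated classes classify their own training set perfectly
  pred <- classify_pixels(rbind(xa, xb), mod)
  expect_equal(mod$classes[pred], rep(c("a", "b"), each = 5))
})

test_that("pixel classification equals the direct density argmax oracle", {
  set.seed(41)
  mus <- list(c(0, 0, 0, 0), c(3, 1, 0, 2), c(-1, 2, 2, 0))
  sigs <- list(diag(4), diag(c(1, 2, 1, 0.5)),
               0.5 * diag(4) + 0.2)
  train <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(200 * 4), 200, 4) %*% chol(sigs[[k]]) +
      matrix(mus[[k]], 200, 4, byrow = TRUE)))
  mod <- train_mlc(train, rep(c("a", "b", "c"), each = 200))

  # a pixel at a class mean goes to that class
  at_mean <- do.call(rbind, lapply(mod$classes, function(cl) mod$fits[[cl]]$mean))
  expect_equal(classify_pixels(at_mean, mod), 1:3, ignore_attr = TRUE)

  # 20 random pixels vs brute-force per-class density evaluation
  px <- matrix(rnorm(20 * 4, sd = 2), 20, 4)
  pred <- classify_pixels(px, mod)
  oracle <- apply(px, 1, function(x)
    which.max(vapply(mod$classes, function(cl)
      brute_log_density(x, mod$fits[[cl]]$mean, mod$fits[[cl]]$cov,
                        mod$priors[[cl]]), numeric(1))))
  expect_equal(as.integer(pred), as.integer(oracle))

  # exact argmax tie resolves to the lowest class index
  tie_mod <- mod
  tie_mod$fits$b <- tie_mod$fits$a
  tie_mod$priors <- c(a = 1/3, b = 1/3, c = 1/3)
  x0 <- matrix(tie_mod$fits$a$mean, 1)
  expect_equal(as.integer(classify_pixels(x0, tie_mod)), 1L)

  # NaN bands fall back to background with a warning tally
  bgmod <- train_mlc(rbind(train[1:200, ], train[201:400, ]),
                     rep(c("background", "tree"), each = 200))
  expect_warning(out <- classify_pixels(rbind(c(NaN, 1, 1, 1), c(0, 0, 0, 0)),
                                        bgmod),
                 "non-finite")
  expect_equal(as.integer(out[1]), match("background", bgmod$classes))
})

test_that("crown dead fractions count pixels exactly and are monotone", {
  labels <- matrix(0L, 4, 4)
  labels[1:2, 1:4] <- 1L          # 8-pixel crown
  labels[4, 1:3] <- 2L            # 3-pixel crown
  cmap <- structure(list(labels = labels,
                         crowns = data.frame(id = 1:2, apex_row = c(1L, 4L),
                                             apex_col = c(1L, 1L)),
                         min_height = 5, res = 1),
                    class = "crown_map")
  dead <- matrix(0L, 4, 4)
  dead[1, 1:3] <- 1L              # 3 of 8 dead
  fr <- crown_dead_fraction(cmap, dead)
  expect_equal(fr$dead_fraction, c(0.375, 0))
  dead2 <- dead; dead2[4, 1:3] <- 1L
  fr2 <- crown_dead_fraction(cmap, dead2)
  expect_equal(fr2$dead_fraction, c(0.375, 1))
  # flipping any live pixel to dead never decreases a fraction
  set.seed(7)
  for (k in 1:10) {
    d3 <- dead
    flip <- sample(which(d3 == 0L), 1)
    d3[flip] <- 1L
    expect_true(all(crown_dead_fraction(cmap, d3)$dead_fraction >=
                      fr$dead_fraction))
  }
})

test_that("crown status uses a strict 37.5% dieback threshold", {
  expect_equal(classify_crown_status(0.40), "dead")
  expect_equal(classify_crown_status(0.375), "live")  # boundary is live
  expect_equal(classify_crown_status(0.0), "live")
  expect_error(classify_crown_status(0.5, threshold = 1.2), "\\[0,1\\]")
})

test_that("threshold calibration selects the unbiased accuracy maximum", {
  # perfectly separated: smallest grid value achieving zero error
  fr <- rep(c(0.10, 0.30), each = 20)
  truth <- rep(c("live", "dead"), each = 20)
  tc <- calibrate_threshold(fr, truth)
  expect_equal(tc$accuracy, 1.0)
  expect_equal(tc$selected, 0.100)
  expect_error(calibrate_threshold(fr, rep("live", 40)), "true-dead")

  # truth generated as dead iff fraction > 0.375 (+ noise): recovered within
  # one grid step
  set.seed(55)
  frac <- runif(600)
  noisy <- frac + rnorm(600, sd = 0.03)
  truth2 <- ifelse(noisy > 0.375, "dead", "live")
  tc2 <- calibrate_threshold(frac, truth2)
  expect_lte(abs(tc2$selected - 0.375), 0.025)

  # curve accuracies equal the confusion-matrix oracle at spot thresholds
  for (t in c(0.1, 0.25, 0.375, 0.5, 0.9)) {
    pred <- ifelse(frac > t, "dead", "live")
    acc <- mean(pred == truth2)
    row <- tc2$curve[abs(tc2$curve$threshold - t) < 1e-9, ]
    expect_equal(row$accuracy, acc)
    expect_equal(row$fpr, sum(pred == "dead" & truth2 == "live") /
                   sum(truth2 == "live"))
    expect_equal(row$fnr, sum(pred == "live" & truth2 == "dead") /
                   sum(truth2 == "dead"))
  }
})

test_that("end-to-end crown status on a well-separated scene reaches 95% accuracy", {
  sc <- forest_scenario(domain_size_m = c(130, 130), n_trees = 130,
                        min_spacing_m = 6, seed = 61,
                        hazard = hazard_model("logistic-status",
                                              b0 = qlogis(0.12)))
  ls <- simulate_mortality(generate_landscape(sc))
  chm <- ls$chm
  cmap <- segment_crowns(chm, detect_treetops(chm))
  img <- render_imagery(ls, 2016)
  set.seed(8)
  idx <- sample(length(img$truth), 3000)
  mod <- train_mlc(matrix(img$bands, ncol = 4)[idx, ],
                   img$classes[img$truth[idx]])
  pred <- classify_pixels(img$bands, mod)
  truth_codes <- truth_as_model_codes(img$truth, img$classes, mod)
  expect_gte(mean(pred == truth_codes), 0.95)

  dead <- collapse_to_dead(pred)
  fr <- crown_dead_fraction(cmap, dead)
  status <- classify_crown_status(fr$dead_fraction)
  # generator truth per segmented crown: status of the nearest true stem
  near <- apply(cbind(cmap$crowns$x, cmap$crowns$y), 1, function(p)
    which.min((ls$trees$x - p[1])^2 + (ls$trees$y - p[2])^2))
  truth_dead <- !is.na(ls$trees$death_year[near]) &
    ls$trees$death_year[near] <= 2016
  expect_gte(mean((status == "dead") == truth_dead), 0.95)
})
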