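test_that("region labelling uses 8-connectivity, area filters and reading order", {
  m <- matrix(0L, 20, 20)
  m[2:6, 2:6] <- 1L       # 5x5 square
  m[12:16, 10:14] <- 1L   # disjoint 5x5 square
  regs <- label_regions(m)
  expect_length(regs, 2L)
  expect_equal(vapply(regs, function(r) r$area_px, 0L), c(25L, 25L))
  expect_equal(regs[[1]]$region_id, 1L)
  expect_equal(regs[[1]]$bbox, c(1L, 1L, 6L, 6L))  # 0-based, half-open

  diag2 <- matrix(0L, 5, 5)
  diag2[2, 2] <- 1L; diag2[3, 3] <- 1L            # touch only diagonally
  expect_length(label_regions(diag2), 1L)

  blob <- matrix(0L, 30, 30)
  blob[5:14, 5:14] <- 1L                           # 100 px
  blob[25, 25] <- 1L; blob[25, 26] <- 1L; blob[26, 25] <- 1L  # 3 px speck
  expect_length(label_regions(blob, min_area_px = 10L), 1L)
  expect_length(label_regions(matrix(0L, 4, 4)), 0L)
})

test_that("region features follow the max/min extent and region-mean conventions", {
  m <- matrix(0L, 40, 40)
  m[11:20, 5:24] <- 1L   # 10 rows x 20 cols rectangle
  reg <- label_regions(m)[[1]]
  expect_equal(reg$length_px, 20L)
  expect_equal(reg$width_px, 10L)

  img <- array(0.6, c(40, 40, 3))
  reg <- extract_region_features(reg, img)
  expect_equal(unname(reg$channel_means), rep(0.6, 3))  # constant image

  # background excluded: poison non-region pixels
  img2 <- array(0, c(40, 40, 3))
  for (b in 1:3) { pl <- img2[, , b]; pl[reg$pixels] <- b / 10; img2[, , b] <- pl }
  reg2 <- extract_region_features(reg, img2)
  expect_equal(unname(reg2$channel_means), c(0.1, 0.2, 0.3))

  ell <- uavpheno:::rasterize_ellipse(201L, 201L, c(100, 100), c(20, 30), 0)$mask
  r_ell <- label_regions(ell * 1L)[[1]]
  expect_equal(r_ell$length_px, 61L)  # inclusive extent of semi-axes (20, 30)
  expect_equal(r_ell$width_px, 41L)

  reg$pixels <- integer(0)
  expect_error(extract_region_features(reg, img), "empty region")
})

test_that("physical sizes delegate to the ground scale", {
  m <- matrix(0L, 80, 80)
  m[10:70, 10:50] <- 1L  # 61 x 41 px
  reg <- label_regions(m)[[1]]
  phys <- region_to_physical(reg, ground_scale(5.2265e-3))
  expect_lt(abs(phys[["length"]] - 0.3188), 1e-4)  # 61 px * 5.2265 mm
  phys_sr <- region_to_physical(reg, ground_scale(5.2265e-3, sr_factor = 4))
  expect_equal(unname(phys_sr), unname(phys) / 4)
})

test_that("SPAD regression recovers noiseless coefficients exactly", {
  withr::with_seed(21, {
    feats <- data.frame(R = stats::runif(50), G = stats::runif(50), B = stats::runif(50))
  })
  spad <- 10 + 0.1 * feats$R + 0.2 * feats$G + 0.05 * feats$B
  fit <- fit_spad_mlr(feats, spad, mode = "RGB")
  expect_lt(abs(fit$intercept - 10), 1e-8)
  expect_lt(max(abs(fit$coefficients - c(R = 0.1, G = 0.2, B = 0.05))), 1e-8)
  expect_equal(as.numeric(predict_spad(fit, feats)), spad, tolerance = 1e-10)

  g_fit <- fit_spad_mlr(feats, spad, mode = "G_only")
  expect_length(g_fit$coefficients, 1L)
  expect_named(g_fit$coefficients, "G")
})

test_that("noisy SPAD coefficients land within sampling error of truth", {
  withr::with_seed(33, {
    n <- 200
    feats <- data.frame(R = stats::runif(n, 0.04, 0.10), G = stats::runif(n, 0.10, 0.22),
                        B = stats::runif(n, 0.03, 0.08))
    spad <- 75 - 60 * feats$R - 120 * feats$G - 40 * feats$B + stats::rnorm(n, 0, 1.5)
  })
  fit <- fit_spad_mlr(feats, spad, mode = "RGB")
  truth <- c(75, -60, -120, -40)
  est <- c(fit$intercept, fit$coefficients)
  expect_true(all(abs(est - truth) < 3 * fit$se))
})

test_that("degenerate SPAD designs are rejected with named columns", {
  feats <- data.frame(R = stats::runif(20), G = stats::runif(20))
  feats$B <- feats$G  # collinear
  spad <- stats::rnorm(20, 45)
  expect_error(fit_spad_mlr(feats, spad, mode = "RGB"), "collinear.*B")
  expect_error(fit_spad_mlr(feats[1:3, ], spad[1:3], mode = "RGB"), "at least 5")
  expect_error(fit_spad_mlr(feats[c("R", "G")], spad, mode = "RGB"), "missing feature")
  fit <- fit_spad_mlr(data.frame(G = stats::runif(20)), spad, mode = "G_only")
  expect_error(predict_spad(fit, data.frame(R = 1)), "missing feature")
})

test_that("SPAD prediction is affine and flags out-of-range values", {
  fit <- fit_spad_mlr(data.frame(R = stats::runif(10), G = stats::runif(10),
                                 B = stats::runif(10)),
                      stats::runif(10, 40, 50), mode = "RGB")
  zero <- data.frame(R = 0, G = 0, B = 0)
  expect_equal(as.numeric(predict_spad(fit, zero)), fit$intercept)
  x <- data.frame(R = 0.2, G = 0.4, B = 0.1)
  p0 <- predict_spad(fit, zero)
  expect_equal(as.numeric(predict_spad(fit, x * 3)) - as.numeric(p0),
               3 * (as.numeric(predict_spad(fit, x)) - as.numeric(p0)),
               tolerance = 1e-10)
  big <- data.frame(R = 1e4, G = 1e4, B = 1e4)
  expect_true(any(attr(predict_spad(fit, big), "out_of_range")))
})

test_that("evaluation statistics match hand-computed cases", {
  y <- c(10, 20, 30)
  r <- evaluate_predictions(y, y)
  expect_equal(c(r$r2, r$rmspe, r$rmse), c(1, 0, 0))
  r_mean <- evaluate_predictions(y, rep(mean(y), 3))
  expect_equal(r_mean$r2, 0)

  # pins the explained-variance (as-printed) form, which can exceed 1
  r3 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r3$r2, 2.5)
  expect_equal(r3$rmse, sqrt(1 / 3))
  expect_equal(r3$r2_residual, 1 - 1 / 2)
  expect_equal(r3$rmspe, sqrt(mean(c(0, 0, 1 / 3)^2)))

  expect_error(evaluate_predictions(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(evaluate_predictions(c(0, 1, 2), c(0, 1, 2)), "RMSPE undefined")
  expect_error(evaluate_predictions(1, 1), "n >= 2")
  expect_error(evaluate_predictions(1:3, 1:2), "length mismatch")
})

test_that("rmse agrees with an independent brute-force sum", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- sample(3:40, 1)
      y <- stats::runif(n, 1, 100)
      p <- y + stats::rnorm(n)
      r <- evaluate_predictions(y, p)
      acc <- 0
      for (j in seq_len(n)) acc <- acc + (y[j] - p[j])^2  # brute force
      expect_rel_equal(r$rmse, sqrt(acc / n))
    }
  })
})

test_that("greedy centroid matching handles exact, missing and tied cases", {
  truth <- data.frame(plant_id = c(4L, 9L),
                      center_row_px = c(10, 40), center_col_px = c(10, 40),
                      true_spad = c(41, 52))
  recs <- data.frame(region_id = 1:2, centroid_row = c(10, 40), centroid_col = c(10, 40))
  m <- match_to_truth(recs, truth, max_dist_px = 5)
  expect_equal(m$matched_truth_id, c(4L, 9L))
  expect_length(attr(m, "unmatched_regions"), 0L)
  expect_length(attr(m, "unmatched_truth"), 0L)

  recs2 <- rbind(recs, data.frame(region_id = 3L, centroid_row = 200, centroid_col = 200))
  m2 <- match_to_truth(recs2, truth, max_dist_px = 5)
  expect_equal(attr(m2, "unmatched_regions"), 3L)

  # two predictions equidistant from one truth: earlier reading order wins
  truth1 <- data.frame(plant_id = 1L, center_row_px = 10, center_col_px = 10)
  recs3 <- data.frame(region_id = 1:2, centroid_row = c(10, 10), centroid_col = c(7, 13))
  m3 <- match_to_truth(recs3, truth1, max_dist_px = 5)
  expect_equal(m3$matched_truth_id, c(1L, NA_integer_))
})

test_that("perfect instance masks recover every plant's size through the pipeline", {
  sc <- generate_scene(tiny_scene_config(seed = 12L))
  scale <- ground_scale(sc$gsd)
  recs <- extract_traits(sc$instance_mask, sc$image, scale, mode = "instance")
  m <- match_to_truth(recs, sc$truth, max_dist_px = 30)
  matched <- m[!is.na(m$matched_truth_id), ]
  expect_equal(nrow(matched), nrow(sc$truth))
  expect_true(all(abs(matched$pred_length_m - matched$true_length_m) <= sc$gsd + 1e-12))
  expect_true(all(abs(matched$pred_width_m - matched$true_width_m) <= sc$gsd + 1e-12))
})

test_that("a zero generating coefficient shows no spurious signal", {
  # bB = 0: the fitted B slope should be statistically null in >= 95% of fits
  hits <- vapply(1:100, function(k) {
    withr::with_seed(500 + k, {
      n <- 60
      feats <- data.frame(R = stats::runif(n, 0.04, 0.10),
                          G = stats::runif(n, 0.10, 0.22),
                          B = stats::runif(n, 0.03, 0.08))
      spad <- 75 - 60 * feats$R - 120 * feats$G + stats::rnorm(n, 0, 1.5)
    })
    fit <- fit_spad_mlr(feats, spad, mode = "RGB")
    abs(fit$coefficients[["B"]] / fit$se[["B"]]) < 3
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
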