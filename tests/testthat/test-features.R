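# brute-force per-pixel oracle for the color statistics
color_stats_oracle <- function(px, mask) {
  idx <- which(mask)
  r <- px[, , 1][idx]; g <- px[, , 2][idx]; b <- px[, , 3][idx]
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  hsv <- t(sapply(seq_along(r), function(i) {
    as.vector(grDevices::rgb2hsv(r[i], g[i], b[i], maxColorValue = 255))
  }))
  th <- 2 * pi * hsv[, 1]
  C <- mean(cos(th)); S <- mean(sin(th)); R <- min(1, sqrt(C^2 + S^2))
  c(mean(r), mean(g), mean(b), psd(r), psd(g), psd(b),
    (atan2(S, C) / (2 * pi)) %% 1, mean(hsv[, 2]), mean(hsv[, 3]),
    if (R >= 1) 0 else sqrt(-2 * log(R)) / (2 * pi), psd(hsv[, 2]), psd(hsv[, 3]))
}

solid_image <- function(H, W, rgb) {
  px <- array(0L, c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  px
}

test_that("color statistics match hand arithmetic and closed forms", {
  # constant-color ROI: every spread statistic is zero
  px <- solid_image(10, 10, c(120, 60, 30))
  cs <- color_stats(px, matrix(TRUE, 10, 10))
  expect_equal(unname(cs[c("StdRed", "StdGreen", "StdBlue",
                           "StdHue", "StdSaturation", "StdValue")]),
               rep(0, 6), tolerance = 1e-12)
  # two pixels R = 100, 200: mean 150, population std 50
  px2 <- solid_image(1, 2, c(0, 0, 0))
  px2[1, 1, 1] <- 100L; px2[1, 2, 1] <- 200L
  cs2 <- color_stats(px2, matrix(TRUE, 1, 2))
  expect_equal(unname(cs2["MeanRed"]), 150)
  expect_equal(unname(cs2["StdRed"]), 50)
  # pure red: S = V = 1, hue 0
  cs3 <- color_stats(solid_image(4, 4, c(255, 0, 0)), matrix(TRUE, 4, 4))
  expect_equal(unname(cs3["MeanSaturation"]), 1)
  expect_equal(unname(cs3["MeanValue"]), 1)
  expect_equal(unname(cs3["MeanHue"]), 0)
  expect_error(color_stats(px, matrix(FALSE, 10, 10)), "empty")
})

test_that("color statistics equal the brute-force oracle", {
  set.seed(77)
  px <- array(sample(0:255, 12 * 15 * 3, replace = TRUE), c(12, 15, 3))
  mask <- matrix(runif(12 * 15) < 0.6, 12, 15)
  expect_equal(unname(color_stats(px, mask)), color_stats_oracle(px, mask),
               tolerance = 1e-9)
})

test_that("hue statistics respect the circular wrap", {
  # hues straddling 0: pure red-ish at h ~ 0.99 and h ~ 0.01
  px <- array(0L, c(1, 2, 3))
  px[1, 1, ] <- c(255L, 0L, 15L)   # h just below 1
  px[1, 2, ] <- c(255L, 15L, 0L)   # h just above 0
  cs <- color_stats(px, matrix(TRUE, 1, 2))
  expect_lt(min(cs[["MeanHue"]], 1 - cs[["MeanHue"]]), 0.02)
  expect_lt(cs[["StdHue"]], 0.02)  # naive sd of {0.01, 0.99} would be ~0.49
})

test_that("pixel factors count the rectangle and the dark pixels", {
  px <- solid_image(30, 40, c(200, 200, 200))
  mask <- matrix(FALSE, 30, 40); mask[6:15, 11:30] <- TRUE
  pf <- pixel_features(px, mask)
  expect_equal(unname(pf["RectArea"]), 200)  # 10 x 20 block
  expect_equal(unname(pf["DarkArea"]), 0)
  set.seed(3)
  dark_at <- sample(which(mask), 17)
  for (ch in 1:3) { p <- px[, , ch]; p[dark_at] <- 5L; px[, , ch] <- p }
  expect_equal(unname(pixel_features(px, mask)["DarkArea"]), 17)
  # monotone in the threshold
  d1 <- pixel_features(px, mask, dark_v_threshold = 0.1)["DarkArea"]
  d2 <- pixel_features(px, mask, dark_v_threshold = 0.5)["DarkArea"]
  expect_lte(unname(d1), unname(d2))
})

test_that("4-bin histograms match direct binning and sum to one", {
  px <- solid_image(1, 4, c(0, 0, 0))
  px[1, , 1] <- c(10L, 70L, 150L, 250L)
  h <- rgb_histogram_4bin(px, matrix(TRUE, 1, 4))
  expect_equal(unname(h[paste0("Red_Bin", 1:4)]), rep(0.25, 4))
  expect_equal(unname(h[paste0("Green_Bin", 1:4)]), c(1, 0, 0, 0))
  # random ROI against an independent counting oracle
  set.seed(41)
  px2 <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  mask <- matrix(runif(400) < 0.5, 20, 20)
  h2 <- rgb_histogram_4bin(px2, mask)
  for (ch in 1:3) {
    vals <- px2[, , ch][mask]
    oracle <- vapply(0:3, function(b) mean(vals >= 64 * b & vals <= 64 * b + 63), 0)
    got <- unname(h2[paste0(c("Red", "Green", "Blue")[ch], "_Bin", 1:4)])
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("histograms are invariant to pixel order", {
  set.seed(9)
  px <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), c(10, 10, 3))
  mask <- matrix(TRUE, 10, 10)
  h1 <- rgb_histogram_4bin(px, mask)
  perm <- sample(100)
  px_sh <- px
  for (ch in 1:3) px_sh[, , ch] <- matrix(px[, , ch][perm], 10, 10)
  expect_equal(rgb_histogram_4bin(px_sh, mask), h1)
})

test_that("feature vectors have the frozen cardinality and order", {
  img <- test_corpus(3, seed = 13)$images[[1]]
  seg <- segment(img, "threshold")
  f1 <- extract_features(img, seg, "L1")
  f2 <- extract_features(img, seg, "L2")
  expect_length(f1, 14)
  expect_length(f2, 38)
  expect_identical(names(f1), daqu_feature_names("L1"))
  expect_identical(names(f2), daqu_feature_names("L2"))
  # the histogram block of the layer-2 vector holds 24 values
  expect_length(grep("_Bin", names(f2)), 24)
  # degenerate segmentation is rejected with a diagnostic
  blank <- daqugrade:::new_segmentation_result(
    matrix(FALSE, 200, 300), "threshold", seg_params(), degenerate = TRUE)
  expect_error(extract_features(img, blank, "L1"), "degenerate")
})

test_that("feature order survives CSV serialization", {
  ds <- test_corpus(3, seed = 13)
  tab <- build_feature_table(ds, "L1", method = "threshold")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(daqugrade:::ft_feature_names(back), daqu_feature_names("L1"))
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("weighted data-point accounting matches the two-layer scheme", {
  ds <- test_corpus(10, seed = 7)
  l1 <- build_feature_table(ds, "L1", method = "threshold")
  pts1 <- feature_points(l1)
  # 20 images at weight 1 and 14 factors vs 10 images at weight 2
  expect_equal(pts1$data_points[pts1$label == "PF"], 20 * 1 * 14)
  expect_equal(pts1$data_points[pts1$label == "S"], 10 * 2 * 14)
  l2 <- build_feature_table(ds, "L2", method = "threshold")
  pts2 <- feature_points(l2)
  expect_equal(sort(pts2$data_points), c(10 * 38, 10 * 38))
  expect_equal(nrow(l2), 20)  # only P and F images enter the layer-2 task
  # empty weight map defaults to unit weights in the layer-2 task
  expect_true(all(l2$weight == 1))
})
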