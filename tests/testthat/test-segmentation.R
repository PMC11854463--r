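test_that("grayscale conversion follows the luma formula", {
  px <- array(0L, c(1, 3, 3))
  px[1, 1, ] <- c(255L, 255L, 255L)
  px[1, 2, ] <- c(255L, 0L, 0L)
  px[1, 3, ] <- c(17L, 17L, 17L)
  g <- to_grayscale(px)
  expect_equal(g[1, 1], 255)
  expect_equal(g[1, 2], 76)   # round(0.299 * 255)
  expect_equal(g[1, 3], 17)   # gray input maps to itself
  expect_error(to_grayscale(matrix(0, 3, 3)), "3")
})

test_that("Otsu threshold equals the exhaustive-scan oracle", {
  set.seed(101)
  for (rep in 1:8) {
    gray <- matrix(sample(0:255, 64 * 64, replace = TRUE,
                          prob = runif(256)^2), 64, 64)
    expect_identical(otsu_threshold(gray)$threshold, otsu_oracle(gray))
  }
  # bimodal raster with a threshold plateau: tie broken at the smallest t
  gray <- matrix(c(10, 10, 200, 200), 2, 2)
  ot <- otsu_threshold(gray)
  expect_identical(ot$threshold, 10L)
  expect_equal(sum(ot$mask), 2)  # the dark pair is foreground
})

test_that("constant image is flagged degenerate with empty mask", {
  ot <- otsu_threshold(matrix(42, 10, 10))
  expect_true(ot$degenerate)
  expect_identical(ot$threshold, 42L)
  expect_false(any(ot$mask))
})

test_that("k-means recovers disjoint constant-color blobs", {
  px <- array(0L, c(30, 60, 3))
  px[, 1:20, 1] <- 200L                     # red blob
  px[, 21:40, 2] <- 200L                    # green blob
  px[, 41:60, 3] <- 200L                    # blue blob
  res <- kmeans_segment(px, seg_params(k = 3, seed = 4))
  lab <- matrix(0L, 30, 60)
  # reconstruct cluster ids from the fitted centers
  X <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  d <- sapply(1:3, function(j) colSums((t(X) - res$centers[j, ])^2))
  assign <- max.col(-d)
  truth <- rep(1:3, each = 20)[col(matrix(0, 30, 60))]
  expect_equal(length(unique(paste(assign, truth))), 3)  # label permutation
})

test_that("k-means objective is non-increasing across Lloyd iterations", {
  ds <- test_corpus(3, seed = 13)
  res <- kmeans_segment(ds$images[[1]], seg_params(k = 3, seed = 2))
  expect_true(all(diff(res$wss_trace) <= 1e-6))
  expect_equal(nrow(res$centers), 3)
})

test_that("k-means matches the stats::kmeans fixed point on its own centers", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 10), 30))
  ref <- kmeans(X, centers = 2, algorithm = "Lloyd", nstart = 5)
  fit <- daqugrade:::lloyd_kmeans(X, ref$centers, max_iter = 20, tol = 1e-8)
  # starting at the converged centers, one pass leaves them unchanged
  expect_equal(fit$centers, ref$centers, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sort(fit$wss_trace)[1], ref$tot.withinss, tolerance = 1e-6)
})

test_that("k > distinct colors is rejected", {
  px <- array(100L, c(20, 20, 3))
  expect_error(kmeans_segment(px, seg_params(k = 3)), "distinct")
})

test_that("morphological fusion closes gaps and bounds the disk area", {
  H <- 120; W <- 120
  px <- array(230L, c(H, W, 3))
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  r <- 40
  ring <- abs(sqrt((rr - 60)^2 + (cc - 60)^2) - r) < 1.2
  ring[58:62, ] <- ring[58:62, ] & (cc[58:62, ] < 95)  # cut gaps < 2 * radius
  for (ch in 1:3) { p <- px[, , ch]; p[ring] <- 30L; px[, , ch] <- p }
  sp <- seg_params(dilation_radius = 4, min_object_px = 30)
  res <- morph_fusion_segment(px, sp)
  disk_area <- sum((rr - 60)^2 + (cc - 60)^2 <= r^2)
  # slack: dilation radius + ring half-width + Gaussian smoothing spread
  dilated_area <- sum((rr - 60)^2 + (cc - 60)^2 <= (r + sp$dilation_radius + 5)^2)
  expect_false(res$degenerate)
  expect_gte(sum(res$mask), disk_area * 0.9)
  expect_lte(sum(res$mask), dilated_area)
})

test_that("specks below min_object_px never survive morphological fusion", {
  H <- 150; W <- 150
  px <- array(230L, c(H, W, 3))
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  disk <- (rr - 75)^2 + (cc - 75)^2 <= 35^2
  for (ch in 1:3) { p <- px[, , ch]; p[disk] <- 60L; px[, , ch] <- p }
  base <- morph_fusion_segment(px, seg_params(min_object_px = 400))
  set.seed(8)
  px_speck <- px
  for (k in 1:10) {  # isolated 2x2 specks far from the disk, below min_object_px
    at_r <- 5 + (k %% 3); at_c <- 8 + 13 * (k - 1)
    for (ch in 1:3) px_speck[at_r + 0:1, at_c + 0:1, ch] <- 10L
  }
  speck <- morph_fusion_segment(px_speck, seg_params(min_object_px = 400))
  lab <- EBImage::bwlabel(speck$mask * 1)   # independent component count
  expect_equal(max(lab), 1)
  expect_equal(sum(speck$mask), sum(base$mask))
})

test_that("blank image yields an empty degenerate fusion mask", {
  px <- array(128L, c(60, 60, 3))
  res <- morph_fusion_segment(px)
  expect_true(res$degenerate)
  expect_false(any(res$mask))
})

test_that("dispatcher records the method and is deterministic", {
  img <- test_corpus(3, seed = 13)$images[[2]]
  expect_error(segment(img, "watershed"), "arg")
  for (m in c("threshold", "kmeans", "morph_fusion")) {
    a <- segment(img, m)
    b <- segment(img, m)
    expect_identical(a$method, m)
    expect_identical(a$mask, b$mask)
    expect_true(is.logical(a$mask))
    expect_identical(dim(a$mask), dim(img$pixels)[1:2])
  }
})

test_that("all three methods overlap the true block at Jaccard >= 0.5", {
  img <- generate_daqu_image("P", test_params(), seed = 21)
  for (m in c("threshold", "kmeans", "morph_fusion")) {
    seg <- segment(img, m, seg_params(seed = 3))
    jac <- sum(seg$mask & img$truth$block) / sum(seg$mask | img$truth$block)
    expect_gte(jac, 0.5)
  }
})
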