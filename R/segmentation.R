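#' Segmentation parameters
#'
#' Free parameters of the three block-segmentation back-ends. Canny hysteresis
#' thresholds are expressed as fractions of the maximum gradient magnitude;
#' the dilation structuring element is a disc. Defaults are tuned for the
#' 400 x 600 working size.
#'
#' @param canny_low,canny_high hysteresis thresholds as fractions of the
#'   maximum gradient magnitude, `0 < low < high < 1`.
#' @param canny_sigma Gaussian pre-smoothing sigma in pixels.
#' @param dilation_radius disc radius (px) used to connect broken edges.
#' @param min_object_px connected components smaller than this are removed.
#' @param k number of k-means color clusters ("three initial data points").
#' @param kmeans_max_iter,kmeans_tol Lloyd iteration budget and center-movement
#'   convergence tolerance (RGB units).
#' @param palette_prior RGB triplet of a typical block color; k-means clusters
#'   whose center is closer to this than to the border-sampled background
#'   color are labelled foreground.
#' @param seed integer seed for the k-means++ initialization.
#'
#' @return A list of class `"seg_params"`.
#' @export
seg_params <- function(canny_low = 0.1, canny_high = 0.3, canny_sigma = 1.4,
                       dilation_radius = 5, min_object_px = 64,
                       k = 3, kmeans_max_iter = 50, kmeans_tol = 1e-3,
                       palette_prior = c(160, 150, 140), seed = 0L) {
  if (!(canny_low > 0 && canny_low < canny_high && canny_high < 1)) {
    abort("need 0 < canny_low < canny_high < 1")
  }
  if (dilation_radius < 1) abort("`dilation_radius` must be >= 1")
  if (k < 1) abort("`k` must be >= 1")
  structure(list(canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma, dilation_radius = dilation_radius,
                 min_object_px = min_object_px, k = as.integer(k),
                 kmeans_max_iter = kmeans_max_iter, kmeans_tol = kmeans_tol,
                 palette_prior = palette_prior, seed = as.integer(seed)),
            class = "seg_params")
}

get_pixels <- function(image) {
  if (inherits(image, "daqu_image")) image$pixels else image
}

#' Convert an RGB raster to 8-bit grayscale luma
#'
#' `round(0.299 R + 0.587 G + 0.114 B)`, clipped to `[0, 255]`.
#'
#' @param image H x W x 3 array (0-255) or a `daqu_image`.
#' @return H x W numeric matrix with values in 0-255.
#' @export
to_grayscale <- function(image) {
  px <- get_pixels(image)
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    abort("`image` must be an H x W x 3 raster")
  }
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  matrix(pmin(pmax(round(g), 0), 255), dim(px)[1], dim(px)[2])
}

#' Otsu adaptive threshold
#'
#' Scans all 256 candidate thresholds and picks the one maximizing the
#' between-class variance of the two gray-level classes (smallest maximizer on
#' ties). Foreground polarity is resolved afterwards: the class whose mean
#' gray level lies farther from the mean of the image border (assumed
#' background) is labelled foreground, so a dark block on a bright background
#' comes out as foreground.
#'
#' @param gray H x W matrix with values in 0-255.
#' @return List with `threshold` (integer), `mask` (logical matrix, TRUE =
#'   foreground) and `degenerate` (TRUE for a constant image, whose mask is
#'   empty).
#' @export
otsu_threshold <- function(gray) {
  if (any(gray < 0 | gray > 255)) abort("gray values must lie in [0, 255]")
  g <- as.integer(round(gray))
  n <- length(g)
  counts <- tabulate(g + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) {
    return(list(threshold = as.integer(g[1]),
                mask = matrix(FALSE, nrow(gray), ncol(gray)),
                degenerate = TRUE))
  }
  p <- counts / n
  levels <- 0:255
  omega <- cumsum(p)                    # P(class0) for t = 0..255, class0 = {<= t}
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # between-class variance for threshold t (class0: <= t, class1: > t)
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_star <- levels[which.max(sigma_b)]  # which.max takes the first (smallest) maximizer
  low <- gray <= t_star

  border <- c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)])
  m_border <- mean(border)
  m_low <- mean(gray[low]); m_high <- mean(gray[!low])
  fg_is_low <- abs(m_low - m_border) >= abs(m_high - m_border)
  mask <- if (fg_is_low) low else !low
  list(threshold = as.integer(t_star), mask = mask, degenerate = FALSE)
}

# seeded k-means++ initialization on an n x 3 matrix
kmeanspp_init <- function(X, k, seed) {
  set.seed(seed)
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- d2 / sum(d2)
      if (!all(is.finite(prob)) || sum(d2) == 0) {
        idx <- sample.int(n, 1)
      } else {
        idx <- sample.int(n, 1, prob = prob)
      }
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  centers
}

# Lloyd iterations; returns assignment, centers and the per-iteration
# within-cluster sum of squares trace (used by the monotonicity property)
lloyd_kmeans <- function(X, centers, max_iter, tol) {
  k <- nrow(centers)
  n <- nrow(X)
  wss_trace <- numeric(0)
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j) {
      rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    })
    assign <- max.col(-d2, ties.method = "first")
    wss_trace <- c(wss_trace, sum(d2[cbind(seq_len(n), assign)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      if (any(assign == j)) new_centers[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
    movement <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (movement < tol) break
  }
  list(assignment = assign, centers = centers, wss_trace = wss_trace)
}

#' K-means color-clustering segmentation
#'
#' Runs seeded k-means++ initialization followed by Lloyd iterations on the
#' per-pixel RGB vectors, then labels as foreground every cluster whose center
#' is closer (Euclidean in RGB) to the block palette prior than to the
#' background color sampled from the image border.
#'
#' @param image H x W x 3 raster or `daqu_image`.
#' @param params a [seg_params()] list.
#' @return A `segmentation_result`: list with `mask`, `method = "kmeans"`,
#'   `centers` (k x 3), `wss_trace`, `degenerate`, `params_used`.
#' @export
kmeans_segment <- function(image, params = seg_params()) {
  px <- get_pixels(image)
  H <- dim(px)[1]; W <- dim(px)[2]
  X <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  n_distinct <- nrow(unique(X))
  if (params$k > n_distinct) {
    abort("`k` exceeds the number of distinct pixel colors")
  }
  centers0 <- kmeanspp_init(X, params$k, params$seed)
  fit <- lloyd_kmeans(X, centers0, params$kmeans_max_iter, params$kmeans_tol)

  border <- border_mask(H, W, 5)
  bg_color <- colMeans(X[as.vector(border), , drop = FALSE])
  d_prior <- sqrt(rowSums((fit$centers -
    matrix(params$palette_prior, params$k, 3, byrow = TRUE))^2))
  d_bg <- sqrt(rowSums((fit$centers - matrix(bg_color, params$k, 3, byrow = TRUE))^2))
  fg_clusters <- which(d_prior < d_bg)
  mask <- matrix(fit$assignment %in% fg_clusters, H, W)

  new_segmentation_result(mask, "kmeans", params,
                          centers = fit$centers, wss_trace = fit$wss_trace,
                          degenerate = length(fg_clusters) == 0)
}

border_mask <- function(H, W, width) {
  m <- matrix(FALSE, H, W)
  m[seq_len(width), ] <- TRUE; m[H - seq_len(width) + 1, ] <- TRUE
  m[, seq_len(width)] <- TRUE; m[, W - seq_len(width) + 1] <- TRUE
  m
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression, hysteresis with thresholds given as fractions of max magnitude.
canny_edges <- function(gray, low_frac, high_frac, sigma = 1.4) {
  g <- EBImage::gblur(gray / 255, sigma = sigma)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(g, sx)
  gy <- EBImage::filter2(g, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))

  H <- nrow(g); W <- ncol(g)
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  ang <- atan2(gy, gx)  # quantize direction to 0/45/90/135 degrees
  a <- ((round(ang / (pi / 4)) %% 4) + 4) %% 4
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (q in 0:3) {
    o <- offs[[as.character(q)]]
    sel <- a == q
    n1[sel] <- shift(mag, o[1], o[2])[sel]
    n2[sel] <- shift(mag, -o[1], -o[2])[sel]
  }
  nms <- mag >= n1 & mag >= n2

  m_max <- max(mag)
  strong <- nms & mag >= high_frac * m_max
  weak <- nms & mag >= low_frac * m_max
  if (!any(strong)) return(matrix(FALSE, H, W))
  lab <- EBImage::bwlabel(weak * 1)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, H, W)
}

#' Morphological fusion segmentation
#'
#' Canny edge detection on the grayscale image, disc dilation to connect
#' broken edges, hole filling via the complement of the border-connected
#' background, removal of connected components below `min_object_px`, and
#' retention of the largest remaining component.
#'
#' @inheritParams kmeans_segment
#' @return A `segmentation_result` with `method = "morph_fusion"`; a blank
#'   image (no edges) yields an empty mask flagged `degenerate`.
#' @export
morph_fusion_segment <- function(image, params = seg_params()) {
  px <- get_pixels(image)
  gray <- to_grayscale(px)
  edges <- canny_edges(gray, params$canny_low, params$canny_high, params$canny_sigma)
  if (!any(edges)) {
    return(new_segmentation_result(matrix(FALSE, nrow(gray), ncol(gray)),
                                   "morph_fusion", params, degenerate = TRUE))
  }
  brush <- EBImage::makeBrush(2 * round(params$dilation_radius) + 1, "disc")
  dil <- EBImage::dilate(edges * 1, brush)
  filled <- EBImage::fillHull(dil) > 0.5
  lab <- EBImage::bwlabel(filled * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_object_px)
  if (length(keep) == 0) {
    return(new_segmentation_result(matrix(FALSE, nrow(gray), ncol(gray)),
                                   "morph_fusion", params, degenerate = TRUE))
  }
  largest <- keep[which.max(sizes[keep])]
  mask <- lab == largest
  new_segmentation_result(mask, "morph_fusion", params, degenerate = FALSE)
}

#' Threshold (Otsu) segmentation
#'
#' Grayscale conversion followed by [otsu_threshold()]; the largest foreground
#' connected component is retained so stray debris does not enter the block
#' mask.
#'
#' @inheritParams kmeans_segment
#' @return A `segmentation_result` with `method = "threshold"` and the chosen
#'   `threshold`.
#' @export
threshold_segment <- function(image, params = seg_params()) {
  gray <- to_grayscale(get_pixels(image))
  ot <- otsu_threshold(gray)
  mask <- ot$mask
  if (!ot$degenerate && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
    mask <- EBImage::fillHull(mask * 1) > 0.5
  }
  new_segmentation_result(mask, "threshold", params,
                          threshold = ot$threshold, degenerate = ot$degenerate)
}

new_segmentation_result <- function(mask, method, params, threshold = NULL,
                                    centers = NULL, wss_trace = NULL,
                                    degenerate = FALSE) {
  stopifnot(is.logical(mask))
  structure(list(mask = mask, method = method, threshold = threshold,
                 centers = centers, wss_trace = wss_trace,
                 degenerate = degenerate, params_used = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method %s, %d x %d, %d fg px%s\n",
              x$method, nrow(x$mask), ncol(x$mask), sum(x$mask),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Segment a Daqu image with one of the three back-ends
#'
#' Dispatcher over [threshold_segment()], [kmeans_segment()] and
#' [morph_fusion_segment()].
#'
#' @inheritParams kmeans_segment
#' @param method one of `"threshold"`, `"kmeans"`, `"morph_fusion"`.
#' @return A `segmentation_result`.
#' @export
#' @examples
#' img <- generate_daqu_image("P", gen_params(image_size = c(200, 300)), seed = 1)
#' seg <- segment(img, "threshold")
#' seg$method
segment <- function(image, method = c("morph_fusion", "threshold", "kmeans"),
                    params = seg_params()) {
  method <- match.arg(method)
  switch(method,
         threshold = threshold_segment(image, params),
         kmeans = kmeans_segment(image, params),
         morph_fusion = morph_fusion_segment(image, params))
}
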