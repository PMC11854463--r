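#' Frozen feature-factor names
#'
#' The 14 layer-1 factors are six RGB statistics, six HSV statistics and two
#' pixel factors; the 38 layer-2 factors append 4-bin RGB histograms (12
#' proportions per region) for the center and Pizhang regions of interest.
#' The order is frozen: models and selectors bind features by this order.
#'
#' @param layer `"L1"` or `"L2"`.
#' @return Character vector of length 14 (`L1`) or 38 (`L2`).
#' @export
daqu_feature_names <- function(layer = c("L1", "L2")) {
  layer <- match.arg(layer)
  base <- c("MeanRed", "MeanGreen", "MeanBlue", "StdRed", "StdGreen", "StdBlue",
            "MeanHue", "MeanSaturation", "MeanValue",
            "StdHue", "StdSaturation", "StdValue",
            "RectArea", "DarkArea")
  if (layer == "L1") return(base)
  bins <- as.vector(t(outer(c("Red", "Green", "Blue"), 1:4,
                            function(ch, b) paste0(ch, "_Bin", b))))
  c(base, paste0("Center_", bins), paste0("Pizhang_", bins))
}

masked_channels <- function(image, roi_mask) {
  px <- get_pixels(image)
  if (!any(roi_mask)) abort("ROI mask is empty")
  list(r = px[, , 1][roi_mask], g = px[, , 2][roi_mask], b = px[, , 3][roi_mask])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Color statistics over a region of interest
#'
#' Means and population standard deviations of the RGB channels (0-255 scale)
#' and of the HSV channels (normalized to `[0, 1]`). Hue is treated as a
#' circular quantity: the mean is the direction of the resultant unit vector
#' and the spread is the circular standard deviation
#' `sqrt(-2 log R)` mapped back to the `[0, 1]` hue scale, so a constant-hue
#' region scores exactly 0.
#'
#' @param image H x W x 3 raster (0-255) or `daqu_image`.
#' @param roi_mask logical matrix selecting the ROI pixels (non-empty).
#' @return Named numeric vector of length 12 (`MeanRed` ... `StdValue`).
#' @export
color_stats <- function(image, roi_mask) {
  ch <- masked_channels(image, roi_mask)
  hsv <- grDevices::rgb2hsv(rbind(ch$r, ch$g, ch$b), maxColorValue = 255)
  theta <- 2 * pi * hsv[1, ]
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- min(1, sqrt(C^2 + S^2))
  mean_hue <- (atan2(S, C) / (2 * pi)) %% 1
  std_hue <- if (R >= 1 - 1e-12) 0 else sqrt(-2 * log(R)) / (2 * pi)
  c(MeanRed = mean(ch$r), MeanGreen = mean(ch$g), MeanBlue = mean(ch$b),
    StdRed = pop_sd(ch$r), StdGreen = pop_sd(ch$g), StdBlue = pop_sd(ch$b),
    MeanHue = mean_hue, MeanSaturation = mean(hsv[2, ]), MeanValue = mean(hsv[3, ]),
    StdHue = std_hue, StdSaturation = pop_sd(hsv[2, ]), StdValue = pop_sd(hsv[3, ]))
}

#' Pixel factors: bounding-rectangle area and dark-pixel count
#'
#' `RectArea` is the area in pixels of the minimum bounding rectangle of the
#' block mask. `DarkArea` counts foreground pixels whose HSV value channel
#' falls below `dark_v_threshold` — the dark cracks, rings and edge patches
#' that mark lower grades.
#'
#' @param image raster or `daqu_image`.
#' @param mask logical block mask (non-empty).
#' @param dark_v_threshold value-channel cutoff defining "dark" (default 0.25).
#' @return Named numeric vector `c(RectArea, DarkArea)`.
#' @export
pixel_features <- function(image, mask, dark_v_threshold = 0.25) {
  if (!any(mask)) abort("`mask` is empty")
  rect <- min_bounding_rect(mask)
  px <- get_pixels(image)
  v <- pmax(px[, , 1][mask], px[, , 2][mask], px[, , 3][mask]) / 255
  c(RectArea = as.numeric(rect["height"]) * as.numeric(rect["width"]),
    DarkArea = sum(v < dark_v_threshold))
}

#' 4-bin RGB histogram over a region of interest
#'
#' Per channel, the proportion of ROI pixels in each of the four fixed bins
#' (0-63, 64-127, 128-191, 192-255); the four proportions of a channel sum
#' to 1.
#'
#' @inheritParams color_stats
#' @return Named numeric vector of length 12
#'   (`Red_Bin1` ... `Blue_Bin4`).
#' @export
rgb_histogram_4bin <- function(image, roi_mask) {
  ch <- masked_channels(image, roi_mask)
  one <- function(x, name) {
    bins <- pmin(x %/% 64L, 3L) + 1L
    p <- tabulate(bins, nbins = 4) / length(x)
    setNames(p, paste0(name, "_Bin", 1:4))
  }
  c(one(ch$r, "Red"), one(ch$g, "Green"), one(ch$b, "Blue"))
}

#' Extract the layer-1 or layer-2 feature vector from a segmented image
#'
#' Layer 1 yields the 14 base factors: color statistics over the layer-1
#' center ROI plus `RectArea`/`DarkArea` computed on the whole block mask.
#' Layer 2 yields 38 factors: the same 14 at the layer-2 center-ROI geometry
#' plus 4-bin RGB histograms over the center ROI and over the Pizhang ROI
#' (24 histogram proportions).
#'
#' @param image raster or `daqu_image`.
#' @param seg_result a `segmentation_result` (non-degenerate).
#' @param layer `"L1"` or `"L2"`.
#' @param dark_v_threshold cutoff passed to [pixel_features()].
#' @param scale ROI scale passed to [roi_partition()] (default derived from
#'   the image size).
#' @return Named numeric vector of length 14 (`L1`) or 38 (`L2`) in the frozen
#'   [daqu_feature_names()] order, with attribute `layer`.
#' @export
extract_features <- function(image, seg_result, layer = c("L1", "L2"),
                             dark_v_threshold = 0.25, scale = NULL) {
  layer <- match.arg(layer)
  if (!inherits(seg_result, "segmentation_result")) {
    abort("`seg_result` must be a segmentation_result")
  }
  if (seg_result$degenerate || !any(seg_result$mask)) {
    abort(paste0("segmentation is degenerate (method ", seg_result$method,
                 "): no foreground to extract features from"))
  }
  part <- roi_partition(seg_result$mask, layer, scale)
  roi <- if (any(part$center_mask)) part$center_mask else seg_result$mask
  vals <- c(color_stats(image, roi),
            pixel_features(image, seg_result$mask, dark_v_threshold))
  if (layer == "L2") {
    piz <- if (part$pizhang_empty) part$center_mask else part$pizhang_mask
    hist_c <- rgb_histogram_4bin(image, roi)
    hist_p <- rgb_histogram_4bin(image, piz)
    vals <- c(vals, setNames(hist_c, paste0("Center_", names(hist_c))),
              setNames(hist_p, paste0("Pizhang_", names(hist_p))))
  }
  stopifnot(identical(names(vals), daqu_feature_names(layer)))
  attr(vals, "layer") <- layer
  vals
}

#' Build the classification feature table for one layer's task
#'
#' Segments every image, extracts the layer's feature vector and assembles a
#' tidy table: one row per image with columns `id`, `grade`, `label`,
#' `weight`, then the features in frozen order. Tasks follow the two-layer
#' scheme: the layer-1 task pools premium and first grade against second
#' grade (`"PF_vs_S"`, positive class `PF`); the layer-2 task uses only
#' premium and first-grade images (`"P_vs_F"`, positive class `P`).
#'
#' Default layer-1 weights are 1 for grades P and F and 2 for grade S, so the
#' two sides of the task carry equal weighted data-point mass (see
#' [feature_points()]).
#'
#' @param dataset a `daqu_dataset` or list with `images` and `manifest`.
#' @param layer `"L1"` or `"L2"`.
#' @param task `"PF_vs_S"` or `"P_vs_F"`; defaults to the layer's own task.
#' @param weight_map named per-grade weights; `NULL` uses the defaults above.
#' @param method,params segmentation back-end and its [seg_params()].
#' @param dark_v_threshold,scale forwarded to [extract_features()].
#' @return A tibble of class `"feature_table"` with attributes `layer` and
#'   `task`.
#' @export
build_feature_table <- function(dataset, layer = c("L1", "L2"), task = NULL,
                                weight_map = NULL,
                                method = "morph_fusion", params = seg_params(),
                                dark_v_threshold = 0.25, scale = NULL) {
  layer <- match.arg(layer)
  if (is.null(task)) task <- if (layer == "L1") "PF_vs_S" else "P_vs_F"
  if (!task %in% c("PF_vs_S", "P_vs_F")) abort("unknown task")
  manifest <- dataset$manifest
  keep <- if (task == "P_vs_F") manifest$grade %in% c("P", "F") else rep(TRUE, nrow(manifest))
  manifest <- manifest[keep, , drop = FALSE]
  images <- dataset$images[keep]

  if (is.null(weight_map)) {
    weight_map <- if (task == "PF_vs_S") c(P = 1, F = 1, S = 2) else c(P = 1, F = 1, S = 1)
  }
  if (any(is.na(weight_map[unique(manifest$grade)]))) {
    abort("`weight_map` must cover every grade present")
  }

  segs <- attr(dataset, "segmentations")
  feats <- purrr::map2(images, manifest$id, function(img, id) {
    seg <- segs[[id]] %||% segment(img, method, params)
    extract_features(img, seg, layer, dark_v_threshold, scale)
  })
  mat <- do.call(rbind, feats)
  label <- if (task == "PF_vs_S") {
    ifelse(manifest$grade == "S", "S", "PF")
  } else {
    manifest$grade
  }
  out <- dplyr::bind_cols(
    tibble(id = manifest$id, grade = manifest$grade,
           label = label, weight = unname(weight_map[manifest$grade])),
    as_tibble(mat)
  )
  new_feature_table(out, layer, task)
}

new_feature_table <- function(df, layer, task) {
  stopifnot(all(c("label", "weight") %in% names(df)))
  if (anyNA(df)) abort("feature table contains missing values")
  structure(df, class = c("feature_table", class(tibble())),
            layer = layer, task = task)
}

#' Assemble a feature table from a plain feature data frame
#'
#' Convenience constructor used when features come from elsewhere (e.g. the
#' planted-feature tables used to validate the selectors).
#'
#' @param features data frame or matrix of feature columns.
#' @param labels vector of class labels (binary tasks use the first sorted
#'   level as positive unless stated otherwise downstream).
#' @param weights positive sample weights (default all 1).
#' @param layer,task metadata tags.
#' @return A `feature_table` tibble.
#' @export
feature_table <- function(features, labels, weights = NULL,
                          layer = "L2", task = "P_vs_F") {
  features <- as_tibble(as.data.frame(features))
  n <- nrow(features)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(labels) != n || length(weights) != n) {
    abort("`labels` and `weights` must match the number of rows")
  }
  if (any(weights <= 0)) abort("`weights` must be positive")
  out <- dplyr::bind_cols(
    tibble(id = sprintf("row_%04d", seq_len(n)),
           grade = as.character(labels),
           label = as.character(labels), weight = weights),
    features
  )
  new_feature_table(out, layer, task)
}

ft_meta_cols <- c("id", "grade", "label", "weight")

ft_feature_names <- function(table) setdiff(names(table), ft_meta_cols)

ft_features <- function(table) {
  as.matrix(table[, ft_feature_names(table), drop = FALSE])
}

#' Weighted data-point accounting for a feature table
#'
#' For each class label, the number of weighted data points is
#' `sum(weights) * p` where `p` is the number of feature factors: with 100
#' images per grade, the layer-1 task under weights (1, 2) carries 2800
#' weighted data points on each side, and the layer-2 task carries 3800 data
#' points per grade.
#'
#' @param table a `feature_table`.
#' @return Tibble with columns `label`, `n_images`, `total_weight`,
#'   `data_points`.
#' @export
feature_points <- function(table) {
  p <- length(ft_feature_names(table))
  table |>
    as_tibble() |>
    dplyr::group_by(label = .data$label) |>
    dplyr::summarise(n_images = dplyr::n(),
                     total_weight = sum(.data$weight),
                     data_points = sum(.data$weight) * p,
                     .groups = "drop")
}

#' Write / read a feature table as CSV with a JSON metadata sidecar
#'
#' @param table a `feature_table`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(as_tibble(table), path)
  jsonlite::write_json(list(layer = attr(table, "layer"),
                            task = attr(table, "task"),
                            features = ft_feature_names(table)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_feature_table(df, meta$layer, meta$task)
}
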