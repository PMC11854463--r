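#' Minimum (axis-aligned) bounding rectangle of a binary mask
#'
#' The acquisition rig fixes block orientation, so the bounding rectangle is
#' axis-aligned. Coordinates are 0-based, row-major, half-open:
#' `c(row0, col0, height, width)`.
#'
#' @param mask logical H x W matrix, non-empty.
#' @return Integer vector `c(row0, col0, height, width)`.
#' @export
#' @examples
#' m <- matrix(FALSE, 20, 30); m[3:10, 4:21] <- TRUE
#' min_bounding_rect(m)
min_bounding_rect <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("`mask` is empty")
  r0 <- min(idx[, 1]) - 1L; r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]) - 1L; c1 <- max(idx[, 2])
  c(row0 = r0, col0 = c0, height = r1 - r0, width = c1 - c0)
}

round_even <- function(x) 2 * round(x / 2)

# Nominal center-ROI sizes at the native 6000 x 4000 acquisition resolution:
# width x height = 200 x 500 px for the layer-1 task and 120 x 500 px for the
# layer-2 task.
roi_nominal_size <- function(layer) {
  switch(layer,
         L1 = c(height = 500, width = 200),
         L2 = c(height = 500, width = 120),
         abort("`layer` must be \"L1\" or \"L2\""))
}

#' Center region-of-interest rectangle
#'
#' Places the fixed-size center rectangle (200 x 500 px for layer 1,
#' 120 x 500 px for layer 2, defined at the native 6000 x 4000 resolution and
#' scaled linearly per axis) at the center of the minimum bounding rectangle
#' of the block mask, clipped to that rectangle. Scaled dimensions are rounded
#' to the nearest even integer.
#'
#' @param mask logical block mask.
#' @param layer `"L1"` or `"L2"`.
#' @param scale length-1 or length-2 (rows, cols) scale factor between the
#'   working resolution and the native resolution; defaults to
#'   `c(H/4000, W/6000)` of the mask.
#' @return Integer `c(row0, col0, height, width)`, 0-based half-open.
#' @export
extract_center_roi <- function(mask, layer = c("L1", "L2"), scale = NULL) {
  layer <- match.arg(layer)
  rect <- min_bounding_rect(mask)
  if (is.null(scale)) scale <- c(nrow(mask) / 4000, ncol(mask) / 6000)
  if (length(scale) == 1) scale <- c(scale, scale)
  if (any(scale <= 0)) abort("`scale` must be positive")
  nom <- roi_nominal_size(layer)
  h <- round_even(nom["height"] * scale[1])
  w <- round_even(nom["width"] * scale[2])
  if (h < 1 || w < 1) abort("scaled center ROI is degenerate (zero area)")
  cy <- rect["row0"] + rect["height"] / 2
  cx <- rect["col0"] + rect["width"] / 2
  r0 <- round(cy - h / 2); c0 <- round(cx - w / 2)
  # clip to the bounding rectangle
  r0 <- max(r0, rect["row0"]); c0 <- max(c0, rect["col0"])
  r1 <- min(r0 + h, rect["row0"] + rect["height"])
  c1 <- min(c0 + w, rect["col0"] + rect["width"])
  out <- c(row0 = r0, col0 = c0, height = r1 - r0, width = c1 - c0)
  storage.mode(out) <- "integer"
  names(out) <- c("row0", "col0", "height", "width")
  out
}

rect_mask <- function(rect, H, W) {
  m <- matrix(FALSE, H, W)
  rs <- (rect["row0"] + 1):(rect["row0"] + rect["height"])
  cs <- (rect["col0"] + 1):(rect["col0"] + rect["width"])
  m[rs, cs] <- TRUE
  m
}

#' Partition a block mask into center and Pizhang regions of interest
#'
#' The center ROI is the foreground inside the layer-dependent fixed
#' rectangle; the Pizhang ROI is the remaining foreground. The two masks are
#' disjoint and jointly cover the foreground exactly.
#'
#' @inheritParams extract_center_roi
#' @return An object of class `"roi_partition"`: list with `bounding_rect`,
#'   `center_rect`, `center_mask`, `pizhang_mask`, `layer` and
#'   `pizhang_empty` flag.
#' @export
#' @examples
#' img <- generate_daqu_image("S", gen_params(image_size = c(200, 300)), seed = 2)
#' part <- roi_partition(img$truth$block, "L1")
#' sum(part$center_mask) + sum(part$pizhang_mask) == sum(img$truth$block)
roi_partition <- function(mask, layer = c("L1", "L2"), scale = NULL) {
  layer <- match.arg(layer)
  rect <- min_bounding_rect(mask)
  center_rect <- extract_center_roi(mask, layer, scale)
  inside <- rect_mask(center_rect, nrow(mask), ncol(mask))
  center_mask <- mask & inside
  pizhang_mask <- mask & !inside
  structure(list(bounding_rect = rect, center_rect = center_rect,
                 center_mask = center_mask, pizhang_mask = pizhang_mask,
                 layer = layer, pizhang_empty = !any(pizhang_mask)),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  cat(sprintf("<roi_partition> layer %s, center %d px, pizhang %d px%s\n",
              x$layer, sum(x$center_mask), sum(x$pizhang_mask),
              if (x$pizhang_empty) " (pizhang empty)" else ""))
  invisible(x)
}
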