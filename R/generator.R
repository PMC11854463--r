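#' Generator parameters for synthetic Daqu cross-section images
#'
#' Builds the parameter set controlling the synthetic image generator. The
#' defaults encode the qualitative grade cues of light-flavor Daqu
#' cross-sections: a bright background, a roughly rectangular block, a raw
#' starchy "Pizhang" rim whose thickness grows with grade number, and a center
#' whose appearance depends on grade — concentrated grayish-blue for premium
#' (P), a red spot or line plus small dark edge patches for first grade (F),
#' and dark cracks/rings plus larger dark edge areas for second grade (S).
#' Husk/straw debris is drawn as small elongated bright-yellow blobs touching
#' the block boundary, and an optional smooth multiplicative shadow gradient
#' can be applied (off by default).
#'
#' The default working size is 400 x 600 px (rows x columns), one tenth of the
#' 4000 x 6000 native acquisition resolution per axis; region-of-interest
#' geometry scales by the same factor (see [roi_partition()]).
#'
#' @param image_size integer `c(H, W)`, both at least 200 px.
#' @param block_fraction fraction of the frame area covered by the block.
#' @param pizhang_thickness_px named per-grade rim thickness in pixels; must be
#'   below `min(H, W) / 4`.
#' @param center_color_mean named list of per-grade RGB triplets (0-255) for
#'   the center region.
#' @param center_color_std named per-grade within-center color spread.
#' @param rim_color_mean RGB triplet of the pale starchy rim.
#' @param red_spot_prob,crack_prob named per-grade probabilities of drawing a
#'   red spot/line and of drawing cracks plus a black ring.
#' @param dark_edge_fraction named per-grade target fraction of block pixels
#'   painted as dark edge patches.
#' @param debris_count number of husk/straw debris blobs near the boundary.
#' @param shadow_strength multiplicative shadow gradient strength in `[0, 1]`.
#' @param noise_sd per-pixel Gaussian channel noise standard deviation.
#' @param background_mean mean gray level of the bright background.
#'
#' @return A list of class `"gen_params"`.
#' @export
#' @examples
#' p <- gen_params(image_size = c(200, 300))
#' img <- generate_daqu_image("P", p, seed = 1)
#' dim(img$pixels)
gen_params <- function(image_size = c(400, 600),
                       block_fraction = 0.62,
                       pizhang_thickness_px = c(P = 8, F = 12, S = 25),
                       center_color_mean = list(P = c(115, 128, 150),
                                                F = c(158, 144, 128),
                                                S = c(138, 132, 124)),
                       center_color_std = c(P = 6, F = 6, S = 8),
                       rim_color_mean = c(204, 188, 156),
                       red_spot_prob = c(P = 0, F = 1, S = 0),
                       crack_prob = c(P = 0, F = 0, S = 1),
                       dark_edge_fraction = c(P = 0, F = 0.05, S = 0.2),
                       debris_count = 5,
                       shadow_strength = 0,
                       noise_sd = 5,
                       background_mean = 220) {
  p <- list(
    image_size = as.integer(image_size),
    block_fraction = block_fraction,
    pizhang_thickness_px = pizhang_thickness_px,
    center_color_mean = center_color_mean,
    center_color_std = center_color_std,
    rim_color_mean = rim_color_mean,
    red_spot_prob = red_spot_prob,
    crack_prob = crack_prob,
    dark_edge_fraction = dark_edge_fraction,
    debris_count = debris_count,
    shadow_strength = shadow_strength,
    noise_sd = noise_sd,
    background_mean = background_mean
  )
  class(p) <- "gen_params"
  validate_gen_params(p)
  p
}

validate_gen_params <- function(p) {
  H <- p$image_size[1]; W <- p$image_size[2]
  if (length(p$image_size) != 2 || any(!is.finite(c(H, W)))) {
    abort("`image_size` must be c(H, W)")
  }
  if (H < 200 || W < 200) abort("`image_size` must be at least 200 x 200 px")
  for (g in daqu_grades()) {
    for (field in c("pizhang_thickness_px", "center_color_std",
                    "red_spot_prob", "crack_prob", "dark_edge_fraction")) {
      if (is.na(p[[field]][g])) abort(paste0("`", field, "` needs an entry for grade ", g))
    }
    if (is.null(p$center_color_mean[[g]])) {
      abort(paste0("`center_color_mean` needs an entry for grade ", g))
    }
  }
  probs <- c(p$red_spot_prob, p$crack_prob, p$dark_edge_fraction,
             shadow = p$shadow_strength)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities and fractions must lie in [0, 1]")
  }
  if (any(p$pizhang_thickness_px >= min(H, W) / 4)) {
    abort("`pizhang_thickness_px` must be below min(H, W)/4")
  }
  if (p$block_fraction <= 0 || p$block_fraction >= 1) {
    abort("`block_fraction` must lie in (0, 1)")
  }
  invisible(p)
}

# rotated-ellipse membership on the pixel grid
ellipse_mask <- function(rr, cc, cy, cx, ry, rx, angle = 0) {
  dc <- cc - cx; dr <- rr - cy
  u <- dc * cos(angle) + dr * sin(angle)
  v <- -dc * sin(angle) + dr * cos(angle)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# thick polyline drawn as stamped discs along interpolated points
stamp_polyline <- function(mask, pts_r, pts_c, width) {
  H <- nrow(mask); W <- ncol(mask)
  n_seg <- length(pts_r) - 1
  rad <- max(1, round(width / 2))
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  for (s in seq_len(n_seg)) {
    len <- max(abs(pts_r[s + 1] - pts_r[s]), abs(pts_c[s + 1] - pts_c[s]), 1)
    t <- seq(0, 1, length.out = ceiling(len) + 1)
    r <- round(pts_r[s] + t * (pts_r[s + 1] - pts_r[s]))
    c <- round(pts_c[s] + t * (pts_c[s + 1] - pts_c[s]))
    rr <- rep(r, each = nrow(off)) + off$dr
    cc <- rep(c, each = nrow(off)) + off$dc
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    mask[cbind(rr[keep], cc[keep])] <- TRUE
  }
  mask
}

paint <- function(pixels, mask, rgb_mean, sd = 4) {
  n <- sum(mask)
  if (n == 0) return(pixels)
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    plane[mask] <- rgb_mean[ch] + rnorm(n, 0, sd)
    pixels[, , ch] <- plane
  }
  pixels
}

erode_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  EBImage::erode(mask * 1, EBImage::makeBrush(2 * round(radius) + 1, "disc")) > 0.5
}

#' Generate one synthetic Daqu cross-section image
#'
#' Draws a single labelled Daqu block image deterministically from
#' `(grade, params, seed)`: identical triples yield bit-identical rasters.
#' Ground-truth masks of the block footprint, the Pizhang rim and the center
#' region are attached under `$truth` so segmentation and ROI code can be
#' validated against the geometry the generator actually drew.
#'
#' @param grade one of `"P"`, `"F"`, `"S"` (see [daqu_grades()]).
#' @param params a [gen_params()] list.
#' @param seed non-negative integer seed.
#'
#' @return An object of class `"daqu_image"`: a list with `pixels`
#'   (H x W x 3 integer array, 0-255), `grade`, `seed`, `params` and `truth`
#'   (logical masks `block`, `rim`, `center`).
#' @export
generate_daqu_image <- function(grade, params = gen_params(), seed = 0L) {
  check_grade(grade)
  validate_gen_params(params)
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0) {
    abort("`seed` must be a single non-negative integer")
  }
  set.seed(as.integer(seed))

  H <- params$image_size[1]; W <- params$image_size[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)

  # block: rounded rectangle, slightly jittered off center
  s <- sqrt(params$block_fraction)
  bh <- round(H * s); bw <- round(W * s)
  cy <- H / 2 + runif(1, -0.015, 0.015) * H
  cx <- W / 2 + runif(1, -0.015, 0.015) * W
  r0 <- 0.12 * min(bh, bw)
  dx <- pmax(abs(cc - cx) - (bw / 2 - r0), 0)
  dy <- pmax(abs(rr - cy) - (bh / 2 - r0), 0)
  block <- dx^2 + dy^2 <= r0^2

  thick <- params$pizhang_thickness_px[grade]
  thick <- max(2, round(thick * (1 + runif(1, -0.1, 0.1))))
  center_region <- erode_mask(block, thick)
  rim <- block & !center_region

  pixels <- array(0, dim = c(H, W, 3))
  pixels <- paint(pixels, !block, rep(params$background_mean, 3), sd = 3)
  pixels <- paint(pixels, rim, params$rim_color_mean, sd = 8)
  pixels <- paint(pixels, center_region, params$center_color_mean[[grade]],
                  sd = params$center_color_std[grade])

  # first-grade cue: red spot or line in the center
  if (runif(1) < params$red_spot_prob[grade]) {
    if (runif(1) < 0.5) {
      spot <- ellipse_mask(rr, cc, cy + runif(1, -0.05, 0.05) * bh,
                           cx + runif(1, -0.05, 0.05) * bw,
                           ry = 0.07 * bh, rx = 0.10 * bw,
                           angle = runif(1, 0, pi))
    } else {
      ang <- runif(1, -0.3, 0.3)
      len <- 0.35 * bw
      spot <- stamp_polyline(matrix(FALSE, H, W),
                             c(cy - len / 2 * sin(ang), cy + len / 2 * sin(ang)),
                             c(cx - len / 2 * cos(ang), cx + len / 2 * cos(ang)),
                             width = max(3, round(0.02 * bh)))
    }
    pixels <- paint(pixels, spot & center_region, c(168, 62, 55), sd = 6)
  }

  # second-grade cue: dark cracks and a black ring
  if (runif(1) < params$crack_prob[grade]) {
    cracks <- matrix(FALSE, H, W)
    for (k in 1:3) {
      n_pt <- 4
      pr <- cy + runif(n_pt, -0.42, 0.42) * bh
      pc <- seq(cx - 0.42 * bw, cx + 0.42 * bw, length.out = n_pt) +
        runif(n_pt, -0.05, 0.05) * bw
      if (runif(1) < 0.5) { tmp <- pr; pr <- pc * H / W; pc <- tmp * W / H }
      cracks <- stamp_polyline(cracks, pr, pc, width = max(2, round(0.012 * bh)))
    }
    ring_r <- 0.22 * min(bh, bw)
    th <- seq(0, 2 * pi, length.out = 240)
    cracks <- stamp_polyline(cracks,
                             cy + ring_r * sin(th) + runif(1, -0.1, 0.1) * bh,
                             cx + ring_r * cos(th),
                             width = max(2, round(0.012 * bh)))
    pixels <- paint(pixels, cracks & center_region, c(45, 40, 36), sd = 4)
  }

  # dark edge patches in the band just inside the rim
  f_dark <- params$dark_edge_fraction[grade]
  if (f_dark > 0) {
    band_w <- max(3, round(0.10 * min(bh, bw)))
    band <- center_region & !erode_mask(center_region, band_w)
    target <- f_dark * sum(block)
    dark <- matrix(FALSE, H, W)
    band_idx <- which(band)
    it <- 0
    while (sum(dark) < target && it < 300 && length(band_idx) > 0) {
      it <- it + 1
      at <- band_idx[sample.int(length(band_idx), 1)]
      pr <- (at - 1) %% H + 1
      pc <- (at - 1) %/% H + 1
      blob <- ellipse_mask(rr, cc, pr, pc,
                           ry = runif(1, 0.5, 1.4) * band_w,
                           rx = runif(1, 0.8, 2.2) * band_w,
                           angle = runif(1, 0, pi))
      dark <- dark | (blob & block)
    }
    pixels <- paint(pixels, dark, c(48, 42, 38), sd = 5)
  }

  # husk/straw debris: elongated bright-yellow blobs touching the boundary
  boundary <- block & !erode_mask(block, 3)
  b_idx <- which(boundary)
  if (params$debris_count > 0 && length(b_idx) > 0) {
    for (k in seq_len(params$debris_count)) {
      at <- b_idx[sample.int(length(b_idx), 1)]
      pr <- (at - 1) %% H + 1
      pc <- (at - 1) %/% H + 1
      blob <- ellipse_mask(rr, cc, pr, pc,
                           ry = runif(1, 2, 4), rx = runif(1, 6, 14),
                           angle = runif(1, 0, pi))
      pixels <- paint(pixels, blob, c(228, 202, 96), sd = 6)
    }
  }

  if (params$shadow_strength > 0) {
    grad <- 1 - params$shadow_strength * (cc - 1) / (W - 1)
    for (ch in 1:3) pixels[, , ch] <- pixels[, , ch] * grad
  }

  pixels <- pixels + rnorm(length(pixels), 0, params$noise_sd)
  pixels <- round(pmin(pmax(pixels, 0), 255))
  storage.mode(pixels) <- "integer"

  structure(
    list(pixels = pixels, grade = grade, seed = as.integer(seed),
         params = params,
         truth = list(block = block, rim = rim, center = center_region)),
    class = "daqu_image"
  )
}

#' @export
print.daqu_image <- function(x, ...) {
  cat(sprintf("<daqu_image> grade %s, %d x %d px, seed %d\n",
              x$grade, dim(x$pixels)[1], dim(x$pixels)[2], x$seed))
  invisible(x)
}

#' Generate a balanced synthetic Daqu image corpus
#'
#' Generates `n_per_grade` images for each of the three grades. Per-image
#' seeds are derived deterministically from the master seed, and the returned
#' manifest records `(id, grade, seed)` so any single image can be regenerated
#' with [generate_daqu_image()] alone.
#'
#' @param n_per_grade images per grade (at least 1).
#' @param params a [gen_params()] list.
#' @param seed master seed.
#'
#' @return A list of class `"daqu_dataset"` with `images` (list of
#'   `daqu_image`) and `manifest` (tibble with columns `id`, `grade`, `seed`).
#' @export
#' @examples
#' ds <- generate_dataset(1, gen_params(image_size = c(200, 300)), seed = 1)
#' ds$manifest
generate_dataset <- function(n_per_grade, params = gen_params(), seed = 0L) {
  if (!is.numeric(n_per_grade) || length(n_per_grade) != 1 || n_per_grade < 1) {
    abort("`n_per_grade` must be a single integer >= 1")
  }
  n_per_grade <- as.integer(n_per_grade)
  set.seed(as.integer(seed))
  grades <- rep(daqu_grades(), each = n_per_grade)
  n <- length(grades)
  image_seeds <- sample.int(.Machine$integer.max - 1L, n)
  manifest <- tibble(
    id = sprintf("img_%04d", seq_len(n)),
    grade = grades,
    seed = image_seeds
  )
  images <- purrr::pmap(manifest, function(id, grade, seed) {
    generate_daqu_image(grade, params, seed)
  })
  names(images) <- manifest$id
  structure(list(images = images, manifest = manifest, params = params,
                 master_seed = as.integer(seed)),
            class = "daqu_dataset")
}

#' @export
print.daqu_dataset <- function(x, ...) {
  cat(sprintf("<daqu_dataset> %d images (%s)\n", nrow(x$manifest),
              paste(table(x$manifest$grade)[daqu_grades()], collapse = "/")))
  invisible(x)
}

#' Write a dataset to disk as PNG images plus a CSV manifest
#'
#' @param dataset a `daqu_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest tibble with a `path` column added.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(dataset$manifest$id, ".png"))
  purrr::walk2(dataset$images, paths, function(img, path) {
    png::writePNG(img$pixels / 255, path)
  })
  manifest <- dplyr::mutate(dataset$manifest, path = paths)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read an RGB image file into the 0-255 integer array used throughout
#'
#' PNG is read natively; JPG is accepted through [EBImage::readImage()].
#'
#' @param path image file path.
#' @return H x W x 3 integer array with values in 0-255.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- aperm(a, c(2, 1, 3))  # EBImage stores x,y; convert to row, col
  }
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3]
  a <- round(a * 255)
  storage.mode(a) <- "integer"
  a
}
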