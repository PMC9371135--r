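# Root-enhancement pipeline: HSV segmentation of the bright greenish
# background, intensity segmentation, mask algebra and 2x2 morphological
# filtering.

#' HSV segmentation thresholds
#'
#' Hue is quantized on the 0--179 scale (half-degrees, as used by common
#' vision toolkits), so the background band (35, 140) spans roughly
#' 70--280 degrees -- greens through blues.  Value is on 0--255.  Band
#' membership is inclusive at both ends.
#'
#' @param h_band hue band segmenting the background colors (default
#'   `c(35, 140)`).
#' @param v_band value band segmenting high-intensity pixels (default
#'   `c(100, 255)`).
#' @param kernel binary structuring element for the morphological filter
#'   (default 2x2 of ones).
#' @param h_scale full scale of the hue axis (default 179; configurable for
#'   toolkits that use 0--360).
#' @return an `hsv_thresholds` list.
#' @export
hsv_thresholds <- function(h_band = c(35, 140), v_band = c(100, 255),
                           kernel = matrix(1, 2, 2), h_scale = 179) {
  if (length(h_band) != 2 || h_band[1] > h_band[2] ||
      h_band[1] < 0 || h_band[2] > h_scale) {
    stop_arg("h_band must be ordered within [0, ", h_scale, "]")
  }
  if (length(v_band) != 2 || v_band[1] > v_band[2] ||
      v_band[1] < 0 || v_band[2] > 255) {
    stop_arg("v_band must be ordered within [0, 255]")
  }
  structure(list(h_band = h_band, v_band = v_band, kernel = kernel,
                 h_scale = h_scale), class = "hsv_thresholds")
}

# RGB array (H x W x 3, values in [0,1]) -> list of H, S, V matrices on the
# 0-h_scale / 0-1 / 0-255 scales.  Standard hexcone model via grDevices.
rgb_to_hsv_mats <- function(img, h_scale = 179) {
  d <- dim(img)
  m <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                as.vector(img[, , 2]),
                                as.vector(img[, , 3])),
                          maxColorValue = 1)
  list(H = matrix(m[1, ] * (h_scale + 1), d[1], d[2]),
       S = matrix(m[2, ], d[1], d[2]),
       V = matrix(m[3, ] * 255, d[1], d[2]))
}

shift_mat <- function(m, di, dj, fill = FALSE) {
  # shift content by (di, dj), padding with `fill`
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) + di
  cj <- seq_len(nc) + dj
  keep_i <- ri >= 1 & ri <= nr
  keep_j <- cj >= 1 & cj <= nc
  out[which(keep_i), which(keep_j)] <- m[ri[keep_i], cj[keep_j]]
  out
}

erode_mask <- function(mask, kernel, pad = FALSE) {
  offs <- which(kernel != 0, arr.ind = TRUE) - 1L  # offsets from origin (1,1)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_mat(mask, offs[k, 1], offs[k, 2], fill = pad)
  }
  out
}

dilate_mask <- function(mask, kernel) {
  offs <- which(kernel != 0, arr.ind = TRUE) - 1L
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_mat(mask, -offs[k, 1], -offs[k, 2])  # reflected SE
  }
  out
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the structuring element (reflected for
#' the dilation), removing structures smaller than the element -- with the
#' default 2x2 kernel, isolated pixels and 1-pixel-thin spurs.  Opening is
#' idempotent.  Pixels outside the image count as background.
#'
#' @param mask logical (or 0/1) matrix.
#' @param kernel binary structuring element (default 2x2 of ones).
#' @return logical matrix of the same dimensions.
#' @export
morphological_open <- function(mask, kernel = matrix(1, 2, 2)) {
  if (!is.matrix(mask)) stop_arg("mask must be a matrix")
  mask <- mask != 0
  dilate_mask(erode_mask(mask, kernel), kernel)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion; fills gaps smaller than the element.
#' Available as an alternative filter for [enhance_root()].  The erosion
#' step pads the border with foreground so that closing never erodes the
#' image edge (the usual extensivity convention).
#'
#' @inheritParams morphological_open
#' @return logical matrix of the same dimensions.
#' @export
morphological_close <- function(mask, kernel = matrix(1, 2, 2)) {
  if (!is.matrix(mask)) stop_arg("mask must be a matrix")
  mask <- mask != 0
  erode_mask(dilate_mask(mask, kernel), kernel, pad = TRUE)
}

#' Enhance the root against the greenish background of a root image
#'
#' The pipeline: (1) convert RGB to HSV; (2) segment the background hues,
#' `H` in `h_band`; (3) segment the high-intensity pixels, `V` in `v_band`;
#' (4) AND the V mask with the negated H mask; (5) morphological filtering
#' with the 2x2 kernel (opening by default); the result is the root mask
#' and its negative the background mask.  The root mask applied to the RGB
#' image yields the root-enhanced image; the background mask applied to the
#' HSV representation yields the root-suppressed HSV output (the original
#' account is ambiguous about which of the two complementary maskings the
#' HSV figure shows, so both the array and an RGB rendering are returned).
#'
#' @param image RGB array `H x W x 3` with values in `[0, 1]` (a 0--255
#'   integer array is rescaled).
#' @param thr an [hsv_thresholds()].
#' @param filter morphological filter applied to the raw mask: `"open"`
#'   (default), `"close"`, or `"none"`.
#' @return an `enhancement_result` list: logical `root_mask` and
#'   `background_mask` (exact complements), `rgb_enhanced` (RGB, zero
#'   outside the root mask), `hsv_enhanced` (H/S/V array, zero outside the
#'   background mask), `hsv_enhanced_rgb` (RGB rendering of the latter),
#'   and the intermediate `mask_H`, `mask_V`.
#' @export
enhance_root <- function(image, thr = hsv_thresholds(),
                         filter = c("open", "close", "none")) {
  filter <- match.arg(filter)
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    stop_arg("image must be an H x W x 3 RGB array")
  }
  if (dim(image)[1] < 2 || dim(image)[2] < 2) stop_arg("image must be at least 2 x 2")
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) > 1) image <- image / 255
  hsv <- rgb_to_hsv_mats(image, thr$h_scale)
  mask_H <- hsv$H >= thr$h_band[1] & hsv$H <= thr$h_band[2]
  mask_V <- hsv$V >= thr$v_band[1] & hsv$V <= thr$v_band[2]
  raw <- mask_V & !mask_H
  root_mask <- switch(filter,
                      open = morphological_open(raw, thr$kernel),
                      close = morphological_close(raw, thr$kernel),
                      none = raw)
  background_mask <- !root_mask
  mask3 <- array(rep(root_mask, 3), dim = dim(image))
  rgb_enhanced <- image * mask3
  hsv_arr <- array(c(hsv$H, hsv$S, hsv$V), dim = dim(image))
  hsv_enhanced <- hsv_arr * array(rep(background_mask, 3), dim = dim(image))
  # render the root-suppressed HSV output back to RGB for viewing
  hcol <- grDevices::hsv(pmin(hsv_enhanced[, , 1] / (thr$h_scale + 1), 1),
                         hsv_enhanced[, , 2],
                         hsv_enhanced[, , 3] / 255)
  rgbm <- grDevices::col2rgb(hcol) / 255
  hsv_enhanced_rgb <- array(0, dim = dim(image))
  hsv_enhanced_rgb[, , 1] <- matrix(rgbm[1, ], dim(image)[1], dim(image)[2])
  hsv_enhanced_rgb[, , 2] <- matrix(rgbm[2, ], dim(image)[1], dim(image)[2])
  hsv_enhanced_rgb[, , 3] <- matrix(rgbm[3, ], dim(image)[1], dim(image)[2])
  structure(list(root_mask = root_mask, background_mask = background_mask,
                 rgb_enhanced = rgb_enhanced, hsv_enhanced = hsv_enhanced,
                 hsv_enhanced_rgb = hsv_enhanced_rgb,
                 mask_H = mask_H, mask_V = mask_V, thresholds = thr),
            class = "enhancement_result")
}

#' Dice overlap score between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of equal dimensions.
#' @return numeric in `[0, 1]`.
#' @export
dice_score <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop_arg("mask dimensions differ")
  a <- mask_a != 0; b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Read and write images as PNG
#'
#' Thin wrappers over the png package.  Masks are written as single-channel
#' 0/255 images.
#'
#' @param path PNG file path.
#' @param image RGB array in `[0, 1]`.
#' @param mask logical matrix.
#' @return `read_image_png`: an array in `[0, 1]`.  Writers return `path`
#'   invisibly.
#' @export
read_image_png <- function(path) png::readPNG(path)

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
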