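#' Generate a synthetic root image with ground truth
#'
#' Renders the scene the root-enhancement pipeline targets: dark reddish
#' root strands hanging over a bright greenish background.  Strands are
#' random vertical walks 2--4 pixels wide, drawn until the requested pixel
#' fraction is reached; background pixels get hues inside the background
#' band (default hue 75 on the 0--179 scale) at high value, root pixels get
#' low reddish hues at moderate value so they pass the intensity band while
#' escaping the background band.  Deterministic for a given seed.
#'
#' @param h,w image dimensions in pixels (>= 16).
#' @param root_fraction target fraction of root pixels, in `[0, 1)`.
#' @param background_hue background hue center on the 0--179 scale (keep it
#'   inside the (35, 140) background band).
#' @param seed integer seed.
#' @return a `root_image_truth` list: `image` (`h x w x 3` RGB array in
#'   `[0, 1]`), `truth_mask` (logical `h x w`), and the achieved
#'   `root_fraction`.
#' @export
synth_root_image <- function(h = 256, w = 256, root_fraction = 0.2,
                             background_hue = 75, seed = 1L) {
  if (h < 16 || w < 16) stop_arg("image must be at least 16 x 16")
  if (root_fraction < 0 || root_fraction >= 1) {
    stop_arg("root_fraction must be in [0, 1)")
  }
  target <- root_fraction * h * w
  mask <- matrix(FALSE, h, w)
  with_stream_seed(seed, "root", {
    cnt <- 0
    while (cnt < target) {
      col <- sample.int(w, 1)
      width <- sample(2:4, 1)
      for (r in seq_len(h)) {
        lo <- max(1, col); hi <- min(w, col + width - 1)
        cnt <- cnt + sum(!mask[r, lo:hi])
        mask[r, lo:hi] <- TRUE
        if (cnt >= target) break
        col <- min(max(col + sample(-1:1, 1), 1), w - width + 1)
      }
    }

    n_bg <- sum(!mask); n_rt <- sum(mask)
    H <- S <- V <- matrix(0, h, w)
    H[!mask] <- pmin(pmax(background_hue + stats::rnorm(n_bg, 0, 3), 36), 139)
    S[!mask] <- pmin(pmax(0.55 + stats::rnorm(n_bg, 0, 0.05), 0.3), 0.9)
    V[!mask] <- pmin(pmax(210 + stats::rnorm(n_bg, 0, 12), 150), 255)
    if (n_rt) {
      H[mask] <- pmin(pmax(8 + stats::rnorm(n_rt, 0, 3), 0), 20)
      S[mask] <- pmin(pmax(0.7 + stats::rnorm(n_rt, 0, 0.05), 0.5), 0.95)
      V[mask] <- pmin(pmax(150 + stats::rnorm(n_rt, 0, 15), 110), 230)
    }
    col_hex <- grDevices::hsv(H / 180, S, V / 255)
    rgbm <- grDevices::col2rgb(col_hex) / 255
    image <- array(0, dim = c(h, w, 3))
    image[, , 1] <- matrix(rgbm[1, ], h, w)
    image[, , 2] <- matrix(rgbm[2, ], h, w)
    image[, , 3] <- matrix(rgbm[3, ], h, w)
    structure(list(image = image, truth_mask = mask,
                   root_fraction = sum(mask) / (h * w)),
              class = "root_image_truth")
  })
}
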