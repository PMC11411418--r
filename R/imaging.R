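#' Render a synthetic array scan
#'
#' Draws the sensing device as a scanner would see it: a dark rectangle on
#' a light background carrying 12 filled circular spots at the layout
#' positions, each with a specified uniform RGB color plus optional
#' Gaussian pixel noise. A small white fiducial square is stamped in the
#' top-left corner of the rectangle so that a 180-degree-rotated scan can
#' be detected at registration time (the spot grid itself is symmetric).
#'
#' @param layout An [array_layout()].
#' @param spot_colors Tibble or data frame with columns `element`, `R`,
#'   `G`, `B` (8-bit units, 0-255), one row per element.
#' @param width_px Rendered rectangle width in pixels; height follows the
#'   rectangle aspect ratio.
#' @param margin_px Light background margin around the rectangle.
#' @param offset_px Integer length-2 extra (x, y) placement offset of the
#'   rectangle inside the image.
#' @param pixel_noise_sd Per-pixel Gaussian noise sd in 8-bit units
#'   (0 = noiseless).
#' @param background Background gray level, 8-bit.
#' @param rect_level Rectangle (hydrophobized field) gray level, 8-bit.
#' @param fiducial Logical; stamp the orientation fiducial.
#' @param seed Optional seed for the pixel noise.
#' @return An H x W x 3 numeric array in `[0, 1]` (png convention), with
#'   attribute `placement` recording the true rectangle corners (for
#'   oracle checks).
#' @export
#' @examples
#' colors <- tibble::tibble(element = element_ids(),
#'                          R = 200, G = 180, B = 160)
#' img <- render_array_scan(array_layout(), colors, width_px = 120)
#' dim(img)
render_array_scan <- function(layout, spot_colors,
                              width_px = 240, margin_px = 20,
                              offset_px = c(0, 0),
                              pixel_noise_sd = 0,
                              background = 245, rect_level = 30,
                              fiducial = TRUE, seed = NULL) {
  validate_layout(layout)
  sc <- as.data.frame(spot_colors)
  if (!all(c("element", "R", "G", "B") %in% names(sc))) {
    abort("spot_colors needs columns element, R, G, B")
  }
  sc <- sc[match(layout$element, sc$element), ]
  if (any(is.na(sc$R))) abort("spot_colors must cover all 12 elements")
  rgb <- as.matrix(sc[, c("R", "G", "B")])
  if (any(rgb < 0 | rgb > 255)) abort("spot colors must lie in [0, 255]")

  rect <- attr(layout, "rect_cm") %||% c(1.0, 0.75)
  aspect <- rect[2] / rect[1]
  height_px <- round(width_px * aspect)
  W <- width_px + 2 * margin_px + abs(offset_px[1])
  H <- height_px + 2 * margin_px + abs(offset_px[2])
  x0 <- margin_px + max(offset_px[1], 0)   # rectangle top-left, 0-based px
  y0 <- margin_px + max(offset_px[2], 0)

  img <- array(background / 255, dim = c(H, W, 3))
  img[(y0 + 1):(y0 + height_px), (x0 + 1):(x0 + width_px), ] <- rect_level / 255

  # pixel-center coordinate grids (0-based)
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H)
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H)
  for (i in seq_len(12)) {
    cx <- x0 + layout$x[i] * width_px
    cy <- y0 + layout$y[i] * height_px
    r <- layout$radius[i] * width_px
    mask <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- rgb[i, ch] / 255
      img[, , ch] <- plane
    }
  }
  if (fiducial) {
    side <- max(3, round(0.04 * width_px))
    fy <- (y0 + 2):(y0 + 1 + side)
    fx <- (x0 + 2):(x0 + 1 + side)
    img[fy, fx, ] <- 1
  }
  if (pixel_noise_sd > 0) {
    addnoise <- function() {
      img + array(rnorm(length(img), 0, pixel_noise_sd / 255), dim = dim(img))
    }
    img <- if (is.null(seed)) addnoise() else withr::with_seed(seed, addnoise())
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  attr(img, "placement") <- list(x0 = x0, y0 = y0,
                                 width_px = width_px, height_px = height_px)
  img
}

#' Write / read a scan image as PNG
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path PNG file path.
#' @return `read_scan()` returns the image array; `write_scan()` the path,
#'   invisibly.
#' @export
write_scan <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) abort(paste0("scan image not found: ", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Locate the sensor rectangle in a scan
#'
#' Thresholds the image against the light background, takes the bounding
#' box of the dark region as the sensor rectangle, and checks its aspect
#' ratio against the layout. If the orientation fiducial (a white square
#' inside the rectangle corner) is found at the bottom-right instead of
#' the top-left corner, the scan is flagged as rotated 180 degrees and
#' the placement carries `rotated = TRUE`; spot centers are then mapped
#' through the rotation so element labels stay correct. If neither corner
#' is decisive the scan is assumed upright.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param layout The [array_layout()] expected in the image.
#' @param dark_threshold Gray level (0-1) below which a pixel counts as
#'   rectangle; default halfway between typical background and field.
#' @param aspect_tol Maximum relative deviation of the detected aspect
#'   ratio from the layout's before registration fails.
#' @return A list `placement` with `x0`, `y0`, `width_px`, `height_px`,
#'   `rotated`.
#' @export
register_array <- function(img, layout = array_layout(),
                           dark_threshold = 0.5, aspect_tol = 0.25) {
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  dark <- gray < dark_threshold
  if (!any(dark)) abort("registration error: no dark rectangle found")
  rows <- which(apply(dark, 1, any))
  cols <- which(apply(dark, 2, any))
  y0 <- min(rows) - 1; y1 <- max(rows) - 1
  x0 <- min(cols) - 1; x1 <- max(cols) - 1
  width_px <- x1 - x0 + 1
  height_px <- y1 - y0 + 1
  rect <- attr(layout, "rect_cm") %||% c(1.0, 0.75)
  aspect <- rect[2] / rect[1]
  found <- height_px / width_px
  if (abs(found - aspect) / aspect > aspect_tol) {
    abort(sprintf(
      "registration error: rectangle aspect %.3f deviates more than %d%% from layout %.3f",
      found, round(aspect_tol * 100), aspect))
  }
  # orientation: mean brightness of the two diagonal corner patches,
  # probed well inside the fiducial footprint (4% of width, 2 px inset)
  side <- max(3, round(0.03 * width_px))
  patch <- function(yy, xx) mean(gray[pmax(yy, 1), pmax(xx, 1)])
  tl <- patch((y0 + 3):(y0 + 2 + side), (x0 + 3):(x0 + 2 + side))
  br <- patch((y1 - 1 - side):(y1 - 2), (x1 - 1 - side):(x1 - 2))
  rotated <- br > 0.8 && tl < 0.8
  list(x0 = x0, y0 = y0, width_px = width_px, height_px = height_px,
       rotated = rotated)
}

#' Extract mean spot colors from a registered scan
#'
#' Maps each layout spot center through the placement and averages the
#' pixels within `shrink_factor` times the nominal spot radius of the
#' center (arithmetic mean per channel, the ImageJ "mean gray value"
#' convention), returning 8-bit color triplets in element order S1..S12.
#' The ROI is shrunk below the printed spot radius to avoid edge bleed
#' from the dark field.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param layout The [array_layout()].
#' @param placement As returned by [register_array()]; defaults to
#'   registering `img` itself.
#' @param shrink_factor ROI radius as a fraction of the nominal spot
#'   radius.
#' @return A tibble `element`, `R`, `G`, `B` (real-valued means on the
#'   0-255 scale).
#' @export
extract_spot_colors <- function(img, layout = array_layout(),
                                placement = NULL, shrink_factor = 0.8) {
  validate_layout(layout)
  if (is.null(placement)) placement <- register_array(img, layout)
  H <- dim(img)[1]; W <- dim(img)[2]
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H)
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H)
  rotated <- isTRUE(placement$rotated)
  out <- purrr::map_dfr(seq_len(12), function(i) {
    lx <- layout$x[i]; ly <- layout$y[i]
    if (rotated) { lx <- 1 - lx; ly <- 1 - ly }
    cx <- placement$x0 + lx * placement$width_px
    cy <- placement$y0 + ly * placement$height_px
    r <- layout$radius[i] * placement$width_px * shrink_factor
    if (cx - r < 0 || cx + r > W || cy - r < 0 || cy + r > H) {
      abort(paste0("extraction error: spot ", layout$element[i],
                   " region extends off-image"))
    }
    mask <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    tibble(element = layout$element[i],
           R = mean(img[, , 1][mask]) * 255,
           G = mean(img[, , 2][mask]) * 255,
           B = mean(img[, , 3][mask]) * 255)
  })
  out
}

#' Color difference between before and after scans
#'
#' The array's raw signal: per sensing element and channel, the
#' after-minus-before difference of mean spot colors from scans of the
#' same device taken before and after exposure.
#'
#' @param before,after Tibbles `element`, `R`, `G`, `B` as returned by
#'   [extract_spot_colors()], in the same element order.
#' @return A tibble `element`, `dR`, `dG`, `dB`, each in `[-255, 255]`.
#' @export
#' @examples
#' b <- tibble::tibble(element = element_ids(), R = 200, G = 200, B = 200)
#' a <- dplyr::mutate(b, R = R - 40, G = G + 10)
#' compute_delta(b, a)
compute_delta <- function(before, after) {
  if (nrow(before) != nrow(after)) {
    abort("before/after extractions have different lengths")
  }
  if (!identical(before$element, after$element)) {
    abort("before/after extractions cover different elements or orders")
  }
  tibble(element = before$element,
         dR = after$R - before$R,
         dG = after$G - before$G,
         dB = after$B - before$B)
}
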