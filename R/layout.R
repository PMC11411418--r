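#' Geometry of the 12-spot paper sensor array
#'
#' The sensing device is a black hydrophobized rectangle (default
#' 1.0 cm x 0.75 cm) carrying 12 white circular spots, each loaded with
#' nanozyme plus one organic dye. `array_layout()` builds the layout as a
#' tibble of normalized spot coordinates (origin top-left, x rightward,
#' y downward, both in `[0, 1]` relative to the rectangle) together with
#' the element ids `S1..S12` in raster order and their dye names.
#'
#' The default places the spots on a 4-column x 3-row grid. Element-to-dye
#' assignment follows the reagent order of the sensing elements:
#' ARS, IC, TB, MG, CR, PR, PAR, BPR, ER, MU, CAS, EBT for S1..S12.
#'
#' @param rect_cm Numeric length-2, physical rectangle size (width, height)
#'   in cm. Default `c(1.0, 0.75)`.
#' @param spot_radius Normalized spot radius (fraction of rectangle width).
#' @return A tibble with columns `element`, `dye`, `x`, `y`, `radius`, of
#'   class `array_layout`; rectangle size stored in attribute `rect_cm`.
#' @export
#' @examples
#' layout <- array_layout()
#' layout
array_layout <- function(rect_cm = c(1.0, 0.75), spot_radius = 0.07) {
  dyes <- c("ARS", "IC", "TB", "MG", "CR", "PR",
            "PAR", "BPR", "ER", "MU", "CAS", "EBT")
  grid <- expand.grid(col = 1:4, row = 1:3)
  out <- tibble(
    element = element_ids(),
    dye = dyes,
    x = (grid$col - 0.5) / 4,
    y = (grid$row - 0.5) / 3,
    radius = spot_radius
  )
  attr(out, "rect_cm") <- rect_cm
  class(out) <- c("array_layout", class(out))
  validate_layout(out)
}

#' Validate an array layout
#'
#' Checks the layout invariants: exactly 12 spots, all spots strictly
#' inside the unit rectangle, and no pair of spots overlapping. Radii are
#' normalized by rectangle width; the y-distance check accounts for the
#' rectangle aspect ratio.
#'
#' @param layout An `array_layout` tibble.
#' @return The layout, invisibly unchanged, or an error.
#' @export
validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  need <- c("element", "x", "y", "radius")
  if (!all(need %in% names(layout))) {
    abort("layout must have columns element, x, y, radius")
  }
  if (nrow(layout) != 12) abort("layout must describe exactly 12 spots")
  rect <- attr(layout, "rect_cm") %||% c(1.0, 0.75)
  aspect <- rect[2] / rect[1]  # height / width
  r <- layout$radius
  inside <- layout$x - r >= 0 & layout$x + r <= 1 &
    layout$y - r / aspect >= 0 & layout$y + r / aspect <= 1
  if (!all(inside)) {
    abort(paste0("spots extend outside the rectangle: ",
                 paste(layout$element[!inside], collapse = ", ")))
  }
  # pairwise overlap in physical (width-normalized) units
  px <- layout$x
  py <- layout$y * aspect
  d <- as.matrix(dist(cbind(px, py)))
  diag(d) <- Inf
  rr <- outer(r, r, "+")
  if (any(d < rr)) abort("layout has overlapping spots")
  invisible(layout)
}

#' Read / write a layout file
#'
#' Layouts are stored as YAML with the rectangle size and one record per
#' spot in normalized coordinates.
#'
#' @param path File path.
#' @param layout An `array_layout` tibble.
#' @return `read_layout()` returns an `array_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("layout file not found: ", path))
  y <- yaml::read_yaml(path)
  out <- purrr::map_dfr(y$spots, as_tibble)
  attr(out, "rect_cm") <- as.numeric(y$rect_cm)
  class(out) <- c("array_layout", class(out))
  validate_layout(out)
  out
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  yaml::write_yaml(
    list(
      rect_cm = as.numeric(attr(layout, "rect_cm") %||% c(1.0, 0.75)),
      spots = purrr::pmap(
        layout[, c("element", "dye", "x", "y", "radius")],
        function(element, dye, x, y, radius) {
          list(element = element, dye = dye, x = x, y = y, radius = radius)
        }
      )
    ),
    path,
    precision = 12
  )
  invisible(path)
}
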