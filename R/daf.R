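#' Discriminant ability function (DAF)
#'
#' The statistic used to pick assay conditions: the ratio of between-group
#' to within-group variance of the per-sample responses. On Euclidean
#' norms (the default, matching how the assay summarizes each sample) it
#' is the one-way ANOVA ratio of mean squares,
#' `MS_between / MS_within`, computed explicitly:
#' `MS_between = sum(n_g (m_g - m)^2) / (G - 1)` and
#' `MS_within = sum((x - m_g)^2) / (N - G)`. Groups with identical means
#' give DAF = 0; zero within-group spread with separated means gives
#' `Inf` (flagged, not an error). A multivariate variant
#' (`method = "wilks"`) scores the full 36-feature vectors as
#' `(1 - lambda) / lambda` from the Wilks' lambda of a one-way MANOVA.
#'
#' @param values Numeric per-sample responses (Euclidean norms), or for
#'   `method = "wilks"` a numeric matrix / data frame of per-sample
#'   feature rows.
#' @param groups Per-sample group labels.
#' @param method `"norm"` (univariate mean-square ratio, default) or
#'   `"wilks"`.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
#' @examples
#' compute_daf(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
compute_daf <- function(values, groups, method = c("norm", "wilks")) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  tab <- table(groups)
  if (length(tab) < 2) abort("DAF needs at least 2 groups")
  if (any(tab < 2)) {
    abort(paste0("DAF needs >= 2 samples per group; too small: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (method == "wilks") {
    m <- as.matrix(as.data.frame(values))
    if (nrow(m) != length(groups)) abort("values/groups length mismatch")
    if (ncol(m) == 1) {
      # one response: Wilks' lambda is SSW / (SSW + SSB)
      x <- m[, 1]
      gm <- tapply(x, groups, mean)
      ssb <- sum(tab * (gm - mean(x))^2)
      ssw <- sum((x - gm[groups])^2)
      return(ssb / ssw)
    }
    fit <- manova(m ~ groups)
    lambda <- summary(fit, test = "Wilks")$stats[1, "Wilks"]
    return(as.numeric((1 - lambda) / lambda))
  }
  x <- as.numeric(values)
  if (length(x) != length(groups)) abort("values/groups length mismatch")
  if (any(!is.finite(x))) abort("non-finite response values")
  n <- length(x)
  g <- length(tab)
  grand <- mean(x)
  gm <- tapply(x, groups, mean)
  ss_between <- sum(tab * (gm - grand)^2)
  ss_within <- sum((x - gm[groups])^2)
  ms_between <- ss_between / (g - 1)
  ms_within <- ss_within / (n - g)
  if (ms_within == 0) {
    if (ms_between == 0) return(0)
    warn("within-group variance is zero with separated groups; DAF = Inf")
    return(Inf)
  }
  ms_between / ms_within
}

#' DAF curve over a scanned assay parameter
#'
#' Computes the DAF at each level of an experimental parameter scan (dye
#' concentration, exposure time, temperature, ...) from a long table of
#' per-sample responses, and selects the operating point on the earliest
#' plateau.
#'
#' @param data Data frame with one row per (parameter level, sample).
#' @param param_col Name of the scanned-parameter column (numeric grid).
#' @param value_col Name of the per-sample response column (Euclidean
#'   norm).
#' @param group_col Name of the group-label column.
#' @param plateau_tol Plateau tolerance passed to
#'   [select_operating_point()].
#' @return A tibble of class `daf_curve` with columns `parameter`, `daf`,
#'   ordered by parameter; attributes `parameter_name` and `selected`.
#' @export
#' @examples
#' scan <- tidyr::expand_grid(time = c(15, 30, 45, 60, 75, 90),
#'                            group = rep(c("a", "b"), each = 3))
#' scan$norm <- ifelse(scan$group == "a", 0, pmin(scan$time, 60) / 10) +
#'   rep_len(c(-.1, 0, .1), nrow(scan))
#' daf_curve(scan, "time", "norm", "group")
daf_curve <- function(data, param_col, value_col, group_col,
                      plateau_tol = 0.05) {
  for (col in c(param_col, value_col, group_col)) {
    if (!col %in% names(data)) abort(paste0("column not found: ", col))
  }
  grid <- sort(unique(data[[param_col]]))
  if (length(grid) == 0) abort("empty parameter scan")
  daf <- purrr::map_dbl(grid, function(p) {
    sub <- data[data[[param_col]] == p, ]
    compute_daf(sub[[value_col]], sub[[group_col]])
  })
  out <- tibble(parameter = grid, daf = daf)
  attr(out, "parameter_name") <- param_col
  attr(out, "selected") <- select_operating_point(out, plateau_tol)
  class(out) <- c("daf_curve", class(out))
  out
}

#' Select the operating point on a DAF curve
#'
#' Rather than the literal argmax, the assay condition chosen is the
#' earliest plateau: the smallest grid value whose DAF is within
#' `plateau_tol` (relative) of the curve maximum. On a saturating curve
#' this reproduces the "response is almost constant beyond here" reading
#' of a condition scan; with `plateau_tol = 0` it reduces to the first
#' argmax, and on a flat curve it returns the smallest grid value.
#'
#' @param curve A [daf_curve()] tibble, or any data frame with columns
#'   `parameter` and `daf`.
#' @param plateau_tol Relative tolerance below the maximum that still
#'   counts as "on the plateau".
#' @return The selected parameter value.
#' @export
select_operating_point <- function(curve, plateau_tol = 0.05) {
  if (!all(c("parameter", "daf") %in% names(curve))) {
    abort("curve must have columns parameter and daf")
  }
  if (nrow(curve) == 0) abort("empty DAF curve")
  if (plateau_tol < 0) abort("plateau_tol must be >= 0")
  o <- order(curve$parameter)
  p <- curve$parameter[o]
  d <- curve$daf[o]
  finite_max <- if (any(is.finite(d))) max(d[is.finite(d)]) else 0
  top <- if (any(is.infinite(d))) Inf else finite_max
  ok <- if (is.infinite(top)) is.infinite(d) else d >= (1 - plateau_tol) * top
  p[which(ok)[1]]
}
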