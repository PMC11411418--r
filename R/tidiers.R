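#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a PCA of sensor responses
#'
#' @param x A `sensor_pca` object.
#' @param ... Unused.
#' @return `tidy()`: the scores tibble. `glance()`: one row with
#'   `n_samples`, `k`, `explained_pc1`, `explained_pc2`,
#'   `explained_total` (all fractions).
#' @export
tidy.sensor_pca <- function(x, ...) x$scores

#' @rdname tidy.sensor_pca
#' @export
glance.sensor_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    k = length(x$explained),
    explained_pc1 = x$explained[1],
    explained_pc2 = if (length(x$explained) >= 2) x$explained[2] else NA_real_,
    explained_total = sum(x$explained)
  )
}

#' Tidy an HCA of sensor responses
#'
#' @param x A `sensor_hca` object.
#' @param ... Unused.
#' @return `tidy()`: the cluster assignments tibble. `glance()`: one row
#'   with `n_samples`, `n_clusters`, `matched_accuracy_pct`.
#' @export
tidy.sensor_hca <- function(x, ...) x$clusters

#' @rdname tidy.sensor_hca
#' @export
glance.sensor_hca <- function(x, ...) {
  tibble(n_samples = nrow(x$clusters), n_clusters = x$n_clusters,
         matched_accuracy_pct = x$matched_accuracy)
}

#' Tidy a classification report
#'
#' @param x A `classification_report` object.
#' @param ... Unused.
#' @return `tidy()`: the per-class sensitivity/specificity tibble.
#'   `glance()`: one row with `accuracy_pct`, `error_rate_pct`, `n`, and
#'   `cv` when cross-validation was used.
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble(accuracy_pct = x$accuracy, error_rate_pct = x$error_rate,
         n = x$n, cv = x$cv %||% NA_character_)
}

#' Tidy a severity regression
#'
#' @param x A `severity_fit` object.
#' @param ... Unused.
#' @return `tidy()`: tibble of `term`, `estimate`. `glance()`: one row
#'   with `slope`, `intercept`, `r_squared`, `n`.
#' @export
tidy.severity_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "grade"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.severity_fit
#' @export
glance.severity_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = x$n)
}

#' Score plot for a sensor PCA
#'
#' First two principal components, colored by the label column given to
#' [run_pca()] (if any), with explained variance in the axis labels.
#'
#' @param object A `sensor_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensor_pca <- function(object, ...) {
  sc <- object$scores
  if (!"PC2" %in% names(sc)) abort("score plot needs at least 2 components")
  lab <- object$label_col
  aes <- if (!is.null(lab)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data[[lab]])
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' DAF curve plot
#'
#' DAF against the scanned parameter with the selected operating point
#' marked.
#'
#' @param object A `daf_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.daf_curve <- function(object, ...) {
  sel <- attr(object, "selected")
  pname <- attr(object, "parameter_name") %||% "parameter"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$parameter, .data$daf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed") +
    ggplot2::labs(x = pname, y = "DAF") +
    ggplot2::theme_minimal()
}

#' Severity-response plot
#'
#' Observed norms against severity grade with the fitted line.
#'
#' @param object A `severity_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.severity_fit <- function(object, ...) {
  d <- tibble(grade = object$fit$model$grades,
              norm = object$fit$model$norms)
  ggplot2::ggplot(d, ggplot2::aes(.data$grade, .data$norm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope) +
    ggplot2::labs(x = "severity grade (ordinal)", y = "response norm",
                  subtitle = sprintf("R² = %.3f", object$r_squared)) +
    ggplot2::theme_minimal()
}
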