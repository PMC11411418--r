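#' Spirometry-based injury severity grading
#'
#' Grades obstructive injury from percent-predicted spirometry: control
#' if FEV1 > 80 with FEV1/FVC > 70; mild if FEV1 > 80 with FEV1/FVC
#' below 70; moderate if FEV1 lies in `[50, 80]`; severe if FEV1 lies in
#' `[30, 50)`. FEV1 below 30 is graded severe and flagged out-of-range.
#'
#' Boundary convention (the printed rules leave ties open): the moderate
#' band is closed `[50, 80]`; control and mild both require FEV1 strictly
#' above 80; a ratio of exactly 70 is assigned to control. All boundary
#' handling lives in this one function.
#'
#' @param fev1_pct FEV1 as percent of predicted (vectorized).
#' @param ratio_pct FEV1/FVC as percent of predicted (vectorized).
#' @return A tibble with columns `fev1_pct`, `ratio_pct`, `grade`
#'   (factor control/mild/moderate/severe), `grade_code` (0-3), and
#'   `out_of_range` (logical, FEV1 < 30).
#' @export
#' @examples
#' grade_spirometry(c(85, 85, 65, 40), c(75, 65, 60, 50))
grade_spirometry <- function(fev1_pct, ratio_pct) {
  if (length(fev1_pct) != length(ratio_pct)) {
    abort("fev1_pct and ratio_pct must have the same length")
  }
  if (any(!is.finite(fev1_pct)) || any(!is.finite(ratio_pct))) {
    abort("spirometry values must be finite")
  }
  if (any(fev1_pct <= 0) || any(ratio_pct <= 0)) {
    abort("spirometry values must be positive")
  }
  if (any(fev1_pct > 150) || any(ratio_pct > 150)) {
    abort("spirometry values above 150% predicted are not plausible")
  }
  grade <- dplyr::case_when(
    fev1_pct > 80 & ratio_pct >= 70 ~ "control",
    fev1_pct > 80 & ratio_pct < 70 ~ "mild",
    fev1_pct >= 50 ~ "moderate",
    TRUE ~ "severe"
  )
  codes <- c(control = 0L, mild = 1L, moderate = 2L, severe = 3L)
  tibble(
    fev1_pct = fev1_pct,
    ratio_pct = ratio_pct,
    grade = factor(grade, levels = names(codes)),
    grade_code = unname(codes[grade]),
    out_of_range = fev1_pct < 30
  )
}

#' Severity-response regression
#'
#' Ordinary least squares of the per-subject sensor response (Euclidean
#' norm, typically of the severity-responsive elements S3 or S7) on the
#' ordinal severity grade (0 control ... 3 severe). The linearity of this
#' relationship is what lets the assay estimate injury severity for an
#' unknown subject.
#'
#' @param norms Per-subject response norms.
#' @param grades Ordinal severity codes (numeric).
#' @return An object of class `severity_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
#' @examples
#' severity_regression(c(1, 2.1, 2.9, 4.2), c(0, 1, 2, 3))$r_squared
severity_regression <- function(norms, grades) {
  if (length(norms) != length(grades)) abort("norms/grades length mismatch")
  if (length(norms) < 3) abort("need at least 3 subjects")
  grades <- as.numeric(grades)
  if (length(unique(grades)) < 2) {
    abort("degenerate fit: all subjects share one severity grade")
  }
  fit <- lm(norms ~ grades)
  # R^2 from sums of squares directly (summary.lm warns on perfect fits)
  r2 <- 1 - sum(residuals(fit)^2) / sum((norms - mean(norms))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = length(norms), fit = fit),
    class = "severity_fit"
  )
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("severity fit: norm = %.3f + %.3f * grade, R2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Pearson correlation with p-value
#'
#' Pearson's r between two covariates (e.g. participant age and the
#' response norm) with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.
#' @return A tibble with columns `pearson_r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_with_p(1:10, 2 * (1:10) + 1)
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("x/y length mismatch")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
         n = length(x))
}

#' Replicate reproducibility (relative standard deviation)
#'
#' RSD of replicate response norms: sample standard deviation (n - 1
#' denominator) over the mean, as a percentage.
#'
#' @param norms Replicate Euclidean norms, n >= 2, nonzero mean.
#' @return A tibble with columns `rsd_pct`, `mean_norm`, `n`.
#' @export
#' @examples
#' rsd(c(98, 100, 102))
rsd <- function(norms) {
  if (length(norms) < 2) abort("RSD needs at least 2 replicates")
  m <- mean(norms)
  if (m == 0) abort("RSD undefined: replicate mean is zero")
  tibble(rsd_pct = 100 * sd(norms) / abs(m), mean_norm = m,
         n = length(norms))
}

#' Cohort-level clinical summary
#'
#' Convenience wrapper running the clinical layer on a cohort response
#' tibble: grades every subject from spirometry, fits the severity
#' regression for each severity-responsive element (S3 and S7 by
#' default, per element and combined), tests the age correlation within
#' each cohort, and reports per-cohort replicate RSD of the full-vector
#' norms.
#'
#' @param cohort A tibble from [generate_cohort_dataset()] or with the
#'   same columns.
#' @param severity_elements Elements whose norms are regressed on grade.
#' @return A list with `grades`, `severity_fits` (named list of
#'   `severity_fit`), `age_correlation` (tibble per cohort), and
#'   `reproducibility` (tibble per cohort).
#' @export
clinical_summary <- function(cohort, severity_elements = c("S3", "S7")) {
  grades <- grade_spirometry(cohort$fev1_pct, cohort$ratio_pct)
  grades$subject_id <- cohort$subject_id
  fits <- purrr::map(
    setNames(severity_elements, severity_elements),
    function(el) {
      norms <- response_norms(cohort, elements = el)$norm
      severity_regression(norms, cohort$grade_code)
    }
  )
  norms_all <- response_norms(cohort)$norm
  fits$combined <- severity_regression(
    response_norms(cohort, elements = severity_elements)$norm,
    cohort$grade_code)
  age_cor <- cohort |>
    dplyr::mutate(norm = norms_all) |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_modify(~ pearson_with_p(.x$age, .x$norm)) |>
    dplyr::ungroup()
  # replicate-level reproducibility: within a severity grade the
  # generator's subjects share one mean response, so the within-grade
  # spread of norms is the replicate noise, not biological signal
  repro <- cohort |>
    dplyr::mutate(norm = norms_all) |>
    dplyr::group_by(.data$cohort, .data$grade) |>
    dplyr::group_modify(~ rsd(.x$norm)) |>
    dplyr::ungroup()
  list(grades = as_tibble(grades), severity_fits = fits,
       age_correlation = age_cor, reproducibility = repro)
}
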