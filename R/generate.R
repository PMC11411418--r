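#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs of the simulated study: replicate count, target
#' replicate noise (as the relative standard deviation of Euclidean norms),
#' RNG seed, the volatile-compound panel, cohort sizes per severity grade,
#' and the participant age range.
#'
#' Defaults mirror the study design: 3 replicates per compound (9 x 3 = 27
#' VOC samples), ~5% replicate RSD, 36 controls plus 114 injured subjects
#' split evenly over mild/moderate/severe, ages 50-75.
#'
#' @param n_replicates Replicates per compound in VOC mode.
#' @param noise_rsd Target relative standard deviation of replicate
#'   Euclidean norms (fraction, e.g. 0.05).
#' @param seed Integer seed; fully determines generator output.
#' @param voc_panel Tibble of `compound`, `class`, `carbon_count`
#'   (default [default_voc_panel()]).
#' @param cohort_sizes Named counts for `control`, `mild`, `moderate`,
#'   `severe`.
#' @param age_range Length-2 numeric, participant ages (years).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_replicates = 3,
                             noise_rsd = 0.05,
                             seed = 1,
                             voc_panel = default_voc_panel(),
                             cohort_sizes = c(control = 36, mild = 38,
                                              moderate = 38, severe = 38),
                             age_range = c(50, 75)) {
  if (noise_rsd < 0) abort("noise_rsd must be >= 0")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (any(cohort_sizes < 0)) abort("cohort sizes must be >= 0")
  if (!all(c("compound", "class", "carbon_count") %in% names(voc_panel))) {
    abort("voc_panel needs columns compound, class, carbon_count")
  }
  structure(
    list(n_replicates = as.integer(n_replicates), noise_rsd = noise_rsd,
         seed = as.integer(seed), voc_panel = voc_panel,
         cohort_sizes = cohort_sizes, age_range = age_range),
    class = "generator_config"
  )
}

# additive Gaussian channel noise scaled so that the RSD of replicate
# Euclidean norms converges to noise_rsd (for small rsd the norm of
# mean + e, e ~ N(0, sd^2 I), has sd ~ channel sd)
noise_sd_for <- function(mean_vec, noise_rsd) {
  noise_rsd * sqrt(sum(mean_vec^2))
}

#' Generate a synthetic volatile-compound response matrix
#'
#' Simulates the corrected 36-feature response of the array to each
#' compound in the panel: the class mean triplet of every element, scaled
#' per element by its carbon-chain trend, plus zero-mean Gaussian channel
#' noise calibrated so replicate Euclidean norms have relative standard
#' deviation `noise_rsd`. With the default 9-compound panel and 3
#' replicates this yields the canonical 27 x 36 response matrix.
#'
#' @param config A [generator_config()].
#' @param profiles Response profiles (default [default_profiles()]).
#' @return A tibble with one row per (compound, replicate): `sample_id`,
#'   `compound`, `class`, `carbon_count`, `replicate`, then the 36
#'   feature columns of [response_cols()].
#' @export
#' @examples
#' voc <- generate_voc_dataset(generator_config(seed = 1))
#' dim(voc[, response_cols()])
generate_voc_dataset <- function(config = generator_config(),
                                 profiles = default_profiles()) {
  stopifnot(inherits(config, "generator_config"))
  validate_profiles(profiles)
  panel <- config$voc_panel[, c("compound", "class", "carbon_count")]
  if (nrow(panel) == 0) abort("voc_panel is empty")
  known <- c("alcohol", "aldehyde", "ester")
  bad <- setdiff(unique(panel$class), known)
  if (length(bad) > 0) {
    abort(paste0("unknown analyte class in panel: ", paste(bad, collapse = ", ")))
  }
  trends <- profiles[!duplicated(profiles$element),
                     c("element", "chain_slope")]
  trends <- trends[match(element_ids(), trends$element), ]
  class_min <- tapply(panel$carbon_count, panel$class, min)

  withr::with_seed(config$seed, {
    rows <- purrr::pmap_dfr(panel, function(compound, class, carbon_count) {
      scale <- 1 + trends$chain_slope * (carbon_count - class_min[[class]])
      mu <- profile_mean_vector(profiles, class, scale = scale)
      sdv <- noise_sd_for(mu, config$noise_rsd)
      purrr::map_dfr(seq_len(config$n_replicates), function(rep) {
        x <- mu + rnorm(36, 0, sdv)
        dplyr::bind_cols(
          tibble(compound = compound, class = class,
                 carbon_count = carbon_count, replicate = rep),
          as_tibble(as.list(x))
        )
      })
    })
  })
  rows <- dplyr::mutate(rows,
    sample_id = paste0(gsub(" ", "_", .data$compound), "_r", .data$replicate),
    .before = 1
  )
  rows
}

# spirometry sampling bands per grade, chosen strictly inside the
# diagnostic ranges so grading round-trips without boundary ambiguity
spiro_bands <- list(
  control  = list(fev1 = c(82, 115), ratio = c(72, 90)),
  mild     = list(fev1 = c(82, 110), ratio = c(45, 68)),
  moderate = list(fev1 = c(52, 78),  ratio = c(40, 68)),
  severe   = list(fev1 = c(32, 48),  ratio = c(30, 60))
)

#' Generate a synthetic urine-cohort response matrix
#'
#' Simulates one corrected response row per subject. Controls follow the
#' `urine_control` profile means; injured subjects at ordinal grade g
#' (mild 1, moderate 2, severe 3) follow
#' `urine_injured + severity_slope * g * urine_severity` per element, so
#' the severity-responsive elements (S3, S7 by default) are silent in
#' controls and grow linearly with injury grade. Spirometry values are
#' drawn inside the diagnostic band of each grade (FEV1 > 80 with
#' FEV1/FVC > 70 for controls; FEV1 > 80 with ratio < 70 for mild;
#' FEV1 50-80 moderate; 30-50 severe), and age is drawn independently of
#' the response, reproducing a null age effect.
#'
#' @inheritParams generate_voc_dataset
#' @return A tibble with one row per subject: `subject_id`, `cohort`
#'   (control/injured), `grade`, `grade_code` (0-3), `age`, `fev1_pct`,
#'   `ratio_pct`, then the 36 feature columns.
#' @export
#' @examples
#' cohort <- generate_cohort_dataset(generator_config(seed = 7))
#' dplyr::count(cohort, grade)
generate_cohort_dataset <- function(config = generator_config(),
                                    profiles = default_profiles()) {
  stopifnot(inherits(config, "generator_config"))
  validate_profiles(profiles)
  sizes <- config$cohort_sizes
  if (sum(sizes) == 0) abort("cohort_sizes are all zero")
  grades <- c(control = 0, mild = 1, moderate = 2, severe = 3)
  if (!all(names(sizes) %in% names(grades))) {
    abort("cohort_sizes names must be control, mild, moderate, severe")
  }

  sev_slope <- profiles[!duplicated(profiles$element),
                        c("element", "severity_slope")]
  sev_slope <- sev_slope$severity_slope[match(element_ids(),
                                              sev_slope$element)]
  # per-element severity increment, expanded to 36 channels
  sev_vec <- profile_mean_vector(profiles, "urine_severity",
                                 scale = sev_slope)
  ctrl_vec <- profile_mean_vector(profiles, "urine_control")
  inj_vec <- profile_mean_vector(profiles, "urine_injured")

  withr::with_seed(config$seed, {
    rows <- purrr::imap_dfr(sizes[sizes > 0], function(n, grade_name) {
      g <- grades[[grade_name]]
      mu <- if (g == 0) ctrl_vec else inj_vec + g * sev_vec
      sdv <- noise_sd_for(mu, config$noise_rsd)
      band <- spiro_bands[[grade_name]]
      purrr::map_dfr(seq_len(n), function(i) {
        x <- mu + rnorm(36, 0, sdv)
        dplyr::bind_cols(
          tibble(
            grade = grade_name,
            grade_code = g,
            cohort = if (g == 0) "control" else "injured",
            age = round(runif(1, config$age_range[1], config$age_range[2])),
            fev1_pct = round(runif(1, band$fev1[1], band$fev1[2]), 1),
            ratio_pct = round(runif(1, band$ratio[1], band$ratio[2]), 1)
          ),
          as_tibble(as.list(x))
        )
      })
    })
  })
  rows <- dplyr::mutate(rows,
    subject_id = sprintf("subj_%03d", dplyr::row_number()), .before = 1)
  rows$grade <- factor(rows$grade,
                       levels = c("control", "mild", "moderate", "severe"))
  rows
}

#' Simulate a condition-optimization scan
#'
#' Emulates the experiments that pick assay conditions: the class mean
#' responses are attenuated by an approach-to-equilibrium factor
#' `s(p) = 1 - exp(-p / midpoint)` of the scanned parameter (exposure
#' time, temperature above ambient, ...), a small VOC or cohort batch is
#' generated at each grid point, and the per-sample Euclidean norms are
#' returned in long format ready for [daf_curve()]. The resulting DAF
#' rises with the parameter and plateaus once `s(p)` saturates, the shape
#' on which the earliest-plateau operating-point rule acts.
#'
#' @inheritParams generate_voc_dataset
#' @param grid Strictly increasing numeric scan grid.
#' @param midpoint Time/temperature constant of the saturation factor, in
#'   grid units.
#' @param mode `"voc"` (groups = compound classes) or `"cohort"`
#'   (groups = control vs injured).
#' @return A long tibble with columns `parameter`, `group`, `norm`.
#' @export
#' @examples
#' scan <- generate_condition_scan(generator_config(seed = 1),
#'                                 grid = seq(15, 90, by = 15))
#' daf_curve(scan, "time", "norm", "group") |> attr("selected")
generate_condition_scan <- function(config = generator_config(),
                                    profiles = default_profiles(),
                                    grid = seq(15, 90, by = 15),
                                    midpoint = 15,
                                    mode = c("voc", "cohort")) {
  mode <- match.arg(mode)
  if (any(diff(grid) <= 0)) abort("scan grid must be strictly increasing")
  purrr::imap_dfr(grid, function(p, i) {
    s <- 1 - exp(-p / midpoint)
    scaled <- profiles
    scaled[, c("dR", "dG", "dB")] <- scaled[, c("dR", "dG", "dB")] * s
    # scanner noise is a fixed floor, not proportional to the attenuated
    # signal: inflate the relative noise at low saturation accordingly,
    # which is what makes the DAF rise and plateau along the scan
    sub <- generator_config(
      n_replicates = config$n_replicates,
      noise_rsd = config$noise_rsd / s,
      seed = config$seed + i,
      voc_panel = config$voc_panel,
      cohort_sizes = c(control = 5, mild = 5, moderate = 5, severe = 5),
      age_range = config$age_range
    )
    if (mode == "voc") {
      d <- response_norms(generate_voc_dataset(sub, scaled))
      tibble(parameter = p, group = d$class, norm = d$norm)
    } else {
      d <- response_norms(generate_cohort_dataset(sub, scaled))
      tibble(parameter = p, group = d$cohort, norm = d$norm)
    }
  })
}
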