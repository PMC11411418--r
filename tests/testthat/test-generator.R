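test_that("default VOC panel and replicates give the canonical 27 x 36 matrix", {
  voc <- generate_voc_dataset(generator_config(seed = 1))
  expect_equal(nrow(voc), 27)
  expect_equal(ncol(voc[, response_cols()]), 36)
  expect_equal(sort(unique(voc$class)), c("alcohol", "aldehyde", "ester"))
  expect_equal(unname(table(voc$compound)), rep(3L, 9), ignore_attr = TRUE)
})

test_that("zero noise, one replicate reproduces profile means with chain trends", {
  cfg <- generator_config(n_replicates = 1, noise_rsd = 0, seed = 5)
  voc <- generate_voc_dataset(cfg)
  expect_equal(nrow(voc), 9)
  row_of <- function(cmp) voc[voc$compound == cmp, ]
  # class-minimum carbon counts: trend factor is 1, means pass through
  expect_equal(row_of("ethanol")$S1_R, -60)
  expect_equal(row_of("ethanol")$S3_G, 25)
  expect_equal(row_of("acetaldehyde")$S6_R, 45)
  expect_equal(row_of("ethyl acetate")$S4_B, 25)
  # chain trend: 4 carbons beyond the class minimum
  expect_equal(row_of("hexanaldehyde")$S6_R, 45 * (1 + 0.15 * 4))
  expect_equal(row_of("hexanaldehyde")$S7_R, -55 * (1 - 0.08 * 4))
  expect_equal(row_of("hexanaldehyde")$S8_B, 35 * (1 - 0.08 * 4))
  # elements without a chain trend are untouched by carbon count
  expect_equal(row_of("hexanol")$S1_R, row_of("ethanol")$S1_R)
})

test_that("the generator is seed-deterministic", {
  a <- generate_voc_dataset(generator_config(seed = 11))
  b <- generate_voc_dataset(generator_config(seed = 11))
  c <- generate_voc_dataset(generator_config(seed = 12))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a[, response_cols()], c[, response_cols()])))
  d <- generate_cohort_dataset(generator_config(seed = 11))
  e <- generate_cohort_dataset(generator_config(seed = 11))
  expect_identical(d, e)
})

test_that("replicate norm RSD converges to the configured noise level", {
  cfg <- generator_config(n_replicates = 200, noise_rsd = 0.05, seed = 2)
  voc <- response_norms(generate_voc_dataset(cfg))
  per_compound <- tapply(voc$norm, voc$compound,
                         function(x) 100 * sd(x) / mean(x))
  # target 5%, checked within +/-20% relative at n = 200
  expect_true(all(per_compound > 4 & per_compound < 6))
})

test_that("cohort generator respects sizes, spirometry bands and grade codes", {
  cohort <- generate_cohort_dataset(generator_config(seed = 7))
  expect_equal(nrow(cohort), 150)
  counts <- table(cohort$grade)
  expect_equal(unname(counts), c(36L, 38L, 38L, 38L), ignore_attr = TRUE)
  expect_equal(sort(unique(cohort$grade_code)), 0:3)
  # printed diagnostic bands per grade
  with_grade <- split(cohort, cohort$grade)
  expect_true(all(with_grade$control$fev1_pct > 80 &
                    with_grade$control$ratio_pct > 70))
  expect_true(all(with_grade$mild$fev1_pct > 80 &
                    with_grade$mild$ratio_pct < 70))
  expect_true(all(with_grade$moderate$fev1_pct >= 50 &
                    with_grade$moderate$fev1_pct <= 80))
  expect_true(all(with_grade$severe$fev1_pct >= 30 &
                    with_grade$severe$fev1_pct < 50))
  # spirometry re-grading recovers the generated grade for every subject
  regraded <- grade_spirometry(cohort$fev1_pct, cohort$ratio_pct)
  expect_identical(as.character(regraded$grade), as.character(cohort$grade))
})

test_that("null severity slope silences the injury-specific elements", {
  prof <- default_profiles()
  prof$severity_slope[] <- 0
  cfg <- generator_config(noise_rsd = 0, seed = 3,
                          cohort_sizes = c(control = 4, mild = 4,
                                           moderate = 4, severe = 4))
  cohort <- generate_cohort_dataset(cfg, prof)
  s37 <- response_cols()[rep(element_ids(), each = 3) %in% c("S3", "S7")]
  expect_true(all(as.matrix(cohort[, s37]) == 0))
})

test_that("noiseless severity response is exactly collinear with grade", {
  cfg <- generator_config(noise_rsd = 0, seed = 3,
                          cohort_sizes = c(control = 0, mild = 3,
                                           moderate = 3, severe = 3))
  cohort <- generate_cohort_dataset(cfg)
  norms <- response_norms(cohort, elements = "S3")$norm
  fit <- severity_regression(norms, cohort$grade_code)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("age is generated independently of the response (null age effect)", {
  pvals <- sapply(1:5, function(s) {
    cohort <- generate_cohort_dataset(generator_config(seed = 100 + s))
    norms <- response_norms(cohort)$norm
    min(
      pearson_with_p(cohort$age[cohort$cohort == "control"],
                     norms[cohort$cohort == "control"])$p_value,
      pearson_with_p(cohort$age[cohort$cohort == "injured"],
                     norms[cohort$cohort == "injured"])$p_value
    )
  })
  # no significant age correlation in at least 4 of 5 seeds (a single
  # false positive at alpha = 0.05 over 10 tests is unremarkable)
  expect_gte(sum(pvals > 0.05), 4)
})

test_that("doubling class separation never hurts downstream clustering", {
  for (s in 1:3) {
    accs <- sapply(c(1, 2), function(scale) {
      prof <- default_profiles()
      prof[, c("dR", "dG", "dB")] <- prof[, c("dR", "dG", "dB")] * scale / 2
      # fixed absolute noise floor: rsd inversely scaled with the signal
      cfg <- generator_config(seed = 40 + s, noise_rsd = 0.45 / scale)
      run_hca(generate_voc_dataset(cfg, prof), 3,
              label_col = "class")$matched_accuracy
    })
    expect_gte(accs[2], accs[1])
  }
})

test_that("generator config validates its inputs", {
  expect_error(generator_config(noise_rsd = -0.1), "noise_rsd")
  expect_error(generator_config(n_replicates = 0), "n_replicates")
  expect_error(generator_config(cohort_sizes = c(control = -1, mild = 1,
                                                 moderate = 1, severe = 1)),
               "cohort")
  bad_panel <- tibble::tibble(compound = "acetone", class = "ketone",
                              carbon_count = 3)
  expect_error(generate_voc_dataset(generator_config(voc_panel = bad_panel)),
               "unknown analyte class")
})
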