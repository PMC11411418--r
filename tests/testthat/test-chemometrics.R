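test_that("PCA on collinear data loads everything on one component", {
  base <- withr::with_seed(1, rnorm(36))
  m <- outer(seq(-2, 2, length.out = 8), base)
  data <- tibble::as_tibble(setNames(as.data.frame(m), response_cols()))
  fit <- run_pca(data, k = 3)
  expect_equal(fit$explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(fit$explained_all), 1, tolerance = 1e-12)
})

test_that("duplicated samples get identical scores", {
  voc <- generate_voc_dataset(generator_config(seed = 2))
  dup <- dplyr::bind_rows(voc, voc[3, ])
  fit <- run_pca(dup, k = 2)
  expect_equal(as.numeric(fit$scores[nrow(dup), c("PC1", "PC2")]),
               as.numeric(fit$scores[3, c("PC1", "PC2")]),
               tolerance = 1e-10)
})

test_that("PCA scores match a covariance eigendecomposition oracle up to sign", {
  m <- withr::with_seed(5, matrix(rnorm(20), 5, 4))
  full <- cbind(m, matrix(0, 5, 32))
  data <- tibble::as_tibble(setNames(as.data.frame(full), response_cols()))
  fit <- run_pca(data, k = 4)
  centered <- scale(full, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centered))
  oracle_scores <- centered %*% eig$vectors[, 1:4]
  got <- as.matrix(fit$scores[, paste0("PC", 1:4)])
  for (j in 1:4) {
    expect_true(
      isTRUE(all.equal(got[, j], oracle_scores[, j], tolerance = 1e-8,
                       check.attributes = FALSE)) ||
      isTRUE(all.equal(got[, j], -oracle_scores[, j], tolerance = 1e-8,
                       check.attributes = FALSE))
    )
  }
  # explained fractions from eigenvalues
  expect_equal(fit$explained,
               (eig$values / sum(eig$values))[1:4], tolerance = 1e-10)
  expect_error(run_pca(data, k = 40), "k exceeds")
})

test_that("well-separated point clouds cluster with perfect matched accuracy", {
  centers <- rbind(rep(0, 36), rep(100, 36), rep(c(-100, 100), 18))
  m <- do.call(rbind, lapply(1:3, function(i) {
    withr::with_seed(i, sweep(matrix(rnorm(10 * 36), 10), 2,
                              centers[i, ], "+"))
  }))
  data <- tibble::as_tibble(setNames(as.data.frame(m), response_cols()))
  data$class <- rep(c("a", "b", "c"), each = 10)
  hca <- run_hca(data, n_clusters = 3, label_col = "class")
  expect_equal(hca$matched_accuracy, 100)
  expect_s3_class(hca$tree, "hclust")
})

test_that("matched accuracy equals the exhaustive assignment oracle on the VOC matrix", {
  voc <- generate_voc_dataset(generator_config(seed = 1))
  hca <- run_hca(voc, n_clusters = 3, label_col = "class")
  cl <- hca$clusters$cluster
  classes <- unique(voc$class)
  # brute force over all 3! cluster -> class bijections
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- max(sapply(perms, function(p) {
    sum(classes[p[cl]] == voc$class)
  }))
  expect_equal(hca$matched_accuracy, 100 * best / nrow(voc))
})

test_that("matched accuracy is invariant to cluster relabeling", {
  classes <- rep(c("x", "y", "z"), each = 5)
  cl <- rep(1:3, each = 5)
  base <- chromanose:::matched_accuracy(cl, classes)
  relabeled <- c(3, 1, 2)[cl]
  expect_equal(chromanose:::matched_accuracy(relabeled, classes), base)
  expect_equal(base, 100)
})

test_that("degenerate identical-point clustering is deterministic", {
  m <- matrix(5, nrow = 6, ncol = 36)
  data <- tibble::as_tibble(setNames(as.data.frame(m), response_cols()))
  a <- run_hca(data, n_clusters = 2)
  b <- run_hca(data, n_clusters = 2)
  expect_identical(a$clusters$cluster, b$clusters$cluster)
  expect_error(run_hca(data, n_clusters = 1), "n_clusters")
  expect_error(run_hca(data[1:2, ], n_clusters = 3), "fewer samples")
})

test_that("dendrograms serialize to Newick text", {
  voc <- generate_voc_dataset(generator_config(seed = 1))
  hca <- run_hca(voc, n_clusters = 3)
  expect_type(hca$newick, "character")
  expect_match(hca$newick, "^\\(.*\\);$")
})

test_that("confusion-matrix metrics match hand formulas", {
  id <- diag(c(5, 7, 9))
  dimnames(id) <- list(letters[1:3], letters[1:3])
  rep_id <- report_metrics(id)
  expect_equal(rep_id$accuracy, 100)
  expect_equal(rep_id$per_class$sensitivity_pct, rep(100, 3))
  expect_equal(rep_id$per_class$specificity_pct, rep(100, 3))

  cm <- matrix(c(39, 11, 10, 40), 2, byrow = TRUE,
               dimnames = list(c("control", "injured"),
                               c("control", "injured")))
  r <- report_metrics(cm)
  expect_equal(r$accuracy, 79)
  expect_equal(r$error_rate, 21)
  expect_equal(r$accuracy + r$error_rate, 100)
  # sensitivity = diag / row sum; specificity = TN / (TN + FP)
  expect_equal(r$per_class$sensitivity_pct, c(100 * 39 / 50, 100 * 40 / 50))
  expect_equal(r$per_class$specificity_pct, c(100 * 40 / 50, 100 * 39 / 50))
  # two-class mirror: sensitivity of one class is specificity of the other
  expect_equal(r$per_class$sensitivity_pct[1], r$per_class$specificity_pct[2])

  one_sided <- matrix(c(10, 0, 12, 0), 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), c("a", "b")))
  r1 <- report_metrics(one_sided)
  expect_equal(r1$per_class$sensitivity_pct, c(100, 0))
  expect_error(report_metrics(matrix(0, 0, 0)), "empty")
  expect_error(report_metrics(matrix(1, 2, 3)), "square")
})

test_that("PCA-LDA separates noiseless linearly separable cohorts perfectly", {
  cfg <- generator_config(noise_rsd = 0.01, seed = 8,
                          cohort_sizes = c(control = 15, mild = 5,
                                           moderate = 5, severe = 5))
  cohort <- generate_cohort_dataset(cfg)
  r <- pca_lda_classify(cohort, "cohort")
  expect_equal(r$accuracy, 100)
  expect_equal(r$error_rate, 0)
  rs <- pca_lda_classify(cohort, "cohort", cv = "resubstitution")
  expect_equal(rs$accuracy, 100)
})

test_that("label-permuted PCA-LDA accuracy stays near chance", {
  cfg <- generator_config(seed = 9, cohort_sizes = c(control = 30, mild = 10,
                                                     moderate = 10, severe = 10))
  cohort <- generate_cohort_dataset(cfg)
  cohort$shuffled <- withr::with_seed(99, sample(cohort$cohort))
  r <- pca_lda_classify(cohort, "shuffled", k = 3)
  n <- nrow(cohort)
  band <- 3 * sqrt(0.25 / n) * 100
  expect_lt(abs(r$accuracy - 50), band + 10)  # generous null band
})

test_that("PCA-LDA validates class sizes and k", {
  voc <- generate_voc_dataset(generator_config(seed = 1))
  solo <- voc[c(1, 4:27), ]  # one class member alone
  solo$one <- c("only", rep("rest", 24))
  expect_error(pca_lda_classify(solo, "one"), "at least 2 samples")
  cohort <- generate_cohort_dataset(generator_config(
    seed = 2, cohort_sizes = c(control = 5, mild = 5, moderate = 0, severe = 0)))
  expect_error(pca_lda_classify(cohort, "cohort", k = 20), "smaller than n")
})

test_that("tidy and glance methods expose the fitted summaries", {
  voc <- generate_voc_dataset(generator_config(seed = 1))
  pca <- run_pca(voc, k = 2, label_col = "class")
  expect_named(glance(pca),
               c("n_samples", "k", "explained_pc1", "explained_pc2",
                 "explained_total"))
  expect_true(all(c("PC1", "PC2", "class") %in% names(tidy(pca))))
  hca <- run_hca(voc, 3, label_col = "class")
  expect_equal(glance(hca)$matched_accuracy_pct, hca$matched_accuracy)
  p <- autoplot(pca)
  expect_s3_class(p, "ggplot")
})
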