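#' Principal component analysis of a response matrix
#'
#' Mean-centered (optionally autoscaled) PCA of the 36 feature columns.
#' RGB channels share units, so centering without autoscaling is the
#' default.
#'
#' @param data Response tibble containing the [response_cols()] columns.
#' @param k Number of components to retain (default
#'   `min(n - 1, 36)`).
#' @param scaling `"none"` (mean-centering only, default) or
#'   `"autoscale"` (unit variance per feature).
#' @param label_col Optional metadata column carried into the scores
#'   tibble for plotting.
#' @return An object of class `sensor_pca`: list with `scores` (tibble of
#'   `sample`, optional label, `PC1..PCk`), `explained` (variance
#'   fractions per retained component), `loadings`, and the `prcomp` fit.
#' @export
#' @examples
#' voc <- generate_voc_dataset(generator_config(seed = 1))
#' fit <- run_pca(voc, k = 2, label_col = "class")
#' glance(fit)
run_pca <- function(data, k = NULL, scaling = c("none", "autoscale"),
                    label_col = NULL) {
  scaling <- match.arg(scaling)
  m <- response_matrix_values(data)
  n <- nrow(m)
  if (n < 2) abort("PCA needs at least 2 samples")
  kmax <- min(n - 1, ncol(m))
  k <- k %||% kmax
  if (k > min(n, ncol(m))) abort("k exceeds min(n, n_features)")
  fit <- prcomp(m, center = TRUE, scale. = (scaling == "autoscale"))
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(k, ncol(fit$x))
  scores <- as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample = seq_len(n)), scores)
  if (!is.null(label_col)) {
    if (!label_col %in% names(data)) abort(paste0("label column not found: ", label_col))
    scores[[label_col]] <- data[[label_col]]
  }
  structure(
    list(scores = scores, explained = expl[seq_len(k)],
         explained_all = expl,
         loadings = fit$rotation[, seq_len(k), drop = FALSE],
         fit = fit, scaling = scaling, label_col = label_col),
    class = "sensor_pca"
  )
}

#' @export
print.sensor_pca <- function(x, ...) {
  cat("PCA of sensor responses:", nrow(x$scores), "samples,",
      length(x$explained), "components retained\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# best one-to-one cluster<->class assignment accuracy, exact search
matched_accuracy <- function(clusters, classes) {
  tab <- table(clusters, classes)
  k <- max(dim(tab))
  if (k > 8) abort("matched accuracy supports at most 8 clusters/classes")
  # pad to square so unmatched clusters/classes score zero
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- permutations(k)
  best <- max(apply(perms, 1, function(p) sum(sq[cbind(seq_len(k), p)])))
  100 * best / length(clusters)
}

#' Hierarchical cluster analysis with label-matched accuracy
#'
#' Agglomerative clustering of the 36-feature responses using Ward's
#' criterion on Euclidean distances (`hclust` method `"ward.D2"`), cut at
#' `n_clusters`. When true class labels are supplied, the "total
#' accuracy" of the clustering is the fraction of samples falling in
#' their class's cluster under the best one-to-one cluster-to-class
#' assignment (exact search over assignments, so the score is
#' well-defined and invariant to cluster relabeling).
#'
#' @param data Response tibble.
#' @param n_clusters Number of clusters to cut the tree into.
#' @param label_col Optional metadata column of true classes.
#' @param linkage `hclust` agglomeration method; default `"ward.D2"`.
#' @return An object of class `sensor_hca`: list with `clusters` (tibble
#'   of `sample`, optional label, `cluster`), `matched_accuracy` (% or
#'   `NA` without labels), the `hclust` tree, and `newick` (dendrogram as
#'   a Newick string when the ape package is available).
#' @export
#' @examples
#' voc <- generate_voc_dataset(generator_config(seed = 1))
#' hca <- run_hca(voc, n_clusters = 3, label_col = "class")
#' hca$matched_accuracy
run_hca <- function(data, n_clusters = 3, label_col = NULL,
                    linkage = "ward.D2") {
  m <- response_matrix_values(data)
  if (n_clusters < 2) abort("n_clusters must be >= 2")
  if (nrow(m) < n_clusters) abort("fewer samples than clusters")
  tree <- hclust(dist(m), method = linkage)
  cl <- cutree(tree, k = n_clusters)
  clusters <- tibble(sample = seq_len(nrow(m)), cluster = as.integer(cl))
  acc <- NA_real_
  if (!is.null(label_col)) {
    if (!label_col %in% names(data)) abort(paste0("label column not found: ", label_col))
    clusters[[label_col]] <- as.character(data[[label_col]])
    acc <- matched_accuracy(cl, clusters[[label_col]])
  }
  newick <- NULL
  if (requireNamespace("ape", quietly = TRUE)) {
    phylo <- ape::as.phylo(tree)
    phylo$tip.label <- paste0("s", seq_len(nrow(m)))
    newick <- ape::write.tree(phylo)
  }
  structure(
    list(clusters = clusters, matched_accuracy = acc, tree = tree,
         newick = newick, n_clusters = n_clusters, label_col = label_col),
    class = "sensor_hca"
  )
}

#' @export
print.sensor_hca <- function(x, ...) {
  cat("Ward HCA:", nrow(x$clusters), "samples in", x$n_clusters, "clusters\n")
  if (!is.na(x$matched_accuracy)) {
    cat(sprintf("matched accuracy: %.1f%%\n", x$matched_accuracy))
  }
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (trace over total, %), error rate, and per-class sensitivity
#' (recall: diagonal over true-class row sum) and specificity
#' (true-negative rate: correct rejections of the class over all
#' non-class samples). For two classes, sensitivity of one class equals
#' specificity of the other.
#'
#' @param confusion Square count matrix, true classes in rows, predicted
#'   in columns, with matching dimnames.
#' @return An object of class `classification_report`: list with
#'   `confusion`, `accuracy`, `error_rate`, and a `per_class` tibble of
#'   `class`, `sensitivity_pct`, `specificity_pct`.
#' @export
#' @examples
#' cm <- matrix(c(39, 11, 10, 40), 2, byrow = TRUE,
#'              dimnames = list(c("control", "injured"),
#'                              c("control", "injured")))
#' report_metrics(cm)$accuracy
report_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0) abort("empty confusion matrix")
  if (nrow(confusion) != ncol(confusion)) abort("confusion matrix must be square")
  if (any(confusion < 0)) abort("confusion counts must be non-negative")
  n <- sum(confusion)
  if (n == 0) abort("confusion matrix has no counts")
  classes <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  acc <- 100 * sum(diag(confusion)) / n
  per_class <- purrr::map_dfr(seq_along(classes), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- n - tp - fn - fp
    tibble(
      class = classes[i],
      sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity_pct = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    )
  })
  structure(
    list(confusion = confusion, accuracy = acc, error_rate = 100 - acc,
         per_class = per_class, n = n),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Accuracy (%%): %.1f, error rate (%%): %.1f\n",
              x$accuracy, x$error_rate))
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

# components explaining >= threshold cumulative variance, with caps
choose_k <- function(sdev, n, n_classes, threshold = 0.95) {
  expl <- cumsum(sdev^2) / sum(sdev^2)
  k <- which(expl >= threshold)[1]
  if (is.na(k)) k <- length(sdev)
  max(1, min(k, n - n_classes - 1))
}

#' PCA-LDA classification with leave-one-out cross-validation
#'
#' The discrimination pipeline for cohort data: principal components are
#' fitted on the training samples of each fold, linear discriminant
#' analysis is trained on the retained scores, and the held-out sample is
#' projected and predicted. Pooled out-of-fold predictions form the
#' confusion matrix and the accuracy / sensitivity / specificity report.
#' The number of retained components defaults to those explaining at
#' least 95% of training variance, capped at `n - n_classes - 1`. A
#' resubstitution mode (fit and predict on all samples) is available for
#' comparison; it is optimistic and not the default.
#'
#' @param data Response tibble.
#' @param label_col Metadata column holding the true class of each
#'   sample.
#' @param k Number of principal components; `NULL` for the variance rule.
#' @param cv `"loo"` (leave-one-out, default) or `"resubstitution"`.
#' @return An object of class `classification_report` (see
#'   [report_metrics()]) with an added `predictions` tibble
#'   (`sample`, `truth`, `predicted`) and `k_used`.
#' @export
#' @examples
#' cohort <- generate_cohort_dataset(generator_config(seed = 3))
#' rep <- pca_lda_classify(cohort, "cohort")
#' rep$accuracy
pca_lda_classify <- function(data, label_col, k = NULL,
                             cv = c("loo", "resubstitution")) {
  cv <- match.arg(cv)
  m <- response_matrix_values(data)
  if (!label_col %in% names(data)) abort(paste0("label column not found: ", label_col))
  y <- factor(as.character(data[[label_col]]))
  if (any(table(y) < 2)) abort("every class needs at least 2 samples")
  n <- nrow(m)
  classes <- levels(y)

  fit_predict <- function(train_idx, test_idx) {
    ytr <- droplevels(y[train_idx])
    if (nlevels(ytr) < 2) return(NULL)  # class collapsed in this fold
    pca <- prcomp(m[train_idx, , drop = FALSE], center = TRUE)
    kk <- k %||% choose_k(pca$sdev, length(train_idx), nlevels(ytr))
    kk <- min(kk, ncol(pca$x))
    if (!is.null(k) && k >= length(train_idx) - 1) {
      abort("k must be smaller than n - 1")
    }
    scores <- pca$x[, seq_len(kk), drop = FALSE]
    lda_fit <- MASS::lda(scores, grouping = ytr)
    test_scores <- scale(m[test_idx, , drop = FALSE], center = pca$center,
                         scale = FALSE) %*% pca$rotation[, seq_len(kk), drop = FALSE]
    list(pred = as.character(predict(lda_fit, test_scores)$class), k = kk)
  }

  if (cv == "resubstitution") {
    res <- fit_predict(seq_len(n), seq_len(n))
    preds <- tibble(sample = seq_len(n), truth = as.character(y),
                    predicted = res$pred)
    k_used <- res$k
  } else {
    skipped <- 0L
    out <- purrr::map(seq_len(n), function(i) {
      res <- fit_predict(setdiff(seq_len(n), i), i)
      if (is.null(res)) return(NULL)
      tibble(sample = i, truth = as.character(y[i]), predicted = res$pred,
             k = res$k)
    })
    dropped <- sum(purrr::map_lgl(out, is.null))
    if (dropped > 0) {
      warn(paste0(dropped, " fold(s) skipped: a class collapsed in training"))
    }
    preds <- dplyr::bind_rows(out)
    k_used <- if (nrow(preds)) round(mean(preds$k)) else NA_integer_
    preds$k <- NULL
  }
  cm <- table(factor(preds$truth, levels = classes),
              factor(preds$predicted, levels = classes))
  report <- report_metrics(unclass(as.matrix(cm)))
  report$predictions <- preds
  report$k_used <- k_used
  report$cv <- cv
  report
}
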