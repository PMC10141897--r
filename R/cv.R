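# Cross-validation experiments: leave-one-patient-out evaluation of the
# PCA/LDA classifier, the adversarial patient-identity experiment, and
# unsupervised exploration.

#' Map ROI metadata to class labels
#'
#' The labelling schemes used by the classification experiments:
#' `six_class` keeps the tissue-region label; `binary_tumour` maps AdC to
#' `"adenocarcinoma"` and every other region to `"non_neoplastic"`;
#' `patient_id`, `lvi` and `sex` copy the corresponding metadata column.
#'
#' @param rois ROI data frame (see [sample_rois()], [label_rois()]).
#' @param scheme One of `"six_class"`, `"binary_tumour"`, `"patient_id"`,
#'   `"lvi"`, `"sex"`.
#' @return A factor, one label per ROI.
#' @export
map_labels <- function(rois, scheme = c("six_class", "binary_tumour",
                                        "patient_id", "lvi", "sex")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    six_class = factor(rois$region),
    binary_tumour = factor(ifelse(rois$region == "AdC", "adenocarcinoma",
                                  "non_neoplastic"),
                           levels = c("adenocarcinoma", "non_neoplastic")),
    patient_id = factor(rois$patient_id),
    lvi = factor(rois$lvi),
    sex = factor(rois$sex))
}

cv_result <- function(confusion, folds, n_pca_effective = NA,
                      pos_class = NULL) {
  total <- sum(confusion)
  acc <- sum(diag(confusion)) / total
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  sens <- spec <- NA_real_
  if (nrow(confusion) == 2) {
    pos <- pos_class %||%
      (if ("adenocarcinoma" %in% rownames(confusion)) "adenocarcinoma"
       else rownames(confusion)[1])
    neg <- setdiff(rownames(confusion), pos)
    sens <- per_class[pos]
    spec <- per_class[neg]
  }
  structure(list(confusion = confusion, accuracy = acc,
                 per_class = per_class, sensitivity = unname(sens),
                 specificity = unname(spec), folds = folds,
                 n_pca_effective = n_pca_effective),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: accuracy %.4f over %d folds", x$accuracy,
              length(x$folds)))
  if (!is.na(x$sensitivity)) {
    cat(sprintf(", sensitivity %.3f, specificity %.3f", x$sensitivity,
                x$specificity))
  }
  cat(">\n")
  print(x$confusion)
  invisible(x)
}

empty_confusion <- function(truth_levels, pred_levels) {
  matrix(0L, length(truth_levels), length(pred_levels),
         dimnames = list(truth = truth_levels, predicted = pred_levels))
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: the model is trained on the ROIs of the other
#' patients and tested on the held-out patient's ROIs, so no patient
#' contributes to both sides of any fold. With `test_set = "biopsy"` the
#' model is trained only on the cross-section ROIs of the other patients
#' and tested on the held-out patient's biopsy ROIs, mirroring the
#' biopsy-transfer design. Confusion counts are accumulated over folds.
#'
#' @param fm A [feature_matrix()].
#' @param labels Class label per ROI row (e.g. from [map_labels()]).
#' @param n_pca,lda_dims Passed to [pcalda()].
#' @param test_set `"same"` (test on the held-out patient's rows of `fm`)
#'   or `"biopsy"` (train on cross sections, test on biopsies).
#' @return A `"cv_result"`: confusion matrix (rows = truth), overall
#'   accuracy, per-class rates, sensitivity/specificity for binary tasks,
#'   fold assignments, and the effective PCA dimension.
#' @export
lopo_cv <- function(fm, labels, n_pca = 1000, lda_dims = NULL,
                    test_set = c("same", "biopsy")) {
  test_set <- match.arg(test_set)
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- factor(labels)
  patients <- fm$rois$patient_id
  ids <- unique(patients)
  if (length(ids) < 2) stop("at least two patients required", call. = FALSE)
  conf <- empty_confusion(levels(labels), levels(labels))
  folds <- list()
  eff <- integer(0)
  for (pid in ids) {
    if (test_set == "same") {
      train <- which(patients != pid)
      test <- which(patients == pid)
    } else {
      train <- which(patients != pid & fm$rois$sample_kind == "cross_section")
      test <- which(patients == pid & fm$rois$sample_kind == "biopsy")
    }
    if (!length(test)) next
    tr_lab <- droplevels(labels[train])
    if (nlevels(tr_lab) < 2) {
      stop("training fold for patient ", pid, " collapses to one class",
           call. = FALSE)
    }
    fit <- pcalda(fm$x[train, , drop = FALSE], tr_lab, n_pca = n_pca,
                  lda_dims = lda_dims)
    pred <- predict(fit, fm$x[test, , drop = FALSE])$class
    conf <- conf + as.matrix(table(factor(labels[test], levels(labels)),
                                   factor(as.character(pred), levels(labels))))
    folds[[pid]] <- list(train = train, test = test)
    eff <- c(eff, fit$n_pca_effective)
  }
  cv_result(conf, folds, n_pca_effective = max(eff))
}

# Random folds stratified by class frequency: each class's rows are
# shuffled and dealt round-robin across folds.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (l in unique(labels)) {
      idx <- sample(which(labels == l))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Adversarial patient-identity experiment
#'
#' Tries to predict which patient a tumour ROI came from, using PCA
#' followed by one-dimensional LDA under ROI-level (not patient-level)
#' stratified k-fold cross-validation. High accuracy relative to chance
#' (one over the number of patients) indicates patient-level batch
#' structure in the spectra.
#'
#' @param fm A [feature_matrix()]; only rows with region `"AdC"` are used.
#' @param n_pca PCA components requested (default 1000).
#' @param n_folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return A `"cv_result"` whose `accuracy` is the overall patient-ID
#'   accuracy.
#' @export
adversarial_patient_cv <- function(fm, n_pca = 1000, n_folds = 10,
                                   seed = 1L) {
  rows <- which(fm$rois$region == "AdC")
  if (!length(rows)) stop("no AdC rows in feature matrix", call. = FALSE)
  x <- fm$x[rows, , drop = FALSE]
  labels <- factor(fm$rois$patient_id[rows])
  if (nlevels(labels) < 2) {
    stop("at least two patients with AdC ROIs required", call. = FALSE)
  }
  fold <- stratified_folds(labels, n_folds, seed)
  conf <- empty_confusion(levels(labels), levels(labels))
  folds <- list()
  eff <- integer(0)
  for (f in sort(unique(fold))) {
    train <- which(fold != f); test <- which(fold == f)
    fit <- pcalda(x[train, , drop = FALSE], droplevels(labels[train]),
                  n_pca = n_pca, lda_dims = 1)
    pred <- predict(fit, x[test, , drop = FALSE])$class
    conf <- conf + as.matrix(table(factor(labels[test], levels(labels)),
                                   factor(as.character(pred), levels(labels))))
    folds[[as.character(f)]] <- list(train = rows[train], test = rows[test])
    eff <- c(eff, fit$n_pca_effective)
  }
  cv_result(conf, folds, n_pca_effective = max(eff))
}

#' Rank single ions by patient-prediction accuracy
#'
#' For each bin independently, a one-dimensional LDA predicts the patient
#' of origin of tumour ROIs under ROI-stratified k-fold cross-validation;
#' bins are ranked by accuracy. Ions that identify patients flag
#' patient-associated (rather than tissue-associated) variation.
#'
#' @inheritParams adversarial_patient_cv
#' @return Data frame `center`, `accuracy`, sorted descending.
#' @export
single_ion_patient_cv <- function(fm, n_folds = 10, seed = 1L) {
  rows <- which(fm$rois$region == "AdC")
  labels <- factor(fm$rois$patient_id[rows])
  if (nlevels(labels) < 2) {
    stop("at least two patients with AdC ROIs required", call. = FALSE)
  }
  fold <- stratified_folds(labels, n_folds, seed)
  acc <- vapply(seq_len(ncol(fm$x)), function(j) {
    xj <- fm$x[rows, j, drop = FALSE]
    correct <- 0L
    for (f in sort(unique(fold))) {
      train <- which(fold != f); test <- which(fold == f)
      fit <- tryCatch(
        fisher_lda(xj[train, , drop = FALSE], droplevels(labels[train]), 1),
        error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, xj[test, , drop = FALSE])$class
      correct <- correct + sum(as.character(pred) ==
                                 as.character(labels[test]))
    }
    correct / length(rows)
  }, 0)
  out <- data.frame(center = fm$bins$center, accuracy = acc)
  out[order(-out$accuracy), ]
}

#' Unsupervised k-means exploration
#'
#' Standard k-means on ROI profiles with a fixed seed, for comparison of
#' cluster structure with the histology annotation (via
#' [adjusted_rand_index()]).
#'
#' @param x Numeric matrix or [feature_matrix()].
#' @param k Number of clusters (`2 <= k <= rows`).
#' @param seed RNG seed.
#' @return Integer cluster label per row.
#' @export
kmeans_explore <- function(x, k, seed = 1L) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k must not exceed the number of rows", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  with_seed(seed, {
    if (k == nrow(x)) {
      # degenerate case: every row its own cluster
      return(seq_len(nrow(x)))
    }
    stats::kmeans(x, centers = k, nstart = 10, iter.max = 50)$cluster
  })
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index (1 for identical partitions, about 0
#'   for independent ones).
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
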