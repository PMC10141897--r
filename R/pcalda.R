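# The core classifier: principal-component reduction followed by Fisher
# linear discriminant analysis. PCA is refit on every training set (so
# cross-validation folds never see test pixels), components are capped at
# the data rank, and the LDA uses a pooled within-class covariance with
# automatic shrinkage because class sizes can be smaller than the
# retained dimension.

# Pooled-covariance Fisher LDA with automatic ridge shrinkage.
fisher_lda <- function(x, grouping, dims = NULL) {
  x <- as.matrix(x)
  grouping <- droplevels(factor(grouping))
  K <- nlevels(grouping)
  if (K < 2) stop("LDA requires at least two classes", call. = FALSE)
  p <- ncol(x)
  n <- nrow(x)
  dims <- min(dims %||% (K - 1L), K - 1L, p)
  counts <- table(grouping)
  means <- matrix(0, K, p)
  for (k in seq_len(K)) {
    means[k, ] <- colMeans(x[grouping == levels(grouping)[k], , drop = FALSE])
  }
  grand <- colMeans(x)
  # pooled within-class scatter (singleton classes contribute nothing)
  Sw <- matrix(0, p, p)
  for (l in levels(grouping)) {
    xi <- x[grouping == l, , drop = FALSE]
    if (nrow(xi) > 1) {
      Sw <- Sw + crossprod(sweep(xi, 2, colMeans(xi)))
    }
  }
  Sw <- Sw / max(n - K, 1)
  Sb <- crossprod(sweep(means, 2, grand) * sqrt(as.vector(counts)))
  # shrink towards a scaled identity until the within scatter is invertible
  tr <- mean(diag(Sw))
  if (tr <= 0) tr <- 1
  lambda <- 0
  repeat {
    Sw_reg <- (1 - lambda) * Sw + lambda * tr * diag(p)
    R <- tryCatch(chol(Sw_reg), error = function(e) NULL)
    if (!is.null(R) && min(diag(R))^2 > tr * 1e-10) break
    lambda <- if (lambda == 0) 1e-8 else lambda * 100
    if (lambda > 0.5) stop("within-class scatter irreparably singular",
                           call. = FALSE)
  }
  M <- backsolve(R, forwardsolve(t(R), Sb))
  ev <- eigen(M)
  W <- backsolve(R, Re(ev$vectors[, seq_len(dims), drop = FALSE]))
  # scale discriminants to unit within-class variance
  wvar <- diag(t(W) %*% Sw_reg %*% W)
  W <- sweep(W, 2, sqrt(pmax(wvar, .Machine$double.eps)), "/")
  z_means <- means %*% W
  structure(list(W = W, means = z_means, levels = levels(grouping),
                 priors = as.vector(counts) / n, dims = dims,
                 lambda = lambda),
            class = "fisher_lda")
}

#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  z <- as.matrix(newdata) %*% object$W
  # Gaussian classes with identity covariance in the whitened Fisher space
  sc <- z %*% t(object$means)
  sc <- sweep(sc, 2, 0.5 * rowSums(object$means^2))
  sc <- sweep(sc, 2, log(object$priors), "+")
  cls <- factor(object$levels[max.col(sc, ties.method = "first")],
                levels = object$levels)
  list(class = cls, x = z)
}

#' Fit a PCA + LDA classifier
#'
#' Mean-centred principal component analysis followed by Fisher linear
#' discriminant analysis on the retained scores. The requested number of
#' components (1000 by default, matching the pipeline's multivariate
#' configuration) is capped at the data rank, `min(n - 1, p)`, and the
#' effective count is recorded. The LDA dimension defaults to the number
#' of classes minus one.
#'
#' @param x Numeric matrix (rows are ROIs) or a [feature_matrix()].
#' @param grouping Class label per row.
#' @param n_pca Number of principal components requested (default 1000).
#' @param lda_dims LDA dimensions (default `nlevels - 1`).
#' @return An object of class `"pcalda"` with `predict`, `print` and
#'   `coef` methods. `predict` returns the predicted class and the
#'   LDA-space embedding.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' fit <- pcalda(x, rep(c("a", "b"), each = 20), n_pca = 2)
#' table(predict(fit, x)$class)
#' @export
pcalda <- function(x, grouping, n_pca = 1000, lda_dims = NULL) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 2) {
    stop("single-class input: at least two classes required", call. = FALSE)
  }
  if (n_pca < 1) stop("n_pca must be >= 1", call. = FALSE)
  rank_cap <- min(n_pca, nrow(x) - 1L, ncol(x))
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = rank_cap)
  keep <- which(pr$sdev[seq_len(rank_cap)] > pr$sdev[1] * 1e-9)
  m <- max(length(keep), 1L)
  scores <- pr$x[, seq_len(m), drop = FALSE]
  lda <- fisher_lda(scores, grouping, dims = lda_dims)
  structure(list(rotation = pr$rotation[, seq_len(m), drop = FALSE],
                 center = pr$center, lda = lda,
                 n_pca_requested = n_pca, n_pca_effective = m,
                 lda_dims = lda$dims, levels = lda$levels),
            class = "pcalda")
}

#' @export
predict.pcalda <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  scores <- sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
  predict(object$lda, scores)
}

#' @export
print.pcalda <- function(x, ...) {
  cat(sprintf(
    "<pcalda: %d PCA components (%d requested), %d-D LDA, classes: %s>\n",
    x$n_pca_effective, x$n_pca_requested, x$lda_dims,
    paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
coef.pcalda <- function(object, ...) {
  object$rotation %*% object$lda$W
}
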