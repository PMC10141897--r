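# Per-ion statistics: volcano differential-abundance screening and
# single-ion discrimination under leave-one-patient-out CV.

#' Fold change between two groups
#'
#' Ratio of raw group means (group 1 over group 2).
#'
#' @param g1,g2 Numeric vectors of intensities.
#' @return `mean(g1) / mean(g2)`.
#' @export
fold_change <- function(g1, g2) {
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty",
                                       call. = FALSE)
  m2 <- mean(g2)
  if (m2 == 0) stop("zero denominator group mean", call. = FALSE)
  mean(g1) / m2
}

#' Volcano differential-abundance analysis
#'
#' For each bin, computes the fold change of raw group means
#' (group 1 / group 2) and a two-sample p-value, and flags bins passing
#' the joint criterion `max(FC, 1/FC) >= fc_threshold` and
#' `p < p_threshold` — the screen used with thresholds (2, 0.001), or
#' with `fc_threshold = 1` when the comparison (such as biological sex)
#' yields few differences. The default test is a Welch t-test on
#' log10-transformed intensities with a half-minimum offset; a
#' Mann-Whitney test is available. Benjamini-Hochberg q-values are
#' reported for information but do not enter the flag.
#'
#' @param fm A [feature_matrix()].
#' @param group_labels Two-level factor (or coercible) per ROI row.
#' @param fc_threshold Fold-change gate (>= 1; default 2).
#' @param p_threshold Significance gate (default 0.001).
#' @param test `"welch"` or `"wilcox"`.
#' @return Data frame with one row per bin: `center`, `fold_change`,
#'   `log2_fc`, `p_value`, `q_value`, `flagged`, `direction`.
#' @export
volcano <- function(fm, group_labels, fc_threshold = 2, p_threshold = 0.001,
                    test = c("welch", "wilcox")) {
  test <- match.arg(test)
  stopifnot(inherits(fm, "feature_matrix"))
  g <- droplevels(factor(group_labels))
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  if (length(i1) < 3 || length(i2) < 3) {
    stop("each group needs at least 3 rows", call. = FALSE)
  }
  pos <- fm$x[fm$x > 0]
  if (!length(pos)) stop("feature matrix has no positive values", call. = FALSE)
  eps <- 0.5 * min(pos)
  n_bins <- ncol(fm$x)
  fc <- p <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    x1 <- fm$x[i1, j]; x2 <- fm$x[i2, j]
    m1 <- mean(x1); m2 <- mean(x2)
    fc[j] <- (if (m1 > 0) m1 else eps) / (if (m2 > 0) m2 else eps)
    p[j] <- if (test == "welch") {
      if (sd(x1) == 0 && sd(x2) == 0) {
        if (isTRUE(all.equal(m1, m2))) 1 else 0
      } else {
        t.test(log10(x1 + eps), log10(x2 + eps))$p.value
      }
    } else {
      suppressWarnings(wilcox.test(x1, x2)$p.value)
    }
  }
  flagged <- pmax(fc, 1 / fc) >= fc_threshold & p < p_threshold
  data.frame(
    center = fm$bins$center,
    fold_change = fc,
    log2_fc = log2(fc),
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    flagged = flagged,
    direction = ifelse(fc >= 1, "up_in_group1", "up_in_group2")
  )
}

#' Volcano plot
#'
#' log2 fold change against -log10 p, flagged bins highlighted.
#'
#' @param vr Result of [volcano()].
#' @param path Optional PNG output path; when `NULL`, draws on the
#'   current device.
#' @param fc_threshold,p_threshold Guide lines (match the call that
#'   produced `vr`).
#' @export
plot_volcano <- function(vr, path = NULL, fc_threshold = 2,
                         p_threshold = 0.001) {
  draw <- function() {
    lp <- -log10(pmax(vr$p_value, 1e-300))
    graphics::plot(vr$log2_fc, lp, pch = 20,
                   col = ifelse(vr$flagged, "firebrick", "grey50"),
                   xlab = "log2 fold change", ylab = "-log10 p")
    graphics::abline(h = -log10(p_threshold), lty = 2)
    if (fc_threshold > 1) {
      graphics::abline(v = c(-1, 1) * log2(fc_threshold), lty = 2)
    }
  }
  if (is.null(path)) {
    draw()
  } else {
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(vr)
}

#' Rank single ions by leave-one-patient-out accuracy
#'
#' For each bin independently, a one-dimensional LDA is trained and
#' tested under leave-one-patient-out cross-validation (for binary tasks
#' this reduces to a class-conditional-mean threshold rule on the ion's
#' intensity); bins are ranked by accumulated test accuracy — the
#' prospective prediction power of each ion.
#'
#' @param fm A [feature_matrix()].
#' @param labels Class label per ROI row (e.g. from [map_labels()]).
#' @return Data frame `center`, `accuracy`, sorted descending, with the
#'   fold patient sets attached as the `"folds"` attribute.
#' @export
single_ion_cv <- function(fm, labels) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- factor(labels)
  patients <- fm$rois$patient_id
  ids <- unique(patients)
  if (length(ids) < 2) stop("at least two patients required", call. = FALSE)
  folds <- lapply(ids, function(pid) {
    list(train = which(patients != pid), test = which(patients == pid))
  })
  names(folds) <- ids
  for (f in folds) {
    if (nlevels(droplevels(labels[f$train])) < 2) {
      stop("a training fold collapses to one class", call. = FALSE)
    }
  }
  acc <- vapply(seq_len(ncol(fm$x)), function(j) {
    correct <- 0L
    for (f in folds) {
      xj <- fm$x[f$train, j, drop = FALSE]
      fit <- tryCatch(
        fisher_lda(xj, droplevels(labels[f$train]), 1),
        error = function(e) NULL)
      if (is.null(fit)) {
        # degenerate ion (constant in training): majority-class rule
        maj <- names(which.max(table(labels[f$train])))
        correct <- correct + sum(labels[f$test] == maj)
        next
      }
      pred <- predict(fit, fm$x[f$test, j, drop = FALSE])$class
      correct <- correct + sum(as.character(pred) ==
                                 as.character(labels[f$test]))
    }
    correct / nrow(fm$x)
  }, 0)
  out <- data.frame(center = fm$bins$center, accuracy = acc)
  out <- out[order(-out$accuracy), ]
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}
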