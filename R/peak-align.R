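# Cross-slide m/z alignment by kernel-density clustering, prevalence
# filtering, and construction of the ROI x bin feature matrix.

# Exact Gaussian KDE at a point set (used for valley refinement).
kde_exact <- function(x, at, bw) {
  vapply(at, function(g) sum(exp(-((x - g)^2) / (2 * bw^2))), 0)
}

#' Partition m/z values by kernel-density valley finding
#'
#' Pools the values, splits them at gaps wide enough that the Gaussian
#' kernels cannot interact (> 8 bandwidths), and within each dense
#' segment evaluates a Gaussian KDE (kernel SD = bandwidth) on a grid of
#' step `bandwidth / 10` padded by four bandwidths. Grid-local density
#' minima between adjacent modes are refined by one-dimensional
#' optimisation of the exact density and become group boundaries.
#'
#' @param x Numeric vector of m/z values.
#' @param bandwidth Kernel SD in Da.
#' @return A list with `assignment` (integer group per element of `x`,
#'   groups numbered in ascending m/z order) and `boundaries` (numeric
#'   vector of interior cut points).
#' @export
kde_partition <- function(x, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (!length(x)) stop("at least one peak is required", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]
  gaps <- which(diff(xs) > 8 * bandwidth)
  seg_start <- c(1L, gaps + 1L)
  seg_end <- c(gaps, length(xs))
  assignment_sorted <- integer(length(xs))
  boundaries <- numeric(0)
  gid <- 0L
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    xi <- xs[idx]
    if (length(xi) == 1L || diff(range(xi)) < 1e-12) {
      gid <- gid + 1L
      assignment_sorted[idx] <- gid
      next
    }
    grid <- seq(min(xi) - 4 * bandwidth, max(xi) + 4 * bandwidth,
                by = bandwidth / 10)
    dens <- kde_eval_cpp(xi, grid, bandwidth)
    n <- length(dens)
    is_min <- which(dens[2:(n - 1)] < dens[3:n] &
                      dens[2:(n - 1)] <= dens[1:(n - 2)]) + 1L
    cuts <- vapply(is_min, function(i) {
      stats::optimize(function(g) kde_exact(xi, g, bandwidth),
                      interval = c(grid[i - 1L], grid[i + 1L]))$minimum
    }, 0)
    # only cuts that actually separate members matter
    cuts <- cuts[cuts > min(xi) & cuts < max(xi)]
    grp <- findInterval(xi, cuts) + 1L
    assignment_sorted[idx] <- gid + grp
    gid <- gid + max(grp)
    boundaries <- c(boundaries, cuts)
  }
  # renumber to consecutive ids (valley pairs with no member between them
  # would otherwise leave gaps); groups ascend with m/z
  assignment_sorted <- match(assignment_sorted, sort(unique(assignment_sorted)))
  assignment <- integer(length(x))
  assignment[ord] <- assignment_sorted
  list(assignment = assignment, boundaries = sort(boundaries))
}

#' Cluster pooled peaks into m/z bins
#'
#' The cross-slide alignment step: peaks pooled from all slides are
#' clustered by [kde_partition()] and each density mode becomes a bin.
#' A bin's centre is the (intensity-unweighted) mean m/z of its member
#' peaks; its half-open interval `[lo, hi)` is delimited by the refined
#' density valleys, with the outermost edges padded by half a bandwidth
#' beyond the extreme members. Modes wider than the nominal bandwidth are
#' not split; the bin records its true extent.
#'
#' @param peaks Data frame with columns `mz` and `slide_id`.
#' @param bandwidth Kernel SD in Da (default 0.003).
#' @return A data frame of bins: `center`, `lo`, `hi`,
#'   `n_slides_present`, `member_count`, sorted by centre, plus an
#'   `assignment` attribute mapping each input peak to its bin row.
#' @export
kde_bin <- function(peaks, bandwidth = 0.003) {
  stopifnot(is.data.frame(peaks), all(c("mz", "slide_id") %in% names(peaks)))
  part <- kde_partition(peaks$mz, bandwidth)
  g <- part$assignment
  ng <- max(g)
  gf <- factor(g, levels = seq_len(ng))
  center <- as.vector(tapply(peaks$mz, gf, mean))
  lo_member <- as.vector(tapply(peaks$mz, gf, min))
  hi_member <- as.vector(tapply(peaks$mz, gf, max))
  # interior boundaries separate consecutive bins; edges get half-bandwidth
  bnd <- part$boundaries
  lo <- numeric(ng); hi <- numeric(ng)
  for (k in seq_len(ng)) {
    left <- bnd[bnd < center[k] & bnd >= (if (k > 1) center[k - 1] else -Inf)]
    right <- bnd[bnd > center[k] & bnd <= (if (k < ng) center[k + 1] else Inf)]
    lo[k] <- if (length(left)) max(left) else lo_member[k] - bandwidth / 2
    hi[k] <- if (length(right)) min(right) else hi_member[k] + bandwidth / 2
  }
  n_slides <- as.vector(tapply(peaks$slide_id, gf, function(s) length(unique(s))))
  cnt <- as.vector(tapply(peaks$mz, gf, length))
  bins <- data.frame(center = center, lo = lo, hi = hi,
                     n_slides_present = as.integer(n_slides),
                     member_count = as.integer(cnt))
  ord <- order(bins$center)
  bins <- bins[ord, ]
  rownames(bins) <- NULL
  remap <- match(g, ord)
  attr(bins, "assignment") <- remap
  bins
}

#' Filter bins by slide prevalence
#'
#' Retains bins present in strictly more than `floor(fraction * n_slides)`
#' slides, the strict-inequality rule used with a 40% threshold on 20
#' slides (present in more than 8). `fraction = 1` degenerates under
#' strict inequality, so it is read as "present in all slides".
#'
#' @param bins Bin data frame from [kde_bin()].
#' @param n_slides Total number of slides pooled.
#' @param fraction Required prevalence fraction in (0, 1].
#' @return The retained bins, original order preserved.
#' @export
prevalence_filter <- function(bins, n_slides, fraction = 0.4) {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  keep <- if (fraction >= 1) {
    bins$n_slides_present >= n_slides
  } else {
    bins$n_slides_present > floor(fraction * n_slides)
  }
  out <- bins[keep, ]
  rownames(out) <- NULL
  out
}

bin_names <- function(centers) {
  nm <- sprintf("%.3f", centers)
  if (anyDuplicated(nm)) {
    stop("bin centres collide after rounding to 3 decimals: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  nm
}

#' Construct a feature matrix
#'
#' Rows are ROIs (with their slide, patient, sample-kind and region
#' metadata), columns are m/z bins, and cells hold TIC-normalized mean
#' intensities.
#'
#' @param x Numeric matrix, ROIs x bins.
#' @param rois Data frame of ROI metadata (one row per matrix row) with
#'   at least `slide_id`, `patient_id`, `sample_kind`, `region`.
#' @param bins Bin data frame (see [kde_bin()]), sorted by centre.
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(x, rois, bins) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(rois)) stop("rois must match matrix rows", call. = FALSE)
  if (ncol(x) != nrow(bins)) stop("bins must match matrix columns", call. = FALSE)
  if (length(x) && (any(!is.finite(x)) || any(x < 0))) {
    stop("feature values must be finite and non-negative", call. = FALSE)
  }
  need <- c("slide_id", "patient_id", "sample_kind", "region")
  if (!all(need %in% names(rois))) {
    stop("rois metadata must include ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(bins$center)) stop("bins must be sorted by centre", call. = FALSE)
  colnames(x) <- bin_names(bins$center)
  rownames(rois) <- NULL
  structure(list(x = x, rois = rois, bins = bins), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d ROIs x %d bins; regions: %s>\n",
              nrow(x$x), ncol(x$x),
              paste(names(table(x$rois$region)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

# Per-pixel summed intensity in each bin for a set of pixel indices.
# Returns a length(pixels) x nrow(bins) matrix.
pixel_bin_matrix <- function(slide, pixels, bins) {
  out <- matrix(0, length(pixels), nrow(bins))
  for (i in seq_along(pixels)) {
    sp <- slide$spectra[[pixels[i]]]
    if (!length(sp$mz)) next
    idx <- findInterval(sp$mz, bins$lo)
    ok <- idx >= 1L & sp$mz < bins$hi[pmax(idx, 1L)]
    if (any(ok)) {
      agg <- rowsum(sp$intensity[ok], idx[ok])
      out[i, as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  out
}

#' Build the ROI x bin feature matrix
#'
#' Each cell is the mean over the ROI's nine pixels of the summed
#' TIC-normalized intensity of peaks falling inside the bin interval;
#' peaks absent from a pixel contribute zero.
#'
#' @param slides Named list of preprocessed [slide_image()]s.
#' @param rois ROI data frame (see [sample_rois()]).
#' @param bins Bin data frame from [kde_bin()] (possibly filtered).
#' @return A [feature_matrix()].
#' @export
build_feature_matrix <- function(slides, rois, bins) {
  if (is.null(names(slides))) {
    names(slides) <- vapply(slides, `[[`, "", "slide_id")
  }
  unknown <- setdiff(unique(rois$slide_id), names(slides))
  if (length(unknown)) {
    stop("ROI references unknown slide(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x <- matrix(0, nrow(rois), nrow(bins))
  for (r in seq_len(nrow(rois))) {
    slide <- slides[[rois$slide_id[r]]]
    px <- roi_pixels(rois$row[r], rois$col[r], slide$dims)
    x[r, ] <- colMeans(pixel_bin_matrix(slide, px, bins))
  }
  feature_matrix(x, rois, bins)
}

# Row-major pixel indices of a 3x3 ROI anchored at 0-based (row, col).
roi_pixels <- function(row, col, dims) {
  as.vector(outer(0:2, 0:2, function(dr, dc) {
    pixel_index(row + dr, col + dc, dims)
  }))
}
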