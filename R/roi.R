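# Stratified sampling of nine-pixel (3x3) regions of interest from
# annotated slides.

#' Sample non-overlapping 3x3 ROIs from one region of a mask
#'
#' Feasible placements are 3x3 squares whose nine pixels all carry the
#' requested region label. Placements are drawn uniformly at random by
#' rejection sampling (overlapping proposals discarded, capped at 10,000
#' proposals); when the region cannot host `k` disjoint ROIs, fewer are
#' returned with a warning. Deterministic given `seed`.
#'
#' @param mask An [annotation_mask()].
#' @param region Region label to sample.
#' @param k Number of ROIs requested (the study design uses about 55 per
#'   annotated region per slide).
#' @param seed Integer seed.
#' @return Data frame with columns `slide_id`, `row`, `col` (0-based
#'   anchor, top-left), `region`, `patient_id`, `sample_kind`.
#' @export
sample_rois <- function(mask, region, k = 55, seed = 1L) {
  if (!region %in% attr(mask, "regions")) {
    stop("region not in mask legend: ", region, call. = FALSE)
  }
  stopifnot(k >= 0)
  lab <- unclass(mask)
  nr <- nrow(lab); nc <- ncol(lab)
  ok <- matrix(FALSE, nr, nc)
  if (nr >= 3 && nc >= 3) {
    hit <- lab == region
    # a placement at (r, c) is feasible iff all 9 covered pixels match
    for (r in 1:(nr - 2)) for (cc in 1:(nc - 2)) {
      ok[r, cc] <- all(hit[r:(r + 2), cc:(cc + 2)])
    }
  }
  anchors <- which(ok, arr.ind = TRUE)
  taken <- matrix(FALSE, nr, nc)
  dr <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L)
  dc <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L)
  got <- list()
  if (nrow(anchors) && k > 0) {
    with_seed(seed, {
      proposals <- 0L
      while (length(got) < k && proposals < 10000L) {
        proposals <- proposals + 1L
        a <- anchors[sample.int(nrow(anchors), 1L), ]
        cells <- cbind(a[1] + dr, a[2] + dc)
        if (any(taken[cells])) next
        taken[cells] <- TRUE
        got[[length(got) + 1L]] <- a
      }
    })
  }
  picked <- if (length(got)) do.call(rbind, got) else
    matrix(integer(0), ncol = 2)
  if (nrow(picked) < k) {
    warning(sprintf("region %s: only %d of %d requested disjoint ROIs placed",
                    region, nrow(picked), k), call. = FALSE)
  }
  data.frame(
    slide_id = rep(attr(mask, "slide_id"), nrow(picked)),
    row = as.integer(picked[, 1] - 1L),
    col = as.integer(picked[, 2] - 1L),
    region = rep(region, nrow(picked)),
    patient_id = rep(attr(mask, "patient_id"), nrow(picked)),
    sample_kind = rep(attr(mask, "sample_kind"), nrow(picked)),
    stringsAsFactors = FALSE
  )
}

#' Sample ROIs for every slide and region of a cohort
#'
#' Applies [sample_rois()] to each mask for each tissue region present on
#' it (background is never sampled), with per-(slide, region) seeds
#' derived from `seed`.
#'
#' @param cohort An `"msi_cohort"`.
#' @param k Requested ROIs per region per slide; either a single count or
#'   a named vector keyed by region label.
#' @param regions Regions to sample (default: all tissue regions).
#' @param seed Integer seed.
#' @param quiet Suppress feasibility warnings from small regions.
#' @return Row-bound ROI data frame.
#' @export
sample_cohort_rois <- function(cohort, k = 55, regions = NULL, seed = 1L,
                               quiet = FALSE) {
  out <- list()
  i <- 0L
  for (mask in cohort$masks) {
    i <- i + 1L
    present <- setdiff(unique(as.vector(unclass(mask))), "background")
    if (!is.null(regions)) present <- intersect(present, regions)
    j <- 0L
    for (reg in present) {
      j <- j + 1L
      kk <- if (!is.null(names(k))) {
        if (reg %in% names(k)) k[[reg]] else 0
      } else {
        k
      }
      if (kk == 0) next
      call <- function() sample_rois(mask, reg, k = kk,
                                     seed = derive_seed(seed, 100L * i + j))
      out[[length(out) + 1L]] <- if (quiet) suppressWarnings(call()) else call()
    }
  }
  do.call(rbind, out)
}

#' Attach clinical labels to ROIs
#'
#' Copies each ROI's patient's lymphovascular-invasion and sex status
#' onto the ROI table for stratified analyses.
#'
#' @param rois ROI data frame (see [sample_rois()]).
#' @param patients Clinical table with `patient_id`, `lvi`, `sex`.
#' @return `rois` with `lvi` and `sex` columns added.
#' @export
label_rois <- function(rois, patients) {
  if (nrow(rois) == 0) {
    rois$lvi <- character(0)
    rois$sex <- character(0)
    return(rois)
  }
  m <- match(rois$patient_id, patients$patient_id)
  if (anyNA(m)) {
    stop("unknown patient_id: ",
         paste(unique(rois$patient_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  rois$lvi <- patients$lvi[m]
  rois$sex <- patients$sex[m]
  rois
}
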