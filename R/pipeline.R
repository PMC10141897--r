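#' Run the preprocessing and feature-extraction pipeline on a cohort
#'
#' Applies per-slide conditioning (lockmass correction, top-N species
#' selection, TIC normalization), aligns the slides' species peak lists
#' into cohort-level m/z bins by kernel-density clustering, filters the
#' bins by slide prevalence, samples stratified 3x3 ROIs, attaches
#' clinical labels, and builds the ROI x bin feature matrix — the input
#' of every downstream model.
#'
#' @param cohort An `"msi_cohort"` (from [generate_cohort()] or
#'   [load_cohort()]).
#' @param cfg A [preprocess_config()].
#' @param k ROIs requested per region per slide (count or named vector;
#'   see [sample_cohort_rois()]).
#' @param regions Regions to sample (default: all tissue regions).
#' @param prevalence Slide-prevalence fraction for [prevalence_filter()]
#'   (default 0.4).
#' @param seed Seed for ROI placement.
#' @param quiet Suppress ROI feasibility warnings.
#' @return A list with `slides` (preprocessed), `bins` (filtered bin
#'   table), `rois`, and `fm` (the [feature_matrix()]).
#' @export
run_pipeline <- function(cohort, cfg = preprocess_config(), k = 20,
                         regions = NULL, prevalence = 0.4, seed = 1L,
                         quiet = TRUE) {
  pp <- lapply(cohort$slides, preprocess_slide, cfg = cfg)
  peaks <- do.call(rbind, lapply(pp, function(s) {
    data.frame(mz = s$peaklist$mz, slide_id = s$slide_id,
               stringsAsFactors = FALSE)
  }))
  bins <- kde_bin(peaks, bandwidth = cfg$bandwidth)
  bins <- prevalence_filter(bins, n_slides = length(pp),
                            fraction = prevalence)
  rois <- sample_cohort_rois(cohort, k = k, regions = regions, seed = seed,
                             quiet = quiet)
  rois <- label_rois(rois, cohort$patients)
  fm <- build_feature_matrix(pp, rois, bins)
  list(slides = pp, bins = bins, rois = rois, fm = fm)
}
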