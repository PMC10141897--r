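# Per-slide spectral conditioning: lockmass recalibration, top-N peak
# selection, TIC normalization. All operations are pure: the input slide
# is never modified.

#' Preprocessing configuration
#'
#' @param lockmass_mz Lockmass reference m/z (default 554.2615, the
#'   deprotonated leucine-enkephalin peak co-sprayed in negative mode).
#' @param lockmass_tol Search window around the reference in Da
#'   (default 0.05).
#' @param top_n Number of slide-wide peak species retained (default 2000).
#' @param bandwidth Kernel bandwidth in Da used to group pixel peaks into
#'   slide-wide species (default 0.003).
#' @param normalize Normalization scheme; only `"tic"` is supported.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(lockmass_mz = 554.2615, lockmass_tol = 0.05,
                              top_n = 2000, bandwidth = 0.003,
                              normalize = "tic") {
  if (top_n < 1) stop_field("top_n", "must be >= 1")
  if (lockmass_tol <= 0) stop_field("lockmass_tol", "must be > 0")
  if (bandwidth <= 0) stop_field("bandwidth", "must be > 0")
  normalize <- match.arg(normalize, "tic")
  structure(list(lockmass_mz = lockmass_mz, lockmass_tol = lockmass_tol,
                 top_n = top_n, bandwidth = bandwidth,
                 normalize = normalize),
            class = "preprocess_config")
}

# Pool all pixel peaks of a slide into (mz, intensity, pixel) vectors.
pool_slide_peaks <- function(slide) {
  n <- lengths(lapply(slide$spectra, `[[`, "mz"))
  list(mz = unlist(lapply(slide$spectra, `[[`, "mz"), use.names = FALSE),
       intensity = unlist(lapply(slide$spectra, `[[`, "intensity"),
                          use.names = FALSE),
       pixel = rep(seq_along(slide$spectra), n))
}

#' Lockmass mass-shift correction
#'
#' Finds the lockmass peak in the slide's pooled (mean) spectrum within
#' `lockmass_tol` of the reference and applies the constant additive
#' shift that puts it exactly on the reference m/z; the shift is recorded
#' in the slide's `mass_shift` field. A single-point additive
#' recalibration is used because one reference mass is available.
#'
#' @param slide A [slide_image()].
#' @param cfg A [preprocess_config()].
#' @return The corrected slide.
#' @export
lockmass_correct <- function(slide, cfg = preprocess_config()) {
  pool <- pool_slide_peaks(slide)
  win <- abs(pool$mz - cfg$lockmass_mz) <= cfg$lockmass_tol
  if (!any(win)) {
    nearest <- pool$mz[which.min(abs(pool$mz - cfg$lockmass_mz))]
    stop(sprintf(
      "no lockmass candidate within %.3g Da of %.4f (nearest observed peak: %.4f)",
      cfg$lockmass_tol, cfg$lockmass_mz, nearest), call. = FALSE)
  }
  observed <- sum(pool$mz[win] * pool$intensity[win]) / sum(pool$intensity[win])
  shift <- cfg$lockmass_mz - observed
  out <- slide
  if (shift != 0) {
    out$spectra <- lapply(slide$spectra, function(sp) {
      list(mz = sp$mz + shift, intensity = sp$intensity)
    })
  }
  out$mass_shift <- shift
  out
}

#' Retain the top-N most intense peak species of a slide
#'
#' Pixel peaks are grouped into slide-wide species by kernel-density
#' clustering at the configured bandwidth; the `top_n` species with the
#' highest slide-wide summed intensity are retained and every pixel keeps
#' only the peaks falling inside a retained species interval. Peak order
#' within pixels is preserved. The slide's species peak list (centre and
#' summed intensity per retained species) is stored in the `peaklist`
#' field for cohort-level alignment.
#'
#' @param slide A [slide_image()], lockmass-corrected.
#' @param top_n Number of species retained (default from `cfg`).
#' @param cfg A [preprocess_config()].
#' @return The filtered slide.
#' @export
select_top_peaks <- function(slide, top_n = cfg$top_n,
                             cfg = preprocess_config()) {
  pool <- pool_slide_peaks(slide)
  if (!length(pool$mz)) {
    out <- slide
    out$peaklist <- data.frame(mz = numeric(), intensity = numeric())
    return(out)
  }
  part <- kde_partition(pool$mz, cfg$bandwidth)
  totals <- rowsum(pool$intensity, part$assignment)
  vals <- as.integer(rownames(totals))
  top <- order(-totals[, 1])[seq_len(min(top_n, nrow(totals)))]
  keep_groups <- sort(vals[top])
  keep_idx <- sort(top)
  keep_peak <- part$assignment %in% keep_groups
  by_pixel <- split(keep_peak, factor(pool$pixel,
                                      levels = seq_along(slide$spectra)))
  out <- slide
  out$spectra <- lapply(seq_along(slide$spectra), function(i) {
    sel <- by_pixel[[i]]
    sp <- slide$spectra[[i]]
    list(mz = sp$mz[sel], intensity = sp$intensity[sel])
  })
  mz_sums <- rowsum(pool$mz, part$assignment)
  cnts <- rowsum(rep(1, length(pool$mz)), part$assignment)
  centers <- (mz_sums / cnts)[keep_idx, 1]
  out$peaklist <- data.frame(mz = centers, intensity = totals[keep_idx, 1])
  out
}

#' TIC-normalize a spectrum
#'
#' Divides intensities by their sum (the pixel's total ion current) so
#' the output intensities sum to one.
#'
#' @param sp A spectrum (list with `mz`, `intensity`).
#' @return The normalized spectrum.
#' @export
tic_normalize <- function(sp) {
  tic <- sum(sp$intensity)
  if (!length(sp$intensity) || tic <= 0) stop("empty TIC", call. = FALSE)
  list(mz = sp$mz, intensity = sp$intensity / tic)
}

#' Preprocess a slide end to end
#'
#' Lockmass correction, then top-N species selection, then per-pixel TIC
#' normalization (pixels left empty by selection are skipped and remain
#' empty).
#'
#' @param slide A [slide_image()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed slide with `tic_normalized = TRUE`.
#' @export
preprocess_slide <- function(slide, cfg = preprocess_config()) {
  out <- lockmass_correct(slide, cfg)
  out <- select_top_peaks(out, cfg = cfg)
  out$spectra <- lapply(out$spectra, function(sp) {
    if (!length(sp$intensity) || sum(sp$intensity) <= 0) return(sp)
    tic_normalize(sp)
  })
  out$tic_normalized <- TRUE
  out
}
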