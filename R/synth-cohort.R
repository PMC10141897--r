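# Synthetic DESI cohort generator.
#
# The generator plants a known spatial and statistical structure: region
# markers at configured fold changes, 13C isotopologues at the natural
# carbon-count abundance ratio, a lockmass peak subject to per-slide mass
# drift, per-pixel TIC variation, and optional per-patient batch effects.
# Everything is a deterministic function of (config, seed).

# Cohort-level background ion library, deterministic given the config seed.
synth_library <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 0L), {
    n <- cfg$background_species
    data.frame(
      mz = sort(runif(n, cfg$mz_range[1], cfg$mz_range[2])),
      base = rlnorm(n, cfg$background_meanlog, cfg$background_sdlog)
    )
  })
}

# Per-(patient, marker) multiplicative level effects, shared between the
# patient's cross section and biopsy.
synth_patient_effects <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1L), {
    matrix(rlnorm(cfg$n_patients * nrow(cfg$markers),
                  meanlog = 0, sdlog = cfg$patient_effect_sd),
           nrow = cfg$n_patients)
  })
}

# Which background species appear on each slide (2*n_patients slides).
synth_slide_presence <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 2L), {
    matrix(runif(2L * cfg$n_patients * cfg$background_species) <
             cfg$background_slide_p,
           nrow = 2L * cfg$n_patients)
  })
}

#' Region geometry of a synthetic slide
#'
#' Cross sections are a background frame around four layered horizontal
#' bands (benign mucosa, submucosa, smooth muscle, serosa, top to bottom)
#' with an adenocarcinoma ellipse breaking through the layers and small
#' rectangular inflammatory-cell infiltrates; biopsies contain benign
#' mucosa and adenocarcinoma halves with an inflammatory patch. The
#' second value maps each adenocarcinoma pixel to a tumour zone (1 or 2);
#' zones only differ metabolically for two-zone slides.
#'
#' @param kind `"cross_section"` or `"biopsy"`.
#' @param dims Grid shape `c(nrow, ncol)`.
#' @return A list with `labels` (character matrix) and `zone` (integer
#'   matrix, 0 outside the tumour).
#' @export
region_geometry <- function(kind, dims) {
  nr <- dims[1]; nc <- dims[2]
  lab <- matrix("background", nr, nc)
  zone <- matrix(0L, nr, nc)
  # background frame; dropped when the grid is too small to afford it
  m <- if (min(nr, nc) >= 7L) 2L else 0L
  rin <- (m + 1L):(nr - m); cin <- (m + 1L):(nc - m)
  if (kind == "cross_section") {
    h <- length(rin)
    cut <- round(h * c(0.25, 0.5, 0.75))
    lab[rin[seq_len(cut[1])], cin] <- "BM"
    lab[rin[(cut[1] + 1):cut[2]], cin] <- "Sub"
    lab[rin[(cut[2] + 1):cut[3]], cin] <- "SM"
    lab[rin[(cut[3] + 1):h], cin] <- "Ser"
    # tumour ellipse centred left of middle, spanning the upper layers
    r0 <- m + 0.40 * h; c0 <- m + 0.30 * length(cin)
    ra <- 0.32 * h; rb <- 0.24 * length(cin)
    for (r in rin) for (cc in cin) {
      if (((r - r0) / ra)^2 + ((cc - c0) / rb)^2 <= 1) {
        lab[r, cc] <- "AdC"
        zone[r, cc] <- if (cc <= c0) 1L else 2L
      }
    }
    # two inflammatory infiltrates flanking the tumour
    ic1r <- pmin(nr - m, round(r0) + 0:4); ic1c <- pmin(nc - m, round(c0 + rb) + 2:6)
    ic2r <- pmin(nr - m, round(r0 + ra) + 1:4); ic2c <- pmin(nc - m, round(c0) + 0:4)
    lab[ic1r, ic1c] <- "IC"
    lab[ic2r, ic2c] <- "IC"
    zone[ic1r, ic1c] <- 0L; zone[ic2r, ic2c] <- 0L
  } else {
    h <- length(rin)
    cut <- round(h * 0.5)
    lab[rin[seq_len(cut)], cin] <- "BM"
    lab[rin[(cut + 1):h], cin] <- "AdC"
    zone[rin[(cut + 1):h], cin] <- 1L
    icr <- rin[pmin(h, cut + 1:3)]; icc <- cin[seq_len(min(3, length(cin)))]
    lab[icr, icc] <- "IC"
    zone[icr, icc] <- 0L
  }
  list(labels = lab, zone = zone)
}

# Build one slide. Peaks are assembled as long vectors (pixel, mz,
# intensity) and split per pixel at the end; this keeps generation fast
# at full slide sizes.
build_slide <- function(cfg, patient_id, patient_index, kind, slide_index,
                        lib, pat_eff, slide_present) {
  dims <- if (kind == "cross_section") cfg$cross_shape else cfg$biopsy_shape
  geom <- region_geometry(kind, dims)
  lab <- geom$labels
  two_zone <- kind == "cross_section" &&
    patient_index %in% cfg$two_zone_patients
  npix <- prod(dims)
  # region label per row-major pixel
  pixreg <- as.vector(t(lab))
  pixzone <- as.vector(t(geom$zone))

  set.seed(derive_seed(cfg$seed, 10L + slide_index))
  drift <- rnorm(1, 0, cfg$mass_drift_sd)
  tic_mult <- rlnorm_cv(npix, cfg$tic_cv)

  acc <- list(pix = list(), mz = list(), int = list())
  add <- function(p, m, i) {
    n <- length(acc$pix) + 1L
    acc$pix[[n]] <<- p; acc$mz[[n]] <<- m; acc$int[[n]] <<- i
  }

  # background species present on this slide
  present_sp <- which(slide_present)
  for (j in present_sp) {
    inpix <- which(runif(npix) < cfg$background_pixel_p)
    if (!length(inpix)) next
    ints <- lib$base[j] * rlnorm_cv(length(inpix), cfg$pixel_noise_cv)
    mzs <- lib$mz[j] + rnorm(length(inpix), 0, cfg$mz_jitter_sd)
    add(inpix, mzs, ints)
  }

  # markers (all pixels outside background frame), their isotopologues
  mk <- cfg$markers
  tissue <- which(pixreg != "background")
  if (length(tissue)) {
    for (k in seq_len(nrow(mk))) {
      fold <- ifelse(pixreg[tissue] == mk$region[k], mk$fold[k], 1)
      if (two_zone && mk$region[k] == "AdC") {
        # zone 2 is a metabolically distinct tumour sub-profile: damped
        # fatty-acid elevation
        fold[pixreg[tissue] == "AdC" & pixzone[tissue] == 2L] <-
          1 + (mk$fold[k] - 1) * 0.25
      }
      if (two_zone && mk$region[k] == "BM") {
        # zone 2 additionally acquires a mucosa-like profile
        fold[pixreg[tissue] == "AdC" & pixzone[tissue] == 2L] <- mk$fold[k]
      }
      mu <- mk$base[k] * fold * pat_eff[patient_index, k]
      ints <- mu * rlnorm_cv(length(tissue), mk$cv[k])
      mzs <- mk$mz[k] + rnorm(length(tissue), 0, cfg$mz_jitter_sd)
      add(tissue, mzs, ints)
      # one-substitution 13C isotopologue at the carbon-count fraction
      iso_ratio <- mk$carbons[k] * 0.0107
      add(tissue, mzs + cfg$isotope_delta, ints * iso_ratio)
    }
  }

  # lockmass in every pixel
  add(seq_len(npix), rep(cfg$lockmass_mz, npix),
      cfg$lockmass_intensity * rlnorm_cv(npix, 0.1))

  pix <- unlist(acc$pix, use.names = FALSE)
  mzv <- unlist(acc$mz, use.names = FALSE)
  inten <- unlist(acc$int, use.names = FALSE)
  inten <- inten * tic_mult[pix]
  mzv <- mzv + drift
  ord <- order(pix, mzv)
  pix <- pix[ord]; mzv <- mzv[ord]; inten <- inten[ord]
  idx <- unname(split(seq_along(pix), factor(pix, levels = seq_len(npix))))
  spectra <- lapply(idx, function(ii) {
    m <- mzv[ii]
    # collapse exact m/z ties (vanishingly rare) to keep strict ascent
    if (length(m) > 1 && any(diff(m) <= 0)) {
      keep <- c(TRUE, diff(m) > 0)
      m <- m[keep]; ii <- ii[keep]
    }
    list(mz = m, intensity = inten[ii])
  })

  slide <- slide_image(
    slide_id = sprintf("P%02d_%s", patient_index,
                       if (kind == "cross_section") "CS" else "BX"),
    patient_id = patient_id, sample_kind = kind, dims = dims,
    spectra = spectra, pixel_size = cfg$pixel_size, mz_range = cfg$mz_range)
  slide$true_drift <- drift
  mask <- annotation_mask(lab, cfg$regions, slide_id = slide$slide_id,
                          patient_id = patient_id, sample_kind = kind)
  attr(mask, "zone") <- geom$zone
  list(slide = slide, mask = mask)
}

#' Generate a synthetic DESI cohort
#'
#' Produces `n_patients` patients, each with one cross-section slide and
#' one biopsy slide plus matching annotation masks, and a clinical
#' metadata table. For the default 10-patient configuration the metadata
#' reproduces the reference cohort (six LVI-positive patients, one
#' MMR-deficient). Output is deterministic given the configuration.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `"msi_cohort"` with elements `slides` (list of
#'   [slide_image()]), `masks` (list of [annotation_mask()]), `patients`
#'   (data frame), `config`, and `patient_effects` (the planted
#'   per-patient marker multipliers, for calibration checks).
#' @examples
#' cohort <- generate_cohort(synth_config(n_patients = 2,
#'   cross_shape = c(12, 18), biopsy_shape = c(8, 8), seed = 7))
#' length(cohort$slides)  # 4
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  lib <- synth_library(config)
  pat_eff <- synth_patient_effects(config)
  presence <- synth_slide_presence(config)

  patients <- synth_patients(config$n_patients)
  slides <- list(); masks <- list()
  slide_index <- 0L
  for (p in seq_len(config$n_patients)) {
    for (kind in c("cross_section", "biopsy")) {
      slide_index <- slide_index + 1L
      out <- build_slide(config, patients$patient_id[p], p, kind,
                         slide_index, lib, pat_eff,
                         presence[slide_index, ])
      slides[[slide_index]] <- out$slide
      masks[[slide_index]] <- out$mask
    }
  }
  names(slides) <- vapply(slides, `[[`, "", "slide_id")
  names(masks) <- names(slides)
  structure(list(slides = slides, masks = masks, patients = patients,
                 config = config, patient_effects = pat_eff,
                 library = lib),
            class = "msi_cohort")
}

# Patient metadata: the reference table for 10 patients, recycled rows
# (with fresh ids) otherwise.
synth_patients <- function(n) {
  ref <- reference_cohort_table()
  idx <- ((seq_len(n) - 1L) %% nrow(ref)) + 1L
  out <- ref[idx, ]
  out$patient_id <- as.character(seq_len(n))
  rownames(out) <- NULL
  out
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat(sprintf("<msi_cohort: %d patients, %d slides (%s)>\n",
              nrow(x$patients), length(x$slides),
              paste(dim(x$masks[[1]]), collapse = "x")))
  invisible(x)
}

#' Simulate a single pixel spectrum
#'
#' Draws one centroided spectrum from the generative model used by
#' [generate_cohort()]: background peaks with log-normal intensities,
#' the configured region markers (elevated by their fold change when the
#' pixel's region matches), their 13C isotopologues, and the lockmass
#' peak, with every m/z shifted by `drift`. Uses the current RNG state;
#' seed externally for reproducibility.
#'
#' @param config A [synth_config()] object.
#' @param region Region label of the pixel.
#' @param patient_effect Multiplier (or vector, one per marker) applied to
#'   marker levels, emulating a patient-level batch effect.
#' @param drift Constant additive m/z shift in Da.
#' @return A [spectrum()].
#' @export
synth_spectrum <- function(config, region, patient_effect = 1, drift = 0) {
  validate_synth_config(config)
  if (!region %in% config$regions) {
    stop("unknown region: ", region, call. = FALSE)
  }
  lib <- synth_library(config)
  mzv <- numeric(0); inten <- numeric(0)
  sel <- runif(nrow(lib)) < config$background_slide_p * config$background_pixel_p
  if (any(sel)) {
    mzv <- lib$mz[sel] + rnorm(sum(sel), 0, config$mz_jitter_sd)
    inten <- lib$base[sel] * rlnorm_cv(sum(sel), config$pixel_noise_cv)
  }
  mk <- config$markers
  if (region != "background") {
    eff <- rep_len(patient_effect, nrow(mk))
    fold <- ifelse(mk$region == region, mk$fold, 1)
    ints <- mk$base * fold * eff * rlnorm_cv(nrow(mk), mk$cv[1])
    mzs <- mk$mz + rnorm(nrow(mk), 0, config$mz_jitter_sd)
    mzv <- c(mzv, mzs, mzs + config$isotope_delta)
    inten <- c(inten, ints, ints * mk$carbons * 0.0107)
  }
  mzv <- c(mzv, config$lockmass_mz)
  inten <- c(inten, config$lockmass_intensity * rlnorm_cv(1, 0.1))
  tic <- rlnorm_cv(1, config$tic_cv)
  ord <- order(mzv)
  spectrum(mzv[ord] + drift, inten[ord] * tic)
}
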