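#' Default marker specification for the synthetic cohort
#'
#' One row per planted marker ion: measured m/z, the tissue region the ion
#' is enriched in, its fold change relative to all other regions, the base
#' intensity in non-enriched regions, the per-pixel coefficient of
#' variation, and the carbon count used to scale the 1-substitution 13C
#' isotopologue. The adenocarcinoma block is the elongation series of
#' saturated and monounsaturated long-chain/very-long-chain fatty acids
#' (C20-C26) reported for colorectal tumours; benign mucosa carries a
#' lyso-PE and two plasmalogen/PE species, inflammatory cells a
#' phosphatidylserine group, and the connective-tissue triad (submucosa,
#' smooth muscle, serosa) one modest marker each so the six regions are
#' spectrally distinguishable.
#'
#' @return A data frame with columns `mz`, `region`, `fold`, `base`, `cv`,
#'   `carbons`.
#' @export
default_markers <- function() {
  data.frame(
    mz = c(309.2794, 337.3109, 365.3419, 393.3729,
           311.2948, 339.3260, 367.3574, 395.3884,
           480.3067, 750.5395, 698.5094,
           810.5245, 812.5350, 766.5360,
           277.0740, 292.0610, 364.1060),
    region = c(rep("AdC", 8),
               rep("BM", 3),
               rep("IC", 3),
               "Sub", "SM", "Ser"),
    fold = c(4.5, 5.4, 6.6, 17.5, 3.3, 2.6, 3.9, 4.3,
             5.5, 2.9, 3.7,
             3.2, 3.0, 3.0,
             3.0, 3.0, 3.0),
    base = 120,
    cv = 0.35,
    carbons = c(20, 22, 24, 26, 20, 22, 24, 26,
                23, 43, 39,
                44, 44, 43,
                12, 12, 16),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic DESI cohort generator
#'
#' Captures the acquisition design the generator emulates: a 10-patient
#' cohort, each patient contributing one full-thickness cross section and
#' one simulated endoscopic biopsy, acquired over m/z 50-1500 at 100 um
#' pixels in negative mode with a leucine-enkephalin lockmass. All sizes,
#' noise levels and planted effects are settable.
#'
#' @param n_patients Number of patients (default 10).
#' @param mz_range Acquired mass range in Da (default `c(50, 1500)`).
#' @param pixel_size Pixel edge in micrometres (default 100).
#' @param cross_shape,biopsy_shape Pixel grid `c(nrow, ncol)` for the two
#'   sample kinds (defaults 40x60 and 20x20).
#' @param regions Region label set. Cross sections use AdC, BM, Sub, SM,
#'   Ser (plus IC and background); biopsies only AdC, BM, IC, background.
#' @param markers Marker specification data frame; see [default_markers()].
#' @param lockmass_mz Lockmass target m/z (default 554.2615, the
#'   deprotonated leucine-enkephalin reference).
#' @param lockmass_intensity Mean lockmass peak intensity (default 2000).
#' @param mass_drift_sd Per-slide mass drift SD in Da (default 0.002).
#' @param mz_jitter_sd Per-peak m/z jitter SD in Da (default 5e-4), well
#'   inside the 0.003 Da binning bandwidth.
#' @param patient_effect_sd Multiplicative log-scale SD of the per-patient,
#'   per-marker level effect (default 0; set > 0 to emulate patient-level
#'   batch structure).
#' @param tic_cv Coefficient of variation of the per-pixel total-intensity
#'   multiplier (default 0.25).
#' @param isotope_delta 13C-12C mass difference in Da (default 1.00336).
#' @param background_species Size of the cohort-wide background ion
#'   library (default 850).
#' @param background_slide_p Probability a background species is present
#'   on a given slide (default 1: every species can appear on every
#'   slide, so that with no planted patient effect the patients are
#'   statistically exchangeable; lower it to emulate slide-specific
#'   peak dropout).
#' @param background_pixel_p Probability a slide-present species appears
#'   in a given pixel (default 0.35). With the defaults the expected
#'   background peak count per pixel is about 300.
#' @param background_meanlog,background_sdlog Log-normal parameters of the
#'   species base intensities (defaults `log(100)` and 1).
#' @param pixel_noise_cv Per-pixel multiplicative noise CV applied to
#'   background peaks (default 0.5).
#' @param two_zone_patients Integer patient indices whose cross-section
#'   tumour is split into two metabolically distinct zones.
#' @param seed Integer seed; the full cohort is a deterministic function
#'   of the configuration.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_patients = 10,
                         mz_range = c(50, 1500),
                         pixel_size = 100,
                         cross_shape = c(40, 60),
                         biopsy_shape = c(20, 20),
                         regions = c("AdC", "BM", "Sub", "SM", "Ser", "IC",
                                     "background"),
                         markers = default_markers(),
                         lockmass_mz = 554.2615,
                         lockmass_intensity = 2000,
                         mass_drift_sd = 0.002,
                         mz_jitter_sd = 5e-4,
                         patient_effect_sd = 0,
                         tic_cv = 0.25,
                         isotope_delta = 1.00336,
                         background_species = 850,
                         background_slide_p = 1,
                         background_pixel_p = 0.35,
                         background_meanlog = log(100),
                         background_sdlog = 1,
                         pixel_noise_cv = 0.5,
                         two_zone_patients = integer(),
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (!is_count(cfg$n_patients) || cfg$n_patients < 1) {
    stop_field("n_patients", "must be a positive integer")
  }
  if (length(cfg$mz_range) != 2 || cfg$mz_range[1] >= cfg$mz_range[2]) {
    stop_field("mz_range", "must be an increasing length-2 interval")
  }
  for (f in c("cross_shape", "biopsy_shape")) {
    s <- cfg[[f]]
    if (length(s) != 2 || any(s < 3)) {
      stop_field(f, "grid dimensions must be >= 3 in each axis")
    }
  }
  need <- c("AdC", "BM", "Sub", "SM", "Ser", "IC", "background")
  if (!all(need %in% cfg$regions)) {
    stop_field("regions", paste("must include", paste(need, collapse = ", ")))
  }
  m <- cfg$markers
  if (!is.data.frame(m) ||
      !all(c("mz", "region", "fold", "base", "cv", "carbons") %in% names(m))) {
    stop_field("markers", "must have columns mz, region, fold, base, cv, carbons")
  }
  if (any(m$mz < cfg$mz_range[1] | m$mz > cfg$mz_range[2])) {
    stop_field("markers", "all marker m/z must lie within mz_range")
  }
  if (any(m$fold <= 0)) stop_field("markers", "fold change must be > 0")
  if (any(!m$region %in% setdiff(cfg$regions, "background"))) {
    stop_field("markers", "marker regions must be tissue regions")
  }
  if (cfg$lockmass_mz < cfg$mz_range[1] || cfg$lockmass_mz > cfg$mz_range[2]) {
    stop_field("lockmass_mz", "must lie within mz_range")
  }
  for (f in c("mass_drift_sd", "mz_jitter_sd", "patient_effect_sd", "tic_cv",
              "pixel_noise_cv")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop_field(f, "must be a non-negative number")
    }
  }
  if (cfg$isotope_delta <= 0) stop_field("isotope_delta", "must be > 0")
  if (!is_count(cfg$background_species) || cfg$background_species < 0) {
    stop_field("background_species", "must be a non-negative integer")
  }
  if (!is_count(cfg$seed)) stop_field("seed", "must be an integer")
  invisible(TRUE)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config: %d patients, m/z %g-%g, cross %dx%d / biopsy %dx%d,\n",
    "  %d markers, drift sd %g Da, patient effect sd %g, seed %d>\n"),
    x$n_patients, x$mz_range[1], x$mz_range[2],
    x$cross_shape[1], x$cross_shape[2], x$biopsy_shape[1], x$biopsy_shape[2],
    nrow(x$markers), x$mass_drift_sd, x$patient_effect_sd, x$seed))
  invisible(x)
}

#' Clinical metadata for the reference 10-patient cohort
#'
#' The clinical table the synthetic cohort reproduces: study identifier,
#' sex, age, procedure, tumour site and type, grade, size, pathological
#' staging, lymphovascular invasion (LVI) and mismatch-repair (MMR)
#' status for ten colorectal cancer resection patients. Six of the ten
#' patients are LVI-positive and one is MMR-deficient.
#'
#' @return A data frame with one row per patient.
#' @export
reference_cohort_table <- function() {
  data.frame(
    patient_id = as.character(1:10),
    sex = c("F", "F", "M", "F", "M", "M", "F", "M", "F", "M"),
    age = c(67, 73, 72, 92, 61, 86, 66, 65, 62, 73),
    procedure = c("Right hemicolectomy", "Subtotal colectomy",
                  "Rectosigmoid resection", "Right hemicolectomy",
                  "Right hemicolectomy", "Right hemicolectomy",
                  "Low anterior resection", "Right hemicolectomy",
                  "Right hemicolectomy", "Sigmoid resection"),
    site = c("Cecum", "Ascending", "Sigmoid", "Cecum", "Hepatic flexure",
             "Ascending", "Rectum", "ICV", "Ascending", "Sigmoid"),
    tumour_type = c("Mucinous", "AdC", "AdC", "AdC", "AdC", "Mucinous",
                    "AdC", "AdC", "AdC", "AdC"),
    grade = c("G2", "G2 (G3 20%)", "G2", "G2", "G2", "G2", "G2", "G2",
              "G2", "G2"),
    size_cm = c(4.9, 9, 6, 7, 2.5, 9, 3.2, 7, 4, 6),
    pt = c("3", "3", "3", "3", "3", "3", "3", "3", "4a", "3"),
    pn = c("1a", "0", "0", "0", "1a", "0", "1a", "0", "2b", "0"),
    pm = c("N", "N", "N", "N", "N", "N", "N", "N", "1c", "N"),
    lvi = c("negative", "negative", "positive", "negative", "positive",
            "negative", "positive", "positive", "positive", "positive"),
    mmr = c("intact", "deficient", "intact", "intact", "intact", "intact",
            "intact", "intact", "intact", "intact"),
    stringsAsFactors = FALSE
  )
}
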