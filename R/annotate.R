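# Putative identification: theoretical deprotonated masses from
# molecular formulas, ppm matching against a bundled reference table,
# and 13C isotopologue pairing.

# IUPAC/CODATA monoisotopic atomic masses (Da).
ELEMENT_MASSES <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809,
  K = 38.96370668, Cl = 34.96885268, F = 18.99840322, Br = 78.9183371,
  I = 126.904473, Se = 79.9165213
)

PROTON_MASS <- 1.00727646688

#' Parse a molecular formula
#'
#' @param formula A Hill-style formula string such as `"C20H38O2"`
#'   (no parentheses or charges).
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("unparseable formula: ", formula, call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Z][a-z]?", "", tokens), "1"))
  unknown <- setdiff(el, names(ELEMENT_MASSES))
  if (length(unknown)) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tapply(cnt, factor(el, levels = unique(el)), sum)
}

#' Theoretical m/z of the deprotonated molecular ion
#'
#' Monoisotopic neutral mass from the molecular formula minus the proton
#' mass (1.00727646688 Da) — the `[M-H]-` species observed in
#' negative-ionization DESI.
#'
#' @param formula Molecular formula string; must contain at least one
#'   hydrogen (deprotonation must be possible).
#' @return Theoretical m/z in Da.
#' @examples
#' theoretical_mz("C20H38O2")  # gondoic acid, 309.2799
#' @export
theoretical_mz <- function(formula) {
  counts <- parse_formula(formula)
  if (!"H" %in% names(counts) || counts[["H"]] < 1) {
    stop("formula has no hydrogen to deprotonate: ", formula, call. = FALSE)
  }
  neutral <- sum(ELEMENT_MASSES[names(counts)] * counts)
  unname(neutral - PROTON_MASS)
}

#' Mass error in parts per million
#'
#' @param measured,theoretical m/z values in Da.
#' @return `|measured - theoretical| / theoretical * 1e6`. Report to one
#'   decimal, the conventional precision.
#' @export
ppm_error <- function(measured, theoretical) {
  stopifnot(all(theoretical > 0))
  abs(measured - theoretical) / theoretical * 1e6
}

#' Load the bundled reference compound table
#'
#' Fatty acids, phospholipids and small metabolites relevant to
#' colorectal DESI profiles, plus the leucine-enkephalin lockmass.
#' Complex-lipid formulas are putative compositions consistent with the
#' lipid class and reported mass (flagged in the `note` column);
#' theoretical `[M-H]-` m/z values are computed from the formulas at load
#' time.
#'
#' @param path CSV with columns `name`, `formula`, `class`, `note`
#'   (default: the table shipped with the package).
#' @return Data frame with an added `theoretical_mz` column.
#' @export
load_reference_compounds <- function(path = system.file(
  "extdata", "reference_compounds.csv", package = "desiclass")) {
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  refs$theoretical_mz <- vapply(refs$formula, theoretical_mz, 0)
  refs
}

#' Match a bin centre against reference compounds
#'
#' @param bin_center Measured m/z (Da).
#' @param refs Reference table (see [load_reference_compounds()]).
#' @param tol_ppm Maximum acceptable mass error (default 10 ppm).
#' @return Candidates with `ppm <= tol_ppm`, sorted by ascending ppm;
#'   zero rows when nothing matches.
#' @export
match_reference <- function(bin_center, refs = load_reference_compounds(),
                            tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  ppm <- ppm_error(bin_center, refs$theoretical_mz)
  out <- refs[ppm <= tol_ppm, , drop = FALSE]
  out$ppm <- ppm[ppm <= tol_ppm]
  out <- out[order(out$ppm), ]
  rownames(out) <- NULL
  out
}

#' Pair bins with their 13C isotopologues
#'
#' For each bin, searches for a bin one 13C-12C mass difference
#' (1.00336 Da) heavier within `tol`; the pair with the smallest
#' deviation wins and a bin can be the isotopologue of at most one
#' lighter bin. The intensity ratio (heavy / light) approximates the
#' one-substitution 13C abundance, i.e. roughly 1.1% per carbon. (These
#' species are sometimes loosely called 13C "isomers"; isotopologue is
#' the precise term.)
#'
#' @param bins Bin data frame with a `center` column.
#' @param intensity Mean intensity per bin (same order); defaults to
#'   `bins$mean_intensity` or `NA`.
#' @param tol Pairing tolerance in Da (default 0.005).
#' @param delta Isotope mass difference (default 1.00336).
#' @return Data frame `mono_center`, `iso_center`, `delta`,
#'   `intensity_ratio`.
#' @export
pair_isotopes <- function(bins, intensity = NULL, tol = 0.005,
                          delta = 1.00336) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  centers <- bins$center
  intensity <- intensity %||% bins$mean_intensity %||%
    rep(NA_real_, length(centers))
  cand <- expand.grid(i = seq_along(centers), j = seq_along(centers))
  cand$dev <- abs(centers[cand$j] - centers[cand$i] - delta)
  cand <- cand[cand$dev <= tol & cand$i != cand$j, ]
  cand <- cand[order(cand$dev), ]
  used_mono <- used_iso <- logical(length(centers))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_mono[i] || used_iso[j]) next
    used_mono[i] <- TRUE; used_iso[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      mono_center = centers[i], iso_center = centers[j],
      delta = centers[j] - centers[i],
      intensity_ratio = intensity[j] / intensity[i])
  }
  if (!length(rows)) {
    return(data.frame(mono_center = numeric(), iso_center = numeric(),
                      delta = numeric(), intensity_ratio = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$mono_center), , drop = FALSE]
}

#' Annotate bins with putative identities and isotope links
#'
#' Convenience wrapper producing one report row per bin: the best
#' reference match within tolerance (if any) and the isotopologue
#' partner (if any).
#'
#' @param bins Bin data frame.
#' @param intensity Mean intensity per bin.
#' @param refs Reference table.
#' @param tol_ppm Match tolerance in ppm.
#' @param iso_tol Isotope pairing tolerance in Da.
#' @return Data frame `center`, `name`, `class`, `theoretical_mz`,
#'   `ppm`, `isotopologue_of`.
#' @export
annotate_bins <- function(bins, intensity = NULL,
                          refs = load_reference_compounds(),
                          tol_ppm = 10, iso_tol = 0.005) {
  pairs <- pair_isotopes(bins, intensity, tol = iso_tol)
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    hit <- match_reference(bins$center[i], refs, tol_ppm)
    iso <- pairs$mono_center[match(bins$center[i], pairs$iso_center)]
    data.frame(
      center = bins$center[i],
      name = if (nrow(hit)) hit$name[1] else NA_character_,
      class = if (nrow(hit)) hit$class[1] else NA_character_,
      theoretical_mz = if (nrow(hit)) hit$theoretical_mz[1] else NA_real_,
      ppm = if (nrow(hit)) hit$ppm[1] else NA_real_,
      isotopologue_of = if (length(iso)) iso else NA_real_)
  })
  do.call(rbind, rows)
}
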