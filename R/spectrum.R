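#' Construct a centroided mass spectrum
#'
#' A spectrum is a pair of equal-length numeric vectors: strictly ascending
#' m/z values (Da) and finite, non-negative intensities. Spectra are stored
#' as centroided peak lists, the form in which instrument software exports
#' DESI pixel data.
#'
#' @param mz Numeric vector of m/z values, strictly ascending.
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @return A list with components `mz` and `intensity`, class `"spectrum"`.
#' @examples
#' s <- spectrum(c(100.1, 200.2), c(5, 3))
#' @export
spectrum <- function(mz = numeric(), intensity = numeric()) {
  validate_spectrum(mz, intensity)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "spectrum")
}

validate_spectrum <- function(mz, intensity, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" at ", where)
  if (length(mz) != length(intensity)) {
    stop("spectrum mz and intensity lengths differ", ctx, call. = FALSE)
  }
  if (length(mz) && any(diff(mz) <= 0)) {
    stop("spectrum m/z values are not strictly ascending", ctx, call. = FALSE)
  }
  if (length(intensity) && (any(!is.finite(intensity)) || any(intensity < 0))) {
    stop("spectrum intensities must be finite and non-negative", ctx,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d peaks", length(x$mz)))
  if (length(x$mz)) {
    cat(sprintf(", m/z %.4f-%.4f, TIC %.3g", min(x$mz), max(x$mz),
                sum(x$intensity)))
  }
  cat(">\n")
  invisible(x)
}

#' Construct a slide image
#'
#' A slide image is a rectangular pixel grid of centroided spectra together
#' with the acquisition metadata the pipeline needs (pixel size, mass range)
#' and the identifiers that tie the slide to a patient and sample kind.
#' Pixels are stored row-major with a 0-based, top-left origin.
#'
#' @param slide_id,patient_id Identifiers.
#' @param sample_kind Either `"cross_section"` or `"biopsy"`.
#' @param dims Integer vector `c(nrow, ncol)` of the pixel grid.
#' @param spectra List of `nrow * ncol` spectra in row-major order.
#' @param pixel_size Pixel edge length in micrometres.
#' @param mz_range Acquired mass range, length-2 numeric (Da).
#' @param missing Optional logical vector flagging pixels that were absent
#'   from the source file and filled with empty spectra.
#' @return An object of class `"slide_image"`.
#' @export
slide_image <- function(slide_id, patient_id, sample_kind, dims, spectra,
                        pixel_size = 100, mz_range = c(50, 1500),
                        missing = NULL) {
  sample_kind <- match.arg(sample_kind, c("cross_section", "biopsy"))
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 1L)) {
    stop("dims must be two positive integers", call. = FALSE)
  }
  if (length(spectra) != prod(dims)) {
    stop("slide grid is not rectangular: expected ", prod(dims),
         " spectra, got ", length(spectra), call. = FALSE)
  }
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    validate_spectrum(sp$mz, sp$intensity, where = pixel_label(i, dims))
  }
  structure(list(
    slide_id = as.character(slide_id),
    patient_id = as.character(patient_id),
    sample_kind = sample_kind,
    dims = dims,
    spectra = spectra,
    pixel_size = pixel_size,
    mz_range = as.numeric(mz_range),
    mass_shift = NA_real_,
    tic_normalized = FALSE,
    missing = missing %||% rep(FALSE, prod(dims))
  ), class = "slide_image")
}

# Row-major pixel index -> "(row, col)" label, 0-based.
pixel_label <- function(i, dims) {
  r <- (i - 1L) %/% dims[2L]
  c <- (i - 1L) %% dims[2L]
  sprintf("pixel (%d, %d)", r, c)
}

# Row-major index of 0-based (row, col).
pixel_index <- function(row, col, dims) row * dims[2L] + col + 1L

#' @export
print.slide_image <- function(x, ...) {
  np <- sum(lengths(lapply(x$spectra, `[[`, "mz")))
  cat(sprintf("<slide_image %s: patient %s, %s, %dx%d px, %d peaks%s%s>\n",
              x$slide_id, x$patient_id, x$sample_kind,
              x$dims[1], x$dims[2], np,
              if (!is.na(x$mass_shift)) sprintf(", shift %+.4f Da", x$mass_shift) else "",
              if (isTRUE(x$tic_normalized)) ", TIC-normalized" else ""))
  invisible(x)
}

#' Construct an annotation mask
#'
#' A raster of tissue-region labels aligned to a slide's pixel grid. Labels
#' must be drawn from the declared region set.
#'
#' @param labels Character matrix of region labels.
#' @param regions Character vector of allowed region labels.
#' @param slide_id,patient_id,sample_kind Identifiers of the paired slide.
#' @return A character matrix of class `"annotation_mask"` with attributes
#'   `regions`, `slide_id`, `patient_id`, `sample_kind`.
#' @export
annotation_mask <- function(labels, regions, slide_id = NA, patient_id = NA,
                            sample_kind = NA) {
  if (!is.matrix(labels) || !is.character(labels)) {
    stop("labels must be a character matrix", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(labels)), regions)
  if (length(bad)) {
    stop("mask labels not in region set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(labels, regions = as.character(regions),
            slide_id = as.character(slide_id),
            patient_id = as.character(patient_id),
            sample_kind = as.character(sample_kind),
            class = c("annotation_mask", "matrix", "array"))
}

#' @export
print.annotation_mask <- function(x, ...) {
  tab <- table(as.vector(unclass(x)))
  cat(sprintf("<annotation_mask %s: %dx%d px; %s>\n",
              attr(x, "slide_id"), nrow(x), ncol(x),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

# Check a mask is shape-compatible with a slide before use.
check_pairing <- function(slide, mask) {
  if (nrow(mask) != slide$dims[1] || ncol(mask) != slide$dims[2]) {
    stop(sprintf("mask shape %dx%d does not match slide %s shape %dx%d",
                 nrow(mask), ncol(mask), slide$slide_id,
                 slide$dims[1], slide$dims[2]), call. = FALSE)
  }
  invisible(TRUE)
}
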