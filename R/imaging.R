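# Ion-image rendering from TIC-normalized pixels: single-ion heatmaps,
# three-channel composites, and PCA overview images.

#' Single-ion heatmap raster
#'
#' Per-pixel summed TIC-normalized intensity of peaks falling inside a
#' bin's interval, on the slide's pixel grid.
#'
#' @param slide A preprocessed (TIC-normalized) [slide_image()].
#' @param bin One-row bin data frame (columns `lo`, `hi`).
#' @return Numeric matrix of the slide's shape, class `"ion_image"` with
#'   the bin centre attached.
#' @export
single_ion_map <- function(slide, bin) {
  v <- pixel_bin_matrix(slide, seq_along(slide$spectra), bin[1, , drop = FALSE])
  img <- matrix(v[, 1], slide$dims[1], slide$dims[2], byrow = TRUE)
  structure(img, center = bin$center[1], class = c("ion_image", "matrix",
                                                   "array"))
}

# Percentile clip (1st-99th by default) then min-max scale to [0, 1].
clip_scale <- function(v, probs = c(0.01, 0.99)) {
  q <- quantile(v, probs, names = FALSE)
  if (q[2] <= q[1]) {
    return(list(values = v * 0, lo = q[1], hi = q[2]))
  }
  list(values = pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1),
       lo = q[1], hi = q[2])
}

#' Three-ion composite image
#'
#' Each RGB channel is a percentile-clipped (1st-99th), min-max scaled
#' single-ion heatmap, so regions enriched for different ions light up
#' in different colours.
#'
#' @param slide A preprocessed [slide_image()].
#' @param bins Exactly three distinct bins (data frame rows).
#' @param probs Clip percentiles (default `c(0.01, 0.99)`).
#' @return `nrow x ncol x 3` array in `[0, 1]`, with per-channel scaling
#'   parameters in the `"scaling"` attribute.
#' @export
composite_map <- function(slide, bins, probs = c(0.01, 0.99)) {
  if (nrow(bins) != 3) stop("exactly 3 bins required", call. = FALSE)
  if (anyDuplicated(bins$center)) stop("duplicate bins", call. = FALSE)
  out <- array(0, c(slide$dims[1], slide$dims[2], 3))
  scaling <- list()
  for (ch in 1:3) {
    img <- single_ion_map(slide, bins[ch, , drop = FALSE])
    cs <- clip_scale(as.vector(img), probs)
    out[, , ch] <- matrix(cs$values, slide$dims[1], slide$dims[2])
    scaling[[ch]] <- list(center = bins$center[ch], lo = cs$lo, hi = cs$hi)
  }
  attr(out, "scaling") <- scaling
  out
}

#' PCA overview image
#'
#' Projects every pixel's binned, TIC-normalized spectrum onto the first
#' three principal components (fit on the slide's own pixels) and
#' min-max scales each component into an RGB channel.
#'
#' @param slide A preprocessed [slide_image()].
#' @param bins Bin data frame defining the feature space.
#' @return `nrow x ncol x 3` array in `[0, 1]`.
#' @export
pca_rgb <- function(slide, bins) {
  x <- pixel_bin_matrix(slide, seq_along(slide$spectra), bins)
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 3)
  eff <- sum(pr$sdev > pr$sdev[1] * 1e-9)
  if (is.na(eff) || eff < 3 || pr$sdev[1] == 0) {
    stop("fewer than 3 effective principal components", call. = FALSE)
  }
  out <- array(0, c(slide$dims[1], slide$dims[2], 3))
  scaling <- list()
  for (ch in 1:3) {
    v <- pr$x[, ch]
    lo <- min(v); hi <- max(v)
    out[, , ch] <- matrix((v - lo) / (hi - lo), slide$dims[1],
                          slide$dims[2], byrow = TRUE)
    scaling[[ch]] <- list(component = ch, lo = lo, hi = hi)
  }
  attr(out, "scaling") <- scaling
  out
}

#' Write an ion image as PNG with a reproducibility sidecar
#'
#' Grayscale matrices and RGB arrays are written as-is; any scaling
#' parameters attached to the image are written to a JSON sidecar so the
#' rendering is reproducible.
#'
#' @param img Matrix or 3-channel array with values in `[0, 1]`, or an
#'   unscaled `"ion_image"` (min-max scaled before writing).
#' @param path PNG output path.
#' @export
write_ion_image <- function(img, path) {
  scaling <- attr(img, "scaling")
  if (is.matrix(img)) {
    lo <- min(img); hi <- max(img)
    if (hi > lo) {
      scaling <- scaling %||% list(lo = lo, hi = hi)
      img <- (img - lo) / (hi - lo)
    }
  }
  png::writePNG(unclass_strip(img), path)
  if (!is.null(scaling)) {
    jsonlite::write_json(scaling, sub("\\.png$", "_scaling.json", path),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

unclass_strip <- function(img) {
  attributes(img) <- attributes(img)[c("dim")]
  img
}
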