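# Slide, mask and table input/output.
#
# Slides travel as imzML 1.1 (XML metadata + external .ibd binary), masks
# as 8-bit grayscale PNG index images with a JSON legend, tables as
# CSV/TSV. Readers validate strictly and refuse silently-corrupt input.

io_log <- function(fmt, ...) {
  if (isTRUE(getOption("desiclass.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
}

# Deterministic 16-byte pseudo-UUID derived from a string id, so that
# writing the same slide twice yields byte-identical files.
slide_uuid <- function(id) {
  b <- as.integer(charToRaw(paste0(id, ":desiclass")))
  h <- rep(seq(7L, 247L, by = 16L), length.out = 16L)
  for (i in seq_along(b)) {
    j <- (i - 1L) %% 16L + 1L
    h[j] <- (h[j] * 31L + b[i]) %% 256L
  }
  as.raw(h)
}

uuid_string <- function(raw16) {
  h <- format(raw16)
  paste0("{", paste0(h[1:4], collapse = ""), "-", paste0(h[5:6], collapse = ""),
         "-", paste0(h[7:8], collapse = ""), "-", paste0(h[9:10], collapse = ""),
         "-", paste0(h[11:16], collapse = ""), "}")
}

ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Write a slide as imzML (processed mode)
#'
#' Writes the XML metadata file at `path` and the binary array file
#' alongside it with extension `.ibd`. Each pixel's m/z and intensity
#' arrays are stored as 64-bit floats; pixel coordinates are written
#' 1-based per the imzML convention.
#'
#' @param slide A [slide_image()].
#' @param path Output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  uuid <- slide_uuid(slide$slide_id)
  ibd <- ibd_path(path)
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  nr <- slide$dims[1]; nc <- slide$dims[2]
  sp_xml <- character(length(slide$spectra))
  for (i in seq_along(slide$spectra)) {
    sp <- slide$spectra[[i]]
    n <- length(sp$mz)
    writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + 8 * n
    writeBin(as.numeric(sp$intensity), con, size = 8, endian = "little")
    int_off <- offset; offset <- offset + 8 * n
    row <- (i - 1L) %/% nc; col <- (i - 1L) %% nc
    sp_xml[i] <- sprintf(
'   <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">
    <scanList count="1"><scan>
     <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
     <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
    </scan></scanList>
    <binaryDataArrayList count="2">
     <binaryDataArray encodedLength="0">
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
      <binary/>
     </binaryDataArray>
     <binaryDataArray encodedLength="0">
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
      <binary/>
     </binaryDataArray>
    </binaryDataArrayList>
   </spectrum>', i - 1L, i, n, col + 1L, row + 1L,
      mz_off, n, 8 * n, int_off, n, 8 * n)
  }
  header <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
 <fileDescription>
  <fileContent>
   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>
   <userParam name="slide_id" value="%s"/>
   <userParam name="patient_id" value="%s"/>
   <userParam name="sample_kind" value="%s"/>
   <userParam name="pixel_size_um" value="%g"/>
   <userParam name="mz_range" value="%g %g"/>
   <userParam name="max_count_x" value="%d"/>
   <userParam name="max_count_y" value="%d"/>
  </fileContent>
 </fileDescription>
 <run id="%s">
  <spectrumList count="%d">
', uuid_string(uuid), slide$slide_id, slide$patient_id, slide$sample_kind,
    slide$pixel_size, slide$mz_range[1], slide$mz_range[2], nc, nr,
    slide$slide_id, length(slide$spectra))
  writeLines(c(header, sp_xml, "  </spectrumList>\n </run>\n</mzML>"),
             path, sep = "\n")
  io_log("wrote slide %s to %s", slide$slide_id, path)
  invisible(path)
}

cv_value <- function(node, accession) {
  v <- xml2::xml_attr(
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession)),
    "value")
  v
}

#' Read a slide from imzML
#'
#' Accepts processed- or continuous-mode imzML with 32- or 64-bit float
#' arrays. Pixels absent from the file are filled with empty spectra and
#' flagged in the slide's `missing` vector. Non-monotone m/z or negative
#' intensities raise an error naming the offending pixel coordinate.
#'
#' @param path Path to an `.imzML` file; the `.ibd` file must sit
#'   alongside it.
#' @param slide_id,patient_id,sample_kind Optional overrides; defaults are
#'   taken from the file's user parameters when present.
#' @return A [slide_image()].
#' @export
read_slide <- function(path, slide_id = NULL, patient_id = NULL,
                       sample_kind = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed imzML XML in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  up <- function(name) {
    xml2::xml_attr(
      xml2::xml_find_first(doc, sprintf("//userParam[@name='%s']", name)),
      "value")
  }
  slide_id <- slide_id %||% (if (!is.na(up("slide_id"))) up("slide_id") else basename(path))
  patient_id <- patient_id %||% (if (!is.na(up("patient_id"))) up("patient_id") else NA_character_)
  sample_kind <- sample_kind %||% (if (!is.na(up("sample_kind"))) up("sample_kind") else "cross_section")
  pixel_size <- if (!is.na(up("pixel_size_um"))) as.numeric(up("pixel_size_um")) else 100
  mz_range <- if (!is.na(up("mz_range"))) as.numeric(strsplit(up("mz_range"), " ")[[1]]) else c(50, 1500)

  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stop("missing .ibd binary next to ", path, call. = FALSE)
  xml_uuid <- xml2::xml_attr(
    xml2::xml_find_first(doc, "//cvParam[@accession='IMS:1000080']"), "value")
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  file_uuid <- readBin(con, "raw", 16)
  if (!is.na(xml_uuid) && nzchar(xml_uuid) &&
      !identical(gsub("[{}-]", "", tolower(xml_uuid)),
                 paste0(format(file_uuid), collapse = ""))) {
    stop("imzML/ibd UUID mismatch for ", path, call. = FALSE)
  }

  nodes <- xml2::xml_find_all(doc, "//spectrum")
  if (!length(nodes)) stop("no spectra in ", path, call. = FALSE)
  xs <- integer(length(nodes)); ys <- integer(length(nodes))
  arr <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    xs[i] <- as.integer(cv_value(node, "IMS:1000050"))
    ys[i] <- as.integer(cv_value(node, "IMS:1000051"))
    if (is.na(xs[i]) || is.na(ys[i])) {
      stop("spectrum ", i, " lacks pixel coordinates in ", path, call. = FALSE)
    }
    bdas <- xml2::xml_find_all(node, ".//binaryDataArray")
    got <- list()
    for (b in bdas) {
      kind <- if (!is.na(xml2::xml_find_first(b, ".//cvParam[@accession='MS:1000514']") |> xml2::xml_attr("name"))) "mz"
              else if (!is.na(xml2::xml_find_first(b, ".//cvParam[@accession='MS:1000515']") |> xml2::xml_attr("name"))) "intensity"
              else next
      size <- if (!is.na(xml2::xml_find_first(b, ".//cvParam[@accession='MS:1000521']") |> xml2::xml_attr("name"))) 4L else 8L
      off <- as.numeric(cv_value(b, "IMS:1000102"))
      len <- as.integer(cv_value(b, "IMS:1000103"))
      got[[kind]] <- list(offset = off, length = len, size = size)
    }
    if (is.null(got$mz) || is.null(got$intensity)) {
      stop("spectrum ", i, " lacks m/z or intensity arrays in ", path,
           call. = FALSE)
    }
    arr[[i]] <- got
  }
  dims <- c(max(ys), max(xs))
  npix <- prod(dims)
  spectra <- rep(list(list(mz = numeric(), intensity = numeric())), npix)
  missing <- rep(TRUE, npix)
  for (i in seq_along(nodes)) {
    got <- arr[[i]]
    seek(con, got$mz$offset)
    mz <- readBin(con, "double", got$mz$length, size = got$mz$size,
                  endian = "little")
    seek(con, got$intensity$offset)
    ints <- readBin(con, "double", got$intensity$length,
                    size = got$intensity$size, endian = "little")
    coord <- sprintf("pixel (%d, %d)", ys[i] - 1L, xs[i] - 1L)
    if (length(mz) != length(ints)) {
      stop("array length mismatch at ", coord, " in ", path, call. = FALSE)
    }
    if (length(mz) > 1 && any(diff(mz) <= 0)) {
      stop("non-monotone m/z at ", coord, " in ", path, call. = FALSE)
    }
    if (length(ints) && (any(!is.finite(ints)) || any(ints < 0))) {
      stop("negative or non-finite intensity at ", coord, " in ", path,
           call. = FALSE)
    }
    k <- pixel_index(ys[i] - 1L, xs[i] - 1L, dims)
    spectra[[k]] <- list(mz = mz, intensity = ints)
    missing[k] <- FALSE
  }
  io_log("read slide %s from %s", slide_id, path)
  slide_image(slide_id, patient_id, sample_kind, dims, spectra,
              pixel_size = pixel_size, mz_range = mz_range,
              missing = missing)
}

#' Write an annotation mask as an indexed PNG plus JSON legend
#'
#' Region labels are mapped to 0-based palette indices (order of the
#' mask's region attribute) stored as 8-bit grayscale values; the legend
#' maps each index back to its label.
#'
#' @param mask An [annotation_mask()].
#' @param path Output PNG path.
#' @param legend_path Output JSON path (default: `path` with `.json`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, legend_path = sub("\\.png$", ".json", path)) {
  regions <- attr(mask, "regions")
  idx <- match(unclass(mask), regions) - 1L
  img <- matrix(idx / 255, nrow(mask), ncol(mask))
  png::writePNG(img, path)
  legend <- as.list(setNames(regions, as.character(seq_along(regions) - 1L)))
  jsonlite::write_json(legend, legend_path, auto_unbox = TRUE, pretty = TRUE)
  io_log("wrote mask %s to %s", attr(mask, "slide_id"), path)
  invisible(path)
}

#' Read an annotation mask from an indexed PNG
#'
#' @param path PNG path; pixel values are 0-based palette indices.
#' @param legend Either a JSON legend path or a named character vector /
#'   list mapping index (as character) to region label.
#' @param slide_id,patient_id,sample_kind Identifiers of the paired slide.
#' @return An [annotation_mask()].
#' @export
read_mask <- function(path, legend, slide_id = NA, patient_id = NA,
                      sample_kind = NA) {
  if (is.character(legend) && length(legend) == 1 && file.exists(legend)) {
    legend <- jsonlite::read_json(legend, simplifyVector = TRUE)
  }
  legend <- unlist(legend)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  idx <- round(img * 255)
  unknown <- setdiff(unique(as.vector(idx)), as.integer(names(legend)))
  if (length(unknown)) {
    stop("palette index ", paste(sort(unknown), collapse = ", "),
         " absent from legend", call. = FALSE)
  }
  labels <- matrix(unname(legend[as.character(idx)]), nrow(idx), ncol(idx))
  annotation_mask(labels, regions = unname(legend), slide_id = slide_id,
                  patient_id = patient_id, sample_kind = sample_kind)
}

#' Write or read a cohort index table
#'
#' The index is a TSV with one row per slide: `slide_id`, `patient_id`,
#' `sample_kind`, `slide_path`, `mask_path`. On read, slide ids must be
#' unique and every referenced path must resolve.
#'
#' @param index A data frame with the columns above.
#' @param path TSV path.
#' @return `write_cohort_index`: `path`, invisibly. `read_cohort_index`:
#'   the validated data frame.
#' @export
write_cohort_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_index
#' @export
read_cohort_index <- function(path) {
  idx <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (anyDuplicated(idx$slide_id)) {
    stop("duplicate slide_id in cohort index", call. = FALSE)
  }
  base <- dirname(path)
  for (col in c("slide_path", "mask_path")) {
    p <- ifelse(file.exists(idx[[col]]), idx[[col]],
                file.path(base, idx[[col]]))
    if (any(!file.exists(p))) {
      stop("unresolvable path(s) in cohort index: ",
           paste(idx[[col]][!file.exists(p)], collapse = ", "),
           call. = FALSE)
    }
    idx[[col]] <- p
  }
  idx
}

# Column names used for the on-disk clinical table.
patients_disk_names <- c(
  patient_id = "Study ID", sex = "Sex", age = "Age", procedure = "Procedure",
  site = "T. Site", tumour_type = "T. Type", grade = "Grade",
  size_cm = "Size", pt = "pT", pn = "pN", pm = "pM", lvi = "LVI", mmr = "MMR")

#' Write or read the clinical metadata table
#'
#' CSV with the conventional clinical column headings (Study ID, Sex,
#' Age, ..., LVI, MMR); internal column names are restored on read.
#'
#' @param patients Data frame as returned by [reference_cohort_table()].
#' @param path CSV path.
#' @export
write_patients <- function(patients, path) {
  out <- patients[, names(patients_disk_names)]
  names(out) <- unname(patients_disk_names)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(unname(patients_disk_names), names(raw))
  if (length(missing_cols)) {
    stop("clinical table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[, unname(patients_disk_names)]
  names(out) <- names(patients_disk_names)
  out$age <- as.numeric(out$age)
  out$size_cm <- as.numeric(out$size_cm)
  if (anyDuplicated(out$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  out
}

#' Save or load a whole cohort
#'
#' `save_cohort()` writes every slide as imzML, every mask as PNG+JSON,
#' the clinical table as CSV and an index TSV tying them together;
#' `load_cohort()` reverses the process from the index.
#'
#' @param cohort An `"msi_cohort"` (see [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `save_cohort`: the index path, invisibly. `load_cohort`: an
#'   `"msi_cohort"` list with `slides`, `masks`, `patients`.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$slides, function(sl) {
    sp <- file.path(dir, paste0(sl$slide_id, ".imzML"))
    mp <- file.path(dir, paste0(sl$slide_id, "_mask.png"))
    write_slide(sl, sp)
    write_mask(cohort$masks[[sl$slide_id]], mp)
    data.frame(slide_id = sl$slide_id, patient_id = sl$patient_id,
               sample_kind = sl$sample_kind,
               slide_path = basename(sp), mask_path = basename(mp),
               stringsAsFactors = FALSE)
  })
  index <- do.call(rbind, rows)
  write_patients(cohort$patients, file.path(dir, "patients.csv"))
  write_cohort_index(index, file.path(dir, "index.tsv"))
  invisible(file.path(dir, "index.tsv"))
}

#' @rdname save_cohort
#' @param index_path Path to the index TSV written by `save_cohort()`.
#' @export
load_cohort <- function(index_path) {
  idx <- read_cohort_index(index_path)
  dir <- dirname(index_path)
  slides <- list(); masks <- list()
  for (i in seq_len(nrow(idx))) {
    sl <- read_slide(idx$slide_path[i], slide_id = idx$slide_id[i],
                     patient_id = idx$patient_id[i],
                     sample_kind = idx$sample_kind[i])
    mk <- read_mask(idx$mask_path[i],
                    sub("\\.png$", ".json", idx$mask_path[i]),
                    slide_id = idx$slide_id[i],
                    patient_id = idx$patient_id[i],
                    sample_kind = idx$sample_kind[i])
    check_pairing(sl, mk)
    slides[[idx$slide_id[i]]] <- sl
    masks[[idx$slide_id[i]]] <- mk
  }
  patients <- read_patients(file.path(dir, "patients.csv"))
  structure(list(slides = slides, masks = masks, patients = patients),
            class = "msi_cohort")
}

#' Write a cross-validation result as JSON
#'
#' Serialises the confusion matrix (with class names), metrics and fold
#' assignments of a `"cv_result"`.
#'
#' @param cv A `"cv_result"` (see [lopo_cv()]).
#' @param path JSON output path.
#' @export
write_cv_result <- function(cv, path) {
  out <- list(
    classes = rownames(cv$confusion),
    confusion = unname(apply(cv$confusion, 1, as.list)),
    accuracy = cv$accuracy,
    per_class = as.list(cv$per_class),
    sensitivity = cv$sensitivity,
    specificity = cv$specificity,
    n_pca_effective = cv$n_pca_effective,
    folds = lapply(cv$folds, function(f) lapply(f, as.integer))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write or read a feature matrix as CSV
#'
#' ROI metadata columns come first, then one column per bin named by the
#' bin centre printed to three decimals. Numeric cells are written with
#' enough digits to round-trip doubles exactly. Bin centres that collide
#' after rounding raise an error.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  bn <- bin_names(fm$bins$center)
  out <- fm$rois
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  mat <- matrix(sprintf("%.17g", fm$x), nrow(fm$x), ncol(fm$x))
  colnames(mat) <- bn
  utils::write.csv(cbind(out, as.data.frame(mat, stringsAsFactors = FALSE)),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  is_bin <- grepl("^[0-9]+\\.[0-9]{3}$", names(raw))
  if (anyDuplicated(names(raw)[is_bin])) {
    stop("duplicate bin column names in ", path, call. = FALSE)
  }
  rois <- raw[, !is_bin, drop = FALSE]
  for (col in intersect(c("row", "col"), names(rois))) {
    rois[[col]] <- as.integer(rois[[col]])
  }
  x <- as.matrix(raw[, is_bin, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- NULL
  centers <- as.numeric(names(raw)[is_bin])
  feature_matrix(x, rois,
                 data.frame(center = centers, lo = NA_real_, hi = NA_real_,
                            n_slides_present = NA_integer_,
                            member_count = NA_integer_))
}
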