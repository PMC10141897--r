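# imzML slides, PNG masks, clinical and feature tables: round trips and
# strict validation.

test_that("slides round-trip through imzML exactly", {
  fx <- small_cohort()
  slide <- fx$cohort$slides[["P02_CS"]]
  path <- file.path(tempdir(), "rt.imzML")
  write_slide(slide, path)
  back <- read_slide(path)
  expect_identical(back$slide_id, slide$slide_id)
  expect_identical(back$patient_id, slide$patient_id)
  expect_identical(back$sample_kind, slide$sample_kind)
  expect_identical(back$dims, slide$dims)
  # 64-bit float storage: bit-identical arrays
  expect_identical(back$spectra, slide$spectra)
  expect_false(any(back$missing))
  # byte-stable writer: writing again produces identical files
  path2 <- file.path(tempdir(), "rt2.imzML")
  write_slide(slide, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  expect_identical(readBin(sub("imzML$", "ibd", path), "raw", 1e7),
                   readBin(sub("imzML$", "ibd", path2), "raw", 1e7))
})

test_that("corrupt pixels are rejected with their coordinate", {
  sp <- list(list(mz = c(100, 200), intensity = c(1, 2)),
             list(mz = c(100, 200), intensity = c(3, 4)))
  slide <- slide_image("bad", "p", "cross_section", c(1, 2), sp)
  path <- file.path(tempdir(), "bad.imzML")
  write_slide(slide, path)
  # overwrite pixel (0, 1)'s m/z array (offset 16 + 2 arrays * 16 bytes)
  con <- file(sub("imzML$", "ibd", path), "r+b")
  seek(con, 16 + 32, rw = "write")
  writeBin(c(200, 100), con, size = 8, endian = "little")
  close(con)
  expect_error(read_slide(path), "non-monotone.*\\(0, 1\\)")
  # negative intensity
  write_slide(slide, path)
  con <- file(sub("imzML$", "ibd", path), "r+b")
  seek(con, 16 + 16, rw = "write")
  writeBin(c(-1, 2), con, size = 8, endian = "little")
  close(con)
  expect_error(read_slide(path), "negative.*\\(0, 0\\)")
})

test_that("continuous-mode imzML with missing pixels is accepted and flagged", {
  # hand-written continuous file: shared m/z array, 32-bit intensities,
  # 3 of 4 grid positions present
  dir <- tempdir()
  ibd <- file.path(dir, "cont.ibd")
  con <- file(ibd, "wb")
  writeBin(as.raw(rep(7, 16)), con)
  mz <- c(100.5, 200.5, 300.5)
  writeBin(mz, con, size = 8, endian = "little")                 # offset 16
  ints <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  for (v in ints) writeBin(v, con, size = 4, endian = "little")  # offsets 40+
  close(con)
  coords <- list(c(1, 1), c(2, 1), c(2, 2))
  spec_xml <- vapply(seq_along(coords), function(i) {
    sprintf(paste0(
      '<spectrum index="%d" id="s%d" defaultArrayLength="3"><scanList><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList><binaryDataArrayList count="2"><binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="16"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="3"/>',
      '</binaryDataArray><binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="3"/>',
      '</binaryDataArray></binaryDataArrayList></spectrum>'),
      i - 1L, i, coords[[i]][1], coords[[i]][2], 40 + (i - 1L) * 12)
  }, "")
  xml <- paste0('<?xml version="1.0"?><mzML><fileDescription><fileContent>',
                '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
                '</fileContent></fileDescription><run><spectrumList count="3">',
                paste(spec_xml, collapse = ""),
                '</spectrumList></run></mzML>')
  writeLines(xml, file.path(dir, "cont.imzML"))
  slide <- read_slide(file.path(dir, "cont.imzML"))
  expect_identical(slide$dims, c(2L, 2L))
  expect_identical(slide$spectra[[1]]$mz, mz)
  expect_equal(slide$spectra[[4]]$intensity, c(7, 8, 9))
  # pixel (x=1, y=2) i.e. row-major index 3 is missing and empty
  expect_identical(slide$missing, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(length(slide$spectra[[3]]$mz), 0L)
})

test_that("masks round-trip through indexed PNG with a JSON legend", {
  fx <- small_cohort()
  mask <- fx$cohort$masks[["P01_CS"]]
  path <- file.path(tempdir(), "mask.png")
  write_mask(mask, path)
  back <- read_mask(path, sub("\\.png$", ".json", path),
                    slide_id = attr(mask, "slide_id"))
  expect_identical(unclass(back)[, ], unclass(mask)[, ])
})

test_that("mask reading validates the legend and pairing validates shape", {
  img <- matrix(1 / 255, 2, 2)
  path <- file.path(tempdir(), "toy.png")
  png::writePNG(img, path)
  out <- read_mask(path, c("0" = "background", "1" = "AdC"))
  expect_true(all(unclass(out) == "AdC"))
  # palette index absent from the legend is reported by number
  png::writePNG(matrix(7 / 255, 2, 2), path)
  expect_error(read_mask(path, c("0" = "background", "1" = "AdC")),
               "index 7")
  # pairing a mask with a slide of a different shape fails
  fx <- small_cohort()
  expect_error(
    desiclass:::check_pairing(fx$cohort$slides[["P01_CS"]], out),
    "does not match")
})

test_that("cohort index and clinical tables validate on read", {
  dir <- file.path(tempdir(), "idx")
  dir.create(dir, showWarnings = FALSE)
  f1 <- file.path(dir, "a.imzML"); writeLines("x", f1)
  f2 <- file.path(dir, "a_mask.png"); writeLines("x", f2)
  idx <- data.frame(slide_id = "a", patient_id = "1",
                    sample_kind = "cross_section",
                    slide_path = "a.imzML", mask_path = "a_mask.png")
  p <- file.path(dir, "index.tsv")
  write_cohort_index(idx, p)
  expect_identical(read_cohort_index(p)$slide_id, "a")
  write_cohort_index(rbind(idx, idx), p)
  expect_error(read_cohort_index(p), "duplicate slide_id")
  idx$mask_path <- "missing.png"
  write_cohort_index(idx, p)
  expect_error(read_cohort_index(p), "unresolvable")

  tab <- reference_cohort_table()
  pc <- file.path(dir, "patients.csv")
  write_patients(tab, pc)
  back <- read_patients(pc)
  expect_identical(back$lvi, tab$lvi)
  expect_identical(back$age, tab$age)
})

test_that("a whole cohort survives save and load", {
  cfg <- synth_config(n_patients = 2, cross_shape = c(10, 14),
                      biopsy_shape = c(8, 8), background_species = 40,
                      seed = 19)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  idx <- save_cohort(co, dir)
  back <- load_cohort(idx)
  expect_identical(names(back$slides), names(co$slides))
  for (id in names(co$slides)) {
    expect_identical(back$slides[[id]]$spectra, co$slides[[id]]$spectra)
    expect_identical(unclass(back$masks[[id]])[, ],
                     unclass(co$masks[[id]])[, ])
  }
  expect_identical(back$patients$lvi, co$patients$lvi)
})

test_that("feature matrices round-trip through CSV", {
  fx <- small_cohort()
  fm <- fx$pipe$fm
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_identical(unname(back$x), unname(fm$x))
  expect_identical(colnames(back$x), colnames(fm$x))
  expect_identical(back$rois$slide_id, fm$rois$slide_id)
  expect_identical(back$rois$region, fm$rois$region)
  expect_equal(back$bins$center, as.numeric(sprintf("%.3f", fm$bins$center)))
  # empty matrix: header-only file, still readable
  empty <- feature_matrix(
    matrix(numeric(), 0, nrow(fm$bins)),
    fm$rois[0, ], fm$bins)
  write_feature_matrix(empty, path)
  back0 <- read_feature_matrix(path)
  expect_identical(nrow(back0$x), 0L)
  expect_identical(ncol(back0$x), ncol(fm$x))
})
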