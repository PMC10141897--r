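# The synthetic cohort generator: structure, determinism, planted
# effects, and the single-spectrum sampler.

test_that("a cohort has one cross section and one biopsy per patient", {
  fx <- small_cohort()
  co <- fx$cohort
  expect_identical(length(co$slides), 6L)
  expect_identical(length(co$masks), 6L)
  expect_identical(nrow(co$patients), 3L)
  kinds <- table(vapply(co$slides, `[[`, "", "sample_kind"))
  expect_identical(as.integer(kinds[c("cross_section", "biopsy")]), c(3L, 3L))
  # masks pair with slides and use only configured labels
  for (id in names(co$slides)) {
    expect_identical(dim(co$masks[[id]]), co$slides[[id]]$dims)
    expect_true(all(unclass(co$masks[[id]]) %in% fx$cfg$regions))
  }
  # cross sections carry the full layered anatomy; biopsies only
  # mucosa/tumour/inflammation
  expect_true(all(c("AdC", "BM", "Sub", "SM", "Ser") %in%
                    unique(as.vector(unclass(co$masks[["P01_CS"]])))))
  expect_true(all(unique(as.vector(unclass(co$masks[["P01_BX"]]))) %in%
                    c("AdC", "BM", "IC", "background")))
})

test_that("generation is deterministic given the configuration", {
  cfg <- synth_config(n_patients = 2, cross_shape = c(12, 18),
                      biopsy_shape = c(8, 8), background_species = 60,
                      seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$slides, b$slides)
  expect_identical(a$masks, b$masks)
  c2 <- generate_cohort(synth_config(n_patients = 2,
                                     cross_shape = c(12, 18),
                                     biopsy_shape = c(8, 8),
                                     background_species = 60, seed = 8))
  expect_false(identical(a$slides, c2$slides))
})

test_that("invalid configurations name the offending field", {
  expect_error(synth_config(n_patients = 0), "n_patients")
  expect_error(synth_config(cross_shape = c(2, 10)), "cross_shape")
  expect_error(synth_config(mz_range = c(1500, 50)), "mz_range")
  mk <- default_markers(); mk$fold[1] <- -2
  expect_error(synth_config(markers = mk), "markers")
  mk2 <- default_markers(); mk2$mz[1] <- 9999
  expect_error(synth_config(markers = mk2), "markers")
  expect_error(synth_config(mass_drift_sd = -1), "mass_drift_sd")
})

test_that("spectra are valid centroid lists with the lockmass in every pixel", {
  fx <- small_cohort()
  slide <- fx$cohort$slides[["P03_CS"]]
  drift <- slide$true_drift
  for (i in sample(length(slide$spectra), 20)) {
    sp <- slide$spectra[[i]]
    expect_true(all(diff(sp$mz) > 0))
    expect_true(all(sp$intensity >= 0))
    expect_true(any(abs(sp$mz - (554.2615 + drift)) < 1e-9))
  }
})

test_that("pixel-level fold change and isotope ratio match the generator's expectation", {
  fx <- default_scale_cohort()
  slide <- fx$slides[["P01_CS"]]
  mask <- fx$cohort$masks[["P01_CS"]]
  bins <- data.frame(center = c(309.2794, 310.28276),
                     lo = c(309.2774, 310.2808), hi = c(309.2814, 310.2848),
                     n_slides_present = 1L, member_count = 1L)
  img_mono <- single_ion_map(slide, bins[1, ])
  adc <- unclass(mask) == "AdC"
  tissue <- !adc & unclass(mask) != "background"
  expect_gt(sum(adc), 400)
  ratio <- mean(img_mono[adc]) / mean(img_mono[tissue])
  # configured fold 4.5; the planted markers' own TIC share dilutes the
  # TIC-normalized ratio by ~10% at the default background
  expect_gt(ratio, 3.8)
  expect_lt(ratio, 5.2)
  # one-substitution 13C isotopologue at the carbon-count fraction
  img_iso <- single_ion_map(slide, bins[2, ])
  expect_equal(mean(img_iso[adc]) / mean(img_mono[adc]), 20 * 0.0107,
               tolerance = 0.05)
})

test_that("biopsies reuse the patient's marker levels", {
  # strong patient effects: cross-section and biopsy AdC levels correlate
  cfg <- synth_config(n_patients = 6, cross_shape = c(16, 24),
                      biopsy_shape = c(10, 10), background_species = 80,
                      patient_effect_sd = 1, seed = 31)
  co <- generate_cohort(cfg)
  pp <- lapply(co$slides, preprocess_slide)
  bins <- data.frame(center = 309.2794, lo = 309.2774, hi = 309.2814,
                     n_slides_present = 1L, member_count = 1L)
  lvl <- function(id) {
    m <- single_ion_map(pp[[id]], bins)
    mean(m[unclass(co$masks[[id]]) == "AdC"])
  }
  cs <- vapply(sprintf("P%02d_CS", 1:6), lvl, 0)
  bx <- vapply(sprintf("P%02d_BX", 1:6), lvl, 0)
  expect_gt(cor(log(cs), log(bx)), 0.8)
})

test_that("synth_spectrum draws single pixels from the same model", {
  cfg <- synth_config(background_species = 50, seed = 3)
  set.seed(1)
  bg <- synth_spectrum(cfg, "background", drift = 0)
  expect_true(any(bg$mz == 554.2615))  # lockmass, undrifted
  expect_true(all(diff(bg$mz) > 0))
  # a fixed drift shifts every m/z by exactly that amount
  set.seed(9); a <- synth_spectrum(cfg, "AdC", drift = 0)
  set.seed(9); b <- synth_spectrum(cfg, "AdC", drift = 0.003)
  expect_equal(b$mz, a$mz + 0.003)
  expect_error(synth_spectrum(cfg, "stroma"), "unknown region")
})

test_that("marker intensity is stochastically larger in its enriched region", {
  cfg <- synth_config(background_species = 50, seed = 3)
  marker_level <- function(region, n = 200) {
    vapply(seq_len(n), function(i) {
      sp <- synth_spectrum(cfg, region)
      sel <- abs(sp$mz - 309.2794) < 0.002
      sum(sp$intensity[sel]) / sum(sp$intensity)
    }, 0)
  }
  set.seed(11)
  adc <- marker_level("AdC")
  ser <- marker_level("Ser")
  expect_lt(wilcox.test(adc, ser, alternative = "greater")$p.value, 0.01)
})

test_that("the reference clinical table drives cohort metadata", {
  tab <- reference_cohort_table()
  expect_identical(sum(tab$lvi == "positive"), 6L)
  expect_identical(sum(tab$mmr == "deficient"), 1L)
  co <- generate_cohort(synth_config(n_patients = 10,
                                     cross_shape = c(6, 8),
                                     biopsy_shape = c(4, 4),
                                     background_species = 10, seed = 2))
  expect_identical(co$patients$lvi, tab$lvi)
  expect_identical(co$patients$sex, tab$sex)
})
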