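# PCA/LDA classification, leave-one-patient-out CV, the adversarial
# patient experiment, and unsupervised exploration.

test_that("pcalda separates linearly separable classes and caps components", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  g <- rep(c("a", "b"), each = 30)
  fit <- pcalda(x, g, n_pca = 1000)
  expect_identical(mean(predict(fit, x)$class == g), 1)
  # requested 1000, data rank caps at min(n - 1, p) = 2
  expect_identical(fit$n_pca_effective, 2L)
  expect_error(pcalda(x, rep("a", 60)), "single-class")
})

test_that("the LDA embedding has lda_dims axes", {
  fx <- small_cohort()
  fm <- cross_section_fm(fx$pipe$fm)
  lab <- map_labels(fm$rois, "six_class")
  fit <- pcalda(fm, lab, n_pca = 40, lda_dims = 3)
  emb <- predict(fit, fm)$x
  expect_identical(ncol(emb), 3L)
  expect_identical(nrow(emb), nrow(fm$x))
})

test_that("fisher_lda agrees with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(4)
  x <- rbind(matrix(rnorm(150, 0), 50), matrix(rnorm(150, 1.2), 50),
             matrix(rnorm(150, 2.6), 50))
  g <- rep(letters[1:3], each = 50)
  ours <- predict(desiclass:::fisher_lda(x, g), x)$class
  theirs <- predict(MASS::lda(x, g), x)$class
  expect_gt(mean(as.character(ours) == as.character(theirs)), 0.97)
})

test_that("leave-one-patient-out folds never share a patient", {
  fx <- small_cohort()
  fm <- cross_section_fm(fx$pipe$fm)
  cv <- lopo_cv(fm, map_labels(fm$rois, "binary_tumour"), n_pca = 40)
  expect_identical(length(cv$folds), 3L)
  for (f in cv$folds) {
    expect_length(intersect(fm$rois$patient_id[f$train],
                            fm$rois$patient_id[f$test]), 0)
  }
  # confusion row sums equal true class counts; accuracy is the trace share
  lab <- map_labels(fm$rois, "binary_tumour")
  expect_identical(unname(rowSums(cv$confusion)),
                   as.numeric(table(lab)[rownames(cv$confusion)]))
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / sum(cv$confusion))
})

test_that("biopsy-transfer folds train on cross sections only", {
  fx <- small_cohort()
  fm <- fx$pipe$fm
  cv <- lopo_cv(fm, map_labels(fm$rois, "binary_tumour"), n_pca = 40,
                test_set = "biopsy")
  for (f in cv$folds) {
    expect_true(all(fm$rois$sample_kind[f$train] == "cross_section"))
    expect_true(all(fm$rois$sample_kind[f$test] == "biopsy"))
    expect_length(intersect(fm$rois$patient_id[f$train],
                            fm$rois$patient_id[f$test]), 0)
  }
  expect_gt(cv$accuracy, 0.9)  # planted markers transfer to biopsies
})

test_that("one ROI per patient degenerates to leave-one-out", {
  set.seed(6)
  x <- cbind(c(rlnorm(8, 0, 0.3), rlnorm(8, 3, 0.3)), runif(16))
  fm <- toy_fm(x, region = rep(c("AdC", "BM"), each = 8),
               patient_id = 1:16)
  cv <- lopo_cv(fm, map_labels(fm$rois, "binary_tumour"), n_pca = 2)
  expect_identical(length(cv$folds), 16L)
  expect_true(all(vapply(cv$folds, function(f) length(f$test), 0L) == 1L))
  expect_gt(cv$accuracy, 0.8)
})

test_that("shuffled labels drive LOPO accuracy to chance", {
  fx <- small_cohort()
  fm <- cross_section_fm(fx$pipe$fm)
  lab <- map_labels(fm$rois, "binary_tumour")
  accs <- vapply(1:4, function(s) {
    shuffled <- desiclass:::with_seed(s, sample(as.character(lab)))
    lopo_cv(fm, shuffled, n_pca = 40)$accuracy
  }, 0)
  p_major <- max(table(lab)) / length(lab)
  se <- sqrt(p_major * (1 - p_major) / length(lab))
  # chance level for a prior-aware classifier is the majority share
  expect_lt(abs(mean(accs) - p_major), 3 * se + 0.05)
})

test_that("binary accuracy rises with the planted fold change", {
  accs <- vapply(c(1, 2, 4), function(fc) {
    mk <- default_markers()[1, ]
    mk$fold <- fc
    cfg <- synth_config(n_patients = 3, cross_shape = c(20, 30),
                        biopsy_shape = c(10, 10), background_species = 150,
                        markers = mk, patient_effect_sd = 0.2,
                        seed = 404)
    co <- generate_cohort(cfg)
    pipe <- run_pipeline(co, k = c(AdC = 8, BM = 2, Sub = 2, SM = 2, Ser = 2),
                         seed = 5)
    fm <- cross_section_fm(pipe$fm)
    lopo_cv(fm, map_labels(fm$rois, "binary_tumour"), n_pca = 40)$accuracy
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_lt(accs[1], 0.75)   # no marker: near chance
  expect_gt(accs[3], 0.9)    # strong marker: recovered
})

test_that("adversarial patient prediction is at chance without patient effects", {
  fx <- small_cohort()  # patient_effect_sd = 0
  adv <- adversarial_patient_cv(fx$pipe$fm, n_pca = 40, seed = 8)
  chance <- 1 / 3
  n <- sum(adv$confusion)
  se <- sqrt(chance * (1 - chance) / n)
  expect_lt(abs(adv$accuracy - chance), 3 * se)
})

test_that("strong patient effects make patients identifiable", {
  cfg <- synth_config(n_patients = 4, cross_shape = c(20, 30),
                      biopsy_shape = c(10, 10), background_species = 150,
                      patient_effect_sd = 1.2, seed = 55)
  co <- generate_cohort(cfg)
  pipe <- run_pipeline(co, k = c(AdC = 10), seed = 3)
  adv <- adversarial_patient_cv(pipe$fm, n_pca = 40, seed = 8)
  expect_gt(adv$accuracy, 2 / 4)
  # per-ion patient ranking: top ion beats chance, and a pure background
  # ion sits near chance
  rk <- single_ion_patient_cv(pipe$fm, seed = 8)
  expect_gt(rk$accuracy[1], 2 / 4)
  bg <- rk[!vapply(rk$center, function(cc) {
    any(abs(cc - cfg$markers$mz) < 0.01 | abs(cc - cfg$markers$mz - 1.00336) < 0.01)
  }, TRUE), ]
  expect_lt(min(bg$accuracy), 0.45)
  # single patient: error
  one <- pipe$fm
  keep <- one$rois$patient_id == "1"
  fm1 <- feature_matrix(one$x[keep, ], one$rois[keep, ], one$bins)
  expect_error(adversarial_patient_cv(fm1), "two patients")
})

test_that("k-means recovers planted structure", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
  cl <- kmeans_explore(x, 2, seed = 3)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 20)), 1)
  expect_identical(kmeans_explore(x, nrow(x), seed = 3), seq_len(nrow(x)))
  expect_error(kmeans_explore(x, nrow(x) + 1, seed = 3), "rows")
})

test_that("two tumour zones split AdC ROIs into two clusters", {
  cfg <- synth_config(n_patients = 2, cross_shape = c(26, 40),
                      biopsy_shape = c(10, 10), background_species = 150,
                      two_zone_patients = 1L, seed = 63)
  co <- generate_cohort(cfg)
  pipe <- run_pipeline(co, k = c(AdC = 14), seed = 6)
  fm <- pipe$fm
  rows <- which(fm$rois$slide_id == "P01_CS" & fm$rois$region == "AdC")
  zone <- attr(co$masks[["P01_CS"]], "zone")
  roi_zone <- vapply(rows, function(r) {
    zone[fm$rois$row[r] + 2, fm$rois$col[r] + 2]  # centre pixel
  }, 0L)
  skip_if(length(unique(roi_zone)) < 2)
  cl <- kmeans_explore(fm$x[rows, ], 2, seed = 12)
  expect_gt(adjusted_rand_index(cl, roi_zone), 0.5)
})
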