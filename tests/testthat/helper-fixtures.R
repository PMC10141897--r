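# Shared fixtures and independent oracles. Expensive cohorts are built
# once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# Small, fast cohort used by most pipeline-level tests.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- synth_config(n_patients = 3, cross_shape = c(24, 36),
                        biopsy_shape = c(12, 12), background_species = 200,
                        seed = 42)
    cohort <- generate_cohort(cfg)
    pipe <- run_pipeline(cohort, k = 8, seed = 1)
    .fixtures$small <- list(cfg = cfg, cohort = cohort, pipe = pipe)
  }
  .fixtures$small
}

# Two patients at the default acquisition scale (full grids, full
# background library) for calibration checks that depend on realistic
# TIC composition.
default_scale_cohort <- function() {
  if (is.null(.fixtures$default_scale)) {
    cfg <- synth_config(n_patients = 2, seed = 77)
    cohort <- generate_cohort(cfg)
    pp <- lapply(cohort$slides, preprocess_slide)
    .fixtures$default_scale <- list(cfg = cfg, cohort = cohort, slides = pp)
  }
  .fixtures$default_scale
}

# Cross-section-only view of a feature matrix.
cross_section_fm <- function(fm) {
  cs <- fm$rois$sample_kind == "cross_section"
  feature_matrix(fm$x[cs, , drop = FALSE], fm$rois[cs, , drop = FALSE],
                 fm$bins)
}

# ---- independent oracles -------------------------------------------------

# Brute-force valley-finding partition on a global fine grid, written
# independently of kde_partition: plain dnorm sums, no segmentation, no
# refinement beyond the 1e-4 grid.
oracle_kde_partition <- function(x, bandwidth, step = 1e-4) {
  grid <- seq(min(x) - 4 * bandwidth, max(x) + 4 * bandwidth, by = step)
  dens <- colSums(exp(-outer(x, grid, "-")^2 / (2 * bandwidth^2)))
  n <- length(dens)
  mins <- which(dens[2:(n - 1)] < dens[3:n] &
                  dens[2:(n - 1)] <= dens[1:(n - 2)]) + 1L
  cuts <- grid[mins]
  cuts <- cuts[cuts > min(x) & cuts < max(x)]
  findInterval(x, sort(cuts)) + 1L
}

# Random clustered m/z instance for oracle-equivalence checks: cluster
# means separated by at least 3 bandwidths, members jittered with
# SD 0.0005 (the generator's jitter scale).
random_cluster_instance <- function(seed, bandwidth = 0.003,
                                    max_peaks = 500) {
  set.seed(seed)
  n_clusters <- sample(2:10, 1)
  base <- runif(1, 100, 1400)
  gaps <- runif(n_clusters, 3 * bandwidth, 40 * bandwidth)
  centers <- base + cumsum(gaps)
  sizes <- sample(5:floor(max_peaks / n_clusters), n_clusters, replace = TRUE)
  mz <- unlist(lapply(seq_len(n_clusters), function(i) {
    rnorm(sizes[i], centers[i], 5e-4)
  }))
  mz[seq_len(min(length(mz), max_peaks))]
}

# Same partition up to relabelling?
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1)
}

# Monte-Carlo oracle for the single-ion leave-one-patient-out regime:
# simulates the reduced generative model directly (log-normal marker,
# per-patient level effect, 9-pixel ROI averaging, TIC dilution by the
# planted marker itself, midpoint threshold estimated from the training
# patients) without touching the pipeline.
oracle_single_ion_accuracy <- function(n_rep = 300, n_patients = 10,
                                       rois_per_class = 16, fold = 4.5,
                                       cv = 0.35, patient_sd = 0.65,
                                       seed = 2024) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  roi_mean <- function(n, mu) {
    colMeans(matrix(mu * rlnorm(9 * n, -sdlog^2 / 2, sdlog), 9, n))
  }
  acc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    eff <- rlnorm(n_patients, 0, patient_sd)
    # per-patient ROI log-intensities for the two classes
    pos <- lapply(seq_len(n_patients), function(p) {
      log(roi_mean(rois_per_class, fold * eff[p]))
    })
    neg <- lapply(seq_len(n_patients), function(p) {
      log(roi_mean(rois_per_class, 1 * eff[p]))
    })
    correct <- 0L
    for (p in seq_len(n_patients)) {
      tr <- setdiff(seq_len(n_patients), p)
      thr <- (mean(unlist(pos[tr])) + mean(unlist(neg[tr]))) / 2
      correct <- correct + sum(pos[[p]] > thr) + sum(neg[[p]] <= thr)
    }
    acc[r] <- correct / (2 * n_patients * rois_per_class)
  }
  acc
}

# A minimal hand-built feature matrix.
toy_fm <- function(x, region, patient_id,
                   sample_kind = rep("cross_section", nrow(x)),
                   centers = seq_len(ncol(x)) + 100) {
  rois <- data.frame(
    slide_id = paste0("S", patient_id), patient_id = as.character(patient_id),
    sample_kind = sample_kind, region = region, stringsAsFactors = FALSE)
  bins <- data.frame(center = centers, lo = centers - 0.0015,
                     hi = centers + 0.0015,
                     n_slides_present = NA_integer_,
                     member_count = NA_integer_)
  feature_matrix(x, rois, bins)
}
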