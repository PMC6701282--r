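test_that("the generator is deterministic given spec and seed", {
  spec <- synth_spec(n_low = 2, n_high = 2, n_volumes = 64, seed = 11)
  t1 <- generate_cohort_table(spec)
  t2 <- generate_cohort_table(spec)
  expect_identical(t1, t2)
  r1 <- generate_bold_run(spec, t1[1, ], 1)
  r2 <- generate_bold_run(spec, t1[1, ], 1)
  expect_identical(r1, r2)
  r3 <- generate_bold_run(spec, t1[2, ], 2)
  expect_false(identical(r1$data, r3$data))
})

test_that("generated runs respect the declared structure", {
  cd <- tiny_cohort()
  spec <- cd$spec
  run <- cd$runs[[1]]
  expect_equal(dim(run$data), c(spec$grid_shape, spec$n_volumes))
  expect_true(all(is.finite(run$data)))
  expect_equal(unname(apply(run$motion[, 1:3], 2, sd)),
               rep(spec$motion_sd_mm, 3), tolerance = 1e-10)
  expect_equal(unname(apply(run$motion[, 4:6], 2, sd)),
               rep(spec$motion_sd_rad, 3), tolerance = 1e-10)
  # tissue masks live inside the brain and exclude the lesion
  expect_true(all(run$brain_mask[run$wm_mask]))
  expect_true(all(run$brain_mask[run$csf_mask]))
  expect_false(any(run$wm_mask & run$lesion_mask))
  expect_false(any(run$csf_mask & run$lesion_mask))
  expect_false(any(run$wm_mask & run$csf_mask))
})

test_that("madrs scores honour the group cut-off and target moments", {
  spec <- synth_spec(seed = 3)
  cohort <- generate_cohort_table(spec)
  lo <- cohort$madrs_total[cohort$group == "low"]
  hi <- cohort$madrs_total[cohort$group == "high"]
  expect_true(all(lo <= 8) && all(lo >= 0))
  expect_true(all(hi > 8) && all(hi <= 60))
  expect_equal(mean(lo), 2.29, tolerance = 0.75)
  expect_equal(mean(hi), 14.88, tolerance = 0.30)
})

test_that("a slow-5 injected effect lands in slow-5, not slow-4", {
  spec <- synth_spec(n_low = 1, n_high = 1, n_volumes = 96,
                     effect_band = "slow5", osc_amplitude = 10,
                     beta_interaction = 0.5, bg_osc_amplitude = 0,
                     lesion_radius_range = c(0, 0), seed = 5)
  cohort <- generate_cohort_table(spec)
  run <- generate_bold_run(spec, cohort[2, ], 2)   # high-group subject
  masks <- synthetic_masks(spec)
  bands <- falff_bands()
  diff_for <- function(band) {
    m <- falff_map(run$data, masks$brain, spec$tr_seconds, band)$raw
    mean(m[masks$effect]) - mean(m[masks$brain & !masks$effect])
  }
  d5 <- diff_for(bands$slow5)
  d4 <- diff_for(bands$slow4)
  expect_gt(d5, 0.05)
  expect_lt(abs(d4), d5)
})

test_that("injected amplitude scales linearly with the symptom score", {
  spec <- synth_spec(n_low = 2, n_high = 10, n_volumes = 96,
                     beta_interaction = 0.5, osc_amplitude = 4,
                     noise_1f_sd = 2, white_sd = 1,
                     lesion_radius_range = c(0, 0), seed = 9)
  cohort <- generate_cohort_table(spec)
  masks <- synthetic_masks(spec)
  band <- falff_bands()$slow5
  hi_rows <- which(cohort$group == "high")
  t <- spec$n_volumes
  est <- vapply(hi_rows, function(i) {
    run <- generate_bold_run(spec, cohort[i, ], i)
    eff_idx <- which(masks$effect)
    amps <- vapply(eff_idx[1:20], function(v) {
      co <- arrayInd(v, spec$grid_shape)
      sp <- amplitude_spectrum(run$data[co[1], co[2], co[3], ],
                               spec$tr_seconds)
      inside <- sp$freq >= band$lo & sp$freq < band$hi
      # Parseval: band RMS amplitude = sqrt(2 * sum |X_k|^2) / t
      sqrt(2 * sum(sp$amplitude[inside]^2)) / t
    }, numeric(1))
    mean(amps)
  }, numeric(1))
  slope <- stats::coef(stats::lm(est ~ cohort$madrs_total[hi_rows]))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.2)
})

test_that("writing a cohort produces loadable NIfTIs with correct headers", {
  spec <- synth_spec(n_low = 1, n_high = 1, n_volumes = 140, seed = 21)
  cd <- generate_cohort(spec)
  dest <- file.path(tempdir(), "synth-write")
  manifest <- write_cohort(cd, dest)
  bolds <- list.files(dest, pattern = "_bold\\.nii\\.gz$",
                      full.names = TRUE)
  expect_length(bolds, 2)
  hdr <- RNifti::niftiHeader(RNifti::readNifti(bolds[1]))
  expect_equal(hdr$dim[1:5], c(4L, 24L, 24L, 24L, 140L))
  expect_equal(hdr$pixdim[2:5], c(3, 3, 3, 3))
  mot <- as.matrix(read.table(file.path(dest, "sub-001_motion.txt")))
  expect_equal(dim(mot), c(140L, 6L))
  # regenerating from the manifest reproduces every file bit-identically
  cd2 <- cohort_from_manifest(file.path(dest, "manifest.json"))
  dest2 <- file.path(tempdir(), "synth-write-2")
  manifest2 <- write_cohort(cd2, dest2)
  expect_identical(manifest$files, manifest2$files)
  unlink(c(dest, dest2), recursive = TRUE)
})

test_that("an effect region outside the brain is rejected", {
  expect_error(synth_spec(effect_center = c(2, 2, 2), effect_radius = 5),
               "outside the brain")
  expect_error(synth_spec(n_volumes = 40), "at least 64")
})
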