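test_that("the interaction design has the documented shape and df", {
  cohort <- generate_cohort_table(synth_spec(seed = 8))   # 38 + 25
  d <- build_design(cohort)
  expect_equal(dim(d$X), c(63L, 4L))
  expect_equal(d$df, 59L)
  expect_equal(d$labels, c("intercept", "group", "score", "group_score"))
  expect_equal(d$X[, "group_score"], d$X[, "group"] * d$X[, "score"],
               ignore_attr = TRUE)
  d7 <- build_design(cohort, covariates = c("age", "sex", "nihss"))
  expect_equal(ncol(d7$X), 7L)
  expect_equal(d7$df, 56L)
  # covariates are mean-centred
  expect_lt(abs(mean(d7$X[, "age"])), 1e-10)
  # degenerate cohorts are rejected
  same <- cohort; same$madrs_total <- 10
  same$group <- assign_group(same$madrs_total)
  expect_error(build_design(same), "single group")
  two_score <- cohort
  two_score$madrs_total <- ifelse(cohort$group == "high", 10L, 3L)
  expect_error(build_design(two_score), "rank deficient")
})

test_that("voxelwise t-statistics match a per-voxel lm oracle", {
  set.seed(20)
  cohort <- generate_cohort_table(synth_spec(n_low = 12, n_high = 8,
                                             seed = 20))
  d <- build_design(cohort)
  n <- nrow(d$X)
  gamma <- 0.05
  maps <- 0.5 * matrix(rnorm(n * 20), n, 20)
  maps[, 1:10] <- maps[, 1:10] + gamma * d$X[, "group_score"]
  fit <- fit_voxelwise(maps, d)
  expect_equal(fit$df, n - 4L)
  oracle <- tmap_lm_oracle(maps, d$X, 4)
  expect_equal(fit$t, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(mean(fit$t[1:10]), mean(fit$t[11:20]))
  # a stronger effect gives larger t on average
  maps2 <- maps; maps2[, 1:10] <- maps2[, 1:10] + 2 * gamma * d$X[, 4]
  fit2 <- fit_voxelwise(maps2, d)
  expect_gt(mean(fit2$t[1:10]), mean(fit$t[1:10]))
  # zero-variance voxels are flagged and given t = 0
  maps3 <- maps; maps3[, 5] <- 1
  fit3 <- fit_voxelwise(maps3, d)
  expect_true(fit3$zero_variance[5])
  expect_equal(fit3$t[5], 0)
})

test_that("null-contrast t-values follow the Student reference", {
  set.seed(21)
  cohort <- generate_cohort_table(synth_spec(n_low = 12, n_high = 8,
                                             seed = 21))
  d <- build_design(cohort)
  maps <- matrix(rnorm(nrow(d$X) * 800), nrow(d$X), 800)
  fit <- fit_voxelwise(maps, d)
  ks <- stats::ks.test(fit$t, stats::pt, df = fit$df)
  expect_gt(ks$p.value, 1e-3)
})

test_that("t_to_z and r_squared behave as documented", {
  expect_equal(t_to_z(0, 10), 0)
  expect_equal(t_to_z(1.96, 1e6), 1.96, tolerance = 1e-3)
  expect_equal(t_to_z(-2.5, 30), -t_to_z(2.5, 30), tolerance = 1e-12)
  ts <- seq(-6, 6, by = 0.5)
  expect_true(all(diff(t_to_z(ts, 15)) > 0))
  # extreme statistics stay finite (log-space evaluation)
  expect_true(is.finite(t_to_z(50, 59)))
  expect_equal(r_squared(0, 59), 0)
  expect_equal(r_squared(5.06, 59), 5.06^2 / (5.06^2 + 59))
  expect_true(all(diff(r_squared(seq(0, 8, 0.5), 20)) > 0))
})

test_that("cluster formation respects threshold and connectivity", {
  dims <- c(12, 12, 12)
  tmap <- array(0, dims)
  df <- 59
  thr <- qt(1 - 0.001, df)
  # one 5-voxel blob
  blob <- rbind(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(5, 5, 6), c(4, 5, 5))
  tmap[blob] <- thr + 1
  cl <- form_clusters(tmap, df)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$extent, 5L)
  expect_equal(cl$clusters$peak_t, thr + 1)
  # two blobs touching only at a corner: 6-connectivity splits them,
  # 26-connectivity joins them
  tmap2 <- array(0, dims)
  tmap2[3, 3, 3] <- thr + 1
  tmap2[4, 4, 4] <- thr + 2
  expect_equal(nrow(form_clusters(tmap2, df, connectivity = 6)$clusters), 2L)
  expect_equal(nrow(form_clusters(tmap2, df, connectivity = 18)$clusters), 2L)
  expect_equal(nrow(form_clusters(tmap2, df, connectivity = 26)$clusters), 1L)
  # sub-threshold maps yield an empty cluster set
  expect_equal(nrow(form_clusters(array(0, dims), df)$clusters), 0L)
})

test_that("component labelling agrees with an igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(22)
  dims <- c(10, 10, 10)
  for (conn in c(6, 18, 26)) {
    sel <- which(runif(prod(dims)) < 0.08)
    coords <- arrayInd(sel, dims)
    lab <- falffband:::.label_components(coords, dims, conn)
    oracle <- label_oracle(coords, conn)
    expect_equal(canonical_labels(lab), canonical_labels(oracle))
  }
})

test_that("adding a constant or relabelling groups leaves t intact", {
  set.seed(23)
  cohort <- generate_cohort_table(synth_spec(n_low = 10, n_high = 8,
                                             seed = 23))
  d <- build_design(cohort)
  maps <- matrix(rnorm(nrow(d$X) * 50), nrow(d$X), 50)
  t0 <- fit_voxelwise(maps, d)$t
  shifted <- maps + 3.14
  expect_equal(fit_voxelwise(shifted, d)$t, t0, tolerance = 1e-9)
  # swap group coding: |t| of the interaction is unchanged
  swapped <- cohort
  swapped$group <- ifelse(cohort$group == "high", "low", "high")
  class(swapped) <- class(cohort)
  x2 <- cbind(intercept = 1,
              group = as.numeric(swapped$group == "high"),
              score = cohort$madrs_total,
              group_score = as.numeric(swapped$group == "high") *
                cohort$madrs_total)
  d2 <- list(X = x2, labels = colnames(x2), contrast = 4L,
             df = nrow(x2) - 4L)
  expect_equal(abs(fit_voxelwise(maps, d2)$t), abs(t0), tolerance = 1e-9)
})

test_that("cluster FWE p-values are valid and monotone in extent", {
  set.seed(24)
  spec <- synth_spec(n_low = 8, n_high = 7, n_volumes = 64,
                     beta_interaction = 0, lesion_radius_range = c(0, 0),
                     seed = 24)
  cd <- generate_cohort(spec)
  maps <- stack_falff(cd, falff_bands()$slow5)
  d <- build_design(cd$cohort)
  fwe <- cluster_fwe(maps, d, cd$masks$brain, p_form = 0.01,
                     n_perm = 99, seed = 1)
  cl <- fwe$clusters
  expect_true(all(fwe$perm_max_extent >= 0))
  if (nrow(cl) >= 2) {
    # sorted by corrected p; larger clusters never have larger p
    expect_true(all(diff(cl$p_fwe) >= 0))
    expect_true(all(cl$p_fwe > 0 & cl$p_fwe <= 1))
    expect_true(all(diff(cl$extent) <= 0 | diff(cl$p_fwe) <= 0))
  }
  expect_warning(
    fwe0 <- cluster_fwe(maps, d, cd$masks$brain, n_perm = 0, seed = 1),
    "n_perm = 0")
  if (nrow(fwe0$clusters)) expect_true(all(fwe0$clusters$p_fwe == 1))
})

test_that("cluster reports map peaks through the affine and labels", {
  dims <- c(12, 12, 12)
  df <- 59
  thr <- qt(1 - 0.001, df)
  tmap <- array(0, dims)
  tmap[10, 12, 11] <- thr + 3
  tmap[10, 11, 11] <- thr + 1
  fake <- list(clusters = NULL, tmap = tmap, df = df, threshold = thr,
               perm_max_extent = integer(0))
  obs <- form_clusters(tmap, df)
  fake$clusters <- obs$clusters
  fake$clusters$peak_z <- t_to_z(fake$clusters$peak_t, df)
  fake$clusters$r2 <- r_squared(fake$clusters$peak_t, df)
  fake$clusters$p_fwe <- 0.01
  fake$clusters$significant <- TRUE
  fake$voxels <- obs$voxels
  rep1 <- report_clusters(fake, affine = diag(4))
  expect_equal(c(rep1$x_mm, rep1$y_mm, rep1$z_mm), c(9, 11, 10))
  aff <- diag(c(-3, 3, 3, 1))
  rep2 <- report_clusters(fake, affine = aff)
  expect_equal(rep2$x_mm, -27)
  # labelled volume: peak label + percentage overlap per label
  labels <- array(1L, dims); labels[, 12, ] <- 2L
  rep3 <- report_clusters(fake, affine = diag(4), label_volume = labels,
                          label_names = c("1" = "regionA", "2" = "regionB"))
  expect_equal(rep3$region, "regionB")
  expect_true(grepl("regionA:50%", rep3$label_overlap))
  expect_true(grepl("regionB:50%", rep3$label_overlap))
  expect_error(report_clusters(fake, label_volume = array(1L, c(5, 5, 5))),
               "grid")
})
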