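test_that("friston24 expansion has the documented block structure", {
  set.seed(1)
  m <- matrix(rnorm(20 * 6), 20, 6)
  x <- friston24(m)
  expect_equal(dim(x), c(20L, 24L))
  expect_equal(x[, 1:6], m, ignore_attr = TRUE)
  expect_equal(x[, 7:12], rbind(0, m[-20, ]), ignore_attr = TRUE)
  expect_equal(x[, 13], m[, 1]^2, ignore_attr = TRUE)   # direct recomputation
  expect_equal(x[, 13:18], m^2, ignore_attr = TRUE)
  expect_equal(x[, 19:24], rbind(0, m[-20, ])^2, ignore_attr = TRUE)
  # constant motion: lag columns equal the originals except row 1
  mc <- matrix(rep(1:6, each = 10), 10, 6)
  xc <- friston24(mc)
  expect_equal(xc[-1, 7:12], mc[-1, ], ignore_attr = TRUE)
  expect_equal(unname(xc[1, 7:12]), rep(0, 6))
  expect_true(all(friston24(matrix(0, 10, 6)) == 0))
  expect_error(friston24(matrix(0, 10, 5)), "6 columns")
})

test_that("mask erosion matches cube geometry and composes", {
  cube <- array(FALSE, c(9, 9, 9))
  cube[3:7, 3:7, 3:7] <- TRUE
  e1 <- erode_mask(cube, 1)
  expect_equal(sum(e1), 27)
  expect_true(all(which(e1) %in% which(cube)))
  e2 <- erode_mask(cube, 2)
  expect_equal(sum(e2), 1)
  expect_true(e2[5, 5, 5])
  # composition: two passes equal one double pass, on a random blob
  set.seed(2)
  blob <- array(runif(14^3) < 0.7, c(14, 14, 14))
  blob[3:12, 3:12, 3:12] <- TRUE   # solid core survives two erosions
  expect_identical(erode_mask(blob, 2), erode_mask(erode_mask(blob, 1), 1))
  expect_error(erode_mask(array(FALSE, c(5, 5, 5)), 1), "empty")
  tiny <- array(FALSE, c(5, 5, 5)); tiny[3, 3, 3] <- TRUE
  expect_error(erode_mask(tiny, 1), "fewer iterations")
})

test_that("acompcor recovers a shared component and returns an orthobasis", {
  set.seed(3)
  t <- 60
  shared <- sin(seq(0, 6 * pi, length.out = t))
  dims <- c(6, 6, 6)
  mask <- array(FALSE, dims); mask[2:4, 2:4, 2:4] <- TRUE
  nvox <- sum(mask)
  data <- array(0, c(dims, t))
  m <- matrix(rnorm(prod(dims) * t, sd = 0.01), prod(dims), t)
  m[which(mask), ] <- m[which(mask), ] +
    matrix(rep(shared, each = nvox), nvox, t)
  data <- array(m, c(dims, t))
  comp <- acompcor(data, mask, 5)
  expect_equal(dim(comp), c(t, 5L))
  # compare against the shared series after the documented linear detrend
  shared_d <- stats::residuals(stats::lm(shared ~ seq_len(t)))
  expect_gt(abs(cor(comp[, 1], shared_d)), 0.99)
  gram <- crossprod(comp)
  expect_equal(gram, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  ev <- attr(comp, "explained_variance")
  expect_gt(ev[1], 0.9)
  expect_equal(ncol(acompcor(data, mask, 0)), 0L)
  small <- array(FALSE, dims); small[2, 2, 2:3] <- TRUE
  expect_error(acompcor(data, small, 5), "fewer than")
  expect_error(acompcor(data, array(FALSE, dims), 5), "empty")
})

test_that("global signal is the in-mask mean per volume", {
  dims <- c(5, 5, 5); t <- 12
  mask <- array(runif(prod(dims)) < 0.5, dims)
  data <- array(rnorm(prod(dims) * t), c(dims, t))
  gs <- global_signal(data, mask)
  # brute-force oracle
  oracle <- vapply(seq_len(t), function(v) mean(data[, , , v][mask]),
                   numeric(1))
  expect_equal(gs, oracle, tolerance = 1e-12)
  uni <- array(7, c(dims, t))
  expect_equal(global_signal(uni, mask), rep(7, t))
  one <- array(FALSE, dims); one[2, 3, 4] <- TRUE
  expect_equal(global_signal(data, one), data[2, 3, 4, ])
  expect_error(global_signal(data, array(FALSE, dims)), "empty")
})

test_that("despike clips isolated spikes and leaves clean data untouched", {
  set.seed(4)
  x <- rnorm(50)
  spiked <- x; spiked[25] <- x[25] + 10 * sd(x)
  out <- despike(spiked)
  expect_identical(out[-25], spiked[-25])     # others bit-identical
  trend <- stats::runmed(spiked, 7, endrule = "median")
  s <- stats::mad(spiked - trend)
  expect_lte(abs(out[25] - trend[25]), 4 * s + 1e-12)
  expect_lt(abs(out[25] - x[25]), abs(spiked[25] - x[25]))
  # monotone ramp: no spikes, exact no-op
  ramp <- seq(0, 5, length.out = 40)
  expect_identical(despike(ramp), ramp)
  # two adjacent spikes both attenuated
  x2 <- rnorm(60); x2[c(30, 31)] <- x2[c(30, 31)] + c(12, -12)
  out2 <- despike(x2)
  expect_true(all(abs(out2[30:31]) < abs(x2[30:31])))
  expect_identical(out2[-(30:31)], x2[-(30:31)])
})

test_that("nuisance regression is an orthogonal projection", {
  set.seed(5)
  t <- 40; dims <- c(4, 4, 4)
  x <- cbind(1, seq_len(t) / t, matrix(rnorm(t * 3), t, 3))
  # data built from a design column: residual vanishes
  data <- array(rep(x[, 3], each = prod(dims)), c(dims, t))
  data <- aperm(array(x[, 3], c(t, dims)), c(2, 3, 4, 1))
  res <- regress_nuisance(data, x)
  expect_lt(sqrt(sum(res^2)) / sqrt(sum(data^2)), 1e-8)
  # residuals orthogonal to every design column
  data2 <- array(rnorm(prod(dims) * t), c(dims, t))
  res2 <- regress_nuisance(data2, x)
  y <- t(matrix(res2, prod(dims), t))
  expect_lt(max(abs(crossprod(x, y))) / sqrt(sum(data2^2)), 1e-6)
  # matches a naive per-voxel normal-equations solve
  y0 <- t(matrix(data2, prod(dims), t))
  beta <- solve(crossprod(x), crossprod(x, y0))
  expect_equal(y, y0 - x %*% beta, tolerance = 1e-10)
  # idempotence: a second regression changes nothing
  res3 <- regress_nuisance(res2, x)
  expect_equal(res3, res2, tolerance = 1e-8)
  expect_error(regress_nuisance(data2, cbind(x, x[, 3])), "rank deficient")
  expect_error(regress_nuisance(data2, x[1:10, ]), "rows")
})

test_that("gaussian smoothing matches the analytic kernel", {
  dims <- c(15, 15, 15)
  imp <- array(0, c(dims, 1)); imp[8, 8, 8, 1] <- 1
  fwhm <- 6; vox <- 3
  sm <- smooth_gaussian(imp, fwhm, vox)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  r <- ceiling(4 * sigma)
  g <- exp(-(-r:r)^2 / (2 * sigma^2)); g <- g / sum(g)
  expected <- outer(outer(g, g), g)
  got <- sm[8 + (-r:r), 8 + (-r:r), 8 + (-r:r), 1]
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(sm), 1, tolerance = 1e-6)    # interior impulse mass
  expect_identical(smooth_gaussian(imp, 0, vox), imp)
})

test_that("the full nuisance design has 37 labelled columns", {
  cd <- tiny_cohort()
  run <- cd$runs[[1]]
  des <- build_nuisance_design(run$data, run$motion, run$wm_mask,
                               run$csf_mask, run$brain_mask,
                               run$lesion_mask)
  expect_equal(ncol(des$design), 37L)
  expect_length(des$dropped, 0)
  expect_true(all(c("intercept", "trend", "global") %in% des$labels))
  expect_equal(sum(grepl("^mot", des$labels)), 24L)
  expect_equal(sum(grepl("^compcor", des$labels)), 10L)
  # all-zero motion: the 24 motion columns are collinear and dropped
  expect_warning(
    des0 <- build_nuisance_design(run$data, run$motion * 0, run$wm_mask,
                                  run$csf_mask, run$brain_mask,
                                  run$lesion_mask),
    "collinear")
  expect_equal(ncol(des0$design), 13L)
})

test_that("lesion voxels are excluded from aCompCor masks before erosion", {
  cd <- tiny_cohort()
  run <- cd$runs[[1]]
  lesion <- run$wm_mask & FALSE
  idx <- which(run$wm_mask)
  lesion[idx[seq_len(20)]] <- TRUE
  des_lesion <- build_nuisance_design(run$data, run$motion, run$wm_mask,
                                      run$csf_mask, run$brain_mask,
                                      lesion_mask = lesion)
  des_carved <- build_nuisance_design(run$data, run$motion,
                                      run$wm_mask & !lesion,
                                      run$csf_mask, run$brain_mask,
                                      lesion_mask = NULL)
  expect_equal(des_lesion$design, des_carved$design)
})
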