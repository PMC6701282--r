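# Independent oracles and small shared fixtures.

# O(t^2) discrete-Fourier amplitude oracle: per-bin |sum x_j e^{-2pi i jk/t}|
# after removing a least-squares line, for k = 1..floor(t/2).
dft_amplitude_oracle <- function(series, tr_seconds) {
  t <- length(series)
  fitline <- stats::lm.fit(cbind(1, seq_len(t)), series)
  x <- fitline$residuals
  nf <- floor(t / 2)
  amp <- vapply(seq_len(nf), function(k) {
    re <- sum(x * cos(-2 * pi * (0:(t - 1)) * k / t))
    im <- sum(x * sin(-2 * pi * (0:(t - 1)) * k / t))
    sqrt(re^2 + im^2)
  }, numeric(1))
  list(freq = seq_len(nf) / (t * tr_seconds), amplitude = amp)
}

falff_oracle <- function(series, tr_seconds, band) {
  sp <- dft_amplitude_oracle(series, tr_seconds)
  inside <- sp$freq >= band$lo & sp$freq < band$hi
  sum(sp$amplitude[inside]) / sum(sp$amplitude)
}

# Per-voxel t-statistic oracle via a scalar lm fit.
tmap_lm_oracle <- function(maps, x, contrast) {
  vapply(seq_len(ncol(maps)), function(v) {
    fit <- stats::lm(maps[, v] ~ x - 1)
    summary(fit)$coefficients[contrast, "t value"]
  }, numeric(1))
}

# Connected-component oracle over suprathreshold voxels via igraph.
label_oracle <- function(coords, connectivity) {
  nv <- nrow(coords)
  if (nv <= 1) return(rep(1L, nv))
  offs <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  edges <- c()
  for (a in seq_len(nv - 1)) for (b in (a + 1):nv) {
    d <- abs(coords[a, ] - coords[b, ])
    if (max(d) <= 1 && sum(d) >= 1 && sum(d) <= offs)
      edges <- c(edges, a, b)
  }
  g <- igraph::make_graph(edges, n = nv, directed = FALSE)
  igraph::components(g)$membership
}

canonical_labels <- function(lab) match(lab, unique(lab))

# Exact fixed-margins p-value for a 2x2 table by hypergeometric
# enumeration (totals small).
exact_fixed_margin_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  obs <- chisq_2x2(tab)
  a_range <- max(0, r1 - c2):min(r1, c1)
  p <- 0
  for (a in a_range) {
    t2 <- matrix(c(a, r1 - a, c1 - a, c2 - (r1 - a)), 2, byrow = TRUE)
    if (chisq_2x2(t2) >= obs - 1e-12)
      p <- p + stats::dhyper(a, c1, c2, r1)
  }
  p
}

# Small cached synthetic cohort shared across test files.
.fixture_env <- new.env()

tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    spec <- synth_spec(n_low = 4, n_high = 4, n_volumes = 64, seed = 42)
    .fixture_env$tiny <- generate_cohort(spec)
  }
  .fixture_env$tiny
}

# Stack z-scored fALFF maps of generated runs into an n x V matrix
# (optionally after nuisance cleaning).
stack_falff <- function(cohort_data, band, clean = FALSE) {
  brain <- cohort_data$masks$brain
  idx <- which(brain)
  tr <- cohort_data$spec$tr_seconds
  maps <- matrix(0, length(cohort_data$runs), length(idx))
  for (i in seq_along(cohort_data$runs)) {
    run <- cohort_data$runs[[i]]
    dat <- if (clean) clean_run(run,
                                voxel_size_mm =
                                  cohort_data$spec$voxel_size_mm)$data
           else run$data
    fm <- zscore_map(falff_map(dat, brain, tr, band))
    maps[i, ] <- fm$zscored[idx]
  }
  maps
}
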