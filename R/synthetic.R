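#' Specification for a synthetic resting-state cohort
#'
#' Bundles every parameter of the synthetic study generator.  Defaults
#' emulate the motivating two-group post-stroke cohort: 38 low- and 25
#' high-symptom subjects, MADRS-SIGMA scores drawn near group means
#' 2.29 (SD 2.31) and 14.88 (SD 6.67), EPI geometry of 3 mm isotropic
#' voxels at TR = 3 s with 140 volumes (7 minutes), and a band-limited
#' oscillation whose amplitude grows with the symptom score in the high
#' group only (the interaction alternative).  The default 24x24x24 test
#' grid keeps a full-cohort run fast; the acquisition-scale 72x72x44
#' grid is available by setting `grid_shape`.
#'
#' @param n_low,n_high Subjects per group.
#' @param grid_shape Integer 3-vector of volume dimensions (min dimension
#'   at least 20 so eroded tissue masks stay non-empty).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param tr_seconds Repetition time in seconds.
#' @param n_volumes Time points; at least 64 so the slow-5 band
#'   (0.01-0.027 Hz) contains spectral bins at TR = 3 s.
#' @param effect_band Band carrying the injected oscillation:
#'   `"broadband"`, `"slow5"` or `"slow4"`.
#' @param effect_center Voxel index 3-vector of the effect-region centre;
#'   `NULL` places it inside the brain automatically.
#' @param effect_radius Radius (voxels) of the spherical effect region.
#' @param beta_interaction Oscillation amplitude added per MADRS point,
#'   high group only (signal units per score unit; >= 0).  The default
#'   (`osc_amplitude / 12`) makes the effect-region amplitude double
#'   across the high group's observed score range (roughly 9 to 30, the
#'   range over which the amplitude actually varies).
#' @param osc_amplitude Baseline oscillation amplitude present in every
#'   subject's effect region (signal units, RMS).
#' @param bg_osc_amplitude Peak amplitude of the stable background
#'   oscillation topography: two fixed smooth spatial fields (one per
#'   subband) scale band-limited oscillations present in every subject,
#'   giving fALFF maps reproducible regional structure like real
#'   brains; 0 disables.
#' @param baseline Mean in-brain signal level.
#' @param physio_amplitude Amplitude of three shared very-low-frequency
#'   physiological nuisance waveforms (below the slow-5 band), carried
#'   strongly by WM/CSF voxels and weakly elsewhere; what aCompCor is
#'   designed to remove.  0 disables.
#' @param noise_exponent Spectral exponent of the coloured noise
#'   (power ~ 1/f^exponent).
#' @param noise_1f_sd,white_sd Standard deviations of the coloured and
#'   white noise components (in-brain).
#' @param motion_sd_mm,motion_sd_rad Per-column SD of the translation
#'   (mm) and rotation (radians) motion parameters.
#' @param motion_coupling SD of the per-voxel weights coupling the first
#'   translation parameter into the signal (signal units per mm).
#' @param lesion_radius_range Min/max lesion sphere radius in voxels;
#'   `c(0, 0)` disables lesions.
#' @param lesion_attenuation Multiplicative signal attenuation inside the
#'   lesion.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   spec (including the seed).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_low = 38L, n_high = 25L,
                       grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = 3, tr_seconds = 3,
                       n_volumes = 140L,
                       effect_band = c("slow5", "slow4", "broadband"),
                       effect_center = NULL, effect_radius = 5,
                       beta_interaction = 1 / 3, osc_amplitude = 4,
                       bg_osc_amplitude = 24, physio_amplitude = 10,
                       baseline = 1000,
                       noise_exponent = 1, noise_1f_sd = 8, white_sd = 4,
                       motion_sd_mm = 0.15, motion_sd_rad = 0.002,
                       motion_coupling = 1,
                       lesion_radius_range = c(2, 4),
                       lesion_attenuation = 0.6,
                       seed = 1L) {
  effect_band <- match.arg(effect_band)
  spec <- list(n_low = as.integer(n_low), n_high = as.integer(n_high),
               grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm, tr_seconds = tr_seconds,
               n_volumes = as.integer(n_volumes),
               effect_band = effect_band, effect_center = effect_center,
               effect_radius = effect_radius,
               beta_interaction = beta_interaction,
               osc_amplitude = osc_amplitude,
               bg_osc_amplitude = bg_osc_amplitude,
               physio_amplitude = physio_amplitude, baseline = baseline,
               noise_exponent = noise_exponent, noise_1f_sd = noise_1f_sd,
               white_sd = white_sd, motion_sd_mm = motion_sd_mm,
               motion_sd_rad = motion_sd_rad,
               motion_coupling = motion_coupling,
               lesion_radius_range = lesion_radius_range,
               lesion_attenuation = lesion_attenuation,
               seed = as.integer(seed))
  .validate_synth_spec(spec)
  class(spec) <- "synth_spec"
  spec
}

.validate_synth_spec <- function(spec) {
  stopifnot(spec$n_low >= 1, spec$n_high >= 1,
            length(spec$grid_shape) == 3, all(spec$grid_shape >= 1),
            spec$tr_seconds > 0, spec$voxel_size_mm > 0,
            spec$beta_interaction >= 0, spec$osc_amplitude >= 0,
            spec$bg_osc_amplitude >= 0, spec$physio_amplitude >= 0,
            spec$effect_radius > 0,
            length(spec$lesion_radius_range) == 2,
            all(spec$lesion_radius_range >= 0))
  if (spec$n_volumes < 64)
    stop("n_volumes must be at least 64 to resolve the slow-5 band")
  if (min(spec$grid_shape) < 24)
    stop("grid_shape dimensions must all be at least 24 so that the ",
         "effect region and eroded tissue masks fit inside the brain")
  geom <- .synth_geometry(spec)
  if (any(geom$effect & !geom$brain))
    stop("effect_region extends outside the brain mask; move ",
         "effect_center or shrink effect_radius")
  invisible(TRUE)
}

.sphere_mask <- function(dims, center, radius) {
  dx <- (seq_len(dims[1]) - center[1])^2
  dy <- (seq_len(dims[2]) - center[2])^2
  dz <- (seq_len(dims[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, "+"), dz, "+")
  array(d2 <= radius^2, dims)
}

.box_mask <- function(dims, center, half) {
  m <- array(FALSE, dims)
  lo <- pmax(1, round(center - half)); hi <- pmin(dims, round(center + half))
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# Deterministic cohort geometry: a spherical brain, rectangular WM and
# CSF compartments on opposite sides (boxes erode predictably under the
# 26-neighbour element, so the twice-eroded aCompCor masks always keep a
# solid core), and the spherical effect region.  All sizes scale with
# the grid.
.synth_geometry <- function(spec) {
  dims <- spec$grid_shape
  ctr <- (dims + 1) / 2
  rb <- 0.46 * min(dims)
  brain <- .sphere_mask(dims, ctr, rb)
  wm <- .box_mask(dims, ctr + c(0, -0.45 * rb, 0), round(0.40 * rb))
  csf <- .box_mask(dims, ctr + c(0.55 * rb, -0.35 * rb, 0),
                   round(0.32 * rb))
  csf <- csf & !wm
  wm <- wm & brain
  csf <- csf & brain
  eff_ctr <- if (is.null(spec$effect_center)) ctr + c(0, 0.30 * rb, 0) else
    spec$effect_center
  effect <- .sphere_mask(dims, eff_ctr, spec$effect_radius)
  # the effect region is grey-matter-like tissue: never part of the
  # WM/CSF compartments that feed aCompCor
  wm <- wm & !effect
  csf <- csf & !effect
  list(brain = brain, wm = wm, csf = csf, effect = effect,
       center = ctr, brain_radius = rb)
}

#' Tissue and effect-region masks of the synthetic anatomy
#'
#' @param spec A [synth_spec()].
#' @return List of logical 3D arrays `brain`, `wm`, `csf`, `effect`.
#' @export
synthetic_masks <- function(spec) {
  g <- .synth_geometry(spec)
  g[c("brain", "wm", "csf", "effect")]
}

.subject_seed <- function(spec, i) {
  as.integer((as.numeric(spec$seed) + 104729 * i) %% 2147483647)
}

.rtrunc_round <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(2 * (n - length(out)) + 8, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(out[seq_len(n)])
}

#' Draw a synthetic cohort table
#'
#' Demographics are sampled near the motivating study's group summaries:
#' MADRS-SIGMA from rounded truncated normals (low: mean 2.29, SD 2.31,
#' range 0-8; high: mean 14.88, SD 6.67, range 9-60), age, NIHSS, sex,
#' depression history and antidepressant flags at the reference rates.
#'
#' @param spec A [synth_spec()].
#' @return A `cohort_table` with `n_low + n_high` rows.
#' @export
generate_cohort_table <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_low + spec$n_high
  grp <- rep(c("low", "high"), c(spec$n_low, spec$n_high))
  madrs <- c(.rtrunc_round(spec$n_low, 2.29, 2.31, 0, 8),
             .rtrunc_round(spec$n_high, 14.88, 6.67, 9, 60))
  age <- ifelse(grp == "low",
                .rtrunc_round(n, 64.68, 13.56, 19, 95),
                .rtrunc_round(n, 59.28, 12.26, 19, 95))
  sex <- ifelse(stats::runif(n) < ifelse(grp == "low", 28 / 38, 19 / 25),
                "female", "male")
  nihss <- pmax(0L, .rtrunc_round(n, 0.6, 1.2, -4, 20))
  hist <- stats::runif(n) < ifelse(grp == "low", 0, 6 / 25)
  antidep <- stats::runif(n) < ifelse(grp == "low", 1 / 38, 3 / 25)
  sad <- stats::runif(n) < ifelse(grp == "low", 5 / 38, 15 / 25)
  disc <- stats::runif(n) < ifelse(grp == "low", 4 / 38, 15 / 25)
  loss <- stats::runif(n) < ifelse(grp == "low", 3 / 38, 16 / 25)
  as_cohort(data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = age, sex = sex, nihss = nihss, madrs_total = madrs,
    history_depression = hist, antidepressant = antidep,
    reported_sadness = sad, reported_discouragement = disc,
    reported_loss_of_interest = loss,
    stringsAsFactors = FALSE))
}

# 1/f-coloured noise, one column per voxel, unit marginal SD.
.colored_noise <- function(t, n_voxels, exponent, tr) {
  w <- matrix(stats::rnorm(t * n_voxels), t, n_voxels)
  if (exponent == 0) return(w)
  f <- pmin(0:(t - 1), t - (0:(t - 1))) / (t * tr)
  fac <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * fac, inverse = TRUE)) / t
  x / stats::sd(as.vector(x))
}

# Band-limited oscillations for a set of voxels: spectral mass exactly
# on the FFT bin centres inside the band, with an independent random
# phase per voxel and bin (spectra ignore phase, so fALFF sees the full
# amplitude while no coherent global component exists for GSR or
# CompCor to latch onto).  Each column has RMS exactly equal to its
# `amp` entry: at exact bins the sinusoids are mutually orthogonal over
# the window, so the normalisation sqrt(n_bins / 2) is exact.
.band_osc_matrix <- function(t, tr, band, amp, coherent = FALSE) {
  k <- seq_len(floor(t / 2))
  f <- k / (t * tr)
  ks <- k[f >= band$lo & f < band$hi]
  if (!length(ks))
    stop("no FFT bins inside band [", band$lo, ", ", band$hi,
         ") for t = ", t, ", TR = ", tr)
  nv <- length(amp)
  tt <- seq_len(t)
  out <- matrix(0, t, nv)
  for (kk in ks) {
    a <- 2 * pi * kk * tt / t
    ph <- stats::runif(if (coherent) 1 else nv, 0, 2 * pi)
    if (coherent) out <- out + sin(a + ph)   # recycled across columns
    else out <- out + outer(sin(a), cos(ph)) + outer(cos(a), sin(ph))
  }
  sweep(out, 2, amp / sqrt(length(ks) / 2), "*")
}

# Smooth deterministic amplitude fields in [0, 1] giving the background
# oscillations a stable, band-specific spatial topography (as regional
# fALFF differences do in real brains).
.bg_fields <- function(dims, ctr, rb) {
  xs <- (seq_len(dims[1]) - ctr[1]) / rb
  ys <- (seq_len(dims[2]) - ctr[2]) / rb
  zs <- (seq_len(dims[3]) - ctr[3]) / rb
  f5 <- 0.5 * (1 + outer(outer(sin(2.0 * xs + 1.0), cos(1.6 * ys), "*"),
                         cos(1.3 * zs + 0.4), "*"))
  f4 <- 0.5 * (1 + outer(outer(cos(1.7 * xs), sin(2.1 * ys + 0.5), "*"),
                         sin(1.9 * zs + 0.8), "*"))
  list(slow5 = f5, slow4 = f4)
}

#' Generate one subject's synthetic BOLD run
#'
#' Voxel time series are baseline + 1/f-coloured noise + white noise +
#' motion-coupled drift, plus -- inside the effect region -- a
#' band-limited oscillation of amplitude
#' `osc_amplitude + beta_interaction * madrs * 1(group == "high")`.
#' A spherical lesion attenuates signal and adds noise; lesion voxels are
#' removed from the WM/CSF masks.  Deterministic given the spec and the
#' subject's row index.
#'
#' @param spec A [synth_spec()].
#' @param record One-row slice of the cohort table (or a list with
#'   `subject_id`, `group`, `madrs_total`).
#' @param subject_index Row index of the subject, used to derive the
#'   per-subject random seed.
#' @return A `bold_run` list: `data` (4D array), `tr_seconds`,
#'   `brain_mask`, `wm_mask`, `csf_mask`, `lesion_mask`, `motion`
#'   (t x 6), `subject_id`.
#' @export
generate_bold_run <- function(spec, record, subject_index) {
  set.seed(.subject_seed(spec, subject_index))
  geom <- .synth_geometry(spec)
  dims <- spec$grid_shape
  t <- spec$n_volumes
  nvox <- prod(dims)
  brain_idx <- which(geom$brain)
  nb <- length(brain_idx)

  # motion: smooth drift (lowest two Fourier modes) plus white jitter,
  # rescaled to the requested per-column SD
  motion <- sapply(1:6, function(j) {
    tt <- seq_len(t)
    drift <- stats::rnorm(1) * sin(2 * pi * tt / t + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(1) * sin(4 * pi * tt / t + stats::runif(1, 0, 2 * pi))
    x <- 0.95 * drift / stats::sd(drift) + 0.05 * stats::rnorm(t)
    x / stats::sd(x)
  })
  motion <- sweep(motion, 2,
                  rep(c(spec$motion_sd_mm, spec$motion_sd_rad), each = 3),
                  "*")

  # grey-matter-like voxels carry 1/f neural noise; WM/CSF voxels carry
  # matched-power white (thermal + unmodelled physiological) noise
  in_wmcsf <- (geom$wm | geom$csf)[geom$brain]
  noise <- .colored_noise(t, nb, spec$noise_exponent, spec$tr_seconds) *
    spec$noise_1f_sd
  if (any(in_wmcsf))
    noise[, in_wmcsf] <- matrix(
      stats::rnorm(t * sum(in_wmcsf), 0, spec$noise_1f_sd),
      t, sum(in_wmcsf))
  y <- spec$baseline + noise +
    matrix(stats::rnorm(t * nb, 0, spec$white_sd), t, nb)

  # motion-coupled drift
  if (spec$motion_coupling > 0) {
    wv <- stats::rnorm(nb, 0, spec$motion_coupling)
    y <- y + outer(motion[, 1], wv)
  }

  # shared physiological nuisance signals: very slow waveforms (below
  # the slow-5 band) carried strongly by WM/CSF voxels and weakly by
  # the rest of the brain -- the structure aCompCor is built to remove
  if (spec$physio_amplitude > 0) {
    phys_band <- list(lo = 1 / (t * spec$tr_seconds + 1), hi = 0.0099)
    for (j in 1:3) {
      p <- .band_osc_matrix(t, spec$tr_seconds, phys_band, 1,
                            coherent = TRUE)[, 1]
      wt <- stats::rnorm(nb, mean = ifelse(in_wmcsf, 1, 0.3), sd = 0.3)
      y <- y + outer(p, wt * spec$physio_amplitude)
    }
  }

  # Stable background oscillation topography (slow-5 and slow-4 fields).
  # A grey-matter phenomenon: zeroed inside the WM/CSF compartments and
  # inside the effect region, whose band content is the effect model's
  # own term.  Phases vary smoothly across space (travelling waves with
  # a wavelength much larger than the smoothing kernel): locally
  # coherent, so smoothing preserves the amplitude topography
  # deterministically, yet globally incoherent, so the global-mean
  # signal carries almost none of it.
  if (spec$bg_osc_amplitude > 0) {
    fields <- .bg_fields(dims, geom$center, geom$brain_radius)
    bands <- falff_bands()
    coords <- arrayInd(brain_idx, dims)
    eff_or_wmcsf <- in_wmcsf | geom$effect[geom$brain]
    tt <- seq_len(t)
    # The wave pattern (directions and phase offsets) is a fixed
    # property of the synthetic anatomy, shared by every subject like
    # the amplitude fields themselves; the subject RNG stream is
    # suspended while it is drawn so per-subject noise is unaffected.
    rng_state <- .Random.seed
    set.seed(780941L)
    for (b in c("slow5", "slow4")) {
      ampv <- spec$bg_osc_amplitude * fields[[b]][geom$brain]
      ampv[eff_or_wmcsf] <- 0
      k <- seq_len(floor(t / 2))
      f <- k / (t * spec$tr_seconds)
      ks <- k[f >= bands[[b]]$lo & f < bands[[b]]$hi]
      wavelength <- 12
      osc <- matrix(0, t, nb)
      for (kk in ks) {
        a <- 2 * pi * kk * tt / t
        q <- stats::rnorm(3)
        q <- q / sqrt(sum(q^2)) / wavelength
        phase <- 2 * pi * (coords %*% q) + stats::runif(1, 0, 2 * pi)
        osc <- osc + outer(sin(a), cos(phase)[, 1]) +
          outer(cos(a), sin(phase)[, 1])
      }
      y <- y + sweep(osc, 2, ampv / sqrt(length(ks) / 2), "*")
    }
    .Random.seed <<- rng_state
  }

  # band-limited oscillation in the effect region: phase-coherent across
  # the region, as a genuine regional signal would be
  eff_in_brain <- which(geom$effect[geom$brain])
  if (length(eff_in_brain) && spec$osc_amplitude + spec$beta_interaction > 0) {
    band <- falff_bands()[[spec$effect_band]]
    amp <- spec$osc_amplitude + spec$beta_interaction *
      record$madrs_total * (record$group == "high")
    y[, eff_in_brain] <- y[, eff_in_brain] +
      .band_osc_matrix(t, spec$tr_seconds, band,
                       rep(amp, length(eff_in_brain)), coherent = TRUE)
  }

  # Lesion: random sphere fully inside the brain.  Placements that would
  # annihilate the twice-eroded WM or CSF masks (making aCompCor
  # impossible) are rejected and redrawn: the lesion exists to exercise
  # mask logic, not to model pathology.
  lesion <- array(FALSE, dims)
  if (spec$lesion_radius_range[2] > 0) {
    r <- stats::runif(1, spec$lesion_radius_range[1],
                      spec$lesion_radius_range[2])
    for (attempt in 1:50) {
      repeat {
        offs <- stats::runif(3, -1, 1) * (geom$brain_radius - r - 1)
        if (sqrt(sum(offs^2)) <= geom$brain_radius - r - 1) break
      }
      cand <- .sphere_mask(dims, geom$center + offs, r) & geom$brain
      ok <- tryCatch(
        sum(erode_mask(geom$wm & !cand, 2)) >= 10 &&
          sum(erode_mask(geom$csf & !cand, 2)) >= 10,
        error = function(e) FALSE)
      if (ok) break
    }
    if (!ok) stop("could not place a lesion compatible with the tissue ",
                  "masks after 50 attempts")
    lesion <- cand
    les_in_brain <- which(lesion[geom$brain])
    if (length(les_in_brain)) {
      y[, les_in_brain] <- spec$baseline * spec$lesion_attenuation +
        (y[, les_in_brain] - spec$baseline) +
        matrix(stats::rnorm(t * length(les_in_brain), 0, spec$white_sd),
               t, length(les_in_brain))
    }
  }

  arr <- matrix(0, nvox, t)
  arr[-brain_idx, ] <- stats::rnorm((nvox - nb) * t, 0, spec$white_sd)
  arr[brain_idx, ] <- t(y)
  run <- list(data = array(arr, c(dims, t)), tr_seconds = spec$tr_seconds,
              brain_mask = geom$brain,
              wm_mask = geom$wm & !lesion,
              csf_mask = geom$csf & !lesion,
              lesion_mask = lesion, motion = motion,
              subject_id = record$subject_id)
  class(run) <- "bold_run"
  run
}

#' Generate a full synthetic cohort
#'
#' @param spec A [synth_spec()].
#' @return A `synthetic_cohort` list: `cohort` (cohort table), `runs`
#'   (list of `bold_run`), `masks` (shared anatomy from
#'   [synthetic_masks()]), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  cohort <- generate_cohort_table(spec)
  runs <- lapply(seq_len(nrow(cohort)), function(i)
    generate_bold_run(spec, cohort[i, ], i))
  out <- list(cohort = cohort, runs = runs, masks = synthetic_masks(spec),
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

.write_nifti_vol <- function(x, path, voxel_mm, tr = NULL) {
  img <- RNifti::asNifti(x * 1)
  nd <- length(dim(x))
  pd <- rep(voxel_mm, 3)
  if (nd == 4) pd <- c(pd, tr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "float")
  path
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI BOLD file and one 6-column whitespace-separated motion text
#' file per subject, per-subject mask NIfTIs, the cohort CSV, and a JSON
#' manifest recording the generator spec, seed and per-file MD5 sums;
#' regenerating from the same spec reproduces the files bit-identically.
#'
#' @param cohort_data A `synthetic_cohort` from [generate_cohort()].
#' @param dest Destination directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort_data, dest) {
  stopifnot(inherits(cohort_data, "synthetic_cohort"))
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dest, 2) != 0) stop("destination not writable: ", dest)
  spec <- cohort_data$spec
  files <- character(0)
  for (i in seq_along(cohort_data$runs)) {
    run <- cohort_data$runs[[i]]
    id <- run$subject_id
    f_bold <- file.path(dest, paste0(id, "_bold.nii.gz"))
    .write_nifti_vol(run$data, f_bold, spec$voxel_size_mm, spec$tr_seconds)
    f_mot <- file.path(dest, paste0(id, "_motion.txt"))
    utils::write.table(format(run$motion, digits = 8, scientific = FALSE),
                       f_mot, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    fs <- c(f_bold, f_mot)
    for (m in c("brain", "wm", "csf", "lesion")) {
      f <- file.path(dest, paste0(id, "_mask_", m, ".nii.gz"))
      .write_nifti_vol(run[[paste0(m, "_mask")]], f, spec$voxel_size_mm)
      fs <- c(fs, f)
    }
    files <- c(files, fs)
  }
  f_csv <- file.path(dest, "cohort.csv")
  write_cohort_table(cohort_data$cohort, f_csv)
  files <- c(files, f_csv)
  manifest <- list(
    package = "falffband",
    version = as.character(utils::packageVersion("falffband")),
    spec = unclass(spec), seed = spec$seed,
    files = as.list(stats::setNames(
      as.character(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(dest, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Rebuild a synthetic cohort from a written manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_cohort()].
#' @return A `synthetic_cohort`, regenerated from the recorded spec.
#' @export
cohort_from_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sp <- m$spec
  spec <- synth_spec(
    n_low = sp$n_low, n_high = sp$n_high, grid_shape = sp$grid_shape,
    voxel_size_mm = sp$voxel_size_mm, tr_seconds = sp$tr_seconds,
    n_volumes = sp$n_volumes, effect_band = sp$effect_band,
    effect_center = sp$effect_center, effect_radius = sp$effect_radius,
    beta_interaction = sp$beta_interaction,
    osc_amplitude = sp$osc_amplitude,
    bg_osc_amplitude = sp$bg_osc_amplitude,
    physio_amplitude = sp$physio_amplitude, baseline = sp$baseline,
    noise_exponent = sp$noise_exponent, noise_1f_sd = sp$noise_1f_sd,
    white_sd = sp$white_sd, motion_sd_mm = sp$motion_sd_mm,
    motion_sd_rad = sp$motion_sd_rad,
    motion_coupling = sp$motion_coupling,
    lesion_radius_range = sp$lesion_radius_range,
    lesion_attenuation = sp$lesion_attenuation, seed = sp$seed)
  generate_cohort(spec)
}
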