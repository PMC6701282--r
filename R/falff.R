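#' Canonical BOLD frequency bands
#'
#' Half-open `[lo, hi)` intervals in Hz: broadband 0.01-0.08, slow-5
#' 0.01-0.027, slow-4 0.027-0.07.  Under the half-open convention the
#' 0.027 Hz boundary belongs to slow-4, and no spectral bin is counted
#' in both subbands.
#'
#' @return Named list of band definitions (each a list with `name`,
#'   `lo`, `hi`).
#' @export
falff_bands <- function() {
  list(broadband = band_definition("broadband", 0.01, 0.08),
       slow5 = band_definition("slow5", 0.01, 0.027),
       slow4 = band_definition("slow4", 0.027, 0.07))
}

#' Define a frequency band
#'
#' @param name Band label.
#' @param lo,hi Band bounds in Hz; the band is the half-open interval
#'   `[lo, hi)` with `0 < lo < hi`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(is.character(name), length(lo) == 1, length(hi) == 1)
  if (!(lo > 0 && hi > lo))
    stop("band bounds must satisfy 0 < lo < hi, got [", lo, ", ", hi, ")")
  structure(list(name = name, lo = lo, hi = hi),
            class = "band_definition")
}

#' One-sided amplitude spectrum of a time series
#'
#' The series is linearly detrended (least-squares line removed) and
#' Fourier transformed; the amplitude at each positive-frequency bin is
#' the square root of its power, i.e. the spectral magnitude `|FFT|` up
#' to a constant factor that cancels in any band ratio.  The DC bin is
#' excluded; frequencies are `k/(t * TR)` for `k = 1..floor(t/2)` (the
#' last bin is Nyquist for even `t`).
#'
#' @param series Numeric time series (length >= 8, finite).
#' @param tr_seconds Sampling interval (TR) in seconds.
#' @param taper Apply a Hann taper after detrending (default FALSE; the
#'   plain detrended FFT is the reference behaviour).
#' @return List with `freq` and `amplitude` vectors.
#' @export
amplitude_spectrum <- function(series, tr_seconds, taper = FALSE) {
  t <- length(series)
  stopifnot(t >= 8, all(is.finite(series)), tr_seconds > 0)
  x <- .detrend_cols(matrix(series, ncol = 1))[, 1]
  if (taper) x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(t) - 1) / (t - 1)))
  nf <- floor(t / 2)
  amp <- Mod(stats::fft(x))[2:(nf + 1)]
  list(freq = seq_len(nf) / (t * tr_seconds), amplitude = amp)
}

.band_bins <- function(freq, band) freq >= band$lo & freq < band$hi

#' Fractional amplitude of low-frequency fluctuations of one series
#'
#' The sum of spectral amplitudes over the band's bins divided by the
#' sum over all positive-frequency bins up to Nyquist.  A constant
#' series has an all-zero spectrum; the ratio is then defined as 0 and
#' flagged via the `"degenerate"` attribute rather than erroring.
#'
#' @param series Numeric time series.
#' @param tr_seconds TR in seconds.
#' @param band A [band_definition()] (or one of [falff_bands()]).
#' @param taper Hann taper flag, see [amplitude_spectrum()].
#' @return Scalar in `[0, 1]`.
#' @export
falff <- function(series, tr_seconds, band, taper = FALSE) {
  sp <- amplitude_spectrum(series, tr_seconds, taper = taper)
  inside <- .band_bins(sp$freq, band)
  if (!any(inside)) {
    t_min <- ceiling(1 / (band$lo * tr_seconds))
    stop("band [", band$lo, ", ", band$hi, ") contains no spectral bins ",
         "at t = ", length(series), ", TR = ", tr_seconds,
         "; at least t = ", t_min, " volumes are needed")
  }
  den <- sum(sp$amplitude)
  if (den == 0) return(structure(0, degenerate = TRUE))
  sum(sp$amplitude[inside]) / den
}

#' Voxelwise fALFF map of a cleaned run
#'
#' Applies the band-ratio fALFF to every in-mask voxel of a (cleaned,
#' smoothed) 4D array; out-of-mask voxels are 0.  The spectra of all
#' in-mask voxels are computed in one vectorised FFT pass.
#'
#' @param data Cleaned 4D array.
#' @param mask Logical 3D brain mask (non-empty).
#' @param tr_seconds TR in seconds.
#' @param band A [band_definition()].
#' @return A `falff_map` list: `raw` (3D array in `[0, 1]`), `band`,
#'   `mask`, `tr_seconds`, `n_volumes`; `zscored` is NULL until
#'   [zscore_map()] is applied.
#' @export
falff_map <- function(data, mask, tr_seconds, band) {
  dims <- dim(data)
  idx <- which(mask)
  if (length(idx) == 0) stop("mask is empty")
  t <- dims[4]
  stopifnot(t >= 8)
  y <- t(matrix(data, prod(dims[1:3]), t)[idx, , drop = FALSE])
  y <- .detrend_cols(y)
  nf <- floor(t / 2)
  amp <- Mod(stats::mvfft(y))[2:(nf + 1), , drop = FALSE]
  freq <- seq_len(nf) / (t * tr_seconds)
  inside <- .band_bins(freq, band)
  if (!any(inside))
    stop("band [", band$lo, ", ", band$hi, ") contains no spectral bins ",
         "at t = ", t, ", TR = ", tr_seconds)
  den <- colSums(amp)
  num <- colSums(amp[inside, , drop = FALSE])
  vals <- ifelse(den > 0, num / den, 0)
  raw <- array(0, dims[1:3])
  raw[idx] <- vals
  structure(list(raw = raw, zscored = NULL, band = band, mask = mask,
                 tr_seconds = tr_seconds, n_volumes = t),
            class = "falff_map")
}

#' Z-standardise a fALFF map over the brain mask
#'
#' Subtracts the global (in-mask) mean and divides by the global SD, so
#' the in-mask distribution has mean 0 and SD 1; out-of-mask voxels stay
#' 0.  Z-scoring makes maps comparable across subjects and decouples
#' amplitude scale from residual motion.
#'
#' @param map A `falff_map` (or a bare 3D array).
#' @param mask Logical 3D mask; defaults to the map's own mask.
#' @return For a `falff_map`, the map with `zscored` filled in; for an
#'   array, the z-scored array.
#' @export
zscore_map <- function(map, mask = NULL) {
  if (inherits(map, "falff_map")) {
    if (is.null(mask)) mask <- map$mask
    map$zscored <- zscore_map(map$raw, mask)
    return(map)
  }
  idx <- which(mask)
  if (length(idx) < 2) stop("need at least 2 in-mask voxels")
  v <- map[idx]
  s <- stats::sd(v)
  if (s == 0) stop("zero global SD: fALFF map is constant within the mask")
  out <- array(0, dim(map))
  out[idx] <- (v - mean(v)) / s
  out
}

#' Compute raw and z-scored fALFF maps for several bands
#'
#' @param data Cleaned 4D array.
#' @param mask Logical 3D brain mask.
#' @param tr_seconds TR in seconds.
#' @param bands List of [band_definition()]s (default all of
#'   [falff_bands()]).
#' @return Named list of z-scored `falff_map`s.
#' @export
compute_falff_maps <- function(data, mask, tr_seconds,
                               bands = falff_bands()) {
  lapply(bands, function(b)
    zscore_map(falff_map(data, mask, tr_seconds, b)))
}
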