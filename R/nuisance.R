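#' Despike a time series by clipping against a running-median trend
#'
#' Points deviating from a running-median trend by more than
#' `clip_k` x MAD of the trend residuals are clipped back to the trend
#' plus/minus that threshold; all other points pass through unchanged.
#' This is a transparent, deterministic despiking operator with the same
#' intent as the opaque despike stages of common fMRI toolchains.
#'
#' @param series Numeric time series (length >= 5).
#' @param clip_k Clip threshold in MAD units (default 4).
#' @param window Odd width of the running-median window (default 7).
#' @return The despiked series.
#' @export
despike <- function(series, clip_k = 4, window = 7) {
  stopifnot(length(series) >= 5, clip_k > 0, window %% 2 == 1)
  trend <- stats::runmed(series, k = min(window, .odd_floor(length(series))),
                         endrule = "median")
  resid <- series - trend
  s <- stats::mad(resid)
  if (s == 0) return(series)
  lim <- clip_k * s
  out <- series
  over <- abs(resid) > lim
  out[over] <- trend[over] + sign(resid[over]) * lim
  out
}

.odd_floor <- function(n) if (n %% 2 == 1) n else n - 1L

# Vectorised median-of-k networks (columns of a matrix in parallel).
.med3 <- function(a, b, c)
  pmax.int(pmin.int(a, b), pmin.int(c, pmax.int(a, b)))
.med5 <- function(a, b, c, d, e)
  .med3(pmax.int(pmin.int(a, b), pmin.int(c, d)),
        pmin.int(pmax.int(a, b), pmax.int(c, d)), e)
# median of 7 via odd-even transposition sort (7 passes, 21 exchanges)
.med7 <- function(a, b, c, d, e, f, g) {
  v <- list(a, b, c, d, e, f, g)
  for (pass in 1:7) {
    pairs <- if (pass %% 2 == 1) list(c(1, 2), c(3, 4), c(5, 6))
             else list(c(2, 3), c(4, 5), c(6, 7))
    for (pr in pairs) {
      lo <- pmin.int(v[[pr[1]]], v[[pr[2]]])
      v[[pr[2]]] <- pmax.int(v[[pr[1]]], v[[pr[2]]])
      v[[pr[1]]] <- lo
    }
  }
  v[[4]]
}

# Row medians of a V x t matrix (t >= 2), the exact stats::median value.
.row_medians <- function(x) {
  n <- ncol(x)
  xt <- t(x)
  h <- (n + 1L) %/% 2L
  even <- n %% 2L == 0L
  vapply(seq_len(ncol(xt)), function(j) {
    v <- sort.int(xt[, j], method = "quick")
    if (even) (v[h] + v[h + 1L]) / 2 else v[h]
  }, numeric(1))
}

# Running median of window 7 for every row of a V x t matrix, matching
# stats::runmed(..., endrule = "median") exactly: interior medians of 7
# plus Tukey end smoothing applied to the endrule-"keep" sequence.
.runmed7_rows <- function(m) {
  t <- ncol(m)
  col <- function(j) m[, j]
  out <- m
  for (j in 4:(t - 3))
    out[, j] <- .med7(col(j - 3), col(j - 2), col(j - 1), col(j),
                      col(j + 1), col(j + 2), col(j + 3))
  sm2 <- .med3(col(1), col(2), col(3))
  sm3 <- .med5(col(1), col(2), col(3), out[, 4], out[, 5])
  sm1 <- .med3(col(1), sm2, 3 * sm2 - 2 * sm3)
  smt1 <- .med3(col(t - 2), col(t - 1), col(t))
  smt2 <- .med5(out[, t - 4], out[, t - 3], col(t - 2), col(t - 1),
                col(t))
  smt <- .med3(col(t), smt1, 3 * smt1 - 2 * smt2)
  out[, 1] <- sm1; out[, 2] <- sm2; out[, 3] <- sm3
  out[, t] <- smt; out[, t - 1] <- smt1; out[, t - 2] <- smt2
  out
}

# Despike every in-mask voxel of a 4D array (vectorised; equal to
# applying despike() voxel by voxel when window = 7).
.despike_run <- function(data, mask, clip_k = 4, window = 7) {
  dims <- dim(data)
  t <- dims[4]
  m <- matrix(data, prod(dims[1:3]), t)
  idx <- which(mask)
  x <- m[idx, , drop = FALSE]
  if (window != 7 || t < 9) {
    m[idx, ] <- t(apply(x, 1, despike, clip_k = clip_k, window = window))
    return(array(m, dims))
  }
  trend <- .runmed7_rows(x)
  resid <- x - trend
  s <- 1.4826 * .row_medians(abs(resid - .row_medians(resid)))
  lim <- clip_k * s
  over <- s > 0 & abs(resid) > lim
  x[over] <- (trend + sign(resid) * lim)[over]
  m[idx, ] <- x
  array(m, dims)
}

#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body motion parameters into 24 regressors: the
#' parameters, their one-volume lags (first row zero-padded), and the
#' elementwise squares of both.
#'
#' @param motion t x 6 matrix (3 translations in mm, 3 rotations in
#'   radians).
#' @return t x 24 matrix with labelled columns.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns, got ",
                              ncol(motion))
  if (nrow(motion) < 2) stop("motion must have at least 2 rows")
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("mot", 1:6, "_lag"),
                     paste0("mot", 1:6, "_sq"),
                     paste0("mot", 1:6, "_lag_sq"))
  out
}

#' Binarise a probabilistic tissue mask
#'
#' @param prob 3D array of tissue probabilities.
#' @param threshold Inclusion threshold (default 0.99, a conservative
#'   cut that minimises partial-volume contamination).
#' @return Logical 3D array.
#' @export
threshold_mask <- function(prob, threshold = 0.99) {
  array(prob >= threshold, dim(prob))
}

#' Binary mask erosion with a full 3x3x3 structuring element
#'
#' One iteration removes every voxel having any of its 26 neighbours (or
#' itself, vacuously) outside the mask; at 3 mm isotropic voxels the
#' element is the conventional one-voxel-thick 3x3x3 mm cube.
#'
#' @param mask Logical 3D array.
#' @param iterations Number of erosion passes (default 1).
#' @return Eroded logical array; errors if the result is empty.
#' @export
erode_mask <- function(mask, iterations = 1) {
  stopifnot(length(dim(mask)) == 3, iterations >= 0)
  mask <- array(as.logical(mask), dim(mask))
  dims <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      out <- out & .shift3(mask, c(dx, dy, dz), fill = FALSE)
    }
    mask <- out
    if (!any(mask))
      stop("mask empty after ", it, " erosion(s); supply a larger mask ",
           "or fewer iterations")
  }
  mask
}

# Shift a 3D array by an integer offset, filling exposed planes.
.shift3 <- function(x, offset, fill = FALSE) {
  dims <- dim(x)
  out <- array(fill, dims)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= dims[a]) return(out)
    if (o >= 0) { dst[[a]] <- (1 + o):dims[a]; src[[a]] <- 1:(dims[a] - o) }
    else        { dst[[a]] <- 1:(dims[a] + o); src[[a]] <- (1 - o):dims[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Anatomical CompCor nuisance components
#'
#' Voxel time series inside the (typically eroded WM or CSF) mask are
#' linearly detrended and variance-normalised, and the leading principal
#' components of the resulting voxels-by-time matrix are returned as
#' nuisance time courses: mutually orthogonal, unit norm, ordered by
#' explained variance.
#'
#' @param data 4D array.
#' @param mask Logical 3D array (non-empty; at least `n_components`
#'   voxels).
#' @param n_components Number of components (default 5).
#' @return t x n_components matrix with attribute
#'   `"explained_variance"`; zero columns when `n_components = 0`.
#' @export
acompcor <- function(data, mask, n_components = 5) {
  dims <- dim(data)
  idx <- which(mask)
  if (length(idx) == 0) stop("aCompCor mask is empty")
  if (n_components == 0) return(matrix(0, dims[4], 0))
  if (length(idx) < n_components)
    stop("aCompCor mask has ", length(idx), " voxels, fewer than ",
         n_components, " components")
  x <- t(matrix(data, prod(dims[1:3]), dims[4])[idx, , drop = FALSE])
  x <- .detrend_cols(x)
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < n_components)
    stop("fewer than ", n_components, " non-constant voxels in aCompCor mask")
  x <- sweep(x, 2, sds[sds > 0], "/")
  sv <- svd(x, nu = n_components, nv = 0)
  comp <- sv$u
  colnames(comp) <- paste0("pc", seq_len(n_components))
  attr(comp, "explained_variance") <-
    sv$d[seq_len(n_components)]^2 / sum(sv$d^2)
  comp
}

# Remove a least-squares line (intercept + slope) from every column.
.detrend_cols <- function(x) {
  t <- nrow(x)
  tt <- seq_len(t) - (t + 1) / 2
  x <- sweep(x, 2, colMeans(x))
  x - outer(tt, colSums(tt * x) / sum(tt^2))
}

#' Global (whole-brain mean) signal
#'
#' @param data 4D array.
#' @param mask Logical 3D brain mask.
#' @return Numeric vector of per-volume means over in-mask voxels.
#' @export
global_signal <- function(data, mask) {
  idx <- which(mask)
  if (length(idx) == 0) stop("brain mask is empty")
  dims <- dim(data)
  colMeans(matrix(data, prod(dims[1:3]), dims[4])[idx, , drop = FALSE])
}

#' Assemble the nuisance design matrix
#'
#' Columns: intercept, linear trend, the Friston-24 motion expansion,
#' `n_components` aCompCor components each from the (lesion-excluded,
#' thresholded, eroded) WM and CSF masks, and optionally the global
#' signal -- 37 columns with all parts enabled.  Collinear columns are
#' dropped with a warning (all-zero motion files occur in synthetic
#' nulls), never silently.
#'
#' @param data 4D array (despiked).
#' @param motion t x 6 motion-parameter matrix.
#' @param wm_mask,csf_mask Binary or probabilistic tissue masks.
#' @param brain_mask Logical 3D brain mask (for the global signal).
#' @param lesion_mask Optional logical 3D lesion mask, removed from the
#'   tissue masks before erosion.
#' @param n_components aCompCor components per tissue (default 5).
#' @param gsr Include the global-signal column (default TRUE).
#' @param erode_iterations Erosion passes on the tissue masks (default
#'   2).
#' @param mask_threshold Binarisation threshold for probabilistic masks
#'   (default 0.99).
#' @return List with `design` (t x k matrix), `labels`, and `dropped`
#'   (labels of collinear columns removed).
#' @export
build_nuisance_design <- function(data, motion, wm_mask, csf_mask,
                                  brain_mask, lesion_mask = NULL,
                                  n_components = 5, gsr = TRUE,
                                  erode_iterations = 2,
                                  mask_threshold = 0.99) {
  t <- dim(data)[4]
  prep <- function(m) {
    if (!is.logical(m)) m <- threshold_mask(m, mask_threshold)
    if (!is.null(lesion_mask)) m <- m & !lesion_mask
    erode_mask(m, erode_iterations)
  }
  wm_e <- prep(wm_mask)
  csf_e <- prep(csf_mask)
  blocks <- list(intercept = matrix(1, t, 1),
                 trend = matrix(seq_len(t) / t, t, 1),
                 motion = friston24(motion),
                 compcor_wm = acompcor(data, wm_e, n_components),
                 compcor_csf = acompcor(data, csf_e, n_components))
  if (gsr) blocks$global <- matrix(global_signal(data, brain_mask), t, 1)
  labels <- unlist(lapply(names(blocks), function(b) {
    k <- ncol(blocks[[b]])
    if (k == 1) b else paste0(b, "_", seq_len(k))
  }))
  x <- do.call(cbind, blocks)
  colnames(x) <- labels
  keep <- .independent_columns(x)
  dropped <- labels[!keep]
  if (length(dropped))
    warning("dropping collinear nuisance column(s): ",
            paste(dropped, collapse = ", "))
  list(design = x[, keep, drop = FALSE], labels = labels[keep],
       dropped = dropped)
}

# Indices of a maximal linearly independent column subset (QR pivoting).
.independent_columns <- function(x, tol = 1e-10) {
  qr_x <- qr(x, tol = tol)
  keep <- rep(FALSE, ncol(x))
  keep[qr_x$pivot[seq_len(qr_x$rank)]] <- TRUE
  keep
}

#' Regress a nuisance design out of a 4D run
#'
#' A single joint ordinary-least-squares fit per voxel; residuals are
#' returned without re-adding the voxel mean (downstream spectral
#' measures ignore the DC component).
#'
#' @param data 4D array.
#' @param design t x k nuisance design matrix (full column rank).
#' @return 4D array of residuals.
#' @export
regress_nuisance <- function(data, design) {
  dims <- dim(data)
  if (nrow(design) != dims[4])
    stop("design has ", nrow(design), " rows but data has ", dims[4],
         " volumes")
  if (qr(design)$rank < ncol(design))
    stop("nuisance design is rank deficient; drop collinear columns first")
  y <- t(matrix(data, prod(dims[1:3]), dims[4]))
  q <- qr.Q(qr(design))
  res <- y - q %*% crossprod(q, y)
  array(t(res), dims)
}

#' Isotropic Gaussian smoothing of a 4D run
#'
#' Separable truncated-Gaussian convolution applied independently per
#' volume, with sigma = fwhm / (2 sqrt(2 ln 2)) / voxel size and
#' zero-padded boundaries; `fwhm_mm = 0` is the identity.  Smoothing is
#' not confined by the brain mask: mask-confined renormalisation changes
#' edge-voxel spectra and is deliberately left off.
#'
#' @param data 4D (or 3D) array.
#' @param fwhm_mm Kernel full width at half maximum in mm (default 6).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(data, fwhm_mm = 6, voxel_size_mm = 3) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(data)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  dims <- dim(data)
  nd <- length(dims)
  kern_mat <- function(n) {
    r <- ceiling(4 * sigma)
    g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    g <- g / sum(g)
    k <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1, j - r); hi <- min(n, j + r)
      k[lo:hi, j] <- g[(lo:hi) - j + r + 1]
    }
    k
  }
  ks <- lapply(dims[1:3], kern_mat)
  x <- data
  for (a in 1:3) {
    perm <- c(a, setdiff(seq_len(nd), a))
    x <- aperm(x, perm)
    dp <- dim(x)
    x <- array(ks[[a]] %*% matrix(x, dims[a]), dp)
    x <- aperm(x, order(perm))
  }
  x
}

#' Run the full nuisance-cleaning chain on one BOLD run
#'
#' Order: despike, joint nuisance regression (trend + Friston-24 +
#' aCompCor + optional global signal), Gaussian smoothing.  The smoothed
#' residuals are what the spectral stage consumes.
#'
#' @param run A `bold_run` (see [generate_bold_run()]) or a list with
#'   the same fields.
#' @param despike_enabled,despike_clip_k Despiking switch and threshold.
#' @param gsr Global-signal regression switch (default TRUE).
#' @param n_compcor aCompCor components per tissue.
#' @param erode_iterations Tissue-mask erosion passes.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param voxel_size_mm Voxel size in mm.
#' @return List: `data` (cleaned 4D array), `design` (the
#'   [build_nuisance_design()] result), and `settings`.
#' @export
clean_run <- function(run, despike_enabled = TRUE, despike_clip_k = 4,
                      gsr = TRUE, n_compcor = 5, erode_iterations = 2,
                      fwhm_mm = 6, voxel_size_mm = 3) {
  x <- run$data
  if (despike_enabled)
    x <- .despike_run(x, run$brain_mask, clip_k = despike_clip_k)
  des <- build_nuisance_design(x, run$motion, run$wm_mask, run$csf_mask,
                               run$brain_mask, run$lesion_mask,
                               n_components = n_compcor, gsr = gsr,
                               erode_iterations = erode_iterations)
  x <- regress_nuisance(x, des$design)
  x <- smooth_gaussian(x, fwhm_mm, voxel_size_mm)
  list(data = x, design = des,
       settings = list(despike_enabled = despike_enabled,
                       despike_clip_k = despike_clip_k, gsr = gsr,
                       n_compcor = n_compcor,
                       erode_iterations = erode_iterations,
                       fwhm_mm = fwhm_mm, voxel_size_mm = voxel_size_mm))
}
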