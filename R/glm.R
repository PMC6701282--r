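#' Build the second-level interaction design matrix
#'
#' Columns: intercept, group (low = 0, high = 1), symptom score
#' (MADRS-SIGMA total, not centred so the interaction column carries the
#' raw group-by-score product), group x score, plus optional mean-centred
#' covariates from `age`, `sex` (female = 0, male = 1 before centring)
#' and `nihss`.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Character subset of `c("age", "sex", "nihss")`.
#' @param center_score Mean-centre the score column (default FALSE; this
#'   changes main-effect columns but not the interaction t).
#' @return List: `X` (n x k matrix), `labels`, `contrast` (index of the
#'   interaction column), `df` (n - k).
#' @export
build_design <- function(cohort, covariates = character(),
                         center_score = FALSE) {
  stopifnot(inherits(cohort, "data.frame"))
  if (length(covariates))
    covariates <- match.arg(covariates, c("age", "sex", "nihss"),
                            several.ok = TRUE)
  if (length(unique(cohort$group)) < 2)
    stop("cohort contains a single group; the interaction model needs both")
  if (any(table(cohort$group) < 2))
    stop("each group needs at least 2 subjects")
  g <- as.numeric(cohort$group == "high")
  s <- cohort$madrs_total
  if (center_score) s <- s - mean(s)
  x <- cbind(intercept = 1, group = g, score = s, group_score = g * s)
  for (cv in covariates) {
    v <- switch(cv, age = cohort$age, nihss = cohort$nihss,
                sex = as.numeric(cohort$sex == "male"))
    x <- cbind(x, scale(v, scale = FALSE)[, 1])
    colnames(x)[ncol(x)] <- cv
  }
  if (qr(x)$rank < ncol(x))
    stop("design matrix is rank deficient (collinear columns, e.g. an ",
         "all-same-score cohort)")
  list(X = x, labels = colnames(x), contrast = 4L,
       df = nrow(x) - ncol(x))
}

#' Voxelwise OLS fit and contrast t-map
#'
#' Per-voxel ordinary least squares of the stacked maps on the design;
#' the t-statistic for a single-column contrast is
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with `df = n - k`.  Voxels
#' with zero variance across subjects get t = 0 and are reported in the
#' `zero_variance` element.
#'
#' @param maps n x V matrix of (z-scored) fALFF values, one row per
#'   subject in cohort order.
#' @param design A [build_design()] result (or a bare matrix).
#' @param contrast Column index tested (defaults to the design's
#'   interaction column).
#' @return List: `t` (length-V), `df`, `beta` (k x V), `zero_variance`
#'   (logical V).
#' @export
fit_voxelwise <- function(maps, design, contrast = NULL) {
  x <- if (is.list(design)) design$X else design
  if (is.null(contrast))
    contrast <- if (is.list(design)) design$contrast else ncol(x)
  n <- nrow(x); k <- ncol(x)
  if (nrow(maps) != n)
    stop("maps have ", nrow(maps), " rows but design has ", n)
  if (n < k + 2) stop("need at least k + 2 subjects, got n = ", n)
  if (qr(x)$rank < k) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(chol(crossprod(x)))
  a <- xtx_inv %*% t(x)
  beta <- a %*% maps
  res <- maps - x %*% beta
  df <- n - k
  rss <- colSums(res^2)
  cc <- xtx_inv[contrast, contrast]
  se <- sqrt(rss / df * cc)
  zero_var <- apply(maps, 2, function(v) all(v == v[1]))
  tval <- ifelse(se > 0, beta[contrast, ] / se, 0)
  tval[zero_var] <- 0
  list(t = tval, df = df, beta = beta, zero_variance = zero_var)
}

#' Convert a t-statistic to a z-score
#'
#' `z = qnorm(pt(t, df))` evaluated tail-symmetrically in log space so
#' large statistics do not saturate; monotone in `t`, exactly 0 at
#' `t = 0`.
#'
#' @param t Numeric vector of t-statistics.
#' @param df Residual degrees of freedom.
#' @return z-scores of the same length.
#' @export
t_to_z <- function(t, df) {
  stopifnot(df >= 1)
  z <- numeric(length(t))
  neg <- t < 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE),
                           log.p = TRUE)
  z
}

#' Effect size r-squared from a t-statistic
#'
#' `r2 = t^2 / (t^2 + df)`: the squared point-biserial correlation of
#' the tested contrast, in `[0, 1)`.
#'
#' @param t Numeric vector of t-statistics.
#' @param df Residual degrees of freedom.
#' @return r-squared values.
#' @export
r_squared <- function(t, df) {
  stopifnot(df >= 1)
  t^2 / (t^2 + df)
}

.connectivity_offsets <- function(connectivity = 18) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  offs[keep, , drop = FALSE]
}

# Label connected components among the given voxels (rows of `coords`,
# 1-based i/j/k) of a `dims` grid.  Returns an integer label per voxel.
.label_components <- function(coords, dims, connectivity = 18) {
  nv <- nrow(coords)
  if (nv == 0) return(integer(0))
  lin <- coords[, 1] + dims[1] * (coords[, 2] - 1) +
    dims[1] * dims[2] * (coords[, 3] - 1)
  pos <- integer(prod(dims))
  pos[lin] <- seq_len(nv)
  offs <- .connectivity_offsets(connectivity)
  lab <- integer(nv)
  cur <- 0L
  for (v in seq_len(nv)) {
    if (lab[v]) next
    cur <- cur + 1L
    queue <- v; lab[v] <- cur
    while (length(queue)) {
      u <- queue[length(queue)]; queue <- queue[-length(queue)]
      cu <- coords[u, ]
      for (o in seq_len(nrow(offs))) {
        cn <- cu + offs[o, ]
        if (any(cn < 1) || any(cn > dims)) next
        p <- pos[cn[1] + dims[1] * (cn[2] - 1) +
                   dims[1] * dims[2] * (cn[3] - 1)]
        if (p && !lab[p]) { lab[p] <- cur; queue <- c(queue, p) }
      }
    }
  }
  lab
}

#' Threshold a t-map and form suprathreshold clusters
#'
#' The cluster-forming threshold is the one-sided upper-tail Student-t
#' quantile at `p_form` (positive contrast); suprathreshold voxels are
#' grouped into connected components under the chosen neighbourhood.
#'
#' @param tmap 3D array of t-statistics.
#' @param df Residual degrees of freedom.
#' @param p_form Cluster-forming p (default 0.001).
#' @param connectivity 6, 18 (default) or 26.
#' @param mask Optional logical 3D array restricting the search.
#' @param two_sided Threshold on `|t|` instead of `t` (default FALSE).
#' @return List: `clusters` (data frame: id, extent, peak_t and peak
#'   voxel indices), `voxels` (per-cluster voxel coordinate matrices),
#'   `threshold`.  Empty cluster set allowed.
#' @export
form_clusters <- function(tmap, df, p_form = 0.001, connectivity = 18,
                          mask = NULL, two_sided = FALSE) {
  thr <- stats::qt(1 - p_form, df)
  stat <- if (two_sided) abs(tmap) else tmap
  sel <- stat > thr
  if (!is.null(mask)) sel <- sel & mask
  idx <- which(sel)
  empty <- list(clusters = data.frame(id = integer(0), extent = integer(0),
                                      peak_t = numeric(0), i = integer(0),
                                      j = integer(0), k = integer(0)),
                voxels = list(), threshold = thr)
  if (length(idx) == 0) return(empty)
  coords <- arrayInd(idx, dim(tmap))
  lab <- .label_components(coords, dim(tmap), connectivity)
  rows <- lapply(sort(unique(lab)), function(l) {
    vi <- which(lab == l)
    tv <- tmap[idx[vi]]
    pk <- vi[which.max(abs(tv))]
    data.frame(id = l, extent = length(vi), peak_t = tv[which.max(abs(tv))],
               i = coords[pk, 1], j = coords[pk, 2], k = coords[pk, 3])
  })
  clusters <- do.call(rbind, rows)
  ord <- order(-clusters$extent)
  voxels <- lapply(clusters$id[ord], function(l)
    coords[lab == l, , drop = FALSE])
  clusters <- clusters[ord, ]
  clusters$id <- seq_len(nrow(clusters))
  rownames(clusters) <- NULL
  list(clusters = clusters, voxels = voxels, threshold = thr)
}

#' Cluster-extent familywise-error control by Freedman-Lane permutation
#'
#' Tests one design column (by default the group x score interaction) at
#' the voxel level with cluster-extent FWE correction.  The reduced
#' model (design without the tested column) is fitted once; permuted
#' datasets are its fitted values plus row-permuted residuals, each
#' refitted under the full model.  The null distribution records the
#' maximum suprathreshold cluster extent per permutation, and each
#' observed cluster gets
#' `p = (1 + #\{max extents >= observed extent\}) / (1 + n_perm)`.
#'
#' @param maps n x V matrix of z-scored fALFF values (subjects x
#'   in-mask voxels).
#' @param design A [build_design()] result.
#' @param mask Logical 3D array whose `TRUE` voxels correspond, in
#'   `which(mask)` order, to the columns of `maps`.
#' @param p_form Cluster-forming p (default 0.001, one-sided positive).
#' @param alpha Cluster-level FWE threshold (default 0.05).
#' @param n_perm Number of permutations (default 500; with 0 all
#'   corrected p are 1 and a warning is given).
#' @param seed Integer seed for the permutation draw.
#' @param connectivity Cluster connectivity (default 18).
#' @param two_sided Form clusters on `|t|` (default FALSE).
#' @param contrast Tested column index (default: the design's
#'   interaction column).
#' @return List: `clusters` data frame (extent, peak voxel, peak_t,
#'   peak_z, r2, p_fwe, significant), `voxels`, `tmap` (3D), `df`,
#'   `threshold`, `perm_max_extent`.
#' @export
cluster_fwe <- function(maps, design, mask, p_form = 0.001, alpha = 0.05,
                        n_perm = 500, seed = 1, connectivity = 18,
                        two_sided = FALSE, contrast = NULL) {
  x <- design$X
  if (is.null(contrast)) contrast <- design$contrast
  n <- nrow(x)
  if (n < 10) warning("n = ", n, " subjects: permutation inference is ",
                      "unreliable below 10")
  if (n_perm == 0) warning("n_perm = 0: all corrected p-values are 1")
  dims <- dim(mask)
  idx <- which(mask)
  stopifnot(length(idx) == ncol(maps))

  fit <- fit_voxelwise(maps, design, contrast)
  tmap <- array(0, dims)
  tmap[idx] <- fit$t
  obs <- form_clusters(tmap, fit$df, p_form, connectivity, mask, two_sided)

  # Freedman-Lane machinery.  Each permuted dataset is Y* = M_P Y with
  # M_P = H_Z + P (I - H_Z) a small n x n matrix, so the per-voxel
  # statistics need only one large matrix product per permutation:
  # numerator c'beta* = (M_P' w)' Y and residuals R_X Y* = (R_X M_P) Y.
  z <- x[, -contrast, drop = FALSE]
  qz <- qr.Q(qr(z))
  hz <- tcrossprod(qz)
  rz <- diag(n) - hz
  xtx_inv <- chol2inv(chol(crossprod(x)))
  w <- as.numeric(x %*% xtx_inv[, contrast])   # X (X'X)^-1 c
  qx <- qr.Q(qr(x))
  cc <- xtx_inv[contrast, contrast]
  df <- n - ncol(x)
  thr <- obs$threshold
  coords_all <- arrayInd(idx, dims)

  set.seed(seed)
  perm_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    pr <- sample.int(n)
    mp <- hz + rz[pr, , drop = FALSE]
    ap <- mp - qx %*% crossprod(qx, mp)          # R_X M_P (n x n)
    big <- rbind(crossprod(mp, w)[, 1], ap) %*% maps
    num <- big[1, ]
    se <- sqrt(colSums(big[-1, , drop = FALSE]^2) / df * cc)
    tv <- ifelse(se > 0, num / se, 0)
    sel <- if (two_sided) abs(tv) > thr else tv > thr
    if (!any(sel)) { perm_max[p] <- 0L; next }
    lab <- .label_components(coords_all[sel, , drop = FALSE], dims,
                             connectivity)
    perm_max[p] <- max(tabulate(lab))
  }

  cl <- obs$clusters
  if (nrow(cl)) {
    cl$peak_z <- t_to_z(cl$peak_t, fit$df)
    cl$r2 <- r_squared(cl$peak_t, fit$df)
    cl$p_fwe <- vapply(cl$extent, function(k)
      (1 + sum(perm_max >= k)) / (1 + n_perm), numeric(1))
    if (n_perm == 0) cl$p_fwe <- rep(1, nrow(cl))
    cl$significant <- cl$p_fwe < alpha
    ord <- order(cl$p_fwe, -cl$extent)
    cl <- cl[ord, ]
    voxels <- obs$voxels[ord]
    cl$id <- seq_len(nrow(cl))
    rownames(cl) <- NULL
  } else voxels <- list()
  list(clusters = cl, voxels = voxels, tmap = tmap, df = fit$df,
       threshold = thr, perm_max_extent = perm_max)
}

#' Render a cluster table with mm coordinates and region labels
#'
#' Peak voxel indices are mapped to mm with the supplied affine
#' (applied to 0-based voxel indices, NIfTI convention); when an integer
#' label volume and name table are given, the peak voxel's region name
#' is reported together with the percentage overlap of the cluster with
#' each label it touches.
#'
#' @param fwe A [cluster_fwe()] result.
#' @param affine 4 x 4 voxel-to-mm matrix (default: identity scaled by
#'   `voxel_size_mm`).
#' @param voxel_size_mm Used to build the default diagonal affine.
#' @param label_volume Optional integer 3D array on the same grid.
#' @param label_names Optional named vector or data frame mapping label
#'   integers to region names.
#' @return Data frame: region, x_mm, y_mm, z_mm, k, t, z, r2, p_fwe,
#'   significant, label_overlap.
#' @export
report_clusters <- function(fwe, affine = NULL, voxel_size_mm = 3,
                            label_volume = NULL, label_names = NULL) {
  cl <- fwe$clusters
  if (is.null(affine))
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
  stopifnot(all(dim(affine) == c(4, 4)))
  if (!is.null(label_volume) && !all(dim(label_volume) == dim(fwe$tmap)))
    stop("label volume grid does not match the statistic map")
  if (nrow(cl) == 0)
    return(data.frame(region = character(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      k = integer(0), t = numeric(0), z = numeric(0),
                      r2 = numeric(0), p_fwe = numeric(0),
                      significant = logical(0),
                      label_overlap = character(0)))
  mm <- t(apply(cl[, c("i", "j", "k")], 1, function(v)
    (affine %*% c(v - 1, 1))[1:3]))
  name_of <- function(l) {
    if (is.null(label_names)) return(as.character(l))
    if (is.data.frame(label_names))
      return(as.character(label_names$name[match(l, label_names$label)]))
    nm <- label_names[as.character(l)]
    ifelse(is.na(nm), as.character(l), nm)
  }
  region <- rep("", nrow(cl))
  overlap <- rep("", nrow(cl))
  if (!is.null(label_volume)) {
    for (r in seq_len(nrow(cl))) {
      region[r] <- name_of(label_volume[cl$i[r], cl$j[r], cl$k[r]])
      vox <- fwe$voxels[[r]]
      labs <- label_volume[cbind(vox[, 1], vox[, 2], vox[, 3])]
      tab <- sort(table(labs), decreasing = TRUE)
      overlap[r] <- paste(sprintf("%s:%.0f%%", name_of(names(tab)),
                                  100 * tab / nrow(vox)), collapse = ";")
    }
  }
  data.frame(region = region, x_mm = mm[, 1], y_mm = mm[, 2],
             z_mm = mm[, 3], k = cl$extent, t = cl$peak_t, z = cl$peak_z,
             r2 = cl$r2, p_fwe = cl$p_fwe, significant = cl$significant,
             label_overlap = overlap)
}

#' Cluster-FWE maps for the model covariates
#'
#' Applies [cluster_fwe()] to each covariate column of the design, as in
#' the fit-with-covariates / inspect / drop-and-refit workflow.
#'
#' @param maps n x V matrix of z-scored maps.
#' @param design A [build_design()] result containing covariate columns.
#' @param mask Logical 3D mask matching `maps`.
#' @param ... Passed to [cluster_fwe()].
#' @return Named list of [cluster_fwe()] results, one per covariate.
#' @export
covariate_clusters <- function(maps, design, mask, ...) {
  covs <- setdiff(design$labels,
                  c("intercept", "group", "score", "group_score"))
  out <- lapply(covs, function(cv)
    cluster_fwe(maps, design, mask,
                contrast = match(cv, design$labels), ...))
  stats::setNames(out, covs)
}
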