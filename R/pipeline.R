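#' Default pipeline configuration
#'
#' A nested list of every pipeline setting, optionally deep-merged with
#' a YAML file and an override list (overrides win over file, file over
#' defaults).  Every run command records the effective configuration in
#' a provenance JSON so any output directory can be reproduced
#' bit-identically.
#'
#' @param path Optional YAML config file.
#' @param overrides Optional nested list of overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    paths = list(data_dir = "data", out_dir = "out",
                 cohort_csv = NULL, label_volume = NULL),
    synthetic = unclass(synth_spec()),
    nuisance = list(despike = list(enabled = TRUE, clip_k = 4),
                    gsr = list(enabled = TRUE),
                    acompcor = list(n_components = 5),
                    erode = list(iterations = 2),
                    smooth = list(fwhm_mm = 6)),
    falff = list(bands = c("broadband", "slow5", "slow4"),
                 taper = list(enabled = FALSE)),
    glm = list(p_form = 0.001, alpha = 0.05, n_perm = 500, seed = 1,
               connectivity = 18, two_sided = FALSE,
               covariates = character(0)),
    stats = list(n_reshuffles = 10000, seed = 1))
  cfg <- defaults
  if (!is.null(path)) cfg <- .deep_merge(cfg, yaml::read_yaml(path))
  cfg <- .deep_merge(cfg, overrides)
  cfg$synthetic$grid_shape <- as.integer(unlist(cfg$synthetic$grid_shape))
  class(cfg) <- "pipeline_config"
  cfg
}

.deep_merge <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(upd[[nm]])))
      base[[nm]] <- .deep_merge(base[[nm]], upd[[nm]])
    else base[[nm]] <- upd[[nm]]
  }
  base
}

.config_spec <- function(config) {
  s <- config$synthetic
  synth_spec(n_low = s$n_low, n_high = s$n_high,
             grid_shape = s$grid_shape, voxel_size_mm = s$voxel_size_mm,
             tr_seconds = s$tr_seconds, n_volumes = s$n_volumes,
             effect_band = s$effect_band, effect_center = s$effect_center,
             effect_radius = s$effect_radius,
             beta_interaction = s$beta_interaction,
             osc_amplitude = s$osc_amplitude,
             bg_osc_amplitude = s$bg_osc_amplitude,
             physio_amplitude = s$physio_amplitude, baseline = s$baseline,
             noise_exponent = s$noise_exponent,
             noise_1f_sd = s$noise_1f_sd, white_sd = s$white_sd,
             motion_sd_mm = s$motion_sd_mm,
             motion_sd_rad = s$motion_sd_rad,
             motion_coupling = s$motion_coupling,
             lesion_radius_range = unlist(s$lesion_radius_range),
             lesion_attenuation = s$lesion_attenuation, seed = s$seed)
}

.write_provenance <- function(dir, config, stage, extra = list()) {
  prov <- c(list(stage = stage, package = "falffband",
                 version = as.character(utils::packageVersion("falffband")),
                 config = unclass(config)), extra)
  jsonlite::write_json(prov, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Simulate and write a synthetic cohort (pipeline stage)
#'
#' @param config A [pipeline_config()]; uses the `synthetic` block and
#'   `paths$data_dir`.
#' @param quiet Suppress progress messages.
#' @return The written manifest, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), quiet = FALSE) {
  spec <- .config_spec(config)
  if (!quiet) message("simulate: generating ", spec$n_low, "+",
                      spec$n_high, " subjects on ",
                      paste(spec$grid_shape, collapse = "x"), " grid")
  cohort_data <- generate_cohort(spec)
  manifest <- write_cohort(cohort_data, config$paths$data_dir)
  .write_provenance(config$paths$data_dir, config, "simulate")
  invisible(manifest)
}

.read_run <- function(data_dir, subject_id, tr_seconds) {
  pick <- function(suffix) {
    f <- file.path(data_dir, paste0(subject_id, suffix))
    if (!file.exists(f)) stop("missing file for subject ", subject_id,
                              ": ", f)
    f
  }
  bold <- RNifti::readNifti(pick("_bold.nii.gz"))
  motion <- as.matrix(utils::read.table(pick("_motion.txt")))
  msk <- function(m) {
    a <- RNifti::readNifti(pick(paste0("_mask_", m, ".nii.gz")))
    array(a > 0.5, dim(a)[1:3])
  }
  run <- list(data = array(as.numeric(bold), dim(bold)[1:4]),
              tr_seconds = tr_seconds, brain_mask = msk("brain"),
              wm_mask = msk("wm"), csf_mask = msk("csf"),
              lesion_mask = msk("lesion"), motion = motion,
              subject_id = subject_id)
  if (nrow(motion) != dim(run$data)[4])
    stop("motion file rows do not match volumes for subject ", subject_id)
  class(run) <- "bold_run"
  run
}

#' Clean runs and write per-subject fALFF z-maps (pipeline stage)
#'
#' For each subject in the cohort table: despike, nuisance regression,
#' smoothing, then one raw + z-scored fALFF NIfTI per configured band,
#' named `<subject>_<band>_falff.nii.gz` / `..._falff_z.nii.gz`, plus a
#' per-subject JSON recording the nuisance columns kept and dropped.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-subject progress messages.
#' @return Invisible data frame of written map paths.
#' @export
run_falff <- function(config = pipeline_config(), quiet = FALSE) {
  dd <- config$paths$data_dir
  od <- config$paths$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  csv <- if (is.null(config$paths$cohort_csv))
    file.path(dd, "cohort.csv") else config$paths$cohort_csv
  cohort <- load_cohort(csv, quiet = quiet)
  tr <- config$synthetic$tr_seconds
  bands <- falff_bands()[unlist(config$falff$bands)]
  nu <- config$nuisance
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    if (!quiet) message("falff: cleaning ", id, " (", i, "/",
                        nrow(cohort), ")")
    run <- .read_run(dd, id, tr)
    cleaned <- clean_run(run,
                         despike_enabled = nu$despike$enabled,
                         despike_clip_k = nu$despike$clip_k,
                         gsr = nu$gsr$enabled,
                         n_compcor = nu$acompcor$n_components,
                         erode_iterations = nu$erode$iterations,
                         fwhm_mm = nu$smooth$fwhm_mm,
                         voxel_size_mm = config$synthetic$voxel_size_mm)
    for (b in names(bands)) {
      fm <- zscore_map(falff_map(cleaned$data, run$brain_mask, tr,
                                 bands[[b]]))
      f_raw <- file.path(od, paste0(id, "_", b, "_falff.nii.gz"))
      f_z <- file.path(od, paste0(id, "_", b, "_falff_z.nii.gz"))
      .write_nifti_vol(fm$raw, f_raw, config$synthetic$voxel_size_mm)
      .write_nifti_vol(fm$zscored, f_z, config$synthetic$voxel_size_mm)
      out[[length(out) + 1]] <- data.frame(subject_id = id, band = b,
                                           raw = f_raw, z = f_z)
    }
    jsonlite::write_json(
      list(subject_id = id,
           design_columns = cleaned$design$labels,
           dropped_columns = cleaned$design$dropped,
           settings = cleaned$settings,
           bands = lapply(bands, unclass)),
      file.path(od, paste0(id, "_falff_provenance.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  }
  .write_provenance(od, config, "falff")
  invisible(do.call(rbind, out))
}

#' Group-level interaction analysis per band (pipeline stage)
#'
#' Stacks the per-subject z-scored fALFF maps of each band, fits the
#' group x score interaction model, runs Freedman-Lane cluster-extent
#' FWE, and writes per band: t/z/r2 NIfTI maps, a cluster TSV with fixed
#' columns (region, x_mm, y_mm, z_mm, k, t, z, r2, p_fwe, significant,
#' label_overlap) and a JSON run report (df, thresholds, n_perm, seed).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisible named list of cluster tables per band.
#' @export
run_analyze <- function(config = pipeline_config(), quiet = FALSE) {
  dd <- config$paths$data_dir
  od <- config$paths$out_dir
  csv <- if (is.null(config$paths$cohort_csv))
    file.path(dd, "cohort.csv") else config$paths$cohort_csv
  cohort <- load_cohort(csv, quiet = quiet)
  brain <- NULL
  design <- build_design(cohort, unlist(config$glm$covariates))
  g <- config$glm
  vox <- config$synthetic$voxel_size_mm
  results <- list()
  for (b in unlist(config$falff$bands)) {
    maps <- NULL
    for (i in seq_len(nrow(cohort))) {
      id <- cohort$subject_id[i]
      f <- file.path(od, paste0(id, "_", b, "_falff_z.nii.gz"))
      if (!file.exists(f)) stop("missing fALFF map for subject ", id,
                                ", band ", b, ": ", f)
      img <- RNifti::readNifti(f)
      if (is.null(brain)) {
        bm <- RNifti::readNifti(file.path(
          dd, paste0(cohort$subject_id[1], "_mask_brain.nii.gz")))
        brain <- array(bm > 0.5, dim(bm)[1:3])
      }
      v <- unclass(img)[which(brain)]
      if (is.null(maps)) maps <- matrix(0, nrow(cohort), length(v))
      maps[i, ] <- v
    }
    if (!quiet) message("analyze: band ", b, " (", ncol(maps),
                        " voxels, ", g$n_perm, " permutations)")
    fwe <- cluster_fwe(maps, design, brain, p_form = g$p_form,
                       alpha = g$alpha, n_perm = g$n_perm, seed = g$seed,
                       connectivity = g$connectivity,
                       two_sided = g$two_sided)
    lab_vol <- lab_names <- NULL
    if (!is.null(config$paths$label_volume)) {
      lv <- RNifti::readNifti(config$paths$label_volume)
      lab_vol <- array(as.integer(round(lv)), dim(lv)[1:3])
    }
    tab <- report_clusters(fwe, voxel_size_mm = vox,
                           label_volume = lab_vol)
    .write_nifti_vol(fwe$tmap, file.path(od, paste0(b, "_tmap.nii.gz")),
                     vox)
    zmap <- array(0, dim(fwe$tmap))
    zmap[which(brain)] <- t_to_z(fwe$tmap[which(brain)], fwe$df)
    .write_nifti_vol(zmap, file.path(od, paste0(b, "_zmap.nii.gz")), vox)
    r2map <- array(0, dim(fwe$tmap))
    r2map[which(brain)] <- r_squared(fwe$tmap[which(brain)], fwe$df)
    .write_nifti_vol(r2map, file.path(od, paste0(b, "_r2map.nii.gz")),
                     vox)
    utils::write.table(tab, file.path(od, paste0(b, "_clusters.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(band = b, n_subjects = nrow(cohort), df = fwe$df,
           cluster_forming_t = fwe$threshold, p_form = g$p_form,
           alpha = g$alpha, n_perm = g$n_perm, seed = g$seed,
           connectivity = g$connectivity,
           n_clusters = nrow(fwe$clusters),
           n_significant = sum(fwe$clusters$significant %||% logical(0))),
      file.path(od, paste0(b, "_analysis_report.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
    results[[b]] <- tab
  }
  .write_provenance(od, config, "analyze")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demographic comparison report (pipeline stage)
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress messages.
#' @return The [cohort_report()], invisibly; TSV and aligned-text
#'   renderings are written to the output directory.
#' @export
run_demographics <- function(config = pipeline_config(), quiet = FALSE) {
  dd <- config$paths$data_dir
  od <- config$paths$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  csv <- if (is.null(config$paths$cohort_csv))
    file.path(dd, "cohort.csv") else config$paths$cohort_csv
  cohort <- load_cohort(csv, quiet = quiet)
  rep <- cohort_report(cohort, n_reshuffles = config$stats$n_reshuffles,
                       seed = config$stats$seed)
  write_cohort_report(rep, file.path(od, "demographics.tsv"))
  txt <- utils::capture.output(print(rep))
  writeLines(txt, file.path(od, "demographics.txt"))
  .write_provenance(od, config, "demographics")
  invisible(rep)
}

#' Run the full pipeline: simulate, falff, analyze, demographics
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisible list with the analysis cluster tables and the
#'   demographic report.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  run_simulate(config, quiet = quiet)
  run_falff(config, quiet = quiet)
  res <- run_analyze(config, quiet = quiet)
  dem <- run_demographics(config, quiet = quiet)
  invisible(list(analysis = res, demographics = dem))
}
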