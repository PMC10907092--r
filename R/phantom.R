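# Synthetic phantom cohorts with known cross-ROI coupling. The generator is
# the ground-truth testbed for the whole pipeline: every downstream claim
# (training recovery, occlusion attribution, ROC separability) is checked
# against the structure planted here.

#' Phantom cohort configuration
#'
#' Defines a paired-modality phantom: an axis-aligned block parcellation on
#' a 3D grid, a latent per-subject disease stage s in [0,1], source ROI
#' means that drift with stage, and target ("tau-like") ROI means
#' m = t(W) %*% u + stage_effect * s, where `coupling[s, t]` is the weight
#' of source ROI s on target ROI t (diagonal = local coupling). Voxels get
#' additive Gaussian noise; an optional multiplicative per-scan scale
#' nuisance exercises SUVR normalization.
#'
#' @param grid_shape length-3 integer, each >= 16.
#' @param n_rois number of ROIs R (>= 8, so a 6-member meta-ROI plus a
#'   reference region fit).
#' @param n_subjects number of subjects.
#' @param scans_per_subject scans per subject; scans share the subject's
#'   stage but have independent noise.
#' @param coupling R x R non-negative matrix, `coupling[s, t]` = influence of
#'   source ROI s on target ROI t. Default: identity plus one remote
#'   off-diagonal coupling (see [default_coupling()]).
#' @param stage_effect per-ROI slope of the target mean on stage; default
#'   0.8 for meta-ROI members, 0.2 elsewhere, 0 for the reference region.
#' @param noise_sd additive voxel noise SD (intensity units), >= 0.
#' @param ref_region_id label used as normalization reference (default: the
#'   last ROI). Its target mean is held fixed at `ref_target_mean` so SUVR
#'   normalization is always well defined.
#' @param seed integer RNG seed; identical (config, seed) gives a
#'   byte-identical cohort.
#' @param scan_sd per-scan SD of source ROI means around the stage line
#'   (scan-to-scan regional variability beyond stage; also what makes a
#'   planted cross-ROI coupling statistically identifiable).
#' @param src_base_range,src_slope_range uniform ranges for the per-ROI
#'   baseline and stage slope of the source means.
#' @param background_mean mean intensity outside all ROIs (both modalities).
#' @param ref_target_mean fixed target mean in the reference region (> 0).
#' @param scale_sd SD of the log-normal global scale nuisance per scan
#'   (0 = off, the default).
#' @param min_roi_voxels smallest acceptable ROI size in voxels.
#' @param stage_cuts increasing cut points in (0,1) mapping stage to the six
#'   clinical-style group labels CU-, CU+, MCI, DLB-spec, FTD-spec, AD-spec.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 32L),
                           n_rois = 12L,
                           n_subjects = 60L,
                           scans_per_subject = 2L,
                           coupling = NULL,
                           stage_effect = NULL,
                           noise_sd = 0.06,
                           ref_region_id = n_rois,
                           seed = 1L,
                           scan_sd = 0.05,
                           src_base_range = c(0.9, 1.4),
                           src_slope_range = c(-0.4, 0.4),
                           background_mean = 0.3,
                           ref_target_mean = 1.0,
                           scale_sd = 0,
                           min_roi_voxels = 8L,
                           stage_cuts = c(0.30, 0.45, 0.60, 0.70, 0.80)) {
  grid_shape <- as.integer(grid_shape)
  n_rois <- as.integer(n_rois)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("`grid_shape` must be 3 integers, each >= 16")
  if (n_rois < 8L) stop("`n_rois` must be >= 8")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (n_subjects < 1L || scans_per_subject < 1L)
    stop("`n_subjects` and `scans_per_subject` must be positive")
  if (is.null(coupling)) coupling <- default_coupling(n_rois)
  coupling <- as.matrix(coupling)
  if (!identical(dim(coupling), c(n_rois, n_rois)))
    stop("`coupling` must be an R x R matrix with R = n_rois")
  if (any(coupling < 0)) stop("`coupling` weights must be non-negative")
  ref_region_id <- as.integer(ref_region_id)
  if (ref_region_id < 1L || ref_region_id > n_rois)
    stop("`ref_region_id` must be an ROI label in 1..n_rois")
  meta <- default_meta_members(n_rois, ref_region_id)
  if (is.null(stage_effect)) {
    stage_effect <- rep(0.2, n_rois)
    stage_effect[meta] <- 0.8
    stage_effect[ref_region_id] <- 0
  }
  if (length(stage_effect) != n_rois)
    stop("`stage_effect` must have one slope per ROI")
  if (ref_target_mean <= 0)
    stop("`ref_target_mean` must be positive (SUVR undefined otherwise)")
  structure(
    list(grid_shape = grid_shape, n_rois = n_rois,
         n_subjects = as.integer(n_subjects),
         scans_per_subject = as.integer(scans_per_subject),
         coupling = coupling, stage_effect = as.numeric(stage_effect),
         noise_sd = noise_sd, ref_region_id = ref_region_id,
         seed = as.integer(seed), scan_sd = scan_sd,
         src_base_range = src_base_range, src_slope_range = src_slope_range,
         background_mean = background_mean, ref_target_mean = ref_target_mean,
         scale_sd = scale_sd, min_roi_voxels = as.integer(min_roi_voxels),
         stage_cuts = stage_cuts, meta_members = meta),
    class = "phantom_config")
}

#' Default coupling matrix: local identity plus one remote link
#'
#' @param n_rois number of ROIs.
#' @param remote_source,remote_target labels of the planted remote coupling
#'   (source ROI drives a physically distant target ROI). Defaults 7 -> 2,
#'   which sit in non-adjacent lattice cells of the default atlas — far
#'   apart, yet within the receptive field of a depth-2 network on a 32^3
#'   grid, so the link is learnable at desk scale.
#' @param weight remote coupling weight.
#' @return R x R matrix, `[s, t]` = source-on-target weight.
#' @export
default_coupling <- function(n_rois, remote_source = 7L, remote_target = 2L,
                             weight = 0.6) {
  W <- diag(n_rois)
  if (n_rois >= max(remote_source, remote_target))
    W[remote_source, remote_target] <- weight
  W
}

default_meta_members <- function(n_rois, ref_region_id) {
  setdiff(seq_len(n_rois), ref_region_id)[1:6]
}

#' Build the phantom ROI atlas
#'
#' ROIs are axis-aligned blocks centred in the cells of a regular lattice
#' partition of the grid, so distinct ROIs are never face-adjacent and
#' "physically remote" ROI pairs exist by construction. Label 0 is
#' background. The atlas is a deterministic function of the configuration.
#'
#' @param config a `phantom_config`.
#' @return an `roi_atlas` with `n_rois` non-empty labels.
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  R <- config$n_rois
  gs <- config$grid_shape
  if (R * config$min_roi_voxels > prod(gs))
    stop(sprintf("grid %s too small to host %d ROIs of >= %d voxels",
                 paste(gs, collapse = "x"), R, config$min_roi_voxels))
  la <- ceiling(R^(1 / 3))
  lb <- ceiling(sqrt(R / la))
  lc <- ceiling(R / (la * lb))
  cell <- gs %/% c(la, lb, lc)
  blk <- pmax(1L, (cell * 6L) %/% 10L)  # central ~60% of each cell
  if (prod(blk) < config$min_roi_voxels)
    stop(sprintf("grid %s too small to host %d ROIs of >= %d voxels",
                 paste(gs, collapse = "x"), R, config$min_roi_voxels))
  labels <- array(0L, dim = gs)
  lab <- 0L
  for (iz in seq_len(lc) - 1L) for (iy in seq_len(lb) - 1L) for (ix in seq_len(la) - 1L) {
    if (lab >= R) break
    lab <- lab + 1L
    orig <- c(ix, iy, iz) * cell + (cell - blk) %/% 2L  # 0-based block origin
    labels[orig[1] + seq_len(blk[1]), orig[2] + seq_len(blk[2]),
           orig[3] + seq_len(blk[3])] <- lab
  }
  if (lab < R) stop("internal: lattice did not place all ROIs")
  nm <- sprintf("roi_%02d", seq_len(R))
  nm[config$ref_region_id] <- "reference"
  names(nm) <- as.character(seq_len(R))
  roi_atlas(labels, names = nm, meta_members = config$meta_members,
            reference_label = config$ref_region_id)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

stage_to_group <- function(stage, cuts) {
  groups <- c("CU-", "CU+", "MCI", "DLB-spec", "FTD-spec", "AD-spec")
  groups[findInterval(stage, cuts) + 1L]
}

#' Generate a paired-modality phantom cohort
#'
#' Draws, under the configured seed: per-ROI source baselines and stage
#' slopes; one latent stage per subject (uniform on [0,1], mapped to a
#' group label by fixed stage cut points and to amyloid status by the first
#' cut); per scan, source ROI means u = base + slope * s + N(0, scan_sd)
#' and target ROI means m = t(W) %*% u + stage_effect * s with the
#' reference-region mean pinned to `ref_target_mean`; then voxel values =
#' ROI mean + N(0, noise_sd). Noiseless target means are stored per scan as
#' `true_roi_means`.
#'
#' @param config a `phantom_config`.
#' @param atlas the atlas from [make_atlas()] with matching `n_rois`.
#' @return An object of class `tau_cohort`: `scans` (list of scan records
#'   with `scan_id`, `subject_id`, `source`, `target`, `true_roi_means`),
#'   `table` (data.frame: subject_id, scan_id, group_label, amyloid_status,
#'   stage) and the `config`.
#' @export
generate_cohort <- function(config, atlas) {
  stopifnot(inherits(config, "phantom_config"), inherits(atlas, "roi_atlas"))
  R <- config$n_rois
  if (!identical(atlas_labels(atlas), seq_len(R)))
    stop("atlas labels do not match config$n_rois")
  lab_idx <- lapply(seq_len(R), function(l) which(atlas$labels == l))
  bg_idx <- which(atlas$labels == 0L)
  Wt <- t(config$coupling)
  with_seed(config$seed, {
    src_base <- stats::runif(R, config$src_base_range[1], config$src_base_range[2])
    src_slope <- stats::runif(R, config$src_slope_range[1], config$src_slope_range[2])
    src_base[config$ref_region_id] <- 1.0
    src_slope[config$ref_region_id] <- 0.0
    scans <- list()
    rows <- list()
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("sub%03d", i)
      s <- stats::runif(1)
      grp <- stage_to_group(s, config$stage_cuts)
      amy <- if (s >= config$stage_cuts[1]) "pos" else "neg"
      for (j in seq_len(config$scans_per_subject)) {
        scan_id <- sprintf("%s_scan%d", sid, j)
        u <- src_base + src_slope * s + stats::rnorm(R, 0, config$scan_sd)
        u[config$ref_region_id] <- 1.0
        m <- as.vector(Wt %*% u) + config$stage_effect * s
        m[config$ref_region_id] <- config$ref_target_mean
        if (m[config$ref_region_id] <= 0)
          stop("reference-region target mean is non-positive; SUVR undefined")
        if (any(m <= 0))
          stop("configuration yields non-positive target ROI means; ",
               "regional MAPE would be undefined")
        src_arr <- array(config$background_mean, dim = config$grid_shape)
        tgt_arr <- array(config$background_mean, dim = config$grid_shape)
        for (l in seq_len(R)) {
          src_arr[lab_idx[[l]]] <- u[l]
          tgt_arr[lab_idx[[l]]] <- m[l]
        }
        if (config$noise_sd > 0) {
          nv <- prod(config$grid_shape)
          src_arr <- src_arr + array(stats::rnorm(nv, 0, config$noise_sd),
                                     dim = config$grid_shape)
          tgt_arr <- tgt_arr + array(stats::rnorm(nv, 0, config$noise_sd),
                                     dim = config$grid_shape)
        }
        if (config$scale_sd > 0) {
          src_arr <- src_arr * exp(stats::rnorm(1, 0, config$scale_sd))
          tgt_arr <- tgt_arr * exp(stats::rnorm(1, 0, config$scale_sd))
        }
        scans[[scan_id]] <- list(
          scan_id = scan_id, subject_id = sid,
          source = volume(src_arr, space = "template"),
          target = volume(tgt_arr, space = "template"),
          true_roi_means = m)
        rows[[scan_id]] <- data.frame(
          subject_id = sid, scan_id = scan_id, group_label = grp,
          amyloid_status = amy, stage = s, stringsAsFactors = FALSE)
      }
    }
    structure(list(scans = scans,
                   table = do.call(rbind, c(rows, make.row.names = FALSE)),
                   config = config),
              class = "tau_cohort")
  })
}

#' @export
print.tau_cohort <- function(x, ...) {
  cat(sprintf("<tau_cohort> %d scans from %d subjects, grid %s, %d ROIs\n",
              length(x$scans), length(unique(x$table$subject_id)),
              paste(x$config$grid_shape, collapse = "x"), x$config$n_rois))
  print(table(x$table$group_label))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One NIfTI per volume (`<scan_id>_source.nii.gz`, `<scan_id>_target.nii.gz`),
#' a `cohort.csv` table and a `true_roi_means.csv` matrix.
#'
#' @param cohort a `tau_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tau_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in cohort$scans) {
    write_volume(sc$source, file.path(dir, paste0(sc$scan_id, "_source.nii.gz")))
    write_volume(sc$target, file.path(dir, paste0(sc$scan_id, "_target.nii.gz")))
  }
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  tm <- do.call(rbind, lapply(cohort$scans, function(sc) sc$true_roi_means))
  rownames(tm) <- names(cohort$scans)
  utils::write.csv(tm, file.path(dir, "true_roi_means.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `cohort.csv` and the per-scan NIfTIs.
#' @return a `tau_cohort` (without the generating `config`).
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  tm_path <- file.path(dir, "true_roi_means.csv")
  tm <- if (file.exists(tm_path)) {
    m <- utils::read.csv(tm_path, row.names = 1)
    as.matrix(m)
  } else NULL
  scans <- lapply(seq_len(nrow(tab)), function(i) {
    sid <- tab$scan_id[i]
    list(scan_id = sid, subject_id = tab$subject_id[i],
         source = read_volume(file.path(dir, paste0(sid, "_source.nii.gz"))),
         target = read_volume(file.path(dir, paste0(sid, "_target.nii.gz"))),
         true_roi_means = if (!is.null(tm)) tm[sid, ] else NULL)
  })
  names(scans) <- tab$scan_id
  structure(list(scans = scans, table = tab, config = NULL),
            class = "tau_cohort")
}
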