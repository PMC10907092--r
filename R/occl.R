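# ROI-wise occlusion sensitivity: zero one ROI in the (normalized,
# network-space) source, re-impute, and record the change in each region's
# MAPE. dMAPE[R1, R2] = MAPE_{R1->R2} - MAPE_{R2}, where R1 is the occluded
# ROI and R2 the region where the MAPE is measured; entries may be negative
# (occlusion can reduce error) and are never clamped. Occlusion is applied
# after intensity normalization so the reference-region median used for
# SUVR scaling is not corrupted by the zeroed voxels.

#' Zero out one ROI of a volume
#'
#' @param vol a `tau_volume` aligned to `atlas`.
#' @param atlas an `roi_atlas`.
#' @param label ROI label to occlude (0 occludes the background).
#' @return the volume with the ROI's voxels set to 0, all others unchanged.
#' @export
occlude_roi <- function(vol, atlas, label) {
  check_aligned(vol, atlas)
  label <- as.integer(label)
  sel <- atlas$labels == label
  if (!any(sel)) stop("no voxels carry label ", label)
  vals <- vol$values
  vals[sel] <- 0
  volume(vals, voxel_size = vol$voxel_size, space = vol$space)
}

#' Occlusion sensitivity matrix
#'
#' For each ROI R1: occlude R1 in every test-scan source, re-impute,
#' extract regional SUVR, compute the per-ROI MAPE against the ground-truth
#' regional SUVR across scans, and subtract the un-occluded baseline MAPE.
#' Row R1 of the result is the influence of occluding R1 on every evaluated
#' region R2.
#'
#' @param model a model handle usable with [impute()].
#' @param scans list of scan records (network-space `source` and `target`),
#'   e.g. `cohort_scans(cohort, fold_partitions(split, fold)$test)`.
#' @param atlas an `roi_atlas`.
#' @return An object of class `occlusion_matrix`: `delta` (R x R matrix,
#'   rows = occluded ROI, columns = evaluated ROI), `row_sums`,
#'   `baseline_mape` (per-ROI un-occluded MAPE) and `roi_order`.
#' @export
occlusion_matrix <- function(model, scans, atlas) {
  if (length(scans) == 0L) stop("need at least one test scan")
  labs <- atlas_labels(atlas)
  R <- length(labs)
  roi_cols <- paste0("roi_", labs)
  truth <- t(vapply(scans, function(sc)
    extract_regional_suvr(sc$target, atlas)[roi_cols], numeric(R)))
  base_pred <- t(vapply(scans, function(sc)
    extract_regional_suvr(impute(model, sc$source), atlas)[roi_cols], numeric(R)))
  baseline <- vapply(seq_len(R), function(r)
    mape(base_pred[, r], truth[, r]), numeric(1))
  delta <- matrix(NA_real_, R, R, dimnames = list(roi_cols, roi_cols))
  for (r1 in seq_len(R)) {
    occ_pred <- t(vapply(scans, function(sc)
      extract_regional_suvr(
        impute(model, occlude_roi(sc$source, atlas, labs[r1])),
        atlas)[roi_cols], numeric(R)))
    occ_mape <- vapply(seq_len(R), function(r2)
      mape(occ_pred[, r2], truth[, r2]), numeric(1))
    delta[r1, ] <- occ_mape - baseline
  }
  structure(list(delta = delta, row_sums = rowSums(delta),
                 baseline_mape = stats::setNames(baseline, roi_cols),
                 roi_order = labs),
            class = "occlusion_matrix")
}

#' @export
print.occlusion_matrix <- function(x, ...) {
  cat(sprintf("<occlusion_matrix> %d ROIs; top influence: occluding %s (row sum %.2f%%)\n",
              nrow(x$delta), names(which.max(x$row_sums)), max(x$row_sums)))
  invisible(x)
}

#' Write an occlusion matrix as CSV
#'
#' Labelled rows (occluded ROI) and columns (evaluated ROI) plus a
#' `row_sum` column (total influence of occluding each ROI).
#'
#' @param x an `occlusion_matrix`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_occlusion_matrix <- function(x, path) {
  stopifnot(inherits(x, "occlusion_matrix"))
  df <- as.data.frame(x$delta)
  df$row_sum <- x$row_sums
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}
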