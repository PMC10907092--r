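#' Crop/pad specification between template and network space
#'
#' The network requires side lengths divisible by 2^depth, so template-space
#' volumes are resized deterministically: slices are cropped from the two
#' ends of the anterior-posterior axis (axis 2; anterior is the high-index
#' end) and zeros are padded at the low-index ("left" and "bottom") ends of
#' axes 1 and 3.
#'
#' @param template_shape length-3 integer, template grid.
#' @param network_shape length-3 integer, network grid.
#' @param crop_anterior slices removed at the anterior (high-index) end of axis 2.
#' @param crop_posterior slices removed at the posterior (low-index) end of axis 2.
#' @param pad_axis1 zero slices added at the low end of axis 1.
#' @param pad_axis3 zero slices added at the low end of axis 3.
#' @return An object of class `crop_pad_spec`.
#' @export
crop_pad_spec <- function(template_shape, network_shape,
                          crop_anterior, crop_posterior,
                          pad_axis1, pad_axis3) {
  template_shape <- as.integer(template_shape)
  network_shape <- as.integer(network_shape)
  cp <- as.integer(c(crop_anterior, crop_posterior, pad_axis1, pad_axis3))
  if (any(cp < 0L)) stop("crop/pad amounts must be non-negative")
  if (template_shape[2] - cp[1] - cp[2] != network_shape[2])
    stop("AP axis: template length - crops must equal network length")
  if (template_shape[1] + cp[3] != network_shape[1])
    stop("axis 1: template length + pad must equal network length")
  if (template_shape[3] + cp[4] != network_shape[3])
    stop("axis 3: template length + pad must equal network length")
  structure(list(template_shape = template_shape, network_shape = network_shape,
                 crop_anterior = cp[1], crop_posterior = cp[2],
                 pad_axis1 = cp[3], pad_axis3 = cp[4]),
            class = "crop_pad_spec")
}

#' The standard 121x145x121 to 128x128x128 crop/pad
#'
#' Eight anterior and nine posterior slices are cropped along the AP axis
#' (145 - 8 - 9 = 128) and seven zero slices are padded at the low ends of
#' axes 1 and 3 (121 + 7 = 128).
#'
#' @return a `crop_pad_spec`.
#' @export
default_crop_pad_spec <- function() {
  crop_pad_spec(template_shape = c(121L, 145L, 121L),
                network_shape = c(128L, 128L, 128L),
                crop_anterior = 8L, crop_posterior = 9L,
                pad_axis1 = 7L, pad_axis3 = 7L)
}

#' Identity crop/pad for a volume already in network shape
#' @param shape length-3 integer grid shape.
#' @return a `crop_pad_spec` with zero crops and pads.
#' @export
identity_crop_pad_spec <- function(shape) {
  crop_pad_spec(shape, shape, 0L, 0L, 0L, 0L)
}

#' Resize a template-space volume to network space
#'
#' Retained voxels are copied unchanged; padded voxels are exactly zero.
#'
#' @param vol a `tau_volume` with shape `spec$template_shape`.
#' @param spec a `crop_pad_spec`.
#' @return a network-space `tau_volume` of shape `spec$network_shape`.
#' @export
crop_pad <- function(vol, spec) {
  stopifnot(inherits(vol, "tau_volume"), inherits(spec, "crop_pad_spec"))
  if (!identical(as.integer(vol$shape), spec$template_shape))
    stop(sprintf("volume shape %s does not match template shape %s",
                 paste(vol$shape, collapse = "x"),
                 paste(spec$template_shape, collapse = "x")))
  ts <- spec$template_shape; ns <- spec$network_shape
  out <- array(0, dim = ns)
  y_keep <- seq.int(spec$crop_posterior + 1L, ts[2] - spec$crop_anterior)
  out[spec$pad_axis1 + seq_len(ts[1]), seq_along(y_keep),
      spec$pad_axis3 + seq_len(ts[3])] <- vol$values[, y_keep, ]
  volume(out, voxel_size = vol$voxel_size, space = "network")
}

#' Restore a network-space volume to template shape
#'
#' Voxels in the retained region equal the input exactly; the re-created
#' cropped AP slices are zero.
#'
#' @param vol a network-space `tau_volume` of shape `spec$network_shape`.
#' @param spec a `crop_pad_spec`.
#' @return a template-space `tau_volume` of shape `spec$template_shape`.
#' @export
invert_crop_pad <- function(vol, spec) {
  stopifnot(inherits(vol, "tau_volume"), inherits(spec, "crop_pad_spec"))
  if (!identical(as.integer(vol$shape), spec$network_shape))
    stop(sprintf("volume shape %s does not match network shape %s",
                 paste(vol$shape, collapse = "x"),
                 paste(spec$network_shape, collapse = "x")))
  ts <- spec$template_shape
  out <- array(0, dim = ts)
  y_keep <- seq.int(spec$crop_posterior + 1L, ts[2] - spec$crop_anterior)
  out[, y_keep, ] <- vol$values[spec$pad_axis1 + seq_len(ts[1]),
                                seq_along(y_keep),
                                spec$pad_axis3 + seq_len(ts[3])]
  volume(out, voxel_size = vol$voxel_size, space = "template")
}

#' SUVR normalization by reference-region median
#'
#' Divides the whole volume by the median uptake within the atlas's
#' reference region, so the reference-region median of the output is 1.
#'
#' @param vol a `tau_volume`.
#' @param atlas an `roi_atlas` aligned to `vol`; its `reference_label`
#'   defines the reference region.
#' @return the SUVR-normalized `tau_volume`.
#' @export
normalize_suvr <- function(vol, atlas) {
  check_aligned(vol, atlas)
  ref <- vol$values[atlas$labels == atlas$reference_label]
  if (length(ref) == 0L)
    stop("reference region (label ", atlas$reference_label, ") is empty")
  m <- stats::median(ref)
  if (!is.finite(m) || m <= 0)
    stop(sprintf("reference-region median must be positive, got %g", m))
  volume(vol$values / m, voxel_size = vol$voxel_size, space = vol$space)
}

#' T1w intensity normalization by white-matter mean
#'
#' Divides the volume by the mean intensity within a white-matter mask, so
#' the in-mask mean of the output is 1.
#'
#' @param vol a `tau_volume`.
#' @param wm_mask a `tau_volume` of the same shape; voxels with value > 0
#'   form the mask.
#' @return the normalized `tau_volume`.
#' @export
normalize_t1w <- function(vol, wm_mask) {
  check_aligned(vol, wm_mask)
  sel <- wm_mask$values > 0
  if (!any(sel)) stop("white-matter mask is empty")
  m <- mean(vol$values[sel])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("white-matter mean must be positive, got %g", m))
  volume(vol$values / m, voxel_size = vol$voxel_size, space = vol$space)
}

#' Normalize and resize a cohort to network space
#'
#' Applies SUVR normalization (source and target) and the crop/pad to every
#' scan, returning a cohort ready for training and imputation.
#'
#' @param cohort a `tau_cohort` (see [generate_cohort()]).
#' @param atlas the aligned `roi_atlas`.
#' @param spec a `crop_pad_spec`, or `NULL` (default) to keep the grid as is
#'   when it is already network-compatible.
#' @return the cohort with normalized (and resized) `source`/`target` volumes.
#' @export
prepare_cohort <- function(cohort, atlas, spec = NULL) {
  stopifnot(inherits(cohort, "tau_cohort"))
  cohort$scans <- lapply(cohort$scans, function(sc) {
    sc$source <- normalize_suvr(sc$source, atlas)
    sc$target <- normalize_suvr(sc$target, atlas)
    if (!is.null(spec)) {
      sc$source <- crop_pad(sc$source, spec)
      sc$target <- crop_pad(sc$target, spec)
    }
    sc
  })
  cohort
}
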