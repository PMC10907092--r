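#' Construct a template- or network-space volume
#'
#' A volume is a 3D scalar grid with voxel size (mm) and a space tag. The
#' axis convention used throughout the package is fixed: axis 1 runs
#' left-right, axis 2 posterior-anterior (so the anterior end is the
#' high-index end of axis 2), axis 3 inferior-superior. Voxel indices are
#' 1-based in R code.
#'
#' @param values 3D numeric array; all values must be finite.
#' @param voxel_size length-3 positive numeric, mm per voxel.
#' @param space `"template"` or `"network"`.
#' @return An object of class `tau_volume`.
#' @export
volume <- function(values, voxel_size = c(1, 1, 1), space = "template") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L)
    stop(sprintf("volume contains %d non-finite voxel(s)", n_bad))
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive numbers")
  space <- match.arg(space, c("template", "network"))
  structure(
    list(values = values, shape = dim(values),
         voxel_size = as.numeric(voxel_size), space = space),
    class = "tau_volume")
}

#' @export
print.tau_volume <- function(x, ...) {
  cat(sprintf("<tau_volume> %s space, %s voxels, voxel size %s mm, range [%.4g, %.4g]\n",
              x$space, paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct an ROI atlas
#'
#' Integer label grid aligned to a companion volume. Label 0 is reserved for
#' background. A designated subset of labels forms the composite meta-ROI
#' (in the real anatomy: amygdala, entorhinal, fusiform, parahippocampal,
#' inferior and middle temporal), and one label is the intensity-
#' normalization reference region.
#'
#' @param labels 3D integer array of ROI labels (0 = background).
#' @param names named character vector or list mapping label -> ROI name
#'   (names are the labels as strings).
#' @param meta_members integer vector of labels forming the meta-ROI.
#' @param reference_label single integer label of the reference region.
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, names, meta_members, reference_label) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (all(labels == 0L)) stop("atlas labels are all background (0)")
  meta_members <- as.integer(meta_members)
  if (length(meta_members) == 0L || any(meta_members == 0L))
    stop("`meta_members` must be a non-empty set of non-background labels")
  reference_label <- as.integer(reference_label)
  present <- sort(unique(as.integer(labels[labels != 0L])))
  missing <- setdiff(c(meta_members, reference_label), present)
  if (length(missing) > 0L)
    stop("labels absent from atlas grid: ", paste(missing, collapse = ", "))
  structure(
    list(labels = labels, names = names, meta_members = meta_members,
         reference_label = reference_label),
    class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  labs <- atlas_labels(x)
  cat(sprintf("<roi_atlas> %s voxels, %d ROIs, meta-ROI {%s}, reference %d\n",
              paste(dim(x$labels), collapse = "x"), length(labs),
              paste(x$meta_members, collapse = ","), x$reference_label))
  invisible(x)
}

#' Non-background labels of an atlas, in increasing order
#' @param atlas an `roi_atlas`.
#' @return integer vector of labels.
#' @export
atlas_labels <- function(atlas) {
  sort(unique(as.integer(atlas$labels[atlas$labels != 0L])))
}

#' Read a 3D single-frame NIfTI volume
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param space space tag to attach, `"template"` (default) or `"network"`.
#' @return a `tau_volume`.
#' @export
read_volume <- function(path, space = "template") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    dim(img) <- d[1:3]
  } else if (length(d) != 3L) {
    stop(sprintf("expected a 3D single-frame volume, got %d dimensions", length(d)))
  }
  vx <- RNifti::pixdim(img)[1:3]
  vals <- array(as.numeric(img), dim = dim(img))
  volume(vals, voxel_size = vx, space = space)
}

#' Write a volume to NIfTI-1
#'
#' Round trip through [read_volume()] preserves shape exactly and values to
#' stored (float32) precision. Orientation metadata is written as identity
#' scaling with the volume's voxel sizes; no reorientation is ever applied.
#'
#' @param vol a `tau_volume`.
#' @param path destination path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "tau_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that a volume and an atlas share the same grid
#'
#' @param vol a `tau_volume`.
#' @param atlas an `roi_atlas` (or a second `tau_volume`).
#' @return `TRUE` invisibly, or an error naming both shapes.
#' @export
check_aligned <- function(vol, atlas) {
  s1 <- vol$shape
  s2 <- if (inherits(atlas, "roi_atlas")) dim(atlas$labels) else atlas$shape
  if (!identical(as.integer(s1), as.integer(s2)))
    stop(sprintf("grids are not aligned: %s vs %s",
                 paste(s1, collapse = "x"), paste(s2, collapse = "x")))
  invisible(TRUE)
}

#' Write an atlas as NIfTI labels plus a JSON label map
#'
#' @param atlas an `roi_atlas`.
#' @param nifti_path destination for the integer label grid.
#' @param json_path destination for names, meta-ROI members and reference label.
#' @return `nifti_path`, invisibly.
#' @export
write_atlas <- function(atlas, nifti_path, json_path) {
  stopifnot(inherits(atlas, "roi_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::writeNifti(img, nifti_path)
  meta <- list(names = as.list(atlas$names),
               meta_members = atlas$meta_members,
               reference_label = atlas$reference_label)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE)
  invisible(nifti_path)
}

#' Read an atlas written by [write_atlas()]
#' @param nifti_path label grid NIfTI.
#' @param json_path JSON label map.
#' @return an `roi_atlas`.
#' @export
read_atlas <- function(nifti_path, json_path) {
  img <- RNifti::readNifti(nifti_path)
  labels <- array(as.integer(round(img)), dim = dim(img))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  roi_atlas(labels, names = unlist(meta$names),
            meta_members = meta$meta_members,
            reference_label = meta$reference_label)
}
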