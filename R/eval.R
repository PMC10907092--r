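# Regional-SUVR evaluation: per-ROI median uptake and the composite
# meta-ROI (mean of member medians), similarity metrics across scans
# (Pearson r, MAPE, voxel-wise RMSE maps, MS-SSIM) and ROC analyses for
# tau positivity and diagnostic-group contrasts.

#' The four standard tau-positivity meta-ROI cutoffs
#' @export
TAU_CUTOFFS <- c(1.11, 1.21, 1.33, 1.46)

#' Regional SUVR of one volume
#'
#' Median uptake within each ROI, plus the meta-ROI value defined as the
#' arithmetic mean of the member-ROI medians.
#'
#' @param vol a `tau_volume` aligned to `atlas`.
#' @param atlas an `roi_atlas`.
#' @return named numeric vector: one entry per ROI label (named
#'   `roi_<label>`) plus `meta_roi`.
#' @export
extract_regional_suvr <- function(vol, atlas) {
  check_aligned(vol, atlas)
  labs <- atlas_labels(atlas)
  med <- vapply(labs, function(l) {
    v <- vol$values[atlas$labels == l]
    if (length(v) == 0L) stop("ROI with label ", l, " is empty")
    stats::median(v)
  }, numeric(1))
  names(med) <- paste0("roi_", labs)
  c(med, meta_roi = mean(med[paste0("roi_", atlas$meta_members)]))
}

#' Regional SUVR table for a set of volumes
#'
#' @param volumes named list of `tau_volume`s (names become row names).
#' @param atlas an `roi_atlas`.
#' @return data.frame, one row per scan, columns `roi_<label>` and
#'   `meta_roi`.
#' @export
regional_suvr_table <- function(volumes, atlas) {
  rows <- lapply(volumes, extract_regional_suvr, atlas = atlas)
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(names(volumes))) rownames(out) <- names(volumes)
  out
}

#' Mean absolute percentage error
#'
#' `100 * mean(|pred - truth| / truth)`; truth must be strictly positive.
#'
#' @param pred,truth equal-length numeric vectors.
#' @return MAPE in percent.
#' @export
mape <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1L)
    stop("`pred` and `truth` must be equal-length, non-empty vectors")
  if (any(truth <= 0))
    stop("MAPE undefined: `truth` has non-positive entries")
  100 * mean(abs(pred - truth) / truth)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3, nonzero variance).
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("`x` and `y` must be equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Voxel-wise RMSE map across scan pairs
#'
#' @param preds,truths equal-length lists of aligned `tau_volume`s.
#' @return a `tau_volume` whose voxel v holds
#'   `sqrt(mean_scans((pred_v - truth_v)^2))`.
#' @export
rmse_map <- function(preds, truths) {
  if (length(preds) != length(truths) || length(preds) < 1L)
    stop("need >= 1 prediction/truth pair with equal counts")
  acc <- array(0, dim = preds[[1]]$shape)
  for (i in seq_along(preds)) {
    check_aligned(preds[[i]], truths[[i]])
    check_aligned(preds[[i]], preds[[1]])
    acc <- acc + (preds[[i]]$values - truths[[i]]$values)^2
  }
  volume(sqrt(acc / length(preds)), voxel_size = preds[[1]]$voxel_size,
         space = preds[[1]]$space)
}

# Separable 3D Gaussian filtering with zero padding, plus the matching
# window-mass map so that local means are properly normalized at borders.
gauss_kernel_1d <- function(sigma, radius) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

filter_axis <- function(arr, k, axis) {
  r <- (length(k) - 1L) / 2L
  d <- dim(arr)
  out <- array(0, dim = d)
  for (t in seq_along(k)) {
    off <- t - 1L - r
    src_lo <- max(1L, 1L + off); src_hi <- min(d[axis], d[axis] + off)
    if (src_lo > src_hi) next
    dst_lo <- src_lo - off; dst_hi <- src_hi - off
    if (axis == 1L) out[dst_lo:dst_hi, , ] <- out[dst_lo:dst_hi, , ] +
        k[t] * arr[src_lo:src_hi, , ]
    else if (axis == 2L) out[, dst_lo:dst_hi, ] <- out[, dst_lo:dst_hi, ] +
        k[t] * arr[, src_lo:src_hi, ]
    else out[, , dst_lo:dst_hi] <- out[, , dst_lo:dst_hi] +
        k[t] * arr[, , src_lo:src_hi]
  }
  out
}

gauss_filter3 <- function(arr, k) {
  filter_axis(filter_axis(filter_axis(arr, k, 1L), k, 2L), k, 3L)
}

ssim_components <- function(a, b, sigma, radius, C1, C2) {
  k <- gauss_kernel_1d(sigma, radius)
  ones <- array(1, dim = dim(a))
  wmass <- gauss_filter3(ones, k)          # local window mass (border-corrected)
  mu_a <- gauss_filter3(a, k) / wmass
  mu_b <- gauss_filter3(b, k) / wmass
  var_a <- gauss_filter3(a * a, k) / wmass - mu_a^2
  var_b <- gauss_filter3(b * b, k) / wmass - mu_b^2
  cov_ab <- gauss_filter3(a * b, k) / wmass - mu_a * mu_b
  lum <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cs <- (2 * cov_ab + C2) / (var_a + var_b + C2)
  list(lum = lum, cs = cs)
}

downsample2 <- function(arr) {
  d <- dim(arr) %/% 2L * 2L
  a <- arr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  (a[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
   a[seq(2, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
   a[seq(1, d[1], 2), seq(2, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
   a[seq(2, d[1], 2), seq(2, d[2], 2), seq(1, d[3], 2), drop = FALSE] +
   a[seq(1, d[1], 2), seq(1, d[2], 2), seq(2, d[3], 2), drop = FALSE] +
   a[seq(2, d[1], 2), seq(1, d[2], 2), seq(2, d[3], 2), drop = FALSE] +
   a[seq(1, d[1], 2), seq(2, d[2], 2), seq(2, d[3], 2), drop = FALSE] +
   a[seq(2, d[1], 2), seq(2, d[2], 2), seq(2, d[3], 2), drop = FALSE]) / 8
}

#' Multi-scale structural similarity (MS-SSIM) of two volumes
#'
#' Standard MS-SSIM with a 3D Gaussian window: contrast-structure terms are
#' collected at each dyadic scale (2x average-pool downsampling between
#' scales) and the luminance term at the coarsest scale; the per-scale
#' exponents are the usual five-scale weights renormalized over the scales
#' actually used. With `scales = 1` this is plain single-scale SSIM.
#' Symmetric in its arguments; 1 for identical volumes; in [0, 1] for
#' non-negative inputs.
#'
#' @param a,b aligned `tau_volume`s.
#' @param scales number of dyadic scales (default 3 for desk-scale grids).
#' @param sigma Gaussian window SD in voxels (default 1.5).
#' @param radius window radius in voxels (default 5, an 11-voxel window).
#' @param data_range dynamic range L for the stabilizing constants
#'   C1 = (0.01 L)^2, C2 = (0.03 L)^2; default `max(a, b)`.
#' @return MS-SSIM value.
#' @export
ms_ssim <- function(a, b, scales = 3L, sigma = 1.5, radius = 5L,
                    data_range = NULL) {
  stopifnot(inherits(a, "tau_volume"), inherits(b, "tau_volume"))
  check_aligned(a, b)
  min_side <- min(a$shape)
  need <- 2^(scales - 1) * (2 * radius + 1)
  if (min_side < need) {
    max_s <- max(1L, floor(log2(min_side / (2 * radius + 1))) + 1L)
    stop(sprintf(
      "volume side %d too small for %d scales with window %d; at most %d scale(s) fit",
      min_side, scales, 2 * radius + 1, max_s))
  }
  if (is.null(data_range)) data_range <- max(a$values, b$values)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  w5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  w <- w5[seq_len(scales)] / sum(w5[seq_len(scales)])
  va <- a$values; vb <- b$values
  out <- 1
  for (s in seq_len(scales)) {
    comp <- ssim_components(va, vb, sigma, radius, C1, C2)
    term <- if (s < scales) mean(comp$cs) else mean(comp$lum * comp$cs)
    # fractional exponents require non-negative scale means; plain SSIM
    # (scales = 1, unit exponent) is passed through untouched
    if (scales > 1L) term <- max(term, 0)
    out <- out * term^w[s]
    if (s < scales) {
      va <- downsample2(va); vb <- downsample2(vb)
    }
  }
  out
}

#' Tau-positivity labels from a regional SUVR table
#'
#' A scan is tau positive when its meta-ROI SUVR strictly exceeds the
#' cutoff (values exactly at the cutoff are negative).
#'
#' @param table data.frame with a `meta_roi` column
#'   (see [regional_suvr_table()]).
#' @param cutoff positivity threshold; the four standard choices are in
#'   [TAU_CUTOFFS].
#' @return logical vector of positivity labels.
#' @export
positivity_labels <- function(table, cutoff = TAU_CUTOFFS[1]) {
  if (is.null(table$meta_roi)) stop("table has no `meta_roi` column")
  if (nrow(table) == 0L) stop("table is empty")
  table$meta_roi > cutoff
}

#' ROC curve and AUROC
#'
#' Sweeps every distinct score as a threshold (predicting positive when
#' score > threshold) and integrates the curve by the trapezoidal rule,
#' which equals the Mann-Whitney pair-ordering probability with ties
#' counted 1/2.
#'
#' @param scores numeric predictor values.
#' @param labels logical (or 0/1) class labels; both classes must occur.
#' @param predictor name recorded in the result.
#' @param positivity_cutoff optional meta-ROI cutoff the labels came from.
#' @return An object of class `roc_result`: `predictor`, `thresholds`,
#'   `fpr`, `tpr`, `auroc`, `positivity_cutoff`.
#' @export
roc_auc <- function(scores, labels, predictor = "score",
                    positivity_cutoff = NULL) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores > t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !labels) / n0, numeric(1))
  # append the (1,1) endpoint reached at threshold below min(scores)
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(predictor = predictor, thresholds = c(thr, -Inf),
                 fpr = fpr, tpr = tpr, auroc = auroc,
                 positivity_cutoff = positivity_cutoff),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> predictor '%s': AUROC = %.4f%s\n", x$predictor,
              x$auroc,
              if (!is.null(x$positivity_cutoff))
                sprintf(" (positivity cutoff %.2f)", x$positivity_cutoff) else ""))
  invisible(x)
}

#' ROC for a diagnostic-group contrast
#'
#' ROC of a regional SUVR column (default the meta-ROI) for one named
#' two-group contrast, e.g. CU versus AD-spectrum. `"CU"` matches both
#' CU- and CU+.
#'
#' @param table regional SUVR table (rows = scans).
#' @param groups character vector of group labels, one per row.
#' @param contrast length-2 character: (negative group, positive group).
#' @param column score column, default `"meta_roi"`.
#' @param flip_sign negate the score first (for predictors, such as
#'   glucose metabolism, where lower values indicate disease).
#' @return a `roc_result`.
#' @export
group_classification <- function(table, groups,
                                 contrast = c("CU", "AD-spec"),
                                 column = "meta_roi", flip_sign = FALSE) {
  if (length(groups) != nrow(table)) stop("one group label per table row required")
  match_group <- function(g) {
    if (g == "CU") groups %in% c("CU-", "CU+") else groups == g
  }
  known <- c("CU", "CU-", "CU+", "MCI", "AD-spec", "FTD-spec", "DLB-spec")
  if (!all(contrast %in% known))
    stop("unknown group name in contrast: ",
         paste(setdiff(contrast, known), collapse = ", "))
  neg <- match_group(contrast[1]); pos <- match_group(contrast[2])
  if (!any(neg) || !any(pos))
    stop("contrast group absent from data: ",
         paste(contrast[c(!any(neg), !any(pos))], collapse = ", "))
  sel <- neg | pos
  sc <- table[[column]][sel]
  if (flip_sign) sc <- -sc
  roc_auc(sc, pos[sel],
          predictor = sprintf("%s: %s vs %s", column, contrast[1], contrast[2]))
}

#' Similarity report between imputed and ground-truth volumes
#'
#' The evaluation layout used throughout: per-ROI Pearson r and MAPE of the
#' regional SUVR across scans (including the meta-ROI), per-scan MS-SSIM,
#' and the voxel-wise RMSE map.
#'
#' @param preds,truths equal-length named lists of aligned `tau_volume`s.
#' @param atlas an `roi_atlas`.
#' @param ms_ssim_scales scales for [ms_ssim()].
#' @return list of class `metric_report`: `regional` (data.frame with
#'   columns roi, pearson_r, mape), `ms_ssim` (per-scan vector),
#'   `rmse_map` (a `tau_volume`), and the two regional SUVR tables.
#' @export
metric_report <- function(preds, truths, atlas, ms_ssim_scales = 3L) {
  stopifnot(length(preds) == length(truths), length(preds) >= 3L)
  tp <- regional_suvr_table(preds, atlas)
  tt <- regional_suvr_table(truths, atlas)
  regional <- data.frame(
    roi = colnames(tt),
    pearson_r = vapply(colnames(tt), function(cn)
      pearson_r(tp[[cn]], tt[[cn]]), numeric(1)),
    mape = vapply(colnames(tt), function(cn)
      mape(tp[[cn]], tt[[cn]]), numeric(1)),
    row.names = NULL)
  mss <- mapply(function(a, b) ms_ssim(a, b, scales = ms_ssim_scales),
                preds, truths)
  structure(list(regional = regional, ms_ssim = mss,
                 rmse_map = rmse_map(preds, truths),
                 pred_table = tp, truth_table = tt),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  m <- x$regional[x$regional$roi == "meta_roi", ]
  cat(sprintf("<metric_report> %d ROIs; meta-ROI r = %.3f, MAPE = %.2f%%; mean MS-SSIM = %.3f\n",
              nrow(x$regional) - 1L, m$pearson_r, m$mape, mean(x$ms_ssim)))
  invisible(x)
}
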