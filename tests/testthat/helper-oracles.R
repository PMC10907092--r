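# Independent brute-force oracles used to validate the metric
# implementations, plus small fixture builders. The oracles deliberately
# use naive loop/pair-counting formulations so they share no code path with
# the package.

brute_mape <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(pred[i] - truth[i]) / truth[i]
  100 * s / length(pred)
}

brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Mann-Whitney pair counting with ties worth 1/2.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

brute_rmse_map <- function(preds, truths) {
  d <- dim(preds[[1]])
  out <- array(0, d)
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    s <- 0
    for (k in seq_along(preds))
      s <- s + (preds[[k]][ix, iy, iz] - truths[[k]][ix, iy, iz])^2
    out[ix, iy, iz] <- sqrt(s / length(preds))
  }
  out
}

# Direct (non-separable) single-scale SSIM: explicit weighted sums over the
# full 3D window with border clipping and window-mass renormalization.
brute_ssim <- function(a, b, sigma, radius, data_range) {
  d <- dim(a)
  k1 <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  z <- array(0, d)
  wsum <- z; sa <- z; sb <- z; saa <- z; sbb <- z; sab <- z
  for (dz in -radius:radius) for (dy in -radius:radius) for (dx in -radius:radius) {
    w <- k1[dx + radius + 1] * k1[dy + radius + 1] * k1[dz + radius + 1]
    xd <- max(1, 1 - dx):min(d[1], d[1] - dx)
    yd <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zd <- max(1, 1 - dz):min(d[3], d[3] - dz)
    xs <- xd + dx; ys <- yd + dy; zs <- zd + dz
    wsum[xd, yd, zd] <- wsum[xd, yd, zd] + w
    sa[xd, yd, zd] <- sa[xd, yd, zd] + w * a[xs, ys, zs]
    sb[xd, yd, zd] <- sb[xd, yd, zd] + w * b[xs, ys, zs]
    saa[xd, yd, zd] <- saa[xd, yd, zd] + w * a[xs, ys, zs]^2
    sbb[xd, yd, zd] <- sbb[xd, yd, zd] + w * b[xs, ys, zs]^2
    sab[xd, yd, zd] <- sab[xd, yd, zd] + w * a[xs, ys, zs] * b[xs, ys, zs]
  }
  mu_a <- sa / wsum; mu_b <- sb / wsum
  var_a <- saa / wsum - mu_a^2
  var_b <- sbb / wsum - mu_b^2
  cov_ab <- sab / wsum - mu_a * mu_b
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  lum <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cs <- (2 * cov_ab + C2) / (var_a + var_b + C2)
  mean(lum * cs)
}

rand_volume <- function(shape, lo = 0.5, hi = 2) {
  volume(array(stats::runif(prod(shape), lo, hi), dim = shape))
}

# Small shared phantom for cheap integration tests.
tiny_phantom <- function(n_subjects = 6, scans_per_subject = 2, noise_sd = 0.06,
                         seed = 42, ...) {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), n_rois = 8,
                        n_subjects = n_subjects,
                        scans_per_subject = scans_per_subject,
                        coupling = diag(8), noise_sd = noise_sd,
                        seed = seed, ...)
  atlas <- make_atlas(cfg)
  list(cfg = cfg, atlas = atlas, cohort = generate_cohort(cfg, atlas))
}
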