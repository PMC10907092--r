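test_that("regional SUVR is the per-ROI median with a mean-of-medians meta-ROI", {
  ph <- tiny_phantom(n_subjects = 1, scans_per_subject = 1)
  at <- ph$atlas
  cv <- volume(array(1.3, dim = c(16, 16, 16)))
  row <- extract_regional_suvr(cv, at)
  expect_true(all(abs(row - 1.3) < 1e-12))
  # medians per ROI: member l gets constant l/10; meta = mean of members
  v <- volume(array(0.5, dim = c(16, 16, 16)))
  members <- at$meta_members
  vals <- c(1.0, 1.2, 1.4, 1.6, 1.8, 2.0)
  for (i in seq_along(members)) v$values[at$labels == members[i]] <- vals[i]
  expect_equal(unname(extract_regional_suvr(v, at)["meta_roi"]), 1.5)
  # median of {1, 2, 9} is 2: plant three voxels in one ROI, rest removed
  idx <- which(at$labels == 1)
  v2 <- volume(array(1, dim = c(16, 16, 16)))
  labs2 <- at$labels; labs2[labs2 == 1L] <- 0L; labs2[idx[1:3]] <- 1L
  at2 <- roi_atlas(labs2, at$names, at$meta_members, at$reference_label)
  v2$values[idx[1:3]] <- c(1, 2, 9)
  expect_equal(unname(extract_regional_suvr(v2, at2)["roi_1"]), 2)
})

test_that("MAPE matches its definition and rejects non-positive truth", {
  expect_equal(mape(c(1, 2), c(1, 2)), 0)
  expect_equal(mape(c(1.1, 1.8), c(1, 2)), 10)
  expect_error(mape(c(1, 1), c(1, 0)), "non-positive")
  expect_error(mape(1:3, 1:2), "equal-length")
  set.seed(11)
  for (i in 1:20) {
    truth <- runif(50, 0.5, 3); pred <- truth + rnorm(50, 0, 0.2)
    expect_equal(mape(pred, truth), brute_mape(pred, truth), tolerance = 1e-12)
  }
})

test_that("Pearson r matches the covariance formula and handles edge cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_r(x, y), brute_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("RMSE maps reduce correctly for identical, single and paired scans", {
  set.seed(13)
  a <- rand_volume(c(6, 6, 6)); b <- rand_volume(c(6, 6, 6))
  expect_identical(rmse_map(list(a), list(a))$values, array(0, dim = c(6, 6, 6)))
  expect_equal(rmse_map(list(a), list(b))$values, abs(a$values - b$values),
               tolerance = 1e-14)
  c1 <- rand_volume(c(6, 6, 6)); c2 <- rand_volume(c(6, 6, 6))
  got <- rmse_map(list(a, c1), list(b, c2))$values
  expect_equal(got, brute_rmse_map(list(a$values, c1$values),
                                   list(b$values, c2$values)),
               tolerance = 1e-12)
})

test_that("MS-SSIM is 1 on identical volumes, symmetric, and bounded", {
  set.seed(14)
  a <- rand_volume(c(16, 16, 16)); b <- rand_volume(c(16, 16, 16))
  expect_equal(ms_ssim(a, a, scales = 2, radius = 3), 1, tolerance = 1e-9)
  s_ab <- ms_ssim(a, b, scales = 2, radius = 3)
  expect_equal(s_ab, ms_ssim(b, a, scales = 2, radius = 3), tolerance = 1e-12)
  expect_gte(s_ab, 0); expect_lte(s_ab, 1)
  expect_error(ms_ssim(a, b, scales = 4, radius = 5), "at most")
})

test_that("single-scale MS-SSIM equals an independent direct SSIM", {
  set.seed(15)
  for (i in 1:5) {
    a <- rand_volume(c(8, 8, 8)); b <- rand_volume(c(8, 8, 8))
    got <- ms_ssim(a, b, scales = 1, sigma = 1.5, radius = 2, data_range = 2)
    want <- brute_ssim(a$values, b$values, sigma = 1.5, radius = 2, data_range = 2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("tau positivity uses a strict threshold on the meta-ROI", {
  tab <- data.frame(meta_roi = c(1.25, 1.33, 1.50))
  expect_identical(positivity_labels(tab, 1.11), c(TRUE, TRUE, TRUE))
  expect_identical(positivity_labels(tab, 1.21), c(TRUE, TRUE, TRUE))
  expect_identical(positivity_labels(tab, 1.33), c(FALSE, FALSE, TRUE))
  expect_identical(positivity_labels(tab, 1.46), c(FALSE, FALSE, TRUE))
  expect_identical(TAU_CUTOFFS, c(1.11, 1.21, 1.33, 1.46))
  expect_error(positivity_labels(data.frame(meta_roi = numeric(0))), "empty")
  expect_error(positivity_labels(data.frame(x = 1)), "meta_roi")
})

test_that("AUROC matches pair counting, handles ties, and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))$auroc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(FALSE, TRUE), 5))$auroc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  set.seed(16)
  for (i in 1:20) {
    sc <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # forces ties
    lb <- runif(20) + 0.3 * sc > 0.65
    if (!any(lb) || all(lb)) next
    r <- roc_auc(sc, lb)
    expect_equal(r$auroc, brute_auroc(sc, lb), tolerance = 1e-12)
    expect_equal(roc_auc(exp(3 * sc), lb)$auroc, r$auroc, tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(17)
    sc <- rnorm(40); lb <- runif(40) > 0.5
    expect_equal(roc_auc(sc, lb)$auroc,
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("group contrasts separate when the meta-ROI shifts and not under the null", {
  set.seed(18)
  n <- 200
  meta_cu <- rnorm(n, 1.1, 0.08)
  meta_ad <- rnorm(n, 1.1 + 5 * 0.08, 0.08)  # 5 sigma shift
  tab <- data.frame(meta_roi = c(meta_cu, meta_ad))
  groups <- rep(c("CU-", "AD-spec"), each = n)
  r <- group_classification(tab, groups, contrast = c("CU", "AD-spec"))
  expect_gt(r$auroc, 0.99)
  # closed form for two equal-variance Gaussians: AUROC = Phi(d'/sqrt(2))
  expect_equal(r$auroc, pnorm(5 / sqrt(2)), tolerance = 0.01)
  perm <- group_classification(tab, sample(groups), contrast = c("CU", "AD-spec"))
  expect_gt(perm$auroc, 0.4); expect_lt(perm$auroc, 0.6)
  expect_error(group_classification(tab, groups, contrast = c("CU", "XX")),
               "unknown group")
  expect_error(group_classification(tab, groups, contrast = c("CU", "MCI")),
               "absent")
  flipped <- group_classification(tab, groups, contrast = c("CU", "AD-spec"),
                                  flip_sign = TRUE)
  expect_equal(flipped$auroc, 1 - r$auroc, tolerance = 1e-12)
})

test_that("the metric report ties the pieces together on a phantom", {
  ph <- tiny_phantom(n_subjects = 4, scans_per_subject = 1, noise_sd = 0.02)
  vols <- lapply(ph$cohort$scans, function(sc) sc$target)
  noisy <- lapply(vols, function(v)
    volume(v$values * 1.02, voxel_size = v$voxel_size, space = v$space))
  rep <- metric_report(noisy, vols, ph$atlas, ms_ssim_scales = 1)
  expect_true(all(rep$regional$mape >= 0))
  expect_true(all(abs(rep$regional$pearson_r) <= 1))
  meta <- rep$regional[rep$regional$roi == "meta_roi", ]
  expect_lt(meta$mape, 3)  # a 2% global scale error cannot exceed ~2% meta MAPE
  # meta-ROI exactness: recomputation from member medians is bit-identical
  members <- paste0("roi_", ph$atlas$meta_members)
  expect_identical(rep$pred_table$meta_roi,
                   unname(rowMeans(rep$pred_table[, members])))
})
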