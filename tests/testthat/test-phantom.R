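test_that("atlas construction yields non-empty, non-adjacent blocks and is deterministic", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32), n_rois = 8,
                        coupling = diag(8), seed = 5)
  at <- make_atlas(cfg)
  expect_identical(atlas_labels(at), 1:8)
  sizes <- table(at$labels[at$labels != 0])
  expect_true(all(sizes >= cfg$min_roi_voxels))
  expect_true(any(at$labels == 0))          # background exists
  expect_length(at$meta_members, 6)
  expect_false(at$reference_label %in% at$meta_members)
  # blocks never touch: dilating each ROI by one voxel meets no other ROI
  for (l in 1:8) {
    idx <- which(at$labels == l, arr.ind = TRUE)
    box_lo <- pmax(apply(idx, 2, min) - 1, 1)
    box_hi <- pmin(apply(idx, 2, max) + 1, dim(at$labels))
    nb <- at$labels[box_lo[1]:box_hi[1], box_lo[2]:box_hi[2], box_lo[3]:box_hi[3]]
    expect_true(all(nb %in% c(0L, l)))
  }
  expect_identical(make_atlas(cfg)$labels, at$labels)
})

test_that("atlas construction fails when the grid cannot host the requested ROIs", {
  expect_error(
    make_atlas(phantom_config(grid_shape = c(16, 16, 16), n_rois = 200,
                              coupling = diag(200), ref_region_id = 200,
                              min_roi_voxels = 64)),
    "too small")  # 200 * 64 > 16^3 voxel capacity
})

test_that("identity coupling with zero noise reproduces source means exactly", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), n_rois = 8,
                        coupling = diag(8), stage_effect = rep(0, 8),
                        noise_sd = 0, n_subjects = 2, seed = 9)
  at <- make_atlas(cfg)
  co <- generate_cohort(cfg, at)
  for (sc in co$scans) {
    u <- vapply(1:8, function(l) mean(sc$source$values[at$labels == l]), numeric(1))
    m <- vapply(1:8, function(l) mean(sc$target$values[at$labels == l]), numeric(1))
    expect_equal(m, u, tolerance = 1e-12)
    expect_equal(m, unname(sc$true_roi_means), tolerance = 1e-12)
  }
})

test_that("coupling recoverability: noiseless target means equal t(W) u + stage term", {
  W <- diag(8); W[7, 3] <- 0.5
  cfg <- phantom_config(grid_shape = c(16, 16, 16), n_rois = 8, coupling = W,
                        noise_sd = 0, n_subjects = 3, seed = 10)
  at <- make_atlas(cfg)
  co <- generate_cohort(cfg, at)
  for (sc in co$scans) {
    u <- vapply(1:8, function(l) mean(sc$source$values[at$labels == l]), numeric(1))
    s <- co$table$stage[co$table$scan_id == sc$scan_id]
    m_expect <- as.vector(t(W) %*% u) + cfg$stage_effect * s
    m_expect[cfg$ref_region_id] <- cfg$ref_target_mean
    m <- vapply(1:8, function(l) mean(sc$target$values[at$labels == l]), numeric(1))
    expect_equal(m, m_expect, tolerance = 1e-12)
  }
})

test_that("identical configuration and seed give a byte-identical cohort", {
  ph1 <- tiny_phantom(seed = 77)
  ph2 <- tiny_phantom(seed = 77)
  expect_identical(ph1$cohort$table, ph2$cohort$table)
  expect_identical(lapply(ph1$cohort$scans, function(s) s$target$values),
                   lapply(ph2$cohort$scans, function(s) s$target$values))
  ph3 <- tiny_phantom(seed = 78)
  expect_false(identical(ph1$cohort$scans[[1]]$target$values,
                         ph3$cohort$scans[[1]]$target$values))
})

test_that("planted off-diagonal coupling is recoverable by regression on ROI means", {
  W <- diag(12); W[10, 2] <- 1
  cfg <- phantom_config(n_rois = 12, n_subjects = 200, scans_per_subject = 1,
                        coupling = W, stage_effect = rep(0, 12), seed = 21)
  at <- make_atlas(cfg)
  co <- generate_cohort(cfg, at)
  U <- t(vapply(co$scans, function(sc)
    vapply(1:12, function(l) mean(sc$source$values[at$labels == l]), numeric(1)),
    numeric(12)))
  m2 <- vapply(co$scans, function(sc)
    mean(sc$target$values[at$labels == 2]), numeric(1))
  fit <- stats::lm(m2 ~ U[, 2] + U[, 10])
  est <- stats::coef(summary(fit))
  expect_lt(abs(est["U[, 10]", "Estimate"] - 1), 3 * est["U[, 10]", "Std. Error"])
  expect_lt(abs(est["U[, 2]", "Estimate"] - 1), 3 * est["U[, 2]", "Std. Error"])
})

test_that("all scans of a subject share stage and group label", {
  ph <- tiny_phantom(n_subjects = 10, scans_per_subject = 3)
  tab <- ph$cohort$table
  per_subj <- split(tab, tab$subject_id)
  for (d in per_subj) {
    expect_length(unique(d$stage), 1)
    expect_length(unique(d$group_label), 1)
    expect_length(unique(d$amyloid_status), 1)
  }
  expect_true(all(tab$group_label %in%
                  c("CU-", "CU+", "MCI", "DLB-spec", "FTD-spec", "AD-spec")))
})

test_that("degenerate configurations are rejected", {
  expect_error(phantom_config(n_rois = 4), ">= 8")
  expect_error(phantom_config(grid_shape = c(8, 32, 32)), ">= 16")
  expect_error(phantom_config(noise_sd = -1), ">= 0")
  expect_error(phantom_config(coupling = diag(5)), "R x R")
  expect_error(phantom_config(ref_target_mean = 0), "positive")
  # non-positive target mean in some ROI -> configuration error
  W <- diag(12); W[1, 1] <- 0  # ROI 1 target mean would be ~0 minus nothing
  cfg <- phantom_config(coupling = W, stage_effect = rep(0, 12),
                        n_subjects = 1, seed = 1)
  at <- make_atlas(cfg)
  expect_error(generate_cohort(cfg, at), "non-positive")
})
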