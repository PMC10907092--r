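test_that("forward pass preserves the grid and accepts bimodal input", {
  spec <- network_spec(depth = 2, base_filters = 2, layers_per_block = 1)
  mod <- build_dense_unet(spec, seed = 1)
  v <- volume(array(0, dim = c(32, 32, 32)), space = "network")
  out <- impute(mod, v)
  expect_identical(out$shape, c(32L, 32L, 32L))
  expect_true(all(is.finite(out$values)))
  spec2 <- network_spec(depth = 2, base_filters = 2, layers_per_block = 1,
                        in_channels = 2)
  mod2 <- build_dense_unet(spec2, seed = 1)
  out2 <- impute(mod2, list(v, v))
  expect_identical(out2$shape, c(32L, 32L, 32L))
  expect_error(impute(mod2, v), "channel")
  bad <- volume(array(0, dim = c(30, 32, 32)), space = "network")
  expect_error(impute(mod, bad), "divisible")
})

test_that("parameter count matches a hand count of the concatenative block graph", {
  # depth 1, base 2, 2 layers/block, k = 3, 1 input channel:
  # encoder block (growth 2):  conv 1->2 and conv 3->2, widths 1,3; out 5 ch
  # bridge (growth 4):         conv 5->4 and conv 9->4; out 13 ch
  # decoder (growth 2):        upconv 13->2; block convs 7->2 and 9->2; out 11 ch
  # head: 1x1x1 conv 11->1
  hand <- (1 * 27 * 2 + 2) + (3 * 27 * 2 + 2) +
          (5 * 27 * 4 + 4) + (9 * 27 * 4 + 4) +
          (13 * 27 * 2 + 2) + (7 * 27 * 2 + 2) + (9 * 27 * 2 + 2) +
          (11 * 1 * 1 + 1)
  spec <- network_spec(depth = 1, base_filters = 2, layers_per_block = 2)
  expect_identical(count_parameters(spec), hand)
  mod <- build_dense_unet(spec, seed = 3)
  realized <- sum(vapply(mod$params, function(p) length(p$W) + length(p$b),
                         numeric(1)))
  expect_identical(realized, hand)
})

test_that("dense blocks widen by one growth unit per layer", {
  spec <- network_spec(depth = 2, base_filters = 4, layers_per_block = 3)
  topo <- tausynth:::dunet_units(spec)
  # encoder level 1: input 1 channel, growth 4, layers see 1, 5, 9 channels
  expect_identical(vapply(1:3, function(j)
    topo$units[[sprintf("enc1_conv%d", j)]]$in_ch, integer(1)), c(1L, 5L, 9L))
  # encoder level 2: growth 8 on the 13-channel level-1 output
  expect_identical(topo$enc_out[1], 13L)
  expect_identical(vapply(1:3, function(j)
    topo$units[[sprintf("enc2_conv%d", j)]]$in_ch, integer(1)), c(13L, 21L, 29L))
})

test_that("an all-zero-weight network outputs exactly zero", {
  spec <- network_spec(depth = 1, base_filters = 2, layers_per_block = 1)
  mod <- build_dense_unet(spec, seed = 1)
  mod$params <- lapply(mod$params, function(p) list(W = p$W * 0, b = p$b * 0))
  v <- rand_volume(c(16, 16, 16))
  v$space <- "network"
  expect_identical(sum(abs(impute(mod, v)$values)), 0)
})

test_that("imputation is bitwise deterministic for fixed weights", {
  spec <- network_spec(depth = 2, base_filters = 3, layers_per_block = 2)
  mod <- build_dense_unet(spec, seed = 7)
  set.seed(8)
  v <- rand_volume(c(16, 16, 16)); v$space <- "network"
  expect_identical(impute(mod, v)$values, impute(mod, v)$values)
  # same seed -> same weights -> same output; different seed differs
  mod_b <- build_dense_unet(spec, seed = 7)
  expect_identical(impute(mod_b, v)$values, impute(mod, v)$values)
  mod_c <- build_dense_unet(spec, seed = 8)
  expect_false(identical(impute(mod_c, v)$values, impute(mod, v)$values))
})

test_that("backpropagated gradients match central finite differences", {
  spec <- network_spec(depth = 1, base_filters = 2, layers_per_block = 2)
  mod <- build_dense_unet(spec, seed = 2)
  set.seed(5)
  dims <- c(8L, 8L, 8L); V <- prod(dims)
  X <- matrix(rnorm(V), V, 1); y <- matrix(rnorm(V), V, 1)
  fwd <- tausynth:::dunet_forward(mod, X, dims, keep_cache = TRUE)
  gr <- tausynth:::dunet_backward(mod, fwd$cache, 2 * (fwd$out - y) / V)
  eps <- 1e-6
  for (nm in names(mod$params)) {
    for (fld in c("W", "b")) {
      pv <- mod$params[[nm]][[fld]]
      for (i in sample(length(pv), min(3, length(pv)))) {
        m2 <- mod
        m2$params[[nm]][[fld]][i] <- pv[i] + eps
        lp <- mean((tausynth:::dunet_forward(m2, X, dims)$out - y)^2)
        m2$params[[nm]][[fld]][i] <- pv[i] - eps
        lm <- mean((tausynth:::dunet_forward(m2, X, dims)$out - y)^2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(gr[[nm]][[fld]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("pooling and upsampling primitives are exact adjoints in shape and value", {
  set.seed(6)
  dims <- c(8L, 8L, 8L)
  X <- matrix(rnorm(prod(dims) * 3), prod(dims), 3)
  mp <- tausynth:::maxpool3d_fw(X, dims)
  expect_identical(dim(mp$Y), c(64L, 3L))
  expect_true(all(mp$Y %in% X))
  up <- tausynth:::upsample3d_fw(mp$Y, dims %/% 2L)
  expect_identical(nrow(up), as.integer(prod(dims)))
  # adjoint identity: <up(x), y> == <x, up^T(y)>
  Yr <- matrix(rnorm(prod(dims) * 3), prod(dims), 3)
  lhs <- sum(up * Yr)
  rhs <- sum(mp$Y * tausynth:::upsample3d_bw(Yr, dims %/% 2L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("model checkpoints round trip with an architecture sidecar", {
  spec <- network_spec(depth = 1, base_filters = 2, layers_per_block = 1)
  mod <- build_dense_unet(spec, seed = 4)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(mod, p)
  back <- load_model(p)
  expect_identical(back$params, mod$params)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_identical(as.integer(side$depth), spec$depth)
})
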