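# 3D Dense-U-Net: an encoder-decoder with dense (concatenative) intra-block
# connectivity. Within a block, each convolution's output (after ReLU) is
# concatenated to the block input before being fed to the next layer, so
# layer j sees c_in + (j-1)*growth channels. The encoder path doubles the
# filter count at each level, the decoder halves it; encoder level l is
# skip-connected to decoder level l. Downsampling is 2x max-pooling,
# upsampling is nearest-neighbour followed by a convolution. The output head
# is a linear 1x1x1 convolution (SUVR regression).
#
# Feature maps are (voxels x channels) matrices; the voxel axis is the
# flattened grid, x fastest, so each channel is a contiguous column.
# Forward/backward primitives live in compiled code (src/dense_ops.cpp).

#' Dense-U-Net architecture specification
#'
#' @param depth number of encoder (= decoder) levels; input side lengths
#'   must be divisible by `2^depth`.
#' @param base_filters growth (filters per dense-block layer) at the first
#'   level; level l uses `base_filters * 2^(l-1)`, the bridge
#'   `base_filters * 2^depth`.
#' @param layers_per_block convolutions per dense block.
#' @param kernel_size odd isotropic kernel size.
#' @param in_channels 1 for unimodal input, 2 for channel-stacked bimodal.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(depth = 4L, base_filters = 16L, layers_per_block = 2L,
                         kernel_size = 3L, in_channels = 1L) {
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  layers_per_block <- as.integer(layers_per_block)
  kernel_size <- as.integer(kernel_size); in_channels <- as.integer(in_channels)
  if (depth < 1L || base_filters < 1L || layers_per_block < 1L || in_channels < 1L)
    stop("depth, base_filters, layers_per_block, in_channels must be positive")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("`kernel_size` must be odd")
  structure(list(depth = depth, base_filters = base_filters,
                 layers_per_block = layers_per_block,
                 kernel_size = kernel_size, in_channels = in_channels),
            class = "network_spec")
}

# Enumerate every convolutional unit (name, in/out channels, kernel) of the
# architecture together with per-level channel bookkeeping.
dunet_units <- function(spec) {
  d <- spec$depth; L <- spec$layers_per_block; k <- spec$kernel_size
  growth <- as.integer(spec$base_filters * 2^(seq_len(d) - 1L))
  g_bridge <- as.integer(spec$base_filters * 2^d)
  units <- list()
  enc_out <- integer(d)
  c_in <- spec$in_channels
  for (l in seq_len(d)) {
    g <- growth[l]
    for (j in seq_len(L))
      units[[sprintf("enc%d_conv%d", l, j)]] <-
        list(in_ch = c_in + (j - 1L) * g, out_ch = g, k = k)
    enc_out[l] <- c_in + L * g
    c_in <- enc_out[l]
  }
  for (j in seq_len(L))
    units[[sprintf("bridge_conv%d", j)]] <-
      list(in_ch = c_in + (j - 1L) * g_bridge, out_ch = g_bridge, k = k)
  prev <- c_in + L * g_bridge
  dec_out <- integer(d)
  for (l in rev(seq_len(d))) {
    g <- growth[l]
    units[[sprintf("dec%d_upconv", l)]] <- list(in_ch = prev, out_ch = g, k = k)
    cat_in <- g + enc_out[l]
    for (j in seq_len(L))
      units[[sprintf("dec%d_conv%d", l, j)]] <-
        list(in_ch = cat_in + (j - 1L) * g, out_ch = g, k = k)
    dec_out[l] <- cat_in + L * g
    prev <- dec_out[l]
  }
  units[["head"]] <- list(in_ch = prev, out_ch = 1L, k = 1L)
  list(units = units, growth = growth, enc_out = enc_out, dec_out = dec_out)
}

#' Parameter count of a Dense-U-Net specification
#'
#' A pure function of the specification: the sum over all convolutional
#' units of `in_ch * k^3 * out_ch` weights plus `out_ch` biases.
#'
#' @param spec a `network_spec`.
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sum(vapply(dunet_units(spec)$units, function(u)
    u$in_ch * u$k^3 * u$out_ch + u$out_ch, numeric(1)))
}

#' Build a Dense-U-Net model
#'
#' Weights are initialized He-uniform (U(-sqrt(6/fan_in), sqrt(6/fan_in)),
#' fan_in = in_ch * k^3), biases at zero, under the given seed.
#'
#' @param spec a `network_spec`.
#' @param seed integer seed for the initialization.
#' @return An object of class `dense_unet` with fields `spec`, `params`
#'   (named list of `W`/`b` pairs) and `parameter_count`.
#' @export
build_dense_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  topo <- dunet_units(spec)
  params <- with_seed(seed, {
    lapply(topo$units, function(u) {
      fan_in <- u$in_ch * u$k^3
      lim <- sqrt(6 / fan_in)
      list(W = matrix(stats::runif(u$out_ch * fan_in, -lim, lim),
                      nrow = u$out_ch, ncol = fan_in),
           b = numeric(u$out_ch))
    })
  })
  structure(list(spec = spec, params = params,
                 parameter_count = count_parameters(spec)),
            class = "dense_unet")
}

#' @export
print.dense_unet <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<dense_unet> depth %d, base filters %d, %d layers/block, ",
                     "kernel %d, %d input channel(s), %s parameters\n"),
              s$depth, s$base_filters, s$layers_per_block, s$kernel_size,
              s$in_channels, format(x$parameter_count, big.mark = ",")))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

# Dense block forward: returns the full concatenation [input; Y1; ...; YL].
dense_block_fw <- function(X, dims, params, prefix, L, k) {
  full <- X
  for (j in seq_len(L)) {
    p <- params[[sprintf("%s_conv%d", prefix, j)]]
    full <- cbind(full, relu(conv3d_fw(full, dims, p$W, p$b, k)))
  }
  full
}

# Dense block backward: dFull is the gradient wrt the full concatenation;
# returns gradient wrt the block input plus per-unit weight gradients.
dense_block_bw <- function(full, dims, params, prefix, L, k, c_in, g, dFull, grads) {
  for (j in rev(seq_len(L))) {
    cols <- (c_in + (j - 1L) * g) + seq_len(g)
    dPre <- dFull[, cols, drop = FALSE] * (full[, cols, drop = FALSE] > 0)
    in_cols <- seq_len(c_in + (j - 1L) * g)
    p <- params[[sprintf("%s_conv%d", prefix, j)]]
    bw <- conv3d_bw(full[, in_cols, drop = FALSE], dims, p$W, dPre, k)
    grads[[sprintf("%s_conv%d", prefix, j)]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dFull[, in_cols] <- dFull[, in_cols, drop = FALSE] + bw$dX
  }
  list(dX = dFull[, seq_len(c_in), drop = FALSE], grads = grads)
}

# Full forward pass. X is (V x in_channels); dims the 3D grid. Returns the
# (V x 1) output and, optionally, every intermediate needed for backward.
dunet_forward <- function(model, X, dims, keep_cache = FALSE) {
  spec <- model$spec; p <- model$params
  d <- spec$depth; L <- spec$layers_per_block; k <- spec$kernel_size
  if (ncol(X) != spec$in_channels)
    stop(sprintf("input has %d channel(s); network expects %d",
                 ncol(X), spec$in_channels))
  if (any(dims %% 2L^d != 0L))
    stop(sprintf("input sides %s must be divisible by 2^depth = %d",
                 paste(dims, collapse = "x"), 2L^d))
  cache <- list(enc = vector("list", d), pool = vector("list", d),
                up = vector("list", d), dec = vector("list", d),
                dims = vector("list", d))
  cur <- X; curd <- as.integer(dims)
  for (l in seq_len(d)) {
    full <- dense_block_fw(cur, curd, p, sprintf("enc%d", l), L, k)
    mp <- maxpool3d_fw(full, curd)
    cache$enc[[l]] <- full; cache$dims[[l]] <- curd
    cache$pool[[l]] <- mp$idx
    cur <- mp$Y; curd <- curd %/% 2L
  }
  bridge_full <- dense_block_fw(cur, curd, p, "bridge", L, k)
  cache$bridge <- bridge_full; cache$bridge_dims <- curd
  cur <- bridge_full
  for (l in rev(seq_len(d))) {
    up <- upsample3d_fw(cur, curd)
    curd <- curd * 2L
    pu <- p[[sprintf("dec%d_upconv", l)]]
    pre <- conv3d_fw(up, curd, pu$W, pu$b, k)
    upa <- relu(pre)
    cat_in <- cbind(upa, cache$enc[[l]])
    full <- dense_block_fw(cat_in, curd, p, sprintf("dec%d", l), L, k)
    cache$up[[l]] <- list(input = up, act = upa)
    cache$dec[[l]] <- full
    cur <- full
  }
  ph <- p[["head"]]
  out <- conv3d_fw(cur, curd, ph$W, ph$b, 1L)
  cache$head_input <- cur
  if (keep_cache) list(out = out, cache = cache) else list(out = out)
}

# Full backward pass: dOut is the (V x 1) gradient of the loss wrt the
# network output. Returns a named list of parameter gradients.
dunet_backward <- function(model, cache, dOut) {
  spec <- model$spec; p <- model$params
  d <- spec$depth; L <- spec$layers_per_block; k <- spec$kernel_size
  topo <- dunet_units(spec)
  g_lv <- topo$growth; enc_out <- topo$enc_out
  grads <- list()
  full_dims <- cache$dims[[1]]
  bw <- conv3d_bw(cache$head_input, full_dims, p$head$W, dOut, 1L)
  grads$head <- list(W = bw$dW, b = as.numeric(bw$db))
  dCur <- bw$dX
  dskip <- vector("list", d)
  # decoder levels, shallow to deep
  for (l in seq_len(d)) {
    dims_l <- cache$dims[[l]]
    g <- g_lv[l]
    c_in <- g + enc_out[l]
    res <- dense_block_bw(cache$dec[[l]], dims_l, p, sprintf("dec%d", l),
                          L, k, c_in, g, dCur, grads)
    grads <- res$grads
    dcat <- res$dX
    dUpa <- dcat[, seq_len(g), drop = FALSE]
    dskip[[l]] <- dcat[, g + seq_len(enc_out[l]), drop = FALSE]
    dPre <- dUpa * (cache$up[[l]]$act > 0)
    pu <- p[[sprintf("dec%d_upconv", l)]]
    bwu <- conv3d_bw(cache$up[[l]]$input, dims_l, pu$W, dPre, k)
    grads[[sprintf("dec%d_upconv", l)]] <- list(W = bwu$dW, b = as.numeric(bwu$db))
    dCur <- upsample3d_bw(bwu$dX, dims_l %/% 2L)
  }
  # bridge
  bd <- cache$bridge_dims
  c_in_b <- enc_out[d]
  res <- dense_block_bw(cache$bridge, bd, p, "bridge", L, k,
                        c_in_b, spec$base_filters * 2L^d, dCur, grads)
  grads <- res$grads
  dPool <- res$dX
  # encoder levels, deep to shallow
  for (l in rev(seq_len(d))) {
    dims_l <- cache$dims[[l]]
    dE <- maxpool3d_bw(dPool, cache$pool[[l]], prod(dims_l)) + dskip[[l]]
    c_in <- if (l == 1L) spec$in_channels else enc_out[l - 1L]
    res <- dense_block_bw(cache$enc[[l]], dims_l, p, sprintf("enc%d", l),
                          L, k, c_in, g_lv[l], dE, grads)
    grads <- res$grads
    dPool <- res$dX
  }
  grads
}

# Convert a volume (or channel-stacked list of volumes) to the network's
# (voxels x channels) matrix representation.
as_network_input <- function(source) {
  if (inherits(source, "tau_volume")) source <- list(source)
  stopifnot(all(vapply(source, inherits, logical(1), "tau_volume")))
  dims <- source[[1]]$shape
  for (v in source) check_aligned(v, source[[1]])
  X <- do.call(cbind, lapply(source, function(v) as.numeric(v$values)))
  list(X = X, dims = as.integer(dims),
       voxel_size = source[[1]]$voxel_size)
}

#' Impute a tau-like volume from a source volume
#'
#' Runs the model forward on a network-space source volume (or a list of
#' volumes stacked along the channel axis for bimodal input) and returns
#' the imputed volume on the same grid. Deterministic given fixed weights.
#'
#' @param model a trained or untrained model handle.
#' @param source a network-space `tau_volume`, or a list of them (channels).
#' @param ... unused.
#' @return the imputed `tau_volume` (network space).
#' @export
impute <- function(model, source, ...) UseMethod("impute")

#' @rdname impute
#' @export
impute.dense_unet <- function(model, source, ...) {
  inp <- as_network_input(source)
  out <- dunet_forward(model, inp$X, inp$dims)$out
  volume(array(as.numeric(out), dim = inp$dims),
         voxel_size = inp$voxel_size, space = "network")
}

#' A model that copies its input
#'
#' Oracle model for occlusion analysis: its "imputation" is the first input
#' channel unchanged, so occluding ROI R1 can only corrupt the prediction
#' inside R1 itself.
#'
#' @return an object of class `copy_model` usable with [impute()].
#' @export
copy_model <- function() structure(list(), class = "copy_model")

#' @rdname impute
#' @export
impute.copy_model <- function(model, source, ...) {
  if (inherits(source, "tau_volume")) source else source[[1]]
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file with the weights; a JSON sidecar
#' (`<path>.json`) records the architecture specification.
#'
#' @param model a `dense_unet`.
#' @param path checkpoint path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dense_unet"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
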