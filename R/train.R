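# Subject-grouped cross-validation and the optimization protocol: Adam with
# MSE loss, mini-batch 2, learning rate 1e-4 halved on validation plateau
# (patience 7) with at least 10 epochs between decays; a pure
# every-10-epochs schedule is also available.

#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam (beta1 = 0.9,
#' beta2 = 0.999), initial learning rate 1e-4, 150 epochs, mini-batch 2,
#' MSE loss, learning rate halved when the validation error fails to
#' improve for 7 epochs (with a minimum of 10 epochs between decays).
#' `schedule = "fixed"` instead halves unconditionally every
#' `decay_every_epochs` epochs.
#'
#' @param lr0 initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param epochs training epochs.
#' @param batch_size mini-batch size (scans).
#' @param lr_decay_factor factor (> 1) by which the learning rate is divided.
#' @param decay_every_epochs minimum epochs between decays (and the period
#'   of the `"fixed"` schedule).
#' @param plateau_patience_epochs epochs without validation improvement
#'   that trigger a decay under the `"plateau"` schedule.
#' @param schedule `"plateau"` (default) or `"fixed"`.
#' @param seed integer seed controlling shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epochs = 150L, batch_size = 2L,
                         lr_decay_factor = 2, decay_every_epochs = 10L,
                         plateau_patience_epochs = 7L,
                         schedule = c("plateau", "fixed"), seed = 1L) {
  schedule <- match.arg(schedule)
  if (lr0 <= 0 || epochs < 1L || batch_size < 1L) stop("invalid training config")
  if (lr_decay_factor <= 1) stop("`lr_decay_factor` must be > 1")
  structure(list(lr0 = lr0, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_decay_factor = lr_decay_factor,
                 decay_every_epochs = as.integer(decay_every_epochs),
                 plateau_patience_epochs = as.integer(plateau_patience_epochs),
                 schedule = schedule, seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-grouped k-fold split
#'
#' Subjects (never scans) are shuffled under the seed and divided into k
#' near-equal groups. In fold i, group i is the test set, the next group
#' (cyclically) the validation set and the remaining k-2 groups the
#' training set — for k = 5 this is the 60/20/20 layout. Every scan of a
#' subject inherits the subject's partition, so no subject ever appears in
#' more than one partition of a fold, and the test sets of the k folds
#' partition the subjects exactly.
#'
#' @param cohort a `tau_cohort`, a data.frame with a `subject_id` column,
#'   or a character vector of subject ids.
#' @param k number of folds (default 5).
#' @param fractions target train/val/test fractions (informational; the
#'   group layout realizes them up to +-1 subject for k = 5).
#' @param seed integer seed.
#' @return An object of class `fold_split` with `k`, `groups` (list of k
#'   subject-id vectors) and `fractions`.
#' @export
make_folds <- function(cohort, k = 5L, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  subjects <- if (inherits(cohort, "tau_cohort")) unique(cohort$table$subject_id)
    else if (is.data.frame(cohort)) unique(cohort$subject_id)
    else unique(as.character(cohort))
  k <- as.integer(k)
  if (length(subjects) < 2L * k)
    stop(sprintf("need at least %d subjects for %d folds, got %d",
                 2L * k, k, length(subjects)))
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  shuffled <- with_seed(seed, sample(subjects))
  groups <- split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
  names(groups) <- NULL
  structure(list(k = k, groups = groups, fractions = fractions, seed = seed),
            class = "fold_split")
}

#' Partitions of one fold
#'
#' @param split a `fold_split`.
#' @param fold fold index in 1..k.
#' @return list with character vectors `train`, `val`, `test` of subject ids.
#' @export
fold_partitions <- function(split, fold) {
  stopifnot(inherits(split, "fold_split"))
  k <- split$k
  fold <- as.integer(fold)
  if (fold < 1L || fold > k) stop("`fold` must be in 1..", k)
  test <- split$groups[[fold]]
  val <- split$groups[[fold %% k + 1L]]
  train <- unlist(split$groups[-c(fold, fold %% k + 1L)], use.names = FALSE)
  list(train = train, val = val, test = test)
}

#' Scans of a cohort belonging to a set of subjects
#' @param cohort a `tau_cohort`.
#' @param subjects character vector of subject ids.
#' @return the list of scan records.
#' @export
cohort_scans <- function(cohort, subjects) {
  stopifnot(inherits(cohort, "tau_cohort"))
  Filter(function(sc) sc$subject_id %in% subjects, cohort$scans)
}

scan_to_xy <- function(sc) {
  inp <- as_network_input(sc$source)
  list(X = inp$X, y = matrix(as.numeric(sc$target$values), ncol = 1),
       dims = inp$dims)
}

#' Train a Dense-U-Net on one fold
#'
#' Optimizes the per-voxel mean squared error with Adam over the training
#' partition, evaluates the validation partition each epoch, applies the
#' configured learning-rate schedule, and retains the weights of the best
#' validation epoch. Volumes must already be in network space (see
#' [prepare_cohort()]).
#'
#' @param model an untrained `dense_unet`.
#' @param cohort a network-space `tau_cohort`.
#' @param split a `fold_split` over the cohort's subjects.
#' @param fold fold index in 1..k.
#' @param config a `train_config`.
#' @return list of class `dunet_fit`: `model` (best-validation weights),
#'   `history` (data.frame epoch/train_mse/val_mse/lr), `fold`, `config`.
#' @export
fit <- function(model, cohort, split, fold, config = train_config()) {
  stopifnot(inherits(model, "dense_unet"), inherits(cohort, "tau_cohort"),
            inherits(split, "fold_split"), inherits(config, "train_config"))
  parts <- fold_partitions(split, fold)
  train_sc <- cohort_scans(cohort, parts$train)
  val_sc <- cohort_scans(cohort, parts$val)
  if (length(train_sc) == 0L) stop("training partition is empty")
  if (length(val_sc) == 0L) stop("validation partition is empty")
  leak <- intersect(parts$train, c(parts$val, parts$test))
  stopifnot(length(leak) == 0L)  # subject-level leakage guard
  train_xy <- lapply(train_sc, scan_to_xy)
  val_xy <- lapply(val_sc, scan_to_xy)
  V <- prod(train_xy[[1]]$dims)
  p <- model$params
  mstate <- lapply(p, function(u) list(W = u$W * 0, b = u$b * 0))
  vstate <- mstate
  lr <- config$lr0
  step <- 0L
  best_val <- Inf; best_params <- p
  last_decay <- 0L; last_improve <- 0L
  hist <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(train_xy))
      ep_loss <- 0
      n_batches <- 0L
      for (b0 in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        gsum <- NULL
        bloss <- 0
        for (i in idx) {
          xy <- train_xy[[i]]
          fwd <- dunet_forward(model, xy$X, xy$dims, keep_cache = TRUE)
          resid <- fwd$out - xy$y
          bloss <- bloss + mean(resid^2)
          g <- dunet_backward(model, fwd$cache, 2 * resid / (V * length(idx)))
          gsum <- if (is.null(gsum)) g else
            Map(function(a, d) list(W = a$W + d$W, b = a$b + d$b), gsum, g)
        }
        bloss <- bloss / length(idx)
        if (!is.finite(bloss))
          stop(sprintf("non-finite training loss at epoch %d; lower the learning rate",
                       epoch))
        ep_loss <- ep_loss + bloss
        n_batches <- n_batches + 1L
        step <- step + 1L
        bc1 <- 1 - config$beta1^step
        bc2 <- 1 - config$beta2^step
        for (nm in names(p)) {
          g <- gsum[[nm]]
          mstate[[nm]]$W <- config$beta1 * mstate[[nm]]$W + (1 - config$beta1) * g$W
          mstate[[nm]]$b <- config$beta1 * mstate[[nm]]$b + (1 - config$beta1) * g$b
          vstate[[nm]]$W <- config$beta2 * vstate[[nm]]$W + (1 - config$beta2) * g$W^2
          vstate[[nm]]$b <- config$beta2 * vstate[[nm]]$b + (1 - config$beta2) * g$b^2
          p[[nm]]$W <- p[[nm]]$W - lr * (mstate[[nm]]$W / bc1) /
            (sqrt(vstate[[nm]]$W / bc2) + 1e-8)
          p[[nm]]$b <- p[[nm]]$b - lr * (mstate[[nm]]$b / bc1) /
            (sqrt(vstate[[nm]]$b / bc2) + 1e-8)
        }
        model$params <- p
      }
      val_loss <- mean(vapply(val_xy, function(xy)
        mean((dunet_forward(model, xy$X, xy$dims)$out - xy$y)^2), numeric(1)))
      if (!is.finite(val_loss))
        stop(sprintf("non-finite validation loss at epoch %d", epoch))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- p
        last_improve <- epoch
      }
      decay <- if (config$schedule == "fixed") {
        epoch %% config$decay_every_epochs == 0L
      } else {
        (epoch - last_improve >= config$plateau_patience_epochs) &&
          (epoch - last_decay >= config$decay_every_epochs)
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_mse = ep_loss / n_batches,
                                  val_mse = val_loss, lr = lr)
      if (decay) {
        lr <- lr / config$lr_decay_factor
        last_decay <- epoch
      }
    }
  })
  model$params <- best_params
  structure(list(model = model,
                 history = do.call(rbind, hist),
                 fold = fold, config = config),
            class = "dunet_fit")
}

#' @export
print.dunet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<dunet_fit> fold %d, %d epochs; train MSE %.3g -> %.3g, best val MSE %.3g\n",
              x$fold, nrow(h), h$train_mse[1], h$train_mse[nrow(h)], min(h$val_mse)))
  invisible(x)
}
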