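#' SV rescale table
#'
#' Per-channel minimum and maximum used to map network outputs from the
#' normalized \[0, 1\] space back to SV units. `default_rescale_table()`
#' ships the global ranges observed on a 30-subject training cohort of
#' compressed acquired MRF data; `rescale_table_from_subjects()` computes
#' the same table from a list of 7-channel SV volumes (the recommended
#' route for phantom experiments, mirroring how the default table was
#' derived from its own training set).
#'
#' @param min,max numeric vectors of length 7 (channel order of
#'   [sv_channel_names()]).
#' @return data.frame of class `rescale_table` with columns `channel`,
#'   `min`, `max`.
#' @export
rescale_table <- function(min, max) {
  stopifnot(length(min) == 7, length(max) == 7)
  if (any(max <= min)) stop("rescale table requires max > min per channel")
  structure(data.frame(channel = sv_channel_names(), min = as.numeric(min),
                       max = as.numeric(max)),
            class = c("rescale_table", "data.frame"))
}

#' @rdname rescale_table
#' @export
default_rescale_table <- function() {
  rescale_table(min = c(0.0, -3.09, -1.83, -2.22, -1.21, -1.95, -1.16),
                max = c(10.35, 0.65, 1.88, 1.36, 1.54, 0.90, 1.30))
}

#' @rdname rescale_table
#' @param sv_volumes list of 4D arrays (x, y, z, 7).
#' @export
rescale_table_from_subjects <- function(sv_volumes) {
  mins <- rep(Inf, 7); maxs <- rep(-Inf, 7)
  for (v in sv_volumes) {
    stopifnot(length(dim(v)) == 4, dim(v)[4] == 7)
    for (c in 1:7) {
      mins[c] <- min(mins[c], min(v[, , , c]))
      maxs[c] <- max(maxs[c], max(v[, , , c]))
    }
  }
  rescale_table(mins, maxs)
}

#' Normalize one training slice pair
#'
#' The MRI slice is divided by the maximum intensity of its parent volume
#' (so a whole volume shares one scale); each of the 7 SV channels is
#' min-max scaled to \[0, 1\] per slice. The per-channel (min, max) pairs
#' are returned so the target scaling is invertible. A channel with zero
#' range carries no trainable information: the pair is flagged so the
#' training loop can skip it.
#'
#' @param mri_slice 2D array.
#' @param sv_slice 3D array (H, W, 7).
#' @param mri_volume_max maximum of the parent MRI volume (default: slice
#'   maximum).
#' @return list with `mri` (2D, in \[0, 1\]), `sv` (3D, each channel in
#'   \[0, 1\]), `sv_range` (7 x 2 matrix of per-channel min/max) and
#'   `degenerate` (TRUE if any channel had zero range).
#' @export
normalize_training_pair <- function(mri_slice, sv_slice,
                                    mri_volume_max = max(mri_slice)) {
  stopifnot(length(dim(sv_slice)) == 3, dim(sv_slice)[3] == 7)
  if (mri_volume_max <= 0) stop("MRI volume maximum must be positive")
  rng <- t(apply(sv_slice, 3, range))
  degenerate <- any(rng[, 2] - rng[, 1] <= 0)
  svn <- sv_slice
  if (!degenerate) {
    for (c in 1:7)
      svn[, , c] <- (sv_slice[, , c] - rng[c, 1]) / (rng[c, 2] - rng[c, 1])
  }
  list(mri = mri_slice / mri_volume_max, sv = svn,
       sv_range = rng, degenerate = degenerate)
}

#' Invert the per-slice SV normalization
#' @param sv_norm 3D array (H, W, 7) in \[0, 1\].
#' @param sv_range 7 x 2 matrix of (min, max) from
#'   [normalize_training_pair()].
#' @return 3D array in SV units.
#' @export
denormalize_sv <- function(sv_norm, sv_range) {
  out <- sv_norm
  for (c in 1:7)
    out[, , c] <- sv_range[c, 1] + sv_norm[, , c] *
      (sv_range[c, 2] - sv_range[c, 1])
  out
}

#' Batches per training epoch
#'
#' With `n_slices` available training slices and batches of `batch_size`
#' randomly drawn slices, one epoch performs
#' `floor(n_slices / batch_size)` iterations.
#' @param n_slices total slice count across training subjects.
#' @param batch_size slices per batch (default 16).
#' @return integer iteration count.
#' @export
batches_per_epoch <- function(n_slices, batch_size = 16) {
  stopifnot(n_slices >= 1, batch_size >= 1)
  as.integer(floor(n_slices / batch_size))
}

# stack (subject, slice) picks into network input/target batch arrays;
# slices whose SV channels are degenerate are flagged
make_batch <- function(subjects, picks) {
  g <- dim(subjects[[1]]$mprage)[1]
  n <- nrow(picks)
  x <- array(0, dim = c(g, g, 1, n))
  yt <- array(0, dim = c(g, g, 7, n))
  keep <- logical(n)
  for (i in seq_len(n)) {
    s <- subjects[[picks$subject[i]]]
    np <- normalize_training_pair(s$mprage[, , picks$slice[i]],
                                  s$sv[, , picks$slice[i], ],
                                  mri_volume_max = max(s$mprage))
    if (np$degenerate) next
    x[, , 1, i] <- np$mri
    yt[, , , i] <- np$sv
    keep[i] <- TRUE
  }
  list(x = x[, , , keep, drop = FALSE], y = yt[, , , keep, drop = FALSE],
       n = sum(keep))
}

composite_mse <- function(net, x, y) {
  # evaluation-mode MSE of all 7 channels against [0, 1] targets
  per <- numeric(7)
  for (c in 1:7) {
    fw <- unet_fwd(net$channels[[c]], net$config, x, training = FALSE)
    yhat <- (fw$y + 1) / 2
    per[c] <- mean((yhat[, , 1, ] - y[, , c, ])^2)
  }
  per
}

#' Train the composite network
#'
#' Runs `epochs` passes; each pass performs
#' `floor(total slices / batch_size)` iterations on batches of slices
#' sampled uniformly across subjects and positions. Every one of the
#' seven channel networks is updated independently against the mean
#' squared error of its own channel (targets are per-slice normalized to
#' \[0, 1\]; predictions map the tanh output through `(y + 1) / 2`).
#' After every epoch the composite MSE is evaluated in inference mode on
#' the verification subjects (never used for updates) and the best
#' weights are checkpointed.
#'
#' @param net a [build_network()] result.
#' @param subjects list of training subjects, each a list with `mprage`
#'   (3D array) and `sv` (4D array, 7 channels).
#' @param epochs number of passes.
#' @param verification list of held-out subjects in the same format
#'   (optional but recommended).
#' @param batch_size slices per iteration (default 16).
#' @param lr ADAM learning rate (default 1e-4).
#' @param seed RNG seed for batch sampling and dropout.
#' @param verbose print per-epoch losses.
#' @return list of class `training_state`: `net` (final weights),
#'   `best_net` (lowest-verification-MSE weights), `best_mse`,
#'   `train_loss` (epochs x 7 matrix), `verify_loss` (epochs x 7),
#'   `best_curve` (running best verification MSE, non-increasing),
#'   `epochs`, `adam`.
#' @export
mrf_train <- function(net, subjects, epochs, verification = list(),
                      batch_size = 16, lr = 1e-4, seed = 0,
                      verbose = FALSE) {
  stopifnot(inherits(net, "composite_network"), length(subjects) >= 1,
            epochs >= 1)
  set.seed(seed)
  g <- dim(subjects[[1]]$mprage)
  n_slices <- length(subjects) * g[3]
  n_batches <- batches_per_epoch(n_slices, batch_size)
  if (n_batches < 1) stop("fewer slices than one batch")
  adam <- lapply(net$channels, adam_state_init)
  train_loss <- verify_loss <- matrix(NA_real_, epochs, 7)
  best_curve <- numeric(epochs)
  best_mse <- Inf
  best_net <- net

  vx <- NULL
  if (length(verification)) {
    vpicks <- do.call(rbind, lapply(seq_along(verification), function(s)
      data.frame(subject = s, slice = seq_len(dim(verification[[s]]$mprage)[3]))))
    vb <- make_batch(verification, vpicks)
    vx <- vb$x; vy <- vb$y
  }

  for (ep in seq_len(epochs)) {
    ep_loss <- matrix(0, n_batches, 7)
    for (it in seq_len(n_batches)) {
      picks <- data.frame(
        subject = sample.int(length(subjects), batch_size, replace = TRUE),
        slice = sample.int(g[3], batch_size, replace = TRUE))
      bt <- make_batch(subjects, picks)
      if (bt$n == 0) next
      for (c in 1:7) {
        fw <- unet_fwd(net$channels[[c]], net$config, bt$x, training = TRUE)
        net$channels[[c]] <- fw$params   # running BN statistics
        yhat <- (fw$y + 1) / 2
        target <- array(bt$y[, , c, ], dim = dim(fw$y))
        resid <- yhat - target
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop(sprintf("NaN/Inf loss in channel %d at epoch %d iteration %d",
                       c, ep, it))
        ep_loss[it, c] <- loss
        dy <- resid * (2 / length(resid)) / 2  # d loss / d tanh output
        gr <- unet_bwd(net$channels[[c]], net$config, fw$cache, dy)
        au <- adam_update(net$channels[[c]], gr, adam[[c]], lr = lr)
        net$channels[[c]] <- au$params
        adam[[c]] <- au$state
      }
    }
    train_loss[ep, ] <- colMeans(ep_loss)
    if (!is.null(vx)) {
      verify_loss[ep, ] <- composite_mse(net, vx, vy)
      vm <- mean(verify_loss[ep, ])
    } else {
      vm <- mean(train_loss[ep, ])
    }
    if (vm < best_mse) {
      best_mse <- vm
      best_net <- net
    }
    best_curve[ep] <- best_mse
    if (verbose)
      message(sprintf("epoch %d: train %.5f, verify %.5f (best %.5f)",
                      ep, mean(train_loss[ep, ]), vm, best_mse))
  }
  structure(list(net = net, best_net = best_net, best_mse = best_mse,
                 train_loss = train_loss, verify_loss = verify_loss,
                 best_curve = best_curve, epochs = epochs, adam = adam,
                 lr = lr, batch_size = batch_size, seed = seed),
            class = "training_state")
}

#' Predict SV volumes from an MPRAGE volume
#'
#' Processes the volume as an independent stack of 2D slices (axis 3) in
#' index order, maps each channel's tanh output through `(y + 1) / 2` and
#' then to SV units with the rescale table's global per-channel
#' (min, max). Slices do not interact.
#'
#' @param net a `composite_network` (typically a `training_state`'s
#'   `best_net`).
#' @param mri_volume 3D array with values in \[0, 1\] and slice side
#'   equal to the network's `input_size`.
#' @param rescale a [rescale_table()].
#' @param chunk slices per forward batch.
#' @return 4D array (x, y, z, 7) in SV units.
#' @export
mrf_predict <- function(net, mri_volume, rescale = default_rescale_table(),
                        chunk = 16L) {
  stopifnot(inherits(net, "composite_network"),
            inherits(rescale, "rescale_table"))
  d <- dim(mri_volume)
  if (d[1] != net$config$input_size || d[2] != net$config$input_size)
    stop("volume slice size does not match the network input size")
  out <- array(0, dim = c(d, 7))
  for (start in seq(1, d[3], by = chunk)) {
    sl <- start:min(start + chunk - 1L, d[3])
    x <- array(mri_volume[, , sl], dim = c(d[1], d[2], 1, length(sl)))
    for (c in 1:7) {
      fw <- unet_fwd(net$channels[[c]], net$config, x, training = FALSE)
      y01 <- (fw$y[, , 1, ] + 1) / 2
      out[, , sl, c] <- rescale$min[c] + y01 * (rescale$max[c] - rescale$min[c])
    }
  }
  out
}

#' Save / load a training checkpoint
#'
#' The container is a directory with the network weights (`weights.rds`),
#' a JSON description of the configuration, rescale table, seed, epoch
#' count and best verification MSE.
#' @param state a `training_state` (or a bare `composite_network`).
#' @param path directory to create.
#' @param rescale optional [rescale_table()] stored alongside.
#' @return `path` invisibly / the restored list.
#' @export
save_checkpoint <- function(state, path, rescale = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  net <- if (inherits(state, "composite_network")) state else state$best_net
  saveRDS(net$channels, file.path(path, "weights.rds"))
  meta <- list(config = unclass(net$config),
               best_mse = if (inherits(state, "training_state"))
                 state$best_mse else NA,
               epochs = if (inherits(state, "training_state"))
                 state$epochs else NA,
               seed = if (inherits(state, "training_state"))
                 state$seed else NA)
  if (!is.null(rescale)) meta$rescale <- as.data.frame(rescale)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(network_config, meta$config[
    c("input_size", "base_filters", "n_levels", "dropout_rate", "seed",
      "bottleneck_batchnorm")])
  net <- structure(list(channels = readRDS(file.path(path, "weights.rds")),
                        config = cfg),
                   class = "composite_network")
  rescale <- if (!is.null(meta$rescale))
    rescale_table(meta$rescale$min, meta$rescale$max) else NULL
  list(net = net, rescale = rescale, meta = meta)
}
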