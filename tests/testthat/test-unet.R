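# Analytic parameter count from the structure dump: convolutions
# contribute k*k*in*out weights + out biases, batch norms 2*out.
analytic_count <- function(config) {
  st <- network_structure(config)
  total <- 0
  for (i in seq_len(nrow(st))) {
    r <- st[i, ]
    if (r$type == "conv")
      total <- total + r$kernel^2 * r$in_ch * r$out_ch + r$out_ch
    else if (r$type == "batchnorm")
      total <- total + 2 * r$out_ch
  }
  total
}

test_that("network outputs are bounded, finite and shape-preserving", {
  cfg <- network_config(input_size = 16, base_filters = 2, n_levels = 2,
                        seed = 1)
  net <- build_network(cfg)
  x <- array(0, c(16, 16, 1, 2))
  fw <- mrfsynth:::unet_fwd(net$channels[[1]], cfg, x, training = FALSE)
  expect_equal(dim(fw$y), c(16, 16, 1, 2))
  expect_true(all(is.finite(fw$y)))
  expect_true(all(abs(fw$y) <= 1))
})

test_that("parameter counts match the layer-by-layer analytic sum", {
  for (cfg in list(
    network_config(input_size = 64, base_filters = 2, n_levels = 2, seed = 1),
    network_config(input_size = 32, base_filters = 4, n_levels = 3, seed = 1),
    network_config(input_size = 16, base_filters = 2, n_levels = 1, seed = 1,
                   bottleneck_batchnorm = FALSE))) {
    net1 <- mrfsynth:::unet_init(cfg, 1)
    expect_equal(count_parameters(net1), analytic_count(cfg))
    net <- build_network(cfg)
    expect_equal(count_parameters(net), 7 * analytic_count(cfg))
  }
  # doubling base filters roughly quadruples deep conv weights
  c1 <- network_config(input_size = 32, base_filters = 4, n_levels = 2,
                       seed = 1)
  c2 <- network_config(input_size = 32, base_filters = 8, n_levels = 2,
                       seed = 1)
  expect_gt(analytic_count(c2) / analytic_count(c1), 3.5)
  expect_lt(analytic_count(c2) / analytic_count(c1), 4.1)
})

test_that("every decoder concatenation grows channels by exactly 1.5x", {
  for (cfg in list(
    network_config(input_size = 64, base_filters = 2, n_levels = 2, seed = 1),
    network_config(input_size = 32, base_filters = 4, n_levels = 3, seed = 1),
    network_config(input_size = 256, base_filters = 16, n_levels = 4,
                   seed = 1))) {
    st <- network_structure(cfg)
    cc <- st[st$type == "concat", ]
    expect_equal(nrow(cc), cfg$n_levels)
    expect_equal(cc$out_ch / cc$in_ch, rep(1.5, cfg$n_levels))
  }
  # the reference-scale config walks 16 -> 256 channels with a 16x16 floor
  st <- network_structure(network_config())
  enc_convs <- st[st$stage == "encoder" & st$type == "conv", ]
  expect_equal(max(enc_convs$out_ch), 256)
  expect_equal(min(st$spatial), 16)
})

test_that("backpropagation matches finite differences", {
  cfg <- network_config(input_size = 8, base_filters = 2, n_levels = 1,
                        dropout_rate = 0, seed = 1)
  p <- mrfsynth:::unet_init(cfg, 1)
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  tgt <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  lossfun <- function(p) {
    fw <- mrfsynth:::unet_fwd(p, cfg, x, training = TRUE)
    mean(((fw$y + 1) / 2 - tgt)^2)
  }
  fw <- mrfsynth:::unet_fwd(p, cfg, x, training = TRUE)
  dy <- (((fw$y + 1) / 2 - tgt) / length(fw$y))
  gr <- mrfsynth:::unet_bwd(p, cfg, fw$cache, dy)
  leaves <- list(
    list(get = function(p) p$enc[[1]]$conv1$w,
         set = function(p, v) { p$enc[[1]]$conv1$w[] <- v; p },
         g = gr$enc[[1]]$conv1$w),
    list(get = function(p) p$enc[[2]]$bn2$gamma,
         set = function(p, v) { p$enc[[2]]$bn2$gamma[] <- v; p },
         g = gr$enc[[2]]$bn2$gamma),
    list(get = function(p) p$bot$conv2$w,
         set = function(p, v) { p$bot$conv2$w[] <- v; p },
         g = gr$bot$conv2$w),
    list(get = function(p) p$dec[[1]]$conv1$w,
         set = function(p, v) { p$dec[[1]]$conv1$w[] <- v; p },
         g = gr$dec[[1]]$conv1$w),
    list(get = function(p) p$head$w,
         set = function(p, v) { p$head$w[] <- v; p },
         g = gr$head$w))
  set.seed(3)
  eps <- 1e-6
  for (lf in leaves) {
    v <- lf$get(p)
    for (i in sample(length(v), min(3, length(v)))) {
      num <- (lossfun(lf$set(p, replace(v, i, v[i] + eps))) -
                lossfun(lf$set(p, replace(v, i, v[i] - eps)))) / (2 * eps)
      expect_equal(lf$g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("slice normalization is invertible and flags flat channels", {
  set.seed(4)
  mri <- matrix(runif(64, 0, 500), 8, 8)
  sv <- array(rnorm(8 * 8 * 7), c(8, 8, 7))
  np <- normalize_training_pair(mri, sv, mri_volume_max = 500)
  expect_equal(max(np$mri) <= 1, TRUE)
  expect_equal(apply(np$sv, 3, min), rep(0, 7), tolerance = 1e-12)
  expect_equal(apply(np$sv, 3, max), rep(1, 7), tolerance = 1e-12)
  back <- denormalize_sv(np$sv, np$sv_range)
  expect_equal(back, sv, tolerance = 1e-12)

  # published global range for Re(SV2) maps 0 to ~0.826
  rt <- default_rescale_table()
  i <- which(rt$channel == "sv2_re")
  expect_equal((0 - rt$min[i]) / (rt$max[i] - rt$min[i]), 0.826,
               tolerance = 5e-4)

  sv[, , 3] <- 2
  expect_true(normalize_training_pair(mri, sv, 500)$degenerate)
})

test_that("one epoch of one batch is exactly one iteration", {
  expect_equal(batches_per_epoch(16, 16), 1L)
  expect_equal(batches_per_epoch(100, 16), 6L)
})

test_that("training updates channels in isolation and deterministically", {
  cfg <- network_config(input_size = 16, base_filters = 2, n_levels = 1,
                        seed = 5)
  set.seed(6)
  subj <- list(list(mprage = array(runif(16 * 16 * 4), c(16, 16, 4)),
                    sv = array(rnorm(16 * 16 * 4 * 7), c(16, 16, 4, 7))))
  net <- build_network(cfg)
  # determinism: identical seeds give identical losses over >= 10 steps
  st2 <- mrf_train(net, subj, epochs = 10, batch_size = 4, seed = 11)
  st3 <- mrf_train(net, subj, epochs = 10, batch_size = 4, seed = 11)
  expect_identical(st2$train_loss, st3$train_loss)
  expect_identical(st2$net$channels[[1]]$head$w, st3$net$channels[[1]]$head$w)

  # gradient isolation: a step of channel c leaves other channels intact
  fw <- mrfsynth:::unet_fwd(net$channels[[3]], cfg,
                            array(subj[[1]]$mprage[, , 1], c(16, 16, 1, 1)),
                            training = TRUE)
  gr <- mrfsynth:::unet_bwd(net$channels[[3]], cfg, fw$cache,
                            fw$y / length(fw$y))
  adam <- mrfsynth:::adam_state_init(net$channels[[3]])
  upd <- mrfsynth:::adam_update(net$channels[[3]], gr, adam, lr = 1e-3)
  net2 <- net
  net2$channels[[3]] <- upd$params
  for (c_ in c(1, 2, 4:7))
    expect_identical(net2$channels[[c_]], net$channels[[c_]])
  expect_false(identical(net2$channels[[3]]$head$w, net$channels[[3]]$head$w))
})

test_that("verification-best checkpoint tracking is monotone", {
  cfg <- network_config(input_size = 16, base_filters = 2, n_levels = 1,
                        seed = 5)
  set.seed(7)
  mk <- function() list(mprage = array(runif(16 * 16 * 4), c(16, 16, 4)),
                        sv = array(rnorm(16 * 16 * 4 * 7), c(16, 16, 4, 7)))
  st <- mrf_train(build_network(cfg), list(mk()), epochs = 5, batch_size = 4,
                  verification = list(mk()), seed = 13)
  expect_true(all(diff(st$best_curve) <= 0))
  expect_true(all(is.finite(st$train_loss)))
  expect_equal(st$best_mse, min(st$best_curve))
})

test_that("prediction respects the rescale table and slice independence", {
  cfg <- network_config(input_size = 16, base_filters = 2, n_levels = 1,
                        seed = 8)
  net <- build_network(cfg)
  set.seed(9)
  vol <- array(runif(16 * 16 * 5), c(16, 16, 5))
  rt <- default_rescale_table()
  sv <- mrf_predict(net, vol, rt)
  for (c_ in 1:7) {
    expect_gte(min(sv[, , , c_]), rt$min[c_])
    expect_lte(max(sv[, , , c_]), rt$max[c_])
  }
  # permuting input slices permutes output slices identically
  perm <- c(3, 1, 5, 2, 4)
  sv_perm <- mrf_predict(net, vol[, , perm], rt)
  expect_equal(sv_perm, sv[, , perm, ], tolerance = 1e-12)
  expect_error(mrf_predict(net, array(0, c(8, 8, 2)), rt), "input size")
})

test_that("checkpoints restore weights, config and rescale table", {
  cfg <- network_config(input_size = 16, base_filters = 2, n_levels = 1,
                        seed = 5)
  net <- build_network(cfg)
  dir <- withr::local_tempdir()
  save_checkpoint(net, dir, rescale = default_rescale_table())
  back <- load_checkpoint(dir)
  expect_equal(back$net$channels, net$channels, tolerance = 1e-15)
  expect_equal(back$net$config$base_filters, 2L)
  expect_equal(back$rescale$max, default_rescale_table()$max)
})
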