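#' Network configuration for the SV channel regressors
#'
#' Each of the seven channel networks is a U-Net for image regression:
#' an encoder of `n_levels + 1` double-convolution blocks whose channel
#' count doubles at every 2x2 max-pooling step (ladder
#' `base_filters * 2^0 ... base_filters * 2^n_levels`), a bottleneck
#' double convolution at the deepest width, bilinear 2x upsampling, and a
#' decoder that at every level concatenates the matching encoder block
#' (growing the channel count by exactly 50%) before two convolutions.
#' All convolutions are 3x3, zero-padded "same"; every encoder
#' convolution is followed by ReLU then batch normalization; decoder
#' convolutions drop the batch normalization; the head is a 1x1
#' convolution to one channel followed by tanh.
#'
#' @param input_size slice side length in pixels (default 256); must be
#'   divisible by `2^n_levels`.
#' @param base_filters channels of the first encoder block (default 16).
#' @param n_levels number of pooling steps (default 4; the deepest
#'   feature block is `input_size / 2^n_levels` on a side).
#' @param dropout_rate dropout fraction applied after each encoder
#'   double-convolution (default 0.1).
#' @param seed integer seed for weight initialization and dropout.
#' @param bottleneck_batchnorm keep batch normalization in the bottleneck
#'   double convolution (default TRUE).
#' @return list of class `network_config`.
#' @export
network_config <- function(input_size = 256, base_filters = 16,
                           n_levels = 4, dropout_rate = 0.1, seed = 0,
                           bottleneck_batchnorm = TRUE) {
  stopifnot(base_filters >= 1, n_levels >= 1, input_size >= 2^n_levels,
            dropout_rate >= 0, dropout_rate < 1)
  if (input_size %% 2^n_levels != 0)
    stop("input_size must be divisible by 2^n_levels")
  structure(list(input_size = as.integer(input_size),
                 base_filters = as.integer(base_filters),
                 n_levels = as.integer(n_levels),
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 bottleneck_batchnorm = isTRUE(bottleneck_batchnorm)),
            class = "network_config")
}

# ---- layer parameter constructors ------------------------------------------

he_uniform <- function(k, in_ch, out_ch) {
  lim <- sqrt(6 / (k * k * in_ch))
  array(stats::runif(k * k * in_ch * out_ch, -lim, lim),
        dim = c(k, k, in_ch, out_ch))
}

conv_params <- function(k, in_ch, out_ch) {
  list(w = he_uniform(k, in_ch, out_ch), b = numeric(out_ch))
}

bn_params <- function(ch) {
  list(gamma = rep(1, ch), beta = numeric(ch),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

#' Per-layer structure of one channel U-Net
#'
#' Emits the network's layer list (stage, level, type, channels in/out,
#' kernel and spatial size) from which parameter counts and the channel
#' arithmetic can be checked independently of the built weights.
#' @param config a [network_config()].
#' @return data.frame, one row per weighted or structural layer.
#' @export
network_structure <- function(config) {
  b <- config$base_filters; L <- config$n_levels; S <- config$input_size
  rows <- list()
  add <- function(stage, level, type, in_ch, out_ch, kernel, spatial) {
    rows[[length(rows) + 1]] <<- data.frame(
      stage = stage, level = level, type = type, in_ch = in_ch,
      out_ch = out_ch, kernel = kernel, spatial = spatial)
  }
  sp <- S
  for (l in seq_len(L + 1)) {
    c_l <- b * 2^(l - 1)
    in_l <- if (l == 1) 1 else b * 2^(l - 2)
    add("encoder", l, "conv", in_l, c_l, 3, sp)
    add("encoder", l, "batchnorm", c_l, c_l, NA, sp)
    add("encoder", l, "conv", c_l, c_l, 3, sp)
    add("encoder", l, "batchnorm", c_l, c_l, NA, sp)
    if (l <= L) { add("encoder", l, "maxpool", c_l, c_l, 2, sp); sp <- sp / 2 }
  }
  C <- b * 2^L
  add("bottleneck", L + 1, "conv", C, C, 3, sp)
  if (config$bottleneck_batchnorm) add("bottleneck", L + 1, "batchnorm", C, C, NA, sp)
  add("bottleneck", L + 1, "conv", C, C, 3, sp)
  if (config$bottleneck_batchnorm) add("bottleneck", L + 1, "batchnorm", C, C, NA, sp)
  add("bottleneck", L + 1, "upsample", C, C, NA, sp); sp <- sp * 2
  for (l in rev(seq_len(L))) {
    c_l <- b * 2^(l - 1)
    add("decoder", l, "concat", 2 * c_l, 3 * c_l, NA, sp)
    add("decoder", l, "conv", 3 * c_l, c_l, 3, sp)
    add("decoder", l, "conv", c_l, c_l, 3, sp)
    if (l > 1) { add("decoder", l, "upsample", c_l, c_l, NA, sp); sp <- sp * 2 }
  }
  add("head", 0, "conv", b, 1, 1, sp)
  add("head", 0, "tanh", 1, 1, NA, sp)
  do.call(rbind, rows)
}

unet_init <- function(config, seed) {
  set.seed(seed)
  b <- config$base_filters; L <- config$n_levels
  enc <- vector("list", L + 1)
  for (l in seq_len(L + 1)) {
    c_l <- b * 2^(l - 1)
    in_l <- if (l == 1) 1 else b * 2^(l - 2)
    enc[[l]] <- list(conv1 = conv_params(3, in_l, c_l), bn1 = bn_params(c_l),
                     conv2 = conv_params(3, c_l, c_l), bn2 = bn_params(c_l))
  }
  C <- b * 2^L
  bot <- list(conv1 = conv_params(3, C, C), conv2 = conv_params(3, C, C))
  if (config$bottleneck_batchnorm) {
    bot$bn1 <- bn_params(C); bot$bn2 <- bn_params(C)
  }
  dec <- vector("list", L)
  for (l in seq_len(L)) {
    c_l <- b * 2^(l - 1)
    dec[[l]] <- list(conv1 = conv_params(3, 3 * c_l, c_l),
                     conv2 = conv_params(3, c_l, c_l))
  }
  head <- conv_params(1, b, 1)
  list(enc = enc, bot = bot, dec = dec, head = head)
}

#' Build the seven-channel composite network
#'
#' Seven independently initialized U-Nets sharing one architecture, one
#' per real SV channel in the order
#' `Re SV1, Re SV2, Im SV2, Re SV3, Im SV3, Re SV4, Im SV4`.
#' The networks share no weights; each is trained against its own MSE
#' loss and their gradients never interact.
#' @param config a [network_config()].
#' @return list of class `composite_network` with elements `channels`
#'   (list of 7 parameter trees) and `config`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  channels <- lapply(1:7, function(i) unet_init(config, config$seed + i))
  names(channels) <- sv_channel_names()
  structure(list(channels = channels, config = config),
            class = "composite_network")
}

# walk a parameter tree, applying f to each trainable leaf (named w, b,
# gamma, beta); running statistics are not trainable
trainable_walk <- function(tree, f) {
  nms <- names(tree)
  for (i in seq_along(tree)) {
    x <- tree[[i]]
    nm <- if (!is.null(nms)) nms[i] else ""
    if (is.list(x)) trainable_walk(x, f)
    else if (nm %in% c("w", "b", "gamma", "beta")) f(nm, x)
  }
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution weights and biases plus batch
#' normalization scale and shift. Running batch statistics are excluded.
#' @param net a `composite_network`, or a single channel's parameter tree.
#' @return integer count.
#' @export
count_parameters <- function(net) {
  trees <- if (inherits(net, "composite_network")) net$channels else list(net)
  total <- 0
  for (tr in trees)
    trainable_walk(tr, function(nm, x) total <<- total + length(x))
  total
}

# ---- primitive layers (forward + backward) ---------------------------------

conv_fwd <- function(x, p) .conv2d_fwd(x, p$w, p$b)

conv_bwd <- function(x, p, dy) .conv2d_bwd(x, p$w, dy)

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

# channel-wise statistics over (H, W, N) without transposing the array:
# per-channel factors recycle along (H, W) within each sample and the
# C-periodic channel pattern repeats across samples
bn_fwd <- function(x, p, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); C <- d[3]
  hw <- d[1] * d[2]
  m <- hw * d[4]
  if (training) {
    mu <- rowSums(matrix(colSums(matrix(x, nrow = hw)), nrow = C)) / m
    v <- rowSums(matrix(colSums(matrix(x^2, nrow = hw)), nrow = C)) / m -
      mu^2
    p$running_mean <- (1 - momentum) * p$running_mean + momentum * mu
    p$running_var <- (1 - momentum) * p$running_var + momentum * v
  } else {
    mu <- p$running_mean
    v <- p$running_var
  }
  s <- sqrt(v + eps)
  xhat <- (x - rep(mu, each = hw)) * rep(1 / s, each = hw)
  y <- xhat * rep(p$gamma, each = hw) + rep(p$beta, each = hw)
  list(y = y, cache = list(xhat = xhat, s = s, dim = d, m = m), params = p)
}

bn_bwd <- function(dy, p, cache) {
  d <- cache$dim; C <- d[3]
  hw <- d[1] * d[2]
  m <- cache$m
  dgamma <- rowSums(matrix(colSums(matrix(dy * cache$xhat, nrow = hw)),
                           nrow = C))
  dbeta <- rowSums(matrix(colSums(matrix(dy, nrow = hw)), nrow = C))
  dxhat <- dy * rep(p$gamma, each = hw)
  mean_dxhat <- rowSums(matrix(colSums(matrix(dxhat, nrow = hw)),
                               nrow = C)) / m
  mean_dxx <- rowSums(matrix(colSums(matrix(dxhat * cache$xhat, nrow = hw)),
                             nrow = C)) / m
  dx <- (dxhat - rep(mean_dxhat, each = hw) -
           cache$xhat * rep(mean_dxx, each = hw)) * rep(1 / cache$s,
                                                        each = hw)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# conv -> ReLU -> [batch norm], as one cached step
enc_step_fwd <- function(x, conv, bn, training) {
  z <- conv_fwd(x, conv)
  r <- relu_fwd(z)
  cache <- list(x = x, relu_mask = z > 0)
  if (!is.null(bn)) {
    bnr <- bn_fwd(r, bn, training)
    cache$bn <- bnr$cache
    list(y = bnr$y, cache = cache, bn_params = bnr$params)
  } else {
    list(y = r, cache = cache, bn_params = NULL)
  }
}

enc_step_bwd <- function(dy, conv, bn, cache) {
  g <- list()
  if (!is.null(bn)) {
    bb <- bn_bwd(dy, bn, cache$bn)
    dy <- bb$dx
    g$bn <- list(gamma = bb$dgamma, beta = bb$dbeta)
  }
  dy <- dy * cache$relu_mask
  cb <- conv_bwd(cache$x, conv, dy)
  g$conv <- list(w = cb$dw, b = cb$db)
  g$dx <- cb$dx
  g
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

# ---- full single-network forward / backward --------------------------------

# x: (H, W, 1, N). Returns y (H, W, 1, N) in [-1, 1] plus caches; `params`
# is returned because training-mode batch norm updates running statistics.
unet_fwd <- function(params, config, x, training = FALSE) {
  L <- config$n_levels
  cache <- list(enc = vector("list", L + 1), drop = vector("list", L + 1),
                pool = vector("list", L), skips = vector("list", L + 1))
  h <- x
  for (l in seq_len(L + 1)) {
    blk <- params$enc[[l]]
    s1 <- enc_step_fwd(h, blk$conv1, blk$bn1, training)
    if (training) params$enc[[l]]$bn1 <- s1$bn_params
    s2 <- enc_step_fwd(s1$y, blk$conv2, blk$bn2, training)
    if (training) params$enc[[l]]$bn2 <- s2$bn_params
    dr <- dropout_fwd(s2$y, config$dropout_rate, training)
    cache$enc[[l]] <- list(s1 = s1$cache, s2 = s2$cache)
    cache$drop[l] <- list(dr$mask)
    cache$skips[[l]] <- dr$y
    h <- dr$y
    if (l <= L) {
      mp <- .maxpool2_fwd(h)
      cache$pool[[l]] <- list(idx = mp$idx, H = dim(h)[1], W = dim(h)[2])
      h <- mp$y
    }
  }
  bn1 <- if (config$bottleneck_batchnorm) params$bot$bn1 else NULL
  bn2 <- if (config$bottleneck_batchnorm) params$bot$bn2 else NULL
  b1 <- enc_step_fwd(h, params$bot$conv1, bn1, training)
  if (training && !is.null(bn1)) params$bot$bn1 <- b1$bn_params
  b2 <- enc_step_fwd(b1$y, params$bot$conv2, bn2, training)
  if (training && !is.null(bn2)) params$bot$bn2 <- b2$bn_params
  cache$bot <- list(s1 = b1$cache, s2 = b2$cache, in_dim = dim(h))
  h <- .upsample2_fwd(b2$y)

  cache$dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    skip <- cache$skips[[l]]
    up_ch <- dim(h)[3]
    hcat <- array(0, dim = dim(h) + c(0, 0, dim(skip)[3], 0))
    hcat[, , seq_len(up_ch), ] <- h
    hcat[, , up_ch + seq_len(dim(skip)[3]), ] <- skip
    blk <- params$dec[[l]]
    d1 <- enc_step_fwd(hcat, blk$conv1, NULL, training)
    d2 <- enc_step_fwd(d1$y, blk$conv2, NULL, training)
    cache$dec[[l]] <- list(s1 = d1$cache, s2 = d2$cache, up_ch = up_ch,
                           pre_up_dim = if (l > 1) dim(d2$y) else NULL)
    h <- d2$y
    if (l > 1) h <- .upsample2_fwd(h)
  }
  z <- conv_fwd(h, params$head)
  y <- tanh(z)
  cache$head <- list(x = h, y = y)
  list(y = y, cache = cache, params = params)
}

unet_bwd <- function(params, config, cache, dy) {
  L <- config$n_levels
  grads <- list(enc = vector("list", L + 1), bot = list(),
                dec = vector("list", L), head = NULL)
  dz <- dy * (1 - cache$head$y^2)
  hb <- conv_bwd(cache$head$x, params$head, dz)
  grads$head <- list(w = hb$dw, b = hb$db)
  dh <- hb$dx

  dskip <- vector("list", L + 1)  # gradient flowing into each skip tensor
  for (l in seq_len(L)) {
    dc <- cache$dec[[l]]
    if (l > 1) dh <- .upsample2_bwd(dh, dc$pre_up_dim[1], dc$pre_up_dim[2])
    blk <- params$dec[[l]]
    g2 <- enc_step_bwd(dh, blk$conv2, NULL, dc$s2)
    g1 <- enc_step_bwd(g2$dx, blk$conv1, NULL, dc$s1)
    grads$dec[[l]] <- list(conv1 = g1$conv, conv2 = g2$conv)
    up_ch <- dc$up_ch
    dcat <- g1$dx
    dh <- dcat[, , seq_len(up_ch), , drop = FALSE]
    dskip[[l]] <- dcat[, , up_ch + seq_len(dim(dcat)[3] - up_ch), ,
                       drop = FALSE]
  }

  din <- cache$bot$in_dim
  dh <- .upsample2_bwd(dh, din[1], din[2])
  bn1 <- if (config$bottleneck_batchnorm) params$bot$bn1 else NULL
  bn2 <- if (config$bottleneck_batchnorm) params$bot$bn2 else NULL
  g2 <- enc_step_bwd(dh, params$bot$conv2, bn2, cache$bot$s2)
  g1 <- enc_step_bwd(g2$dx, params$bot$conv1, bn1, cache$bot$s1)
  grads$bot <- list(conv1 = g1$conv, conv2 = g2$conv)
  if (config$bottleneck_batchnorm) {
    grads$bot$bn1 <- g1$bn; grads$bot$bn2 <- g2$bn
  }
  dh <- g1$dx

  for (l in rev(seq_len(L + 1))) {
    if (l <= L) {
      pl <- cache$pool[[l]]
      dh <- .maxpool2_bwd(dh, pl$idx, pl$H, pl$W)
    }
    if (!is.null(dskip[[l]])) dh <- dh + dskip[[l]]
    if (!is.null(cache$drop[[l]])) dh <- dh * cache$drop[[l]]
    blk <- params$enc[[l]]
    g2 <- enc_step_bwd(dh, blk$conv2, blk$bn2, cache$enc[[l]]$s2)
    g1 <- enc_step_bwd(g2$dx, blk$conv1, blk$bn1, cache$enc[[l]]$s1)
    grads$enc[[l]] <- list(conv1 = g1$conv, bn1 = g1$bn,
                           conv2 = g2$conv, bn2 = g2$bn)
    dh <- g1$dx
  }
  grads
}

# grads tree uses {conv1 = list(w, b), bn1 = list(gamma, beta), ...};
# params use {conv1 = list(w, b), bn1 = list(gamma, beta, running_*)}.
# ADAM walks both trees in parallel.
adam_state_init <- function(params) {
  walk <- function(tree) {
    out <- vector("list", length(tree))
    names(out) <- names(tree)
    for (i in seq_along(tree)) {
      x <- tree[[i]]
      nm <- if (!is.null(names(tree))) names(tree)[i] else ""
      if (is.list(x)) out[[i]] <- walk(x)
      else if (nm %in% c("w", "b", "gamma", "beta"))
        out[[i]] <- list(m = x * 0, v = x * 0)
    }
    out
  }
  list(tree = walk(params), t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(ptree, gtree, stree) {
    nms <- names(ptree)
    for (i in seq_along(ptree)) {
      nm <- if (!is.null(nms)) nms[i] else ""
      key <- if (nzchar(nm)) nm else i
      x <- ptree[[i]]
      g <- if (nzchar(nm)) gtree[[nm]] else gtree[[i]]
      if (is.null(g)) next
      if (is.list(x)) {
        res <- upd(x, g, stree[[key]])
        ptree[[i]] <- res$p
        stree[[key]] <- res$s
      } else if (nm %in% c("w", "b", "gamma", "beta")) {
        st <- stree[[key]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        ptree[[i]] <- x - lr * mhat / (sqrt(vhat) + eps)
        stree[[key]] <- st
      }
    }
    list(p = ptree, s = stree)
  }
  res <- upd(params, grads, state$tree)
  state$tree <- res$s
  list(params = res$p, state = state)
}
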