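# Fully convolutional encoder-decoder with a 3-class categorical head.
# The architecture follows the U-Net-style scheme of the method: an encoder
# of 3x3 conv / (batchnorm) / ReLU blocks with 2x2 max pooling between
# stages, and a decoder that upsamples by bilinear interpolation followed
# by convolution, ending in a 1x1 conv to (background, CD138-, CD138+)
# logits at input resolution. No deep-learning framework is available in
# this toolchain, so forward and backward passes are implemented here on
# top of the Rcpp kernels in src/conv_ops.cpp.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Configuration of the fully convolutional network
#'
#' @param encoder_channels integer vector of channel widths, one per
#'   encoder stage; its length sets the number of stages. The default
#'   `c(8, 16)` is a desk-scale network trainable on a CPU in minutes; a
#'   VGG-scale preset is available via [network_preset()].
#' @param use_batchnorm add batch normalization after every convolution.
#' @param n_classes number of output classes; fixed at 3 here.
#' @return object of class `network_config`. Its `receptive_field_radius`
#'   element is derived analytically from the layer stack.
#' @export
network_config <- function(encoder_channels = c(8, 16),
                           use_batchnorm = TRUE, n_classes = 3) {
  if (length(encoder_channels) < 1 || any(encoder_channels < 1))
    pc_stop("pc_spec_error", "need at least one encoder stage")
  if (n_classes != 3)
    pc_stop("pc_spec_error", "this model is a 3-class (bg/neg/pos) head")
  cfg <- structure(list(encoder_channels = as.integer(encoder_channels),
                        n_stages = length(encoder_channels),
                        use_batchnorm = isTRUE(use_batchnorm),
                        n_classes = 3L),
                   class = "network_config")
  cfg$receptive_field_radius <- rf_radius(cfg)
  cfg
}

#' VGG-scale preset configuration
#'
#' An interpretation of the published full-scale setup (a VGG-style
#' encoder with batch normalization). Provided as a configuration preset
#' only; the tests and the bundled examples use the small default network.
#'
#' @return a `network_config` with 5 stages of 64-512 channels.
#' @export
network_preset <- function() {
  network_config(encoder_channels = c(64, 128, 256, 512, 512),
                 use_batchnorm = TRUE)
}

# analytic receptive-field radius: accumulate (k-1)*jump over the layer
# stack (jump = product of strides so far; upsampling halves it, bilinear
# interpolation itself has kernel extent 2)
rf_radius <- function(config) {
  j <- 1; total <- 0
  S <- config$n_stages
  for (s in seq_len(S)) {
    total <- total + 2 * (2 * j) # two 3x3 convs
    if (s < S) {
      total <- total + j # 2x2 pool
      j <- 2 * j
    }
  }
  for (s in rev(seq_len(max(S - 1, 0)))) {
    total <- total + j # bilinear x2
    j <- j / 2
    total <- total + 2 * j # 3x3 conv
  }
  as.integer(ceiling(total / 2))
}

new_conv <- function(cin, cout, k) {
  w <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
             dim = c(k, k, cin, cout))
  list(type = "conv", k = k, cin = cin, cout = cout, w = w,
       b = numeric(cout))
}

new_bn <- function(c) list(type = "bn", c = c, gamma = rep(1, c),
                           beta = numeric(c), rmean = numeric(c),
                           rvar = rep(1, c))

#' Build a network from a configuration
#'
#' Initializes convolution weights with He-scaled Gaussians under the
#' given seed, so builds are reproducible.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `pc_network`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    layers <- list()
    add <- function(ly) layers[[length(layers) + 1]] <<- ly
    prev <- 3L
    S <- config$n_stages
    for (s in seq_len(S)) {
      ch <- config$encoder_channels[s]
      for (rep in 1:2) {
        add(new_conv(prev, ch, 3L))
        if (config$use_batchnorm) add(new_bn(ch))
        add(list(type = "relu"))
        prev <- ch
      }
      if (s < S) add(list(type = "pool"))
    }
    for (s in rev(seq_len(S - 1))) {
      add(list(type = "up"))
      ch <- config$encoder_channels[s]
      add(new_conv(prev, ch, 3L))
      if (config$use_batchnorm) add(new_bn(ch))
      add(list(type = "relu"))
      prev <- ch
    }
    add(new_conv(prev, config$n_classes, 1L))
    structure(list(config = config, layers = layers, seed = as.integer(seed)),
              class = "pc_network")
  })
}

check_input_shape <- function(net, d) {
  div <- 2^(net$config$n_stages - 1)
  if (length(d) != 3 || d[3] != 3)
    pc_stop("pc_shape_error", "network input must be H x W x 3")
  if (d[1] %% div != 0 || d[2] %% div != 0)
    pc_stop("pc_shape_error",
            "input %dx%d not divisible by 2^(n_stages-1) = %d",
            d[1], d[2], div)
}

bn_forward <- function(ly, x, train) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, nrow = n) # n x C
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc^2)
    ly$rmean <- (1 - BN_MOMENTUM) * ly$rmean + BN_MOMENTUM * mu
    ly$rvar <- (1 - BN_MOMENTUM) * ly$rvar + BN_MOMENTUM * va
  } else {
    mu <- ly$rmean
    va <- ly$rvar
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
  list(out = array(out, d), layer = ly,
       cache = list(xhat = xhat, istd = istd, d = d))
}

bn_backward <- function(ly, cache, dout) {
  d <- cache$d
  n <- d[1] * d[2]
  dm <- matrix(dout, nrow = n)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, ly$gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# forward pass; keep = TRUE retains per-layer caches for backprop, train
# toggles batchnorm batch statistics (and running-stat updates)
net_forward <- function(net, x, train = FALSE, keep = FALSE) {
  check_input_shape(net, dim(x))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      if (keep) caches[[i]] <- list(x = x)
      x <- cpp_conv2d(x, as.numeric(ly$w), ly$b, ly$k, ly$k, ly$cin, ly$cout)
    } else if (ly$type == "bn") {
      r <- bn_forward(ly, x, train)
      if (train) net$layers[[i]] <- r$layer
      if (keep) caches[[i]] <- r$cache
      x <- r$out
    } else if (ly$type == "relu") {
      mask <- x > 0
      if (keep) caches[[i]] <- list(mask = mask)
      x <- x * mask
    } else if (ly$type == "pool") {
      r <- cpp_maxpool2(x)
      if (keep) caches[[i]] <- list(idx = r$idx)
      x <- r$out
    } else if (ly$type == "up") {
      x <- cpp_upsample2(x)
    }
  }
  list(out = x, caches = caches, net = net)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      r <- cpp_conv2d_backward(caches[[i]]$x, as.numeric(ly$w), dout,
                               ly$k, ly$k, ly$cin, ly$cout)
      grads[[i]] <- list(dw = array(r$dw, dim(ly$w)), db = as.numeric(r$db))
      dout <- r$dx
    } else if (ly$type == "bn") {
      r <- bn_backward(ly, caches[[i]], dout)
      grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
      dout <- r$dx
    } else if (ly$type == "relu") {
      dout <- dout * caches[[i]]$mask
    } else if (ly$type == "pool") {
      dout <- cpp_maxpool2_backward(dout, caches[[i]]$idx)
    } else if (ly$type == "up") {
      dout <- cpp_upsample2_backward(dout)
    }
  }
  grads
}

# per-pixel 3-way softmax of a logits array, returned as H x W x 3
softmax3 <- function(logits) {
  d <- dim(logits)
  lg <- matrix(logits, ncol = 3)
  mx <- pmax(lg[, 1], lg[, 2], lg[, 3])
  ex <- exp(lg - mx)
  array(ex / rowSums(ex), d)
}

#' Normalization statistics for network input
#'
#' @param images list of `H x W x 3` arrays (the training images).
#' @return list with per-channel `mean` and `sd`.
#' @export
fit_normalizer <- function(images) {
  ch <- function(k) unlist(lapply(images, function(im) as.numeric(im[, , k])))
  m <- vapply(1:3, function(k) mean(ch(k)), numeric(1))
  s <- vapply(1:3, function(k) sd(ch(k)), numeric(1))
  s[s < 1e-8] <- 1
  list(mean = m, sd = s)
}

apply_normalizer <- function(image, normalizer) {
  for (k in 1:3)
    image[, , k] <- (image[, , k] - normalizer$mean[k]) / normalizer$sd[k]
  image
}

#' Predict class pseudoprobability heatmaps for an image
#'
#' Runs the network in evaluation mode (frozen batchnorm statistics) and
#' applies a per-pixel softmax, yielding three maps (background, CD138-,
#' CD138+) that sum to one at every pixel.
#'
#' @param network a `pc_network`.
#' @param image raw `H x W x 3` image, 0-255 scale; `H` and `W` must be
#'   divisible by `2^(n_stages - 1)`.
#' @param normalizer statistics from [fit_normalizer()] (stored in the
#'   checkpoint for trained models).
#' @param pixel_size microns per pixel carried along for downstream use.
#' @return object of class `class_heatmaps`: list `bg`, `neg`, `pos`
#'   matrices plus `pixel_size` attribute slot.
#' @export
predict_heatmaps <- function(network, image, normalizer, pixel_size = 0.25) {
  if (anyNA(image) || any(!is.finite(image)))
    pc_stop("pc_format_error", "image contains NA or non-finite values")
  x <- apply_normalizer(image, normalizer)
  p <- softmax3(net_forward(network, x)$out)
  structure(list(bg = p[, , 1], neg = p[, , 2], pos = p[, , 3],
                 pixel_size = pixel_size),
            class = "class_heatmaps")
}

#' Empirically probe the receptive-field radius
#'
#' Perturbs the center pixel of a random input and measures the Chebyshev
#' radius of the region where logits change; the analytic
#' `receptive_field_radius` in the configuration should be an upper bound
#' within a small slack of this probe.
#'
#' @param network a `pc_network`.
#' @param size probe image side (divisible by the network's constraint).
#' @param n_probes number of random probes to take the max over.
#' @param seed RNG seed for probe inputs.
#' @return integer probe radius in pixels.
#' @export
probe_rf_radius <- function(network, size = 64, n_probes = 3, seed = 99) {
  with_seed(seed, {
    rad <- 0
    cy <- size %/% 2
    for (p in seq_len(n_probes)) {
      x <- array(rnorm(size * size * 3), dim = c(size, size, 3))
      base <- net_forward(network, x)$out
      x2 <- x
      x2[cy, cy, ] <- x2[cy, cy, ] + 10
      pert <- net_forward(network, x2)$out
      diff <- apply(abs(pert - base) > 1e-9, c(1, 2), any)
      nz <- which(diff, arr.ind = TRUE)
      if (nrow(nz) > 0)
        rad <- max(rad, max(abs(nz[, 1] - cy), abs(nz[, 2] - cy)))
    }
    as.integer(rad)
  })
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the network (weights + configuration), the input
#' normalizer and training metadata (seed, best epoch, validation
#' macro-F1).
#'
#' @param checkpoint list with elements `network`, `normalizer`, `meta`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint$network, "pc_network"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck$network, "pc_network"))
    pc_stop("pc_format_error", "%s is not a plasmacount checkpoint", path)
  ck
}
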