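# Training: paired geometric augmentation of image and label raster,
# pixelwise class-weighted categorical cross-entropy minimized by SGD, and
# model selection by validation macro-F1 computed with the full
# detection + matching pipeline after every epoch, as in the original
# training protocol. Hyperparameters (learning rate, class weights) are
# exposed through a grid search.

#' Training hyperparameters
#'
#' @param learning_rate SGD step size (> 0).
#' @param class_weights positive weights `(bg, neg, pos)` for the
#'   pixelwise cross-entropy; cell classes are upweighted because labeled
#'   discs cover only a few percent of the pixels.
#' @param max_epochs maximum epochs, default 200.
#' @param momentum SGD momentum (0 disables), default 0.9.
#' @param seed RNG seed governing shuffling and augmentation draws.
#' @return object of class `hyperparams`.
#' @export
hyperparams <- function(learning_rate = 0.05, class_weights = c(1, 10, 10),
                        max_epochs = 200, momentum = 0.9, seed = 1L) {
  if (learning_rate <= 0) pc_stop("pc_spec_error", "learning_rate must be > 0")
  if (length(class_weights) != 3 || any(class_weights <= 0))
    pc_stop("pc_spec_error", "class_weights must be 3 positive values")
  if (!is_count(max_epochs) || max_epochs < 1)
    pc_stop("pc_spec_error", "max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 class_weights = as.numeric(class_weights),
                 max_epochs = as.integer(max_epochs),
                 momentum = momentum, seed = as.integer(seed)),
            class = "hyperparams")
}

#' Augmentation policy
#'
#' Random horizontal/vertical flips, rotations with reflect padding of the
#' uncovered corners, and multiplicative brightness jitter (image only).
#'
#' @param hflip,vflip flip probabilities in `[0, 1]`.
#' @param rotation `"uniform"` (angles uniform in `[0, 360)`),
#'   `"right"` (multiples of 90 degrees only) or `"none"`.
#' @param brightness multiplicative jitter range, default `c(0.8, 1.25)`
#'   (symmetric in log space).
#' @return object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(hflip = 0.5, vflip = 0.5,
                                rotation = c("uniform", "right", "none"),
                                brightness = c(0.8, 1.25)) {
  rotation <- match.arg(rotation)
  if (any(c(hflip, vflip) < 0 | c(hflip, vflip) > 1))
    pc_stop("pc_spec_error", "flip probabilities must be in [0, 1]")
  if (length(brightness) != 2 || any(brightness <= 0))
    pc_stop("pc_spec_error", "brightness range must be positive")
  structure(list(hflip = hflip, vflip = vflip, rotation = rotation,
                 brightness = brightness),
            class = "augmentation_policy")
}

#' Sample one augmentation draw from a policy
#'
#' @param policy an [augmentation_policy()].
#' @return list `hflip`, `vflip` (logical), `angle` (degrees),
#'   `brightness` (factor); pass to [augment()].
#' @export
sample_draw <- function(policy) {
  angle <- switch(policy$rotation,
                  none = 0,
                  right = 90 * sample.int(4, 1) - 90,
                  uniform = runif(1, 0, 360))
  list(hflip = runif(1) < policy$hflip,
       vflip = runif(1) < policy$vflip,
       angle = angle,
       brightness = exp(runif(1, log(policy$brightness[1]),
                              log(policy$brightness[2]))))
}

identity_draw <- function() list(hflip = FALSE, vflip = FALSE, angle = 0,
                                 brightness = 1)

# rotate an H x W matrix (or H x W x C array) about its center by `angle`
# degrees; voids are refilled by symmetric reflection. Right angles are
# handled exactly by array transposition so that four 90-degree rotations
# compose to the identity bit-for-bit.
rotate_raster <- function(x, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  angle <- angle %% 360
  is_mat <- is.matrix(x)
  if (is_mat) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (isTRUE(all.equal(angle %% 90, 0))) {
    k <- round(angle / 90) %% 4
    out <- x
    for (i in seq_len(k)) {
      # 90 degrees counterclockwise in (row, col) space
      out <- aperm(out, c(2, 1, 3))[dim(out)[2]:1, , , drop = FALSE]
    }
  } else {
    H <- d[1]; W <- d[2]
    th <- angle * pi / 180
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    gy <- matrix(seq_len(H) - 1 - cy, H, W)
    gx <- matrix(rep(seq_len(W) - 1 - cx, each = H), H, W)
    # inverse map: source = R(-theta) * target
    sx <- cos(th) * gx - sin(th) * gy + cx
    sy <- sin(th) * gx + cos(th) * gy + cy
    out <- array(0, d)
    np <- H * W
    if (interp == "nearest") {
      ri <- as.vector(reflect_index(round(sy), H)) + 1
      ci <- as.vector(reflect_index(round(sx), W)) + 1
      for (ch in seq_len(d[3]))
        out[, , ch] <- matrix(x[cbind(ri, ci, rep(ch, np))], H, W)
    } else {
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- as.vector(sy - y0); fx <- as.vector(sx - x0)
      r0 <- as.vector(reflect_index(y0, H)) + 1
      r1 <- as.vector(reflect_index(y0 + 1, H)) + 1
      c0 <- as.vector(reflect_index(x0, W)) + 1
      c1 <- as.vector(reflect_index(x0 + 1, W)) + 1
      for (ch in seq_len(d[3])) {
        chv <- rep(ch, np)
        v <- (1 - fy) * ((1 - fx) * x[cbind(r0, c0, chv)] +
                           fx * x[cbind(r0, c1, chv)]) +
          fy * ((1 - fx) * x[cbind(r1, c0, chv)] +
                  fx * x[cbind(r1, c1, chv)])
        out[, , ch] <- matrix(v, H, W)
      }
    }
  }
  if (is_mat) dim(out) <- d[1:2]
  out
}

#' Apply one augmentation draw to an image/label pair
#'
#' The identical geometric transform (flips then rotation) is applied to
#' both rasters -- bilinear for the image, nearest-neighbor for the labels
#' so class codes are preserved -- while brightness jitter touches the
#' image only.
#'
#' @param image `H x W x 3` array.
#' @param labels `H x W` integer label matrix.
#' @param draw a draw from [sample_draw()] (or [identity_draw] semantics
#'   via `draw = NULL`).
#' @return list `image`, `labels`.
#' @export
augment <- function(image, labels, draw = NULL) {
  if (is.null(draw)) draw <- identity_draw()
  if (!identical(dim(image)[1:2], dim(labels)[1:2]) &&
      !identical(dim(image)[1:2], dim(labels)))
    pc_stop("pc_shape_error", "image and labels must share their 2-D shape")
  if (draw$hflip) {
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    labels <- labels[, ncol(labels):1, drop = FALSE]
  }
  if (draw$vflip) {
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    labels <- labels[nrow(labels):1, , drop = FALSE]
  }
  if (draw$angle %% 360 != 0) {
    image <- rotate_raster(image, draw$angle, "bilinear")
    labels <- rotate_raster(labels, draw$angle, "nearest")
  }
  if (draw$brightness != 1)
    image <- clip(image * draw$brightness, 0, 255)
  list(image = image, labels = matrix(as.integer(labels), nrow(labels)))
}

# pixelwise class-weighted categorical cross-entropy; returns the scalar
# loss (normalized by total weight) and the gradient wrt the logits
weighted_ce <- function(logits, labels, class_weights) {
  d <- dim(logits)
  p <- matrix(softmax3(logits), ncol = 3)
  y <- as.integer(labels) + 1L
  w <- class_weights[y]
  wt <- sum(w)
  eps <- 1e-12
  loss <- -sum(w * log(p[cbind(seq_along(y), y)] + eps)) / wt
  onehot <- matrix(0, length(y), 3)
  onehot[cbind(seq_along(y), y)] <- 1
  dlog <- (p - onehot) * (w / wt)
  list(loss = loss, dlogits = array(dlog, d))
}

sgd_step <- function(net, grads, vel, lr, momentum) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      vel[[i]]$w <- momentum * vel[[i]]$w - lr * g$dw
      vel[[i]]$b <- momentum * vel[[i]]$b - lr * g$db
      net$layers[[i]]$w <- ly$w + vel[[i]]$w
      net$layers[[i]]$b <- ly$b + vel[[i]]$b
    } else if (ly$type == "bn") {
      vel[[i]]$gamma <- momentum * vel[[i]]$gamma - lr * g$dgamma
      vel[[i]]$beta <- momentum * vel[[i]]$beta - lr * g$dbeta
      net$layers[[i]]$gamma <- ly$gamma + vel[[i]]$gamma
      net$layers[[i]]$beta <- ly$beta + vel[[i]]$beta
    }
  }
  list(net = net, vel = vel)
}

init_velocity <- function(net) {
  lapply(net$layers, function(ly) {
    if (ly$type == "conv") list(w = array(0, dim(ly$w)), b = numeric(length(ly$b)))
    else if (ly$type == "bn") list(gamma = numeric(ly$c), beta = numeric(ly$c))
    else NULL
  })
}

#' Make a training sample from a synthetic scene
#'
#' Encodes the scene's ground-truth points and dilates them into the
#' training target.
#'
#' @param scene a `synthetic_scene`.
#' @param dilation_radius label dilation radius, default 5 px.
#' @return list `image`, `labels` (dilated), `points`.
#' @export
scene_sample <- function(scene, dilation_radius = 5) {
  lbl <- encode_labels(scene$truth, dim(scene$image)[1:2])
  list(image = scene$image,
       labels = dilate_labels(lbl, dilation_radius, quiet = TRUE),
       points = scene$truth)
}

# pooled validation macro-F1 via the full detection + matching pipeline
validation_f1 <- function(net, normalizer, val, detect_args) {
  cm <- matrix(0L, 3, 3, dimnames = list(truth = CM_LEVELS,
                                         predicted = CM_LEVELS))
  for (s in val) {
    hm <- predict_heatmaps(net, s$image, normalizer)
    det <- do.call(call_detections, c(list(hm), detect_args))
    m <- match_points(s$points, det)
    cm <- cm + confusion_matrix3(m, s$points$class, det$class)
  }
  macro_f1(cm)
}

#' Split samples into training and validation sets at the tile level
#'
#' @param samples list of samples.
#' @param val_fraction validation fraction, default 0.2 (an 80/20 split).
#' @param seed RNG seed.
#' @return list `train`, `val`.
#' @export
train_val_split <- function(samples, val_fraction = 0.2, seed = 1L) {
  n <- length(samples)
  n_val <- max(1L, round(val_fraction * n))
  with_seed(seed, {
    vi <- sample.int(n, n_val)
    list(train = samples[setdiff(seq_len(n), vi)], val = samples[vi])
  })
}

#' Train the network by SGD on weighted cross-entropy
#'
#' Runs plain stochastic gradient descent (optional momentum) on the
#' pixelwise class-weighted categorical cross-entropy for up to
#' `hp$max_epochs` epochs, applying a fresh augmentation draw to every
#' training sample in every epoch. After each epoch the validation
#' macro-F1 is computed by running the complete detection + matching
#' pipeline on the (un-augmented) validation samples; the returned
#' checkpoint holds the weights of the best-validation epoch. Fully
#' reproducible for fixed `(hp$seed, hp)`.
#'
#' @param samples training samples, each a list `image`, `labels`
#'   (already dilated -- dilation is preprocessing, not part of the
#'   loss), `points`.
#' @param val validation samples, same structure.
#' @param hp a [hyperparams()].
#' @param config a [network_config()].
#' @param policy an [augmentation_policy()].
#' @param detect_args list of overrides for [call_detections()] during
#'   validation.
#' @param verbose print one line per epoch.
#' @return list `checkpoint` (`network`, `normalizer`, `meta`) and
#'   `history` (data.frame `epoch`, `loss`, `val_macro_f1`).
#' @export
train <- function(samples, val, hp, config = network_config(),
                  policy = augmentation_policy(),
                  detect_args = list(), verbose = FALSE) {
  stopifnot(inherits(hp, "hyperparams"))
  if (length(samples) == 0 || length(val) == 0)
    pc_stop("pc_spec_error", "training and validation sets must be nonempty")
  normalizer <- fit_normalizer(lapply(samples, `[[`, "image"))
  with_seed(hp$seed, {
    net <- build_network(config, seed = hp$seed)
    vel <- init_velocity(net)
    best <- list(f1 = -Inf, loss = Inf, net = NULL, epoch = 0L)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_macro_f1 = numeric(0))
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample.int(length(samples))
      ep_loss <- 0
      for (i in ord) {
        aug <- augment(samples[[i]]$image, samples[[i]]$labels,
                       sample_draw(policy))
        x <- apply_normalizer(aug$image, normalizer)
        fw <- net_forward(net, x, train = TRUE, keep = TRUE)
        net <- fw$net
        ce <- weighted_ce(fw$out, aug$labels, hp$class_weights)
        if (!is.finite(ce$loss))
          pc_stop("pc_training_error",
                  "non-finite loss at epoch %d (lr = %g); aborting",
                  epoch, hp$learning_rate)
        ep_loss <- ep_loss + ce$loss
        grads <- net_backward(net, fw$caches, ce$dlogits)
        st <- sgd_step(net, grads, vel, hp$learning_rate, hp$momentum)
        net <- st$net
        vel <- st$vel
      }
      ep_loss <- ep_loss / length(samples)
      f1 <- validation_f1(net, normalizer, val, detect_args)
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                           val_macro_f1 = f1))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val macro-F1 %.4f",
                        epoch, ep_loss, f1))
      # select by validation macro-F1; among equal-F1 epochs prefer the
      # lower training loss (the more converged weights)
      if (f1 > best$f1 || (f1 == best$f1 && ep_loss < best$loss))
        best <- list(f1 = f1, loss = ep_loss, net = net, epoch = epoch)
    }
    list(checkpoint = list(network = best$net, normalizer = normalizer,
                           meta = list(seed = hp$seed, epoch = best$epoch,
                                       val_macro_f1 = best$f1,
                                       hyperparams = hp)),
         history = history)
  })
}

#' Grid search over learning rate and class weights
#'
#' Exhaustively trains one model per grid cell and selects the cell with
#' the best validation macro-F1 (ties broken by grid order). Cells whose
#' training aborts (e.g. a divergent learning rate) are marked failed and
#' never selected.
#'
#' @param samples,val,config,policy as in [train()].
#' @param learning_rates,class_weights lists/vectors of candidate values
#'   (class weight candidates are length-3 vectors).
#' @param hp_base base [hyperparams()] supplying epochs/momentum/seed.
#' @return list `best_hp`, `best` (the winning [train()] result), and
#'   `table` (data.frame of all cells with their scores).
#' @export
grid_search <- function(samples, val, learning_rates, class_weights,
                        hp_base = hyperparams(), config = network_config(),
                        policy = augmentation_policy()) {
  if (length(learning_rates) == 0 || length(class_weights) == 0)
    pc_stop("pc_spec_error", "grid must be nonempty")
  if (!is.list(class_weights)) class_weights <- list(class_weights)
  tab <- data.frame()
  best <- NULL; best_hp <- NULL; best_f1 <- -Inf
  for (lr in learning_rates) {
    for (cw in class_weights) {
      hp <- hp_base
      hp$learning_rate <- lr
      hp$class_weights <- as.numeric(cw)
      res <- tryCatch(train(samples, val, hp, config, policy),
                      pc_training_error = function(e) e)
      failed <- inherits(res, "condition")
      f1 <- if (failed) NA_real_ else res$checkpoint$meta$val_macro_f1
      tab <- rbind(tab, data.frame(
        learning_rate = lr, w_bg = cw[1], w_neg = cw[2], w_pos = cw[3],
        val_macro_f1 = f1, failed = failed))
      if (!failed && f1 > best_f1) {
        best_f1 <- f1; best <- res; best_hp <- hp
      }
    }
  }
  if (is.null(best))
    pc_stop("pc_training_error", "every grid cell failed")
  list(best_hp = best_hp, best = best, table = tab)
}
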