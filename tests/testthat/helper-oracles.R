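# Independent oracles used across the suite. These are deliberately
# naive (loops, enumeration, stats::aov) so they share no code with the
# implementation paths they check.

# greedy score-descending peak suppression, written with plain loops
oracle_detect_peaks <- function(map, min_distance = 10, threshold = 0.5) {
  H <- nrow(map); W <- ncol(map)
  cand <- list()
  for (r in 1:H) for (c in 1:W) {
    v <- map[r, c]
    if (v < threshold) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- min(max(r + dr, 1), H)
      cc <- min(max(c + dc, 1), W)
      if (map[rr, cc] > v) ok <- FALSE
    }
    if (ok) cand[[length(cand) + 1]] <- c(x = c - 1, y = r - 1, score = v)
  }
  if (length(cand) == 0)
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "score"], cand[, "y"], cand[, "x"]), ,
               drop = FALSE]
  acc <- matrix(numeric(0), ncol = 2)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    far <- TRUE
    if (nrow(acc) > 0) {
      d <- sqrt((acc[, 1] - cand[i, "x"])^2 + (acc[, 2] - cand[i, "y"])^2)
      far <- all(d > min_distance)
    }
    if (far) {
      keep[i] <- TRUE
      acc <- rbind(acc, cand[i, c("x", "y")])
    }
  }
  out <- as.data.frame(cand[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

# all permutations of a vector (n <= 7)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# exhaustive-enumeration matching under the distance gate: maximize the
# number of pairs within threshold, then minimize their total distance
oracle_match <- function(truth, det, threshold = 15) {
  n <- nrow(truth); m <- nrow(det)
  if (n == 0 || m == 0) return(list(n_matched = 0L, total = 0))
  d <- sqrt(outer(truth$x, det$x, `-`)^2 + outer(truth$y, det$y, `-`)^2)
  best <- list(n_matched = -1L, total = Inf)
  small_is_truth <- n <= m
  small <- if (small_is_truth) n else m
  large <- if (small_is_truth) m else n
  for (p in all_perms(seq_len(large))) {
    sel <- p[seq_len(small)]
    dd <- if (small_is_truth) d[cbind(seq_len(small), sel)]
          else d[cbind(sel, seq_len(small))]
    inl <- dd <= threshold
    cnt <- sum(inl)
    tot <- sum(dd[inl])
    if (cnt > best$n_matched ||
        (cnt == best$n_matched && tot < best$total - 1e-12))
      best <- list(n_matched = cnt, total = tot)
  }
  best
}

# two-way ANOVA mean squares via stats::aov, then the ICC(A,1) formula
oracle_icc <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small-world fixtures ---------------------------------------------------

tiny_spec <- function(seed = 7, ...) {
  scene_spec(width = 96, height = 96, n_positive = 2, n_negative = 6,
             n_artifact_blobs = 0, seed = seed, ...)
}

make_patch_samples <- function(n, seed0, spec_fn = scene_spec) {
  lapply(seq_len(n), function(i)
    scene_sample(generate_patch(spec_fn(seed = seed0 + i))))
}

# a deterministic random-weight checkpoint for contract tests that do not
# need a trained model
untrained_checkpoint <- function(seed = 1) {
  cfg <- network_config()
  list(network = build_network(cfg, seed = seed),
       normalizer = list(mean = c(128, 128, 128), sd = c(60, 60, 60)),
       meta = list(seed = seed, epoch = 0, val_macro_f1 = NA))
}

# planted Gaussian bumps on a zero map
plant_gaussians <- function(H, W, centers, amps, sigma = 2) {
  m <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    gy <- matrix(seq_len(H) - 1 - centers[i, 2], H, W)
    gx <- matrix(rep(seq_len(W) - 1 - centers[i, 1], each = H), H, W)
    m <- m + amps[i] * exp(-(gx^2 + gy^2) / (2 * sigma^2))
  }
  m
}
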