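# Peak-based cell detection on class pseudoprobability heatmaps: 3x3
# median filtering followed by Gaussian blur, then local-maximum peak
# calling under a minimum-distance constraint of 10 px, per class, with a
# cross-class merge so one cell is never counted as both classes.

#' Smooth a heatmap for peak calling
#'
#' Applies a 3x3 median filter (kills single-pixel impulses) followed by a
#' Gaussian blur, both with symmetric-reflection boundary handling. Values
#' in `[0, 1]` stay in `[0, 1]`.
#'
#' @param map numeric matrix of finite values.
#' @param sigma Gaussian standard deviation in pixels (default 1.0).
#' @return smoothed matrix of the same size.
#' @export
smooth_heatmap <- function(map, sigma = 1.0) {
  if (anyNA(map) || any(!is.finite(map)))
    pc_stop("pc_format_error", "heatmap contains non-finite values")
  cpp_gaussian_blur(cpp_median3(map), sigma)
}

# shift a matrix by (dr, dc) with edge duplication
shift_edge <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- clip(seq_len(H) - dr, 1L, H)
  ci <- clip(seq_len(W) - dc, 1L, W)
  m[ri, ci, drop = FALSE]
}

#' Detect peaks in a smoothed heatmap
#'
#' Returns local maxima with score at or above `threshold`, greedily
#' suppressed in descending score order so that every returned pair of
#' peaks is strictly farther apart than `min_distance` (Euclidean, px).
#' Ties in score are broken in row-major scan order (by `y`, then `x`).
#'
#' @param map smoothed numeric matrix.
#' @param min_distance minimum separation; peaks at distance
#'   `<= min_distance` from an accepted higher peak are suppressed.
#'   Default 10 px.
#' @param threshold minimum peak score, default 0.5 (majority class under
#'   the 3-way softmax).
#' @return data.frame `x`, `y` (0-based), `score`, possibly empty.
#' @export
detect_peaks <- function(map, min_distance = 10, threshold = 0.5) {
  H <- nrow(map); W <- ncol(map)
  is_max <- matrix(TRUE, H, W)
  for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & map >= shift_edge(map, dr, dc)
  }
  cand <- which(is_max & map >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0)))
  sc <- map[cand]
  xs <- cand[, 2] - 1L
  ys <- cand[, 1] - 1L
  ord <- order(-sc, ys, xs)
  greedy_suppress(xs[ord], ys[ord], sc[ord], min_distance)
}

# accept candidates in the given order unless within min_distance of an
# already accepted point (shared by detect_peaks and the cross-class merge)
greedy_suppress <- function(xs, ys, sc, min_distance, labels = NULL) {
  keep <- logical(length(xs))
  ax <- numeric(0); ay <- numeric(0)
  for (i in seq_along(xs)) {
    if (length(ax) == 0 ||
        min((ax - xs[i])^2 + (ay - ys[i])^2) > min_distance^2) {
      keep[i] <- TRUE
      ax <- c(ax, xs[i]); ay <- c(ay, ys[i])
    }
  }
  out <- data.frame(x = as.integer(xs[keep]), y = as.integer(ys[keep]),
                    score = sc[keep])
  if (!is.null(labels)) out$class <- labels[keep]
  out
}

#' Call class-labeled cell detections from heatmaps
#'
#' Smooths the CD138- and CD138+ maps, finds peaks in each independently,
#' then merges across classes: where a negative and a positive peak lie
#' within `min_distance` of each other, the higher-scoring one wins (exact
#' ties go to the positive class). Detections are returned sorted by
#' `(y, x)`.
#'
#' @param heatmaps a `class_heatmaps` object from [predict_heatmaps()].
#' @param min_distance minimum peak separation, default 10 px.
#' @param threshold minimum peak pseudoprobability, default 0.5.
#' @param sigma Gaussian smoothing sd, default 1.0 px.
#' @param presmoothed set TRUE if `heatmaps` are already smoothed.
#' @return data.frame `x`, `y`, `score`, `class` (`neg`/`pos`).
#' @export
call_detections <- function(heatmaps, min_distance = 10, threshold = 0.5,
                            sigma = 1.0, presmoothed = FALSE) {
  stopifnot(inherits(heatmaps, "class_heatmaps"))
  per_class <- lapply(c(neg = "neg", pos = "pos"), function(cl) {
    m <- heatmaps[[cl]]
    if (!presmoothed) m <- smooth_heatmap(m, sigma)
    pk <- detect_peaks(m, min_distance, threshold)
    if (nrow(pk) > 0) pk$class <- cl
    pk
  })
  allpk <- do.call(rbind, per_class[vapply(per_class, nrow, 1L) > 0])
  if (is.null(allpk) || nrow(allpk) == 0)
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  # positive-first tie-break, then score-descending greedy merge
  ord <- order(-allpk$score, allpk$class != "pos", allpk$y, allpk$x)
  merged <- greedy_suppress(allpk$x[ord], allpk$y[ord], allpk$score[ord],
                            min_distance, labels = allpk$class[ord])
  rownames(merged) <- NULL
  merged[order(merged$y, merged$x), , drop = FALSE]
}
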