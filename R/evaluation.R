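# Concordance evaluation: detections are paired with ground-truth
# annotations by a linear sum assignment on Euclidean distances under a
# 15 px (3.75 um) gate, feeding a three-class confusion matrix over
# {CD138-, CD138+, background} from which macro-averaged F1 is computed.
# Agreement between raters/methods on plasma-cell percentages uses the
# two-way random-effects absolute-agreement single-measure ICC.

# O(n^3) Hungarian algorithm (shortest augmenting path with potentials)
# for a square cost matrix; returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) pc_stop("pc_spec_error", "cost matrix must be square")
  if (n == 0) return(integer(0))
  # arrays indexed 1..n+1 where index 1 is the virtual column 0
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Match detections to ground-truth points by linear sum assignment
#'
#' Solves the minimum-total-cost assignment on the Euclidean distance
#' matrix in which every distance above `threshold` is replaced by a
#' sentinel cost `B = threshold * (n + m) + 1` (larger than any feasible
#' total of real distances, so the solver maximizes the number of gated
#' matches before minimizing distance). Pairs assigned at the sentinel
#' cost are discarded as unmatched. Matching is class-agnostic; classes
#' are compared downstream in the confusion matrix.
#'
#' @param truth,detections data.frames with columns `x`, `y` (either may
#'   be empty).
#' @param threshold gating distance in pixels, default 15 (3.75 um at
#'   0.25 um/px).
#' @return object of class `match_result`: `pairs` (data.frame
#'   `truth_idx`, `det_idx`, `distance`), `unmatched_truth`,
#'   `unmatched_detections` (integer index vectors), `threshold`.
#' @export
match_points <- function(truth, detections, threshold = 15) {
  n <- nrow(truth); m <- nrow(detections)
  empty <- data.frame(truth_idx = integer(0), det_idx = integer(0),
                      distance = numeric(0))
  if (n == 0 || m == 0)
    return(structure(list(pairs = empty, unmatched_truth = seq_len(n),
                          unmatched_detections = seq_len(m),
                          threshold = threshold), class = "match_result"))
  d <- sqrt(outer(truth$x, detections$x, `-`)^2 +
            outer(truth$y, detections$y, `-`)^2)
  B <- threshold * (n + m) + 1
  cost <- matrix(B, max(n, m), max(n, m))
  gated <- d
  gated[gated > threshold] <- B
  cost[seq_len(n), seq_len(m)] <- gated
  assign <- solve_assignment(cost)
  ti <- seq_len(n)
  di <- assign[seq_len(n)]
  ok <- di <= m & cost[cbind(ti, di)] < B
  pairs <- data.frame(truth_idx = ti[ok], det_idx = di[ok],
                      distance = d[cbind(ti[ok], di[ok])])
  structure(list(pairs = pairs,
                 unmatched_truth = setdiff(seq_len(n), pairs$truth_idx),
                 unmatched_detections = setdiff(seq_len(m), pairs$det_idx),
                 threshold = threshold),
            class = "match_result")
}

CM_LEVELS <- c("neg", "pos", "bg")

#' Three-class confusion matrix from a match result
#'
#' Matched pairs count at (truth class, detection class); unmatched truth
#' at (truth class, background); unmatched detections at (background,
#' detection class). The (background, background) cell is identically 0.
#'
#' @param match a [match_points()] result.
#' @param truth_classes,det_classes class vectors (`neg`/`pos`) aligned
#'   with the point lists passed to [match_points()].
#' @return 3x3 integer matrix, rows = truth, columns = predicted, in
#'   order `neg`, `pos`, `bg`.
#' @export
confusion_matrix3 <- function(match, truth_classes, det_classes) {
  stopifnot(inherits(match, "match_result"))
  cm <- matrix(0L, 3, 3, dimnames = list(truth = CM_LEVELS,
                                         predicted = CM_LEVELS))
  for (k in seq_len(nrow(match$pairs))) {
    tc <- truth_classes[match$pairs$truth_idx[k]]
    dc <- det_classes[match$pairs$det_idx[k]]
    cm[tc, dc] <- cm[tc, dc] + 1L
  }
  for (i in match$unmatched_truth)
    cm[truth_classes[i], "bg"] <- cm[truth_classes[i], "bg"] + 1L
  for (j in match$unmatched_detections)
    cm["bg", det_classes[j]] <- cm["bg", det_classes[j]] + 1L
  cm
}

#' Macro-averaged F1 over the two cell classes
#'
#' Per-class F1 (`2TP / (2TP + FP + FN)`) for CD138- and CD138+ only;
#' background rows/columns contribute to FP/FN but not a class of their
#' own. A class with no truth and no predictions scores F1 = 1 by
#' convention so that perfectly handled empty patches do not penalize
#' model selection.
#'
#' @param cm 3x3 confusion matrix from [confusion_matrix3()].
#' @return macro-averaged F1 in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  f1 <- vapply(c("neg", "pos"), function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Plasma-cell percentage
#'
#' The marrow plasma-cell burden: CD138+ cells as a percentage of all
#' nucleated cells counted.
#'
#' @param n_pos,n_neg CD138+ and CD138- cell counts.
#' @return `100 * n_pos / (n_pos + n_neg)`.
#' @export
plasma_percentage <- function(n_pos, n_neg) {
  if (n_pos + n_neg <= 0)
    pc_stop("pc_undefined_percentage", "no cells: percentage undefined")
  100 * n_pos / (n_pos + n_neg)
}

#' Midpoint of a reported plasma-cell percentage
#'
#' Clinical reports state percentages as ranges ("5-10%"), single values
#' ("12%"), or qualitative phrases; for analysis the middle value of the
#' range is used, with "normal", "not increased" and "less than 5%" all
#' recorded as 2.5% (the middle of 0-5%).
#'
#' @param report character token.
#' @return numeric percentage.
#' @export
report_midpoint <- function(report) {
  tok <- tolower(trimws(report))
  if (tok %in% c("normal", "not increased", "less than 5%")) return(2.5)
  range_re <- "^([0-9]+\\.?[0-9]*)\\s*[-–—]\\s*([0-9]+\\.?[0-9]*)\\s*%$"
  if (grepl(range_re, tok)) {
    a <- as.numeric(sub(range_re, "\\1", tok))
    b <- as.numeric(sub(range_re, "\\2", tok))
    return((a + b) / 2)
  }
  single_re <- "^([0-9]+\\.?[0-9]*)\\s*%$"
  if (grepl(single_re, tok))
    return(as.numeric(sub(single_re, "\\1", tok)))
  pc_stop("pc_parse_error", "unparseable percentage report: '%s'", report)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measure ICC(A,1) from the two-way ANOVA decomposition of an
#' `n subjects x k raters` table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`, where MSR, MSC
#' and MSE are the subject, rater and residual mean squares. Absolute
#' agreement (unlike consistency) penalizes systematic offsets between
#' raters.
#'
#' @param ratings numeric matrix, `n >= 2` rows (subjects), `k >= 2`
#'   columns (raters), e.g. plasma-cell percentages per case.
#' @return ICC value; a table with zero total variance returns 1 with a
#'   warning.
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2)
    pc_stop("pc_spec_error", "need at least 2 subjects and 2 raters")
  if (anyNA(ratings) || any(!is.finite(ratings)))
    pc_stop("pc_format_error", "ratings must be finite")
  grand <- mean(ratings)
  if (all(ratings == ratings[1])) {
    warning("all ratings identical; ICC defined as 1")
    return(1.0)
  }
  rm_ <- rowMeans(ratings)
  cm_ <- colMeans(ratings)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Convert a pixel distance to microns
#'
#' @param d distance in pixels (>= 0).
#' @param pixel_size microns per pixel; 0.25 for a 40x scan.
#' @return distance in microns.
#' @export
pixels_to_microns <- function(d, pixel_size = 0.25) {
  if (any(d < 0)) pc_stop("pc_spec_error", "distance must be >= 0")
  d * pixel_size
}

#' Evaluate detections against ground truth on one patch
#'
#' Convenience wrapper: match, confusion matrix, macro-F1, and the
#' detected plasma-cell percentage.
#'
#' @param truth,detections data.frames `x`, `y`, `class`.
#' @param threshold matching gate in pixels, default 15.
#' @return list `match`, `confusion`, `macro_f1`, `percentage` (NA when
#'   no cells were detected).
#' @export
evaluate_detections <- function(truth, detections, threshold = 15) {
  m <- match_points(truth, detections, threshold)
  cm <- confusion_matrix3(m, truth$class, detections$class)
  n_pos <- sum(detections$class == "pos")
  n_neg <- sum(detections$class == "neg")
  list(match = m, confusion = cm, macro_f1 = macro_f1(cm),
       percentage = if (n_pos + n_neg > 0)
         plasma_percentage(n_pos, n_neg) else NA_real_)
}
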