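test_that("match_points handles identity, gating, and empty inputs", {
  pts <- data.frame(x = c(10, 50, 80), y = c(10, 20, 70))
  m <- match_points(pts, pts)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$pairs$distance, rep(0, 3))
  expect_length(m$unmatched_truth, 0)
  expect_length(m$unmatched_detections, 0)

  # 16 px apart exceeds the 15 px gate: both unmatched
  t1 <- data.frame(x = 10, y = 10)
  d1 <- data.frame(x = 26, y = 10)
  m16 <- match_points(t1, d1)
  expect_equal(nrow(m16$pairs), 0)
  expect_equal(m16$unmatched_truth, 1L)
  expect_equal(m16$unmatched_detections, 1L)
  # 15 px exactly is within the gate
  m15 <- match_points(t1, data.frame(x = 25, y = 10))
  expect_equal(nrow(m15$pairs), 1)

  me <- match_points(t1[0, ], d1)
  expect_equal(me$unmatched_detections, 1L)
})

test_that("assignment matching equals exhaustive enumeration on random instances", {
  withr::with_seed(2024, {
    for (rep in 1:200) {
      n <- sample(0:6, 1); m <- sample(0:6, 1)
      truth <- data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60))
      det <- data.frame(x = runif(m, 0, 60), y = runif(m, 0, 60))
      got <- match_points(truth, det)
      want <- oracle_match(truth, det)
      expect_equal(nrow(got$pairs), max(want$n_matched, 0))
      expect_equal(sum(got$pairs$distance), max(want$total, 0),
                   tolerance = 1e-9)
      expect_true(all(got$pairs$distance <= 15))
      # index uniqueness
      expect_false(anyDuplicated(got$pairs$truth_idx) > 0)
      expect_false(anyDuplicated(got$pairs$det_idx) > 0)
    }
  })
})

test_that("matching is invariant under rigid motion of both point sets", {
  withr::with_seed(5, {
    truth <- data.frame(x = runif(5, 0, 50), y = runif(5, 0, 50))
    det <- data.frame(x = truth$x + rnorm(5, 0, 4),
                      y = truth$y + rnorm(5, 0, 4))
  })
  base <- match_points(truth, det)
  th <- 0.7
  rot <- function(p) data.frame(x = cos(th) * p$x - sin(th) * p$y + 100,
                                y = sin(th) * p$x + cos(th) * p$y + 50)
  moved <- match_points(rot(truth), rot(det))
  expect_equal(moved$pairs$truth_idx, base$pairs$truth_idx)
  expect_equal(moved$pairs$det_idx, base$pairs$det_idx)
  expect_equal(moved$pairs$distance, base$pairs$distance, tolerance = 1e-9)
})

test_that("confusion matrix bookkeeping follows the matching", {
  # perfect detection: diagonal with class totals
  truth <- data.frame(x = c(10, 30, 50), y = c(10, 10, 10),
                      class = c("neg", "neg", "pos"))
  m <- match_points(truth, truth)
  cm <- confusion_matrix3(m, truth$class, truth$class)
  expect_equal(unname(diag(cm)), c(2, 1, 0))
  expect_equal(sum(cm), 3)
  expect_equal(macro_f1(cm), 1)

  # 1 positive truth, no detections -> (pos, bg)
  m0 <- match_points(data.frame(x = 1, y = 1),
                     data.frame(x = numeric(0), y = numeric(0)))
  cm0 <- confusion_matrix3(m0, "pos", character(0))
  expect_equal(cm0["pos", "bg"], 1L)
  expect_equal(sum(cm0), 1)

  # 10 truth (4 pos), one pos detected as neg, one spurious pos
  xs <- seq(0, 180, by = 20)
  truth10 <- data.frame(x = xs[1:10], y = 0,
                        class = c(rep("neg", 6), rep("pos", 4)))
  det10 <- data.frame(x = c(xs[1:10], 300), y = 0,
                      class = c(rep("neg", 6), "neg", rep("pos", 3), "pos"))
  mm <- match_points(truth10, det10)
  cmm <- confusion_matrix3(mm, truth10$class, det10$class)
  expect_equal(unname(cmm), rbind(c(6, 0, 0), c(1, 3, 0), c(0, 1, 0)))
  # hand-computed macro-F1: F1_neg = 2*6/(12+1+0) = 12/13,
  # F1_pos = 2*3/(6+1+1) = 3/4 (precision = recall = 3/4)
  expect_equal(macro_f1(cmm), (12 / 13 + 3 / 4) / 2, tolerance = 1e-12)

  # cell total = matched + unmatched truth + unmatched detections
  expect_equal(sum(cmm), nrow(mm$pairs) + length(mm$unmatched_truth) +
                 length(mm$unmatched_detections))
})

test_that("macro_f1 conventions and symmetry", {
  empty <- matrix(0L, 3, 3, dimnames = list(truth = c("neg", "pos", "bg"),
                                            predicted = c("neg", "pos", "bg")))
  expect_equal(macro_f1(empty), 1) # degenerate empty patch

  withr::with_seed(8, {
    cm <- matrix(sample(0:9, 9, replace = TRUE), 3, 3,
                 dimnames = dimnames(empty))
    cm[3, 3] <- 0L
  })
  swapped <- cm[c(2, 1, 3), c(2, 1, 3)]
  dimnames(swapped) <- dimnames(cm)
  expect_equal(macro_f1(cm), macro_f1(swapped))
})

test_that("plasma percentage arithmetic and guards", {
  expect_equal(plasma_percentage(2, 8), 20)
  expect_equal(plasma_percentage(0, 50), 0)
  expect_equal(plasma_percentage(50, 0), 100)
  expect_error(plasma_percentage(0, 0), class = "pc_undefined_percentage")
})

test_that("report midpoints follow the reading rules", {
  expect_equal(report_midpoint("5-10%"), 7.5)
  expect_equal(report_midpoint("5–10%"), 7.5) # en dash
  expect_equal(report_midpoint("not increased"), 2.5)
  expect_equal(report_midpoint("normal"), 2.5)
  expect_equal(report_midpoint("less than 5%"), 2.5)
  expect_equal(report_midpoint("12%"), 12)
  expect_error(report_midpoint("plenty"), class = "pc_parse_error")
})

test_that("icc_absolute matches the ANOVA oracle and its invariances", {
  # identical columns: perfect agreement
  y <- c(3, 8, 15, 22, 40)
  expect_equal(icc_absolute(cbind(y, y)), 1)

  # constant offset: strictly < 1 and decreasing in |offset|
  v2 <- icc_absolute(cbind(y, y + 2))
  v6 <- icc_absolute(cbind(y, y + 6))
  expect_lt(v2, 1)
  expect_lt(v6, v2)
  expect_equal(v2, oracle_icc(cbind(y, y + 2)), tolerance = 1e-10)

  # random tables against the explicit sums-of-squares oracle
  withr::with_seed(99, {
    for (rep in 1:100) {
      tab <- matrix(runif(20, 0, 50), 10, 2)
      expect_equal(icc_absolute(tab), oracle_icc(tab), tolerance = 1e-10)
    }
  })

  # invariance under a common positive affine map
  withr::with_seed(100, {
    tab <- matrix(runif(30, 0, 50), 10, 3)
  })
  expect_equal(icc_absolute(tab), icc_absolute(3.2 * tab + 11),
               tolerance = 1e-9)

  expect_warning(ve <- icc_absolute(matrix(5, 4, 2)), "identical")
  expect_equal(ve, 1)
  expect_error(icc_absolute(matrix(1:2, 1, 2)), class = "pc_spec_error")
})

test_that("pixel-micron conversion", {
  expect_equal(pixels_to_microns(15), 3.75)
  expect_equal(pixels_to_microns(512), 128)
  expect_equal(pixels_to_microns(0), 0)
  expect_error(pixels_to_microns(-1), class = "pc_spec_error")
})
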