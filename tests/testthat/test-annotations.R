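test_that("encode_labels places class codes at point pixels", {
  pts <- data.frame(x = c(10, 30), y = c(12, 40),
                    class = c("neg", "pos"), stringsAsFactors = FALSE)
  r <- encode_labels(pts, c(64, 64))
  expect_equal(r[13, 11], 1L) # (x=10, y=12) -> row 13, col 11
  expect_equal(r[41, 31], 2L)
  expect_equal(sum(r != 0), 2)

  expect_equal(sum(encode_labels(pts[0, ], c(16, 16))), 0)

  expect_error(encode_labels(data.frame(x = 70, y = 1, class = "neg"),
                             c(64, 64)), class = "pc_bounds_error")
  dup <- data.frame(x = c(5, 5), y = c(5, 5), class = c("neg", "pos"))
  expect_error(encode_labels(dup, c(64, 64)), class = "pc_duplicate_error")
})

test_that("encode/decode roundtrip is the identity on random point sets", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- sample(0:40, 1)
      pix <- sample(64 * 64, n) - 1
      pts <- data.frame(x = pix %% 64, y = pix %/% 64,
                        class = sample(c("neg", "pos"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
      pts <- pts[order(pts$y, pts$x), , drop = FALSE]
      rownames(pts) <- NULL
      back <- decode_labels(encode_labels(pts, c(64, 64)))
      rownames(back) <- NULL
      expect_equal(back, pts)
    }
  })
})

test_that("dilate_labels grows discs with max semantics", {
  pts <- data.frame(x = 20, y = 20, class = "pos")
  r <- encode_labels(pts, c(41, 41))
  expect_identical(dilate_labels(r, 0), r)
  d <- dilate_labels(r, 5)
  # Euclidean disc of radius 5 contains exactly 81 pixels
  expect_equal(sum(d == 2), 81)
  gy <- row(d) - 21; gx <- col(d) - 21
  expect_true(all((d == 2) == (gx^2 + gy^2 <= 25)))

  # a value-1 and value-2 point 6 px apart: overlap pixels carry 2
  two <- encode_labels(data.frame(x = c(20, 26), y = c(20, 20),
                                  class = c("neg", "pos")), c(41, 41))
  expect_message(d2 <- dilate_labels(two, 5), "overlap")
  d1only <- dilate_labels(encode_labels(
    data.frame(x = 20, y = 20, class = "neg"), c(41, 41)), 5)
  dposonly <- dilate_labels(encode_labels(
    data.frame(x = 26, y = 20, class = "pos"), c(41, 41)), 5)
  expect_identical(d2, pmax(d1only, dposonly))
  expect_true(any(d1only > 0 & dposonly > 0)) # they do overlap
  expect_true(all(d2[d1only > 0 & dposonly > 0] == 2))

  # dilation is extensive: output >= input pointwise
  expect_true(all(d2 >= two))
})

test_that("export_tile pads with reflection and drops pad-ring labels", {
  withr::with_seed(9, {
    img <- array(runif(200 * 200 * 3, 0, 255), dim = c(200, 200, 3))
  })
  pts <- data.frame(x = c(60, 40), y = c(70, 95), class = c("pos", "neg"))
  lbl <- encode_labels(pts, c(200, 200))

  out <- export_tile(img, lbl, tile_spec(50, 60, core_size = 64, pad = 32))
  expect_equal(dim(out$image), c(128, 128, 3))
  # the (60,70) point is inside the core; (40,95) lies in the pad ring
  expect_equal(sum(out$labels != 0), 1)
  expect_equal(out$labels[70 - 60 + 32 + 1, 60 - 50 + 32 + 1], 2L)

  # pad 0 is a plain crop
  crop <- export_tile(img, lbl, tile_spec(0, 0, core_size = 64, pad = 0))
  expect_identical(crop$image, img[1:64, 1:64, ])

  # default geometry: 512 core + 2 * 32 pad = 576
  big <- array(0, dim = c(600, 600, 3))
  lb <- matrix(0L, 600, 600)
  expect_equal(dim(export_tile(big, lb, tile_spec(20, 20))$image)[1:2],
               c(576, 576))

  expect_error(export_tile(img, lbl, tile_spec(150, 150, core_size = 64)),
               class = "pc_bounds_error")
})

test_that("pad-0 tiles over a grid reconstruct the parent exactly", {
  withr::with_seed(4, {
    img <- array(runif(128 * 128 * 3, 0, 255), dim = c(128, 128, 3))
  })
  lbl <- matrix(0L, 128, 128)
  rec <- array(0, dim(img))
  for (ty in c(0, 64)) for (tx in c(0, 64)) {
    tl <- export_tile(img, lbl, tile_spec(tx, ty, core_size = 64, pad = 0))
    rec[ty + 1:64, tx + 1:64, ] <- tl$image
  }
  expect_identical(rec, img)
})

test_that("point files roundtrip and reject malformed input", {
  withr::with_seed(13, {
    pts <- data.frame(x = sample(0:2047, 100), y = sample(0:2047, 100),
                      class = sample(c("neg", "pos"), 100, replace = TRUE),
                      stringsAsFactors = FALSE)
  })
  f <- tempfile(fileext = ".tsv")
  write_points(f, pts)
  expect_equal(read_points(f), pts)

  writeLines("x\ty\tclass", f)
  expect_equal(nrow(read_points(f)), 0)

  writeLines(c("x\ty\tclass", "5\t6\tmaybe"), f)
  expect_error(read_points(f), class = "pc_parse_error")
  expect_error(read_points(f), "line 2")

  writeLines(c("x\ty\tclass", "5\t6"), f)
  expect_error(read_points(f), class = "pc_parse_error")
  unlink(f)
})
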