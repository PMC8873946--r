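ppm_bytes <- function(image) {
  f <- tempfile(fileext = ".ppm")
  on.exit(unlink(f))
  write_ppm(image, f)
  readBin(f, "raw", n = file.size(f))
}

test_that("analyze_snapshot validates input and reports structured results", {
  ck <- untrained_checkpoint()
  sc <- generate_patch(tiny_spec(seed = 41))
  res <- analyze_snapshot(sc$image, ck)
  expect_s3_class(res, "snapshot_result")
  expect_equal(dim(res$overlay), dim(sc$image))
  expect_equal(res$n_pos + res$n_neg, nrow(res$detections))
  if (res$percentage_defined)
    expect_equal(res$percentage, plasma_percentage(res$n_pos, res$n_neg))

  # determinism: same image twice gives identical results
  res2 <- analyze_snapshot(sc$image, ck)
  expect_identical(res[c("n_pos", "n_neg", "percentage")],
                   res2[c("n_pos", "n_neg", "percentage")])

  # non-divisible sizes are handled by reflect padding, margin discarded
  odd <- sc$image[1:95, 1:93, , drop = FALSE]
  ro <- analyze_snapshot(odd, ck)
  expect_equal(dim(ro$overlay), dim(odd))
  expect_true(all(ro$detections$x < 93 & ro$detections$y < 95))

  expect_error(analyze_snapshot(sc$image, ck, max_dim = 64),
               class = "pc_size_error")
  expect_error(analyze_snapshot(matrix(0, 8, 8), ck),
               class = "pc_format_error")
})

test_that("a blank background image yields 0/0 with undefined percentage", {
  ck <- untrained_checkpoint()
  # zero the head so all maps are 1/3 < threshold: no detections at all
  last <- length(ck$network$layers)
  ck$network$layers[[last]]$w[] <- 0
  ck$network$layers[[last]]$b[] <- 0
  blank <- array(235, dim = c(64, 64, 3))
  res <- analyze_snapshot(blank, ck)
  expect_equal(res$n_pos, 0)
  expect_equal(res$n_neg, 0)
  expect_false(res$percentage_defined)
  expect_true(is.na(res$percentage))
})

test_that("the request handler implements the service contract", {
  ck <- untrained_checkpoint()
  sc <- generate_patch(tiny_spec(seed = 43))

  h <- handle_request("GET", "/health", checkpoint = ck)
  expect_equal(h$status, 200L)
  hj <- jsonlite::fromJSON(h$body)
  expect_equal(hj$status, "ok")
  expect_match(hj$model, "plasmacount")

  # POST a PPM -> 200 with counts and percentage fields
  r <- handle_request("POST", "/analyze", body = ppm_bytes(sc$image),
                      content_type = "image/x-portable-pixmap",
                      checkpoint = ck)
  expect_equal(r$status, 200L)
  rj <- jsonlite::fromJSON(r$body)
  expect_true(all(c("n_pos", "n_neg", "percentage") %in% names(rj)))
  expect_equal(rj$overlay_height, 96)

  # multipart upload of the same image gives the identical payload
  bd <- "----testboundary42"
  part <- c(charToRaw(sprintf("--%s\r\n", bd)),
            charToRaw("Content-Disposition: form-data; name=\"file\"; filename=\"a.ppm\"\r\nContent-Type: image/x-portable-pixmap\r\n\r\n"),
            ppm_bytes(sc$image),
            charToRaw(sprintf("\r\n--%s--\r\n", bd)))
  rm_ <- handle_request("POST", "/analyze", body = part,
                        content_type = paste0("multipart/form-data; boundary=", bd),
                        checkpoint = ck)
  expect_equal(rm_$status, 200L)
  expect_equal(jsonlite::fromJSON(rm_$body)$n_pos, rj$n_pos)

  # a text file is rejected as undecodable
  bad <- handle_request("POST", "/analyze", body = charToRaw("hello world"),
                        content_type = "text/plain", checkpoint = ck)
  expect_equal(bad$status, 415L)

  # empty and oversized uploads
  expect_equal(handle_request("POST", "/analyze", body = raw(0),
                              checkpoint = ck)$status, 400L)
  expect_equal(handle_request("POST", "/analyze", body = raw(10),
                              checkpoint = ck, max_bytes = 5)$status, 413L)

  expect_equal(handle_request("GET", "/nope", checkpoint = ck)$status, 404L)
})

test_that("overlay marks every detection and draws a scale bar", {
  ck <- untrained_checkpoint()
  img <- array(128, dim = c(96, 96, 3))
  det <- data.frame(x = c(20, 60), y = c(20, 60), score = c(0.9, 0.8),
                    class = c("pos", "neg"))
  ov <- draw_overlay(img, det, pixel_size = 0.25)
  expect_equal(dim(ov), dim(img))
  # marker rings recolor pixels near each detection
  expect_false(all(ov[17:25, 17:25, 1] == 128))
  expect_false(all(ov[57:65, 57:65, 1] == 128))
  # scale bar: 10 um at 0.25 um/px = 40 px of dark pixels near bottom-left
  expect_true(all(ov[86:89, 6:45, 1] == 20))
})

test_that("serve() refuses a missing checkpoint path", {
  expect_error(serve(tempfile(fileext = ".rds")), class = "pc_io_error")
})
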