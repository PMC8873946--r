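# Snapshot-analysis service: a microscope-camera snapshot is uploaded,
# run through the detection pipeline once, and answered with absolute
# CD138+/CD138- counts, the plasma-cell percentage, and a labeled overlay
# with a scale bar. The request handler is a pure function of
# (checkpoint, request), so responses carry no hidden state; a minimal
# blocking HTTP loop over a base-R socket is provided for interactive
# use, since no web framework is available in this toolchain.

#' Analyze a single snapshot image
#'
#' Reflect-pads the image to the network's divisibility constraint (any
#' detection landing in that padded margin is discarded), runs heatmap
#' prediction and peak calling, and assembles counts, percentage and a
#' class-labeled overlay. Deterministic for a fixed checkpoint.
#'
#' @param image `H x W x 3` array, 0-255.
#' @param checkpoint trained model checkpoint.
#' @param pixel_size microns per pixel for the scale bar, default 0.25.
#' @param max_dim reject images with a side beyond this bound.
#' @param detect_args overrides for [call_detections()].
#' @return object of class `snapshot_result`: `n_pos`, `n_neg`,
#'   `percentage` (`NA` with `percentage_defined = FALSE` when no cells),
#'   `detections`, `overlay` (same dims as input), `pixel_size`,
#'   `model_id`.
#' @export
analyze_snapshot <- function(image, checkpoint, pixel_size = 0.25,
                             max_dim = 4096, detect_args = list()) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    pc_stop("pc_format_error", "snapshot must decode to an RGB image")
  if (d[1] > max_dim || d[2] > max_dim)
    pc_stop("pc_size_error", "snapshot %dx%d exceeds the %d px bound",
            d[1], d[2], max_dim)
  div <- 2^(checkpoint$network$config$n_stages - 1)
  pd <- pad_to_divisible(image, div)
  hm <- predict_heatmaps(checkpoint$network, pd$image, checkpoint$normalizer,
                         pixel_size)
  det <- do.call(call_detections, c(list(hm), detect_args))
  det <- det[det$x < d[2] & det$y < d[1], , drop = FALSE]
  rownames(det) <- NULL
  n_pos <- sum(det$class == "pos")
  n_neg <- sum(det$class == "neg")
  defined <- n_pos + n_neg > 0
  structure(list(
    n_pos = n_pos, n_neg = n_neg,
    percentage = if (defined) plasma_percentage(n_pos, n_neg) else NA_real_,
    percentage_defined = defined,
    detections = det,
    overlay = draw_overlay(image, det, pixel_size),
    pixel_size = pixel_size,
    model_id = checkpoint_id(checkpoint)),
    class = "snapshot_result")
}

checkpoint_id <- function(checkpoint) {
  m <- checkpoint$meta
  sprintf("plasmacount-seed%s-epoch%s",
          if (is.null(m$seed)) "NA" else m$seed,
          if (is.null(m$epoch)) "NA" else m$epoch)
}

MARKER_COLORS <- list(pos = c(255, 140, 0), neg = c(30, 90, 255))

#' Draw a class-labeled overlay with a scale bar
#'
#' Marks each detection with a small class-colored circle (orange for
#' CD138+, blue for CD138-) and draws a 10 um scale bar at the bottom
#' left.
#'
#' @param image `H x W x 3` array.
#' @param detections data.frame `x`, `y`, `class`.
#' @param pixel_size microns per pixel (sets the scale-bar length).
#' @return overlay array, same dims as `image`.
#' @export
draw_overlay <- function(image, detections, pixel_size = 0.25) {
  H <- dim(image)[1]; W <- dim(image)[2]
  for (i in seq_len(nrow(detections))) {
    col <- MARKER_COLORS[[detections$class[i]]]
    image <- paint_annulus(image, detections$x[i], detections$y[i],
                           4.5, col, r_inner = 2.5)
  }
  bar_px <- max(2L, round(10 / pixel_size)) # 10 um
  if (bar_px < W - 12) {
    rows <- (H - 10):(H - 7)
    cols <- 6:(6 + bar_px - 1)
    for (ch in 1:3) image[rows, cols, ch] <- c(20, 20, 20)[ch]
  }
  image
}

json_response <- function(status, payload) {
  list(status = status, content_type = "application/json",
       body = jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                               null = "null", na = "null"))
}

# extract the first file payload from a multipart/form-data body
parse_multipart <- function(body, content_type) {
  bd <- sub(".*boundary=", "", content_type)
  if (!nzchar(bd)) pc_stop("pc_format_error", "multipart without boundary")
  marker <- charToRaw(paste0("--", bd))
  # locate part boundaries in the raw body
  hits <- which(vapply(seq_len(length(body) - length(marker) + 1L),
                       function(i) all(body[i + seq_along(marker) - 1L] == marker),
                       logical(1)))
  if (length(hits) < 2) pc_stop("pc_format_error", "malformed multipart body")
  start <- hits[1] + length(marker)
  end <- hits[2] - 1L
  part <- body[start:end]
  sep <- charToRaw("\r\n\r\n")
  pos <- which(vapply(seq_len(length(part) - 3L),
                      function(i) all(part[i + 0:3] == sep), logical(1)))
  if (length(pos) == 0) pc_stop("pc_format_error", "multipart part lacks header")
  payload <- part[(pos[1] + 4L):length(part)]
  # strip the trailing CRLF before the closing boundary
  n <- length(payload)
  if (n >= 2 && payload[n - 1L] == as.raw(13) && payload[n] == as.raw(10))
    payload <- payload[seq_len(n - 2L)]
  payload
}

#' Handle one HTTP-style request against a loaded model
#'
#' The pure core of the snapshot service; [serve()] is a thin socket loop
#' around it. Routes: `GET /health` returns the model id; `POST /analyze`
#' accepts an image (raw PPM/PGM bytes, or multipart/form-data whose
#' first part is the image) and returns counts, percentage and overlay
#' dimensions as JSON.
#'
#' @param method,path request line components.
#' @param body raw vector (may be `NULL` for GET).
#' @param content_type request content type.
#' @param checkpoint trained model checkpoint.
#' @param max_bytes upload size limit, default 32 MiB.
#' @return list `status`, `content_type`, `body` (JSON string).
#' @export
handle_request <- function(method, path, body = NULL, content_type = "",
                           checkpoint, max_bytes = 32 * 1024^2) {
  if (method == "GET" && path == "/health")
    return(json_response(200L, list(status = "ok",
                                    model = checkpoint_id(checkpoint))))
  if (method == "POST" && path == "/analyze") {
    if (is.null(body) || length(body) == 0)
      return(json_response(400L, list(error = "empty upload")))
    if (length(body) > max_bytes)
      return(json_response(413L, list(error = "upload too large")))
    if (grepl("multipart/form-data", content_type, fixed = TRUE)) {
      body <- tryCatch(parse_multipart(body, content_type),
                       pc_error = function(e) e)
      if (inherits(body, "condition"))
        return(json_response(400L, list(error = conditionMessage(body))))
    }
    img <- tryCatch(decode_pnm_bytes(body), pc_error = function(e) e,
                    error = function(e) e)
    if (inherits(img, "condition") || is.matrix(img))
      return(json_response(415L,
                           list(error = "could not decode upload as a PPM image")))
    res <- tryCatch(analyze_snapshot(img, checkpoint),
                    pc_size_error = function(e) e,
                    pc_format_error = function(e) e)
    if (inherits(res, "condition"))
      return(json_response(if (inherits(res, "pc_size_error")) 413L else 415L,
                           list(error = conditionMessage(res))))
    return(json_response(200L, list(
      n_pos = res$n_pos, n_neg = res$n_neg,
      percentage = res$percentage,
      percentage_defined = res$percentage_defined,
      pixel_size = res$pixel_size, model = res$model_id,
      overlay_height = dim(res$overlay)[1],
      overlay_width = dim(res$overlay)[2])))
  }
  json_response(404L, list(error = sprintf("no route for %s %s", method, path)))
}

#' Serve the snapshot-analysis service over HTTP
#'
#' A minimal single-threaded blocking server over a base-R socket; each
#' request is answered by [handle_request()]. Intended for local use.
#'
#' @param checkpoint trained model checkpoint (or a path loadable by
#'   [load_checkpoint()]).
#' @param port TCP port, default 8080.
#' @param max_requests stop after this many requests (Inf = run forever).
#' @export
serve <- function(checkpoint, port = 8080, max_requests = Inf) {
  if (is.character(checkpoint)) {
    if (!file.exists(checkpoint))
      pc_stop("pc_io_error", "checkpoint not found: %s", checkpoint)
    checkpoint <- load_checkpoint(checkpoint)
  }
  message(sprintf("plasmacount service on port %d (model %s)", port,
                  checkpoint_id(checkpoint)))
  served <- 0
  while (served < max_requests) {
    con <- suppressWarnings(socketConnection(
      host = "127.0.0.1", port = port, server = TRUE, blocking = TRUE,
      open = "r+b", timeout = 30))
    req <- tryCatch(read_http_request(con), error = function(e) NULL)
    if (!is.null(req)) {
      resp <- handle_request(req$method, req$path, req$body,
                             req$content_type, checkpoint)
      body_raw <- charToRaw(as.character(resp$body))
      hdr <- sprintf(paste0("HTTP/1.1 %d OK\r\nContent-Type: %s\r\n",
                            "Content-Length: %d\r\nConnection: close\r\n\r\n"),
                     resp$status, resp$content_type, length(body_raw))
      writeBin(c(charToRaw(hdr), body_raw), con)
    }
    close(con)
    served <- served + 1
  }
  invisible(served)
}

read_http_request <- function(con) {
  request_line <- readLines(con, n = 1)
  parts <- strsplit(request_line, " ")[[1]]
  headers <- character(0)
  repeat {
    h <- readLines(con, n = 1)
    if (length(h) == 0 || !nzchar(h)) break
    headers <- c(headers, h)
  }
  get_header <- function(name) {
    hit <- grep(paste0("^", name, ":"), headers, ignore.case = TRUE,
                value = TRUE)
    if (length(hit) == 0) "" else trimws(sub("^[^:]+:", "", hit[1]))
  }
  clen <- suppressWarnings(as.integer(get_header("Content-Length")))
  body <- if (!is.na(clen) && clen > 0) readBin(con, "raw", n = clen) else NULL
  list(method = parts[1], path = parts[2], body = body,
       content_type = get_header("Content-Type"))
}
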