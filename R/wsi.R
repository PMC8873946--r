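# Shift-and-stitch whole-slide inference: a sliding window (2048 px by
# default) is padded by 32 px of context on each side (2112 px network
# input), predictions are made per padded tile, detections falling in the
# pad ring are discarded (they belong to the owning neighbor), and
# core-local detections are offset back into slide coordinates. With pad
# at least the network's receptive-field radius this makes stitching
# exact and independent of tile order, with no deduplication needed.
# Reads beyond the slide border use reflection padding.

#' Slide reader over an in-memory image
#'
#' The minimal slide abstraction used for inference: a function
#' `f(x0, y0, w, h)` returning the requested region with mirror
#' reflection outside the slide, carrying `width`/`height` attributes.
#' [ppm_slide_reader()] wraps an image stored as a PPM file.
#'
#' @param image `H x W x 3` array.
#' @return object of class `slide_reader`.
#' @export
array_slide_reader <- function(image) {
  d <- dim(image)
  structure(function(x0, y0, w, h) mirror_crop(image, x0, y0, w, h),
            width = d[2], height = d[1], class = "slide_reader")
}

#' @rdname array_slide_reader
#' @param path path to a P6 PPM file.
#' @export
ppm_slide_reader <- function(path) array_slide_reader(read_pnm(path))

#' Plan the tiling of a slide
#'
#' Covers the slide with a row-major grid of disjoint `window`-sized core
#' rectangles, truncating the last row/column at the slide edge. When a
#' tissue mask is supplied (possibly at a stated downsample factor),
#' tiles whose core contains no masked pixel are omitted.
#'
#' @param width,height slide dimensions at level 0, pixels.
#' @param window core window size, default 2048 px.
#' @param pad context padding per side, default 32 px (network input
#'   `window + 2 pad`, 2112 by default).
#' @param mask optional logical matrix; `mask_downsample` gives its
#'   scale relative to level 0.
#' @param mask_downsample positive integer downsample factor.
#' @return object of class `tiling_plan`: list with `tiles` (list of
#'   `x`, `y`, `w`, `h`, `id`), `window`, `pad`, `width`, `height`,
#'   `mask`, `mask_downsample`.
#' @export
plan_tiles <- function(width, height, window = 2048, pad = 32,
                       mask = NULL, mask_downsample = 1) {
  if (width < 1 || height < 1 || window < 1 || pad < 0)
    pc_stop("pc_spec_error", "invalid slide/window geometry")
  if (!is.null(mask)) {
    exp_dim <- c(ceiling(height / mask_downsample),
                 ceiling(width / mask_downsample))
    if (!identical(dim(mask), as.integer(exp_dim)))
      pc_stop("pc_geometry_error",
              "mask is %dx%d but expected %dx%d at downsample %d",
              nrow(mask), ncol(mask), exp_dim[1], exp_dim[2],
              mask_downsample)
  }
  tiles <- list()
  id <- 0L
  for (y0 in seq(0, height - 1, by = window)) {
    for (x0 in seq(0, width - 1, by = window)) {
      w <- min(window, width - x0)
      h <- min(window, height - y0)
      if (!is.null(mask)) {
        rs <- (floor(y0 / mask_downsample) + 1):
          min(nrow(mask), ceiling((y0 + h) / mask_downsample))
        cs <- (floor(x0 / mask_downsample) + 1):
          min(ncol(mask), ceiling((x0 + w) / mask_downsample))
        if (!any(mask[rs, cs])) next
      }
      id <- id + 1L
      tiles[[id]] <- list(x = x0, y = y0, w = w, h = h, id = id)
    }
  }
  structure(list(tiles = tiles, window = window, pad = pad,
                 width = width, height = height, mask = mask,
                 mask_downsample = mask_downsample),
            class = "tiling_plan")
}

# reflect-pad an image on the right/bottom so both dims divide `div`
pad_to_divisible <- function(image, div) {
  d <- dim(image)
  H2 <- ceiling(d[1] / div) * div
  W2 <- ceiling(d[2] / div) * div
  if (H2 == d[1] && W2 == d[2]) return(list(image = image, H = d[1], W = d[2]))
  list(image = mirror_crop(image, 0, 0, W2, H2), H = d[1], W = d[2])
}

#' Run detection on one padded tile
#'
#' Reads the padded window (with reflection at slide edges), runs the
#' heatmap + peak-calling pipeline, discards detections whose coordinates
#' fall in the pad ring, and reports survivors in core-local coordinates.
#'
#' @param reader a [array_slide_reader()].
#' @param tile one tile from a [plan_tiles()] plan.
#' @param checkpoint trained model checkpoint (`network`, `normalizer`).
#' @param pad context padding per side, px.
#' @param detect_args overrides for [call_detections()].
#' @return data.frame `x`, `y`, `score`, `class` in core-local pixels.
#' @export
infer_tile <- function(reader, tile, checkpoint, pad = 32,
                       detect_args = list()) {
  img <- tryCatch(
    reader(tile$x - pad, tile$y - pad, tile$w + 2 * pad, tile$h + 2 * pad),
    error = function(e) pc_stop("pc_io_error", "tile %d read failed: %s",
                                tile$id, conditionMessage(e)))
  div <- 2^(checkpoint$network$config$n_stages - 1)
  pd <- pad_to_divisible(img, div)
  hm <- predict_heatmaps(checkpoint$network, pd$image, checkpoint$normalizer)
  # crop any divisibility padding back off before peak calling
  hm$bg <- hm$bg[seq_len(pd$H), seq_len(pd$W)]
  hm$neg <- hm$neg[seq_len(pd$H), seq_len(pd$W)]
  hm$pos <- hm$pos[seq_len(pd$H), seq_len(pd$W)]
  det <- do.call(call_detections, c(list(hm), detect_args))
  keep <- det$x >= pad & det$x < pad + tile$w &
    det$y >= pad & det$y < pad + tile$h
  det <- det[keep, , drop = FALSE]
  det$x <- det$x - pad
  det$y <- det$y - pad
  rownames(det) <- NULL
  det
}

#' Stitch per-tile detections into slide coordinates
#'
#' Offsets core-local detections into the slide frame; because cores are
#' disjoint and pad-ring detections were discarded, concatenation is
#' exact and order-independent. Detections outside the tissue mask (when
#' one is in the plan) are dropped.
#'
#' @param plan a [plan_tiles()] plan.
#' @param tile_detections list of [infer_tile()] results aligned with
#'   `plan$tiles`.
#' @return list `detections` (sorted by `y`, `x`) and `summary`
#'   (`n_pos`, `n_neg`, `percentage` -- `NA` when no cells --
#'   `tiles_processed`).
#' @export
stitch <- function(plan, tile_detections) {
  stopifnot(inherits(plan, "tiling_plan"))
  out <- list()
  for (i in seq_along(plan$tiles)) {
    det <- tile_detections[[i]]
    if (is.null(det) || nrow(det) == 0) next
    det$x <- det$x + plan$tiles[[i]]$x
    det$y <- det$y + plan$tiles[[i]]$y
    out[[length(out) + 1]] <- det
  }
  det <- if (length(out)) do.call(rbind, out)
  else data.frame(x = integer(0), y = integer(0), score = numeric(0),
                  class = character(0), stringsAsFactors = FALSE)
  if (!is.null(plan$mask) && nrow(det) > 0) {
    ds <- plan$mask_downsample
    ok <- plan$mask[cbind(floor(det$y / ds) + 1, floor(det$x / ds) + 1)]
    det <- det[ok, , drop = FALSE]
  }
  det <- det[order(det$y, det$x), , drop = FALSE]
  rownames(det) <- NULL
  n_pos <- sum(det$class == "pos")
  n_neg <- sum(det$class == "neg")
  list(detections = det,
       summary = list(n_pos = n_pos, n_neg = n_neg,
                      percentage = if (n_pos + n_neg > 0)
                        plasma_percentage(n_pos, n_neg) else NA_real_,
                      tiles_processed = length(plan$tiles)))
}

#' Whole-slide inference pipeline
#'
#' Plans the tiling, runs every tile, stitches, and optionally writes the
#' point TSV (level-0 coordinates, QuPath-importable) plus a JSON summary.
#'
#' @param reader slide reader (or an `H x W x 3` array, wrapped
#'   automatically).
#' @param checkpoint trained model checkpoint.
#' @param window,pad tiling geometry; defaults 2048 and 32.
#' @param mask,mask_downsample optional tissue mask as in [plan_tiles()].
#' @param out_dir if given, write `detections.tsv` and `summary.json`.
#' @param detect_args overrides for [call_detections()].
#' @return the [stitch()] result, plus the `plan`.
#' @export
run_wsi <- function(reader, checkpoint, window = 2048, pad = 32,
                    mask = NULL, mask_downsample = 1, out_dir = NULL,
                    detect_args = list()) {
  if (is.array(reader)) reader <- array_slide_reader(reader)
  rf <- checkpoint$network$config$receptive_field_radius
  if (pad < rf)
    warning(sprintf(paste0("pad (%d px) is smaller than the network's ",
                           "receptive-field radius (%d px); stitching may ",
                           "differ from whole-image inference"), pad, rf))
  plan <- plan_tiles(attr(reader, "width"), attr(reader, "height"),
                     window, pad, mask, mask_downsample)
  dets <- lapply(plan$tiles, function(tl)
    infer_tile(reader, tl, checkpoint, pad, detect_args))
  res <- stitch(plan, dets)
  res$plan <- plan
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_points(file.path(out_dir, "detections.tsv"), res$detections)
    jsonlite::write_json(res$summary,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}
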