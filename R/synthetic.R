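# Synthetic CD138 immunohistochemistry patches with known ground truth.
# The rendering is deliberately stylized: what matters downstream is the
# color topology that separates the classes (a blue hematoxylin nucleus with
# a surrounding brown DAB membrane ring for plasma cells, a bare nucleus for
# other nucleated cells) plus background, noise and occasional nonspecific
# brown blobs -- enough structure to exercise training, peak calling,
# matching and stitching with exact ground truth.

MEMBRANE_THICKNESS <- 3L # px; fixed ring width separating the classes

#' Specification of a synthetic IHC scene
#'
#' Collects the parameters of the synthetic patch generator. Defaults
#' describe the stock test world: a 192x192 patch with 5 plasma cells (25%)
#' among 20 nucleated cells, nucleus radii 4-7 px, 16 px centroid
#' separation, one nonspecific-staining blob, and mild Gaussian noise.
#'
#' @param width,height patch size in pixels.
#' @param n_positive,n_negative number of CD138+ / CD138- cells.
#' @param cell_radius_range integer 2-vector, min/max nucleus radius (px).
#' @param min_separation minimum pairwise centroid distance (px).
#' @param membrane_color,nucleus_color,background_color RGB triples in
#'   0-255 emulating DAB brown, hematoxylin blue, and slide background.
#' @param n_artifact_blobs number of nonspecific brown blobs (no truth).
#' @param noise_sd per-channel i.i.d. Gaussian noise sd (intensity units).
#' @param pixel_size microns per pixel; 0.25 corresponds to a 40x scan.
#' @param seed RNG seed making generation fully reproducible.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 192, height = 192,
                       n_positive = 5, n_negative = 15,
                       cell_radius_range = c(4, 7),
                       min_separation = 16,
                       membrane_color = c(140, 85, 40),
                       nucleus_color = c(70, 70, 150),
                       background_color = c(235, 230, 228),
                       n_artifact_blobs = 1,
                       noise_sd = 8,
                       pixel_size = 0.25,
                       seed = 1L) {
  if (!is_count(n_positive) || !is_count(n_negative))
    pc_stop("pc_spec_error", "cell counts must be non-negative integers")
  if (min_separation <= 0)
    pc_stop("pc_spec_error", "min_separation must be > 0")
  if (length(cell_radius_range) != 2L ||
      cell_radius_range[1] > cell_radius_range[2] || cell_radius_range[1] < 1)
    pc_stop("pc_spec_error", "cell_radius_range must be (min, max), min >= 1")
  cols <- list(membrane_color, nucleus_color, background_color)
  if (any(vapply(cols, function(x) length(x) != 3L || any(x < 0 | x > 255),
                 logical(1))))
    pc_stop("pc_spec_error", "colors must be RGB triples in [0, 255]")
  if (width <= 2 * cell_radius_range[2] || height <= 2 * cell_radius_range[2])
    pc_stop("pc_spec_error", "patch must exceed twice the max cell radius")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 cell_radius_range = as.integer(cell_radius_range),
                 min_separation = min_separation,
                 membrane_color = membrane_color,
                 nucleus_color = nucleus_color,
                 background_color = background_color,
                 n_artifact_blobs = as.integer(n_artifact_blobs),
                 noise_sd = noise_sd, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# paint a filled disc (ring if r_inner > 0) of `color` onto `img`, in place
paint_annulus <- function(img, cx, cy, r_outer, color, r_inner = 0) {
  H <- dim(img)[1]; W <- dim(img)[2]
  xs <- max(0L, floor(cx - r_outer)):min(W - 1L, ceiling(cx + r_outer))
  ys <- max(0L, floor(cy - r_outer)):min(H - 1L, ceiling(cy + r_outer))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  d2 <- dx^2 + dy^2
  sel <- if (r_inner > 0) d2 <= r_outer^2 & d2 > r_inner^2
         else d2 <= r_outer^2
  for (ch in 1:3) {
    sl <- img[ys + 1L, xs + 1L, ch]
    sl[sel] <- color[ch]
    img[ys + 1L, xs + 1L, ch] <- sl
  }
  img
}

# rejection-sample n points >= min_sep apart, margin px inside the frame,
# also >= min_dist_other from the rows of `other` (k x 2 matrix), cap tries
sample_separated <- function(n, width, height, margin, min_sep,
                             other = NULL, min_dist_other = 0,
                             max_attempts = 10000L, what = "cell") {
  pts <- matrix(numeric(0), ncol = 2)
  if (width - 1 - 2 * margin < 0 || height - 1 - 2 * margin < 0)
    pc_stop("pc_placement_error",
            "frame too small for placement margin %d", margin)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      x <- round(runif(1, margin, width - 1 - margin))
      y <- round(runif(1, margin, height - 1 - margin))
      if (nrow(pts) > 0 &&
          min((pts[, 1] - x)^2 + (pts[, 2] - y)^2) < min_sep^2) next
      if (!is.null(other) && nrow(other) > 0 &&
          min((other[, 1] - x)^2 + (other[, 2] - y)^2) < min_dist_other^2) next
      pts <- rbind(pts, c(x, y))
      ok <- TRUE
      break
    }
    if (!ok)
      pc_stop("pc_placement_error",
              paste0("could not place %s %d of %d after %d attempts ",
                     "(min_separation = %s in a %dx%d frame)"),
              what, i, n, max_attempts, format(min_sep), width, height)
  }
  pts
}

#' Generate a synthetic IHC patch with known ground truth
#'
#' Renders plasma cells as a nucleus disc surrounded by a 3 px brown
#' membrane ring, other nucleated cells as a bare nucleus disc, plus
#' optional nonspecific brown blobs carrying no ground-truth point, then
#' adds clipped Gaussian noise. Placement is rejection sampling (capped at
#' 10,000 attempts per object) and the whole procedure is deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return object of class `synthetic_scene`: list with `image`
#'   (`H x W x 3`, 0-255), `truth` (data.frame `x`, `y`, `class` with
#'   levels `neg`/`pos`), `tissue_mask` (logical `H x W`), `spec`.
#' @export
generate_patch <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_patch_impl(spec))
}

generate_patch_impl <- function(spec) {
  W <- spec$width; H <- spec$height
  rmax <- spec$cell_radius_range[2]
  margin <- rmax + MEMBRANE_THICKNESS + 1L
  n_cells <- spec$n_positive + spec$n_negative

  centers <- sample_separated(n_cells, W, H, margin, spec$min_separation)
  classes <- c(rep("pos", spec$n_positive), rep("neg", spec$n_negative))
  radii <- if (n_cells > 0)
    round(runif(n_cells, spec$cell_radius_range[1], rmax)) else integer(0)

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- spec$background_color[ch]

  # nonspecific-staining blobs: brown, no truth point may fall inside, so
  # keep blob centers away from every cell centroid by blob radius + margin
  if (spec$n_artifact_blobs > 0) {
    blob_r <- round(runif(spec$n_artifact_blobs, 6, 12))
    blob_centers <- sample_separated(
      spec$n_artifact_blobs, W, H, max(blob_r) + 1L, 2,
      other = centers, min_dist_other = max(blob_r) + 3,
      what = "artifact blob")
    for (i in seq_len(spec$n_artifact_blobs))
      img <- paint_annulus(img, blob_centers[i, 1], blob_centers[i, 2],
                           blob_r[i], spec$membrane_color)
  }

  for (i in seq_len(n_cells)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radii[i]
    if (classes[i] == "pos")
      img <- paint_annulus(img, cx, cy, r + MEMBRANE_THICKNESS,
                           spec$membrane_color, r_inner = r)
    img <- paint_annulus(img, cx, cy, r, spec$nucleus_color)
  }

  if (spec$noise_sd > 0)
    img <- clip(img + array(rnorm(length(img), 0, spec$noise_sd), dim(img)),
                0, 255)

  truth <- data.frame(x = if (n_cells > 0) as.integer(centers[, 1]) else integer(0),
                      y = if (n_cells > 0) as.integer(centers[, 2]) else integer(0),
                      class = classes, stringsAsFactors = FALSE)
  structure(list(image = img, truth = truth,
                 tissue_mask = matrix(TRUE, H, W), spec = spec),
            class = "synthetic_scene")
}

#' Generate a synthetic slide as a mosaic of patches
#'
#' Assembles a `rows x cols` grid of independently seeded patches (patch
#' `i` uses `spec$seed + i`) into one large scene whose truth list is in
#' slide coordinates. An optional background `margin` surrounds the mosaic;
#' the tissue mask is `TRUE` exactly over the patch mosaic.
#'
#' @param spec per-patch [scene_spec()].
#' @param rows,cols grid dimensions (>= 1).
#' @param margin background border around the mosaic, px (default 0).
#' @return a `synthetic_scene` covering the whole slide.
#' @export
generate_slide <- function(spec, rows = 2, cols = 2, margin = 0) {
  stopifnot(inherits(spec, "scene_spec"))
  if (rows < 1 || cols < 1)
    pc_stop("pc_spec_error", "grid must be at least 1x1")
  W <- cols * spec$width + 2L * margin
  H <- rows * spec$height + 2L * margin
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- spec$background_color[ch]
  mask <- matrix(FALSE, H, W)
  truth <- list()
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      k <- k + 1L
      pspec <- spec
      pspec$seed <- spec$seed + k
      scene <- generate_patch(pspec)
      y0 <- margin + (r - 1L) * spec$height
      x0 <- margin + (c - 1L) * spec$width
      img[y0 + seq_len(spec$height), x0 + seq_len(spec$width), ] <- scene$image
      mask[y0 + seq_len(spec$height), x0 + seq_len(spec$width)] <- TRUE
      tr <- scene$truth
      tr$x <- as.integer(tr$x + x0)
      tr$y <- as.integer(tr$y + y0)
      truth[[k]] <- tr
    }
  }
  truth <- do.call(rbind, truth)
  structure(list(image = img, truth = truth, tissue_mask = mask, spec = spec),
            class = "synthetic_scene")
}

#' Write a synthetic scene to disk
#'
#' Writes `<stem>_img.ppm`, `<stem>_mask.pgm` and the ground-truth points
#' as `<stem>_truth.tsv` in the point-file dialect of [write_points()].
#'
#' @param scene a `synthetic_scene`.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, stem) {
  stopifnot(inherits(scene, "synthetic_scene"))
  paths <- c(img = paste0(stem, "_img.ppm"),
             mask = paste0(stem, "_mask.pgm"),
             truth = paste0(stem, "_truth.tsv"))
  write_ppm(scene$image, paths["img"])
  write_pgm(scene$tissue_mask * 255, paths["mask"])
  write_points(paths["truth"], scene$truth)
  invisible(paths)
}
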