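# Raster I/O. The toolchain here has no PNG/TIFF codec, so rasters are
# exchanged as binary PPM (P6, RGB) and PGM (P5, single channel) with
# maxval 255 -- a plain, widely readable format.

#' Write an RGB image as binary PPM (P6)
#'
#' @param image `H x W x 3` numeric array with values in `[0, 255]`.
#' @param path output file path.
#' @export
write_ppm <- function(image, path) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    pc_stop("pc_format_error", "write_ppm expects an H x W x 3 array")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", d[2], d[1]), con, eos = NULL)
  # PPM is row-major with interleaved channels
  px <- aperm(image, c(3, 2, 1))
  writeBin(as.raw(clip(round(px), 0, 255)), con)
  invisible(path)
}

#' Write a single-channel image as binary PGM (P5)
#'
#' @param image `H x W` numeric matrix, values in `[0, 255]`.
#' @param path output file path.
#' @export
write_pgm <- function(image, path) {
  if (!is.matrix(image))
    pc_stop("pc_format_error", "write_pgm expects a matrix")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con,
            eos = NULL)
  writeBin(as.raw(clip(round(t(image)), 0, 255)), con)
  invisible(path)
}

read_pnm_header <- function(con) {
  tok <- character(0)
  while (length(tok) < 4L) {
    line <- suppressWarnings(readLines(con, n = 1L))
    if (length(line) == 0L)
      pc_stop("pc_format_error", "truncated PNM header")
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
  }
  tok <- tok[tok != ""]
  list(magic = tok[1], width = as.integer(tok[2]),
       height = as.integer(tok[3]), maxval = as.integer(tok[4]))
}

#' Read a binary PPM/PGM image
#'
#' @param path file path; magic number selects RGB (P6) or grayscale (P5).
#' @return `H x W x 3` array for P6, `H x W` matrix for P5, values 0-255.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con)
  if (!hd$magic %in% c("P5", "P6") || is.na(hd$width) || is.na(hd$height))
    pc_stop("pc_format_error", "unsupported or malformed PNM file: %s", path)
  nch <- if (hd$magic == "P6") 3L else 1L
  n <- hd$width * hd$height * nch
  bytes <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(bytes) != n)
    pc_stop("pc_format_error", "truncated PNM pixel data: %s", path)
  if (nch == 1L) {
    matrix(as.numeric(bytes), nrow = hd$height, ncol = hd$width, byrow = TRUE)
  } else {
    aperm(array(as.numeric(bytes), dim = c(3, hd$width, hd$height)),
          c(3, 2, 1))
  }
}

# decode PNM from an in-memory raw vector (used by the snapshot service)
decode_pnm_bytes <- function(bytes) {
  tmp <- tempfile(fileext = ".pnm")
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  read_pnm(tmp)
}
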