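#' @useDynLib plasmacount, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils read.delim write.table head
NULL

# condition helper: all package errors carry a subclass for programmatic tests
pc_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "pc_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# symmetric (edge-duplicating) reflection of 0-based indices into [0, n)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * n
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i - 1L, i)
}

#' Read a rectangular region of an image with mirror reflection
#'
#' Reads the `w` x `h` region with top-left corner `(x0, y0)` (0-based) from
#' an `H x W x C` array (or `H x W` matrix). Coordinates outside the source
#' are filled by symmetric reflection, the edge-handling used when padded
#' tiles extend past the slide border.
#'
#' @param image numeric array `H x W x C` or matrix.
#' @param x0,y0 0-based column/row of the region's top-left corner.
#' @param w,h region width and height in pixels.
#' @return array (or matrix) of size `h x w (x C)`.
#' @export
mirror_crop <- function(image, x0, y0, w, h) {
  d <- dim(image)
  rows <- reflect_index(y0 + seq_len(h) - 1L, d[1]) + 1L
  cols <- reflect_index(x0 + seq_len(w) - 1L, d[2]) + 1L
  if (length(d) == 2L) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

# clip to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
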