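# Minimal raster support.  Images are numeric arrays [height, width, 3]
# with values in [0, 1] (row = y, col = x, both 1-based when indexing the
# array; the geometric convention elsewhere stays 0-based half-open).
# File I/O uses the PPM format (P6), which every image tool can read and
# which needs no external dependency.

#' Create a flat RGB raster
#'
#' @param width,height Dimensions in pixels.
#' @param color Length-3 RGB fill in [0, 1].
#' @return A numeric array `[height, width, 3]`.
#' @export
raster_new <- function(width, height, color = c(0, 0, 0)) {
  array(rep(color, each = as.integer(height) * as.integer(width)),
        dim = c(height, width, 3))
}

raster_dims <- function(img) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stop("raster must be a [h, w, 3] array")
  c(width = d[2], height = d[1])
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Write / read a binary PPM (P6) image
#'
#' @param img A `[h, w, 3]` numeric array in [0, 1].
#' @param path File path.
#' @return `read_ppm` returns the array; `write_ppm` the path, invisibly.
#' @export
write_ppm <- function(img, path) {
  d <- raster_dims(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", d["width"], d["height"]), con,
            eos = NULL)
  # PPM is row-major RGB-interleaved
  vals <- as.integer(round(clamp01(img) * 255))
  arr <- array(vals, dim = dim(img))
  inter <- aperm(arr, c(3, 2, 1))  # channel, x, y -> flattens to RGBRGB...
  writeBin(as.raw(as.vector(inter)), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) break
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (magic != "P6") stop("read_ppm: only binary P6 is supported")
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxv <- as.integer(read_token())
  raw <- readBin(con, "raw", n = w * h * 3)
  vals <- as.integer(raw) / maxv
  inter <- array(vals, dim = c(3, w, h))
  aperm(inter, c(3, 2, 1))
}

# Nearest-neighbour resize to width x height.
resize_nn <- function(img, width, height) {
  d <- raster_dims(img)
  xi <- pmin(d["width"], floor((seq_len(width) - 0.5) * d["width"] / width) + 1)
  yi <- pmin(d["height"], floor((seq_len(height) - 0.5) * d["height"] / height) + 1)
  img[yi, xi, , drop = FALSE]
}
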