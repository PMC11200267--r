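# Blocking geometry for large UAV frames.
#
# Conventions used throughout the package: pixel coordinates are 0-based,
# x grows rightward, y grows downward, and every window is a half-open
# interval [x0, x0 + side) x [y0, y0 + side).  This makes tiling algebra
# exact in integer arithmetic.

#' Image specification
#'
#' Pixel dimensions plus ground sampling distance (GSD).  The GSD is the
#' ground length represented by one pixel, in cm/pixel; it anchors all
#' footprint computations.
#'
#' @param width_px,height_px Image dimensions in pixels (>= 1).
#' @param gsd_cm_per_px Ground sampling distance in cm/pixel (> 0).
#'   The default 0.25 corresponds to a low-altitude full-frame survey.
#' @return An object of class `image_spec`.
#' @examples
#' uav_frame_spec()          # the 8192 x 5460 survey frame
#' image_spec(2048, 2048)    # desk-scale frame
#' @export
image_spec <- function(width_px, height_px, gsd_cm_per_px = 0.25) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || width_px < 1L) stop("width_px must be >= 1")
  if (is.na(height_px) || height_px < 1L) stop("height_px must be >= 1")
  if (!is.numeric(gsd_cm_per_px) || gsd_cm_per_px <= 0)
    stop("gsd_cm_per_px must be > 0")
  structure(
    list(width_px = width_px, height_px = height_px,
         gsd_cm_per_px = as.numeric(gsd_cm_per_px)),
    class = "image_spec"
  )
}

#' @rdname image_spec
#' @export
uav_frame_spec <- function() image_spec(8192L, 5460L, 0.25)

#' @export
print.image_spec <- function(x, ...) {
  cat(sprintf("<image_spec> %d x %d px @ %g cm/px (%.4g m^2)\n",
              x$width_px, x$height_px, x$gsd_cm_per_px, footprint_m2(x)))
  invisible(x)
}

is_image_spec <- function(x) inherits(x, "image_spec")

new_blocking_plan <- function(pattern, block_side, overlap, blocks, img) {
  structure(
    list(pattern = pattern,
         block_side = as.integer(block_side),
         overlap = as.integer(overlap),
         blocks = blocks,
         image = img),
    class = "blocking_plan"
  )
}

#' @export
print.blocking_plan <- function(x, ...) {
  cat(sprintf("<blocking_plan> pattern %s: %d block(s) of %d px, overlap %d px\n",
              x$pattern, nrow(x$blocks), x$block_side, x$overlap))
  invisible(x)
}

# Build the block data.frame for a cross-product grid of origins.
grid_blocks <- function(xs, ys, side) {
  nx <- length(xs); ny <- length(ys)
  data.frame(
    block_id = seq_len(nx * ny),
    row = rep(seq_len(ny), each = nx),
    col = rep(seq_len(nx), times = ny),
    x0 = rep(as.integer(xs), times = ny),
    y0 = rep(as.integer(ys), each = nx),
    side = as.integer(side)
  )
}

# Top-left origin that centers a union of side `union_side` in an extent;
# odd parities shift left/up by one pixel (deterministic).
centered_origin <- function(extent, union_side) {
  as.integer(floor((extent - union_side) / 2))
}

check_centered_fit <- function(img, union_side, what) {
  avail <- min(img$width_px, img$height_px)
  if (union_side > avail)
    stop(sprintf("image too small for %s: requires %d px, only %d available",
                 what, union_side, avail))
}

plan_centered_k <- function(img, k, block_side, overlap, pattern) {
  stopifnot(is_image_spec(img))
  block_side <- as.integer(block_side); overlap <- as.integer(overlap)
  if (block_side < 1L) stop("block_side must be >= 1")
  if (overlap < 0L || overlap >= block_side)
    stop("overlap must satisfy 0 <= overlap < block_side")
  union_side <- k * block_side - (k - 1L) * overlap
  check_centered_fit(img, union_side, sprintf("a centered %dx%d arrangement", k, k))
  ox <- centered_origin(img$width_px, union_side)
  oy <- centered_origin(img$height_px, union_side)
  stride <- block_side - overlap
  offs <- (seq_len(k) - 1L) * stride
  new_blocking_plan(pattern, block_side, overlap,
                    grid_blocks(ox + offs, oy + offs, block_side), img)
}

#' Center-anchored blocking patterns
#'
#' Three fixed decompositions of a UAV frame into detector-sized square
#' crops, anchored on the image center where perspective distortion is
#' smallest:
#'
#' * Pattern 1: a 2 x 2 arrangement of blocks with mutual overlap; on the
#'   default frame the union is a centered square of 2*1024 - 200 = 1848 px.
#' * Pattern 2: a 3 x 3 centered arrangement; union side 3*1024 - 2*200 =
#'   2672 px.
#' * Pattern 3: the full non-overlapping grid of floor(W/b) x floor(H/b)
#'   blocks; the leftover margin is split evenly (extra pixel to the
#'   right/bottom) so the grid stays centered, or anchored at the top-left
#'   corner with `anchor = "topleft"`.
#'
#' Blocks are ordered row-major; plans are deterministic.
#'
#' @param img An [image_spec()].
#' @param block_side Square window side in pixels (detector input size).
#' @param overlap Overlap between adjacent blocks in pixels
#'   (`0 <= overlap < block_side`).
#' @param anchor For pattern 3: `"center"` (default) or `"topleft"`.
#' @return A `blocking_plan` with a `blocks` data.frame
#'   (`block_id,row,col,x0,y0,side`).
#' @examples
#' plan_pattern1(uav_frame_spec())   # union side 1848 px
#' plan_pattern2(uav_frame_spec())   # union side 2672 px
#' plan_pattern3(uav_frame_spec())   # 8 x 5 = 40 blocks
#' @export
plan_pattern1 <- function(img, block_side = 1024L, overlap = 200L) {
  plan_centered_k(img, 2L, block_side, overlap, "P1")
}

#' @rdname plan_pattern1
#' @export
plan_pattern2 <- function(img, block_side = 1024L, overlap = 200L) {
  plan_centered_k(img, 3L, block_side, overlap, "P2")
}

#' @rdname plan_pattern1
#' @export
plan_pattern3 <- function(img, block_side = 1024L,
                          anchor = c("center", "topleft")) {
  stopifnot(is_image_spec(img))
  anchor <- match.arg(anchor)
  block_side <- as.integer(block_side)
  if (block_side < 1L) stop("block_side must be >= 1")
  if (block_side > min(img$width_px, img$height_px))
    stop(sprintf("image too small for a %d px block: only %d px available",
                 block_side, min(img$width_px, img$height_px)))
  nc <- img$width_px %/% block_side
  nr <- img$height_px %/% block_side
  if (anchor == "center") {
    mx <- img$width_px - nc * block_side
    my <- img$height_px - nr * block_side
    ox <- as.integer(mx %/% 2L)   # extra pixel goes to the right/bottom
    oy <- as.integer(my %/% 2L)
  } else {
    ox <- 0L; oy <- 0L
  }
  xs <- ox + (seq_len(nc) - 1L) * block_side
  ys <- oy + (seq_len(nr) - 1L) * block_side
  new_blocking_plan("P3", block_side, 0L, grid_blocks(xs, ys, block_side), img)
}

#' Sliding-window blocking plan
#'
#' Row-major grid with stride `block_side - overlap`; the final row and
#' column snap inward so every window is in-bounds and of fixed size, and
#' every image pixel is covered by at least one window.
#'
#' @inheritParams plan_pattern1
#' @return A `blocking_plan` (pattern `"SLIDING"`).
#' @export
plan_sliding <- function(img, block_side = 1024L, overlap = 200L) {
  stopifnot(is_image_spec(img))
  block_side <- as.integer(block_side); overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= block_side)
    stop("overlap must satisfy 0 <= overlap < block_side")
  if (block_side > min(img$width_px, img$height_px))
    stop(sprintf("image too small for a %d px block: only %d px available",
                 block_side, min(img$width_px, img$height_px)))
  stride <- block_side - overlap
  axis_positions <- function(extent) {
    last <- extent - block_side
    xs <- seq.int(0L, last, by = stride)
    if (xs[length(xs)] < last) xs <- c(xs, last)  # snap final window inward
    as.integer(unique(xs))
  }
  new_blocking_plan("SLIDING", block_side, overlap,
                    grid_blocks(axis_positions(img$width_px),
                                axis_positions(img$height_px), block_side),
                    img)
}

#' Ground footprint of an image in square meters
#'
#' @param img An [image_spec()].
#' @return `(width * gsd / 100) * (height * gsd / 100)` in m^2.
#' @examples
#' footprint_m2(uav_frame_spec())  # 279.552, i.e. ~280 m^2
#' @export
footprint_m2 <- function(img) {
  stopifnot(is_image_spec(img))
  (img$width_px * img$gsd_cm_per_px / 100) *
    (img$height_px * img$gsd_cm_per_px / 100)
}

# Length of the union of half-open intervals [starts, starts + side).
union_interval_length <- function(starts, side) {
  starts <- sort(unique(starts))
  ends <- starts + side
  total <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Area of a blocking plan's union
#'
#' All plans produced by this package are cross-product grids (every x
#' origin is paired with every y origin), so the union of the blocks is the
#' product of the unions along each axis.
#'
#' @param plan A `blocking_plan`.
#' @return Union area in px^2.
#' @export
plan_union_area_px2 <- function(plan) {
  union_interval_length(plan$blocks$x0, plan$block_side) *
    union_interval_length(plan$blocks$y0, plan$block_side)
}

#' Fraction of the image area covered by a plan's blocks
#'
#' Supports the efficiency argument for blocking strategies: the larger the
#' usable fraction of each frame, the fewer frames a survey needs.
#'
#' @param plan A `blocking_plan` built for `img`.
#' @param img The [image_spec()] the plan was built for.
#' @return A value in (0, 1].
#' @export
block_area_fraction <- function(plan, img) {
  stopifnot(is_image_spec(img))
  plan_union_area_px2(plan) / (as.numeric(img$width_px) * img$height_px)
}

#' Side length of the union square of a centered plan
#'
#' For patterns 1 and 2 the union is a square of side
#' `k * block_side - (k - 1) * overlap`; this measures it from the realized
#' blocks.
#'
#' @param plan A `blocking_plan`.
#' @return Union extent along x (== along y for square unions), in pixels.
#' @export
plan_union_side_px <- function(plan) {
  b <- plan$blocks
  max(b$x0 + b$side) - min(b$x0)
}

#' Serialize / read a blocking plan
#'
#' CSV columns are `block_id,row,col,x0,y0,side`; JSON carries the same
#' table plus the pattern, block side, overlap and image spec.
#'
#' @param plan A `blocking_plan`.
#' @param path Output file path.
#' @export
write_plan_csv <- function(plan, path) {
  utils::write.csv(plan$blocks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plan_csv
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(pattern = plan$pattern, block_side = plan$block_side,
              overlap = plan$overlap,
              image = unclass(plan$image), blocks = plan$blocks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
as.data.frame.blocking_plan <- function(x, ...) x$blocks
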