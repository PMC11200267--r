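# YOLO-format annotation handling, fixed-square standardization, the box
# size sweep harness, dataset statistics and block-level label cropping.
#
# Boxes live in a plain data.frame with columns
#   class (integer 0/1/2), cx, cy, w, h   -- pixel units, box centers.
# Category codes are stable across all files: 0 = Tassel-N (tassel removed
# or absent), 1 = Tassel-S (formed, not emerged), 2 = Tassel-L (emerged,
# mature).

#' Tassel categories
#'
#' Stable integer codes for the three plant-center states.
#'
#' @return Named integer vector `c("Tassel-N" = 0L, "Tassel-S" = 1L,
#'   "Tassel-L" = 2L)`.
#' @export
tassel_categories <- function() {
  c("Tassel-N" = 0L, "Tassel-S" = 1L, "Tassel-L" = 2L)
}

#' @rdname tassel_categories
#' @param code Integer codes in `0:2`.
#' @export
category_label <- function(code) {
  names(tassel_categories())[match(code, tassel_categories())]
}

empty_boxes <- function() {
  data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

validate_boxes <- function(boxes) {
  need <- c("class", "cx", "cy", "w", "h")
  if (!all(need %in% names(boxes)))
    stop("boxes must have columns class, cx, cy, w, h")
  if (nrow(boxes) > 0) {
    if (!all(boxes$class %in% tassel_categories()))
      stop("box class codes must be in {0, 1, 2}")
    if (any(boxes$w <= 0) || any(boxes$h <= 0))
      stop("box widths and heights must be > 0")
  }
  boxes
}

#' Annotation set: labeled boxes attached to one image
#'
#' @param image_id Unique image identifier (string).
#' @param img The [image_spec()] the boxes refer to.
#' @param boxes A data.frame with columns `class, cx, cy, w, h` in pixel
#'   units (centers and sizes).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, img, boxes = empty_boxes()) {
  stopifnot(is_image_spec(img))
  structure(
    list(image_id = as.character(image_id), image_spec = img,
         boxes = validate_boxes(as.data.frame(boxes))),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  tab <- table(factor(category_label(x$boxes$class),
                      levels = names(tassel_categories())))
  cat(sprintf("<annotation_set> '%s' (%d x %d px): %d boxes [%s]\n",
              x$image_id, x$image_spec$width_px, x$image_spec$height_px,
              nrow(x$boxes), paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

is_annotation_set <- function(x) inherits(x, "annotation_set")

#' Read YOLO-format labels
#'
#' Each line is `class cx cy w h` with coordinates normalized to the image
#' dimensions.  Values are converted to pixel units against `img`; line
#' order is preserved.
#'
#' @param x A file path or a character vector of label lines.
#' @param img The [image_spec()] of the image the labels belong to.
#' @param image_id Identifier for the resulting set (defaults to the file
#'   name without extension, or `"image"` for in-memory input).
#' @return An [annotation_set()].
#' @export
read_yolo <- function(x, img, image_id = NULL) {
  stopifnot(is_image_spec(img))
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    if (is.null(image_id))
      image_id <- sub("\\.[^.]*$", "", basename(x))
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    if (is.null(image_id)) image_id <- "image"
  }
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) return(annotation_set(image_id, img))
  orig_line <- which(keep)
  parts <- strsplit(lines, "[[:space:]]+")
  nfield <- lengths(parts)
  if (any(nfield != 5L))
    stop(sprintf("YOLO format error at line %d: expected 5 fields, got %d",
                 orig_line[which(nfield != 5L)[1]], nfield[nfield != 5L][1]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 5, byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("YOLO format error at line %d: non-numeric field",
                 orig_line[which(apply(m, 1, anyNA))[1]]))
  cls <- m[, 1]
  if (any(cls != round(cls)) || any(!(cls %in% tassel_categories())))
    stop(sprintf("YOLO format error at line %d: class code %s not in {0,1,2}",
                 orig_line[which(!(cls %in% tassel_categories()))[1]],
                 format(cls[!(cls %in% tassel_categories())][1])))
  vals <- m[, 2:5, drop = FALSE]
  bad <- which(vals < 0 | vals > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("YOLO format error at line %d: normalized value %g outside [0,1]",
                 orig_line[bad[1, 1]], vals[bad[1, , drop = FALSE]]))
  boxes <- data.frame(
    class = as.integer(cls),
    cx = m[, 2] * img$width_px,
    cy = m[, 3] * img$height_px,
    w = m[, 4] * img$width_px,
    h = m[, 5] * img$height_px
  )
  annotation_set(image_id, img, boxes)
}

#' Write YOLO-format labels
#'
#' Emits 6-decimal normalized values, one line per box, in box order.
#'
#' @param anns An [annotation_set()].
#' @param path Optional output file; when omitted the lines are returned.
#' @return Character vector of label lines (invisibly when writing).
#' @export
write_yolo <- function(anns, path = NULL) {
  stopifnot(is_annotation_set(anns))
  b <- anns$boxes
  img <- anns$image_spec
  lines <- if (nrow(b) == 0) character(0) else
    sprintf("%d %.6f %.6f %.6f %.6f", b$class,
            b$cx / img$width_px, b$cy / img$height_px,
            b$w / img$width_px, b$h / img$height_px)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Clip boxes (data.frame) to [0, W] x [0, H]; drops boxes that do not
# intersect the image.  Extra columns pass through.
clip_boxes <- function(boxes, width, height) {
  if (nrow(boxes) == 0) return(boxes)
  x1 <- pmax(boxes$cx - boxes$w / 2, 0)
  x2 <- pmin(boxes$cx + boxes$w / 2, width)
  y1 <- pmax(boxes$cy - boxes$h / 2, 0)
  y2 <- pmin(boxes$cy + boxes$h / 2, height)
  keep <- x2 > x1 & y2 > y1
  boxes <- boxes[keep, , drop = FALSE]
  boxes$cx <- (x1[keep] + x2[keep]) / 2
  boxes$cy <- (y1[keep] + y2[keep]) / 2
  boxes$w <- x2[keep] - x1[keep]
  boxes$h <- y2[keep] - y1[keep]
  rownames(boxes) <- NULL
  boxes
}

#' Standardize annotation boxes to fixed squares
#'
#' Replaces every box whose category has a target side by a square of that
#' side at the same center, then clips to the image.  Categories without a
#' target (by default Tassel-L, whose emerged tassels have real boundaries)
#' pass through unchanged.  The box count is preserved; the pre-clip
#' geometry is recorded in columns `pre_w`/`pre_h`.
#'
#' @param anns An [annotation_set()].
#' @param target_side Named numeric vector mapping category labels to target
#'   sides in pixels, e.g. `c("Tassel-N" = 140, "Tassel-S" = 140)` (the
#'   default).  Use [optimal_target_sides()] for the per-category optima
#'   found by the box-size sweep.
#' @return A standardized [annotation_set()].
#' @export
standardize_boxes <- function(anns,
                              target_side = c("Tassel-N" = 140,
                                              "Tassel-S" = 140)) {
  stopifnot(is_annotation_set(anns))
  if (length(target_side) > 0) {
    if (is.null(names(target_side)) ||
        !all(names(target_side) %in% names(tassel_categories())))
      stop("target_side must be named with category labels")
    if (any(target_side <= 0)) stop("target sides must be positive")
  }
  b <- anns$boxes
  if (nrow(b) > 0) {
    codes <- tassel_categories()[names(target_side)]
    idx <- match(b$class, codes)
    hit <- !is.na(idx)
    b$w[hit] <- target_side[idx[hit]]
    b$h[hit] <- target_side[idx[hit]]
    b$pre_w <- b$w
    b$pre_h <- b$h
    b <- clip_boxes(b, anns$image_spec$width_px, anns$image_spec$height_px)
  }
  annotation_set(anns$image_id, anns$image_spec, b)
}

#' @rdname standardize_boxes
#' @export
optimal_target_sides <- function() c("Tassel-N" = 200, "Tassel-S" = 160)

#' Box-size sweep harness
#'
#' Derives one standardized dataset per candidate side, applying the side to
#' the listed categories only.  This is the enumeration used to locate the
#' box size that maximizes detection precision (coarse 50-px steps over
#' 50-500 px, then 10-px steps over 50-300 px).
#'
#' @param dataset A list of [annotation_set()] objects.
#' @param sides Strictly increasing integer vector of candidate sides (px).
#' @param categories Category labels to standardize (default Tassel-N/S).
#' @return A named list (one element per side) of derived datasets, with a
#'   `record` attribute: a data.frame mapping each side to its element name.
#' @export
sweep_sizes <- function(dataset, sides,
                        categories = c("Tassel-N", "Tassel-S")) {
  if (length(sides) == 0) stop("sides must be nonempty")
  if (any(diff(sides) <= 0)) stop("sides must be strictly increasing")
  if (!all(categories %in% names(tassel_categories())))
    stop("unknown category label")
  out <- lapply(sides, function(s) {
    tgt <- stats::setNames(rep(s, length(categories)), categories)
    lapply(dataset, standardize_boxes, target_side = tgt)
  })
  names(out) <- sprintf("side_%d", sides)
  attr(out, "record") <- data.frame(side = as.integer(sides),
                                    dataset = names(out))
  out
}

#' Dataset-level annotation statistics
#'
#' Per-category and pooled counts, box-area moments, and length-width
#' ratio moments.  The ratio is `min(w, h) / max(w, h)` so it lies in
#' (0, 1]; 1 means a square box.
#'
#' @param dataset A nonempty list of [annotation_set()] objects (a single
#'   set is also accepted).
#' @return A data.frame with one row per category plus an `"All"` row:
#'   columns `category, n, proportion, area_mean, area_sd, ratio_mean,
#'   ratio_sd`.
#' @export
dataset_stats <- function(dataset) {
  if (is_annotation_set(dataset)) dataset <- list(dataset)
  boxes <- do.call(rbind, lapply(dataset, function(a) a$boxes[, 1:5]))
  if (is.null(boxes) || nrow(boxes) == 0)
    stop("dataset_stats: empty dataset")
  area <- boxes$w * boxes$h
  ratio <- pmin(boxes$w, boxes$h) / pmax(boxes$w, boxes$h)
  one <- function(sel, label) {
    data.frame(category = label, n = sum(sel),
               proportion = sum(sel) / nrow(boxes),
               area_mean = mean(area[sel]), area_sd = stats::sd(area[sel]),
               ratio_mean = mean(ratio[sel]), ratio_sd = stats::sd(ratio[sel]))
  }
  cats <- tassel_categories()
  rows <- lapply(names(cats), function(lb) one(boxes$class == cats[[lb]], lb))
  out <- rbind(do.call(rbind, rows), one(rep(TRUE, nrow(boxes)), "All"))
  rownames(out) <- NULL
  out
}

#' Crop annotations to a block
#'
#' Boxes intersecting the block are translated to block-local coordinates
#' and clipped; boxes whose visible area fraction falls below
#' `min_visible_frac` are dropped.  The source row index within the parent
#' set is kept in a `source_box` column so objects duplicated across
#' overlapping blocks can be identified.
#'
#' @param anns An [annotation_set()] over the full frame.
#' @param block One row of a `blocking_plan`'s `blocks` data.frame (or any
#'   list with `x0`, `y0`, `side`, optionally `block_id`).
#' @param min_visible_frac Minimum visible fraction of the original box
#'   area required to keep a truncated box (default 0.5).
#' @return An [annotation_set()] in block-local coordinates.
#' @export
crop_annotations_to_block <- function(anns, block, min_visible_frac = 0.5) {
  stopifnot(is_annotation_set(anns))
  b <- anns$boxes
  side <- as.integer(block$side)
  block_spec <- image_spec(side, side, anns$image_spec$gsd_cm_per_px)
  bid <- if (!is.null(block$block_id)) block$block_id else NA_integer_
  out_id <- sprintf("%s_b%s", anns$image_id, bid)
  if (nrow(b) == 0) return(annotation_set(out_id, block_spec))
  x1 <- pmax(b$cx - b$w / 2, block$x0)
  x2 <- pmin(b$cx + b$w / 2, block$x0 + side)
  y1 <- pmax(b$cy - b$h / 2, block$y0)
  y2 <- pmin(b$cy + b$h / 2, block$y0 + side)
  vis <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0) / (b$w * b$h)
  keep <- vis >= min_visible_frac & vis > 0
  out <- data.frame(
    class = b$class[keep],
    cx = (x1[keep] + x2[keep]) / 2 - block$x0,
    cy = (y1[keep] + y2[keep]) / 2 - block$y0,
    w = x2[keep] - x1[keep],
    h = y2[keep] - y1[keep],
    # full-box center in block coordinates: the plant-center anchor, which
    # clipping must not move (duplicate merging relies on it)
    cx_full = b$cx[keep] - block$x0,
    cy_full = b$cy[keep] - block$y0,
    source_box = which(keep)
  )
  annotation_set(out_id, block_spec, out)
}

#' Seeded train/validation/test split
#'
#' Splits a dataset by image at a fixed ratio (default 8:1:1) with
#' reproducible ordering.
#'
#' @param dataset A list of [annotation_set()] objects.
#' @param ratios Named numeric vector of split weights.
#' @param seed Integer seed.
#' @return A data.frame `image_id, split`.
#' @export
split_dataset <- function(dataset, ratios = c(train = 8, val = 1, test = 1),
                          seed = 1L) {
  ids <- vapply(dataset, function(a) a$image_id, character(1))
  n <- length(ids)
  if (n == 0) stop("empty dataset")
  withr::with_seed(seed, {
    perm <- sample.int(n)
  })
  props <- ratios / sum(ratios)
  cuts <- round(cumsum(props) * n)
  sizes <- diff(c(0L, cuts))
  split <- rep(names(ratios), times = sizes)
  data.frame(image_id = ids, split = split[order(perm)])
}
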