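# Label-aware data augmentation: the five operations used to expand the
# standardized training set (rotation, random cropping, brightness
# adjustment, shadow addition, chromatic adjustment).  Photometric ops
# leave box coordinates untouched; geometric ops transform boxes together
# with the raster.  All randomness is seeded and restorable.

AUG_OPS <- c("ROTATE", "RANDOM_CROP", "BRIGHTNESS", "SHADOW", "CHROMA")

#' Augmentation specification
#'
#' @param op One of `"ROTATE"`, `"RANDOM_CROP"`, `"BRIGHTNESS"`,
#'   `"SHADOW"`, `"CHROMA"`.
#' @param params Op-specific parameter list:
#'   * ROTATE: `angle` in degrees (clockwise; right angles are exact).
#'   * RANDOM_CROP: `frac` in (0, 1], side fraction of the crop window,
#'     which is resized back to the input size (so object sizes scale by
#'     `1/frac`); optional `x0`, `y0` to pin the window.
#'   * BRIGHTNESS: `gain` > 0.
#'   * SHADOW: `opacity` in [0, 1], `extent` in (0, 1] (radius fraction of
#'     the shorter side) for a random convex quadrilateral.
#'   * CHROMA: `gains`, length-3 positive per-channel multipliers.
#' @param seed Integer seed fixing any randomness in the op.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(op, params = list(), seed = 1L) {
  op <- match.arg(op, AUG_OPS)
  defaults <- switch(op,
    ROTATE = list(angle = 90),
    RANDOM_CROP = list(frac = 0.5, x0 = NULL, y0 = NULL),
    BRIGHTNESS = list(gain = 1.1),
    SHADOW = list(opacity = 0.4, extent = 0.3),
    CHROMA = list(gains = c(1.0, 1.0, 1.0))
  )
  p <- utils::modifyList(defaults, params)
  if (op == "RANDOM_CROP" && (p$frac <= 0 || p$frac > 1))
    stop("RANDOM_CROP frac must be in (0, 1]")
  if (op == "BRIGHTNESS" && p$gain <= 0) stop("BRIGHTNESS gain must be > 0")
  if (op == "SHADOW" && (p$opacity < 0 || p$opacity > 1))
    stop("SHADOW opacity must be in [0, 1]")
  if (op == "CHROMA" && (length(p$gains) != 3 || any(p$gains <= 0)))
    stop("CHROMA gains must be 3 positive values")
  structure(list(op = op, params = p, seed = as.integer(seed)),
            class = "augmentation_spec")
}

rot90cw_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]

rot90cw_raster <- function(img) {
  d <- dim(img)
  out <- array(0, dim = c(d[2], d[1], 3))
  for (ch in 1:3) out[, , ch] <- rot90cw_mat(img[, , ch])
  out
}

# Map box corners through a point transform and refit the axis-aligned hull.
refit_boxes <- function(boxes, point_map) {
  if (nrow(boxes) == 0) return(boxes)
  cs <- lapply(list(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)), function(s) {
    point_map(boxes$cx + s[1] * boxes$w / 2, boxes$cy + s[2] * boxes$h / 2)
  })
  xs <- sapply(cs, `[[`, "x"); ys <- sapply(cs, `[[`, "y")
  if (nrow(boxes) == 1) { xs <- matrix(xs, 1); ys <- matrix(ys, 1) }
  x1 <- apply(xs, 1, min); x2 <- apply(xs, 1, max)
  y1 <- apply(ys, 1, min); y2 <- apply(ys, 1, max)
  boxes$cx <- (x1 + x2) / 2; boxes$cy <- (y1 + y2) / 2
  boxes$w <- x2 - x1; boxes$h <- y2 - y1
  boxes
}

aug_rotate <- function(img, anns, angle) {
  W <- anns$image_spec$width_px; H <- anns$image_spec$height_px
  angle <- angle %% 360
  if (angle %% 90 == 0) {
    k <- (angle %/% 90) %% 4
    boxes <- anns$boxes
    newW <- W; newH <- H
    for (i in seq_len(k)) {
      # 90 deg clockwise about the frame: (x, y) -> (H - y, x)
      if (nrow(boxes) > 0) {
        ncx <- newH - boxes$cy; ncy <- boxes$cx
        nw <- boxes$h; nh <- boxes$w
        boxes$cx <- ncx; boxes$cy <- ncy; boxes$w <- nw; boxes$h <- nh
      }
      if (!is.null(img)) img <- rot90cw_raster(img)
      tmp <- newW; newW <- newH; newH <- tmp
    }
    spec <- image_spec(newW, newH, anns$image_spec$gsd_cm_per_px)
    return(list(image = img,
                anns = annotation_set(anns$image_id, spec, boxes)))
  }
  # small-angle rotation about the image center, output size preserved
  th <- angle * pi / 180
  cxr <- W / 2; cyr <- H / 2
  fwd <- function(x, y) {
    dx <- x - cxr; dy <- y - cyr
    list(x = cos(th) * dx - sin(th) * dy + cxr,
         y = sin(th) * dx + cos(th) * dy + cyr)
  }
  boxes <- refit_boxes(anns$boxes, fwd)
  if (nrow(boxes) > 0) boxes <- clip_boxes(boxes, W, H)
  if (!is.null(img)) {
    yy <- matrix(seq_len(H) - 0.5, nrow = H, ncol = W)
    xx <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
    dx <- xx - cxr; dy <- yy - cyr
    sx <- cos(th) * dx + sin(th) * dy + cxr   # inverse rotation
    sy <- -sin(th) * dx + cos(th) * dy + cyr
    ci <- pmin(pmax(ceiling(sx), 1L), W)
    ri <- pmin(pmax(ceiling(sy), 1L), H)
    idx <- cbind(as.vector(ri), as.vector(ci))
    out <- img
    for (ch in 1:3) out[, , ch] <- matrix(img[, , ch][idx], nrow = H)
    img <- out
  }
  list(image = img, anns = annotation_set(anns$image_id, anns$image_spec, boxes))
}

aug_random_crop <- function(img, anns, frac, x0 = NULL, y0 = NULL, seed = 1L,
                            min_visible_frac = 0.5) {
  W <- anns$image_spec$width_px; H <- anns$image_spec$height_px
  cw <- max(round(W * frac), 1L); chh <- max(round(H * frac), 1L)
  if (cw < 1 || chh < 1) stop("crop window smaller than 1 px")
  if (is.null(x0) || is.null(y0)) {
    pos <- withr::with_seed(seed, c(
      if (W > cw) sample.int(W - cw + 1L, 1L) - 1L else 0L,
      if (H > chh) sample.int(H - chh + 1L, 1L) - 1L else 0L))
    if (is.null(x0)) x0 <- pos[1]
    if (is.null(y0)) y0 <- pos[2]
  }
  b <- anns$boxes
  if (nrow(b) > 0) {
    area0 <- b$w * b$h
    b$cx <- b$cx - x0; b$cy <- b$cy - y0
    x1 <- pmax(b$cx - b$w / 2, 0); x2 <- pmin(b$cx + b$w / 2, cw)
    y1 <- pmax(b$cy - b$h / 2, 0); y2 <- pmin(b$cy + b$h / 2, chh)
    vis <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0) / area0
    keep <- vis >= min_visible_frac
    b <- b[keep, , drop = FALSE]
    if (nrow(b) > 0) {
      b$cx <- (x1[keep] + x2[keep]) / 2; b$cy <- (y1[keep] + y2[keep]) / 2
      b$w <- x2[keep] - x1[keep]; b$h <- y2[keep] - y1[keep]
      # resize back to the input frame: sizes scale by 1/frac
      b$cx <- b$cx * W / cw; b$w <- b$w * W / cw
      b$cy <- b$cy * H / chh; b$h <- b$h * H / chh
    }
    rownames(b) <- NULL
  }
  if (!is.null(img)) {
    img <- img[(y0 + 1):(y0 + chh), (x0 + 1):(x0 + cw), , drop = FALSE]
    img <- resize_nn(img, W, H)
  }
  list(image = img, anns = annotation_set(anns$image_id, anns$image_spec, b))
}

aug_shadow <- function(img, opacity, extent, seed) {
  if (is.null(img)) return(NULL)
  d <- raster_dims(img)
  W <- d["width"]; H <- d["height"]
  q <- withr::with_seed(seed, {
    ctr <- c(stats::runif(1, 0.2, 0.8) * W, stats::runif(1, 0.2, 0.8) * H)
    r <- extent * min(W, H)
    ang <- sort(stats::runif(4, 0, 2 * pi))
    list(x = ctr[1] + r * cos(ang), y = ctr[2] + r * sin(ang))
  })
  # convex polygon with vertices in angular order: inside = same side of
  # every directed edge
  xx <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
  yy <- matrix(seq_len(H) - 0.5, nrow = H, ncol = W)
  inside <- matrix(TRUE, H, W)
  for (i in 1:4) {
    j <- i %% 4 + 1
    ex <- q$x[j] - q$x[i]; ey <- q$y[j] - q$y[i]
    cross <- ex * (yy - q$y[i]) - ey * (xx - q$x[i])
    inside <- inside & (cross >= 0)
  }
  fac <- 1 - opacity * inside
  for (ch in 1:3) img[, , ch] <- img[, , ch] * fac
  img
}

#' Apply one augmentation to an image and its annotations
#'
#' Photometric operations (BRIGHTNESS, SHADOW, CHROMA) never change box
#' coordinates.  ROTATE maps box corners and refits the axis-aligned hull
#' (right angles are exact; small angles inflate boxes slightly).
#' RANDOM_CROP crops, drops boxes below the visibility threshold, and
#' resizes back to the input size so downstream detector input is
#' unchanged -- object sizes scale by `1/frac`.
#'
#' @param img A `[h, w, 3]` raster in [0, 1], or `NULL` for label-only
#'   augmentation (geometric ops still transform the boxes).
#' @param anns The matching [annotation_set()].
#' @param spec An [augmentation_spec()].
#' @return `list(image =, anns =)`.
#' @export
augment_one <- function(img, anns, spec) {
  stopifnot(inherits(spec, "augmentation_spec"), is_annotation_set(anns))
  if (!is.null(img)) {
    d <- raster_dims(img)
    if (d["width"] != anns$image_spec$width_px ||
        d["height"] != anns$image_spec$height_px)
      stop("image and annotation dimensions disagree")
  }
  p <- spec$params
  switch(spec$op,
    ROTATE = aug_rotate(img, anns, p$angle),
    RANDOM_CROP = aug_random_crop(img, anns, p$frac, p$x0, p$y0, spec$seed),
    BRIGHTNESS = list(image = if (is.null(img)) NULL else clamp01(img * p$gain),
                      anns = anns),
    SHADOW = list(image = aug_shadow(img, p$opacity, p$extent, spec$seed),
                  anns = anns),
    CHROMA = list(
      image = if (is.null(img)) NULL else {
        for (ch in 1:3) img[, , ch] <- clamp01(img[, , ch] * p$gains[ch])
        img
      },
      anns = anns)
  )
}

sample_aug_spec <- function(op, seed) {
  params <- withr::with_seed(seed, switch(op,
    ROTATE = list(angle = if (stats::runif(1) < 0.5)
      sample(c(90, 180, 270), 1) else stats::runif(1, -15, 15)),
    RANDOM_CROP = list(frac = stats::runif(1, 0.5, 0.9)),
    BRIGHTNESS = list(gain = stats::runif(1, 0.7, 1.3)),
    SHADOW = list(opacity = stats::runif(1, 0.3, 0.6),
                  extent = stats::runif(1, 0.2, 0.4)),
    CHROMA = list(gains = stats::runif(3, 0.8, 1.2))
  ))
  augmentation_spec(op, params, seed = seed)
}

#' Expand a dataset by sampled augmentation
#'
#' Keeps every source entry and adds derived copies, sampling operations
#' uniformly with replacement until `target_count` entries exist.  (The
#' canonical expansion is 800 sources to 4,200 entries, which is not an
#' integer multiple of the five ops -- hence sampling rather than applying
#' each op once per image.)  A manifest records the provenance of every
#' derived entry; the same seed reproduces it byte for byte.
#'
#' @param dataset List of entries, each `list(image =, anns =)` (image may
#'   be `NULL`) or a bare [annotation_set()].
#' @param target_count Total entries wanted (>= `length(dataset)`).
#' @param seed Integer seed.
#' @param ops Operations to sample from (default all five).
#' @return `list(dataset =, manifest =)` where the manifest has columns
#'   `derived_id, source_id, op, params_json, seed`.
#' @export
augment_dataset <- function(dataset, target_count, seed = 1L, ops = AUG_OPS) {
  if (length(dataset) == 0) stop("source dataset is empty")
  dataset <- lapply(dataset, function(e) {
    if (is_annotation_set(e)) list(image = NULL, anns = e) else e
  })
  n_src <- length(dataset)
  if (target_count < n_src)
    stop("target_count must be >= the source count")
  n_new <- target_count - n_src
  draws <- withr::with_seed(seed, data.frame(
    src = if (n_new > 0) sample.int(n_src, n_new, replace = TRUE) else integer(0),
    op = if (n_new > 0) sample(ops, n_new, replace = TRUE) else character(0),
    op_seed = if (n_new > 0)
      sample.int(.Machine$integer.max %/% 2L, n_new) else integer(0)
  ))
  out <- dataset
  manifest <- vector("list", n_new)
  for (i in seq_len(n_new)) {
    src <- dataset[[draws$src[i]]]
    spec <- sample_aug_spec(draws$op[i], draws$op_seed[i])
    res <- augment_one(src$image, src$anns, spec)
    derived_id <- sprintf("%s_aug%04d", src$anns$image_id, i)
    res$anns$image_id <- derived_id
    out[[n_src + i]] <- res
    manifest[[i]] <- data.frame(
      derived_id = derived_id,
      source_id = src$anns$image_id,
      op = spec$op,
      params_json = as.character(
        jsonlite::toJSON(spec$params, auto_unbox = TRUE, digits = 8)),
      seed = spec$seed
    )
  }
  manifest <- if (n_new > 0) do.call(rbind, manifest) else
    data.frame(derived_id = character(0), source_id = character(0),
               op = character(0), params_json = character(0),
               seed = integer(0))
  list(dataset = out, manifest = manifest)
}
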