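# Synthetic maize-canopy scenes with exact ground truth, so the whole
# blocking -> detection -> fusion -> evaluation chain runs without any
# field data.  Plants sit on a jittered agronomic grid (default 25 cm
# plant spacing, 60 cm row spacing); each plant carries one tassel state.
# Glyph rendering is deliberately schematic: the evaluation surface of the
# package is geometry and counting, and the mock detector is
# truth-conditioned, so photorealism would buy nothing.

STAGES <- c("SPIKELET", "TASSELING", "DETASSELED")

stage_default_mixture <- function(stage, sex = c("female", "male")) {
  sex <- match.arg(sex)
  switch(stage,
    SPIKELET = c(0.02, 0.88, 0.10),     # Tassel-S dominant, sporadic L
    TASSELING = c(0.02, 0.18, 0.80),    # Tassel-L occupies most plants
    DETASSELED = if (sex == "female") c(0.90, 0.08, 0.02)
                 else c(0.05, 0.35, 0.60)  # male pollen rows keep S/L
  )
}

#' Scene configuration
#'
#' @param image [image_spec()] of the frame (desk default 2048 x 2048 at
#'   0.25 cm/px; use [uav_frame_spec()] for the full survey frame).
#' @param plant_spacing_cm,row_spacing_cm Agronomic grid (defaults 25 and
#'   60 cm -> 100 and 240 px at the default GSD).
#' @param stage Growth stage: `"SPIKELET"`, `"TASSELING"` or
#'   `"DETASSELED"`.
#' @param mixture Optional length-3 probability vector (N, S, L) overriding
#'   the stage default for every plant.
#' @param female_rows,male_rows Row arrangement of the hybridization field
#'   (default 4 female : 1 male); only the DETASSELED stage differentiates
#'   the sexes.
#' @param occlusion_prob Probability that a plant's tassel is hidden by
#'   leaves and therefore absent from both truth and render.
#' @param jitter_px SD of plant-position jitter in pixels.
#' @param elongation Perspective-distortion surrogate: the radial axis of
#'   emerged-tassel boxes (and glyphs) is stretched by
#'   `1 + elongation * r / 1000` at radial distance `r` px from the frame
#'   center.  0 disables it.
#' @param box_side Fixed square side for Tassel-N/S truth boxes (px).
#' @param l_area_mean,l_area_sd Area distribution (px^2) of emerged-tassel
#'   boxes before elongation; the aspect ratio is `l_ratio`.
#' @param l_ratio Length-width ratio (min/max) of emerged-tassel boxes.
#' @param seed Integer seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image = image_spec(2048, 2048, 0.25),
                         plant_spacing_cm = 25, row_spacing_cm = 60,
                         stage = "TASSELING", mixture = NULL,
                         female_rows = 4L, male_rows = 1L,
                         occlusion_prob = 0.05, jitter_px = 10,
                         elongation = 0.05, box_side = 140,
                         l_area_mean = 8647, l_area_sd = 2000,
                         l_ratio = 0.75, seed = 1L) {
  stage <- match.arg(stage, STAGES)
  stopifnot(is_image_spec(image))
  if (plant_spacing_cm <= 0 || row_spacing_cm <= 0)
    stop("spacings must be > 0")
  if (!is.null(mixture)) {
    if (length(mixture) != 3 || any(mixture < 0) ||
        abs(sum(mixture) - 1) > 1e-9)
      stop("mixture must be a length-3 probability vector")
  }
  if (occlusion_prob < 0 || occlusion_prob > 1)
    stop("occlusion_prob must be in [0, 1]")
  plant_px <- plant_spacing_cm / image$gsd_cm_per_px
  row_px <- row_spacing_cm / image$gsd_cm_per_px
  glyph_px <- 60  # conservative glyph footprint
  if (plant_px < glyph_px || row_px < glyph_px)
    stop(sprintf("spacing (%g x %g px) smaller than the glyph footprint (%d px)",
                 plant_px, row_px, glyph_px))
  structure(list(image = image, plant_spacing_cm = plant_spacing_cm,
                 row_spacing_cm = row_spacing_cm, plant_px = plant_px,
                 row_px = row_px, stage = stage, mixture = mixture,
                 female_rows = as.integer(female_rows),
                 male_rows = as.integer(male_rows),
                 occlusion_prob = occlusion_prob, jitter_px = jitter_px,
                 elongation = elongation, box_side = box_side,
                 l_area_mean = l_area_mean, l_area_sd = l_area_sd,
                 l_ratio = l_ratio, seed = as.integer(seed)),
            class = "scene_config")
}

# Paint a filled ellipse into a raster window (in place, returns raster).
paint_ellipse <- function(img, cx, cy, rx, ry, color) {
  d <- dim(img)
  x1 <- max(1L, floor(cx - rx)); x2 <- min(d[2], ceiling(cx + rx))
  y1 <- max(1L, floor(cy - ry)); y2 <- min(d[1], ceiling(cy + ry))
  if (x2 < x1 || y2 < y1) return(img)
  xs <- x1:x2; ys <- y1:y2
  mask <- outer((ys - 0.5 - cy)^2 / ry^2, (xs - 0.5 - cx)^2 / rx^2, `+`) <= 1
  for (ch in 1:3) {
    win <- img[ys, xs, ch]
    win[mask] <- color[ch]
    img[ys, xs, ch] <- win
  }
  img
}

#' Generate a synthetic canopy scene
#'
#' Lays plants on the jittered grid, assigns each a tassel state from the
#' stage mixture (the detasseled stage assigns Tassel-N predominantly on
#' female rows and S/L on male pollen rows), builds truth boxes --
#' fixed squares for Tassel-N/S, glyph-hugging rectangles for Tassel-L --
#' and optionally renders a schematic raster.  Deterministic under the
#' config seed.
#'
#' @param cfg A [scene_config()].
#' @param render Render the raster (`TRUE`) or produce truth only
#'   (`FALSE`; full 8192 x 5460 frames are cheap this way because the mock
#'   detector never looks at pixels).
#' @param image_id Identifier for the annotation set.
#' @return `list(image = <raster or NULL>, truth = <scene_truth>)` where
#'   `scene_truth` carries the [annotation_set()], per-category `totals`,
#'   and the `plants` grid metadata.
#' @export
generate_scene <- function(cfg, render = TRUE, image_id = "scene") {
  stopifnot(inherits(cfg, "scene_config"))
  img <- cfg$image
  W <- img$width_px; H <- img$height_px
  margin <- 80
  ys <- seq(margin, H - margin, by = cfg$row_px)
  xs <- seq(margin, W - margin, by = cfg$plant_px)
  n_rows <- length(ys); n_per_row <- length(xs)
  cycle <- c(rep("female", cfg$female_rows), rep("male", cfg$male_rows))
  withr::with_seed(cfg$seed, {
    plants <- data.frame(
      row = rep(seq_len(n_rows), each = n_per_row),
      pos = rep(seq_len(n_per_row), times = n_rows),
      sex = rep(cycle[((seq_len(n_rows) - 1L) %% length(cycle)) + 1L],
                each = n_per_row)
    )
    n <- nrow(plants)
    # truncated jitter: mechanical seeding keeps plants near their grid
    # node, and the cap guarantees distinct plants stay farther apart
    # than the 50-px duplicate-merge radius at default spacings
    jx_max <- min(3 * cfg$jitter_px, 0.24 * cfg$plant_px)
    jy_max <- min(3 * cfg$jitter_px, 0.24 * cfg$row_px)
    jx <- pmin(pmax(stats::rnorm(n, 0, cfg$jitter_px), -jx_max), jx_max)
    jy <- pmin(pmax(stats::rnorm(n, 0, cfg$jitter_px), -jy_max), jy_max)
    plants$cx <- pmin(pmax(rep(xs, times = n_rows) + jx, margin / 2),
                      W - margin / 2)
    plants$cy <- pmin(pmax(rep(ys, each = n_per_row) + jy, margin / 2),
                      H - margin / 2)
    plants$class <- vapply(seq_len(n), function(i) {
      mix <- if (!is.null(cfg$mixture)) cfg$mixture
             else stage_default_mixture(cfg$stage, plants$sex[i])
      sample.int(3L, 1L, prob = mix) - 1L
    }, integer(1))
    plants$occluded <- stats::runif(n) < cfg$occlusion_prob
    vis <- plants[!plants$occluded, , drop = FALSE]
    # truth boxes
    nv <- nrow(vis)
    w <- numeric(nv); h <- numeric(nv)
    ns <- vis$class != 2L
    w[ns] <- cfg$box_side; h[ns] <- cfg$box_side
    if (any(!ns)) {
      nl <- sum(!ns)
      area <- pmax(stats::rnorm(nl, cfg$l_area_mean, cfg$l_area_sd), 2000)
      long <- sqrt(area / cfg$l_ratio)
      short <- area / long
      horiz <- stats::runif(nl) < 0.5
      w[!ns] <- ifelse(horiz, long, short)
      h[!ns] <- ifelse(horiz, short, long)
      # perspective surrogate: stretch the dominant radial axis
      if (cfg$elongation > 0) {
        dx <- vis$cx[!ns] - W / 2; dy <- vis$cy[!ns] - H / 2
        r <- sqrt(dx^2 + dy^2)
        f <- 1 + cfg$elongation * r / 1000
        xdom <- abs(dx) >= abs(dy)
        w[!ns][xdom] <- w[!ns][xdom] * f[xdom]
        h[!ns][!xdom] <- h[!ns][!xdom] * f[!xdom]
      }
    }
    boxes <- clip_boxes(data.frame(class = vis$class, cx = vis$cx,
                                   cy = vis$cy, w = w, h = h), W, H)
    anns <- annotation_set(image_id, img, boxes)
    raster <- NULL
    if (render) {
      raster <- raster_new(W, H, c(0.16, 0.33, 0.10))
      noise <- stats::runif(H * W, -0.03, 0.03)
      for (ch in 1:3) raster[, , ch] <- clamp01(raster[, , ch] + noise)
      for (i in seq_len(nv)) {
        cx <- vis$cx[i]; cy <- vis$cy[i]
        raster <- switch(as.character(vis$class[i]),
          "0" = paint_ellipse(raster, cx, cy, 24, 24, c(0.08, 0.15, 0.05)),
          "1" = paint_ellipse(raster, cx, cy, 14, 14, c(0.75, 0.78, 0.55)),
          "2" = {
            tmp <- paint_ellipse(raster, cx, cy, w[i] / 2 * 0.9,
                                 h[i] / 2 * 0.9, c(0.82, 0.72, 0.35))
            paint_ellipse(tmp, cx, cy, 6, 6, c(0.9, 0.85, 0.5))
          })
      }
    }
  })
  totals <- vapply(tassel_categories(),
                   function(code) sum(anns$boxes$class == code), integer(1))
  truth <- structure(list(anns = anns, totals = totals, plants = plants,
                          config = cfg),
                     class = "scene_truth")
  list(image = raster, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %s stage: %d plants, truth [%s]\n",
              x$config$stage, nrow(x$plants),
              paste(names(x$totals), x$totals, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Raster-free annotation fixtures
#'
#' Samples datasets of labeled boxes with requested category mixture and
#' box-size moments -- enough statistical structure to exercise the
#' annotation, statistics and metric code without rendering anything.
#'
#' @param n_images Number of images.
#' @param boxes_per_image Either a fixed count or a function
#'   `f(n_images)` returning per-image counts.
#' @param mixture Length-3 category probability vector (N, S, L).
#' @param area_mean,area_sd Box-area distribution (px^2, normal, truncated
#'   at 100).
#' @param ratio_mean,ratio_sd Length-width ratio distribution (min/max,
#'   truncated to (0.05, 1]).
#' @param img [image_spec()] for every image.
#' @param seed Integer seed.
#' @return A list of [annotation_set()] objects.
#' @export
generate_annotation_fixture <- function(n_images = 10,
                                        boxes_per_image = 50,
                                        mixture = c(0.4093, 0.3524, 0.2383),
                                        area_mean = 5784, area_sd = 1186,
                                        ratio_mean = 0.95, ratio_sd = 0.06,
                                        img = image_spec(1024, 1024, 0.25),
                                        seed = 1L) {
  if (length(mixture) != 3 || any(mixture < 0))
    stop("mixture must be 3 non-negative probabilities")
  counts <- if (is.function(boxes_per_image)) boxes_per_image(n_images)
            else rep(boxes_per_image, n_images)
  withr::with_seed(seed, {
    lapply(seq_len(n_images), function(j) {
      n <- counts[j]
      cls <- sample.int(3L, n, replace = TRUE, prob = mixture) - 1L
      area <- pmax(stats::rnorm(n, area_mean, area_sd), 100)
      ratio <- pmin(pmax(stats::rnorm(n, ratio_mean, ratio_sd), 0.05), 1)
      long <- sqrt(area / ratio)
      short <- area / long
      horiz <- stats::runif(n) < 0.5
      w <- ifelse(horiz, long, short)
      h <- ifelse(horiz, short, long)
      m <- max(long) / 2
      annotation_set(sprintf("fixture_%03d", j), img, data.frame(
        class = cls,
        cx = stats::runif(n, m, img$width_px - m),
        cy = stats::runif(n, m, img$height_px - m),
        w = w, h = h))
    })
  })
}
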