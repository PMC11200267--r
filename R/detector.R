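# The pluggable detection contract.  Detections are rows of a data.frame
#   class, cx, cy, w, h, conf, block_id
# in block-local pixel coordinates until remapped (see fusion.R).
#
# The mock detector is truth-conditioned: it samples detection errors on
# the ground-truth boxes of a block instead of doing vision.  Its radial
# miss-rate term is a surrogate for perspective distortion, which degrades
# real detectors increasingly with distance from the UAV frame center.

empty_detections <- function() {
  data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0), conf = numeric(0),
             block_id = integer(0))
}

#' Mock detector error model
#'
#' @param miss_center Per-category miss probability for an object at the
#'   frame center (length 1 or 3, recycled; in [0, 1]).
#' @param miss_slope_per_1000px Added miss probability per 1,000 px of
#'   radial distance of the object from the UAV-frame center (>= 0).  This
#'   is the perspective-distortion surrogate; 0 disables it.
#' @param fp_rate Expected number of spurious detections per block
#'   (Poisson; >= 0).
#' @param jitter_sd Localization noise SD in pixels (>= 0).
#' @param confusion 3x3 row-stochastic category confusion matrix
#'   (rows = true category N/S/L, columns = reported category).
#' @param conf_base,conf_sd Reported confidence is
#'   `conf_base + N(0, conf_sd)`, clamped to [0, 1].
#' @return An object of class `mock_detector_params`.
#' @export
mock_detector_params <- function(miss_center = 0.02,
                                 miss_slope_per_1000px = 0,
                                 fp_rate = 0,
                                 jitter_sd = 0,
                                 confusion = diag(3),
                                 conf_base = 0.85,
                                 conf_sd = 0.05) {
  miss_center <- rep_len(miss_center, 3)
  if (any(miss_center < 0 | miss_center > 1))
    stop("miss_center must be in [0, 1]")
  if (miss_slope_per_1000px < 0) stop("miss_slope_per_1000px must be >= 0")
  if (fp_rate < 0) stop("fp_rate must be >= 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3, 3)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-9))
    stop("confusion must be a 3x3 row-stochastic matrix")
  structure(list(miss_center = miss_center,
                 miss_slope_per_1000px = miss_slope_per_1000px,
                 fp_rate = fp_rate, jitter_sd = jitter_sd,
                 confusion = confusion, conf_base = conf_base,
                 conf_sd = conf_sd),
            class = "mock_detector_params")
}

#' @rdname mock_detector_params
#' @export
perfect_detector_params <- function() {
  mock_detector_params(miss_center = 0, miss_slope_per_1000px = 0,
                       fp_rate = 0, jitter_sd = 0, conf_base = 1, conf_sd = 0)
}

#' Run the mock detector on one block
#'
#' Each ground-truth box is independently dropped with probability
#' `miss_center[category] + slope * r / 1000` (clamped to [0, 1]), where
#' `r` is the distance of the object from the UAV-frame center.  Survivors
#' are emitted with jittered centers, a category drawn from the confusion
#' matrix, and a sampled confidence.  `fp_rate` spurious detections per
#' block (Poisson) are placed uniformly.  Deterministic under `seed`.
#'
#' @param truth Block-local ground truth: an [annotation_set()] as produced
#'   by [crop_annotations_to_block()].
#' @param block The block row (needs `x0`, `y0`, `side`, `block_id`).
#' @param frame The full-frame [image_spec()] (for the radial term).
#' @param params A [mock_detector_params()].
#' @param seed Integer seed.
#' @return A detections data.frame
#'   (`class, cx, cy, w, h, conf, block_id`), block-local coordinates.
#' @export
detect_mock <- function(truth, block, frame, params, seed = 1L) {
  stopifnot(inherits(params, "mock_detector_params"),
            is_annotation_set(truth), is_image_spec(frame))
  b <- truth$boxes
  side <- as.integer(block$side)
  withr::with_seed(seed, {
    dets <- empty_detections()
    if (nrow(b) > 0) {
      gx <- b$cx + block$x0; gy <- b$cy + block$y0
      r <- sqrt((gx - frame$width_px / 2)^2 + (gy - frame$height_px / 2)^2)
      p_miss <- pmin(1, params$miss_center[b$class + 1L] +
                          params$miss_slope_per_1000px * r / 1000)
      kept <- stats::runif(nrow(b)) >= p_miss
      if (any(kept)) {
        k <- which(kept)
        cls <- vapply(k, function(i) {
          sample.int(3L, 1L, prob = params$confusion[b$class[i] + 1L, ]) - 1L
        }, integer(1))
        # anchor on the plant center (full-box center) when the truth comes
        # from label cropping: a detector trained on plant-center squares
        # localizes the plant, not the truncation artifact
        ax <- if (!is.null(b$cx_full)) pmin(pmax(b$cx_full, 0), side) else b$cx
        ay <- if (!is.null(b$cy_full)) pmin(pmax(b$cy_full, 0), side) else b$cy
        dets <- data.frame(
          class = cls,
          cx = ax[k] + stats::rnorm(length(k), 0, params$jitter_sd),
          cy = ay[k] + stats::rnorm(length(k), 0, params$jitter_sd),
          w = b$w[k], h = b$h[k],
          conf = clamp01(params$conf_base +
                           stats::rnorm(length(k), 0, params$conf_sd)),
          block_id = as.integer(block$block_id)
        )
        dets$cx <- pmin(pmax(dets$cx, 0), side)
        dets$cy <- pmin(pmax(dets$cy, 0), side)
      }
    }
    n_fp <- stats::rpois(1, params$fp_rate)
    if (n_fp > 0) {
      fp <- data.frame(
        class = sample.int(3L, n_fp, replace = TRUE) - 1L,
        cx = stats::runif(n_fp, 0, side),
        cy = stats::runif(n_fp, 0, side),
        w = 140, h = 140,
        conf = clamp01(stats::runif(n_fp, 0.3, 0.9)),
        block_id = as.integer(block$block_id)
      )
      dets <- rbind(dets, fp)
    }
    rownames(dets) <- NULL
    dets
  })
}

#' Run the mock detector over every block of a plan
#'
#' Crops the frame truth to each block (visibility threshold
#' `min_visible_frac`), runs [detect_mock()] per block with a seed derived
#' from `seed`, and row-binds the block-local detections.
#'
#' @param truth Full-frame [annotation_set()].
#' @param plan A `blocking_plan` over the truth's image.
#' @param params A [mock_detector_params()].
#' @param seed Integer seed.
#' @param min_visible_frac Passed to [crop_annotations_to_block()].
#' @return A detections data.frame, block-local, tagged with `block_id`.
#' @export
detect_plan <- function(truth, plan, params, seed = 1L,
                        min_visible_frac = 0.5) {
  blocks <- plan$blocks
  res <- lapply(seq_len(nrow(blocks)), function(i) {
    blk <- blocks[i, ]
    local_truth <- crop_annotations_to_block(truth, blk, min_visible_frac)
    detect_mock(local_truth, blk, truth$image_spec, params,
                seed = as.integer((as.numeric(seed) * 131 + blk$block_id) %%
                                    2147483647))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_detections()
  rownames(out) <- NULL
  out
}

#' Import externally produced block detections
#'
#' Parses the 6-column detection format `class cx cy w h conf` (coordinates
#' normalized to the block side) written next to each block crop by real
#' detectors, and tags each record with its block.
#'
#' @param x A named list (names = block ids) of file paths or character
#'   vectors of detection lines.
#' @param plan The `blocking_plan` the blocks came from.
#' @return A detections data.frame in block-local pixel coordinates.
#' @export
import_detections <- function(x, plan) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("x must be a named list keyed by block id")
  side <- plan$block_side
  known <- plan$blocks$block_id
  out <- lapply(names(x), function(bid_chr) {
    bid <- as.integer(bid_chr)
    if (!(bid %in% known))
      stop(sprintf("unknown block id '%s'", bid_chr))
    item <- x[[bid_chr]]
    lines <- if (length(item) == 1 && !grepl("\n", item) && file.exists(item))
      readLines(item, warn = FALSE)
    else unlist(strsplit(item, "\n", fixed = TRUE))
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(empty_detections())
    parts <- strsplit(lines, "[[:space:]]+")
    bad <- which(lengths(parts) != 6L)
    if (length(bad) > 0)
      stop(sprintf("detection format error (block %s, line %d): expected 6 fields",
                   bid_chr, bad[1]))
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 6,
                byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("detection format error (block %s, line %d): non-numeric field",
                   bid_chr, which(apply(m, 1, anyNA))[1]))
    if (any(!(m[, 1] %in% tassel_categories())))
      stop(sprintf("detection format error (block %s): class code outside {0,1,2}",
                   bid_chr))
    if (any(m[, 2:6] < 0 | m[, 2:6] > 1))
      stop(sprintf("detection format error (block %s, line %d): value outside [0,1]",
                   bid_chr, which(apply(m[, 2:6, drop = FALSE] < 0 |
                                          m[, 2:6, drop = FALSE] > 1, 1, any))[1]))
    data.frame(class = as.integer(m[, 1]),
               cx = m[, 2] * side, cy = m[, 3] * side,
               w = m[, 4] * side, h = m[, 5] * side,
               conf = m[, 6], block_id = bid)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export block-local detections to the 6-column text format
#'
#' @param dets Detections data.frame for a single block.
#' @param side Block side in pixels (for normalization).
#' @return Character vector of lines `class cx cy w h conf`.
#' @export
export_detections <- function(dets, side) {
  if (nrow(dets) == 0) return(character(0))
  sprintf("%d %.6f %.6f %.6f %.6f %.6f", dets$class,
          dets$cx / side, dets$cy / side, dets$w / side, dets$h / side,
          dets$conf)
}

#' Confidence screening
#'
#' Keeps detections with confidence at or above the threshold, preserving
#' order.  Lowering the threshold never decreases the detection count
#' (and, downstream, can only raise the missed-detection rate toward zero).
#'
#' @param dets Detections data.frame.
#' @param confidence_threshold Threshold in [0, 1] (default 0.3).
#' @return The filtered detections.
#' @export
screen <- function(dets, confidence_threshold = 0.3) {
  if (confidence_threshold < 0 || confidence_threshold > 1)
    stop("confidence_threshold must be in [0, 1]")
  out <- dets[dets$conf >= confidence_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
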