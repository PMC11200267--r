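# Block-to-frame remapping and category-wise redundant-detection merging.
#
# Overlapping blocks detect the same tassel more than once; merging is by
# proximity within a category (default radius 50 px), not by IoU
# suppression, because duplicated detections of one plant center can have
# barely-overlapping boxes yet nearly coincident centers.

#' Remap block-local detections to frame coordinates
#'
#' Adds the block origin to each detection center; box sizes are
#' unchanged.  The result gains `global_cx`/`global_cy` columns.
#'
#' @param dets Detections data.frame with a `block_id` column.
#' @param plan The `blocking_plan` the block ids refer to.
#' @return The detections with global coordinates attached.
#' @export
to_global <- function(dets, plan) {
  if (nrow(dets) == 0) {
    dets$global_cx <- numeric(0); dets$global_cy <- numeric(0)
    return(dets)
  }
  if (is.null(dets$block_id) || anyNA(dets$block_id))
    stop("detections must carry a block_id to be remapped")
  i <- match(dets$block_id, plan$blocks$block_id)
  if (anyNA(i)) stop("detection references a block id not in the plan")
  dets$global_cx <- dets$cx + plan$blocks$x0[i]
  dets$global_cy <- dets$cy + plan$blocks$y0[i]
  dets
}

# Union-find single linkage: connected components of the "centers within
# radius" graph, computed without materializing the full distance matrix.
single_linkage_components <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r2 <- radius^2
  for (i in seq_len(max(n - 1, 0))) {
    d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
    for (j in which(d2 <= r2)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge redundant detections by category and proximity
#'
#' Within each category, detections are clustered by single linkage on
#' center distance at the given radius; categories never merge across.
#' Each cluster yields one fused object at the confidence-weighted mean
#' center, carrying the maximum member confidence.  Input is first sorted
#' by confidence (descending), then x, then y, which makes the result
#' invariant to input permutation.
#'
#' A one-pass greedy alternative (`method = "greedy"`) absorbs each
#' detection into the first already-kept object of its category within the
#' radius, in the same sorted order.
#'
#' @param dets Detections with `global_cx`/`global_cy` (see [to_global()]).
#' @param radius_px Merge radius in pixels (default 50).
#' @param method `"single"` (default) or `"greedy"`.
#' @return A data.frame of fused objects:
#'   `class, cx, cy, conf, members, member_ids` (the latter a
#'   semicolon-joined list of input row indices after sorting).
#' @export
merge_redundant <- function(dets, radius_px = 50, method = c("single", "greedy")) {
  if (radius_px < 0) stop("radius_px must be >= 0")
  method <- match.arg(method)
  empty <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      conf = numeric(0), members = integer(0),
                      member_ids = character(0))
  if (nrow(dets) == 0) return(empty)
  if (is.null(dets$global_cx))
    stop("detections must be in global coordinates (run to_global first)")
  ord <- order(-dets$conf, dets$global_cx, dets$global_cy)
  d <- dets[ord, , drop = FALSE]
  d$.row <- seq_len(nrow(d))
  out <- lapply(sort(unique(d$class)), function(cl) {
    g <- d[d$class == cl, , drop = FALSE]
    comp <- if (method == "single") {
      single_linkage_components(g$global_cx, g$global_cy, radius_px)
    } else {
      greedy_components(g$global_cx, g$global_cy, radius_px)
    }
    rows <- lapply(unique(comp), function(cc) {
      m <- g[comp == cc, , drop = FALSE]
      wts <- m$conf
      if (sum(wts) == 0) wts <- rep(1, nrow(m))
      data.frame(class = cl,
                 cx = sum(m$global_cx * wts) / sum(wts),
                 cy = sum(m$global_cy * wts) / sum(wts),
                 conf = max(m$conf),
                 members = nrow(m),
                 member_ids = paste(m$.row, collapse = ";"))
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$class, out$cx, out$cy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

greedy_components <- function(x, y, radius) {
  n <- length(x)
  comp <- integer(n)
  kept_x <- numeric(0); kept_y <- numeric(0); kept_id <- integer(0)
  r2 <- radius^2
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(kept_x) > 0) {
      d2 <- (kept_x - x[i])^2 + (kept_y - y[i])^2
      w <- which(d2 <= r2)
      if (length(w) > 0) hit <- kept_id[w[1]]
    }
    if (hit == 0L) {
      kept_x <- c(kept_x, x[i]); kept_y <- c(kept_y, y[i])
      kept_id <- c(kept_id, i)
      comp[i] <- i
    } else comp[i] <- hit
  }
  comp
}

#' Remap and fuse all detections of a plan
#'
#' Applies [to_global()] and [merge_redundant()], returning per-category
#' fused counts ready for count-level evaluation.
#'
#' @param dets Block-local detections with `block_id`.
#' @param plan The `blocking_plan`.
#' @param radius_px Merge radius (default 50 px).
#' @param method Passed to [merge_redundant()].
#' @return `list(fused = <data.frame>, counts = <named integer vector>)`
#'   with one count per category label.
#' @export
fuse_plan <- function(dets, plan, radius_px = 50, method = "single") {
  fused <- merge_redundant(to_global(dets, plan), radius_px, method)
  counts <- vapply(tassel_categories(),
                   function(code) sum(fused$class == code), integer(1))
  list(fused = fused, counts = counts)
}

#' Write fused objects to CSV
#'
#' Columns: `category,cx,cy,conf,members`.
#'
#' @param fused A fused-objects data.frame from [merge_redundant()].
#' @param path Output path.
#' @export
write_fused_csv <- function(fused, path) {
  out <- data.frame(category = category_label(fused$class),
                    cx = fused$cx, cy = fused$cy, conf = fused$conf,
                    members = fused$members)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
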