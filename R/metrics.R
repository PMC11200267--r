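# Detection-level metrics (IoU matching, precision/recall/accuracy, AP and
# mAP@0.5) and count-level metrics (ED, ACC, RMSE, MAE, MPAE, MDR).
#
# Conventions:
# * Matching is category-strict, greedy in confidence order, one-to-one
#   (VOC style).
# * TN is undefined for open-world detection; it is fixed to 0, so the
#   "accuracy" variant TP / (TP + FP + FN) is auxiliary only.
# * AP uses all-points interpolation (area under the precision envelope),
#   sweeping every distinct confidence value; an 11-point variant is
#   available for comparability with older protocols.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are given as centers plus sizes (`cx, cy, w, h`); all arguments
#' are vectorized.
#'
#' @param a,b Data.frames (or lists) with `cx, cy, w, h`.
#' @return IoU values in [0, 1].
#' @export
iou <- function(a, b) {
  ix <- pmax(pmin(a$cx + a$w / 2, b$cx + b$w / 2) -
               pmax(a$cx - a$w / 2, b$cx - b$w / 2), 0)
  iy <- pmax(pmin(a$cy + a$h / 2, b$cy + b$h / 2) -
               pmax(a$cy - a$h / 2, b$cy - b$h / 2), 0)
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Match detections to ground truth
#'
#' Per category, detections are visited in descending confidence order
#' (ties: input order) and matched greedily, one-to-one, to the unmatched
#' truth box of the same category with the highest IoU at or above the
#' threshold.  Unmatched detections are false positives; unmatched truths
#' are false negatives.
#'
#' @param dets Detections data.frame (`class, cx, cy, w, h, conf`).
#' @param truth Ground-truth boxes in the same coordinate frame
#'   (data.frame or [annotation_set()]).
#' @param iou_threshold Minimum IoU to accept a match (default 0.5, the
#'   mAP@0.5 convention).
#' @return A `match_result` list: `per_category` (TP/FP/FN counts),
#'   `det_labels` (per-detection class, confidence, TP flag), `pairs`
#'   (matched det/truth indices with IoU).
#' @export
match_detections <- function(dets, truth, iou_threshold = 0.5) {
  if (is_annotation_set(truth)) truth <- truth$boxes
  det_tp <- logical(nrow(dets))
  pairs <- list()
  truth_used <- logical(nrow(truth))
  ord <- order(-dets$conf)
  for (i in ord) {
    cand <- which(!truth_used & truth$class == dets$class[i])
    if (length(cand) == 0) next
    ious <- iou(dets[i, ], truth[cand, ])
    best <- which.max(ious)                       # ties: first (truth order)
    if (ious[best] >= iou_threshold) {
      det_tp[i] <- TRUE
      truth_used[cand[best]] <- TRUE
      pairs[[length(pairs) + 1]] <-
        data.frame(det = i, truth = cand[best], iou = ious[best])
    }
  }
  cats <- tassel_categories()
  per_category <- do.call(rbind, lapply(names(cats), function(lb) {
    code <- cats[[lb]]
    data.frame(category = lb,
               TP = sum(det_tp & dets$class == code),
               FP = sum(!det_tp & dets$class == code),
               FN = sum(!truth_used & truth$class == code))
  }))
  structure(list(
    per_category = per_category,
    det_labels = data.frame(class = dets$class, conf = dets$conf, tp = det_tp),
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(det = integer(0), truth = integer(0), iou = numeric(0))
  ), class = "match_result")
}

#' Precision, recall and accuracy from a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, and the auxiliary
#' `Acc = (TP + TN) / (TP + FN + FP + TN)` with TN fixed at 0.  A 0/0
#' quotient is reported as 0 with `defined = FALSE`.
#'
#' @param m A `match_result` from [match_detections()].
#' @return `list(precision =, recall =, accuracy =, defined =)` computed on
#'   counts pooled over categories.
#' @export
precision_recall_accuracy <- function(m) {
  tp <- sum(m$per_category$TP)
  fp <- sum(m$per_category$FP)
  fn <- sum(m$per_category$FN)
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(precision = safe(tp, tp + fp),
       recall = safe(tp, tp + fn),
       accuracy = safe(tp, tp + fp + fn),
       defined = (tp + fp) > 0 && (tp + fn) > 0)
}

#' Average precision from labeled detections
#'
#' All-points interpolation: detections are swept over every distinct
#' confidence value (ties enter together); precision is replaced by its
#' running envelope from the right and integrated over recall.
#'
#' @param conf Detection confidences.
#' @param tp Logical TP labels, aligned with `conf`.
#' @param truth_count Number of ground-truth objects (> 0; 0 returns `NA`
#'   with a warning since recall is undefined).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in [0, 1], or `NA` when undefined.
#' @export
average_precision <- function(conf, tp, truth_count,
                              interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  if (truth_count == 0) {
    warning("average_precision undefined for truth_count = 0")
    return(NA_real_)
  }
  if (length(conf) == 0) return(0)
  ord <- order(-conf)
  conf <- conf[ord]; tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  # group tied confidences: operating points exist only at group boundaries
  boundary <- c(conf[-length(conf)] != conf[-1], TRUE)
  rec <- cum_tp[boundary] / truth_count
  prec <- cum_tp[boundary] / (cum_tp[boundary] + cum_fp[boundary])
  if (interpolation == "11point") {
    return(mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p) == 0) 0 else max(p)
    }, numeric(1))))
  }
  mrec <- c(0, rec)
  mpre <- c(0, prec)
  for (i in rev(seq_len(length(mpre) - 1))) # precision envelope
    mpre[i] <- max(mpre[i], mpre[i + 1])
  sum((mrec[-1] - mrec[-length(mrec)]) * mpre[-1])
}

#' Per-category AP and mAP@0.5
#'
#' @param m A `match_result` from [match_detections()] (labels carry
#'   per-detection TP flags and confidences).
#' @param truth_counts Named (or ordered) per-category ground-truth counts;
#'   by default recovered from the match result (`TP + FN`).
#' @param na_rm Drop undefined per-category APs from the mean (default
#'   FALSE: any undefined AP makes the mAP `NA`).
#' @param interpolation Passed to [average_precision()].
#' @return `list(ap = named numeric(3), map = numeric(1))`.
#' @export
map_at_50 <- function(m, truth_counts = NULL, na_rm = FALSE,
                      interpolation = "all") {
  cats <- tassel_categories()
  if (is.null(truth_counts))
    truth_counts <- stats::setNames(m$per_category$TP + m$per_category$FN,
                                    m$per_category$category)
  ap <- vapply(names(cats), function(lb) {
    sel <- m$det_labels$class == cats[[lb]]
    if (truth_counts[[lb]] == 0) return(NA_real_)
    average_precision(m$det_labels$conf[sel], m$det_labels$tp[sel],
                      truth_counts[[lb]], interpolation)
  }, numeric(1))
  list(ap = ap, map = mean(ap, na.rm = na_rm))
}

#' Build a count summary
#'
#' The long-format container for count-level evaluation: one row per image
#' and category with the predicted and manually measured counts.
#'
#' @param image Image identifiers.
#' @param class Category codes (0/1/2).
#' @param predict,gt Non-negative integer counts.
#' @return A `count_summary` data.frame.
#' @export
count_summary <- function(image, class, predict, gt) {
  if (any(predict < 0) || any(gt < 0)) stop("counts must be >= 0")
  if (!all(class %in% tassel_categories())) stop("class codes must be 0/1/2")
  structure(data.frame(image = as.character(image), class = as.integer(class),
                       predict = as.numeric(predict), gt = as.numeric(gt)),
            class = c("count_summary", "data.frame"))
}

#' Count-level performance metrics
#'
#' Given per-image, per-category predicted and ground-truth counts, with
#' `P_ij`, `G_ij` the counts for category i in image j, computes
#'
#' * `ED  = mean_j sqrt( sum_i (P_ij - G_ij)^2 )` (per-image Euclidean
#'   distance across categories);
#' * `ED_per_category[c] = mean_j |P_cj - G_cj|` (the per-category view);
#' * `ACC = mean_j ( sum_i P_ij / sum_i G_ij )`;
#' * `RMSE = sqrt( mean_j ( sum_i G_ij - sum_i P_ij )^2 )`;
#' * `MAE = mean_j | sum_i G_ij - sum_i P_ij |`;
#' * `MPAE = mean_j | sum_i G_ij - sum_i P_ij | / sum_i G_ij`;
#' * `MDR = mean_j ( sum_i P_ij - sum_i G_ij ) / sum_i G_ij`.
#'
#' `ACC - 1 == MDR` holds identically, and `MPAE >= |MDR|` with equality
#' when every image's deviation shares one sign.  Images with a zero total
#' ground-truth count are excluded with a warning (the ratio metrics are
#' undefined there); the exclusion count is reported.
#'
#' @param cs A [count_summary()].
#' @return A list with elements `ED, ED_per_category, ACC, RMSE, MAE, MPAE,
#'   MDR, n_images, n_excluded`.
#' @export
count_metrics <- function(cs) {
  if (nrow(cs) == 0) stop("empty count summary")
  images <- unique(cs$image)
  gt_tot <- tapply(cs$gt, cs$image, sum)[images]
  excl <- names(gt_tot)[gt_tot == 0]
  if (length(excl) > 0) {
    warning(sprintf("count_metrics: excluding %d image(s) with zero ground truth",
                    length(excl)))
    cs <- cs[!(cs$image %in% excl), , drop = FALSE]
    images <- setdiff(images, excl)
    if (length(images) == 0) stop("no images with ground truth remain")
  }
  per_image <- function(f) vapply(images, function(im) {
    s <- cs[cs$image == im, , drop = FALSE]; f(s)
  }, numeric(1))
  ed_j <- per_image(function(s) sqrt(sum((s$predict - s$gt)^2)))
  sp <- per_image(function(s) sum(s$predict))
  sg <- per_image(function(s) sum(s$gt))
  cats <- tassel_categories()
  ed_cat <- vapply(names(cats), function(lb) {
    code <- cats[[lb]]
    mean(vapply(images, function(im) {
      s <- cs[cs$image == im & cs$class == code, , drop = FALSE]
      abs(sum(s$predict) - sum(s$gt))
    }, numeric(1)))
  }, numeric(1))
  list(ED = mean(ed_j),
       ED_per_category = ed_cat,
       ACC = mean(sp / sg),
       RMSE = sqrt(mean((sg - sp)^2)),
       MAE = mean(abs(sg - sp)),
       MPAE = mean(abs(sg - sp) / sg),
       MDR = mean((sp - sg) / sg),
       n_images = length(images),
       n_excluded = length(excl))
}

#' Per-block normalization of the ED metric
#'
#' Blocking patterns differ in block count (4, 9 and 40 on the default
#' frame), so pattern-level EDs are not directly comparable; dividing by
#' the block count puts them on a common per-block scale.
#'
#' @param ed Pattern-level mean ED.
#' @param n_blocks Number of blocks in the pattern (> 0).
#' @param digits Rounding for display (default 2).
#' @return `round(ed / n_blocks, digits)`.
#' @export
per_block_ed <- function(ed, n_blocks, digits = 2) {
  if (n_blocks <= 0) stop("n_blocks must be > 0")
  round(ed / n_blocks, digits)
}
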