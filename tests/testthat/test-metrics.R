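box <- function(cx, cy, w = 1, h = 1) list(cx = cx, cy = cy, w = w, h = h)

det_df <- function(class, cx, cy, w, h, conf) {
  data.frame(class = class, cx = cx, cy = cy, w = w, h = h, conf = conf)
}

test_that("iou covers identical, disjoint and half-offset boxes", {
  expect_equal(iou(box(0, 0), box(0, 0)), 1)
  expect_equal(iou(box(0, 0), box(5, 5)), 0)
  expect_equal(iou(box(0, 0), box(0.5, 0)), 1 / 3)
  # vectorized
  a <- data.frame(cx = c(0, 0), cy = c(0, 0), w = 1, h = 1)
  b <- data.frame(cx = c(0, 0.5), cy = c(0, 0), w = 1, h = 1)
  expect_equal(iou(a, b), c(1, 1 / 3))
})

test_that("matching is greedy, one-to-one and category-strict", {
  truth <- data.frame(class = c(0L, 0L), cx = c(0, 1.2), cy = 0, w = 1, h = 1)
  # one detection overlapping both truths -> exactly one TP, one FN
  d <- det_df(0L, 0.3, 0, 1.5, 1, 0.9)
  m <- match_detections(d, truth, 0.3)
  pc <- m$per_category[m$per_category$category == "Tassel-N", ]
  expect_equal(c(pc$TP, pc$FP, pc$FN), c(1, 0, 1))

  # wrong-category detection over a truth box -> 1 FP + 1 FN
  m2 <- match_detections(det_df(1L, 0, 0, 1, 1, 0.9),
                         data.frame(class = 0L, cx = 0, cy = 0, w = 1, h = 1))
  expect_equal(sum(m2$per_category$FP), 1)
  expect_equal(sum(m2$per_category$FN), 1)

  # perfect detections
  m3 <- match_detections(det_df(truth$class, truth$cx, truth$cy, 1, 1, 1),
                         truth)
  expect_equal(sum(m3$per_category$FP) + sum(m3$per_category$FN), 0)
  pra <- precision_recall_accuracy(m3)
  expect_equal(c(pra$precision, pra$recall), c(1, 1))
})

test_that("precision/recall/accuracy follow the counting formulas", {
  m <- list(per_category = data.frame(category = "Tassel-N", TP = 9, FP = 1,
                                      FN = 1))
  pra <- precision_recall_accuracy(m)
  expect_equal(pra$precision, 0.9)
  expect_equal(pra$recall, 0.9)
  expect_equal(pra$accuracy, 9 / 11)   # TN fixed at 0
  empty <- precision_recall_accuracy(
    list(per_category = data.frame(category = "x", TP = 0, FP = 0, FN = 0)))
  expect_false(empty$defined)
  expect_equal(empty$precision, 0)
  for (seed in 1:5) {
    v <- withr::with_seed(seed, sample(0:20, 3, replace = TRUE))
    pra <- precision_recall_accuracy(
      list(per_category = data.frame(category = "x", TP = v[1], FP = v[2],
                                     FN = v[3])))
    if (v[1] + v[2] > 0) expect_equal(pra$precision, v[1] / (v[1] + v[2]))
  }
})

test_that("AP: hand case 5/6, trivial singles, threshold-sweep oracle", {
  expect_equal(average_precision(1, TRUE, 1), 1)
  # labels (conf desc) TP, FP, TP with 2 truths -> all-points AP = 5/6
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2),
               5 / 6)
  expect_warning(ap0 <- average_precision(0.5, TRUE, 0), "undefined")
  expect_true(is.na(ap0))
  # exhaustive sweep oracle on random instances up to 50 detections
  for (seed in 1:20) {
    inst <- withr::with_seed(seed, {
      n <- sample(1:50, 1)
      list(conf = round(runif(n), 2),   # rounding forces confidence ties
           tp = runif(n) < 0.6, nt = sample(1:60, 1))
    })
    inst$tp[inst$nt < sum(inst$tp)] <- FALSE  # cannot have more TP than truth
    expect_equal(average_precision(inst$conf, inst$tp, inst$nt),
                 oracle_ap(inst$conf, inst$tp, inst$nt),
                 info = sprintf("seed %d", seed))
  }
})

test_that("AP is invariant to monotone confidence rescaling", {
  inst <- withr::with_seed(4, list(conf = runif(30), tp = runif(30) < 0.5))
  a1 <- average_precision(inst$conf, inst$tp, 20)
  a2 <- average_precision(plogis(3 * inst$conf - 1), inst$tp, 20)
  expect_equal(a1, a2)
})

test_that("mAP is the unweighted mean over categories", {
  # the published per-category APs average to the published mAP
  expect_equal(round(mean(c(0.943, 0.923, 0.968)), 3), 0.945)
  # perfect detections for all three categories -> AP 1 each, mAP 1
  truth <- data.frame(class = 0:2, cx = c(0, 10, 20), cy = 0, w = 2, h = 2)
  m <- match_detections(det_df(0:2, c(0, 10, 20), 0, 2, 2, c(0.9, 0.8, 0.7)),
                        truth)
  res <- map_at_50(m)
  expect_equal(unname(res$ap), c(1, 1, 1))
  expect_equal(res$map, 1)
  # a category with no truth makes the mAP NA unless na_rm
  truth2 <- truth[truth$class != 2, ]
  m2 <- match_detections(det_df(0:1, c(0, 10), 0, 2, 2, c(0.9, 0.8)), truth2)
  expect_true(is.na(map_at_50(m2)$map))
  expect_equal(map_at_50(m2, na_rm = TRUE)$map, 1)
})

test_that("count metrics match the hand-computed single-image case", {
  cs <- count_summary("img1", 0:2, predict = c(8, 5, 5), gt = c(10, 5, 5))
  m <- count_metrics(cs)
  expect_equal(m$ED, 2)
  expect_equal(m$ACC, 0.9)
  expect_equal(m$MDR, -0.1)
  expect_equal(m$MPAE, 0.1)
  expect_equal(m$MAE, 2)
  expect_equal(m$RMSE, 2)
  expect_equal(unname(m$ED_per_category), c(2, 0, 0))
})

test_that("exact counts give zero error everywhere", {
  cs <- rbind(count_summary("a", 0:2, c(3, 4, 5), c(3, 4, 5)),
              count_summary("b", 0:2, c(1, 0, 2), c(1, 0, 2)))
  m <- count_metrics(cs)
  expect_equal(m$ED, 0)
  expect_equal(m$ACC, 1)
  expect_equal(c(m$MDR, m$RMSE, m$MAE, m$MPAE), rep(0, 4))
})

test_that("ACC - 1 == MDR, MPAE >= |MDR|, RMSE >= MAE on random summaries", {
  for (seed in 1:20) {
    cs <- withr::with_seed(seed, {
      n_img <- sample(2:8, 1)
      do.call(rbind, lapply(seq_len(n_img), function(j) {
        gt <- sample(1:30, 3, replace = TRUE)
        count_summary(sprintf("im%d", j), 0:2,
                      predict = pmax(gt + sample(-3:3, 3, replace = TRUE), 0),
                      gt = gt)
      }))
    })
    m <- count_metrics(cs)
    expect_equal(m$ACC - 1, m$MDR, tolerance = 1e-12)
    expect_gte(m$MPAE, abs(m$MDR) - 1e-12)
    expect_gte(m$RMSE, m$MAE - 1e-12)
    # MPAE == |MDR| iff all per-image deviations share one sign
    sp <- tapply(cs$predict, cs$image, sum)
    sg <- tapply(cs$gt, cs$image, sum)
    if (all(sp >= sg) || all(sp <= sg))
      expect_equal(m$MPAE, abs(m$MDR), tolerance = 1e-12)
  }
})

test_that("zero-ground-truth images are excluded with a warning", {
  cs <- rbind(count_summary("a", 0:2, c(1, 1, 1), c(1, 1, 1)),
              count_summary("b", 0:2, c(2, 0, 0), c(0, 0, 0)))
  expect_warning(m <- count_metrics(cs), "zero ground truth")
  expect_equal(m$n_excluded, 1)
  expect_equal(m$n_images, 1)
  expect_equal(m$ACC, 1)
})

test_that("per-block ED normalization matches the printed arithmetic", {
  expect_equal(per_block_ed(1.67, 4), 0.42)
  expect_equal(per_block_ed(5.18, 9), 0.58)
  expect_equal(per_block_ed(89.96, 40), 2.25)
  expect_equal(per_block_ed(0, 7), 0)
  expect_error(per_block_ed(1, 0), "n_blocks")
})
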