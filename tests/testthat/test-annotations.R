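img1k <- image_spec(1024, 1024, 0.25)

test_that("read_yolo converts normalized labels to pixel units", {
  a <- read_yolo("0 0.5 0.5 0.1 0.1", img1k)
  expect_equal(nrow(a$boxes), 1)
  expect_equal(a$boxes$class, 0L)
  expect_equal(c(a$boxes$cx, a$boxes$cy), c(512, 512))
  expect_equal(c(a$boxes$w, a$boxes$h), c(102.4, 102.4))
  expect_equal(nrow(read_yolo("", img1k)$boxes), 0)
})

test_that("read_yolo rejects malformed input with line numbers", {
  expect_error(read_yolo(c("0 0.5 0.5 0.1 0.1", "7 0.5 0.5 0.1 0.1"), img1k),
               "line 2.*class code")
  expect_error(read_yolo(c("0 0.5 0.5 0.1 0.1", "1 1.5 0.5 0.1 0.1"), img1k),
               "line 2.*outside")
  expect_error(read_yolo("0 0.5 0.5 0.1", img1k), "5 fields")
  expect_error(read_yolo("0 a 0.5 0.1 0.1", img1k), "non-numeric")
})

test_that("write_yolo / read_yolo round-trip within 1e-6 normalized units", {
  for (n in c(0, 1, 100)) {
    a <- rand_anns(n, img1k, seed = n + 1)
    b <- read_yolo(write_yolo(a), img1k)
    expect_equal(nrow(b$boxes), n)
    if (n > 0) {
      expect_lt(max(abs(b$boxes$cx - a$boxes$cx) / 1024), 1e-6)
      expect_lt(max(abs(b$boxes$w - a$boxes$w) / 1024), 1e-6)
      expect_identical(b$boxes$class, a$boxes$class)
    }
  }
})

test_that("standardize_boxes fixes N/S squares and leaves Tassel-L alone", {
  a <- annotation_set("x", img1k, data.frame(
    class = c(0L, 2L), cx = c(512, 300), cy = c(512, 300),
    w = c(76, 120), h = c(76, 90)))
  s <- standardize_boxes(a)
  expect_equal(c(s$boxes$w[1], s$boxes$h[1]), c(140, 140))
  expect_equal(c(s$boxes$cx[1], s$boxes$cy[1]), c(512, 512))
  expect_equal(c(s$boxes$w[2], s$boxes$h[2]), c(120, 90))  # L untouched
})

test_that("standardized boxes are clipped at image borders", {
  a <- annotation_set("x", img1k, data.frame(
    class = 0L, cx = 10, cy = 512, w = 76, h = 76))
  s <- standardize_boxes(a, c("Tassel-N" = 140))
  expect_equal(s$boxes$w, 80)   # [0, 80] after clipping the 140 square
  expect_equal(s$boxes$h, 140)
  expect_equal(s$boxes$pre_w, 140)
})

test_that("standardization preserves count/centers and is idempotent", {
  for (seed in 1:5) {
    a <- rand_anns(40, img1k, seed, max_side = 100)
    # keep centers away from edges so clipping cannot move them
    a$boxes$cx <- pmin(pmax(a$boxes$cx, 120), 1024 - 120)
    a$boxes$cy <- pmin(pmax(a$boxes$cy, 120), 1024 - 120)
    s1 <- standardize_boxes(a)
    expect_equal(nrow(s1$boxes), nrow(a$boxes))
    expect_equal(s1$boxes$cx, a$boxes$cx)
    expect_equal(s1$boxes$cy, a$boxes$cy)
    s2 <- standardize_boxes(s1)
    expect_equal(s2$boxes[, c("class", "cx", "cy", "w", "h")],
                 s1$boxes[, c("class", "cx", "cy", "w", "h")])
  }
})

test_that("sweep_sizes enumerates the coarse and refined grids", {
  ds <- list(rand_anns(20, img1k, 1))
  coarse <- sweep_sizes(ds, seq(50, 500, by = 50))
  expect_length(coarse, 10)
  fine <- sweep_sizes(ds, seq(50, 300, by = 10))
  expect_length(fine, 26)
  expect_equal(attr(fine, "record")$side, seq(50, 300, by = 10))
  # a sweep at the current size is the identity
  sq <- annotation_set("sq", img1k, data.frame(
    class = 0L, cx = 500, cy = 500, w = 140, h = 140))
  out <- sweep_sizes(list(sq), 140)
  expect_equal(out[[1]][[1]]$boxes[, c("cx", "cy", "w", "h")],
               sq$boxes[, c("cx", "cy", "w", "h")])
  expect_error(sweep_sizes(ds, c(100, 100)), "increasing")
})

test_that("dataset_stats matches hand arithmetic", {
  a <- annotation_set("x", img1k, data.frame(
    class = c(0L, 0L), cx = c(300, 600), cy = c(300, 600),
    w = c(100, 50), h = c(100, 200)))
  st <- dataset_stats(list(a))
  all_row <- st[st$category == "All", ]
  expect_equal(all_row$area_mean, 10000)
  expect_equal(all_row$ratio_mean, mean(c(1.0, 0.25)))
  n_row <- st[st$category == "Tassel-N", ]
  expect_equal(n_row$n, 2)
  expect_equal(n_row$proportion, 1)
  expect_error(dataset_stats(list()), "empty")
})

test_that("a dataset with box area 5784 px^2 has ~76 px mean side", {
  side <- sqrt(5784)
  a <- annotation_set("x", img1k, data.frame(
    class = rep(1L, 5), cx = seq(100, 900, 200), cy = 500,
    w = side, h = side))
  st <- dataset_stats(a)
  expect_equal(st$area_mean[st$category == "All"], 5784)
  expect_equal(round(side), 76)
  expect_equal(st$ratio_mean[st$category == "All"], 1.0)
  expect_equal(st$ratio_sd[st$category == "All"], 0.0)
})

test_that("overall mean area is the count-weighted per-category mean", {
  for (seed in 1:5) {
    ds <- generate_annotation_fixture(3, 40, seed = seed)
    st <- dataset_stats(ds)
    cat_rows <- st[st$category != "All", ]
    expect_equal(st$area_mean[st$category == "All"],
                 sum(cat_rows$n * cat_rows$area_mean) / sum(cat_rows$n))
    expect_equal(sum(cat_rows$proportion), 1, tolerance = 1e-9)
  }
})

test_that("crop_annotations_to_block translates, clips and thresholds", {
  frame <- uav_frame_spec()
  p <- plan_pattern1(frame)
  blk <- p$blocks[1, ]
  inside <- annotation_set("x", frame, data.frame(
    class = 1L, cx = blk$x0 + 500, cy = blk$y0 + 500, w = 100, h = 100))
  cr <- crop_annotations_to_block(inside, blk)
  expect_equal(c(cr$boxes$cx, cr$boxes$cy), c(500, 500))
  expect_equal(cr$boxes$source_box, 1L)

  # 30% visible at threshold 0.5 -> dropped (box hangs off the left edge)
  part <- annotation_set("x", frame, data.frame(
    class = 1L, cx = blk$x0 - 20, cy = blk$y0 + 500, w = 100, h = 100))
  expect_equal(nrow(crop_annotations_to_block(part, blk)$boxes), 0)
  expect_equal(nrow(crop_annotations_to_block(part, blk, 0.3)$boxes), 1)

  # a box inside the 200-px overlap strip is >= 50% visible in both blocks
  blk2 <- p$blocks[2, ]  # right neighbour
  strip_cx <- blk2$x0 + 100  # middle of the overlap strip
  strad <- annotation_set("x", frame, data.frame(
    class = 1L, cx = strip_cx, cy = blk$y0 + 500, w = 120, h = 120))
  expect_equal(nrow(crop_annotations_to_block(strad, blk)$boxes), 1)
  expect_equal(nrow(crop_annotations_to_block(strad, blk2)$boxes), 1)
})

test_that("boxes centered in some block survive cropping at threshold 0.25", {
  # center inside a block bounds the visible fraction below by 1/4, so the
  # guarantee holds at 0.25 (not at 0.5: a box straddling a tile corner can
  # fall below 1/2 in all blocks)
  img <- image_spec(300, 300)
  plan <- plan_sliding(img, 100, 20)
  for (seed in 1:5) {
    boxes <- rand_boxes(30, img, seed, max_side = 60)
    a <- annotation_set("x", img, boxes)
    seen <- integer(0)
    for (i in seq_len(nrow(plan$blocks))) {
      cr <- crop_annotations_to_block(a, plan$blocks[i, ], 0.25)
      seen <- union(seen, cr$boxes$source_box)
    }
    center_in_block <- vapply(seq_len(nrow(boxes)), function(i) {
      any(boxes$cx[i] >= plan$blocks$x0 &
            boxes$cx[i] < plan$blocks$x0 + 100 &
            boxes$cy[i] >= plan$blocks$y0 &
            boxes$cy[i] < plan$blocks$y0 + 100)
    }, logical(1))
    expect_true(all(which(center_in_block) %in% seen))
  }
})

test_that("split_dataset is seeded and respects the 8:1:1 ratio", {
  ds <- generate_annotation_fixture(20, 5, seed = 3)
  s1 <- split_dataset(ds, seed = 11)
  s2 <- split_dataset(ds, seed = 11)
  expect_identical(s1, s2)
  expect_equal(as.vector(table(s1$split)[c("train", "val", "test")]),
               c(16, 2, 2))
})
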