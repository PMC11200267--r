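gdet <- function(class, x, y, conf = 0.9) {
  data.frame(class = class, cx = x, cy = y, w = 100, h = 100, conf = conf,
             block_id = NA_integer_, global_cx = x, global_cy = y)
}

test_that("to_global offsets by the block origin", {
  frame <- uav_frame_spec()
  plan <- plan_pattern2(frame)
  center_block <- plan$blocks[plan$blocks$row == 2 & plan$blocks$col == 2, ]
  expect_equal(c(center_block$x0, center_block$y0), c(3584, 2218))
  d <- data.frame(class = 0L, cx = 100, cy = 100, w = 50, h = 50,
                  conf = 0.8, block_id = center_block$block_id)
  g <- to_global(d, plan)
  expect_equal(c(g$global_cx, g$global_cy), c(3684, 2318))
  # block at the origin is the identity; remap - unmap round-trips
  p0 <- plan_pattern3(image_spec(1024, 1024), 1024)
  d0 <- data.frame(class = 0L, cx = 10, cy = 20, w = 5, h = 5, conf = 1,
                   block_id = 1L)
  g0 <- to_global(d0, p0)
  expect_equal(c(g0$global_cx, g0$global_cy), c(10, 20))
  i <- match(g$block_id, plan$blocks$block_id)
  expect_equal(g$global_cx - plan$blocks$x0[i], d$cx)
  expect_error(to_global(transform(d, block_id = NA), plan), "block_id")
})

test_that("merge radius and the category barrier behave as specified", {
  expect_equal(nrow(merge_redundant(rbind(gdet(1L, 0, 0), gdet(1L, 30, 0)))), 1)
  expect_equal(nrow(merge_redundant(rbind(gdet(1L, 0, 0), gdet(1L, 60, 0)))), 2)
  # Tassel-S and Tassel-L 10 px apart never merge
  m <- merge_redundant(rbind(gdet(1L, 0, 0), gdet(2L, 10, 0)))
  expect_equal(nrow(m), 2)
  expect_setequal(m$class, c(1L, 2L))
  expect_error(merge_redundant(gdet(1L, 0, 0), radius_px = -1), "radius")
})

test_that("chains merge under single linkage but split under greedy", {
  chain <- rbind(gdet(0L, 0, 0, 0.9), gdet(0L, 40, 0, 0.8),
                 gdet(0L, 80, 0, 0.7))
  expect_equal(nrow(merge_redundant(chain)), 1)
  expect_equal(merge_redundant(chain)$members, 3)
  expect_equal(nrow(merge_redundant(chain, method = "greedy")), 2)
})

test_that("fused position is the confidence-weighted mean, conf the max", {
  two <- rbind(gdet(1L, 0, 0, 0.9), gdet(1L, 30, 0, 0.3))
  m <- merge_redundant(two)
  expect_equal(m$cx, (0 * 0.9 + 30 * 0.3) / 1.2)
  expect_equal(m$conf, 0.9)
  expect_equal(m$members, 2)
})

test_that("single linkage equals the brute-force closure oracle", {
  for (seed in 1:8) {
    n <- c(20, 50, 120, 200)[(seed %% 4) + 1]
    d <- withr::with_seed(seed, gdet(
      sample(0:2, n, replace = TRUE),
      runif(n, 0, 600), runif(n, 0, 600), runif(n)))
    fused <- merge_redundant(d, radius_px = 50)
    # oracle per category (merging never crosses categories)
    expected <- sum(vapply(unique(d$class), function(cl) {
      g <- d[d$class == cl, ]
      length(unique(brute_components(g$global_cx, g$global_cy, 50)))
    }, numeric(1)))
    expect_equal(nrow(fused), expected)
    expect_equal(sum(fused$members), n)
  }
})

test_that("merge is invariant to input permutation", {
  d <- withr::with_seed(3, gdet(sample(0:2, 60, replace = TRUE),
                                runif(60, 0, 400), runif(60, 0, 400),
                                runif(60)))
  ref <- merge_redundant(d)
  for (seed in 1:4) {
    perm <- withr::with_seed(seed, sample.int(nrow(d)))
    out <- merge_redundant(d[perm, ])
    expect_equal(out[, c("class", "cx", "cy", "conf", "members")],
                 ref[, c("class", "cx", "cy", "conf", "members")])
  }
})

test_that("fused count <= raw count, equality iff no close same-class pair", {
  for (seed in 11:15) {
    d <- withr::with_seed(seed, gdet(sample(0:2, 40, replace = TRUE),
                                     runif(40, 0, 500), runif(40, 0, 500),
                                     runif(40)))
    fused <- merge_redundant(d)
    expect_lte(nrow(fused), nrow(d))
    close_pair <- any(vapply(seq_len(39), function(i) {
      any(d$class[(i + 1):40] == d$class[i] &
            (d$global_cx[(i + 1):40] - d$global_cx[i])^2 +
            (d$global_cy[(i + 1):40] - d$global_cy[i])^2 <= 50^2)
    }, logical(1)))
    expect_equal(nrow(fused) < nrow(d), close_pair)
  }
})

test_that("jittered duplicates collapse back to the true count", {
  truth_xy <- expand.grid(x = seq(100, 900, by = 200),
                          y = seq(100, 900, by = 200))
  for (seed in 1:3) {
    dup <- withr::with_seed(seed, {
      j <- function() rnorm(nrow(truth_xy), 0, 5)
      rbind(gdet(1L, truth_xy$x + j(), truth_xy$y + j()),
            gdet(1L, truth_xy$x + j(), truth_xy$y + j()))
    })
    expect_equal(nrow(merge_redundant(dup, 50)), nrow(truth_xy))
  }
})

test_that("fuse_plan deduplicates overlap-strip objects and counts truth", {
  frame <- image_spec(2048, 2048)
  plan <- plan_pattern1(frame, 1024, 200)
  # same physical object detected in two horizontally adjacent blocks:
  # global position (x=960, y=500) sits in the 200-px overlap strip
  b1 <- plan$blocks[1, ]; b2 <- plan$blocks[2, ]
  d <- rbind(
    data.frame(class = 2L, cx = 960 - b1$x0, cy = 500 - b1$y0, w = 100,
               h = 100, conf = 0.9, block_id = b1$block_id),
    data.frame(class = 2L, cx = 960 - b2$x0, cy = 500 - b2$y0, w = 100,
               h = 100, conf = 0.8, block_id = b2$block_id))
  out <- fuse_plan(d, plan)
  expect_equal(sum(out$counts), 1)
  expect_equal(out$counts[["Tassel-L"]], 1)
  expect_equal(out$fused$members, 2)
  # empty input
  empty <- fuse_plan(d[0, ], plan)
  expect_equal(sum(empty$counts), 0)
})

test_that("perfect detection on a plan reproduces evaluable truth counts", {
  img <- desk_img()
  sc <- generate_scene(scene_config(image = img, occlusion_prob = 0,
                                    seed = 5), render = FALSE)
  plan <- plan_pattern1(img, 512, 100)
  dets <- detect_plan(sc$truth$anns, plan, perfect_detector_params(),
                      seed = 1)
  fused <- fuse_plan(dets, plan)
  gt <- plan_ground_truth_counts(sc$truth$anns, plan)
  expect_equal(fused$counts, gt)
})
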