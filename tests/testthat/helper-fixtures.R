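# Shared fixtures and independent oracles.

# Random in-bounds boxes (pixel units) for an image spec.
rand_boxes <- function(n, img, seed = 1, max_side = 200) {
  withr::with_seed(seed, {
    w <- runif(n, 10, max_side)
    h <- runif(n, 10, max_side)
    data.frame(
      class = sample(0:2, n, replace = TRUE),
      cx = runif(n, w / 2, img$width_px - w / 2),
      cy = runif(n, h / 2, img$height_px - h / 2),
      w = w, h = h
    )
  })
}

rand_anns <- function(n, img, seed = 1, max_side = 200, id = "t") {
  annotation_set(id, img, rand_boxes(n, img, seed, max_side))
}

# Brute-force transitive closure: repeatedly merge any two clusters that
# contain points within `radius` of each other, until a fixpoint.
# Independent of the union-find implementation under test.
brute_components <- function(x, y, radius) {
  n <- length(x)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          (x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) return(comp)
  }
}

# Exhaustive threshold-sweep AP oracle: build the finite (recall,
# precision) point set by filtering at every distinct confidence, then
# integrate the all-points envelope directly from the definition.
oracle_ap <- function(conf, tp, n_truth) {
  if (length(conf) == 0) return(0)
  thr <- sort(unique(conf), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    keep <- conf >= t
    c(r = sum(tp[keep]) / n_truth, p = sum(tp[keep]) / sum(keep))
  }, c(r = 0, p = 0)))
  recs <- sort(unique(pts[, "r"]))
  recs <- recs[recs > 0]
  prev <- 0
  ap <- 0
  for (r in recs) {
    ap <- ap + (r - prev) * max(pts[pts[, "r"] >= r, "p"])
    prev <- r
  }
  ap
}

desk_img <- function() image_spec(2048, 2048, 0.25)
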