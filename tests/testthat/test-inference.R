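test_that("default offset fractions give the 16-layer grid", {
  g <- offset_grid(512)
  expect_equal(nrow(g), 16)
  expect_true(any(g[, 1] == 0 & g[, 2] == 0))
  expect_true(any(g[, 1] == 128 & g[, 2] == 384))
  expect_true(any(g[, 1] == 384 & g[, 2] == 384))
  expect_setequal(unique(g[, 1]), c(0, 128, 256, 384))
})

test_that("fraction set {0} yields the single base layer", {
  g <- offset_grid(512, fractions = 0)
  expect_equal(nrow(g), 1)
  expect_equal(unname(g[1, ]), c(0, 0))
})

test_that("offsets are the Cartesian product of floored fractions", {
  g <- offset_grid(100, fractions = c(0, 0.5))
  expect_equal(nrow(g), 4)
  got <- apply(g, 1, paste, collapse = ",")
  expect_setequal(got, c("0,0", "0,50", "50,0", "50,50"))
})

test_that("offset fractions are validated and duplicates collapse", {
  expect_error(offset_grid(100, c(0, 1)), "\\[0, 1\\)")
  expect_error(offset_grid(100, c(0.25, 0.5)), "include 0")
  expect_warning(g <- offset_grid(10, c(0, 0.5, 0.51)), "collapsed")
  expect_equal(nrow(g), 4)
})

stack_scene <- function(h = 40, w = 40) {
  structure(list(image = array(runif(h * w * 3, 0, 255), c(h, w, 3)),
                 mask = matrix(0L, h, w),
                 class_table = data.frame(class_id = 0:5,
                                          name = paste0("c", 0:5)),
                 gsd_cm = 1.2), class = "labeled_scene")
}

test_that("a constant stub model produces constant layers", {
  set.seed(1)
  sc <- stack_scene()
  stack <- predict_offset_stack(constant_predictor(3L), sc, tile_size = 16)
  expect_length(stack$layers, 16)
  for (l in stack$layers) {
    expect_equal(dim(l), c(40, 40))
    expect_true(all(l == 3L))
  }
})

test_that("a single-tile scene with base fractions equals one prediction", {
  set.seed(2)
  sc <- stack_scene(16, 16)
  pred_fun <- function(image, origin_row, origin_col)
    matrix(as.integer(round(mean(image)) %% 6), nrow(image), ncol(image))
  stack <- predict_offset_stack(pred_fun, sc, tile_size = 16, fractions = 0)
  expect_length(stack$layers, 1)
  expect_identical(stack$layers[[1]], pred_fun(sc$image, 0, 0))
})

test_that("layer contents match a direct simulation of the tiling geometry", {
  set.seed(3)
  sc <- stack_scene(30, 30)
  tsz <- 16
  # stub: class id = parity of the tile's origin (scene coordinates)
  parity_fun <- function(image, origin_row, origin_col)
    matrix(as.integer((origin_row / tsz + origin_col / tsz) %% 2),
           nrow(image), ncol(image))
  stack <- predict_offset_stack(parity_fun, sc, tile_size = tsz,
                                fractions = c(0, 0.5))
  for (li in seq_len(nrow(stack$offsets))) {
    ro <- stack$offsets[li, 1]; co <- stack$offsets[li, 2]
    # oracle: re-enumerate tile origins and paint the expected ids
    expected <- matrix(NA_integer_, 30, 30)
    r_starts <- seq(ro - tsz, 30, by = tsz)
    c_starts <- seq(co - tsz, 30, by = tsz)
    for (r0 in r_starts) for (c0 in c_starts) {
      rs <- intersect(seq(r0 + 1, r0 + tsz), 1:30)
      cs <- intersect(seq(c0 + 1, c0 + tsz), 1:30)
      if (!length(rs) || !length(cs)) next
      expected[rs, cs] <- as.integer((r0 / tsz + c0 / tsz) %% 2)
    }
    expect_identical(stack$layers[[li]], expected)
  }
})

test_that("every pixel of every layer carries a valid class id", {
  set.seed(4)
  sc <- stack_scene(26, 38)
  m <- build_model(model_config("unet", n_classes = 6, depth = 1,
                                base_width = 2))
  stack <- predict_offset_stack(m, sc, tile_size = 8)
  for (l in stack$layers) {
    expect_false(anyNA(l))
    expect_true(all(l %in% 0:5))
  }
})

test_that("majority vote equals per-pixel histogram argmax with low-id ties", {
  set.seed(5)
  for (i in 1:10) {
    layers <- lapply(1:16, function(j) matrix(sample(0:5, 48, TRUE), 6, 8))
    vote <- majority_vote(layers)
    for (r in 1:6) for (c in 1:8) {
      votes <- vapply(layers, function(l) l[r, c], integer(1))
      counts <- table(votes)
      best <- max(counts)
      expect_equal(vote[r, c],
                   min(as.integer(names(counts)[counts == best])))
    }
  }
})

test_that("explicit tie and majority cases resolve as documented", {
  l2 <- matrix(2L, 2, 2); l5 <- matrix(5L, 2, 2)
  vote <- majority_vote(c(rep(list(l2), 9), rep(list(l5), 7)))
  expect_true(all(vote == 2L))
  l1 <- matrix(1L, 2, 2); l3 <- matrix(3L, 2, 2)
  vote <- majority_vote(c(rep(list(l1), 8), rep(list(l3), 8)))
  expect_true(all(vote == 1L))
  expect_error(majority_vote(list()), "empty")
})

test_that("vote is invariant to layer order for a deterministic model", {
  set.seed(6)
  layers <- lapply(1:16, function(j) matrix(sample(0:3, 60, TRUE), 6, 10))
  expect_identical(majority_vote(layers), majority_vote(rev(layers)))
})

test_that("identical layers vote to themselves", {
  l <- matrix(sample(0:2, 20, TRUE), 4, 5)
  expect_identical(majority_vote(rep(list(l), 5)), l)
})
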