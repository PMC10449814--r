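test_that("degenerate composition: a lone background class fills the mask", {
  spec <- scene_spec(64, 64, list(
    class_spec(5L, "bg", 1.0, c(100, 100, 100), background = TRUE)))
  sc <- generate_scene(spec, seed = 1)
  expect_true(all(sc$mask == 5L))
  expect_equal(dim(sc$image), c(64, 64, 3))
})

test_that("generate_scene is a pure function of (spec, seed)", {
  spec <- scene_spec(96, 96, three_class_specs())
  a <- generate_scene(spec, seed = 42)
  b <- generate_scene(spec, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_scene(spec, seed = 43)
  expect_false(identical(a$mask, c$mask))
})

test_that("empirical proportions of a large scene approach the targets", {
  classes <- list(
    class_spec(0L, "bg", 0.70, c(150, 120, 90), background = TRUE),
    class_spec(1L, "a", 0.15, c(40, 130, 45), patch_area_mean = 2000),
    class_spec(2L, "b", 0.10, c(190, 180, 60), patch_area_mean = 1500),
    class_spec(3L, "c", 0.05, c(90, 60, 140), patch_area_mean = 1000))
  sc <- generate_scene(scene_spec(2048, 2048, classes), seed = 7)
  # oracle: exhaustive pixel count of the returned mask
  counts <- c(sum(sc$mask == 0L), sum(sc$mask == 1L), sum(sc$mask == 2L),
              sum(sc$mask == 3L))
  expect_equal(sum(counts), 2048^2)
  p <- counts / 2048^2
  expect_true(all(abs(p - c(0.70, 0.15, 0.10, 0.05)) < 0.03))
  # package path agrees with the oracle exactly
  expect_equal(unname(empirical_class_proportions(sc$mask, sc$class_table)),
               p)
  # background keeps the largest share
  expect_equal(which.max(p), 1L)
})

test_that("scene spec validation rejects bad compositions", {
  expect_error(scene_spec(64, 64, list(
    class_spec(0L, "bg", 0.5, c(1, 1, 1), background = TRUE),
    class_spec(1L, "a", 0.4, c(2, 2, 2)))), "sum to 1")
  expect_error(scene_spec(64, 64, list(
    class_spec(0L, "bg", 0.5, c(1, 1, 1)),
    class_spec(1L, "a", 0.5, c(2, 2, 2)))), "background")
  expect_error(scene_spec(32, 64, list(
    class_spec(0L, "bg", 1, c(1, 1, 1), background = TRUE))), "at least 64")
  # patches that cannot fit the scene
  expect_error(scene_spec(64, 64, list(
    class_spec(0L, "bg", 0.5, c(1, 1, 1), background = TRUE),
    class_spec(1L, "a", 0.5, c(2, 2, 2), patch_area_mean = 1e5))),
    "too small")
})

test_that("perturb_scene at strength 0 is the identity", {
  sc <- small_scene(3)
  out <- perturb_scene(sc, 0, seed = 9)
  expect_identical(out$image, sc$image)
  expect_identical(out$mask, sc$mask)
})

test_that("perturb_scene is deterministic and never touches the mask", {
  sc <- small_scene(4)
  a <- perturb_scene(sc, 1, seed = 11)
  b <- perturb_scene(sc, 1, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, sc$mask)
  expect_false(identical(a$image, sc$image))
})

test_that("per-class mean colour shift is non-decreasing in strength", {
  sc <- small_scene(5)
  # oracle: direct per-class mean-RGB difference by pixel averaging
  shift_of <- function(pert) {
    vapply(sc$class_table$class_id, function(cid) {
      sel <- sc$mask == cid
      d <- 0
      for (ch in 1:3)
        d <- d + abs(mean(pert$image[, , ch][sel]) -
                       mean(sc$image[, , ch][sel]))
      d
    }, numeric(1))
  }
  s0 <- shift_of(perturb_scene(sc, 0, seed = 2))
  s5 <- shift_of(perturb_scene(sc, 0.5, seed = 2))
  s1 <- shift_of(perturb_scene(sc, 1, seed = 2))
  expect_true(all(s0 <= s5 + 1e-9))
  expect_true(all(s5 <= s1 + 1e-9))
})

test_that("empirical_class_proportions matches a brute-force tally", {
  ct <- data.frame(class_id = c(0L, 1L, 2L), name = c("a", "b", "c"))
  expect_equal(unname(empirical_class_proportions(
    matrix(0L, 4, 4), ct)), c(1, 0, 0))
  expect_equal(unname(empirical_class_proportions(
    matrix(c(0L, 0L, 1L, 2L), 2, 2), ct)), c(0.5, 0.25, 0.25))
  set.seed(8)
  m <- matrix(sample(0:2, 64 * 64, TRUE, prob = c(0.6, 0.3, 0.1)), 64, 64)
  tally <- c(0, 0, 0)
  for (v in as.vector(m)) tally[v + 1] <- tally[v + 1] + 1
  p <- empirical_class_proportions(m, ct)
  expect_identical(unname(p), tally / sum(tally))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(empirical_class_proportions(matrix(7L, 2, 2), ct), "7")
})

test_that("scene round-trips through PNG + CSV losslessly for the mask", {
  sc <- small_scene(6)
  d <- withr::local_tempdir()
  write_scene(sc, d, "s")
  back <- read_scene(d, "s")
  expect_identical(back$mask, sc$mask)
  expect_equal(back$image, sc$image)
  expect_equal(back$class_table$class_id, sc$class_table$class_id)
  expect_equal(back$gsd_cm, sc$gsd_cm)
})
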