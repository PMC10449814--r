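test_that("a solid square is one patch of the right area", {
  m <- matrix(0L, 10, 10)
  m[3:5, 4:6] <- 1L
  patches <- label_patches(m, 1L)
  expect_length(patches, 1)
  expect_equal(patches[[1]]$area_px, 9)
})

test_that("diagonal neighbours merge under queen but not rook adjacency", {
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_length(label_patches(m, 1L, connectivity = 8), 1)
  expect_length(label_patches(m, 1L, connectivity = 4), 2)
  expect_error(label_patches(m, 1L, connectivity = 6), "4 or 8")
  expect_length(label_patches(m, 9L), 0)
})

test_that("component labelling matches an independent flood fill", {
  set.seed(1)
  for (conn in c(4, 8)) {
    for (i in 1:10) {
      m <- matrix(as.integer(runif(30 * 30) < 0.4), 30, 30)
      got <- label_patches(m, 1L, connectivity = conn)
      oracle <- oracle_components(m, 1L, conn)
      expect_length(got, max(oracle))
      # same partition: each oracle component appears as exactly one patch
      sizes_got <- sort(vapply(got, `[[`, numeric(1), "area_px"))
      sizes_oracle <- sort(tabulate(oracle[oracle > 0]))
      expect_equal(sizes_got, sizes_oracle)
    }
  }
})

test_that("a single pixel has circumscribing radius sqrt(2)/2", {
  p <- patch_from_logical(matrix(TRUE, 1, 1))
  circ <- smallest_circumscribing_circle(p)
  expect_equal(circ$radius, sqrt(2) / 2, tolerance = 1e-9)
})

test_that("a 1x10 pixel row has radius sqrt(101)/2", {
  p <- patch_from_logical(matrix(TRUE, 1, 10))
  circ <- smallest_circumscribing_circle(p)
  expect_equal(circ$radius, sqrt(101) / 2, tolerance = 1e-9)
})

test_that("minimal circle equals the brute-force pair/triple oracle", {
  set.seed(2)
  for (i in 1:15) {
    m <- matrix(runif(49) < 0.35, 7, 7)
    if (!any(m)) next
    p <- patch_from_logical(m)
    got <- smallest_circumscribing_circle(p)
    pts <- unique(rbind(cbind(p$pixels[, 1] - 1, p$pixels[, 2] - 1),
                        cbind(p$pixels[, 1] - 1, p$pixels[, 2]),
                        cbind(p$pixels[, 1], p$pixels[, 2] - 1),
                        cbind(p$pixels[, 1], p$pixels[, 2])))
    oracle <- oracle_mec(pts)
    expect_equal(got$radius, oracle$radius, tolerance = 1e-7)
  }
})

disc_patch <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
  patch_from_logical(m)
}

test_that("a rasterised disc recovers its radius within a pixel", {
  p <- disc_patch(20)
  circ <- smallest_circumscribing_circle(p)
  expect_lte(abs(circ$radius - 20), 1)
})

test_that("disc compactness is near 0 and line compactness approaches 1", {
  expect_lte(patch_compactness(disc_patch(20)), 0.1)
  comp <- vapply(c(5, 20, 60), function(n)
    patch_compactness(patch_from_logical(matrix(TRUE, 1, n))), numeric(1))
  expect_true(all(diff(comp) > 0))
  expect_gt(comp[3], 0.9)
})

test_that("a square patch has compactness 1 - 2/pi", {
  p <- patch_from_logical(matrix(TRUE, 30, 30))
  expect_equal(patch_compactness(p), 1 - 2 / pi, tolerance = 0.02)
})

test_that("compactness is invariant under translation and 90-deg rotation", {
  set.seed(3)
  m <- matrix(FALSE, 20, 20)
  m[4:9, 3:5] <- TRUE; m[6, 6:9] <- TRUE
  base <- patch_compactness(patch_from_logical(m))
  shifted <- matrix(FALSE, 25, 25)
  shifted[4:9 + 5, 3:5 + 7] <- TRUE; shifted[11, 6:9 + 7] <- TRUE
  expect_equal(patch_compactness(patch_from_logical(shifted)), base,
               tolerance = 1e-9)
  rotated <- patch_from_logical(t(m)[, nrow(m):1])
  expect_equal(patch_compactness(rotated), base, tolerance = 1e-9)
})

test_that("areas convert to hectares correctly", {
  m <- matrix(0L, 120, 120)
  m[1:100, 1:100] <- 1L
  ct <- data.frame(class_id = c(0L, 1L), name = c("bg", "a"))
  res <- class_landscape_metrics(m, ct, gsd_cm = 10)
  # 100x100 px at 10 cm/px = 100 m^2 = 0.01 ha
  expect_equal(res$total_area_ha[res$class_id == 1], 0.01)
})

test_that("two equal patches halve the mean patch area", {
  m <- matrix(0L, 64, 64)
  m[1:10, 1:10] <- 1L
  m[30:39, 30:39] <- 1L
  ct <- data.frame(class_id = c(0L, 1L), name = c("bg", "a"))
  res <- class_landscape_metrics(m, ct, gsd_cm = 100)
  row <- res[res$class_id == 1, ]
  expect_equal(row$n_patches, 2)
  expect_equal(row$mean_patch_area_ha, row$total_area_ha / 2)
})

test_that("total areas conserve the scene and match generator bookkeeping", {
  sc <- small_scene(9)
  res <- class_landscape_metrics(sc$mask, sc$class_table, sc$gsd_cm,
                                 background_id = 0L)
  px_area_ha <- (sc$gsd_cm / 100)^2 / 1e4
  expect_equal(sum(res$total_area_ha, na.rm = TRUE),
               length(sc$mask) * px_area_ha, tolerance = 1e-9)
  for (i in seq_len(nrow(res))) {
    budget <- sc$pixel_budget[as.character(res$class_id[i])]
    got_px <- res$total_area_ha[i] / px_area_ha
    expect_lte(abs(got_px - budget), 1)
  }
  expect_true(res$background[res$class_id == 0])
})

test_that("absent classes report NA metrics, not zero", {
  m <- matrix(0L, 64, 64)
  ct <- data.frame(class_id = c(0L, 1L), name = c("bg", "ghost"))
  res <- class_landscape_metrics(m, ct, gsd_cm = 1.2)
  expect_true(is.na(res$total_area_ha[res$class_id == 1]))
  expect_equal(res$n_patches[res$class_id == 1], 0)
})

test_that("exact linear data recover slope and intercept", {
  metric <- seq(0.1, 1.6, by = 0.1)
  res <- f1_metric_regression(metric, 2 * metric)
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-12)
  expect_equal(res$df, 14)
})

test_that("a constant metric is rejected", {
  expect_error(f1_metric_regression(rep(1, 16), runif(16)), "zero variance")
})

test_that("an injected slope is recovered within the fit's own 95% CI", {
  set.seed(11)
  metric <- runif(16, 0, 2)
  f1 <- 0.3 + 0.25 * metric + rnorm(16, sd = 0.05)
  res <- f1_metric_regression(metric, f1)
  fit <- lm(f1 ~ metric)
  ci <- confint(fit)[2, ]
  expect_gte(0.25, ci[1])
  expect_lte(0.25, ci[2])
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(res$df, 14)
})
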