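px_to_ha <- function(area_px, gsd_cm) area_px * (gsd_cm / 100)^2 / 1e4

#' Connected patches of one class
#'
#' Partitions the pixels of a class into maximal connected components under
#' 4- (rook) or 8- (queen) connectivity; the patch is the unit of all
#' landscape metrics.
#'
#' @param mask integer class-id matrix.
#' @param class_id class to extract; an absent class yields an empty list.
#' @param connectivity 4 or 8 (default 8, the common landscape-metrics
#'   convention).
#' @return list of patches; each has `class_id`, `pixels` (two-column matrix
#'   of 1-based row/col indices) and `area_px`.
#' @export
label_patches <- function(mask, class_id, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask),
                                     ncol(mask)),
                              as.integer(class_id), as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    dimnames(px) <- NULL
    structure(list(class_id = class_id, pixels = px, area_px = nrow(px)),
              class = "patch")
  })
}

# circle helpers on (y, x) points ------------------------------------------

circle_two <- function(p, q) {
  ctr <- (p + q) / 2
  list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
}

circle_three <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {     # collinear: diametral circle of the farthest pair
    cands <- list(circle_two(a, b), circle_two(a, c), circle_two(b, c))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  uy <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  ux <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  ctr <- c(uy, ux)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(p, circ, tol = 1e-9)
  sqrt(sum((p - circ$center)^2)) <= circ$radius + tol

# Welzl-style incremental minimal enclosing circle of an n x 2 point matrix.
min_enclosing_circle <- function(pts) {
  n <- nrow(pts)
  circ <- list(center = pts[1, ], radius = 0)
  for (i in seq_len(n)[-1]) {
    if (in_circle(pts[i, ], circ)) next
    circ <- list(center = pts[i, ], radius = 0)
    for (j in seq_len(i - 1L)) {
      if (in_circle(pts[j, ], circ)) next
      circ <- circle_two(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (in_circle(pts[k, ], circ)) next
        circ <- circle_three(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  circ
}

patch_corner_points <- function(patch) {
  px <- patch$pixels
  pts <- rbind(cbind(px[, 1] - 1, px[, 2] - 1), cbind(px[, 1] - 1, px[, 2]),
               cbind(px[, 1], px[, 2] - 1), cbind(px[, 1], px[, 2]))
  pts <- unique(pts)
  if (nrow(pts) > 3L) pts[chull(pts[, 2], pts[, 1]), , drop = FALSE]
  else pts
}

#' Smallest circumscribing circle of a patch
#'
#' Minimal circle enclosing the patch's pixel squares, computed on the pixel
#' corner points (so a single pixel has radius sqrt(2)/2, the half-diagonal of
#' its unit square). Corner points are reduced to their convex hull before the
#' incremental minimal-circle construction.
#'
#' @param patch a patch from [label_patches()].
#' @return list with `center` (y, x in pixel units) and `radius` (pixels).
#' @export
smallest_circumscribing_circle <- function(patch) {
  if (nrow(patch$pixels) < 1L) stop("empty patch", call. = FALSE)
  min_enclosing_circle(patch_corner_points(patch))
}

#' Ratio-based patch compactness
#'
#' `1 - area_patch / area_circle`, with the circle from
#' [smallest_circumscribing_circle()]: values near 0 indicate circular
#' patches, values approaching 1 maximally elongated ones.
#'
#' @param patch a patch from [label_patches()].
#' @return compactness in `[0, 1]`.
#' @export
patch_compactness <- function(patch) {
  circ <- smallest_circumscribing_circle(patch)
  min(1, max(0, 1 - patch$area_px / (pi * circ$radius^2)))
}

#' Landscape metrics per class
#'
#' Per class: number of patches, mean patch area (ha), total class area (ha),
#' mean circumscribing-circle area (ha) and mean ratio-based compactness.
#' Classes absent from the mask get NA metrics (absent, not zero).
#'
#' @param mask integer class-id matrix.
#' @param class_table data frame with `class_id`, `name`.
#' @param gsd_cm ground sampling distance in cm per pixel.
#' @param connectivity 4 or 8.
#' @param background_id optional background class id, flagged in the output.
#' @return data frame, one row per class.
#' @export
class_landscape_metrics <- function(mask, class_table, gsd_cm,
                                    connectivity = 8, background_id = NULL) {
  rows <- lapply(seq_len(nrow(class_table)), function(i) {
    cid <- class_table$class_id[i]
    patches <- label_patches(mask, cid, connectivity)
    if (length(patches) == 0L)
      return(data.frame(class_id = cid, name = class_table$name[i],
                        n_patches = 0L, mean_patch_area_ha = NA_real_,
                        total_area_ha = NA_real_,
                        mean_circle_area_ha = NA_real_,
                        mean_compactness = NA_real_,
                        background = identical(cid, background_id) ||
                          cid %in% (background_id %||% integer(0))))
    areas <- vapply(patches, `[[`, numeric(1), "area_px")
    circles <- lapply(patches, smallest_circumscribing_circle)
    radii <- vapply(circles, `[[`, numeric(1), "radius")
    comp <- pmin(1, pmax(0, 1 - areas / (pi * radii^2)))
    data.frame(class_id = cid, name = class_table$name[i],
               n_patches = length(patches),
               mean_patch_area_ha = mean(px_to_ha(areas, gsd_cm)),
               total_area_ha = px_to_ha(sum(areas), gsd_cm),
               mean_circle_area_ha = mean(px_to_ha(pi * radii^2, gsd_cm)),
               mean_compactness = mean(comp),
               background = cid %in% (background_id %||% integer(0)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear regression of per-class F1 on a landscape metric
#'
#' Ordinary least squares of `f1 ~ metric` with a two-sided p-value for the
#' slope and `df = n - 2`. Intended to be run with the background class
#' excluded, so that 16 vegetation classes give df = 14.
#'
#' @param metric_values per-class metric vector.
#' @param f1_values per-class F1 vector, paired with `metric_values`.
#' @return list with `slope`, `intercept`, `p_value`, `df`.
#' @export
f1_metric_regression <- function(metric_values, f1_values) {
  if (length(metric_values) != length(f1_values))
    stop("paired vectors must have equal length", call. = FALSE)
  keep <- is.finite(metric_values) & is.finite(f1_values)
  x <- metric_values[keep]; y <- f1_values[keep]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (var(x) == 0)
    stop("metric has zero variance; regression is degenerate", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits warn harmlessly
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = sm$coefficients[2, 4], df = length(x) - 2L)
}
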