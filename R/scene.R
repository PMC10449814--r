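#' Describe one segmentation class of a synthetic scene
#'
#' A class specification controls how one vegetation class (or the bare
#' ground/herb background) is realised in a generated orthomosaic: its share
#' of the scene, patch geometry, base colour, and the granule size of its
#' fine-scale canopy texture.
#'
#' @param class_id small non-negative integer id (unique within a scene).
#' @param name class name.
#' @param target_proportion target fraction of scene pixels in `[0, 1]`.
#' @param base_color RGB triple in `[0, 255]`.
#' @param texture_scale characteristic granule size of the class texture in
#'   pixels (> 0); savanna canopies differ mainly in such fine structure.
#' @param patch_area_mean mean patch area in pixels (> 0).
#' @param elongation patch eccentricity in `[0, 1]`; 0 gives circular blobs.
#' @param background flag exactly one class per scene as background; it
#'   absorbs every pixel not claimed by a vegetation patch.
#' @return a `class_spec` list.
#' @export
class_spec <- function(class_id, name, target_proportion, base_color,
                       texture_scale = 4, patch_area_mean = 1500,
                       elongation = 0.3, background = FALSE) {
  stopifnot_scalar(class_id, "class_id")
  if (class_id < 0 || class_id != round(class_id))
    stop("'class_id' must be a small non-negative integer", call. = FALSE)
  stopifnot_scalar(target_proportion, "target_proportion")
  if (target_proportion < 0 || target_proportion > 1)
    stop("'target_proportion' must be in [0, 1]", call. = FALSE)
  if (length(base_color) != 3L || any(base_color < 0) || any(base_color > 255))
    stop("'base_color' must be an RGB triple in [0, 255]", call. = FALSE)
  if (texture_scale <= 0) stop("'texture_scale' must be > 0", call. = FALSE)
  if (patch_area_mean <= 0) stop("'patch_area_mean' must be > 0", call. = FALSE)
  if (elongation < 0 || elongation > 1)
    stop("'elongation' must be in [0, 1]", call. = FALSE)
  structure(list(class_id = as.integer(class_id), name = as.character(name),
                 target_proportion = target_proportion,
                 base_color = as.numeric(base_color),
                 texture_scale = texture_scale,
                 patch_area_mean = patch_area_mean,
                 elongation = elongation, background = isTRUE(background)),
            class = "class_spec")
}

#' Describe a synthetic labelled orthomosaic
#'
#' @param height_px,width_px scene size in pixels (>= 64).
#' @param classes list of [class_spec()] objects; target proportions must sum
#'   to 1 and exactly one class must be flagged as background.
#' @param gsd_cm ground sampling distance in cm per pixel; the default 1.2
#'   matches consumer-grade UAV imagery flown at ~40 m.
#' @param perturbation_strength default strength of the phenology-shift
#'   perturbation in `[0, 1]` (used by pipeline presets).
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(height_px, width_px, classes, gsd_cm = 1.2,
                       perturbation_strength = 0) {
  spec <- structure(list(height_px = as.integer(height_px),
                         width_px = as.integer(width_px),
                         classes = classes, gsd_cm = gsd_cm,
                         perturbation_strength = perturbation_strength),
                    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

#' @noRd
validate_scene_spec <- function(spec) {
  if (spec$height_px < 64L || spec$width_px < 64L)
    stop("scene dimensions must be at least 64 x 64 pixels", call. = FALSE)
  if (spec$gsd_cm <= 0) stop("'gsd_cm' must be > 0", call. = FALSE)
  if (spec$perturbation_strength < 0 || spec$perturbation_strength > 1)
    stop("'perturbation_strength' must be in [0, 1]", call. = FALSE)
  cls <- spec$classes
  if (length(cls) < 1L) stop("at least one class is required", call. = FALSE)
  ids <- vapply(cls, `[[`, integer(1), "class_id")
  if (anyDuplicated(ids)) stop("class_ids must be unique", call. = FALSE)
  props <- vapply(cls, `[[`, numeric(1), "target_proportion")
  if (abs(sum(props) - 1) > 1e-6)
    stop(sprintf("target proportions must sum to 1 (got %.8f)", sum(props)),
         call. = FALSE)
  bg <- vapply(cls, `[[`, logical(1), "background")
  if (sum(bg) != 1L)
    stop("exactly one class must be flagged as background", call. = FALSE)
  # patches must fit into the scene: check the major axis of a patch drawn at
  # the truncation cap (4 x mean area) against the short scene side
  for (cs in cls) {
    if (cs$background) next
    aspect <- 1 + 4 * cs$elongation
    major <- 2 * sqrt(4 * cs$patch_area_mean * aspect / pi)
    if (major > min(spec$height_px, spec$width_px))
      stop(sprintf(
        "scene too small for patches of class %d ('%s'): mean patch area %.0f px needs a scene side of at least %.0f px",
        cs$class_id, cs$name, cs$patch_area_mean, ceiling(major)),
        call. = FALSE)
  }
  invisible(spec)
}

class_table_of <- function(classes) {
  data.frame(class_id = vapply(classes, `[[`, integer(1), "class_id"),
             name = vapply(classes, `[[`, character(1), "name"),
             stringsAsFactors = FALSE)
}

new_labeled_scene <- function(image, mask, class_table, gsd_cm,
                              pixel_budget = NULL) {
  structure(list(image = image, mask = mask, class_table = class_table,
                 gsd_cm = gsd_cm, pixel_budget = pixel_budget),
            class = "labeled_scene")
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene> %d x %d px, %d classes, gsd %.2f cm/px\n",
              nrow(x$mask), ncol(x$mask), nrow(x$class_table), x$gsd_cm))
  invisible(x)
}

# Rasterise an ellipse; returns linear pixel indices into an H x W matrix.
ellipse_pixels <- function(cy, cx, area, aspect, theta, H, W) {
  a <- sqrt(area * aspect / pi)
  b <- a / aspect
  r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - cy; dx <- cc - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy * ct, dx * st, `+`)        # rotated coordinates
  v <- outer(-dy * st, dx * ct, `+`)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  ri <- rr[(idx - 1L) %% length(rr) + 1L]
  ci <- cc[(idx - 1L) %/% length(rr) + 1L]
  ri + (ci - 1L) * H
}

#' Generate a seeded synthetic labelled orthomosaic
#'
#' Builds a single-label class mask by placing randomly oriented elliptical
#' canopy patches for each vegetation class until its pixel budget
#' (`target_proportion` x scene area) is met; patches never overwrite pixels
#' already claimed by an earlier class, and the background class fills the
#' rest. The RGB image is painted per class as its base colour plus
#' band-passed noise at the class texture scale, emulating the fine-grained
#' leaf-scale structure that separates savanna tree species, plus a little
#' white-noise grain.
#'
#' Deterministic for a fixed `(spec, seed)` pair; empirical class proportions
#' approach the targets as the scene grows.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; the only source of randomness.
#' @return a `labeled_scene` with elements `image` (H x W x 3, values in
#'   `[0, 255]`), `mask` (H x W integer class ids), `class_table`, `gsd_cm`
#'   and `pixel_budget` (pixels actually claimed per class, the generator's
#'   own ledger).
#' @export
generate_scene <- function(spec, seed) {
  validate_scene_spec(spec)
  H <- spec$height_px; W <- spec$width_px
  cls <- spec$classes
  bg_id <- cls[[which(vapply(cls, `[[`, logical(1), "background"))]]$class_id
  with_seed(seed, {
    mask <- matrix(bg_id, H, W)
    claimed <- setNames(numeric(length(cls)),
                        vapply(cls, `[[`, integer(1), "class_id"))
    for (cs in cls) {
      if (cs$background) next
      budget <- round(cs$target_proportion * H * W)
      got <- 0L
      attempts <- 0L
      aspect <- 1 + 4 * cs$elongation
      while (got < budget && attempts < 10000L) {
        attempts <- attempts + 1L
        area <- min(rgamma(1, shape = 4, scale = cs$patch_area_mean / 4),
                    4 * cs$patch_area_mean)
        px <- ellipse_pixels(runif(1, 1, H), runif(1, 1, W),
                             area, aspect, runif(1, 0, pi), H, W)
        free <- px[mask[px] == bg_id]
        if (length(free) == 0L) next
        mask[free] <- cs$class_id
        got <- got + length(free)
      }
      if (got < budget)
        warning(sprintf(
          "class %d ('%s') reached %d of %d budgeted pixels after %d attempts",
          cs$class_id, cs$name, got, budget, attempts))
      claimed[as.character(cs$class_id)] <- got
    }
    claimed[as.character(bg_id)] <- H * W - sum(claimed)
    image <- array(0, dim = c(H, W, 3))
    for (cs in cls) {
      sel <- mask == cs$class_id
      if (!any(sel)) next
      tex <- bandpass_noise(H, W, cs$texture_scale)
      chan_gain <- c(1, 0.85, 0.7)    # texture expressed mostly in red/green
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[sel] <- cs$base_color[ch] + 22 * chan_gain[ch] * tex[sel]
        image[, , ch] <- plane
      }
    }
    image <- clip255(image + array(rnorm(H * W * 3, sd = 3),
                                   dim = c(H, W, 3)))
    image <- round(image)
    new_labeled_scene(image, mask, class_table_of(cls), spec$gsd_cm,
                      pixel_budget = claimed)
  })
}

#' Perturb scene appearance to emulate a phenology shift
#'
#' Applies a class-conditional hue/texture drift to the image while leaving
#' the mask untouched, emulating the morphological change between recording
#' campaigns months apart (leaf orientation, senescence) that degrades
#' temporal model transfer. At `strength = 0` the scene is returned
#' unchanged; the per-class mean colour shift grows linearly with `strength`.
#'
#' @param scene a `labeled_scene`.
#' @param strength perturbation strength in `[0, 1]`.
#' @param seed integer seed.
#' @return the perturbed `labeled_scene` (mask bit-identical to the input).
#' @export
perturb_scene <- function(scene, strength, seed) {
  stopifnot_scalar(strength, "strength")
  if (strength < 0 || strength > 1)
    stop("'strength' must be in [0, 1]", call. = FALSE)
  if (strength == 0) return(scene)
  H <- nrow(scene$mask); W <- ncol(scene$mask)
  with_seed(seed, {
    image <- scene$image
    for (cid in scene$class_table$class_id) {
      shift <- runif(3, -1, 1)
      shift <- 28 * shift / max(abs(shift))
      tex <- bandpass_noise(H, W, 5)
      sel <- scene$mask == cid
      if (!any(sel)) next
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[sel] <- plane[sel] + strength * (shift[ch] + 10 * tex[sel])
        image[, , ch] <- plane
      }
    }
    out <- scene
    out$image <- round(clip255(image))
    out
  })
}

#' Empirical class proportions of a mask
#'
#' Pixel shares per class in the order of `class_table`; the `p_i` feeding
#' inverse-power class weighting.
#'
#' @param mask integer class-id matrix.
#' @param class_table data frame with columns `class_id`, `name`.
#' @return named numeric vector summing to 1.
#' @export
empirical_class_proportions <- function(mask, class_table) {
  ids <- class_table$class_id
  m <- match(as.vector(mask), ids)
  if (anyNA(m)) {
    bad <- unique(as.vector(mask)[is.na(m)])
    stop(sprintf("mask contains class id(s) not in class table: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  p <- tabulate(m, nbins = length(ids)) / length(mask)
  names(p) <- class_table$name
  p
}

#' Write a labelled scene to disk as PNG rasters plus a CSV class table
#'
#' The image is written as an 8-bit RGB PNG, the mask as an 8-bit grey PNG
#' (lossless for class ids up to 255), the class table and the ground
#' sampling distance as CSV sidecars.
#'
#' @param scene a `labeled_scene`.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  if (max(scene$mask) > 255L)
    stop("mask class ids above 255 cannot be stored in an 8-bit PNG",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(name, c("_image.png", "_mask.png",
                                         "_classes.csv", "_meta.csv")))
  png::writePNG(scene$image / 255, paths[1])
  png::writePNG(scene$mask / 255, paths[2])
  write.csv(scene$class_table, paths[3], row.names = FALSE)
  write.csv(data.frame(gsd_cm = scene$gsd_cm), paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a labelled scene written by [write_scene()]
#' @param dir directory containing the files.
#' @param name file stem used when writing.
#' @return a `labeled_scene`.
#' @export
read_scene <- function(dir, name = "scene") {
  img <- png::readPNG(file.path(dir, paste0(name, "_image.png"))) * 255
  msk <- round(png::readPNG(file.path(dir, paste0(name, "_mask.png"))) * 255)
  ct <- read.csv(file.path(dir, paste0(name, "_classes.csv")),
                 stringsAsFactors = FALSE)
  meta <- read.csv(file.path(dir, paste0(name, "_meta.csv")))
  new_labeled_scene(round(img), matrix(as.integer(msk), nrow(msk), ncol(msk)),
                    ct, meta$gsd_cm)
}
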