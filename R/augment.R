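#' Augmentation parameters
#'
#' Defaults follow the study protocol: random horizontal flip, rotation within
#' +/- 0.35 rad, scaling in `[0.9, 1.1]`, brightness changes up to +/- 25%
#' (multiplicative), contrast changes of 50-200% (scaling of the deviation
#' from the image mean) and saturation changes of 60-175% (scaling of the HSV
#' S channel).
#'
#' @param p_hflip probability of a horizontal flip.
#' @param rot_range_rad symmetric rotation bound in radians.
#' @param scale_range multiplicative scaling interval.
#' @param brightness_delta maximum relative brightness change.
#' @param contrast_range contrast factor interval.
#' @param saturation_range saturation factor interval.
#' @return an `augment_params` list.
#' @export
augment_params <- function(p_hflip = 0.5, rot_range_rad = 0.35,
                           scale_range = c(0.9, 1.1), brightness_delta = 0.25,
                           contrast_range = c(0.5, 2.0),
                           saturation_range = c(0.6, 1.75)) {
  if (p_hflip < 0 || p_hflip > 1)
    stop("'p_hflip' must be in [0, 1]", call. = FALSE)
  for (iv in list(scale_range, contrast_range, saturation_range))
    if (length(iv) != 2L || iv[2] < iv[1])
      stop("interval parameters must be non-empty (lo, hi) pairs",
           call. = FALSE)
  if (rot_range_rad < 0 || brightness_delta < 0)
    stop("ranges must be non-negative", call. = FALSE)
  structure(list(p_hflip = p_hflip, rot_range_rad = rot_range_rad,
                 scale_range = scale_range,
                 brightness_delta = brightness_delta,
                 contrast_range = contrast_range,
                 saturation_range = saturation_range),
            class = "augment_params")
}

# Inverse-mapped rotation+scale about the tile centre. Image is sampled
# bilinearly with reflection fill; the mask nearest-neighbour with clamping to
# the nearest valid pixel, so no ignore label is ever introduced.
warp_pair <- function(image, mask, angle, scale) {
  H <- nrow(mask); W <- ncol(mask)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dy <- g$r - cy; dx <- g$c - cx
  ct <- cos(-angle); st <- sin(-angle)
  sy <- (dy * ct - dx * st) / scale + cy
  sx <- (dy * st + dx * ct) / scale + cx
  # mask: nearest neighbour, clamped
  mr <- clamp_index(as.integer(round(sy)), H)
  mc <- clamp_index(as.integer(round(sx)), W)
  new_mask <- matrix(mask[cbind(mr, mc)], H, W)
  # image: bilinear with reflected indices
  r0 <- floor(sy); c0 <- floor(sx)
  fr <- sy - r0; fc <- sx - c0
  i00 <- cbind(reflect_index(r0, H), reflect_index(c0, W))
  i01 <- cbind(reflect_index(r0, H), reflect_index(c0 + 1, W))
  i10 <- cbind(reflect_index(r0 + 1, H), reflect_index(c0, W))
  i11 <- cbind(reflect_index(r0 + 1, H), reflect_index(c0 + 1, W))
  new_image <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3])) {
    pl <- image[, , ch]
    v <- pl[i00] * (1 - fr) * (1 - fc) + pl[i01] * (1 - fr) * fc +
      pl[i10] * fr * (1 - fc) + pl[i11] * fr * fc
    new_image[, , ch] <- matrix(v, H, W)
  }
  list(image = new_image, mask = new_mask)
}

rgb_to_hsv_arr <- function(img01) {
  r <- img01[, , 1]; g <- img01[, , 2]; b <- img01[, , 3]
  v <- pmax(r, pmax(g, b))
  m <- pmin(r, pmin(g, b))
  d <- v - m
  s <- ifelse(v > 0, d / v, 0)
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  hr <- nz & v == r
  hg <- nz & v == g & !hr
  hb <- nz & !hr & !hg
  h[hr] <- ((g - b)[hr] / d[hr]) %% 6
  h[hg] <- (b - r)[hg] / d[hg] + 2
  h[hb] <- (r - g)[hb] / d[hb] + 4
  list(h = h * 60, s = s, v = v)
}

hsv_to_rgb_arr <- function(h, s, v) {
  c <- v * s
  hp <- (h / 60) %% 6
  x <- c * (1 - abs(hp %% 2 - 1))
  m <- v - c
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  seg <- floor(hp)
  set <- function(idx, rr, gg, bb) {
    r[idx] <<- rr[idx]; g[idx] <<- gg[idx]; b[idx] <<- bb[idx]
  }
  set(seg == 0, c, x, 0 * c); set(seg == 1, x, c, 0 * c)
  set(seg == 2, 0 * c, c, x); set(seg == 3, 0 * c, x, c)
  set(seg == 4, x, 0 * c, c); set(seg == 5, c, 0 * c, x)
  out <- array(0, c(nrow(h), ncol(h), 3))
  out[, , 1] <- r + m; out[, , 2] <- g + m; out[, , 3] <- b + m
  out
}

#' Label-consistent augmentation of an image/mask tile pair
#'
#' Geometric operations (horizontal flip, rotation, scaling) are applied
#' identically to image and mask; photometric operations (brightness,
#' contrast, saturation) touch the image only. The operation order is flip,
#' rotate, scale, brightness, contrast, saturation; rotation and scaling are
#' applied as one resampling pass (bilinear for the image, nearest-neighbour
#' for the mask), and an operation drawn at its identity value is skipped so
#' degenerate parameter ranges reproduce the input bit for bit.
#'
#' @param image H x W x 3 raster with values in `[0, 255]`.
#' @param mask H x W integer class-id raster.
#' @param params an [augment_params()] object.
#' @param seed integer seed; fixed `(inputs, params, seed)` give bit-identical
#'   outputs.
#' @return list with augmented `image` and `mask` of the input dimensions.
#' @export
augment_pair <- function(image, mask, params, seed) {
  if (nrow(mask) != dim(image)[1] || ncol(mask) != dim(image)[2])
    stop("image and mask dimensions differ", call. = FALSE)
  draws <- with_seed(seed, list(
    flip = runif(1) < params$p_hflip,
    angle = runif(1, -params$rot_range_rad, params$rot_range_rad),
    scale = runif(1, params$scale_range[1], params$scale_range[2]),
    bright = runif(1, 1 - params$brightness_delta,
                   1 + params$brightness_delta),
    contrast = runif(1, params$contrast_range[1], params$contrast_range[2]),
    sat = runif(1, params$saturation_range[1], params$saturation_range[2])))
  if (draws$flip) {
    image <- image[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (draws$angle != 0 || draws$scale != 1) {
    wp <- warp_pair(image, mask, draws$angle, draws$scale)
    image <- wp$image; mask <- wp$mask
  }
  if (draws$bright != 1) image <- image * draws$bright
  if (draws$contrast != 1) {
    mu <- mean(image)
    image <- mu + (image - mu) * draws$contrast
  }
  if (draws$sat != 1) {
    hsv <- rgb_to_hsv_arr(clip255(image) / 255)
    s <- pmin(pmax(hsv$s * draws$sat, 0), 1)
    image <- hsv_to_rgb_arr(hsv$h, s, hsv$v) * 255
  }
  list(image = clip255(image), mask = mask)
}
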