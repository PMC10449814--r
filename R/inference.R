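#' Offset grid for ensemble tiled inference
#'
#' Cartesian product of row and column offsets at the given fractions of the
#' tile size; the default fractions 0, 25, 50 and 75% give the 16 prediction
#' layers of the ensemble scheme. Offsets are floored to whole pixels.
#'
#' @param tile_size tile side length T.
#' @param fractions offset fractions in `[0, 1)`; must include 0. Fractions
#'   that collapse to the same pixel offset are merged with a warning.
#' @return integer matrix with columns `row_offset`, `col_offset`, one row per
#'   layer (row-major over row offsets, then column offsets).
#' @export
offset_grid <- function(tile_size, fractions = c(0, 0.25, 0.5, 0.75)) {
  if (any(fractions < 0 | fractions >= 1))
    stop("offset fractions must lie in [0, 1)", call. = FALSE)
  if (!any(fractions == 0))
    stop("offset fractions must include 0", call. = FALSE)
  offs <- unique(as.integer(floor(fractions * tile_size)))
  if (length(offs) < length(fractions))
    warning("duplicate offsets after flooring were collapsed")
  offs <- sort(offs)
  g <- expand.grid(col_offset = offs, row_offset = offs)
  cbind(row_offset = g$row_offset, col_offset = g$col_offset)
}

# Normalise the model argument: a segmentation_model becomes a tile predictor
# function(image, origin_row, origin_col) -> class-id matrix. Plain functions
# (stubs, alternative models) are used as-is.
as_tile_predictor <- function(model, class_ids) {
  if (is.function(model)) return(model)
  if (inherits(model, "segmentation_model")) {
    if (model$config$n_classes != length(class_ids))
      stop("model n_classes does not match the class table", call. = FALSE)
    return(function(image, origin_row, origin_col)
      predict_tile_mask(model, image, class_ids))
  }
  stop("'model' must be a segmentation_model or a predictor function",
       call. = FALSE)
}

#' Predict a scene as a stack of offset tile layers
#'
#' For each offset of the grid, the scene is reflection-padded so that a full
#' grid of tiles (stride T, starting at the offset) covers every pixel, each
#' tile is predicted, and the result is cropped back to the scene extent.
#' Every pixel is therefore covered exactly once per layer and receives one
#' vote per layer.
#'
#' @param model a `segmentation_model`, or a predictor
#'   `function(image, origin_row, origin_col)` returning a class-id matrix
#'   (origins are scene coordinates of the tile's top-left pixel, 0-based,
#'   possibly negative for shifted layers).
#' @param scene a `labeled_scene`.
#' @param tile_size tile side length.
#' @param fractions offset fractions, as in [offset_grid()].
#' @return an `offset_stack`: list with `layers` (list of H x W class-id
#'   matrices), `offsets`, `tile_size`.
#' @export
predict_offset_stack <- function(model, scene, tile_size,
                                 fractions = c(0, 0.25, 0.5, 0.75)) {
  grid <- offset_grid(tile_size, fractions)
  class_ids <- scene$class_table$class_id
  predictor <- as_tile_predictor(model, class_ids)
  H <- nrow(scene$mask); W <- ncol(scene$mask)
  T <- as.integer(tile_size)
  layers <- vector("list", nrow(grid))
  for (li in seq_len(nrow(grid))) {
    ro <- grid[li, 1]; co <- grid[li, 2]
    pad_top <- (T - ro) %% T
    pad_left <- (T - co) %% T
    pad_bottom <- (T - (H + pad_top) %% T) %% T
    pad_right <- (T - (W + pad_left) %% T) %% T
    img <- reflect_pad(scene$image, pad_top, pad_left, pad_bottom, pad_right)
    canvas <- matrix(NA_integer_, dim(img)[1], dim(img)[2])
    for (r0 in seq(0L, dim(img)[1] - T, by = T)) {
      for (c0 in seq(0L, dim(img)[2] - T, by = T)) {
        tile <- img[r0 + seq_len(T), c0 + seq_len(T), , drop = FALSE]
        canvas[r0 + seq_len(T), c0 + seq_len(T)] <-
          predictor(tile, r0 - pad_top, c0 - pad_left)
      }
    }
    layers[[li]] <- canvas[pad_top + seq_len(H), pad_left + seq_len(W),
                           drop = FALSE]
  }
  structure(list(layers = layers, offsets = grid, tile_size = T),
            class = "offset_stack")
}

#' Per-pixel majority vote over prediction layers
#'
#' Each pixel takes the class id predicted by most layers; ties break toward
#' the lowest class id, so the vote is deterministic.
#'
#' @param stack an `offset_stack` (or bare list of class-id matrices).
#' @return H x W integer class-id matrix.
#' @export
majority_vote <- function(stack) {
  layers <- if (inherits(stack, "offset_stack")) stack$layers else stack
  if (length(layers) == 0L) stop("empty prediction stack", call. = FALSE)
  ids <- sort(unique(unlist(lapply(layers, function(l) unique(as.vector(l))))))
  H <- nrow(layers[[1]]); W <- ncol(layers[[1]])
  best_count <- matrix(-1L, H, W)
  winner <- matrix(ids[1], H, W)
  for (id in ids) {            # ascending ids: strict > implements the
    cnt <- matrix(0L, H, W)    # lowest-id tie-break
    for (l in layers) cnt <- cnt + (l == id)
    take <- cnt > best_count
    winner[take] <- id
    best_count[take] <- cnt[take]
  }
  winner
}

#' Predict a full scene with offset-ensemble majority voting
#'
#' Convenience wrapper: [predict_offset_stack()] followed by
#' [majority_vote()].
#'
#' @inheritParams predict_offset_stack
#' @return H x W integer class-id matrix.
#' @export
predict_scene <- function(model, scene, tile_size,
                          fractions = c(0, 0.25, 0.5, 0.75)) {
  majority_vote(predict_offset_stack(model, scene, tile_size, fractions))
}
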