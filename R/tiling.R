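#' Cut a scene into non-overlapping square tiles
#'
#' Tiles are laid on a regular grid from the top-left origin; partial tiles at
#' the right and bottom edges are discarded, so the count is
#' `floor(H/T) * floor(W/T)`. Origins are 0-based top-left pixel indices and
#' tiles cover the half-open ranges `[origin, origin + T)`.
#'
#' @param scene a `labeled_scene`.
#' @param tile_size side length T in pixels (the study sizes are 256, 512 and
#'   1024; any positive size is accepted).
#' @return list of tiles, row-major; each tile has `image`, `mask`,
#'   `origin_row`, `origin_col`, `tile_size`. An empty list (with a warning)
#'   if the scene is smaller than one tile.
#' @export
tile_scene <- function(scene, tile_size) {
  stopifnot_scalar(tile_size, "tile_size")
  if (tile_size < 1) stop("'tile_size' must be >= 1", call. = FALSE)
  T <- as.integer(tile_size)
  H <- nrow(scene$mask); W <- ncol(scene$mask)
  nr <- H %/% T; nc <- W %/% T
  if (nr == 0L || nc == 0L) {
    warning(sprintf("scene (%d x %d) smaller than one %d px tile; no tiles",
                    H, W, T))
    return(list())
  }
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * T; c0 <- (j - 1L) * T
      k <- k + 1L
      tiles[[k]] <- structure(
        list(image = scene$image[r0 + seq_len(T), c0 + seq_len(T), , drop = FALSE],
             mask = scene$mask[r0 + seq_len(T), c0 + seq_len(T), drop = FALSE],
             origin_row = r0, origin_col = c0, tile_size = T),
        class = "scene_tile")
    }
  }
  tiles
}

#' Reassemble tiles onto a canvas at their origins
#'
#' Inverse of [tile_scene()] on the covered region; used to verify that tiling
#' is lossless.
#'
#' @param tiles list of tiles from [tile_scene()].
#' @param height_px,width_px canvas size.
#' @return list with `image` and `mask` canvases (uncovered pixels are NA).
#' @export
assemble_tiles <- function(tiles, height_px, width_px) {
  img <- array(NA_real_, c(height_px, width_px, 3))
  msk <- matrix(NA_integer_, height_px, width_px)
  for (t in tiles) {
    rs <- t$origin_row + seq_len(t$tile_size)
    cs <- t$origin_col + seq_len(t$tile_size)
    img[rs, cs, ] <- t$image
    msk[rs, cs] <- t$mask
  }
  list(image = img, mask = msk)
}

#' Assign whole scenes to spatially separated train/validation/test roles
#'
#' Splits operate at whole-scene granularity only: train, validation and test
#' data never share a scene, which is the guard against spatial
#' autocorrelation inflating apparent accuracy.
#'
#' @param scene_ids vector of scene identifiers.
#' @param scheme named list with elements `train`, `validation`, `test`, each
#'   a vector of scene ids (missing roles are treated as empty).
#' @return data frame (`scene_id`, `role`), one row per scene.
#' @export
spatial_split <- function(scene_ids, scheme) {
  roles <- c("train", "validation", "test")
  scheme <- scheme[intersect(names(scheme), roles)]
  all_assigned <- unlist(scheme, use.names = FALSE)
  dup <- unique(all_assigned[duplicated(all_assigned)])
  if (length(dup))
    stop(sprintf("scene(s) assigned to more than one role: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  missing <- setdiff(scene_ids, all_assigned)
  if (length(missing))
    stop(sprintf("scheme does not cover scene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, lapply(roles, function(r) {
    ids <- intersect(scheme[[r]] %||% character(0), scene_ids)
    if (length(ids)) data.frame(scene_id = ids, role = r,
                                stringsAsFactors = FALSE)
  }))
  for (r in c("validation", "test"))
    if (!any(out$role == r))
      warning(sprintf("no scenes assigned to role '%s'", r))
  rownames(out) <- NULL
  structure(out, class = c("split_assignment", "data.frame"))
}

#' Persist tiles as paired PNG files plus a manifest CSV
#'
#' @param tiles list of tiles from [tile_scene()].
#' @param dir output directory.
#' @param scene_id scene identifier recorded in the manifest.
#' @param role split role recorded in the manifest.
#' @return invisibly, the manifest data frame (also written to
#'   `manifest.csv`, appended if one exists).
#' @export
write_tiles <- function(tiles, dir, scene_id, role = "train") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(tiles), function(i) {
    t <- tiles[[i]]
    tid <- sprintf("%s_r%d_c%d", scene_id, t$origin_row, t$origin_col)
    png::writePNG(t$image / 255, file.path(dir, paste0(tid, "_image.png")))
    png::writePNG(t$mask / 255, file.path(dir, paste0(tid, "_mask.png")))
    data.frame(tile_id = tid, scene_id = scene_id,
               origin_row = t$origin_row, origin_col = t$origin_col,
               tile_size = t$tile_size, role = role,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath))
    manifest <- rbind(read.csv(mpath, stringsAsFactors = FALSE), manifest)
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(manifest)
}
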