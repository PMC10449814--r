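#' Model configuration
#'
#' Describes one of the three encoder-decoder segmentation architectures at a
#' configurable scale. The study-scale variants are presets; the same builders
#' produce small instances suited to CPU experiments.
#'
#' @param architecture one of `"unet"`, `"fc_densenet"`, `"deeplabv3plus"`.
#' @param n_classes number of output classes.
#' @param depth number of down/upsampling stages (tile side must be divisible
#'   by `2^depth`).
#' @param base_width channels of the first stage.
#' @param atrous_rates dilation rates of the atrous spatial pyramid pooling
#'   branches (DeepLabv3+ only).
#' @param growth_rate channels added by each layer of a dense block
#'   (FC-DenseNet only).
#' @param block_layers layers per dense block (FC-DenseNet only).
#' @return a `model_config` list.
#' @export
model_config <- function(architecture = c("unet", "fc_densenet",
                                          "deeplabv3plus"),
                         n_classes, depth = 2L, base_width = 8L,
                         atrous_rates = c(1L, 2L, 4L), growth_rate = 4L,
                         block_layers = 2L) {
  architecture <- match.arg(architecture)
  stopifnot_scalar(n_classes, "n_classes")
  if (n_classes < 2) stop("'n_classes' must be >= 2", call. = FALSE)
  if (depth < 1) stop("'depth' must be >= 1", call. = FALSE)
  structure(list(architecture = architecture,
                 n_classes = as.integer(n_classes),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 atrous_rates = as.integer(atrous_rates),
                 growth_rate = as.integer(growth_rate),
                 block_layers = as.integer(block_layers)),
            class = "model_config")
}

# --- graph builders ---------------------------------------------------------

unet_graph <- function(cfg) {
  nodes <- list(new_node("input", integer(0)))
  last <- function() length(nodes)
  conv <- function(from, ch, k = 3L, act = "relu", dil = 1L, tag = NULL) {
    nodes[[length(nodes) + 1L]] <<- new_node("conv", from, ch, k, dil, act,
                                             tag)
    last()
  }
  skips <- integer(cfg$depth)
  cur <- 1L
  for (d in seq_len(cfg$depth)) {
    w <- cfg$base_width * 2L^(d - 1L)
    cur <- conv(cur, w); cur <- conv(cur, w)
    skips[d] <- cur
    nodes[[length(nodes) + 1L]] <- new_node("pool", cur)
    cur <- last()
  }
  w <- cfg$base_width * 2L^cfg$depth
  cur <- conv(cur, w); cur <- conv(cur, w)
  for (d in rev(seq_len(cfg$depth))) {
    nodes[[length(nodes) + 1L]] <- new_node("up", cur); cur <- last()
    nodes[[length(nodes) + 1L]] <- new_node("concat", c(cur, skips[d]))
    cur <- last()
    w <- cfg$base_width * 2L^(d - 1L)
    cur <- conv(cur, w); cur <- conv(cur, w)
  }
  conv(cur, cfg$n_classes, k = 1L, act = "linear")
  nodes
}

fc_densenet_graph <- function(cfg) {
  nodes <- list(new_node("input", integer(0)))
  last <- function() length(nodes)
  add <- function(nd) {
    nodes[[length(nodes) + 1L]] <<- nd
    last()
  }
  # dense block: each layer convolves the running concatenation and its
  # output is concatenated back in (within-block dense connectivity)
  dense_block <- function(from) {
    cur <- from
    for (l in seq_len(cfg$block_layers)) {
      cv <- add(new_node("conv", cur, cfg$growth_rate, tag = "dense"))
      cur <- add(new_node("concat", c(cur, cv)))
    }
    cur
  }
  cur <- add(new_node("conv", 1L, cfg$base_width))
  skips <- integer(cfg$depth)
  for (d in seq_len(cfg$depth)) {
    cur <- dense_block(cur)
    skips[d] <- cur
    cur <- add(new_node("conv", cur, cfg$base_width * d, k = 1L)) # transition
    cur <- add(new_node("pool", cur))
  }
  cur <- dense_block(cur)
  for (d in rev(seq_len(cfg$depth))) {
    cur <- add(new_node("up", cur))
    cur <- add(new_node("concat", c(cur, skips[d])))
    cur <- dense_block(cur)
  }
  add(new_node("conv", cur, cfg$n_classes, k = 1L, act = "linear"))
  nodes
}

deeplab_graph <- function(cfg) {
  nodes <- list(new_node("input", integer(0)))
  last <- function() length(nodes)
  add <- function(nd) {
    nodes[[length(nodes) + 1L]] <<- nd
    last()
  }
  w <- cfg$base_width
  # encoder: `depth` pooling stages; low-level features kept after stage 1
  cur <- add(new_node("conv", 1L, w))
  cur <- add(new_node("pool", cur))
  low <- add(new_node("conv", cur, w))
  cur <- low
  for (d in seq_len(cfg$depth - 1L)) {
    cur <- add(new_node("conv", cur, w * 2L^d))
    cur <- add(new_node("pool", cur))
    cur <- add(new_node("conv", cur, w * 2L^d))
  }
  # ASPP: one atrous conv per rate plus a global-average-pooling branch
  branches <- integer(0)
  for (r in cfg$atrous_rates)
    branches <- c(branches,
                  add(new_node("conv", cur, w, k = 3L, dil = r,
                               tag = "aspp")))
  gp <- add(new_node("gap", cur))
  branches <- c(branches, add(new_node("conv", gp, w, k = 1L, tag = "aspp")))
  cur <- add(new_node("concat", branches))
  cur <- add(new_node("conv", cur, w, k = 1L))          # projection
  # decoder: upsample to the low-level stride, fuse, refine, restore
  for (d in seq_len(cfg$depth - 1L)) cur <- add(new_node("up", cur))
  lowr <- add(new_node("conv", low, w, k = 1L))
  cur <- add(new_node("concat", c(cur, lowr)))
  cur <- add(new_node("conv", cur, w))
  cur <- add(new_node("up", cur))
  add(new_node("conv", cur, cfg$n_classes, k = 1L, act = "linear"))
  nodes
}

#' Build a segmentation model
#'
#' Instantiates the configured architecture with randomly (He) initialised
#' parameters. For any input tile of side divisible by `2^depth` the model
#' emits per-pixel class scores at the input resolution whose softmax rows
#' form a probability simplex. Architecture contracts: `unet` is a symmetric
#' encoder/decoder with skip concatenations; `fc_densenet` uses dense blocks
#' with within-block concatenation on both paths; `deeplabv3plus` applies
#' atrous spatial pyramid pooling (one dilated branch per rate plus a pooling
#' branch) and a decoder fusing a low-level feature map.
#'
#' @param config a [model_config()].
#' @param seed seed for parameter initialisation.
#' @return a `segmentation_model`; `model$branches$aspp` lists the declared
#'   ASPP branch nodes for DeepLabv3+.
#' @export
build_model <- function(config, seed = 1L) {
  nodes <- switch(config$architecture,
                  unet = unet_graph(config),
                  fc_densenet = fc_densenet_graph(config),
                  deeplabv3plus = deeplab_graph(config))
  params <- init_params(nodes, in_ch = 3L, seed = seed)
  tags <- vapply(nodes, function(nd) nd$tag %||% "", character(1))
  structure(list(config = config, nodes = nodes, params = params,
                 branches = list(aspp = which(tags == "aspp"),
                                 dense = which(tags == "dense"))),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model> %s, %d classes, depth %d, %d parameters\n",
              x$config$architecture, x$config$n_classes, x$config$depth,
              n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `segmentation_model`.
#' @export
n_params <- function(model) n_params_of(model$params)

check_tile_dims <- function(model, h, w) {
  div <- 2L^model$config$depth
  if (h %% div != 0L || w %% div != 0L)
    stop(sprintf("tile size %d x %d is not divisible by 2^depth = %d",
                 h, w, div), call. = FALSE)
}

#' Per-pixel class probabilities for one tile
#'
#' @param model a `segmentation_model`.
#' @param image H x W x 3 raster in `[0, 255]` (scaled to `[0, 1]`
#'   internally).
#' @return H x W x n_classes array; probabilities sum to 1 per pixel.
#' @export
predict_tile_probs <- function(model, image) {
  check_tile_dims(model, dim(image)[1], dim(image)[2])
  fw <- net_forward(model$nodes, model$params, image / 255)
  z <- fw$out
  npx <- prod(dim(z)[1:2])
  p <- softmax_rows(matrix(z, npx, dim(z)[3]))
  array(p, dim(z))
}

#' Hard class prediction for one tile
#' @param model a `segmentation_model`.
#' @param image H x W x 3 raster in `[0, 255]`.
#' @param class_ids class id for each model output channel, in order.
#' @return H x W integer matrix of class ids.
#' @export
predict_tile_mask <- function(model, image,
                              class_ids = seq_len(model$config$n_classes) - 1L) {
  p <- predict_tile_probs(model, image)
  npx <- prod(dim(p)[1:2])
  idx <- max.col(matrix(p, npx, dim(p)[3]), ties.method = "first")
  matrix(as.integer(class_ids[idx]), dim(p)[1], dim(p)[2])
}
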