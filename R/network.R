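# Static-graph CNN engine.
#
# A network is a list of nodes evaluated in order; each node names the nodes
# it consumes, so encoder-decoder graphs with skip connections, dense blocks
# and parallel atrous branches are all expressible. Supported ops:
#   input               the H x W x 3 tile
#   conv                k x k convolution (same zero padding, optional
#                       dilation), bias, optional ReLU
#   pool                2 x 2 max pooling, stride 2
#   up                  nearest-neighbour x2 upsampling
#   concat              channel concatenation of >= 2 nodes
#   gap                 global average pooling broadcast back to H x W
# Heavy kernels (convolution, pooling, upsampling) live in C++.

new_node <- function(op, from, out_ch = NULL, k = 3L, dil = 1L,
                     act = "relu", tag = NULL) {
  list(op = op, from = from, out_ch = out_ch, k = as.integer(k),
       dil = as.integer(dil), act = act, tag = tag)
}

# Channel count of every node, given the input channel count.
graph_channels <- function(nodes, in_ch = 3L) {
  ch <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    ch[i] <- switch(nd$op,
      input = in_ch,
      conv = nd$out_ch,
      pool = ch[nd$from],
      up = ch[nd$from],
      gap = ch[nd$from],
      concat = sum(ch[nd$from]),
      stop("unknown op: ", nd$op))
  }
  ch
}

# He-initialised parameters for every conv node.
init_params <- function(nodes, in_ch = 3L, seed = 1L) {
  ch <- graph_channels(nodes, in_ch)
  with_seed(seed, {
    params <- vector("list", length(nodes))
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      if (nd$op != "conv") next
      cin <- ch[nd$from]
      fan_in <- nd$k * nd$k * cin
      params[[i]] <- list(
        W = matrix(rnorm(fan_in * nd$out_ch, sd = sqrt(2 / fan_in)),
                   fan_in, nd$out_ch),
        b = numeric(nd$out_ch))
    }
    params
  })
}

n_params_of <- function(params)
  sum(vapply(params, function(p)
    if (is.null(p)) 0L else length(p$W) + length(p$b), integer(1)))

relu_fwd <- function(y) {
  y[y < 0] <- 0
  y
}

# Forward pass; returns output of the last node plus (optionally) the caches
# needed for backprop.
net_forward <- function(nodes, params, x, keep_cache = FALSE) {
  vals <- vector("list", length(nodes))
  cache <- if (keep_cache) vector("list", length(nodes)) else NULL
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    vals[[i]] <- switch(nd$op,
      input = x,
      conv = {
        y <- cpp_conv_fwd(vals[[nd$from]], params[[i]]$W, params[[i]]$b,
                          nd$k, nd$dil)
        if (nd$act == "relu") {
          if (keep_cache) cache[[i]] <- y > 0
          y <- relu_fwd(y)
        }
        y
      },
      pool = {
        v <- vals[[nd$from]]
        if (nrow(v) %% 2L != 0L || ncol(v) %% 2L != 0L)
          stop("tile size must be divisible by 2^depth for pooling",
               call. = FALSE)
        r <- cpp_maxpool_fwd(v)
        if (keep_cache) cache[[i]] <- r$idx
        r$y
      },
      up = cpp_upsample_fwd(vals[[nd$from]]),
      gap = {
        v <- vals[[nd$from]]
        mu <- colMeans(matrix(v, prod(dim(v)[1:2]), dim(v)[3]))
        array(rep(mu, each = prod(dim(v)[1:2])), dim(v))
      },
      concat = {
        parts <- vals[nd$from]
        d <- dim(parts[[1]])
        array(unlist(parts, use.names = FALSE),
              c(d[1], d[2], sum(vapply(parts, function(p) dim(p)[3],
                                       numeric(1)))))
      })
  }
  list(out = vals[[length(nodes)]], vals = vals, cache = cache)
}

# Backward pass from d(loss)/d(output of last node); returns gradients shaped
# like `params`.
net_backward <- function(nodes, params, fw, dout) {
  dvals <- vector("list", length(nodes))
  grads <- vector("list", length(nodes))
  dvals[[length(nodes)]] <- dout
  add_grad <- function(i, g) {
    dvals[[i]] <<- if (is.null(dvals[[i]])) g else dvals[[i]] + g
  }
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    dy <- dvals[[i]]
    if (is.null(dy) || nd$op == "input") next
    switch(nd$op,
      conv = {
        if (nd$act == "relu") dy <- dy * fw$cache[[i]]
        bw <- cpp_conv_bwd(fw$vals[[nd$from]], params[[i]]$W, dy, nd$k,
                           nd$dil)
        grads[[i]] <- list(W = bw$dw, b = as.numeric(bw$db))
        add_grad(nd$from, bw$dx)
      },
      pool = {
        v <- fw$vals[[nd$from]]
        add_grad(nd$from, cpp_maxpool_bwd(nrow(v), ncol(v), dim(v)[3],
                                          fw$cache[[i]], dy))
      },
      up = add_grad(nd$from, cpp_upsample_bwd(dy)),
      gap = {
        v <- fw$vals[[nd$from]]
        npx <- prod(dim(v)[1:2])
        dmu <- colSums(matrix(dy, npx, dim(v)[3])) / npx
        add_grad(nd$from, array(rep(dmu, each = npx), dim(v)))
      },
      concat = {
        off <- 0L
        for (j in nd$from) {
          cj <- dim(fw$vals[[j]])[3]
          add_grad(j, dy[, , off + seq_len(cj), drop = FALSE])
          off <- off + cj
        }
      })
  }
  grads
}

# One Adam step over all conv parameters; state holds first/second moments.
adam_init <- function(params)
  list(t = 0L,
       m = lapply(params, function(p)
         if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p)
         if (is.null(p)) NULL else list(W = p$W * 0, b = p$b * 0)))

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (f in c("W", "b")) {
      g <- grads[[i]][[f]]
      state$m[[i]][[f]] <- beta1 * state$m[[i]][[f]] + (1 - beta1) * g
      state$v[[i]][[f]] <- beta2 * state$v[[i]][[f]] + (1 - beta2) * g^2
      params[[i]][[f]] <- params[[i]][[f]] -
        lr * (state$m[[i]][[f]] / bc1) /
          (sqrt(state$v[[i]][[f]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
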