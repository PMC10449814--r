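# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops / direct arithmetic, independent of the package's code paths.

three_class_specs <- function() {
  list(
    class_spec(0L, "bare_ground", 0.70, c(150, 120, 90), texture_scale = 2,
               background = TRUE),
    class_spec(1L, "broadleaf", 0.18, c(40, 130, 45), texture_scale = 3,
               patch_area_mean = 500, elongation = 0.2),
    class_spec(2L, "fineleaf", 0.12, c(190, 180, 60), texture_scale = 7,
               patch_area_mean = 350, elongation = 0.5))
}

small_scene <- function(seed = 1, h = 128, w = 128) {
  generate_scene(scene_spec(h, w, three_class_specs()), seed = seed)
}

random_tile <- function(seed, h = 16, w = 16, n_classes = 3) {
  set.seed(seed)
  list(image = array(runif(h * w * 3, 0, 255), c(h, w, 3)),
       mask = matrix(sample(0:(n_classes - 1), h * w, TRUE), h, w))
}

# nested-loop confusion matrix
oracle_cm <- function(truth, pred, n_classes) {
  cm <- matrix(0L, n_classes, n_classes)
  for (r in seq_len(nrow(truth)))
    for (c in seq_len(ncol(truth)))
      cm[truth[r, c] + 1L, pred[r, c] + 1L] <-
        cm[truth[r, c] + 1L, pred[r, c] + 1L] + 1L
  cm
}

# direct-formula metrics from a confusion matrix
oracle_metrics <- function(cm) {
  n <- nrow(cm)
  p <- r <- f1 <- iou <- numeric(n)
  include_iou <- logical(n)
  for (i in seq_len(n)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    p[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    r[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (p[i] + r[i] > 0) 2 * p[i] * r[i] / (p[i] + r[i]) else 0
    include_iou[i] <- tp + fp + fn > 0
    iou[i] <- if (include_iou[i]) tp / (tp + fp + fn) else NA_real_
  }
  total <- sum(cm)
  oa <- sum(diag(cm)) / total
  pe <- 0
  for (i in seq_len(n)) pe <- pe + sum(cm[i, ]) * sum(cm[, i]) / total^2
  list(precision = p, recall = r, f1 = f1, mean_f1 = mean(f1),
       oa = oa, kappa = (oa - pe) / (1 - pe),
       miou = mean(iou[include_iou]))
}

# BFS flood fill, independent of the C++ labeller
oracle_components <- function(mask, target, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  moves <- if (connectivity == 8)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  comp <- 0L
  for (sc in seq_len(W)) for (sr in seq_len(H)) {
    if (mask[sr, sc] != target || lab[sr, sc] != 0L) next
    comp <- comp + 1L
    queue <- list(c(sr, sc))
    lab[sr, sc] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(moves))) {
        rr <- cur[1] + moves[k, 1]; cc <- cur[2] + moves[k, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (mask[rr, cc] != target || lab[rr, cc] != 0L) next
        lab[rr, cc] <- comp
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  lab
}

# brute-force minimal enclosing circle over all pairs and triples
oracle_mec <- function(pts) {
  n <- nrow(pts)
  contains_all <- function(ctr, rad) {
    for (i in seq_len(n))
      if (sqrt(sum((pts[i, ] - ctr)^2)) > rad + 1e-9) return(FALSE)
    TRUE
  }
  best <- list(center = pts[1, ], radius = Inf)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ctr <- (pts[i, ] + pts[j, ]) / 2
    rad <- sqrt(sum((pts[i, ] - ctr)^2))
    if (rad < best$radius && contains_all(ctr, rad))
      best <- list(center = ctr, radius = rad)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j <= i || k <= j) next
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
    ctr <- c((a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) +
                c2 * (a[2] - b[2])) / d,
             (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) +
                c2 * (b[1] - a[1])) / d)
    rad <- sqrt(sum((a - ctr)^2))
    if (rad < best$radius && contains_all(ctr, rad))
      best <- list(center = ctr, radius = rad)
  }
  best
}

# make a patch object directly from a logical matrix (single class)
patch_from_logical <- function(m) {
  px <- which(m, arr.ind = TRUE)
  dimnames(px) <- NULL
  structure(list(class_id = 1L, pixels = px, area_px = nrow(px)),
            class = "patch")
}

# stub predictor: constant class
constant_predictor <- function(id)
  function(image, origin_row, origin_col)
    matrix(as.integer(id), nrow(image), ncol(image))
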