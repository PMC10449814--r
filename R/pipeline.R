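#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full experiment: scene
#' simulation, tiling, training sweep, inference and evaluation. Accepts the
#' same structure from a YAML file via [read_pipeline_config()]. Every default
#' matches the study protocol where one exists (tile sweep 256/512/1024, Adam
#' settings, epoch cap and patience, per-architecture weight exponents).
#'
#' @param scene list describing the scene template: `height_px`, `width_px`,
#'   `gsd_cm` and `classes` (a list of [class_spec()] argument lists).
#' @param n_train,n_validation,n_test scenes generated per role.
#' @param architectures architectures to sweep.
#' @param tile_sizes tile side lengths to sweep.
#' @param model extra [model_config()] arguments (depth, base_width, ...).
#' @param train extra [train_config()] arguments.
#' @param smoothing_span LOESS span for epoch selection.
#' @param out_dir run directory.
#' @param seed global seed; all per-scene and per-model seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scene, n_train = 2L, n_validation = 1L,
                            n_test = 1L,
                            architectures = "unet",
                            tile_sizes = c(256L, 512L, 1024L),
                            model = list(), train = list(),
                            smoothing_span = 0.3,
                            out_dir = tempfile("savannaseg_run_"),
                            seed = 1L) {
  if (length(architectures) < 1L || length(tile_sizes) < 1L)
    stop("sweep grids must be non-empty", call. = FALSE)
  if (n_train < 1L || n_validation < 1L || n_test < 1L)
    stop("each split role needs at least one scene", call. = FALSE)
  cfg <- structure(list(scene = scene, n_train = as.integer(n_train),
                        n_validation = as.integer(n_validation),
                        n_test = as.integer(n_test),
                        architectures = architectures,
                        tile_sizes = as.integer(tile_sizes),
                        model = model, train = train,
                        smoothing_span = smoothing_span,
                        out_dir = out_dir, seed = as.integer(seed)),
                   class = "pipeline_config")
  scene_spec_of(cfg)      # validates the scene template
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

scene_spec_of <- function(config) {
  sc <- config$scene
  classes <- lapply(sc$classes, function(cl) do.call(class_spec, cl))
  scene_spec(sc$height_px, sc$width_px, classes,
             gsd_cm = sc$gsd_cm %||% 1.2)
}

#' Shipped preset: three spectrally separable classes
#'
#' A small, well-separated configuration used for desk-scale end-to-end runs:
#' a dominant bare-ground background (70%) and two vegetation classes (18% and
#' 12%) with distinct base colours and texture scales, 192 px scenes, 64 px
#' tiles and a depth-2 U-Net with 8 base channels trained for up to 25 epochs
#' at learning rate 1e-3.
#'
#' @param out_dir run directory.
#' @param seed global seed.
#' @return a `pipeline_config`.
#' @export
preset_separable_config <- function(out_dir = tempfile("savannaseg_run_"),
                                    seed = 1L) {
  pipeline_config(
    scene = list(
      height_px = 192L, width_px = 192L, gsd_cm = 1.2,
      classes = list(
        list(class_id = 0L, name = "bare_ground", target_proportion = 0.70,
             base_color = c(150, 120, 90), texture_scale = 2,
             background = TRUE),
        list(class_id = 1L, name = "broadleaf", target_proportion = 0.18,
             base_color = c(40, 130, 45), texture_scale = 3,
             patch_area_mean = 500, elongation = 0.2),
        list(class_id = 2L, name = "fineleaf", target_proportion = 0.12,
             base_color = c(190, 180, 60), texture_scale = 7,
             patch_area_mean = 350, elongation = 0.5))),
    n_train = 2L, n_validation = 1L, n_test = 1L,
    architectures = "unet", tile_sizes = 64L,
    model = list(depth = 2L, base_width = 8L),
    train = list(max_epochs = 25L, patience = 40L, learning_rate = 1e-3,
                 batch_size = 2L),
    smoothing_span = 0.75,
    out_dir = out_dir, seed = seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

# landscape metrics pooled over several masks (patches never span scenes)
aggregate_landscape_metrics <- function(masks, class_table, gsd_cm,
                                        connectivity = 8,
                                        background_id = NULL) {
  per <- lapply(masks, class_landscape_metrics, class_table = class_table,
                gsd_cm = gsd_cm, connectivity = connectivity,
                background_id = background_id)
  out <- per[[1]]
  for (i in seq_len(nrow(out))) {
    n <- vapply(per, function(d) d$n_patches[i], integer(1))
    tot <- vapply(per, function(d) d$total_area_ha[i], numeric(1))
    comp <- vapply(per, function(d) d$mean_compactness[i], numeric(1))
    circ <- vapply(per, function(d) d$mean_circle_area_ha[i], numeric(1))
    out$n_patches[i] <- sum(n)
    out$total_area_ha[i] <- if (any(n > 0)) sum(tot, na.rm = TRUE) else NA
    out$mean_patch_area_ha[i] <- if (any(n > 0))
      sum(tot, na.rm = TRUE) / sum(n) else NA
    out$mean_compactness[i] <- if (any(n > 0))
      sum(comp * n, na.rm = TRUE) / sum(n) else NA
    out$mean_circle_area_ha[i] <- if (any(n > 0))
      sum(circ * n, na.rm = TRUE) / sum(n) else NA
  }
  out
}

#' Run the full experiment described by a configuration
#'
#' Simulates spatially disjoint train/validation/test scenes, tiles the
#' training scenes, derives class proportions and inverse-power weights, and
#' for every (architecture, tile size) cell trains a model, selects the best
#' epoch on the LOESS-smoothed validation curve, predicts the test scenes with
#' the 16-layer offset majority vote, and scores predictions with the full
#' metrics report plus per-class landscape metrics and F1-vs-metric
#' regressions. All artifacts are written under `config$out_dir` and listed in
#' a run manifest.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param verbose print per-epoch progress.
#' @return invisibly, a `pipeline_run`: `summary` data frame (one row per
#'   cell), `cells` (per-cell logs, models and reports), `scenes`, `split`,
#'   `config`, `dir`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  spec <- scene_spec_of(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  scenes <- stage("simulate", {
    roles <- c(rep("train", config$n_train),
               rep("validation", config$n_validation),
               rep("test", config$n_test))
    out <- lapply(seq_along(roles), function(i)
      generate_scene(spec, seed = seed * 1000L + i))
    names(out) <- sprintf("scene_%02d", seq_along(roles))
    attr(out, "roles") <- roles
    out
  })
  roles <- attr(scenes, "roles")
  split <- stage("split", spatial_split(
    names(scenes),
    list(train = names(scenes)[roles == "train"],
         validation = names(scenes)[roles == "validation"],
         test = names(scenes)[roles == "test"])))
  train_scenes <- scenes[roles == "train"]
  val_scenes <- scenes[roles == "validation"]
  test_scenes <- scenes[roles == "test"]
  class_table <- scenes[[1]]$class_table
  class_ids <- class_table$class_id
  bg_id <- class_ids[1]

  p <- stage("class-proportions", {
    counts <- Reduce(`+`, lapply(train_scenes, function(sc)
      empirical_class_proportions(sc$mask, class_table) *
        length(sc$mask)))
    counts / sum(counts)
  })

  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  cells <- list()
  summary_rows <- list()

  for (arch in config$architectures) {
    for (tsz in config$tile_sizes) {
      cell_name <- sprintf("%s_%d", arch, tsz)
      cell_dir <- file.path(config$out_dir, cell_name)
      dir.create(cell_dir, recursive = TRUE, showWarnings = FALSE)

      tiles <- stage("tile", {
        tl <- unlist(lapply(train_scenes, tile_scene, tile_size = tsz),
                     recursive = FALSE)
        if (length(tl) == 0L)
          stop("no training tiles at tile size ", tsz)
        tl
      })
      manifest <- stage("tile-manifest", {
        rows <- do.call(rbind, lapply(names(train_scenes), function(sid) {
          st <- tile_scene(scenes[[sid]], tsz)
          if (length(st) == 0L) return(NULL)
          data.frame(
            tile_id = sprintf("%s_r%d_c%d", sid,
                              vapply(st, `[[`, integer(1), "origin_row"),
                              vapply(st, `[[`, integer(1), "origin_col")),
            scene_id = sid,
            origin_row = vapply(st, `[[`, integer(1), "origin_row"),
            origin_col = vapply(st, `[[`, integer(1), "origin_col"),
            tile_size = tsz, role = "train", stringsAsFactors = FALSE)
        }))
        path <- file.path(cell_dir, "tile_manifest.csv")
        write.csv(rows, path, row.names = FALSE)
        note(path)
        rows
      })

      x_exp <- config$train$weight_exponent %||% default_weight_exponent(arch)
      weights <- compute_class_weights(p, x_exp)

      log <- stage("train", {
        mcfg <- do.call(model_config, c(list(architecture = arch,
                                             n_classes = length(class_ids)),
                                        config$model))
        model <- build_model(mcfg, seed = seed + 17L)
        targs <- config$train
        targs$weight_exponent <- NULL
        tcfg <- do.call(train_config,
                        c(list(tile_size = tsz, seed = seed), targs))
        train(model, tiles, val_scenes, weights, tcfg,
              class_ids = class_ids, verbose = verbose)
      })
      path <- file.path(cell_dir, "training_log.csv")
      write_training_log(log, path); note(path)

      best_epoch <- stage("select", {
        # LOESS smoothing needs a few epochs; short runs use the raw argmax
        if (nrow(log$history) >= 3L)
          select_best_epoch(log, smoothing_span = config$smoothing_span)
        else log$best_epoch
      })
      best_model <- model_at_epoch(log, best_epoch)

      eval_out <- stage("evaluate", {
        cm_total <- matrix(0L, length(class_ids), length(class_ids))
        for (si in seq_along(test_scenes)) {
          sc <- test_scenes[[si]]
          pred <- predict_scene(best_model, sc, tsz)
          pp <- file.path(cell_dir,
                          sprintf("prediction_%s.png",
                                  names(test_scenes)[si]))
          png::writePNG(pred / 255, pp); note(pp)
          cm_total <- cm_total + confusion_matrix(
            matrix(match(sc$mask, class_ids) - 1L, nrow(sc$mask)),
            matrix(match(pred, class_ids) - 1L, nrow(pred)),
            length(class_ids))
        }
        list(cm = cm_total, report = summary_metrics(cm_total))
      })
      path <- file.path(cell_dir, "metrics.csv")
      write_metrics_report(eval_out$report, path); note(path)

      landscape <- stage("class-metrics", aggregate_landscape_metrics(
        lapply(train_scenes, `[[`, "mask"), class_table, spec$gsd_cm,
        background_id = bg_id))
      path <- file.path(cell_dir, "landscape_metrics.csv")
      write.csv(landscape, path, row.names = FALSE); note(path)

      regression <- stage("regression", {
        veg <- landscape[!landscape$background &
                           is.finite(landscape$mean_patch_area_ha), ]
        f1 <- eval_out$report$per_class$f1[match(veg$class_id, class_ids)]
        metrics <- c(mean_patch_area = "mean_patch_area_ha",
                     class_area = "total_area_ha",
                     compactness = "mean_compactness")
        if (nrow(veg) < 3L) NULL else do.call(rbind, lapply(
          names(metrics), function(mn) {
            r <- tryCatch(f1_metric_regression(veg[[metrics[mn]]], f1),
                          error = function(e) NULL)
            if (is.null(r)) NULL else
              data.frame(metric = mn, slope = r$slope,
                         intercept = r$intercept, p_value = r$p_value,
                         df = r$df)
          }))
      })
      if (!is.null(regression)) {
        path <- file.path(cell_dir, "regression.csv")
        write.csv(regression, path, row.names = FALSE); note(path)
      }

      cells[[cell_name]] <- list(
        architecture = arch, tile_size = tsz, log = log,
        best_epoch = best_epoch, model = best_model, weights = weights,
        cm = eval_out$cm, report = eval_out$report, landscape = landscape,
        regression = regression, tile_manifest = manifest)
      summary_rows[[cell_name]] <- data.frame(
        architecture = arch, tile_size = tsz, best_epoch = best_epoch,
        epochs_run = nrow(log$history),
        mean_f1 = eval_out$report$mean_f1,
        overall_accuracy = eval_out$report$overall_accuracy,
        kappa = eval_out$report$kappa, miou = eval_out$report$miou)
    }
  }

  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  path <- file.path(config$out_dir, "summary.csv")
  write.csv(summary, path, row.names = FALSE); note(path)
  jsonlite::write_json(
    list(seed = seed, artifacts = basename_rel(artifacts, config$out_dir)),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)

  invisible(structure(list(summary = summary, cells = cells, scenes = scenes,
                           split = split, test_scenes = test_scenes,
                           config = config, dir = config$out_dir),
                      class = "pipeline_run"))
}

basename_rel <- function(paths, root)
  sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", root), "/?"), "",
      paths)

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$summary)
  invisible(x)
}

#' Evaluate temporal transfer under increasing appearance drift
#'
#' Re-evaluates a trained cell of a run on perturbed copies of the test
#' scenes, one rung per perturbation strength; strength 0 reuses the original
#' scenes, so its mean F1 equals the unperturbed test result exactly. A
#' monotone decay of mean F1 with strength mirrors the accuracy loss observed
#' when models are applied to imagery from a later phenological phase.
#'
#' @param run a `pipeline_run`.
#' @param strengths non-empty vector of perturbation strengths in `[0, 1]`.
#' @param cell cell name (default: first cell).
#' @param seed seed for the perturbation draws.
#' @return data frame (`strength`, `mean_f1`, `miou`).
#' @export
temporal_transfer_eval <- function(run, strengths, cell = NULL, seed = 1L) {
  if (length(strengths) == 0L)
    stop("empty perturbation ladder", call. = FALSE)
  cell <- cell %||% names(run$cells)[1]
  cl <- run$cells[[cell]]
  if (is.null(cl) || is.null(cl$model))
    stop("run has no trained model for cell '", cell, "'", call. = FALSE)
  class_ids <- run$scenes[[1]]$class_table$class_id
  rows <- lapply(strengths, function(s) {
    cm <- matrix(0L, length(class_ids), length(class_ids))
    for (i in seq_along(run$test_scenes)) {
      sc <- perturb_scene(run$test_scenes[[i]], s, seed + i)
      pred <- predict_scene(cl$model, sc, cl$tile_size)
      cm <- cm + confusion_matrix(
        matrix(match(sc$mask, class_ids) - 1L, nrow(sc$mask)),
        matrix(match(pred, class_ids) - 1L, nrow(pred)),
        length(class_ids))
    }
    rep <- summary_metrics(cm)
    data.frame(strength = s, mean_f1 = rep$mean_f1, miou = rep$miou)
  })
  do.call(rbind, rows)
}
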