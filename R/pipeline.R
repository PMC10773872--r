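#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end run: synthetic data
#' generation, preprocessing, the three model specifications, loss and
#' training settings, and ensemble evaluation.  Unknown keys are
#' rejected.  The defaults describe a desk-scale run that finishes in a
#' few minutes on one CPU.
#'
#' @param ... named overrides of the defaults, nested lists merged
#'   key-by-key (e.g. `training = list(epochs = 10)`).
#' @return A list with class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(data = list(n_train = 32), seed = 7)
#' cfg$data$n_train
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    data = list(n_train = 96, n_val = 24, n_test = 24, patch_size = 64,
                noise_sd = 8 / 255, n_slides = 2, slide_size = 256),
    preprocess = list(min_tissue_ratio = 0.2, require_tissue_class = TRUE,
                      ratio_on = "image"),
    model = list(depth = 3, base_filters = 8, use_bn = TRUE),
    loss = list(beta = 1, alpha = 0.25, gamma = 2, smooth = 1e-5,
                focal_multiplier = 1, class_weights = "auto"),
    training = list(learning_rate = 1e-4, epochs = 6, batch_size = 8,
                    lr_factor = 0.5, lr_patience = 5, min_lr = 1e-6),
    ensemble = list(grid_step = 0.2, k_repeats = 3, subsample = 0.7)
  )
  ov <- list(...)
  merge_into <- function(base, over, path = "") {
    for (nm in names(over)) {
      key <- if (path == "") nm else paste0(path, "$", nm)
      if (!nm %in% names(base)) stop("unknown config key: ", key)
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], over[[nm]], key)
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_into(defaults, ov), class = "pipeline_config")
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

.pipeline_families <- c("unet", "aunet", "arunet")

# deterministic toy slides for the map stage
.pipeline_slides <- function(config) {
  sz <- config$data$slide_size
  lapply(seq_len(config$data$n_slides), function(i) {
    generate_toy_slide(slide_layout(
      sz, sz,
      cores = list(
        list(center = c(0.32, 0.35) * sz, axes = c(0.26, 0.2) * sz,
             rotation = 0.4, labels = c("N", "GP3")),
        list(center = c(0.68, 0.66) * sz, axes = c(0.24, 0.18) * sz,
             rotation = -0.3, labels = c("N", "GP4"))),
      seed = config$seed + 1000 + i),
      noise_sd = config$data$noise_sd)
  })
}

.predict_manifest <- function(model, manifest, dir) {
  lapply(seq_len(nrow(manifest)), function(i) {
    predict_patch(model, read_image(file.path(dir, manifest$image_path[i])))
  })
}

#' Run the full segmentation pipeline
#'
#' Executes, in order, any subset of the stages `simulate` (synthetic
#' patch dataset), `train` (the three families), `evaluate`
#' (Jaccard/Dice/mean-IoU per model and split), `ensemble` (grid search
#' for WME weights on the validation split), `ttest` (paired
#' comparisons of the five methods over seeded evaluation repeats), and
#' `maps` (slide-level score maps and overlays for toy slides).  Later
#' stages read the artifacts of earlier ones from `out_dir`, so stages
#' can be re-run individually.  Every CSV artifact carries the config
#' hash that produced it.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param stages character vector of stages to run.
#' @param dry_run print the stage plan and write nothing.
#' @param verbose print stage progress.
#' @return Invisibly, a list of the key artifacts produced (paths and
#'   data frames).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "train", "evaluate",
                                    "ensemble", "ttest", "maps"),
                         dry_run = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, c("simulate", "train", "evaluate",
                                "ensemble", "ttest", "maps"),
                      several.ok = TRUE)
  if (dry_run) {
    cat("pipeline plan (dry run, nothing written):\n")
    for (s in stages) cat("  -", s, "\n")
    cat("out_dir:", out_dir, "\nconfig hash:", .config_hash(config), "\n")
    return(invisible(list(stages = stages)))
  }
  hash <- .config_hash(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  data_dir <- file.path(out_dir, "data")
  runs_dir <- file.path(out_dir, "runs")
  maps_dir <- file.path(out_dir, "maps")
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  out <- list(config_hash = hash)

  if ("simulate" %in% stages) {
    say("stage simulate")
    out$manifest <- generate_dataset(
      data_dir, config$data$n_train, config$data$n_val, config$data$n_test,
      size = config$data$patch_size, seed = config$seed,
      noise_sd = config$data$noise_sd)
  }

  manifest <- function() {
    p <- file.path(data_dir, "manifest.csv")
    if (!file.exists(p)) stop("no dataset at ", p, "; run stage 'simulate'")
    m <- read.csv(p, stringsAsFactors = FALSE)
    attr(m, "dir") <- data_dir
    m
  }

  if ("train" %in% stages) {
    man <- manifest()
    dir.create(runs_dir, recursive = TRUE, showWarnings = FALSE)
    tr <- man[man$split == "train", ]
    va <- man[man$split == "val", ]
    lcfg <- do.call(loss_config, c(
      config$loss[setdiff(names(config$loss), "class_weights")],
      list(class_weights = if (identical(config$loss$class_weights, "auto")) {
        compute_class_weights(lapply(
          file.path(data_dir, tr$mask_path), read_mask))
      } else {
        do.call(class_weights, as.list(config$loss$class_weights))
      })))
    tcfg <- do.call(training_config,
                    c(config$training, list(seed = config$seed)))
    for (fi in seq_along(.pipeline_families)) {
      fam <- .pipeline_families[fi]
      say("stage train: ", fam)
      spec <- model_spec(fam, depth = config$model$depth,
                         base_filters = config$model$base_filters,
                         input_size = config$data$patch_size,
                         seed = config$seed + fi,
                         use_bn = config$model$use_bn)
      tg <- make_generator(tr, data_dir, tcfg$batch_size, TRUE,
                           seed = config$seed + fi)
      vg <- make_generator(va, data_dir, tcfg$batch_size, FALSE,
                           seed = config$seed + fi)
      fit <- train_model(build_model(spec), tg, vg, tcfg, lcfg)
      save_checkpoint(fit$model, file.path(runs_dir, paste0(fam, ".rds")))
      h <- fit$history
      h$config_hash <- hash
      write.csv(h, file.path(runs_dir, paste0(fam, "_history.csv")),
                row.names = FALSE)
    }
  }

  models <- function() {
    ps <- file.path(runs_dir, paste0(.pipeline_families, ".rds"))
    if (!all(file.exists(ps))) stop("missing checkpoints under ", runs_dir,
                                    "; run stage 'train'")
    setNames(lapply(ps, load_checkpoint), .pipeline_families)
  }

  if ("evaluate" %in% stages) {
    say("stage evaluate")
    man <- manifest()
    mods <- models()
    rows <- list()
    for (fam in .pipeline_families) {
      for (sp in c("val", "test")) {
        ms <- man[man$split == sp, ]
        if (nrow(ms) == 0) next
        probs <- .predict_manifest(mods[[fam]], ms, data_dir)
        masks <- lapply(file.path(data_dir, ms$mask_path), read_mask)
        ev <- evaluate_fields(probs, masks)
        rows[[length(rows) + 1L]] <-
          data.frame(model = fam, set = sp, jaccard = ev$jaccard,
                     dice = ev$dice, mean_iou = ev$mean_iou,
                     iou_class0 = ev$iou_class0,
                     iou_class1 = ev$iou_class1, config_hash = hash)
      }
    }
    out$metrics <- do.call(rbind, rows)
    write.csv(out$metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
  }

  val_fields <- function(mods, man) {
    va <- man[man$split == "val", ]
    list(fields = lapply(mods, .predict_manifest, manifest = va,
                         dir = data_dir),
         masks = lapply(file.path(data_dir, va$mask_path), read_mask))
  }

  if ("ensemble" %in% stages) {
    say("stage ensemble")
    vf <- val_fields(models(), manifest())
    gs <- grid_search_weights(vf$fields, vf$masks,
                              step = config$ensemble$grid_step)
    gs$table$config_hash <- hash
    write.csv(gs$table, file.path(out_dir, "ensemble_grid.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(weights = gs$weights, score = gs$score, config_hash = hash),
      file.path(out_dir, "ensemble_weights.json"), auto_unbox = TRUE,
      digits = NA)
    out$ensemble <- gs[c("weights", "score")]
  }

  best_weights <- function() {
    p <- file.path(out_dir, "ensemble_weights.json")
    if (!file.exists(p)) stop("no ensemble weights at ", p,
                              "; run stage 'ensemble'")
    unlist(jsonlite::read_json(p, simplifyVector = TRUE)$weights)
  }

  if ("ttest" %in% stages) {
    say("stage ttest")
    vf <- val_fields(models(), manifest())
    w <- best_weights()
    n <- length(vf$masks)
    k <- config$ensemble$k_repeats
    method_fields <- c(vf$fields, list(
      ME = lapply(seq_len(n), function(i)
        ensemble_probs(lapply(vf$fields, `[[`, i))),
      WME = lapply(seq_len(n), function(i)
        weighted_ensemble_probs(lapply(vf$fields, `[[`, i), w))))
    scores <- sapply(method_fields, function(fl) {
      vapply(seq_len(k), function(r) {
        old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
        set.seed(config$seed + 100 + r)
        idx <- sort(sample.int(n, max(2, round(config$ensemble$subsample * n))))
        evaluate_fields(fl[idx], vf$masks[idx])$mean_iou
      }, numeric(1))
    })
    pairs <- utils::combn(colnames(scores), 2)
    tt <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- scores[, pairs[1, i]]; b <- scores[, pairs[2, i]]
      r <- tryCatch(paired_ttest(a, b), error = function(e) NULL)
      data.frame(method_a = pairs[1, i], method_b = pairs[2, i],
                 t_value = if (is.null(r)) NA_real_ else r$t_value,
                 p_value = if (is.null(r)) NA_real_ else r$p_value,
                 df = k - 1L, config_hash = hash)
    }))
    out$ttest <- tt
    write.csv(tt, file.path(out_dir, "ttest.csv"), row.names = FALSE)
  }

  if ("maps" %in% stages) {
    say("stage maps")
    dir.create(maps_dir, recursive = TRUE, showWarnings = FALSE)
    mods <- models()
    w <- best_weights()
    ps <- config$data$patch_size
    slides <- .pipeline_slides(config)
    for (si in seq_along(slides)) {
      sl <- slides[[si]]
      pairs <- extract_patches(sl$image, sl$labels, ps, slide_id =
                                 sprintf("toy%02d", si))
      kept <- filter_patches(pairs, config$preprocess$min_tissue_ratio,
                             config$preprocess$require_tissue_class,
                             config$preprocess$ratio_on)
      preds <- lapply(kept, function(p) {
        fl <- lapply(mods, predict_patch, image = p$image)
        list(grid_row = p$grid_row, grid_col = p$grid_col,
             prob = weighted_ensemble_probs(fl, w))
      })
      sm <- assemble_score_map(preds, dim(sl$labels), ps,
                               slide_id = sprintf("toy%02d", si))
      write_score_map(sm, file.path(maps_dir,
                                    sprintf("toy%02d_scores.png", si)))
      ov <- render_overlay(sl$image, sm)
      write_image(ov, file.path(maps_dir, sprintf("toy%02d_overlay.png", si)))
      out$maps <- c(out$maps, list(sm))
    }
  }

  say(sprintf("pipeline done in %.1f s",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out)
}
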