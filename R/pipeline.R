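# End-to-end drivers tying the modules together: dataset-level evaluation
# (zero-shot AUC + FROC), and the demo chain
# simulate -> pretrain -> finetune -> infer -> evaluate at the tiny preset.

#' Evaluate localization on a dataset
#'
#' Runs zero-shot inference for one finding over every image, builds the
#' FROC curve against the box annotations (Hungarian-matched, distance hit
#' criterion) and reports sensitivity at the requested average-FP levels
#' plus the global classification AUC.  Setting `map_type = "attention"`
#' evaluates the attention-map baseline through the identical FROC code
#' path.
#'
#' @param model A trained `pa_model`.
#' @param dataset A `pa_dataset`.
#' @param class_name Finding to query.
#' @param fp_levels Average-FP operating points to report.
#' @param connectivity Blob connectivity (4 or 8).
#' @param min_radius,scale Hit-criterion parameters, see [allowed_radius()].
#' @param map_type `"prediction"` (patchwise zero-shot maps) or
#'   `"attention"` (class-token attention baseline).
#' @return List with `auc`, `froc` (a `pa_froc` tibble), `sensitivity`
#'   (tibble of fp_level/sensitivity), `global_prob` and `maps`.
#' @export
evaluate_localization <- function(model, dataset, class_name,
                                  fp_levels = c(0.25, 0.5),
                                  connectivity = 4, min_radius = 1,
                                  scale = 1.0,
                                  map_type = c("prediction", "attention")) {
  map_type <- match.arg(map_type)
  imgs <- dataset$images
  grid <- model$config$grid
  labels <- dataset_labels(dataset, class_name)
  sc <- infer_scores(model, imgs, class_name,
                     want_maps = map_type == "prediction")
  maps <- if (map_type == "prediction") {
    sc$maps
  } else {
    lapply(imgs, function(im) {
      m <- attention_map(model, im, class_name)
      attr(m, "raw_attention") <- NULL
      m
    })
  }
  raw_side <- nrow(imgs[[1L]])
  ann <- dataset$annotations
  gts <- lapply(names(imgs), function(id) {
    b <- ann[ann$image_id == id & ann$class_name == class_name, , drop = FALSE]
    scale_boxes(b, raw_side, grid$image_side)
  })
  curve <- froc(maps, gts, grid, connectivity = connectivity,
                min_radius = min_radius, scale = scale)
  auc <- if (length(unique(labels)) == 2L) roc_auc(sc$global_prob, labels) else NA_real_
  sens <- tibble::tibble(
    fp_level = fp_levels,
    sensitivity = vapply(fp_levels, function(f) sensitivity_at_fp(curve, f),
                         numeric(1L)))
  list(auc = auc, froc = curve, sensitivity = sens,
       global_prob = sc$global_prob, maps = maps)
}

#' Run the end-to-end tiny-preset demo
#'
#' Chains the whole method at desk scale: generates a seeded synthetic
#' training and test set with one large-lesion class at prevalence 0.4,
#' pretrains with the global and linear-combination losses, finetunes with
#' all four losses, and evaluates patchwise zero-shot prediction maps with
#' the Hungarian-matched FROC.  Sample sizes default to 600 training and
#' 200 test images with 3 pretraining and 10 finetuning epochs.
#'
#' @param seed Integer seed driving every stochastic component.
#' @param dir Optional output directory for `summary.json`, the FROC CSV
#'   and the final checkpoint.
#' @param n_train,n_test Dataset sizes.
#' @param pretrain_epochs,finetune_epochs Epoch budgets for the two phases.
#' @param class_name Name of the planted finding class.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with `summary` (seed, sizes, test AUC,
#'   sensitivity at 0.25 and 0.5 avg FP), `fit_pretrain`, `fit_finetune`
#'   and `evaluation`.
#' @export
run_demo <- function(seed = 1L, dir = NULL, n_train = 600L, n_test = 200L,
                     pretrain_epochs = 3L, finetune_epochs = 10L,
                     class_name = "opacity", quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("simulating %d train / %d test images (seed %d)", n_train, n_test, seed)
  train_ds <- generate_dataset(synthetic_config(n_train, class_names = class_name,
                                                seed = seed))
  test_ds <- generate_dataset(synthetic_config(n_test, class_names = class_name,
                                               seed = seed + 1000L))
  model <- init_model(tiny_model_config(class_name), seed = seed)
  say("pretraining (%d epochs)", pretrain_epochs)
  pre <- fit(model, train_ds,
             train_config("pretrain", epochs = pretrain_epochs, seed = seed))
  say("finetuning on '%s' (%d epochs)", class_name, finetune_epochs)
  ft <- fit(pre$model, train_ds,
            train_config("finetune", epochs = finetune_epochs,
                         class_name = class_name, seed = seed))
  say("evaluating on the test set")
  ev <- evaluate_localization(ft$model, test_ds, class_name)
  summary <- list(seed = seed, n_train = n_train, n_test = n_test,
                  class_name = class_name,
                  test_auc = ev$auc,
                  sensitivity_at_0.25_fp = ev$sensitivity$sensitivity[1L],
                  sensitivity_at_0.5_fp = ev$sensitivity$sensitivity[2L])
  say("test AUC %.3f | sens@0.25FP %.3f | sens@0.5FP %.3f",
      summary$test_auc, summary$sensitivity_at_0.25_fp,
      summary$sensitivity_at_0.5_fp)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(tibble::as_tibble(ev$froc), file.path(dir, "froc.csv"))
    save_checkpoint(ft$model, file.path(dir, "model.rds"))
  }
  invisible(list(summary = summary, fit_pretrain = pre, fit_finetune = ft,
                 evaluation = ev))
}
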