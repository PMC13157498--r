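# Pretraining (global + linear-combination losses) and finetuning (all four
# losses) with SGD, the two-group learning-rate split (backbone vs new
# layers), Xavier-initialised heads, and imbalance-aware weighted sampling.

#' Training configuration
#'
#' @param phase `"pretrain"` (global + linear-combination losses on
#'   image/report pairs) or `"finetune"` (all four losses; requires
#'   `class_name` and box annotations).
#' @param epochs Number of passes over the training split.
#' @param batch_size Images per SGD step (>= 2 for the contrastive terms;
#'   the desk-scale default of 8 favours more SGD steps per epoch).
#' @param lr_backbone Learning rate for the image encoder, text encoder and
#'   downscaler (0.0001 by default).
#' @param lr_new_layers Learning rate for the FC heads and the combining
#'   transformer: P, S, F, M and the logit scale (0.01 by default).
#' @param momentum SGD momentum (0.9; set 0 for plain SGD).
#' @param weights A [loss_weights()]; equal weighting by default.
#' @param class_name Finding under supervision (finetune).
#' @param balance_sampling Draw training images with replacement, weighted
#'   by inverse class frequency, so batches are balanced in expectation
#'   (default `TRUE` for finetuning).
#' @param val_fraction Seeded held-out fraction used for per-epoch AUC and
#'   model selection.
#' @param coverage_threshold Patch-mask coverage threshold, see
#'   [bbox_to_patch_mask()].
#' @param seed Seed controlling the split, sampling, and any random patch
#'   selection.
#' @return An object of class `pa_train_config`.
#' @export
train_config <- function(phase = c("pretrain", "finetune"),
                         epochs = 3L,
                         batch_size = 8L,
                         lr_backbone = 1e-4,
                         lr_new_layers = 1e-2,
                         momentum = 0.9,
                         weights = loss_weights(),
                         class_name = NULL,
                         balance_sampling = NULL,
                         val_fraction = 0.2,
                         coverage_threshold = 0.10,
                         seed = 1L) {
  phase <- match.arg(phase)
  if (lr_backbone < 0 || lr_new_layers < 0) {
    stop("configuration error: learning rates must be non-negative", call. = FALSE)
  }
  if (phase == "finetune" && is.null(class_name)) {
    stop("configuration error: finetuning requires class_name", call. = FALSE)
  }
  if (is.null(balance_sampling)) balance_sampling <- phase == "finetune"
  structure(list(phase = phase, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_backbone = lr_backbone, lr_new_layers = lr_new_layers,
                 momentum = momentum, weights = weights,
                 class_name = class_name, balance_sampling = balance_sampling,
                 val_fraction = val_fraction,
                 coverage_threshold = coverage_threshold,
                 seed = as.integer(seed)),
            class = "pa_train_config")
}

#' Inverse-frequency sampling weights
#'
#' Weights proportional to the inverse class frequency, normalised to sum
#' to the dataset size, so a weighted draw yields an expected positive
#' fraction of one half per batch.
#'
#' @param labels Binary per-image labels.
#' @return Numeric weights, one per image.
#' @export
balanced_sample_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == n) {
    stop("sampling error: both classes must be present", call. = FALSE)
  }
  w <- ifelse(labels == 1L, n / (2 * n_pos), n / (2 * (n - n_pos)))
  w
}

# one SGD(+momentum) step over a nested parameter list; non-matrix entries
# (e.g. conv strides) pass through untouched
sgd_update <- function(p, g, v, lr, momentum) {
  if (is.matrix(p)) {
    if (is.null(v)) v <- p * 0
    v <- momentum * v + g
    return(list(p = p - lr * v, v = v))
  }
  if (is.list(p)) {
    if (is.null(v)) v <- vector("list", length(p))
    out <- p
    for (i in seq_along(p)) {
      r <- sgd_update(p[[i]], g[[i]], v[[i]], lr, momentum)
      out[[i]] <- r$p
      v[[i]] <- r$v
    }
    return(list(p = out, v = v))
  }
  list(p = p, v = NULL)
}

backbone_groups <- c("ds", "img", "txt")

# build the batch loss graph; returns the total node and component values
batch_loss_nodes <- function(mp, cfg, images, texts, phase, class_name, Gs,
                             flags, weights, reduce) {
  scale <- logit_scale_node(mp)
  img_nodes <- lapply(images, function(im) downscale_node(mp, cfg, im))
  enc <- encode_image_node(mp, cfg, img_nodes)
  gP <- project_P_node(mp, ag_rows(enc$tokens, enc$g_idx))
  uniq <- unique(texts)
  tP <- ag_rows(project_P_node(mp, encode_text_node(mp, cfg, uniq)),
                match(texts, uniq))
  l_global <- global_loss_node(gP, tP, scale)
  N <- enc$N
  patches <- ag_rows(enc$tokens, unlist(enc$p_idx))
  within <- lapply(seq_len(enc$B), function(i) ((i - 1L) * N + 1L):(i * N))
  l_lcl <- lcl_node(mp, patches, within, tP, scale)
  if (phase == "pretrain") {
    total <- ag_wsum(list(l_global, l_lcl), c(weights$gamma1, weights$gamma2))
    return(list(total = total,
                comps = c(l_global = ag_value(l_global)[1L],
                          l_lcl = ag_value(l_lcl)[1L])))
  }
  btS <- project_S_node(mp, encode_text_node(mp, cfg, c("No Finding", class_name)))
  pS <- project_S_node(mp, patches)
  logits <- ag_scale(ag_mm(pS, ag_t(btS)), scale)
  targ <- unlist(Gs) + 1L
  l_patch <- if (reduce == "mean") {
    ag_ce(logits, targ)
  } else {
    ag_scale_const(ag_ce(logits, targ, reduce = "sum"), 1 / enc$B)
  }
  pE <- ag_rows(mp$img$pos, 2L:(N + 1L))
  per_img <- lapply(seq_len(enc$B), function(i) {
    sel <- select_patch_indices(Gs[[i]])
    p_i <- ag_rows(enc$tokens, enc$p_idx[[i]])
    p_c <- attention_pool_node(mp, cfg, ag_rows(p_i, sel), ag_rows(pE, sel))
    lg <- ag_scale(ag_mm(project_S_node(mp, p_c), ag_t(btS)), scale)
    ag_ce(lg, as.integer(flags[i]) + 1L)
  })
  l_cp <- ag_wsum(per_img, rep(1 / enc$B, enc$B))
  total <- ag_wsum(list(l_global, l_lcl, l_patch, l_cp),
                   c(weights$lambda1, weights$lambda2, weights$lambda3,
                     weights$lambda4))
  list(total = total,
       comps = c(l_global = ag_value(l_global)[1L],
                 l_lcl = ag_value(l_lcl)[1L],
                 l_patch = ag_value(l_patch)[1L],
                 l_c_patch = ag_value(l_cp)[1L]))
}

#' @importFrom generics fit
#' @export
generics::fit

#' Train a model
#'
#' Runs the configured phase with SGD: at each step the batch loss graph is
#' built on the autodiff tape, backpropagated, and the two parameter groups
#' are updated at their respective learning rates.  A seeded validation
#' split is scored after every epoch with the zero-shot global
#' classification AUC; the returned checkpoint is the epoch with the
#' highest validation AUC.  Training aborts with a diagnostic naming the
#' offending loss component if any component becomes non-finite.
#'
#' @param object A `pa_model`.
#' @param dataset A `pa_dataset` with reports (pretrain) and annotations
#'   (finetune).
#' @param config A [train_config()].
#' @param ... Unused.
#' @return An object of class `pa_fit`: list with `model` (best-epoch
#'   weights, with normalisation statistics attached), `history` (tibble
#'   of per-epoch loss components and validation AUC), `best_epoch`,
#'   `config` and `eval_class`.
#' @method fit pa_model
#' @export
fit.pa_model <- function(object, dataset, config, ...) {
  model <- object
  stopifnot(inherits(dataset, "pa_dataset"), inherits(config, "pa_train_config"))
  cfg <- model$config
  n <- length(dataset$images)
  ids <- names(dataset$images)
  eval_class <- config$class_name
  if (is.null(eval_class)) {
    cls <- setdiff(unique(dataset$reports$text), "No Finding")
    eval_class <- cls[1L]
  }
  labels <- dataset_labels(dataset, eval_class)
  reduce <- cfg$patch_loss_reduce
  history <- list()
  best <- list(auc = -Inf, params = model$params, epoch = 0L)

  with_local_seed(config$seed, {
    val_idx <- sort(sample.int(n, max(1L, round(config$val_fraction * n))))
    train_idx <- setdiff(seq_len(n), val_idx)

    # per-image min-max, then train-split mean/SD standardisation
    mm <- lapply(dataset$images, normalize_image)
    mstats <- list(mean = mean(unlist(lapply(mm[train_idx], mean))),
                   sd = stats::sd(unlist(lapply(mm[train_idx], as.vector))))
    if (!is.finite(mstats$sd) || mstats$sd <= 0) mstats$sd <- 1
    model$norm <- mstats
    imgs <- lapply(mm, function(x) (x - mstats$mean) / mstats$sd)

    masks <- NULL
    if (config$phase == "finetune") {
      masks <- dataset_patch_masks(dataset, cfg$grid, config$class_name,
                                   config$coverage_threshold)
      # row-major patch order vectors
      masks <- lapply(masks, function(m) as.integer(as.vector(t(m$mask))))
    }
    samp_w <- if (config$balance_sampling) {
      balanced_sample_weights(labels[train_idx])
    } else NULL

    texts <- dataset$reports$text[match(ids, dataset$reports$image_id)]
    vel <- NULL
    for (epoch in seq_len(config$epochs)) {
      order_idx <- if (!is.null(samp_w)) {
        train_idx[sample.int(length(train_idx), length(train_idx),
                             replace = TRUE, prob = samp_w)]
      } else {
        train_idx[sample.int(length(train_idx))]
      }
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      comp_sums <- NULL
      nb <- 0L
      for (bidx in batches) {
        if (length(bidx) < 2L) next
        ag_reset()
        mp <- wrap_params(model$params)
        res <- batch_loss_nodes(
          mp, cfg,
          images = imgs[bidx],
          texts = texts[bidx],
          phase = config$phase,
          class_name = config$class_name,
          Gs = if (is.null(masks)) NULL else masks[bidx],
          flags = labels[bidx],
          weights = config$weights,
          reduce = reduce)
        if (any(!is.finite(res$comps))) {
          stop(sprintf("training aborted: non-finite loss component(s): %s",
                       paste(names(res$comps)[!is.finite(res$comps)],
                             collapse = ", ")), call. = FALSE)
        }
        ag_backward(res$total)
        grads <- collect_grads(mp)
        if (is.null(vel)) vel <- vector("list", length(model$params))
        names(vel) <- names(model$params)
        for (nm in names(model$params)) {
          lr <- if (nm %in% backbone_groups) config$lr_backbone else config$lr_new_layers
          r <- sgd_update(model$params[[nm]], grads[[nm]], vel[[nm]], lr,
                          config$momentum)
          model$params[[nm]] <- r$p
          vel[[nm]] <- r$v
        }
        comp_sums <- if (is.null(comp_sums)) res$comps else comp_sums + res$comps
        nb <- nb + 1L
      }
      comps <- comp_sums / max(nb, 1L)
      val_auc <- NA_real_
      vl <- labels[val_idx]
      if (length(unique(vl)) == 2L) {
        sc <- infer_scores(model, dataset$images[val_idx], eval_class,
                           want_maps = FALSE)
        val_auc <- roc_auc(sc$global_prob, vl)
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, !!!as.list(comps),
        total = sum(comps * unlist(config$weights)[seq_along(comps) +
                                                     if (config$phase == "finetune") 2L else 0L]),
        val_auc = val_auc)
      if (!is.na(val_auc) && val_auc > best$auc) {
        best <- list(auc = val_auc, params = model$params, epoch = epoch)
      }
    }
  })

  if (is.finite(best$auc)) {
    model$params <- best$params
  } else {
    best$epoch <- config$epochs
  }
  structure(list(model = model,
                 history = if (length(history)) dplyr::bind_rows(history) else
                   tibble::tibble(epoch = integer(), val_auc = numeric()),
                 best_epoch = best$epoch,
                 config = config,
                 eval_class = eval_class),
            class = "pa_fit")
}

#' @export
print.pa_fit <- function(x, ...) {
  cat(sprintf("<pa_fit %s: %d epoch(s), best epoch %d (val AUC %s)>\n",
              x$config$phase, nrow(x$history), x$best_epoch,
              if (nrow(x$history)) sprintf("%.3f", max(x$history$val_auc, na.rm = TRUE))
              else "NA"))
  invisible(x)
}
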