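# Zero-shot prompting.  At inference the patch embeddings are S-projected
# and correlated with the S-space embeddings of the "No Finding" and
# finding prompts; a softmax over the two scaled similarities gives the
# per-patch probability of the queried finding.  The global score uses the
# same prompt pair in the P-projected (shared) space.  The attention-map
# baseline extracts the last encoder layer's class-token attention and is
# fed to the identical FROC evaluator.

#' Normalise an image for the encoder
#'
#' Per-image min-max scaling to \[0, 1\] followed, when dataset statistics
#' are available (recorded on the model by [fit()]), by mean/SD
#' standardisation.
#'
#' @param img Intensity matrix.
#' @param norm `NULL` or a list with `mean` and `sd`.
#' @return Normalised matrix.
#' @export
normalize_image <- function(img, norm = NULL) {
  rng <- range(img)
  x <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  if (!is.null(norm)) x <- (x - norm$mean) / norm$sd
  x
}

softmax2_pos <- function(s0, s1) {
  m <- pmax(s0, s1)
  e0 <- exp(s0 - m); e1 <- exp(s1 - m)
  e1 / (e0 + e1)
}

# batched value-level forward: global probabilities and (optionally) patch
# probability grids for a list of raw images, against one finding prompt
infer_scores <- function(model, images, class_name, want_maps = TRUE,
                         chunk = 32L) {
  cfg <- model$config
  gs <- cfg$grid$grid_side
  n <- length(images)
  global_prob <- numeric(n)
  maps <- if (want_maps) vector("list", n) else NULL
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ic in idx_chunks) {
    ag_reset()
    mp <- wrap_params(model$params)
    scale <- ag_value(logit_scale_node(mp))[1L]
    txt <- encode_text_node(mp, cfg, c("No Finding", class_name))
    btP <- ag_value(project_P_node(mp, txt))
    btS <- ag_value(project_S_node(mp, txt))
    img_nodes <- lapply(images[ic], function(im)
      downscale_node(mp, cfg, normalize_image(im, model$norm)))
    enc <- encode_image_node(mp, cfg, img_nodes)
    tok <- ag_value(enc$tokens)
    gP <- ag_value(project_P_node(mp, ag_rows(enc$tokens, enc$g_idx)))
    for (b in seq_along(ic)) {
      i <- ic[b]
      global_prob[i] <- softmax2_pos(scale * sum(gP[b, ] * btP[1L, ]),
                                     scale * sum(gP[b, ] * btP[2L, ]))
      if (want_maps) {
        pS <- ag_value(project_S_node(mp, ag_rows(enc$tokens, enc$p_idx[[b]])))
        pr <- softmax2_pos(scale * (pS %*% btS[1L, ]),
                           scale * (pS %*% btS[2L, ]))
        maps[[i]] <- matrix(pr, gs, gs, byrow = TRUE)
      }
    }
  }
  list(global_prob = global_prob, maps = maps)
}

#' Patchwise zero-shot prediction map
#'
#' @param model A trained `pa_model`.
#' @param image Raw intensity matrix.
#' @param class_name Finding prompt (replaces "Finding"); must tokenize
#'   under the model vocabulary.
#' @return An object of class `pa_prediction_map`: list with `probs`
#'   (`grid_side` x `grid_side` matrix of per-patch finding probabilities),
#'   `global_prob` and `class_name`.
#' @export
patch_prediction_map <- function(model, image, class_name) {
  sc <- infer_scores(model, list(image), class_name, want_maps = TRUE)
  structure(list(probs = sc$maps[[1L]], global_prob = sc$global_prob[1L],
                 class_name = class_name),
            class = "pa_prediction_map")
}

#' @export
print.pa_prediction_map <- function(x, ...) {
  cat(sprintf("<pa_prediction_map '%s': global prob %.3f, max patch prob %.3f>\n",
              x$class_name, x$global_prob, max(x$probs)))
  invisible(x)
}

#' Operating threshold at a target true-positive rate
#'
#' The largest threshold whose TPR on the validation scores (predicting
#' positive when `score >= threshold`) reaches `target_tpr` (90% by
#' default).
#'
#' @param val_scores Numeric validation scores.
#' @param val_labels Binary labels.
#' @param target_tpr Required true-positive rate.
#' @return Threshold value; when even the minimum score cannot reach the
#'   target, the minimum score is returned with a warning.
#' @export
operating_threshold <- function(val_scores, val_labels, target_tpr = 0.90) {
  val_labels <- as.integer(val_labels)
  if (length(unique(val_labels)) < 2L) {
    stop("both classes must be present in the validation labels", call. = FALSE)
  }
  pos <- val_scores[val_labels == 1L]
  cand <- sort(unique(val_scores), decreasing = TRUE)
  for (t in cand) {
    if (mean(pos >= t) >= target_tpr) return(t)
  }
  warning("target TPR unreachable; returning the minimum score")
  min(val_scores)
}

#' Attention-map localization baseline
#'
#' Attention of the global (class) token to each patch token in the last
#' encoder layer, averaged over heads, reshaped to the patch grid and
#' min-max normalised.  This is the saliency baseline evaluated through the
#' identical FROC path as the prediction maps.  At tiny scale the map does
#' not condition on the text query; `class_name` is accepted for interface
#' parity.
#'
#' @param model A `pa_model`.
#' @param image Raw intensity matrix.
#' @param class_name Finding prompt (unused by the extraction itself).
#' @return `grid_side` x `grid_side` matrix in \[0, 1\]; the attribute
#'   `"raw_attention"` holds the per-head class-token attention rows
#'   (including the class-token column) before normalisation.
#' @export
attention_map <- function(model, image, class_name = NULL) {
  cfg <- model$config
  gs <- cfg$grid$grid_side
  ag_reset(record_attention = TRUE)
  mp <- wrap_params(model$params)
  img_node <- downscale_node(mp, cfg, normalize_image(image, model$norm))
  enc <- encode_image_node(mp, cfg, list(img_node), tag_prefix = "img")
  tag <- sprintf("img_b%d_s1", cfg$encoder_depth)
  As <- get(tag, envir = .tape$attn)
  rows <- do.call(rbind, lapply(As, function(A) A[1L, ]))   # heads x (N+1)
  avg <- colMeans(rows)[-1L]                                # drop class col
  m <- matrix(avg, gs, gs, byrow = TRUE)
  rng <- range(m)
  out <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  attr(out, "raw_attention") <- lapply(As, function(A) A[1L, ])
  out
}
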