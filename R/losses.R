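# The four loss terms and their weighted totals.
#
# L_global  - symmetric contrastive cross-entropy between projected global
#             image embeddings and projected text embeddings over a batch.
# L_lcl     - the same contrastive loss on the F-combined projected patch
#             embeddings (the linear combination loss).
# L_patch   - per-patch two-class cross-entropy aligning each S-projected
#             patch embedding with the "No Finding"/"Finding" text
#             embeddings according to the ground-truth mask G.
# L_c_patch - two-class cross-entropy on the attention-pooled, S-projected
#             combination of the in-mask patches (a random patch stands in
#             on no-finding images).
#
# One learnable logit scale (temperature) is shared by all four terms.
# The per-patch logit written in the method as a single cosine similarity is
# realised as the two-logit softmax over [bt0'', bt1''] with target G_n --
# the unique reading under which a cross-entropy over patch logits is
# well-defined; the same resolution applies to the pooled logit.

#' Loss weights
#'
#' @param gamma1,gamma2 Pretraining weights on L_global and L_lcl.
#' @param lambda1,lambda2,lambda3,lambda4 Finetuning weights on L_global,
#'   L_lcl, L_patch and L_c_patch.  All default to 1 (equal weighting).
#' @return An object of class `pa_loss_weights`.
#' @export
loss_weights <- function(gamma1 = 1, gamma2 = 1,
                         lambda1 = 1, lambda2 = 1, lambda3 = 1, lambda4 = 1) {
  w <- c(gamma1 = gamma1, gamma2 = gamma2, lambda1 = lambda1,
         lambda2 = lambda2, lambda3 = lambda3, lambda4 = lambda4)
  if (any(w < 0)) stop("configuration error: loss weights must be non-negative",
                       call. = FALSE)
  structure(as.list(w), class = "pa_loss_weights")
}

## ---- node-level builders (shared with the training loop) --------------

global_loss_node <- function(img, txt, scale) {
  B <- nrow(img$value)
  if (B < 2L || nrow(txt$value) != B) {
    stop("contract error: contrastive batch needs matched image/text rows with B >= 2",
         call. = FALSE)
  }
  logits <- ag_scale(ag_mm(img, ag_t(txt)), scale)
  l_i2t <- ag_ce(logits, seq_len(B))
  l_t2i <- ag_ce(ag_t(logits), seq_len(B))
  ag_scale_const(ag_add(l_i2t, l_t2i), 0.5)
}

# patches: (B*N) x d_enc node; p_idx: per-image row indices into `patches`
lcl_node <- function(mp, patches, p_idx, txt, scale) {
  pp <- project_P_node(mp, patches)
  comb <- ag_l2rows(ag_vcat(lapply(p_idx, function(idx)
    ag_mm(mp$F, ag_rows(pp, idx)))))
  global_loss_node(comb, txt, scale)
}

# p_dd: N x d unit-row node; btpair: 2 x d node (rows bt0'', bt1'')
patch_loss_node <- function(p_dd, btpair, G, scale, reduce = "mean") {
  if (length(G) != nrow(p_dd$value)) {
    stop("geometry error: mask length must equal the number of patches",
         call. = FALSE)
  }
  logits <- ag_scale(ag_mm(p_dd, ag_t(btpair)), scale)
  ag_ce(logits, as.integer(G) + 1L, reduce = reduce)
}

combined_patch_loss_node <- function(mp, cfg, p, pE, G, btpair, is_finding, scale) {
  sel <- select_patch_indices(G)
  p_c <- attention_pool_node(mp, cfg, ag_rows(p, sel), ag_rows(pE, sel))
  pc_dd <- project_S_node(mp, p_c)
  logits <- ag_scale(ag_mm(pc_dd, ag_t(btpair)), scale)
  ag_ce(logits, as.integer(is_finding) + 1L)
}

# indices of the G = 1 patches, order preserved; a single uniformly random
# patch on all-zero masks (the no-finding rule) -- uses the current RNG
# stream, so callers control determinism through their seed
select_patch_indices <- function(G) {
  idx <- which(as.integer(G) == 1L)
  if (length(idx) == 0L) idx <- sample.int(length(G), 1L)
  idx
}

## ---- exported value-level surface ------------------------------------

#' Global contrastive loss
#'
#' Symmetric CLIP-style loss: the mean of the image-to-text and
#' text-to-image cross-entropies over the temperature-scaled B x B cosine
#' similarity matrix of a batch of paired unit embeddings.
#'
#' @param image_embs,text_embs `B x d` matrices of unit rows, row i of each
#'   forming a positive pair (`B >= 2`).
#' @param logit_scale Positive temperature multiplying the similarities.
#' @return Non-negative scalar loss.
#' @export
global_contrastive_loss <- function(image_embs, text_embs, logit_scale) {
  ag_reset()
  ag_value(global_loss_node(ag_const(image_embs), ag_const(text_embs),
                            ag_const(matrix(logit_scale))))[1L]
}

#' Linear combination loss
#'
#' Projects each image's patch embeddings with the shared projection P,
#' combines them with the FC layer F, re-normalises, and applies the
#' global contrastive loss against the text embeddings.
#'
#' @param model A `pa_model`.
#' @param p_batch List of `N x d_enc` patch-embedding matrices, one per
#'   image.
#' @param text_embs `B x d_shared` matrix of unit text embeddings.
#' @param logit_scale Temperature; defaults to the model's.
#' @return Non-negative scalar loss.
#' @export
lcl_loss <- function(model, p_batch, text_embs, logit_scale = NULL) {
  if (is.null(logit_scale)) logit_scale <- logit_scale(model)
  N <- nrow(p_batch[[1L]])
  ag_reset()
  mp <- wrap_params(model$params)
  patches <- ag_const(do.call(rbind, p_batch))
  p_idx <- lapply(seq_along(p_batch), function(i) ((i - 1L) * N + 1L):(i * N))
  ag_value(lcl_node(mp, patches, p_idx, ag_const(text_embs),
                    ag_const(matrix(logit_scale))))[1L]
}

#' Patch loss
#'
#' For each patch, two-class logits are the scaled cosine similarities of
#' the S-projected patch embedding to the "No Finding" and "Finding" text
#' embeddings; the cross-entropy target is the mask entry G_n.  Reduced as
#' the mean over patches by default (grid-size invariant); `reduce = "sum"`
#' restores the literal per-patch summation.
#'
#' @param p_dd `N x d_shared` matrix of unit S-projected patch embeddings.
#' @param bt0_dd,bt1_dd Unit vectors: S-space embeddings of "No Finding"
#'   and of the finding prompt.
#' @param G Binary mask vector of length `N` (row-major grid order).
#' @param logit_scale Temperature.
#' @param reduce `"mean"` or `"sum"`.
#' @return Non-negative scalar loss.
#' @export
patch_loss <- function(p_dd, bt0_dd, bt1_dd, G, logit_scale,
                       reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  ag_reset()
  btpair <- ag_const(rbind(as.vector(bt0_dd), as.vector(bt1_dd)))
  ag_value(patch_loss_node(ag_const(p_dd), btpair, G,
                           ag_const(matrix(logit_scale)), reduce))[1L]
}

#' Select the in-mask patch embeddings
#'
#' Rows of `p` and `pE` where `G = 1`, order preserved.  On an all-zero
#' mask (a no-finding image) one uniformly random patch is returned; seed
#' the RNG for determinism.
#'
#' @param p,pE `N x d_enc` patch and positional embedding matrices.
#' @param G Binary mask vector of length `N`.
#' @return List with `p_S`, `pE_S` and the selected `indices`.
#' @export
select_patches <- function(p, pE, G) {
  idx <- select_patch_indices(G)
  list(p_S = p[idx, , drop = FALSE], pE_S = pE[idx, , drop = FALSE],
       indices = idx)
}

#' Combined patch loss
#'
#' Attention-pools the selected patches with M, projects the pooled
#' embedding with S, forms two-class logits against the prompt pair and
#' applies cross-entropy with target 1 for finding images and 0 for
#' no-finding images.
#'
#' @param model A `pa_model`.
#' @param p,pE `N x d_enc` patch and positional embeddings.
#' @param G Binary mask vector of length `N`.
#' @param bt0_dd,bt1_dd Unit S-space prompt embeddings.
#' @param is_finding Logical: does the image carry the finding?
#' @param logit_scale Temperature; defaults to the model's.
#' @return Non-negative scalar loss.
#' @export
combined_patch_loss <- function(model, p, pE, G, bt0_dd, bt1_dd, is_finding,
                                logit_scale = NULL) {
  if (is.null(logit_scale)) logit_scale <- logit_scale(model)
  ag_reset()
  mp <- wrap_params(model$params)
  btpair <- ag_const(rbind(as.vector(bt0_dd), as.vector(bt1_dd)))
  ag_value(combined_patch_loss_node(mp, model$config, ag_const(p), ag_const(pE),
                                    G, btpair, is_finding,
                                    ag_const(matrix(logit_scale))))[1L]
}

#' Weighted loss totals
#'
#' `total_pretrain_loss()` is `gamma1 * L_global + gamma2 * L_lcl`;
#' `total_finetune_loss()` is the lambda-weighted sum of all four terms.
#' With the default weights (all 1) both equal the plain sum.
#'
#' @param l_global,l_lcl,l_patch,l_c_patch Scalar loss components.
#' @param weights A [loss_weights()].
#' @return Scalar total loss.
#' @export
total_pretrain_loss <- function(l_global, l_lcl, weights = loss_weights()) {
  stopifnot(inherits(weights, "pa_loss_weights"))
  weights$gamma1 * l_global + weights$gamma2 * l_lcl
}

#' @rdname total_pretrain_loss
#' @export
total_finetune_loss <- function(l_global, l_lcl, l_patch, l_c_patch,
                                weights = loss_weights()) {
  stopifnot(inherits(weights, "pa_loss_weights"))
  weights$lambda1 * l_global + weights$lambda2 * l_lcl +
    weights$lambda3 * l_patch + weights$lambda4 * l_c_patch
}
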