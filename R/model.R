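# The network: learnable downscaler, patch-token image encoder, text
# encoder, shared projection P, secondary projection S, linear patch
# combiner F, and the attention-pooling combiner M.  One code path serves
# both the tiny desk-scale instance and the full-scale geometry presets;
# only the configuration differs.
#
# Forward passes come in two layers: `*_node()` functions build autodiff
# graphs on the tape (used by the losses and the training loop), and the
# exported functions wrap them, returning plain numeric results.

#' Model configuration
#'
#' @param grid A [grid_spec()] fixing encoder input and patch geometry.
#' @param d_enc Encoder width (patch/text token dimension).
#' @param d_shared Width of the joint vision-language space entered through
#'   the projections P and S.
#' @param encoder_depth,encoder_heads Image-encoder transformer depth and
#'   head count.
#' @param mlp_hidden Hidden width of the transformer MLPs (default
#'   `4 * d_enc`).
#' @param vocab Character vector of known lower-case word tokens for the
#'   text encoder (built from the class names via [build_vocab()]).
#' @param text_depth,text_heads Text-encoder depth and head count.
#' @param text_maxlen Maximum prompt length in word tokens.
#' @param combiner_depth,combiner_heads,combiner_hidden The attention-pooling
#'   combiner M: 2 layers and 4 heads by default, with hidden width 2048 at
#'   the full-scale input width of 1024.
#' @param logit_scale_init Initial value of the learnable log temperature
#'   shared by all similarity computations (`log(1/0.07)`, the CLIP
#'   convention).
#' @param downscaler_intermediate_side Side of the fixed bicubic
#'   intermediate preceding the learnable convolution stage (900 at full
#'   scale).
#' @param downscaler_strides Integer vector, one entry per 3x3 convolution
#'   block of the downscaler.
#' @param patch_loss_reduce `"mean"` (grid-size invariant, default) or
#'   `"sum"` (the literal per-patch summation) for the patch loss.
#' @return An object of class `pa_model_config`.
#' @export
model_config <- function(grid = grid_spec(64, 8),
                         d_enc = 64L,
                         d_shared = 32L,
                         encoder_depth = 2L,
                         encoder_heads = 2L,
                         mlp_hidden = 4L * d_enc,
                         vocab = build_vocab("opacity"),
                         text_depth = 2L,
                         text_heads = 2L,
                         text_maxlen = 8L,
                         combiner_depth = 2L,
                         combiner_heads = 4L,
                         combiner_hidden = 2L * d_enc,
                         logit_scale_init = log(1 / 0.07),
                         downscaler_intermediate_side = grid$image_side,
                         downscaler_strides = 1L,
                         patch_loss_reduce = c("mean", "sum")) {
  stopifnot(inherits(grid, "pa_grid"))
  dims <- c(d_enc, d_shared, encoder_depth, encoder_heads, mlp_hidden,
            text_depth, text_heads, text_maxlen, combiner_depth,
            combiner_heads, combiner_hidden)
  if (any(dims < 1)) stop("configuration error: all dimensions must be positive",
                          call. = FALSE)
  if (d_enc %% encoder_heads != 0L || d_enc %% text_heads != 0L ||
      d_enc %% combiner_heads != 0L) {
    stop("configuration error: d_enc must be divisible by every head count",
         call. = FALSE)
  }
  structure(list(grid = grid, d_enc = as.integer(d_enc),
                 d_shared = as.integer(d_shared),
                 encoder_depth = as.integer(encoder_depth),
                 encoder_heads = as.integer(encoder_heads),
                 mlp_hidden = as.integer(mlp_hidden),
                 vocab = vocab,
                 text_depth = as.integer(text_depth),
                 text_heads = as.integer(text_heads),
                 text_maxlen = as.integer(text_maxlen),
                 combiner_depth = as.integer(combiner_depth),
                 combiner_heads = as.integer(combiner_heads),
                 combiner_hidden = as.integer(combiner_hidden),
                 logit_scale_init = logit_scale_init,
                 downscaler_intermediate_side = as.integer(downscaler_intermediate_side),
                 downscaler_strides = as.integer(downscaler_strides),
                 patch_loss_reduce = match.arg(patch_loss_reduce)),
            class = "pa_model_config")
}

#' Word vocabulary for the text encoder
#'
#' Lower-cases and tokenizes the class names and adds the prompt words
#' `"no"` and `"finding"`.
#'
#' @param class_names Character vector of finding names.
#' @return Sorted character vector of unique word tokens.
#' @export
build_vocab <- function(class_names) {
  words <- unlist(lapply(c(class_names, "No Finding", "Finding"), split_words))
  sort(unique(words))
}

split_words <- function(s) {
  s <- tolower(gsub("[^a-z0-9 ]", " ", tolower(s)))
  w <- strsplit(trimws(s), "\\s+")[[1L]]
  w[nzchar(w)]
}

#' Preset configurations
#'
#' `tiny_model_config()` is the desk-scale instance (64-pixel input, 8-pixel
#' patches, width 64, 2-layer encoders) that trains end-to-end on one CPU.
#' `fullscale_model_config()` reproduces the patch-grid geometry of the standard
#' CLIP vision backbones at 224-pixel input: grids of 7 (ViT-B/32), 14
#' (ViT-B/16) or 16 (ViT-L/14) patches per side, with the 900-pixel bicubic
#' intermediate and stride-2 convolution blocks in front, combiner input
#' 1024 and hidden 2048.
#'
#' @param class_names Finding names the text encoder must know.
#' @param backbone One of `"vit-b32"`, `"vit-b16"`, `"vit-l14"`.
#' @return A `pa_model_config`.
#' @export
tiny_model_config <- function(class_names = "opacity") {
  model_config(grid = grid_spec(64, 8), d_enc = 64L, d_shared = 32L,
               encoder_depth = 2L, encoder_heads = 2L,
               vocab = build_vocab(class_names),
               combiner_heads = 4L, combiner_hidden = 128L,
               downscaler_intermediate_side = 64L, downscaler_strides = 1L)
}

#' @rdname tiny_model_config
#' @export
fullscale_model_config <- function(backbone = c("vit-l14", "vit-b16", "vit-b32"),
                               class_names = "opacity") {
  backbone <- match.arg(backbone)
  patch <- switch(backbone, "vit-l14" = 14L, "vit-b16" = 16L, "vit-b32" = 32L)
  d_enc <- switch(backbone, "vit-l14" = 1024L, "vit-b16" = 768L, "vit-b32" = 768L)
  model_config(grid = grid_spec(224, patch), d_enc = d_enc, d_shared = 512L,
               encoder_heads = 8L, vocab = build_vocab(class_names),
               combiner_heads = 4L, combiner_hidden = 2048L,
               downscaler_intermediate_side = 900L,
               downscaler_strides = c(2L, 2L))
}

## ---- parameter initialisation -----------------------------------------

xavier_uniform <- function(nr, nc) {
  b <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

randn <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_block <- function(d, hidden, xavier = FALSE) {
  w <- if (xavier) function(a, b) xavier_uniform(a, b) else function(a, b) randn(a, b)
  list(ln1_g = matrix(1, 1L, d), ln1_b = matrix(0, 1L, d),
       Wq = w(d, d), bq = matrix(0, 1L, d),
       Wk = w(d, d), bk = matrix(0, 1L, d),
       Wv = w(d, d), bv = matrix(0, 1L, d),
       Wo = w(d, d), bo = matrix(0, 1L, d),
       ln2_g = matrix(1, 1L, d), ln2_b = matrix(0, 1L, d),
       W1 = w(d, hidden), b1 = matrix(0, 1L, hidden),
       W2 = w(hidden, d), b2 = matrix(0, 1L, d))
}

#' Initialise a model
#'
#' Encoder weights are drawn from N(0, 0.02); the downscaler convolutions
#' start at the identity kernel so the optimisation begins from a faithful
#' resampling; the new heads (P, S, F and the combiner M) receive Xavier
#' uniform initialisation with no bias terms on their linear maps, via
#' [init_new_layers()].
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the draw.
#' @return An object of class `pa_model`: list with `config`, `params` and
#'   image normalisation statistics `norm` (populated by [fit()]).
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "pa_model_config"))
  g <- config$grid
  N <- g$grid_side^2
  d <- config$d_enc
  params <- with_local_seed(seed, {
    p <- list()
    p$ds <- lapply(config$downscaler_strides, function(s) {
      kern <- matrix(0, 3L, 3L)
      kern[2L, 2L] <- 1
      list(kern = kern, bias = matrix(0, 1L, 1L), stride = s)
    })
    p$img <- list(
      W_e = randn(g$patch_size^2, d), b_e = matrix(0, 1L, d),
      cls = randn(1L, d), pos = randn(N + 1L, d),
      blocks = lapply(seq_len(config$encoder_depth), function(i)
        init_block(d, config$mlp_hidden)),
      lnf_g = matrix(1, 1L, d), lnf_b = matrix(0, 1L, d))
    p$txt <- list(
      emb = randn(length(config$vocab), d),
      pos = randn(config$text_maxlen + 1L, d),
      cls = randn(1L, d),
      blocks = lapply(seq_len(config$text_depth), function(i)
        init_block(d, config$mlp_hidden)),
      lnf_g = matrix(1, 1L, d), lnf_b = matrix(0, 1L, d))
    p$logit_scale <- matrix(config$logit_scale_init, 1L, 1L)
    p
  })
  model <- structure(list(config = config, params = params, norm = NULL),
                     class = "pa_model")
  init_new_layers(model, seed = seed + 1L)
}

#' Re-initialise the new task heads
#'
#' Applies Xavier uniform initialisation, with no bias terms, to the shared
#' projection P, the secondary projection S, the patch-combining FC layer F
#' and the linear maps of the attention-pooling combiner M.  Two calls with
#' the same seed give identical weights.
#'
#' @param model A `pa_model`.
#' @param seed Integer seed.
#' @return The model with freshly initialised heads.
#' @export
init_new_layers <- function(model, seed = 1L) {
  cfg <- model$config
  N <- cfg$grid$grid_side^2
  model$params[c("P", "S", "F", "M")] <- with_local_seed(seed, {
    list(
      P = xavier_uniform(cfg$d_enc, cfg$d_shared),
      S = xavier_uniform(cfg$d_enc, cfg$d_shared),
      F = xavier_uniform(1L, N),
      M = list(cls = randn(1L, cfg$d_enc),
               blocks = lapply(seq_len(cfg$combiner_depth), function(i)
                 init_block(cfg$d_enc, cfg$combiner_hidden, xavier = TRUE)),
               lnf_g = matrix(1, 1L, cfg$d_enc),
               lnf_b = matrix(0, 1L, cfg$d_enc))
    )
  })
  model
}

#' @export
print.pa_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<pa_model %s d_enc=%d d=%d depth=%d heads=%d vocab=%d>\n",
              format(cfg$grid), cfg$d_enc, cfg$d_shared, cfg$encoder_depth,
              cfg$encoder_heads, length(cfg$vocab)))
  invisible(x)
}

# recursively wrap a nested parameter list as autodiff leaves
wrap_params <- function(p) {
  if (is.matrix(p)) return(ag_leaf(p))
  lapply(p, function(e) if (is.list(e) || is.matrix(e)) wrap_params(e) else e)
}

# recursively read accumulated gradients (zeros where a leaf was unused)
collect_grads <- function(w) {
  if (is.environment(w)) {
    g <- w$grad
    if (is.null(g)) g <- matrix(0, nrow(w$value), ncol(w$value))
    return(g)
  }
  lapply(w, function(e) if (is.list(e) || is.environment(e)) collect_grads(e) else e)
}

## ---- forward passes ---------------------------------------------------

# split an encoder-side image into row-major grid order patch vectors
patchify_mat <- function(img, patch) {
  side <- nrow(img)
  gs <- side %/% patch
  out <- matrix(0, gs * gs, patch * patch)
  n <- 0L
  for (gr in seq_len(gs)) {
    for (gc in seq_len(gs)) {
      n <- n + 1L
      out[n, ] <- as.vector(img[(gr - 1L) * patch + seq_len(patch),
                                (gc - 1L) * patch + seq_len(patch)])
    }
  }
  out
}

# pre-norm transformer over stacked token sequences; `ranges` lists the row
# indices of each sequence inside `x`
fwd_blocks <- function(x, blocks, heads, ranges, tag_prefix = NULL) {
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    h <- ag_layernorm(x, b$ln1_g, b$ln1_b)
    q <- ag_add_bias(ag_mm(h, b$Wq), b$bq)
    k <- ag_add_bias(ag_mm(h, b$Wk), b$bk)
    v <- ag_add_bias(ag_mm(h, b$Wv), b$bv)
    att <- if (length(ranges) == 1L) {
      ag_mha(q, k, v, heads, tag = if (is.null(tag_prefix)) NULL else
        sprintf("%s_b%d_s1", tag_prefix, bi))
    } else {
      ag_vcat(lapply(seq_along(ranges), function(si) {
        idx <- ranges[[si]]
        ag_mha(ag_rows(q, idx), ag_rows(k, idx), ag_rows(v, idx), heads,
               tag = if (is.null(tag_prefix)) NULL else
                 sprintf("%s_b%d_s%d", tag_prefix, bi, si))
      }))
    }
    x <- ag_add(x, ag_add_bias(ag_mm(att, b$Wo), b$bo))
    h2 <- ag_layernorm(x, b$ln2_g, b$ln2_b)
    m1 <- ag_gelu(ag_add_bias(ag_mm(h2, b$W1), b$b1))
    x <- ag_add(x, ag_add_bias(ag_mm(m1, b$W2), b$b2))
  }
  x
}

# learnable downscaler: fixed bicubic to the intermediate side, learnable
# convolution blocks, fixed bilinear landing exactly on the encoder side
downscale_node <- function(mp, cfg, raw_image) {
  if (!is.matrix(raw_image) || nrow(raw_image) == 0L || ncol(raw_image) == 0L) {
    stop("validation error: empty image", call. = FALSE)
  }
  inter <- cfg$downscaler_intermediate_side
  x_val <- if (nrow(raw_image) == inter && ncol(raw_image) == inter) {
    raw_image
  } else {
    resize_image(raw_image, inter, inter, "bicubic")
  }
  x <- ag_const(x_val)
  for (blk in mp$ds) {
    x <- ag_relu(ag_conv2d(x, blk$kern, blk$bias, stride = blk$stride))
  }
  side <- cfg$grid$image_side
  if (nrow(x$value) != side || ncol(x$value) != side) {
    x <- ag_resize(x, side, side, "bilinear")
  }
  x
}

# image encoder over a list of encoder-side images (node level); images may
# be plain matrices (treated as constants) or nodes (e.g. downscaler
# outputs, keeping the gradient path into the convolution stage).
# Returns the stacked final tokens plus index bookkeeping.
encode_image_node <- function(mp, cfg, images, use_pos = TRUE, tag_prefix = NULL) {
  g <- cfg$grid
  N <- g$grid_side^2
  B <- length(images)
  Xn <- lapply(images, function(im) {
    v <- if (is.environment(im)) im$value else im
    if (nrow(v) != g$image_side || ncol(v) != g$image_side) {
      stop("geometry error: encoder input must be image_side x image_side",
           call. = FALSE)
    }
    if (is.environment(im)) ag_patchify(im, g$patch_size)
    else ag_const(patchify_mat(im, g$patch_size))
  })
  X <- if (B == 1L) Xn[[1L]] else ag_vcat(Xn)
  E <- ag_add_bias(ag_mm(X, mp$img$W_e), mp$img$b_e)
  toks <- vector("list", B)
  for (i in seq_len(B)) {
    ti <- ag_vcat(list(mp$img$cls, ag_rows(E, ((i - 1L) * N + 1L):(i * N))))
    toks[[i]] <- if (use_pos) ag_add(ti, mp$img$pos) else ti
  }
  x <- ag_vcat(toks)
  Tlen <- N + 1L
  ranges <- lapply(seq_len(B), function(i) ((i - 1L) * Tlen + 1L):(i * Tlen))
  x <- fwd_blocks(x, mp$img$blocks, cfg$encoder_heads, ranges, tag_prefix)
  x <- ag_layernorm(x, mp$img$lnf_g, mp$img$lnf_b)
  g_idx <- vapply(ranges, function(r) r[1L], integer(1L))
  p_idx <- lapply(ranges, function(r) r[-1L])
  list(tokens = x, g_idx = g_idx, p_idx = p_idx, B = B, N = N)
}

#' Tokenize a text prompt
#'
#' @param prompt Non-empty prompt string.
#' @param config A `pa_model_config` supplying the vocabulary.
#' @return Integer vector of 1-based token ids.
#' @export
tokenize_prompt <- function(prompt, config) {
  if (!is.character(prompt) || length(prompt) != 1L || !nzchar(trimws(prompt))) {
    stop("tokenizer error: prompt must be a non-empty string", call. = FALSE)
  }
  w <- split_words(prompt)
  ids <- match(w, config$vocab)
  if (anyNA(ids)) {
    stop(sprintf("tokenizer error: unknown token(s): %s",
                 paste(w[is.na(ids)], collapse = ", ")), call. = FALSE)
  }
  if (length(ids) > config$text_maxlen) {
    stop("tokenizer error: prompt longer than text_maxlen", call. = FALSE)
  }
  ids
}

# text encoder (node level); returns an n_prompts x d_enc node of class
# token embeddings, one row per prompt
encode_text_node <- function(mp, cfg, prompts) {
  rows <- lapply(prompts, function(pr) {
    ids <- tokenize_prompt(pr, cfg)
    ti <- ag_vcat(list(mp$txt$cls, ag_rows(mp$txt$emb, ids)))
    x <- ag_add(ti, ag_rows(mp$txt$pos, seq_len(length(ids) + 1L)))
    x <- fwd_blocks(x, mp$txt$blocks, cfg$text_heads, list(seq_len(length(ids) + 1L)))
    x <- ag_layernorm(x, mp$txt$lnf_g, mp$txt$lnf_b)
    ag_rows(x, 1L)
  })
  ag_vcat(rows)
}

# attention-pooling combiner M (node level): tokens are the elementwise sum
# of selected patch and positional embeddings, a learnable class token is
# prepended, and the L2-normalised class-token output is returned (1 x d_enc)
attention_pool_node <- function(mp, cfg, p_S, pE_S) {
  if (nrow(p_S$value) == 0L) {
    stop("selection error: attention pooling needs at least one patch",
         call. = FALSE)
  }
  toks <- ag_add(p_S, pE_S)
  x <- ag_vcat(list(mp$M$cls, toks))
  x <- fwd_blocks(x, mp$M$blocks, cfg$combiner_heads,
                  list(seq_len(nrow(x$value))))
  x <- ag_layernorm(x, mp$M$lnf_g, mp$M$lnf_b)
  ag_l2rows(ag_rows(x, 1L))
}

# shared projection helpers (node level)
project_P_node <- function(mp, x) ag_l2rows(ag_mm(x, mp$P))
project_S_node <- function(mp, x) ag_l2rows(ag_mm(x, mp$S))

logit_scale_node <- function(mp) ag_exp_clamp(mp$logit_scale, lo = 1, hi = 100)

## ---- exported value-level surface ------------------------------------

#' Learnable downscaling of a raw image to encoder size
#'
#' Uniform bicubic resampling to the configured intermediate side, the
#' learnable convolution blocks (through which gradients flow during
#' training), and a fixed bilinear landing on exactly
#' `grid$image_side` pixels.
#'
#' @param model A `pa_model`.
#' @param raw_image Numeric intensity matrix.
#' @return `image_side` x `image_side` numeric matrix.
#' @export
downscale <- function(model, raw_image) {
  ag_reset()
  mp <- wrap_params(model$params)
  ag_value(downscale_node(mp, model$config, raw_image))
}

#' Encode an image into global and patch embeddings
#'
#' @param model A `pa_model`.
#' @param image Encoder-side intensity matrix (`image_side` pixels square).
#' @return List with `g` (global class-token embedding, length `d_enc`),
#'   `p` (`N x d_enc` patch embeddings in row-major grid order) and `pE`
#'   (the positional embedding table rows aligned to `p`).
#' @export
encode_image <- function(model, image) {
  ag_reset()
  mp <- wrap_params(model$params)
  enc <- encode_image_node(mp, model$config, list(image))
  tok <- ag_value(enc$tokens)
  list(g = tok[enc$g_idx[1L], ],
       p = tok[enc$p_idx[[1L]], , drop = FALSE],
       pE = model$params$img$pos[-1L, , drop = FALSE])
}

#' Encode a text prompt
#'
#' @param model A `pa_model`.
#' @param prompt Prompt string (a class name, `"Finding"` or `"No Finding"`).
#' @return Numeric vector of length `d_enc`.
#' @export
encode_text <- function(model, prompt) {
  ag_reset()
  mp <- wrap_params(model$params)
  as.vector(ag_value(encode_text_node(mp, model$config, prompt)))
}

#' Project embeddings into the joint shared space
#'
#' `project_shared()` applies the shared projection P (used for the global
#' image embedding and the text embedding alike), `project_patches_P()`
#' applies the same P weights to patch embeddings, and
#' `project_patches_S()` applies the independent secondary projection S.
#' All outputs are L2-normalised rows; all-zero inputs map to zero.
#'
#' @param model A `pa_model`.
#' @param x Numeric vector (length `d_enc`) or matrix (`n x d_enc`).
#' @return Matrix of unit rows in the `d_shared` space.
#' @export
project_shared <- function(model, x) {
  ag_reset()
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  ag_value(project_P_node(wrap_params(model$params), ag_const(x)))
}

#' @rdname project_shared
#' @export
project_patches_P <- function(model, x) project_shared(model, x)

#' @rdname project_shared
#' @export
project_patches_S <- function(model, x) {
  ag_reset()
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  ag_value(project_S_node(wrap_params(model$params), ag_const(x)))
}

#' Linearly combine projected patch embeddings
#'
#' One fully connected layer acting across the patch axis: the combined
#' embedding is the F-weighted sum of the `N` projected patch embeddings,
#' re-normalised to unit length.  F has no bias term.
#'
#' @param model A `pa_model`.
#' @param p_prime `N x d_shared` matrix of projected patch embeddings.
#' @return Unit-length numeric vector of length `d_shared`.
#' @export
linear_combine_F <- function(model, p_prime) {
  N <- model$config$grid$grid_side^2
  if (!is.matrix(p_prime) || nrow(p_prime) != N) {
    stop("geometry error: p_prime must have one row per patch", call. = FALSE)
  }
  ag_reset()
  mp <- wrap_params(model$params)
  as.vector(ag_value(ag_l2rows(ag_mm(mp$F, ag_const(p_prime)))))
}

#' Attention-pool selected patch embeddings
#'
#' Tokens are the elementwise sum of the selected patch embeddings and their
#' positional embeddings; a learnable class token is prepended; the
#' combiner transformer M is applied and the L2-normalised class-token
#' output returned.
#'
#' @param model A `pa_model`.
#' @param p_S,pE_S `k x d_enc` matrices of selected patch and positional
#'   embeddings (`k >= 1`).
#' @return Unit-length numeric vector of length `d_enc`.
#' @export
attention_pool_M <- function(model, p_S, pE_S) {
  ag_reset()
  mp <- wrap_params(model$params)
  as.vector(ag_value(attention_pool_node(mp, model$config,
                                         ag_const(p_S), ag_const(pE_S))))
}

#' Current logit scale (temperature)
#'
#' @param model A `pa_model`.
#' @return The exponentiated, clamped learnable temperature.
#' @export
logit_scale <- function(model) {
  min(max(exp(model$params$logit_scale[1L]), 1), 100)
}

#' Save / load a model checkpoint
#'
#' @param model A `pa_model` (optionally with fit metadata attached).
#' @param path Checkpoint file path.
#' @return `load_checkpoint()` returns the `pa_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "patchalign-checkpoint", version = 1L,
               config = model$config, params = model$params,
               norm = model$norm), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "patchalign-checkpoint")) {
    stop("not a patchalign checkpoint", call. = FALSE)
  }
  structure(list(config = ck$config, params = ck$params, norm = ck$norm),
            class = "pa_model")
}
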