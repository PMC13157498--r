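test_that("global contrastive loss hits its analytic limits", {
  B <- 4
  # orthonormal, perfectly aligned pairs; high temperature drives loss to 0
  I <- diag(B)
  expect_lt(global_contrastive_loss(I, I, 100), 1e-6)
  # all embeddings identical: uniform logits, ln B in each direction
  e <- matrix(rep(c(1, rep(0, 5)), B), B, byrow = TRUE)
  expect_equal(global_contrastive_loss(e, e, 10), log(B), tolerance = 1e-12)
  expect_error(global_contrastive_loss(I[1, , drop = FALSE], I[1, , drop = FALSE], 10),
               "contract error")
})

test_that("global contrastive loss matches the softmax-CE oracle on random batches", {
  set.seed(301)
  for (trial in 1:10) {
    B <- 3
    ie <- random_unit_rows(B, 4)
    te <- random_unit_rows(B, 4)
    s <- runif(1, 1, 30)
    expect_equal(global_contrastive_loss(ie, te, s), clip_loss_oracle(ie, te, s),
                 tolerance = 1e-6)
  }
})

test_that("the linear combination loss reduces to the global loss on degenerate F", {
  m <- make_tiny_model(seed = 11)
  B <- 4
  # identical patches per image + one-hot F -> the combined embedding equals
  # the (projected) patch embedding, so L_lcl equals L_global on those
  m$params$F[] <- 0
  m$params$F[1, 7] <- 1
  p_batch <- lapply(seq_len(B), function(i) {
    row <- rnorm(64)
    matrix(rep(row, 64), 64, byrow = TRUE)
  })
  te <- random_unit_rows(B, 32)
  g_embs <- do.call(rbind, lapply(p_batch, function(p) project_shared(m, p[1, ])))
  expect_equal(lcl_loss(m, p_batch, te, 12),
               global_contrastive_loss(g_embs, te, 12), tolerance = 1e-9)
  # uniform F on identical patches reduces identically
  m$params$F[] <- 1 / 64
  expect_equal(lcl_loss(m, p_batch, te, 12),
               global_contrastive_loss(g_embs, te, 12), tolerance = 1e-9)
})

test_that("the linear combination loss matches the composed closed-form oracle", {
  set.seed(302)
  m <- make_tiny_model(seed = 13)
  B <- 3
  p_batch <- lapply(seq_len(B), function(i) matrix(rnorm(64 * 64), 64))
  te <- random_unit_rows(B, 32)
  s <- 9
  comb <- do.call(rbind, lapply(p_batch, function(p) {
    pp <- unit_rows(p %*% m$params$P)
    v <- as.vector(m$params$F %*% pp)
    v / sqrt(sum(v^2))
  }))
  expect_equal(lcl_loss(m, p_batch, te, s), clip_loss_oracle(comb, te, s),
               tolerance = 1e-6)
})

test_that("patch loss hits its analytic limits", {
  d <- 16
  bt1 <- c(1, rep(0, d - 1))
  bt0 <- c(0, 1, rep(0, d - 2))
  N <- 6
  # every patch equals bt1 and is labelled 1: high scale -> 0
  p_all1 <- matrix(rep(bt1, N), N, byrow = TRUE)
  expect_lt(patch_loss(p_all1, bt0, bt1, rep(1, N), 1e3), 1e-6)
  # patches orthogonal to both prompts: exactly ln 2 per patch
  p_orth <- matrix(rep(c(0, 0, 1, rep(0, d - 3)), N), N, byrow = TRUE)
  expect_equal(patch_loss(p_orth, bt0, bt1, rep(1, N), 50), log(2), tolerance = 1e-12)
  expect_equal(patch_loss(p_orth, bt0, bt1, rep(0, N), 50, reduce = "sum"),
               N * log(2), tolerance = 1e-12)
  expect_error(patch_loss(p_orth, bt0, bt1, rep(1, N - 1), 10), "geometry error")
})

test_that("patch loss matches a per-patch softmax-CE oracle", {
  set.seed(303)
  for (trial in 1:5) {
    N <- 9; d <- 8
    p <- random_unit_rows(N, d)
    bt0 <- random_unit_rows(1, d)[1, ]
    bt1 <- random_unit_rows(1, d)[1, ]
    G <- rbinom(N, 1, 0.5)
    s <- runif(1, 2, 40)
    logits <- s * cbind(p %*% bt0, p %*% bt1)
    expect_equal(patch_loss(p, bt0, bt1, G, s), ce_oracle(logits, G + 1L),
                 tolerance = 1e-6)
  }
})

test_that("an all-zero mask is the label-flip of an all-one mask with prompts swapped", {
  set.seed(304)
  N <- 12; d <- 10
  p <- random_unit_rows(N, d)
  bt0 <- random_unit_rows(1, d)[1, ]
  bt1 <- random_unit_rows(1, d)[1, ]
  expect_equal(patch_loss(p, bt0, bt1, rep(0, N), 15),
               patch_loss(p, bt1, bt0, rep(1, N), 15), tolerance = 1e-12)
})

test_that("patch selection equals boolean indexing and is seeded when empty", {
  set.seed(305)
  p <- matrix(rnorm(20 * 4), 20)
  pE <- matrix(rnorm(20 * 4), 20)
  for (trial in 1:50) {
    G <- rbinom(20, 1, 0.4)
    sel <- select_patches(p, pE, G)
    expect_identical(sel$indices, which(G == 1L))
    expect_identical(sel$p_S, p[G == 1, , drop = FALSE])
    expect_identical(sel$pE_S, pE[G == 1, , drop = FALSE])
  }
  set.seed(42)
  a <- select_patches(p, pE, rep(0, 20))
  set.seed(42)
  b <- select_patches(p, pE, rep(0, 20))
  expect_identical(a$indices, b$indices)
  expect_length(a$indices, 1L)
})

test_that("combined patch loss matches the composed forward oracle", {
  set.seed(306)
  m <- make_tiny_model(seed = 17)
  N <- 64
  p <- matrix(rnorm(N * 64), N)
  pE <- matrix(rnorm(N * 64), N)
  bt0 <- random_unit_rows(1, 32)[1, ]
  bt1 <- random_unit_rows(1, 32)[1, ]
  G <- integer(N); G[c(3, 9, 10, 40)] <- 1L
  s <- 11
  # oracle: compose the exported building blocks directly
  pc <- attention_pool_M(m, p[G == 1, ], pE[G == 1, ])
  pc_dd <- as.vector(project_patches_S(m, pc))
  logits <- s * matrix(c(sum(pc_dd * bt0), sum(pc_dd * bt1)), 1)
  expect_equal(combined_patch_loss(m, p, pE, G, bt0, bt1, TRUE, s),
               ce_oracle(logits, 2L), tolerance = 1e-6)
  expect_equal(combined_patch_loss(m, p, pE, G, bt0, bt1, FALSE, s),
               ce_oracle(logits, 1L), tolerance = 1e-6)
})

test_that("combined patch loss hits its analytic limits", {
  set.seed(307)
  m <- make_tiny_model(seed = 19)
  N <- 64
  p <- matrix(rnorm(N * 64), N)
  pE <- matrix(rnorm(N * 64), N)
  G <- integer(N); G[5:12] <- 1L
  pc_dd <- as.vector(project_patches_S(m, attention_pool_M(m, p[G == 1, ], pE[G == 1, ])))
  # prompt equal to the pooled embedding, counter-prompt orthogonal: high scale -> 0
  bt1 <- pc_dd
  bt0 <- rnorm(32)
  bt0 <- bt0 - sum(bt0 * bt1) * bt1
  bt0 <- bt0 / sqrt(sum(bt0^2))
  expect_lt(combined_patch_loss(m, p, pE, G, bt0, bt1, TRUE, 1e3), 1e-6)
  # equidistant prompts: exactly ln 2
  expect_equal(combined_patch_loss(m, p, pE, G, bt1, bt1, TRUE, 30), log(2),
               tolerance = 1e-12)
})

test_that("weighted totals are linear and default to the plain sum", {
  expect_equal(total_pretrain_loss(1.5, 2.5), 4)
  expect_equal(total_finetune_loss(1, 2, 3, 4), 10)
  w <- loss_weights(lambda1 = 1, lambda2 = 0, lambda3 = 0, lambda4 = 0)
  expect_equal(total_finetune_loss(7, 2, 3, 4, w), 7)
  w2 <- loss_weights(gamma1 = 2, gamma2 = 2, lambda1 = 2, lambda2 = 2,
                     lambda3 = 2, lambda4 = 2)
  expect_equal(total_finetune_loss(1, 2, 3, 4, w2), 2 * total_finetune_loss(1, 2, 3, 4))
  expect_equal(total_pretrain_loss(1, 2, w2), 2 * total_pretrain_loss(1, 2))
  expect_error(loss_weights(lambda3 = -1), "configuration error")
})

test_that("every loss is non-negative and finite on random inputs", {
  set.seed(308)
  m <- make_tiny_model(seed = 23)
  for (trial in 1:5) {
    B <- 3
    ie <- random_unit_rows(B, 8); te <- random_unit_rows(B, 8)
    expect_gte(global_contrastive_loss(ie, te, 14), 0)
    p <- random_unit_rows(10, 6)
    l <- patch_loss(p, random_unit_rows(1, 6)[1, ], random_unit_rows(1, 6)[1, ],
                    rbinom(10, 1, 0.5), 14)
    expect_true(is.finite(l) && l >= 0)
  }
})

test_that("loss decreases over 50 optimisation steps on a fixed batch", {
  ds <- make_tiny_dataset(n = 16, seed = 31, prevalence = 0.5)
  m <- make_tiny_model(seed = 31)
  cfgm <- m$config
  imgs <- lapply(ds$images, normalize_image)
  masks <- dataset_patch_masks(ds, cfgm$grid, "opacity")
  Gs <- lapply(masks, function(x) as.integer(as.vector(t(x$mask))))
  flags <- dataset_labels(ds, "opacity")
  texts <- ds$reports$text
  vel <- NULL
  losses <- numeric(50)
  set.seed(31)
  for (step in 1:50) {
    patchalign:::ag_reset()
    mp <- patchalign:::wrap_params(m$params)
    res <- patchalign:::batch_loss_nodes(mp, cfgm, imgs, texts, "finetune",
                                         "opacity", Gs, flags, loss_weights(),
                                         "mean")
    losses[step] <- patchalign:::ag_value(res$total)[1]
    patchalign:::ag_backward(res$total)
    grads <- patchalign:::collect_grads(mp)
    if (is.null(vel)) { vel <- vector("list", length(m$params)); names(vel) <- names(m$params) }
    for (nm in names(m$params)) {
      lr <- if (nm %in% patchalign:::backbone_groups) 1e-4 else 1e-2
      r <- patchalign:::sgd_update(m$params[[nm]], grads[[nm]], vel[[nm]], lr, 0.9)
      m$params[[nm]] <- r$p
      vel[[nm]] <- r$v
    }
  }
  smooth <- stats::filter(losses, rep(1 / 5, 5), sides = 1)[5:50]
  drop <- smooth[1] - smooth[length(smooth)]
  expect_gt(drop, 0.5)                          # clearly decreasing overall
  # monotone up to momentum jitter: no smoothed uptick beyond 5% of the drop
  expect_lt(max(diff(smooth)), 0.05 * drop)
})

test_that("tape gradients of the full finetune loss match finite differences", {
  ds <- make_tiny_dataset(n = 4, seed = 37, prevalence = 0.5)
  m <- make_tiny_model(seed = 37)
  cfgm <- m$config
  # strictly positive inputs keep the downscaler ReLU away from its kink, so
  # central differences are valid for the convolution kernel probe too
  imgs <- lapply(ds$images, function(x) normalize_image(x) + 0.05)
  masks <- dataset_patch_masks(ds, cfgm$grid, "opacity")
  Gs <- lapply(masks, function(x) as.integer(as.vector(t(x$mask))))
  flags <- dataset_labels(ds, "opacity")
  texts <- ds$reports$text
  loss_for <- function(params) {
    set.seed(99)  # fix any random patch selection
    patchalign:::ag_reset()
    mp <- patchalign:::wrap_params(params)
    res <- patchalign:::batch_loss_nodes(mp, cfgm, imgs, texts, "finetune",
                                         "opacity", Gs, flags, loss_weights(),
                                         "mean")
    patchalign:::ag_value(res$total)[1]
  }
  set.seed(99)
  patchalign:::ag_reset()
  mp <- patchalign:::wrap_params(m$params)
  res <- patchalign:::batch_loss_nodes(mp, cfgm, imgs, texts, "finetune",
                                       "opacity", Gs, flags, loss_weights(),
                                       "mean")
  patchalign:::ag_backward(res$total)
  grads <- patchalign:::collect_grads(mp)

  probes <- list(list("P"), list("S"), list("F"), list("logit_scale"),
                 list("img", "W_e"), list("img", "pos"),
                 list("img", "blocks", 1L, "Wq"), list("img", "blocks", 2L, "W2"),
                 list("txt", "emb"), list("M", "cls"),
                 list("M", "blocks", 1L, "Wv"), list("ds", 1L, "kern"))
  set.seed(41)
  for (pr in probes) {
    mat <- purrr::pluck(m$params, !!!pr)
    g <- purrr::pluck(grads, !!!pr)
    idx <- sample(length(mat), min(3, length(mat)))
    fd <- num_grad_entries(function(x) {
      p2 <- m$params
      purrr::pluck(p2, !!!pr) <- x
      loss_for(p2)
    }, mat, idx)
    expect_lt(max(abs(g[idx] - fd)), 1e-4)
  }
})
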