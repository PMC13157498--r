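test_that("preset geometries reproduce the standard backbone grids", {
  expect_identical(fullscale_model_config("vit-l14")$grid$grid_side, 16L)
  expect_identical(fullscale_model_config("vit-b16")$grid$grid_side, 14L)
  expect_identical(fullscale_model_config("vit-b32")$grid$grid_side, 7L)
  cfg <- fullscale_model_config("vit-l14")
  expect_identical(cfg$combiner_depth, 2L)
  expect_identical(cfg$combiner_heads, 4L)
  expect_identical(cfg$combiner_hidden, 2048L)
  expect_identical(cfg$d_enc, 1024L)
  expect_identical(cfg$downscaler_intermediate_side, 900L)
  expect_identical(tiny_model_config()$grid$grid_side, 8L)
})

test_that("encoder emits one patch embedding per grid cell plus a global token", {
  m <- make_tiny_model()
  img <- matrix(runif(64 * 64), 64)
  enc <- encode_image(m, img)
  expect_length(enc$g, 64)
  expect_identical(dim(enc$p), c(64L, 64L))
  expect_identical(dim(enc$pE), c(64L, 64L))
  expect_error(encode_image(m, matrix(0, 32, 32)), "geometry error")
})

test_that("without positional embeddings the encoder is patch-permutation equivariant", {
  m <- make_tiny_model(seed = 5)
  m$params$img$pos[] <- 0
  img <- matrix(runif(64 * 64), 64)
  enc1 <- encode_image(m, img)
  # swap two patch blocks of the input (grid cells (1,1) and (3,4), row-major 1 and 20)
  img2 <- img
  img2[1:8, 1:8] <- img[17:24, 25:32]
  img2[17:24, 25:32] <- img[1:8, 1:8]
  enc2 <- encode_image(m, img2)
  perm <- seq_len(64)
  perm[c(1, 20)] <- c(20, 1)
  expect_lt(max(abs(enc2$p - enc1$p[perm, ])), 1e-8)
  expect_lt(max(abs(enc2$g - enc1$g)), 1e-8)
})

test_that("distinct prompts produce distinct embeddings; unknown tokens error", {
  m <- make_tiny_model()
  t1 <- encode_text(m, "opacity")
  t2 <- encode_text(m, "No Finding")
  expect_gt(max(abs(t1 - t2)), 1e-6)
  expect_error(encode_text(m, "pneumothorax"), "tokenizer error")
  expect_error(encode_text(m, "  "), "tokenizer error")
})

test_that("projections return unit rows, guard zeros, and preserve cosine under scaling", {
  m <- make_tiny_model(seed = 2)
  x <- matrix(rnorm(5 * 64), 5)
  for (proj in list(project_shared, project_patches_S)) {
    y <- proj(m, x)
    expect_equal(sqrt(rowSums(y^2)), rep(1, 5), tolerance = 1e-12)
  }
  expect_identical(project_shared(m, rep(0, 64)), matrix(0, 1, 32))
  # cosine similarity invariant to positive input scaling
  a <- rnorm(64); b <- rnorm(64)
  cosab <- function(s1, s2) {
    pa <- project_shared(m, s1 * a)
    pb <- project_shared(m, s2 * b)
    sum(pa * pb)
  }
  base <- cosab(1, 1)
  expect_equal(cosab(3, 1), base, tolerance = 1e-10)
  expect_equal(cosab(0.1, 7), base, tolerance = 1e-10)
})

test_that("P and S are distinct maps and P is shared between global and patch use", {
  m <- make_tiny_model(seed = 3)
  expect_gt(max(abs(m$params$P - m$params$S)), 1e-6)
  x <- matrix(rnorm(2 * 64), 2)
  expect_identical(project_shared(m, x), project_patches_P(m, x))
})

test_that("the linear combiner F reduces to mean and selection in closed form", {
  m <- make_tiny_model(seed = 4)
  p_prime <- unit_rows(matrix(rnorm(64 * 32), 64))
  m$params$F[] <- 1 / 64
  mu <- colMeans(p_prime)
  expect_equal(linear_combine_F(m, p_prime), mu / sqrt(sum(mu^2)), tolerance = 1e-12)
  m$params$F[] <- 0
  m$params$F[1, 17] <- 1
  expect_equal(linear_combine_F(m, p_prime), p_prime[17, ], tolerance = 1e-12)
  expect_error(linear_combine_F(m, p_prime[1:10, ]), "geometry error")
})

test_that("attention pooling returns a unit class-token embedding", {
  m <- make_tiny_model(seed = 6)
  k <- 5
  p_S <- matrix(rnorm(k * 64), k)
  pE_S <- matrix(rnorm(k * 64), k)
  pc <- attention_pool_M(m, p_S, pE_S)
  expect_equal(sqrt(sum(pc^2)), 1, tolerance = 1e-12)
  expect_error(attention_pool_M(m, p_S[0, , drop = FALSE], pE_S[0, , drop = FALSE]),
               "selection error")
})

test_that("attention pooling is invariant under joint row permutation", {
  m <- make_tiny_model(seed = 8)
  for (k in c(2, 7, 16)) {
    p_S <- matrix(rnorm(k * 64), k)
    pE_S <- matrix(rnorm(k * 64), k)
    perm <- sample(k)
    a <- attention_pool_M(m, p_S, pE_S)
    b <- attention_pool_M(m, p_S[perm, ], pE_S[perm, ])
    expect_lt(max(abs(a - b)), 1e-5)
  }
})

test_that("downscaling lands exactly on the encoder side for any larger input", {
  m <- make_tiny_model()
  for (side in c(64, 90, 128)) {
    out <- downscale(m, matrix(runif(side * side), side))
    expect_identical(dim(out), c(64L, 64L))
  }
  expect_error(downscale(m, matrix(numeric(0), 0, 0)), "validation error")
})

test_that("zeroed final convolution gives a constant bias output", {
  m <- make_tiny_model()
  m$params$ds[[1]]$kern[] <- 0
  m$params$ds[[1]]$bias[] <- 0.25
  out <- downscale(m, matrix(runif(64 * 64), 64))
  expect_equal(out, matrix(0.25, 64, 64), tolerance = 1e-12)
})

test_that("identity-initialised downscaler reproduces its input at native size", {
  m <- make_tiny_model()
  img <- matrix(runif(64 * 64), 64)
  expect_equal(downscale(m, img), img, tolerance = 1e-12)
})

test_that("bicubic resampling matches a direct kernel-evaluation oracle", {
  set.seed(31)
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(resize_image(ramp, 2, 2), bicubic_oracle(ramp, 2, 2),
               tolerance = 1e-5)
  x <- matrix(runif(81), 9, 9)
  expect_equal(resize_image(x, 5, 3), bicubic_oracle(x, 5, 3), tolerance = 1e-5)
  expect_equal(resize_image(x, 12, 12), bicubic_oracle(x, 12, 12), tolerance = 1e-5)
})

test_that("checkpoints round-trip bit-identically", {
  m <- make_tiny_model(seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
  expect_error(load_checkpoint({
    p2 <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(a = 1), p2)
    p2
  }), "not a patchalign checkpoint")
})

test_that("head initialisation is Xavier-bounded, bias-free and seed-reproducible", {
  m1 <- init_new_layers(make_tiny_model(), seed = 42)
  m2 <- init_new_layers(make_tiny_model(), seed = 42)
  expect_identical(m1$params$F, m2$params$F)
  expect_identical(m1$params$M, m2$params$M)
  # F: 1 x N, no bias term exists by construction
  bound_F <- sqrt(6 / (1 + 64))
  expect_true(all(abs(m1$params$F) <= bound_F))
  bound_P <- sqrt(6 / (64 + 32))
  expect_true(all(abs(m1$params$P) <= bound_P))
  expect_true(all(abs(m1$params$S) <= bound_P))
  # combiner linear maps are Xavier-bounded with zero biases
  blk <- m1$params$M$blocks[[1]]
  expect_true(all(abs(blk$Wq) <= sqrt(6 / (64 + 64))))
  expect_true(all(blk$bq == 0) && all(blk$b1 == 0))
})

test_that("the logit scale is the clamped exponential of its parameter", {
  m <- make_tiny_model()
  expect_equal(logit_scale(m), 1 / 0.07, tolerance = 1e-10)
  m$params$logit_scale[] <- 10
  expect_equal(logit_scale(m), 100)
  m$params$logit_scale[] <- -5
  expect_equal(logit_scale(m), 1)
})
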