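test_that("blob extraction handles empty and singleton grids", {
  expect_length(extract_blobs(matrix(0, 8, 8), 0.5), 0)
  probs <- matrix(0, 8, 8)
  probs[2, 3] <- 0.9
  dets <- extract_blobs(probs, 0.5)
  expect_length(dets, 1)
  expect_equal(dets[[1]]$center, c(2, 3))
  expect_equal(dets[[1]]$score, 0.9)
})

test_that("blob extraction equals a flood-fill oracle on random grids", {
  set.seed(811)
  canon <- function(blobs) {
    cells <- lapply(blobs, function(b) {
      m <- b$patches[order(b$patches[, 1], b$patches[, 2]), , drop = FALSE]
      paste(m[, 1], m[, 2], collapse = ";")
    })
    sort(unlist(cells))
  }
  for (trial in 1:60) {
    g <- matrix(runif(64), 8)
    thr <- runif(1, 0.2, 0.8)
    conn <- sample(c(4, 8), 1)
    got <- extract_blobs(g, thr, connectivity = conn)
    want <- flood_fill_oracle(g > thr, conn)
    expect_identical(length(got), length(want))
    expect_identical(canon(got),
                     sort(vapply(want, function(m)
                       paste(m[, 1], m[, 2], collapse = ";"), character(1))))
    for (b in got) {
      expect_equal(b$center, colMeans(b$patches))
      expect_equal(b$score, max(g[b$patches]))
    }
  }
})

test_that("matching respects the allowed radius in simple cases", {
  g <- grid_spec(64, 8)
  gt <- data.frame(x_min = 16, y_min = 16, x_max = 32, y_max = 32)
  # gt centre at patch coords (3.5, 3.5); detection inside one patch radius
  inside <- list(list(patches = matrix(c(4, 4), 1), center = c(4, 4), score = 0.9))
  m1 <- match_detections(inside, gt, g)
  expect_identical(c(m1$tp, m1$fp, m1$fn), c(1L, 0L, 0L))
  far <- list(list(patches = matrix(c(8, 8), 1), center = c(8, 8), score = 0.9))
  m2 <- match_detections(far, gt, g)
  expect_identical(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
  m3 <- match_detections(list(), gt, g)
  expect_identical(c(m3$tp, m3$fp, m3$fn), c(0L, 0L, 1L))
  m4 <- match_detections(inside, NULL, g)
  expect_identical(c(m4$tp, m4$fp, m4$fn), c(0L, 1L, 0L))
})

test_that("Hungarian TP counts equal exhaustive enumeration on random instances", {
  set.seed(812)
  g <- grid_spec(64, 8)
  for (trial in 1:150) {
    nd <- sample(0:4, 1)
    ng <- sample(0:4, 1)
    dets <- lapply(seq_len(nd), function(i) {
      ctr <- runif(2, 1, 8)
      list(patches = matrix(round(ctr), 1), center = ctr, score = runif(1))
    })
    gt <- if (ng > 0) {
      x0 <- runif(ng, 0, 40); y0 <- runif(ng, 0, 40)
      data.frame(x_min = x0, y_min = y0,
                 x_max = x0 + runif(ng, 4, 24), y_max = y0 + runif(ng, 4, 24))
    } else {
      data.frame(x_min = numeric(), y_min = numeric(),
                 x_max = numeric(), y_max = numeric())
    }
    got <- match_detections(dets, gt, g)
    if (nd > 0 && ng > 0) {
      ctrs <- do.call(rbind, lapply(dets, function(d) d$center))
      gr <- (gt$y_min + gt$y_max) / 2 / 8 + 0.5
      gc <- (gt$x_min + gt$x_max) / 2 / 8 + 0.5
      dist <- sqrt(outer(ctrs[, 1], gr, "-")^2 + outer(ctrs[, 2], gc, "-")^2)
      radii <- vapply(seq_len(ng), function(k) allowed_radius(gt[k, ], g),
                      numeric(1))
      allowed <- sweep(dist, 2, radii, "<=")
      expect_identical(got$tp, max_matching_oracle(allowed))
    } else {
      expect_identical(got$tp, 0L)
    }
    expect_identical(got$fp, nd - got$tp)
    expect_identical(got$fn, ng - got$tp)
    expect_lte(got$tp, min(nd, ng))
  }
})

test_that("an oracle predictor gives sensitivity 1 at zero average FP", {
  g <- grid_spec(64, 8)
  set.seed(813)
  maps <- list(); gts <- list()
  for (i in 1:3) {
    # one box aligned to whole patches so the mask centroid matches its centre
    r0 <- sample(1:4, 1); c0 <- sample(1:4, 1); w <- sample(2:3, 1)
    box <- data.frame(x_min = (c0 - 1) * 8, y_min = (r0 - 1) * 8,
                      x_max = (c0 - 1 + w) * 8, y_max = (r0 - 1 + w) * 8)
    maps[[i]] <- bbox_to_patch_mask(box, g)$mask * 1.0
    gts[[i]] <- box
  }
  curve <- froc(maps, gts, g)
  expect_equal(sensitivity_at_fp(curve, 0), 1)
  row <- curve[curve$threshold == 0.5, ]   # any threshold in (0,1)
  expect_equal(nrow(row), 0L)              # exact sweep only keeps observed values
  at <- curve[which(curve$threshold < 1)[1], ]
  expect_equal(at$sensitivity, 1)
  expect_equal(at$avg_fp, 0)
})

test_that("a flat sub-threshold grid yields no detections", {
  g <- grid_spec(64, 8)
  maps <- list(matrix(0.5, 8, 8))
  gts <- list(data.frame(x_min = 0, y_min = 0, x_max = 16, y_max = 16))
  st <- patchalign:::image_step_stats(maps[[1]], gts[[1]], g, 4, 1, 1)
  # only threshold 0.5 exists; at t >= 0.5 nothing is active
  curve <- froc(maps, gts, g, thresholds = 0.6)
  expect_equal(curve$sensitivity, 0)
  expect_equal(curve$avg_fp, 0)
})

test_that("a hand-built three-image toy reproduces its hand-computed curve", {
  g <- grid_spec(32, 8)   # 4 x 4 grid
  box_at <- function(r, c) data.frame(x_min = (c - 1) * 8, y_min = (r - 1) * 8,
                                      x_max = c * 8, y_max = r * 8)
  m1 <- matrix(0, 4, 4); m1[2, 2] <- 0.9                 # hit for gt at (2,2)
  m2 <- matrix(0, 4, 4); m2[1, 1] <- 0.8; m2[4, 4] <- 0.6  # hit + far FP
  m3 <- matrix(0, 4, 4); m3[3, 3] <- 0.4                 # FP only (no gt)
  maps <- list(m1, m2, m3)
  gts <- list(box_at(2, 2), box_at(1, 1), NULL)
  curve <- froc(maps, gts, g)
  # hand computation: thresholds 0.9, 0.8, 0.6, 0.4, 0
  # t=0.9: nothing active (strict >) -> sens 0, fp 0
  # t=0.8: m1 blob -> TP -> sens 1/2, fp 0
  # t=0.6: + m2 (1,1) TP -> sens 1, fp 0
  # t=0.4: + m2 (4,4) FP -> sens 1, fp 1/3
  # t=0:   + m3 (3,3) FP -> sens 1, fp 2/3
  expect_equal(curve$threshold, c(0.9, 0.8, 0.6, 0.4, 0))
  expect_equal(curve$sensitivity, c(0, 0.5, 1, 1, 1))
  expect_equal(curve$avg_fp, c(0, 0, 0, 1 / 3, 2 / 3))
  expect_equal(sensitivity_at_fp(curve, 0.25), 1)
  expect_equal(sensitivity_at_fp(curve, 0.5), 1)
})

test_that("FROC curves are monotone in both coordinates on random maps", {
  set.seed(814)
  g <- grid_spec(64, 8)
  maps <- lapply(1:6, function(i) matrix(runif(64), 8))
  gts <- lapply(1:6, function(i) {
    if (i %% 2 == 0) return(NULL)
    x0 <- sample(0:40, 1); y0 <- sample(0:40, 1)
    data.frame(x_min = x0, y_min = y0, x_max = x0 + 16, y_max = y0 + 16)
  })
  curve <- froc(maps, gts, g)
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$avg_fp) >= 0))
  expect_true(all(curve$sensitivity >= 0 & curve$sensitivity <= 1))
  expect_true(all(diff(curve$threshold) < 0))
})

test_that("sensitivity at fixed FP is the max under the constraint", {
  curve <- structure(tibble::tibble(threshold = 1, sensitivity = 1, avg_fp = 0),
                     class = c("pa_froc", "tbl_df", "tbl", "data.frame"))
  expect_equal(sensitivity_at_fp(curve, 0.25), 1)
  curve2 <- structure(tibble::tibble(threshold = 0.5, sensitivity = 0.8, avg_fp = 2),
                      class = c("pa_froc", "tbl_df", "tbl", "data.frame"))
  expect_equal(sensitivity_at_fp(curve2, 0.5), 0)
  expect_error(sensitivity_at_fp(curve, -1), "non-negative")
  set.seed(815)
  for (trial in 1:20) {
    n <- 10
    cv <- structure(tibble::tibble(threshold = seq(1, 0, length.out = n),
                                   sensitivity = cummax(runif(n)),
                                   avg_fp = cummax(runif(n, 0, 3))),
                    class = c("pa_froc", "tbl_df", "tbl", "data.frame"))
    lvl <- runif(1, 0, 3)
    want <- if (any(cv$avg_fp <= lvl)) max(cv$sensitivity[cv$avg_fp <= lvl]) else 0
    expect_equal(sensitivity_at_fp(cv, lvl), want)
  }
})

test_that("rank AUC matches the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(roc_auc(runif(5), rep(1, 5)), "undefined-AUC")
  set.seed(816)
  for (trial in 1:200) {
    n <- sample(6:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(1:3, 1))   # induce ties
    expect_equal(roc_auc(scores, labels), auc_pairwise_oracle(scores, labels),
                 tolerance = 1e-10)
  }
})
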