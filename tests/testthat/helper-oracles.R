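# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (loops, enumeration, direct formulas) kept separate from
# the package code paths it checks.

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

random_unit_rows <- function(nr, nc) unit_rows(matrix(rnorm(nr * nc), nr, nc))

# direct softmax cross-entropy, one row per sample
ce_oracle <- function(logits, targets, reduce = "mean") {
  nll <- vapply(seq_len(nrow(logits)), function(i) {
    z <- logits[i, ]
    z <- z - max(z)
    -log(exp(z[targets[i]]) / sum(exp(z)))
  }, numeric(1L))
  if (reduce == "mean") mean(nll) else sum(nll)
}

# symmetric contrastive loss oracle on unit embeddings
clip_loss_oracle <- function(ie, te, scale) {
  L <- scale * (ie %*% t(te))
  B <- nrow(L)
  (ce_oracle(L, seq_len(B)) + ce_oracle(t(L), seq_len(B))) / 2
}

# 1-pixel rasterization mask oracle (integer boxes only): count covered
# pixels per patch, threshold strictly
mask_pixel_oracle <- function(boxes, grid, threshold = 0.10) {
  side <- grid$image_side
  p <- grid$patch_size
  gs <- grid$grid_side
  cov <- matrix(FALSE, side, side)  # [y + 1, x + 1]
  if (nrow(boxes) > 0L) {
    for (i in seq_len(nrow(boxes))) {
      ys <- (boxes$y_min[i] + 1):boxes$y_max[i]
      xs <- (boxes$x_min[i] + 1):boxes$x_max[i]
      cov[ys, xs] <- TRUE
    }
  }
  mask <- matrix(0L, gs, gs)
  for (gr in seq_len(gs)) {
    for (gc in seq_len(gs)) {
      cnt <- sum(cov[(gr - 1L) * p + seq_len(p), (gc - 1L) * p + seq_len(p)])
      if (cnt > threshold * p^2) mask[gr, gc] <- 1L
    }
  }
  mask
}

# recursive flood fill: list of connected components, each a sorted
# (row, col) matrix
flood_fill_oracle <- function(act, connectivity = 4) {
  nr <- nrow(act); nc <- ncol(act)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- as.matrix(expand.grid(-1:1, -1:1))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  }
  comps <- list()
  grow <- function(r, c) {
    cells <- matrix(c(r, c), 1)
    seen[r, c] <<- TRUE
    for (k in seq_len(nrow(nb))) {
      rr <- r + nb[k, 1]; cc <- c + nb[k, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          act[rr, cc] && !seen[rr, cc]) {
        cells <- rbind(cells, grow(rr, cc))
      }
    }
    cells
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (act[r, c] && !seen[r, c]) {
        cells <- grow(r, c)
        comps[[length(comps) + 1L]] <- cells[order(cells[, 1], cells[, 2]), ,
                                             drop = FALSE]
      }
    }
  }
  comps
}

# maximum bipartite matching size by exhaustive recursion (allowed: logical
# detections x ground-truth matrix)
max_matching_oracle <- function(allowed) {
  nd <- nrow(allowed); ng <- ncol(allowed)
  if (nd == 0L || ng == 0L) return(0L)
  best <- 0L
  rec <- function(d, used, count) {
    if (count + (nd - d + 1L) <= best) return()
    if (d > nd) {
      best <<- max(best, count)
      return()
    }
    rec(d + 1L, used, count)
    for (g in which(allowed[d, ] & !used)) {
      used[g] <- TRUE
      rec(d + 1L, used, count + 1L)
      used[g] <- FALSE
    }
  }
  rec(1L, rep(FALSE, ng), 0L)
  best
}

# pairwise-comparison AUC with half credit for ties
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# naive separable Keys bicubic resampling (independent double loop)
bicubic_oracle <- function(img, h, w) {
  keys <- function(t) {
    a <- -0.5
    at <- abs(t)
    if (at <= 1) (a + 2) * at^3 - (a + 3) * at^2 + 1
    else if (at < 2) a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a
    else 0
  }
  line <- function(v, n_out) {
    n_in <- length(v)
    out <- numeric(n_out)
    for (o in seq_len(n_out)) {
      s <- (o - 0.5) * n_in / n_out - 0.5
      i0 <- floor(s)
      acc <- 0
      for (t in -1:2) {
        idx <- min(max(i0 + t, 0), n_in - 1) + 1
        acc <- acc + keys(s - (i0 + t)) * v[idx]
      }
      out[o] <- acc
    }
    out
  }
  tmp <- apply(img, 2, line, n_out = h)          # rows
  if (h == 1) tmp <- matrix(tmp, 1)
  out <- t(apply(tmp, 1, line, n_out = w))       # cols
  if (w == 1) out <- t(out)
  out
}

# central finite differences of f at x (matrix), entrywise over idx
num_grad_entries <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1L))
}

# quick fixture dataset shared by model/loss/train tests
make_tiny_dataset <- function(n = 40, seed = 7, classes = "opacity",
                              prevalence = 0.4) {
  generate_dataset(synthetic_config(n, class_names = classes,
                                    prevalence = prevalence, seed = seed))
}

make_tiny_model <- function(seed = 1, classes = "opacity") {
  init_model(tiny_model_config(classes), seed = seed)
}
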