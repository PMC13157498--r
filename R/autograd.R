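# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a node: an environment holding a numeric
# matrix `value`, an accumulated `grad`, its `parents` and a `backfn` mapping
# the output gradient to per-parent gradients.  Nodes are appended to a
# package-level tape in creation order; `ag_backward()` walks the tape in
# reverse.  Scalars are 1x1 matrices.  The op set is exactly what the tiny
# transformer stack needs; fused ops (layer norm, multi-head attention,
# softmax cross-entropy, convolution) carry hand-derived backward passes to
# keep the tape short.

.tape <- new.env(parent = emptyenv())
.tape$nodes <- vector("list", 0L)
.tape$k <- 0L
.tape$attn <- NULL

#' @noRd
ag_reset <- function(record_attention = FALSE) {
  .tape$nodes <- vector("list", 2048L)
  .tape$k <- 0L
  .tape$attn <- if (record_attention) new.env(parent = emptyenv()) else NULL
  invisible(NULL)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

new_node <- function(value, parents = list(), backfn = NULL, const = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$const <- const
  k <- .tape$k + 1L
  if (k > length(.tape$nodes)) {
    .tape$nodes <- c(.tape$nodes, vector("list", max(2048L, length(.tape$nodes))))
  }
  .tape$nodes[[k]] <- nd
  .tape$k <- k
  nd$id <- k
  nd
}

#' @noRd
ag_leaf <- function(value) new_node(as_mat(value))

#' @noRd
ag_const <- function(value) new_node(as_mat(value), const = TRUE)

#' @noRd
ag_value <- function(node) node$value

#' @noRd
ag_backward <- function(node) {
  node$grad <- matrix(1, nrow(node$value), ncol(node$value))
  for (i in seq.int(node$id, 1L)) {
    nd <- .tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      pj <- ps[[j]]
      gj <- gs[[j]]
      if (is.null(gj) || pj$const) next
      pj$grad <- if (is.null(pj$grad)) gj else pj$grad + gj
    }
  }
  invisible(NULL)
}

## ---- elementary ops ---------------------------------------------------

ag_mm <- function(a, b) {
  new_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

ag_t <- function(a) new_node(t(a$value), list(a), function(g) list(t(g)))

ag_add <- function(a, b) new_node(a$value + b$value, list(a, b), function(g) list(g, g))

ag_sub <- function(a, b) new_node(a$value - b$value, list(a, b), function(g) list(g, -g))

# b is a 1 x d bias row broadcast over the rows of a
ag_add_bias <- function(a, b) {
  nr <- nrow(a$value)
  v <- a$value + rep(as.vector(b$value), each = nr)
  new_node(v, list(a, b), function(g) list(g, matrix(colSums(g), 1L)))
}

ag_emul <- function(a, b) {
  new_node(a$value * b$value, list(a, b), function(g) list(g * b$value, g * a$value))
}

# multiply a matrix node by a 1x1 scalar node
ag_scale <- function(a, s) {
  sv <- s$value[1L]
  new_node(a$value * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * a$value), 1L, 1L))
  })
}

ag_scale_const <- function(a, k) new_node(a$value * k, list(a), function(g) list(g * k))

ag_relu <- function(a) {
  m <- a$value > 0
  new_node(a$value * m, list(a), function(g) list(g * m))
}

ag_gelu <- function(a) {
  x <- a$value
  ph <- stats::pnorm(x)
  new_node(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

# exp of a scalar parameter, clamped to [lo, hi]; gradient is zero where the
# clamp is active (used for the learnable temperature / logit scale)
ag_exp_clamp <- function(s, lo = 1, hi = 100) {
  e <- exp(s$value[1L])
  cl <- min(max(e, lo), hi)
  new_node(matrix(cl, 1L, 1L), list(s), function(g) {
    list(matrix(if (e > lo && e < hi) g[1L] * e else 0, 1L, 1L))
  })
}

## ---- structural ops ---------------------------------------------------

# row selection (gather); repeated indices accumulate in the backward pass
ag_rows <- function(a, idx) {
  nr <- nrow(a$value)
  new_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    dx <- matrix(0, nr, ncol(g))
    if (anyDuplicated(idx)) {
      acc <- rowsum(g, group = idx)
      dx[as.integer(rownames(acc)), ] <- acc
    } else {
      dx[idx, ] <- g
    }
    list(dx)
  })
}

# image -> row-major grid of flattened patch vectors (pure rearrangement)
ag_patchify <- function(x, patch) {
  side <- nrow(x$value)
  gs <- side %/% patch
  new_node(patchify_mat(x$value, patch), list(x), function(g) {
    dx <- matrix(0, side, side)
    n <- 0L
    for (gr in seq_len(gs)) {
      for (gc in seq_len(gs)) {
        n <- n + 1L
        dx[(gr - 1L) * patch + seq_len(patch), (gc - 1L) * patch + seq_len(patch)] <-
          matrix(g[n, ], patch, patch)
      }
    }
    list(dx)
  })
}

ag_vcat <- function(lst) {
  vals <- lapply(lst, function(n) n$value)
  nr <- vapply(vals, nrow, integer(1L))
  ends <- cumsum(nr)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  new_node(do.call(rbind, vals), lst, function(g) {
    lapply(seq_along(lst), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# weighted sum of 1x1 scalar nodes
ag_wsum <- function(lst, w) {
  val <- 0
  for (i in seq_along(lst)) val <- val + w[i] * lst[[i]]$value[1L]
  new_node(matrix(val, 1L, 1L), lst, function(g) {
    lapply(w, function(wi) matrix(wi * g[1L], 1L, 1L))
  })
}

## ---- fused ops --------------------------------------------------------

# row-wise layer normalisation with learnable 1 x d gain/shift
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  nr <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- as.vector(gamma$value)
  bv <- as.vector(beta$value)
  y <- xhat * rep(gv, each = nr) + rep(bv, each = nr)
  new_node(y, list(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    dxhat <- g * rep(gv, each = nr)
    r1 <- rowSums(dxhat)
    r2 <- rowSums(dxhat * xhat)
    dx <- (inv / d) * (d * dxhat - r1 - xhat * r2)
    list(dx, dgamma, dbeta)
  })
}

# multi-head scaled dot-product attention over one token sequence.
# q, k, v: T x d nodes; head h uses the h-th column block of width d/heads.
# When the tape was reset with record_attention = TRUE and `tag` is given,
# the per-head post-softmax attention matrices are stashed under that tag.
ag_mha <- function(q, k, v, heads, tag = NULL) {
  Q <- q$value; K <- k$value; V <- v$value
  d <- ncol(Q)
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  Tq <- nrow(Q)
  out <- matrix(0, Tq, d)
  As <- vector("list", heads)
  for (h in seq_len(heads)) {
    cs <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, cs, drop = FALSE] %*% t(K[, cs, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    A <- E / rowSums(E)
    As[[h]] <- A
    out[, cs] <- A %*% V[, cs, drop = FALSE]
  }
  if (!is.null(.tape$attn) && !is.null(tag)) assign(tag, As, envir = .tape$attn)
  new_node(out, list(q, k, v), function(g) {
    dQ <- matrix(0, Tq, d)
    dK <- matrix(0, nrow(K), d)
    dV <- matrix(0, nrow(V), d)
    for (h in seq_len(heads)) {
      cs <- ((h - 1L) * dh + 1L):(h * dh)
      A <- As[[h]]
      gO <- g[, cs, drop = FALSE]
      dV[, cs] <- t(A) %*% gO
      dA <- gO %*% t(V[, cs, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cs] <- dS %*% K[, cs, drop = FALSE] / sqrt(dh)
      dK[, cs] <- t(dS) %*% Q[, cs, drop = FALSE] / sqrt(dh)
    }
    list(dQ, dK, dV)
  })
}

# L2 normalisation of each row; all-zero rows map to zero (similarity 0 by
# convention) and receive zero gradient
ag_l2rows <- function(a, eps = 1e-12) {
  x <- a$value
  n2 <- rowSums(x * x)
  zero <- n2 < eps
  n <- sqrt(pmax(n2, eps))
  y <- x / n
  y[zero, ] <- 0
  new_node(y, list(a), function(g) {
    dot <- rowSums(g * x)
    dx <- g / n - x * (dot / n^3)
    dx[zero, ] <- 0
    list(dx)
  })
}

# fused softmax cross-entropy; logits T x C, targets in 1..C
ag_ce <- function(logits, targets, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  Z <- logits$value
  n <- nrow(Z)
  tv <- as.integer(targets)
  stopifnot(length(tv) == n, all(tv >= 1L), all(tv <= ncol(Z)))
  Zs <- Z - apply(Z, 1L, max)
  E <- exp(Zs)
  P <- E / rowSums(E)
  picked <- P[cbind(seq_len(n), tv)]
  nll <- -log(pmax(picked, 1e-300))
  val <- if (reduce == "mean") mean(nll) else sum(nll)
  new_node(matrix(val, 1L, 1L), list(logits), function(g) {
    D <- P
    ii <- cbind(seq_len(n), tv)
    D[ii] <- D[ii] - 1
    if (reduce == "mean") D <- D / n
    list(D * g[1L])
  })
}

## ---- convolution and resampling --------------------------------------

# single-channel 2-D convolution, odd square kernel, zero padding that keeps
# the spatial size at stride 1 (output side = ceiling(side / stride))
ag_conv2d <- function(x, kern, bias, stride = 1L) {
  X <- x$value
  kk <- nrow(kern$value)
  stopifnot(kk == ncol(kern$value), kk %% 2L == 1L)
  pad <- (kk - 1L) %/% 2L
  H <- nrow(X); W <- ncol(X)
  r0 <- seq.int(1L, H, by = stride)
  c0 <- seq.int(1L, W, by = stride)
  Ho <- length(r0); Wo <- length(c0)
  Xp <- matrix(0, H + 2L * pad, W + 2L * pad)
  Xp[pad + seq_len(H), pad + seq_len(W)] <- X
  C <- matrix(0, Ho * Wo, kk * kk)
  for (j in seq_len(kk)) {
    for (i in seq_len(kk)) {
      C[, (j - 1L) * kk + i] <- as.vector(Xp[r0 + i - 1L, c0 + j - 1L])
    }
  }
  v <- matrix(C %*% as.vector(kern$value) + bias$value[1L], Ho, Wo)
  new_node(v, list(x, kern, bias), function(g) {
    gv <- as.vector(g)
    dkern <- matrix(crossprod(C, gv), kk, kk)
    dbias <- matrix(sum(gv), 1L, 1L)
    dXp <- matrix(0, H + 2L * pad, W + 2L * pad)
    kv <- kern$value
    for (j in seq_len(kk)) {
      for (i in seq_len(kk)) {
        ri <- r0 + i - 1L
        ci <- c0 + j - 1L
        dXp[ri, ci] <- dXp[ri, ci] + g * kv[i, j]
      }
    }
    list(dXp[pad + seq_len(H), pad + seq_len(W)], dkern, dbias)
  })
}

# Keys bicubic kernel, a = -0.5 (the conventional photographic choice)
cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1,
         (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# dense n_out x n_in separable resampling operator with half-pixel centre
# alignment and edge replication
resample_operator <- function(n_in, n_out, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    s <- (o - 0.5) * scale - 0.5          # 0-based source coordinate
    i0 <- floor(s)
    if (method == "bilinear") {
      taps <- i0 + c(0, 1)
      wts <- c(1 - (s - i0), s - i0)
    } else {
      taps <- i0 + c(-1, 0, 1, 2)
      wts <- cubic_kernel(s - taps)
    }
    taps <- pmin(pmax(taps, 0), n_in - 1L) + 1L
    for (m in seq_along(taps)) A[o, taps[m]] <- A[o, taps[m]] + wts[m]
  }
  A
}

#' Resample a grayscale image matrix
#'
#' Separable resampling with half-pixel centre alignment and edge
#' replication, used by the downscaler front end.
#'
#' @param img Numeric matrix of intensities.
#' @param height,width Output dimensions in pixels.
#' @param method `"bicubic"` (Keys kernel, a = -0.5) or `"bilinear"`.
#' @return A `height` x `width` numeric matrix.
#' @export
resize_image <- function(img, height, width, method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), nrow(img) >= 1L, ncol(img) >= 1L)
  A <- resample_operator(nrow(img), height, method)
  B <- resample_operator(ncol(img), width, method)
  A %*% img %*% t(B)
}

# autograd view of the fixed (parameter-free) resampling stage
ag_resize <- function(x, height, width, method = "bilinear") {
  A <- resample_operator(nrow(x$value), height, method)
  B <- resample_operator(ncol(x$value), width, method)
  new_node(A %*% x$value %*% t(B), list(x), function(g) {
    list(crossprod(A, g) %*% B)
  })
}
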