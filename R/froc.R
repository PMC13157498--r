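# Evaluation: the grid of patch probabilities is treated as a low-resolution
# image.  Supra-threshold patches are grouped into connected-component
# "blobs"; blob centres are matched one-to-one to ground-truth box centres
# by minimum-cost (Hungarian) assignment under the distance hit criterion,
# with the allowed radius scaled by box size and floored at one patch; TP,
# FP and FN pooled over images give the FROC curve of sensitivity versus
# average false positives per image.

#' Extract prediction blobs from a thresholded probability grid
#'
#' Connected components (4-connectivity by default) of the set of patches
#' with probability strictly above `threshold`.
#'
#' @param probs Numeric matrix of per-patch probabilities (rows = grid
#'   rows).
#' @param threshold Scalar threshold; a patch is active when
#'   `probs > threshold`.
#' @param connectivity 4 (edge-adjacent) or 8 (also diagonal).
#' @return List of detections; each is a list with `patches` (k x 2 matrix
#'   of (row, col) grid coordinates), `center` (centroid, possibly
#'   fractional) and `score` (maximum patch probability in the blob).
#' @export
extract_blobs <- function(probs, threshold, connectivity = 4) {
  blobs_from_mask(probs > threshold, probs, connectivity)
}

blobs_from_mask <- function(act, probs, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(act); nc <- ncol(act)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), times = 3L); dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(dr == 0L & dc == 0L); dr <- dr[keep]; dc <- dc[keep]
  }
  nlab <- 0L
  out <- list()
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!act[r0, c0] || lab[r0, c0] != 0L) next
      nlab <- nlab + 1L
      queue <- matrix(c(r0, c0), 1L, 2L)
      lab[r0, c0] <- nlab
      cells <- queue
      while (nrow(queue) > 0L) {
        cur <- queue[1L, ]
        queue <- queue[-1L, , drop = FALSE]
        for (k in seq_along(dr)) {
          r <- cur[1L] + dr[k]; cc <- cur[2L] + dc[k]
          if (r >= 1L && r <= nr && cc >= 1L && cc <= nc &&
              act[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- nlab
            queue <- rbind(queue, c(r, cc))
            cells <- rbind(cells, c(r, cc))
          }
        }
      }
      out[[nlab]] <- list(
        patches = cells,
        center = c(mean(cells[, 1L]), mean(cells[, 2L])),
        score = max(probs[cells])
      )
    }
  }
  out
}

## ---- Hungarian assignment ---------------------------------------------

# minimum-cost one-to-one assignment (Jonker-Volgenant potentials with
# shortest augmenting paths).  Returns, for each row of `cost`, the matched
# column (NA when the row side is larger than the column side and the row
# stayed unmatched).
hungarian_lsap <- function(cost) {
  n0 <- nrow(cost); m0 <- ncol(cost)
  if (n0 == 0L || m0 == 0L) return(rep(NA_integer_, n0))
  transposed <- n0 > m0
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n)
  v <- numeric(m + 1L)          # index m+1 is the virtual start column
  p <- integer(m + 1L)          # p[j]: row currently assigned to column j
  way <- integer(m)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == m + 1L) p[m + 1L] else p[j1]
      if (j1 == m + 1L) break
      j0 <- j1
    }
  }
  rowmatch <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0L) rowmatch[p[j]] <- j
  if (!transposed) return(rowmatch)
  colmatch <- rep(NA_integer_, n0)
  for (r in seq_len(n)) if (!is.na(rowmatch[r])) colmatch[rowmatch[r]] <- r
  colmatch
}

#' Match detections to ground-truth boxes
#'
#' Cost is the Euclidean centre-to-centre distance in patch units; pairs
#' farther apart than the box's [allowed_radius()] are forbidden; the
#' minimum-cost one-to-one assignment (Hungarian) determines the hits.
#'
#' @param detections List of detections from [extract_blobs()].
#' @param gt_boxes Data frame of ground-truth boxes in encoder-input pixel
#'   coordinates.
#' @param grid A [grid_spec()].
#' @param min_radius,scale Passed to [allowed_radius()].
#' @return List with `tp`, `fp`, `fn` counts and `assignment` (tibble of
#'   matched detection/gt indices and their distances).
#' @export
match_detections <- function(detections, gt_boxes, grid, min_radius = 1,
                             scale = 1.0) {
  gt_boxes <- drop_no_finding(gt_boxes)
  nd <- length(detections)
  ng <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  empty <- tibble::tibble(detection = integer(), gt = integer(),
                          distance = numeric())
  if (nd == 0L || ng == 0L) {
    return(list(tp = 0L, fp = nd, fn = ng, assignment = empty))
  }
  p <- grid$patch_size
  dc <- do.call(rbind, lapply(detections, function(d) d$center))
  gc_row <- (gt_boxes$y_min + gt_boxes$y_max) / 2 / p + 0.5
  gc_col <- (gt_boxes$x_min + gt_boxes$x_max) / 2 / p + 0.5
  radii <- vapply(seq_len(ng), function(g)
    allowed_radius(gt_boxes[g, ], grid, min_radius, scale), numeric(1L))
  dist <- sqrt(outer(dc[, 1L], gc_row, "-")^2 + outer(dc[, 2L], gc_col, "-")^2)
  BIG <- 1e9
  cost <- dist
  cost[sweep(dist, 2L, radii, ">")] <- BIG
  mt <- hungarian_lsap(cost)
  pairs <- which(!is.na(mt))
  ok <- pairs[cost[cbind(pairs, mt[pairs])] < BIG / 2]
  tp <- length(ok)
  list(tp = tp, fp = nd - tp, fn = ng - tp,
       assignment = tibble::tibble(detection = ok, gt = mt[ok],
                                   distance = dist[cbind(ok, mt[ok])]))
}

drop_no_finding <- function(boxes) {
  if (is.null(boxes)) return(NULL)
  boxes <- tibble::as_tibble(boxes)
  if ("class_name" %in% names(boxes)) {
    boxes <- boxes[boxes$class_name != "No Finding", , drop = FALSE]
  }
  boxes[stats::complete.cases(boxes[, c("x_min", "y_min", "x_max", "y_max")]), ,
        drop = FALSE]
}

# per-image TP/FP/FN step tables over that image's own unique probability
# values (descending); row k holds the counts for thresholds just below
# vals[k], i.e. active set {probs >= vals[k]}
image_step_stats <- function(probs, gt_boxes, grid, connectivity, min_radius,
                             scale) {
  vals <- sort(unique(as.vector(probs)), decreasing = TRUE)
  ng <- {
    b <- drop_no_finding(gt_boxes)
    if (is.null(b)) 0L else nrow(b)
  }
  tp <- fp <- fn <- integer(length(vals))
  for (k in seq_along(vals)) {
    dets <- blobs_from_mask(probs >= vals[k], probs, connectivity)
    m <- match_detections(dets, gt_boxes, grid, min_radius, scale)
    tp[k] <- m$tp; fp[k] <- m$fp; fn[k] <- m$fn
  }
  list(vals = vals, tp = tp, fp = fp, fn = fn, ng = ng)
}

#' Free-response ROC curve
#'
#' Exact threshold sweep over the pooled unique patch probabilities: at each
#' threshold, blobs are extracted and Hungarian-matched per image; true
#' positives and false negatives are pooled over all ground-truth instances
#' for the sensitivity, and false positives are averaged over images.  The
#' reported curve is the monotone (running-maximum) envelope in both
#' coordinates, so sensitivity and average FP are non-decreasing as the
#' threshold decreases.
#'
#' @param maps List of per-image probability grids (matrices).
#' @param gts List (same length) of per-image ground-truth box data frames
#'   in encoder-input pixel coordinates; `NULL` or empty for no-finding
#'   images.
#' @param grid A [grid_spec()].
#' @param thresholds Optional threshold vector; defaults to the pooled
#'   unique probability values (exact sweep).
#' @param connectivity Blob connectivity, 4 or 8.
#' @param min_radius,scale Hit-criterion parameters, see [allowed_radius()].
#' @return A tibble of class `pa_froc` with columns `threshold`,
#'   `sensitivity`, `avg_fp`; attributes record the image and instance
#'   counts.
#' @export
froc <- function(maps, gts, grid, thresholds = NULL, connectivity = 4,
                 min_radius = 1, scale = 1.0) {
  if (length(maps) == 0L) stop("evaluation error: empty dataset", call. = FALSE)
  stopifnot(length(maps) == length(gts))
  steps <- lapply(seq_along(maps), function(i)
    image_step_stats(maps[[i]], gts[[i]], grid, connectivity, min_radius, scale))
  total_gt <- sum(vapply(steps, function(s) s$ng, integer(1L)))
  if (is.null(thresholds)) {
    thresholds <- sort(unique(unlist(lapply(maps, as.vector))),
                       decreasing = TRUE)
  } else {
    thresholds <- sort(unique(thresholds), decreasing = TRUE)
  }
  n_img <- length(maps)
  tp <- fp <- numeric(length(thresholds))
  for (s in steps) {
    asc <- rev(s$vals)
    # number of this image's values strictly above each threshold
    k <- length(s$vals) - findInterval(thresholds, asc)
    has <- k > 0L
    tp[has] <- tp[has] + s$tp[k[has]]
    fp[has] <- fp[has] + s$fp[k[has]]
  }
  sens_raw <- if (total_gt > 0L) tp / total_gt else rep(0, length(thresholds))
  fp_raw <- fp / n_img
  out <- tibble::tibble(threshold = thresholds,
                        sensitivity = cummax(sens_raw),
                        avg_fp = cummax(fp_raw))
  class(out) <- c("pa_froc", class(out))
  attr(out, "n_images") <- n_img
  attr(out, "n_gt") <- total_gt
  out
}

#' Sensitivity at a fixed average false-positive rate
#'
#' The maximum sensitivity over curve points whose average FP does not
#' exceed `fp_level` (step interpolation); 0 when no point qualifies.
#'
#' @param curve A `pa_froc` curve.
#' @param fp_level Non-negative average-FP operating point (e.g. 0.25, 0.5).
#' @return Sensitivity in \[0, 1\].
#' @export
sensitivity_at_fp <- function(curve, fp_level) {
  if (!is.numeric(fp_level) || fp_level < 0) {
    stop("fp_level must be non-negative", call. = FALSE)
  }
  ok <- curve$avg_fp <= fp_level
  if (!any(ok)) return(0)
  max(curve$sensitivity[ok])
}

#' Area under the ROC curve
#'
#' Rank-based AUC of scores against binary labels (probability that a
#' random positive outscores a random negative, ties counting one half).
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("undefined-AUC error: both classes must be present", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}
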