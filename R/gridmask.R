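# Patch-grid geometry: the grid coordinate system, the bounding-box ->
# patch ground-truth mask used as supervision, and the size-scaled allowed
# matching radius used by the FROC evaluator.
#
# Conventions (used package-wide): pixel coordinates are 0-based and
# half-open, so a box (x_min, y_min, x_max, y_max) covers pixel columns
# x_min..x_max-1.  Grid patches are indexed 1-based (row, col) in R style;
# patch (i, j) spans pixels [ (j-1)*patch, j*patch ) x [ (i-1)*patch, i*patch ).

#' Patch-grid specification
#'
#' Fixes the geometry shared by the encoder, the supervision masks and the
#' evaluator: a square encoder input of `image_side` pixels tiled by
#' non-overlapping square patches.
#'
#' @param image_side Encoder input side in pixels.
#' @param patch_size Patch side in pixels; must divide `image_side`.
#' @return An object of class `pa_grid` with fields `image_side`,
#'   `patch_size` and `grid_side`.
#' @examples
#' grid_spec(224, 14)   # 16 x 16 patch grid
#' @export
grid_spec <- function(image_side, patch_size) {
  side <- grid_shape(image_side, patch_size)
  structure(list(image_side = as.integer(image_side),
                 patch_size = as.integer(patch_size),
                 grid_side = side),
            class = "pa_grid")
}

#' @export
format.pa_grid <- function(x, ...) {
  sprintf("<pa_grid %dpx / patch %dpx -> %d x %d>", x$image_side, x$patch_size,
          x$grid_side, x$grid_side)
}

#' @export
print.pa_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Number of patches per side of the grid
#'
#' @inheritParams grid_spec
#' @return `image_side / patch_size` as an integer.
#' @export
grid_shape <- function(image_side, patch_size) {
  image_side <- as.integer(image_side)
  patch_size <- as.integer(patch_size)
  if (length(image_side) != 1L || length(patch_size) != 1L ||
      is.na(image_side) || is.na(patch_size) || patch_size < 1L ||
      image_side < 1L) {
    stop("geometry error: image_side and patch_size must be positive integers",
         call. = FALSE)
  }
  if (image_side %% patch_size != 0L) {
    stop(sprintf("geometry error: image_side %d is not divisible by patch_size %d",
                 image_side, patch_size), call. = FALSE)
  }
  image_side %/% patch_size
}

# exact area of the union of axis-aligned rectangles (n x 4 matrix of
# x0, y0, x1, y1), by an x-sweep with y-interval union per strip
rect_union_area <- function(r) {
  if (is.null(r) || nrow(r) == 0L) return(0)
  keep <- r[, 3] > r[, 1] & r[, 4] > r[, 2]
  r <- r[keep, , drop = FALSE]
  if (nrow(r) == 0L) return(0)
  xs <- sort(unique(c(r[, 1], r[, 3])))
  area <- 0
  for (i in seq_len(length(xs) - 1L)) {
    x0 <- xs[i]; x1 <- xs[i + 1L]
    sel <- r[, 1] <= x0 & r[, 3] >= x1
    if (!any(sel)) next
    ys <- r[sel, c(2, 4), drop = FALSE]
    ys <- ys[order(ys[, 1]), , drop = FALSE]
    tot <- 0
    cs <- ys[1, 1]; ce <- ys[1, 2]
    if (nrow(ys) > 1L) {
      for (j in 2:nrow(ys)) {
        if (ys[j, 1] > ce) {
          tot <- tot + (ce - cs)
          cs <- ys[j, 1]; ce <- ys[j, 2]
        } else {
          ce <- max(ce, ys[j, 2])
        }
      }
    }
    tot <- tot + (ce - cs)
    area <- area + (x1 - x0) * tot
  }
  area
}

validate_boxes <- function(boxes, image_side = NULL) {
  if (is.null(boxes)) return(invisible(NULL))
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(boxes))) {
    stop("validation error: boxes need columns x_min, y_min, x_max, y_max",
         call. = FALSE)
  }
  if (nrow(boxes) == 0L) return(invisible(NULL))
  bad <- boxes$x_min >= boxes$x_max | boxes$y_min >= boxes$y_max
  if (any(bad)) {
    stop(sprintf("validation error: degenerate box (x_min >= x_max or y_min >= y_max) in row %d",
                 which(bad)[1L]), call. = FALSE)
  }
  if (!is.null(image_side)) {
    out <- boxes$x_min < 0 | boxes$y_min < 0 |
      boxes$x_max > image_side | boxes$y_max > image_side
    if (any(out)) {
      stop(sprintf("validation error: box outside image bounds in row %d",
                   which(out)[1L]), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Convert bounding boxes to a patch ground-truth mask
#'
#' A patch is marked positive when the union of the finding boxes covers
#' strictly more than `coverage_threshold` of the patch area (default 10%).
#' Coverage is computed by exact rectangle intersection; overlapping boxes
#' are unioned per patch before thresholding, so the mask is a single binary
#' field per finding.
#'
#' @param boxes Data frame of boxes in encoder-input pixel coordinates
#'   (0-based, half-open), columns `x_min`, `y_min`, `x_max`, `y_max`.
#'   Rows with `class_name == "No Finding"` (or all-`NA` coordinates) are
#'   ignored.  An empty set of boxes yields the all-zero mask.
#' @param grid A [grid_spec()].
#' @param coverage_threshold Fraction of patch area that must be exceeded
#'   (strictly) for a patch to be positive.
#' @return An object of class `pa_patch_gt`: list with `mask` (a
#'   `grid_side` x `grid_side` 0/1 matrix, rows = grid rows = image y),
#'   `boxes` (the finding boxes used) and `relative_sizes` (per-box width
#'   and height as fractions of `image_side`).
#' @export
bbox_to_patch_mask <- function(boxes, grid, coverage_threshold = 0.10) {
  stopifnot(inherits(grid, "pa_grid"))
  if (is.null(boxes)) {
    boxes <- tibble::tibble(x_min = numeric(), y_min = numeric(),
                            x_max = numeric(), y_max = numeric())
  }
  boxes <- tibble::as_tibble(boxes)
  if ("class_name" %in% names(boxes)) {
    boxes <- boxes[boxes$class_name != "No Finding", , drop = FALSE]
  }
  boxes <- boxes[stats::complete.cases(boxes[, c("x_min", "y_min", "x_max", "y_max")]), ,
                 drop = FALSE]
  validate_boxes(boxes, grid$image_side)
  gs <- grid$grid_side
  p <- grid$patch_size
  mask <- matrix(0L, gs, gs)
  if (nrow(boxes) > 0L) {
    rmat <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
    # patches possibly touched by any box
    jr <- range(pmax(1L, floor(rmat[, 1] / p) + 1L), pmin(gs, ceiling(rmat[, 3] / p)))
    ir <- range(pmax(1L, floor(rmat[, 2] / p) + 1L), pmin(gs, ceiling(rmat[, 4] / p)))
    thr <- coverage_threshold * p^2
    for (i in ir[1]:ir[2]) {
      y0 <- (i - 1L) * p; y1 <- i * p
      for (j in jr[1]:jr[2]) {
        x0 <- (j - 1L) * p; x1 <- j * p
        clipped <- cbind(pmax(rmat[, 1], x0), pmax(rmat[, 2], y0),
                         pmin(rmat[, 3], x1), pmin(rmat[, 4], y1))
        if (rect_union_area(clipped) > thr) mask[i, j] <- 1L
      }
    }
  }
  rel <- tibble::tibble(
    width = (boxes$x_max - boxes$x_min) / grid$image_side,
    height = (boxes$y_max - boxes$y_min) / grid$image_side
  )
  structure(list(mask = mask, boxes = boxes, relative_sizes = rel, grid = grid),
            class = "pa_patch_gt")
}

#' Allowed matching radius for a ground-truth box
#'
#' The hit criterion of the evaluator: a detection counts as a true positive
#' when its centre lies within this radius (in patch units) of the box
#' centre.  The radius scales with the box size -- half the box's shorter
#' side expressed in patches, times `scale`, floored to an integer patch
#' count -- and never falls below `min_radius` (default one patch), so
#' matched predictions are constrained to lie within the ground-truth
#' region even for sub-patch findings.
#'
#' @param box A single box (1-row data frame or named list/vector) with
#'   `x_min`, `y_min`, `x_max`, `y_max` in encoder-input pixels.
#' @param grid A [grid_spec()].
#' @param min_radius Lower bound in patch units.
#' @param scale Multiplier on the size-derived radius.
#' @return Radius in patch units (numeric scalar).
#' @export
allowed_radius <- function(box, grid, min_radius = 1, scale = 1.0) {
  stopifnot(inherits(grid, "pa_grid"))
  bx <- as.list(box)
  w <- as.numeric(bx$x_max) - as.numeric(bx$x_min)
  h <- as.numeric(bx$y_max) - as.numeric(bx$y_min)
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0) {
    stop("validation error: degenerate box", call. = FALSE)
  }
  shorter <- min(w, h) / grid$patch_size   # in patch units
  max(min_radius, floor(scale * shorter / 2))
}

#' Rescale boxes with an image resize
#'
#' Applies the same geometric transform to box coordinates as a uniform
#' resize of the image from `from_side` to `to_side` pixels, so masks can
#' be generated in encoder patch space.
#'
#' @param boxes Data frame with `x_min`, `y_min`, `x_max`, `y_max`.
#' @param from_side,to_side Square image sides in pixels before and after.
#' @return The boxes with coordinates scaled by `to_side / from_side`.
#' @export
scale_boxes <- function(boxes, from_side, to_side) {
  f <- to_side / from_side
  boxes <- tibble::as_tibble(boxes)
  for (cl in c("x_min", "y_min", "x_max", "y_max")) {
    boxes[[cl]] <- boxes[[cl]] * f
  }
  boxes
}

## ---- offline mask serialization (run-length encoded JSON) -------------

#' Write / read patch ground-truth masks as run-length-encoded JSON
#'
#' Masks are precomputed offline alongside the annotations; the JSON holds,
#' per image id, the grid side and the run-length encoding of the mask laid
#' out column-major.
#'
#' @param masks Named list of 0/1 matrices (names are image ids).
#' @param path JSON file path.
#' @return `write_patch_masks()` returns `path` invisibly;
#'   `read_patch_masks()` returns the named list of masks.
#' @export
write_patch_masks <- function(masks, path) {
  enc <- lapply(masks, function(m) {
    r <- rle(as.integer(m))
    list(grid_side = nrow(m), lengths = r$lengths, values = r$values)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patch_masks
#' @export
read_patch_masks <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(enc, function(e) {
    v <- inverse.rle(structure(list(lengths = as.integer(e$lengths),
                                    values = as.integer(e$values)),
                               class = "rle"))
    matrix(v, e$grid_side, e$grid_side)
  })
}
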