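# Seeded synthetic image/text/box datasets with the statistical structure the
# training method assumes: a "No Finding" majority, class imbalance,
# controllable lesion size and contrast, and paired short text reports.
# Lesions are filled ellipses with class-specific texture (solid intensity
# offset for odd-numbered classes, a striped offset for even-numbered ones)
# so distinct classes are visually separable by a tiny encoder.

#' Configuration for the synthetic phantom generator
#'
#' @param n_images Number of images to generate.
#' @param image_side Image side in pixels (square images).
#' @param class_names Character vector of finding names.
#' @param prevalence Per-class probability that an image carries that class;
#'   the remainder `1 - sum(prevalence)` is the "No Finding" probability.
#' @param lesion_size_range Either a length-2 numeric (min, max lesion
#'   diameter in pixels, recycled over classes) or a list of length-2
#'   numerics, one per class.  Minimum must be >= 1.
#' @param lesion_contrast Additive intensity offset of lesions, in \[0, 1\].
#' @param background_noise_sd Standard deviation of the Gaussian background
#'   noise (intensity units; background base level is 0.35).
#' @param max_lesions_per_image Upper bound on lesions per positive image
#'   (the count is drawn uniformly from 1..max).
#' @param seed Integer seed; the same configuration and seed give a
#'   byte-identical dataset.
#' @return An object of class `pa_synth_config`.
#' @export
synthetic_config <- function(n_images,
                             image_side = 64L,
                             class_names = "opacity",
                             prevalence = 0.4,
                             lesion_size_range = c(20, 36),
                             lesion_contrast = 0.35,
                             background_noise_sd = 0.08,
                             max_lesions_per_image = 1L,
                             seed = 1L) {
  if (length(prevalence) != length(class_names)) {
    stop("configuration error: prevalence must have one entry per class",
         call. = FALSE)
  }
  if (any(prevalence < 0) || sum(prevalence) > 1 + 1e-12) {
    stop("configuration error: prevalence entries must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  if (!is.list(lesion_size_range)) {
    lesion_size_range <- rep(list(lesion_size_range), length(class_names))
  }
  if (length(lesion_size_range) != length(class_names)) {
    stop("configuration error: lesion_size_range must match class_names",
         call. = FALSE)
  }
  for (r in lesion_size_range) {
    if (length(r) != 2L || r[1] < 1 || r[2] < r[1] || r[2] > image_side) {
      stop("configuration error: each lesion size range needs 1 <= min <= max <= image_side",
           call. = FALSE)
    }
  }
  structure(list(n_images = as.integer(n_images),
                 image_side = as.integer(image_side),
                 class_names = class_names,
                 prevalence = prevalence,
                 lesion_size_range = lesion_size_range,
                 lesion_contrast = lesion_contrast,
                 background_noise_sd = background_noise_sd,
                 max_lesions_per_image = as.integer(max_lesions_per_image),
                 seed = as.integer(seed)),
            class = "pa_synth_config")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic image/text/box dataset
#'
#' Each image is Gaussian background noise (base level 0.35) plus zero or
#' more elliptical lesions of one class.  Every lesion gets a tight
#' annotation box (0-based, half-open pixel coordinates) that exactly
#' contains its pixel support; "No Finding" images get one annotation row
#' with empty coordinates.  The paired report text is the class name, or
#' "No Finding".
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, one 8-bit grayscale PNG per
#'   image plus `annotations.csv` and `reports.csv` are written there.
#' @return An object of class `pa_dataset`: list with `images` (named list
#'   of intensity matrices in \[0, 1\]), `annotations` and `reports`
#'   (tibbles) and `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "pa_synth_config"))
  side <- config$image_side
  n <- config$n_images
  cum <- cumsum(config$prevalence)
  images <- vector("list", n)
  ids <- sprintf("img%05d", seq_len(n))
  names(images) <- ids
  ann <- vector("list", n)
  rep_text <- character(n)

  with_local_seed(config$seed, {
    # 0-based pixel coordinate fields (rows = y, cols = x)
    px <- matrix(rep(0:(side - 1L), each = side), side, side)   # x by column
    py <- matrix(rep(0:(side - 1L), times = side), side, side)  # y by row
    for (i in seq_len(n)) {
      img <- matrix(stats::rnorm(side * side, mean = 0.35,
                                 sd = config$background_noise_sd), side, side)
      u <- stats::runif(1)
      cls_idx <- if (length(cum) > 0L) which(u <= cum)[1L] else NA_integer_
      if (is.na(cls_idx)) {
        rep_text[i] <- "No Finding"
        ann[[i]] <- tibble::tibble(image_id = ids[i], class_name = "No Finding",
                                   x_min = NA_real_, y_min = NA_real_,
                                   x_max = NA_real_, y_max = NA_real_)
      } else {
        cls <- config$class_names[cls_idx]
        rng <- config$lesion_size_range[[cls_idx]]
        n_les <- if (config$max_lesions_per_image > 1L) {
          sample.int(config$max_lesions_per_image, 1L)
        } else 1L
        rows <- vector("list", n_les)
        for (l in seq_len(n_les)) {
          a <- stats::runif(1, rng[1], rng[2]) / 2   # semi-axes in pixels
          b <- stats::runif(1, rng[1], rng[2]) / 2
          cx <- stats::runif(1, a, side - a)
          cy <- stats::runif(1, b, side - b)
          inside <- ((px - cx) / a)^2 + ((py - cy) / b)^2 <= 1
          # guarantee at least the centre pixel
          inside[round(cy) + 1L, round(cx) + 1L] <- TRUE
          offset <- if (cls_idx %% 2L == 1L) {
            config$lesion_contrast
          } else {
            config$lesion_contrast * (0.5 + 0.5 * ((px %/% 3L) %% 2L))
          }
          img <- img + inside * offset
          xs <- px[inside]; ys <- py[inside]
          rows[[l]] <- tibble::tibble(image_id = ids[i], class_name = cls,
                                      x_min = min(xs), y_min = min(ys),
                                      x_max = max(xs) + 1, y_max = max(ys) + 1)
        }
        ann[[i]] <- dplyr::bind_rows(rows)
        rep_text[i] <- cls
      }
      images[[i]] <- pmin(pmax(img, 0), 1)
    }
  })

  ds <- structure(list(images = images,
                       annotations = dplyr::bind_rows(ann),
                       reports = tibble::tibble(image_id = ids, text = rep_text),
                       config = config),
                  class = "pa_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.pa_dataset <- function(x, ...) {
  nf <- sum(x$reports$text == "No Finding")
  cat(sprintf("<pa_dataset: %d images (%dpx), %d with findings, classes: %s>\n",
              length(x$images), x$config$image_side,
              length(x$images) - nf,
              paste(x$config$class_names, collapse = ", ")))
  invisible(x)
}

#' Write / load a dataset directory
#'
#' @param dataset A `pa_dataset`.
#' @param dir Directory receiving `<image_id>.png` files plus
#'   `annotations.csv` and `reports.csv`.
#' @return `write_dataset()` returns `dir` invisibly; `load_dataset()`
#'   returns a `pa_dataset` (without the generating config).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(dataset$images)) {
    png::writePNG(dataset$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  write_annotations(dataset$annotations, file.path(dir, "annotations.csv"))
  write_reports(dataset$reports, file.path(dir, "reports.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(dir) {
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  reports <- read_reports(file.path(dir, "reports.csv"))
  ids <- reports$image_id
  images <- lapply(ids, function(id) {
    img <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
  names(images) <- ids
  structure(list(images = images, annotations = ann, reports = reports,
                 config = NULL),
            class = "pa_dataset")
}

ann_schema <- c("image_id", "class_name", "x_min", "y_min", "x_max", "y_max")

#' Read and write box annotations
#'
#' CSV schema: header `image_id,class_name,x_min,y_min,x_max,y_max`;
#' coordinates are 0-based half-open pixels.  Rows with class
#' `"No Finding"` carry empty coordinate fields.  `write_annotations()`
#' followed by `read_annotations()` is the identity on valid records.
#'
#' @param path CSV file path.
#' @param image_side Optional image side in pixels; when supplied, boxes are
#'   additionally checked to lie within the image bounds.
#' @param records Data frame of annotation records following the schema.
#' @return A tibble of annotation records.
#' @export
read_annotations <- function(path, image_side = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!identical(names(df), ann_schema)) {
    stop(sprintf("parse error: header must be '%s'", paste(ann_schema, collapse = ",")),
         call. = FALSE)
  }
  n <- nrow(df)
  coords <- c("x_min", "y_min", "x_max", "y_max")
  out <- tibble::tibble(image_id = df$image_id, class_name = df$class_name,
                        x_min = rep(NA_real_, n), y_min = NA_real_,
                        x_max = NA_real_, y_max = NA_real_)
  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    cls <- df$class_name[i]
    if (is.na(df$image_id[i]) || is.na(cls) || !nzchar(df$image_id[i])) {
      stop(sprintf("parse error at line %d: missing image_id or class_name", line),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(unlist(df[i, coords])))
    present <- !is.na(df[i, coords])
    if (cls == "No Finding") {
      if (any(present)) {
        stop(sprintf("parse error at line %d: 'No Finding' rows must have empty coordinates",
                     line), call. = FALSE)
      }
      next
    }
    if (!all(present)) {
      stop(sprintf("parse error at line %d: missing box coordinates", line),
           call. = FALSE)
    }
    if (any(is.na(vals))) {
      stop(sprintf("parse error at line %d: non-numeric box coordinates", line),
           call. = FALSE)
    }
    if (vals[1] >= vals[3] || vals[2] >= vals[4]) {
      stop(sprintf("validation error at line %d: x_min < x_max and y_min < y_max required",
                   line), call. = FALSE)
    }
    if (!is.null(image_side) &&
        (vals[1] < 0 || vals[2] < 0 || vals[3] > image_side || vals[4] > image_side)) {
      stop(sprintf("validation error at line %d: box outside image bounds", line),
           call. = FALSE)
    }
    out[i, coords] <- as.list(vals)
  }
  out
}

#' @rdname read_annotations
#' @export
write_annotations <- function(records, path) {
  records <- tibble::as_tibble(records)[, ann_schema]
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write paired text reports
#'
#' Two-column CSV `image_id,text`; report texts in the fixtures are bare
#' class names (matching the inference prompts) or `"No Finding"`.
#'
#' @param path CSV file path.
#' @param reports Data frame with columns `image_id` and `text`.
#' @return A tibble with columns `image_id` and `text`.
#' @export
read_reports <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!identical(names(df), c("image_id", "text"))) {
    stop("parse error: header must be 'image_id,text'", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_reports
#' @export
write_reports <- function(reports, path) {
  readr::write_csv(tibble::as_tibble(reports)[, c("image_id", "text")], path,
                   na = "", progress = FALSE)
  invisible(path)
}

#' Per-image binary labels for one finding class
#'
#' @param dataset A `pa_dataset`.
#' @param class_name Finding class of interest.
#' @return Named integer vector (1 = image carries the class), ordered like
#'   `dataset$images`.
#' @export
dataset_labels <- function(dataset, class_name) {
  pos <- unique(dataset$annotations$image_id[dataset$annotations$class_name == class_name])
  out <- as.integer(names(dataset$images) %in% pos)
  names(out) <- names(dataset$images)
  out
}

#' Precompute patch ground-truth masks for a dataset
#'
#' @param dataset A `pa_dataset`.
#' @param grid A [grid_spec()]; boxes are rescaled from the raw image side
#'   to the encoder side before rasterization.
#' @param class_name Finding class whose boxes form the mask.
#' @param coverage_threshold Passed to [bbox_to_patch_mask()].
#' @return Named list of `pa_patch_gt` objects, one per image.
#' @export
dataset_patch_masks <- function(dataset, grid, class_name, coverage_threshold = 0.10) {
  raw_side <- nrow(dataset$images[[1L]])
  ann <- dataset$annotations
  out <- lapply(names(dataset$images), function(id) {
    b <- ann[ann$image_id == id & ann$class_name == class_name, , drop = FALSE]
    b <- scale_boxes(b, raw_side, grid$image_side)
    bbox_to_patch_mask(b, grid, coverage_threshold)
  })
  names(out) <- names(dataset$images)
  out
}
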