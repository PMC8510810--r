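#' @title Synthetic H&E-like tile generator
#' @name synthdata
#' @description
#' Seeded generator of hematoxylin-and-eosin-caricature tiles: a textured
#' pink background, dark purple irregular elliptical "mitotic" blobs with
#' per-blob masks, boxes and centroid weak labels, and lighter distractor
#' nuclei that are absent from the mask. The geometry and label structure
#' match what the pipeline consumes; stain realism is a non-goal.
NULL

#' Synthetic tile configuration
#'
#' @param tile_size `(H, W)` in pixels (scalar recycled; minimum 32).
#' @param n_mitoses mitoses per tile; a scalar, or a range `c(lo, hi)`
#'   sampled per tile.
#' @param n_distractors non-mitotic nuclei per tile (scalar or range).
#' @param mitosis_axes_range ellipse semi-axes range in px (default 3-6).
#' @param distractor_axes_range distractor semi-axes range (default 2-5).
#' @param irregularity relative boundary-perturbation amplitude (default
#'   0.25).
#' @param bg_rgb,mitosis_rgb,distractor_rgb mean colours in `[0, 1]`.
#' @param noise_sd per-pixel Gaussian colour noise (default 0.03).
#' @param min_separation_px minimum distance between blob centres
#'   (default 14).
#' @param weak_label_jitter_sd annotator-variance jitter of the centroid
#'   weak labels, in px (default 0: exact centroids).
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(tile_size = 64L, n_mitoses = c(2L, 4L),
                         n_distractors = c(3L, 6L),
                         mitosis_axes_range = c(3, 6),
                         distractor_axes_range = c(2, 5),
                         irregularity = 0.25,
                         bg_rgb = c(0.91, 0.79, 0.84),
                         mitosis_rgb = c(0.30, 0.15, 0.42),
                         distractor_rgb = c(0.62, 0.45, 0.68),
                         noise_sd = 0.03, min_separation_px = 14,
                         weak_label_jitter_sd = 0, seed = 1L) {
  tile_size <- rep_len(as.integer(tile_size), 2L)
  if (any(tile_size < 32L)) stop("`tile_size` must be >= 32")
  if (2 * max(mitosis_axes_range) >= min(tile_size)) {
    stop("mitosis axes do not fit inside the tile")
  }
  if (min_separation_px < 0) stop("`min_separation_px` must be >= 0")
  structure(list(tile_size = tile_size, n_mitoses = n_mitoses,
                 n_distractors = n_distractors,
                 mitosis_axes_range = mitosis_axes_range,
                 distractor_axes_range = distractor_axes_range,
                 irregularity = irregularity, bg_rgb = bg_rgb,
                 mitosis_rgb = mitosis_rgb, distractor_rgb = distractor_rgb,
                 noise_sd = noise_sd, min_separation_px = min_separation_px,
                 weak_label_jitter_sd = weak_label_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.sample_count <- function(spec) {
  if (length(spec) == 1L) return(as.integer(spec))
  sample(seq(spec[1], spec[2]), 1L)
}

# rasterize one irregular ellipse; returns logical (H, W) matrix.
# Boundary: r(theta) = ellipse radius * (1 + irregularity * smooth noise).
.draw_blob <- function(H, W, cx, cy, ax, ay, phi, irregularity) {
  nharm <- 3L
  amp <- stats::rnorm(nharm, sd = irregularity / nharm)
  pha <- stats::runif(nharm, 0, 2 * pi)
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H) - 1, W), H, W) - cy
  xr <- xs * cos(phi) + ys * sin(phi)
  yr <- -xs * sin(phi) + ys * cos(phi)
  r <- sqrt((xr / ax)^2 + (yr / ay)^2)
  th <- atan2(yr / ay, xr / ax)
  pert <- 1
  for (k in seq_len(nharm)) pert <- pert + amp[k] * cos(k * th + pha[k])
  r <= pmax(0.2, pert)
}

#' Generate one synthetic tile
#'
#' Blob centres are placed by rejection sampling honouring
#' `min_separation_px`; mitoses are drawn into both image and mask,
#' distractors only into the image. Fully determined by `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `synth_tile`: list with `image` (`(H, W, 3)`
#'   in `[0, 1]`), `mask` (`(H, W)` 0/1), `boxes` (tibble, one row per
#'   mitosis), `weak_labels` (tibble `(x, y)` centroids) and `cfg`.
#' @export
generate_tile <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  H <- cfg$tile_size[1]; W <- cfg$tile_size[2]
  img <- array(rep(cfg$bg_rgb, each = H * W), c(H, W, 3))
  # low-frequency eosin texture: smoothed noise added to all channels
  tex <- matrix(stats::rnorm(ceiling(H / 8) * ceiling(W / 8), sd = 0.02),
                ceiling(H / 8), ceiling(W / 8))
  tex <- resize_bilinear(array(tex, c(dim(tex), 1L)), H, W)[, , 1]
  for (c in 1:3) img[, , c] <- img[, , c] + tex
  mask <- matrix(0L, H, W)

  n_mit <- .sample_count(cfg$n_mitoses)
  n_dis <- .sample_count(cfg$n_distractors)
  centers <- matrix(numeric(0), 0, 2)
  place <- function(margin) {
    for (try in 1:200) {
      cx <- stats::runif(1, margin, W - 1 - margin)
      cy <- stats::runif(1, margin, H - 1 - margin)
      if (nrow(centers) == 0L ||
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) >=
            cfg$min_separation_px) {
        return(c(cx, cy))
      }
    }
    NULL
  }
  comps <- list()
  placed_mit <- 0L
  for (i in seq_len(n_mit)) {
    ax <- stats::runif(1, cfg$mitosis_axes_range[1], cfg$mitosis_axes_range[2])
    ay <- stats::runif(1, cfg$mitosis_axes_range[1], cfg$mitosis_axes_range[2])
    ctr <- place(max(ax, ay) * (1 + cfg$irregularity) + 1)
    if (is.null(ctr)) {
      stop("placement failed after bounded retries: placed ", placed_mit,
           " of ", n_mit, " mitoses; lower min_separation_px or counts")
    }
    centers <- rbind(centers, ctr)
    blob <- .draw_blob(H, W, ctr[1], ctr[2], ax, ay,
                       stats::runif(1, 0, pi), cfg$irregularity)
    shade <- stats::runif(1, 0.9, 1.1)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[blob] <- cfg$mitosis_rgb[c] * shade
      img[, , c] <- ch
    }
    mask[blob] <- 1L
    comps[[length(comps) + 1L]] <- blob
    placed_mit <- placed_mit + 1L
  }
  for (i in seq_len(n_dis)) {
    ax <- stats::runif(1, cfg$distractor_axes_range[1],
                       cfg$distractor_axes_range[2])
    ay <- stats::runif(1, cfg$distractor_axes_range[1],
                       cfg$distractor_axes_range[2])
    ctr <- place(max(ax, ay) + 1)
    if (is.null(ctr)) next  # distractors are best-effort
    centers <- rbind(centers, ctr)
    blob <- .draw_blob(H, W, ctr[1], ctr[2], ax, ay,
                       stats::runif(1, 0, pi), cfg$irregularity)
    shade <- stats::runif(1, 0.9, 1.1)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[blob] <- cfg$distractor_rgb[c] * shade
      img[, , c] <- ch
    }
  }
  img <- img + array(stats::rnorm(H * W * 3, sd = cfg$noise_sd), c(H, W, 3))
  img <- pmin(pmax(img, 0), 1)

  boxes <- new_boxes()
  weak <- tibble::tibble(x = numeric(0), y = numeric(0))
  for (blob in comps) {
    idx <- which(blob)
    ys <- (idx - 1L) %% H
    xs <- (idx - 1L) %/% H
    boxes <- rbind(boxes, new_boxes(x0 = min(xs), y0 = min(ys),
                                    x1 = max(xs) + 1L, y1 = max(ys) + 1L))
    wx <- mean(xs); wy <- mean(ys)
    if (cfg$weak_label_jitter_sd > 0) {
      wx <- wx + stats::rnorm(1, sd = cfg$weak_label_jitter_sd)
      wy <- wy + stats::rnorm(1, sd = cfg$weak_label_jitter_sd)
    }
    # a jittered centroid must still land on its own component
    wi <- round(wy) + round(wx) * H + 1L
    if (wi < 1L || wi > H * W || !blob[wi]) {
      j <- which.min((xs - wx)^2 + (ys - wy)^2)
      wx <- xs[j]; wy <- ys[j]
    }
    weak <- tibble::add_row(weak, x = wx, y = wy)
  }
  structure(list(image = img, mask = mask, boxes = boxes,
                 weak_labels = weak, cfg = cfg),
            class = "synth_tile")
}

#' @export
print.synth_tile <- function(x, ...) {
  cat("<synth_tile>", nrow(x$mask), "x", ncol(x$mask), "px,",
      nrow(x$boxes), "mitoses,", sum(x$mask), "foreground px\n")
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes per-tile PNG images and masks, weak-label CSVs (`x,y`, no header),
#' box CSVs (`x0,y0,x1,y1,positive`) and a JSON manifest with a seeded,
#' disjoint train/validation split. Regenerating with the same seed yields
#' byte-identical files.
#'
#' @param n_tiles number of tiles (>= 1).
#' @param cfg a [synth_config()]; tile `i` uses seed `cfg$seed + i`.
#' @param split fraction of tiles in the training split, in (0, 1).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
generate_dataset <- function(n_tiles, cfg = synth_config(), split = 0.8,
                             dir = tempfile("synthds")) {
  stopifnot(n_tiles >= 1L, split > 0, split < 1)
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (d in c("images", "masks", "labels", "boxes")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  n_train <- max(1L, min(n_tiles - 1L, round(split * n_tiles)))
  set.seed(cfg$seed)
  train_idx <- sort(sample.int(n_tiles, n_train))
  entries <- list()
  for (i in seq_len(n_tiles)) {
    tcfg <- cfg
    tcfg$seed <- cfg$seed + i
    tile <- generate_tile(tcfg)
    stem <- sprintf("tile%03d", i)
    png::writePNG(tile$image, file.path(dir, "images", paste0(stem, ".png")))
    png::writePNG(tile$mask * 1.0,
                  file.path(dir, "masks", paste0(stem, ".png")))
    write_weak_labels(file.path(dir, "labels", paste0(stem, ".csv")),
                      tile$weak_labels)
    boxes <- tile$boxes
    boxes$positive <- TRUE
    write_boxes(file.path(dir, "boxes", paste0(stem, ".csv")), boxes)
    entries[[i]] <- list(stem = stem,
                         split = if (i %in% train_idx) "train" else "val",
                         n_mitoses = nrow(tile$boxes), seed = tcfg$seed)
  }
  manifest <- list(n_tiles = n_tiles, split = split, seed = cfg$seed,
                   tile_size = cfg$tile_size, entries = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a generated dataset from disk
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @param split `"train"`, `"val"` or `"all"`.
#' @return list with parallel lists `tiles`, `masks`, `weak_labels`,
#'   `boxes`, and the vector `stems`.
#' @export
load_dataset <- function(dir, split = c("all", "train", "val")) {
  split <- match.arg(split)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ent <- Filter(function(e) split == "all" || e$split == split, mf$entries)
  tiles <- list(); masks <- list(); weak <- list(); boxes <- list()
  stems <- character(0)
  for (e in ent) {
    stems <- c(stems, e$stem)
    tiles[[length(tiles) + 1L]] <-
      png::readPNG(file.path(dir, "images", paste0(e$stem, ".png")))
    m <- png::readPNG(file.path(dir, "masks", paste0(e$stem, ".png")))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    masks[[length(masks) + 1L]] <- (m > 0.5) + 0L
    weak[[length(weak) + 1L]] <-
      read_weak_labels(file.path(dir, "labels", paste0(e$stem, ".csv")))
    boxes[[length(boxes) + 1L]] <-
      read_boxes(file.path(dir, "boxes", paste0(e$stem, ".csv")))
  }
  list(tiles = tiles, masks = masks, weak_labels = weak, boxes = boxes,
       stems = stems)
}
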