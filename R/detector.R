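#' @title Region-based mitosis detector
#' @name detector
#' @description
#' An R-CNN-style detector trained on the generated strong labels: region
#' proposals (selective search, or a multi-scale sliding window), a small
#' CNN feature extractor on warped fixed-size region crops, a linear-SVM
#' region classifier, and ridge bounding-box regression. Minibatches follow
#' the 32-positive / 96-negative recipe.
NULL

box_vec <- function(a) {
  if (is.data.frame(a)) return(as.numeric(a[1, c("x0", "y0", "x1", "y1")]))
  if (!is.null(names(a)) && all(c("x0", "y0", "x1", "y1") %in% names(a))) {
    return(as.numeric(a[c("x0", "y0", "x1", "y1")]))
  }
  as.numeric(a[1:4])
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as `c(x0, y0, x1, y1)` vectors or one-row data frames.
#' @return scalar IoU in `[0, 1]`; symmetric in its arguments.
#' @examples
#' iou(c(0, 0, 4, 4), c(2, 2, 6, 6))  # 4/28
#' @export
iou <- function(a, b) {
  a <- box_vec(a)
  b <- box_vec(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU matrix between two box tibbles: nrow(A) x nrow(B)
iou_matrix <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(matrix(0, nrow(A), nrow(B)))
  ix <- pmax(0, outer(A$x1, B$x1, pmin) - outer(A$x0, B$x0, pmax))
  iy <- pmax(0, outer(A$y1, B$y1, pmin) - outer(A$y0, B$y0, pmax))
  inter <- ix * iy
  areaA <- (A$x1 - A$x0) * (A$y1 - A$y0)
  areaB <- (B$x1 - B$x0) * (B$y1 - B$y0)
  un <- outer(areaA, areaB, "+") - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Generate region proposals on a tile
#'
#' Two methods: `"selective_search"` — a seeded-grid k-means
#' over-segmentation followed by hierarchical region merging scored on
#' colour-histogram similarity, size and fill (every region ever formed
#' contributes its bounding box) — and `"sliding_window"` — a deterministic
#' multi-scale window grid. Both are deterministic for fixed parameters, and
#' every proposal is clipped to image bounds.
#'
#' @param tile `(H, W, 3)` array in `[0, 1]`.
#' @param method `"selective_search"` or `"sliding_window"`.
#' @param params method parameters. Sliding window: `windows` (vector of
#'   window sides), `stride` (recycled per window). Selective search:
#'   `grid_step` (seed spacing, default 8), `n_bins` (colour histogram bins,
#'   default 8), `max_proposals` (default 200), `min_size` (minimum region
#'   side, default 3).
#' @return tibble of proposals `(x0, y0, x1, y1)`.
#' @export
propose_regions <- function(tile, method = c("sliding_window", "selective_search"),
                            params = list()) {
  method <- match.arg(method)
  d <- dim(tile)
  H <- d[1]; W <- d[2]
  if (method == "sliding_window") {
    windows <- params$windows %||% c(12L, 16L, 24L)
    stride <- params$stride %||% pmax(2L, windows %/% 2L)
    stride <- rep_len(stride, length(windows))
    out <- list()
    for (i in seq_along(windows)) {
      win <- windows[i]; st <- stride[i]
      if (win > W || win > H) next
      xs <- seq(0L, W - win, by = st)
      ys <- seq(0L, H - win, by = st)
      g <- expand.grid(x0 = xs, y0 = ys)
      out[[length(out) + 1L]] <-
        new_boxes(x0 = g$x0, y0 = g$y0, x1 = g$x0 + win, y1 = g$y0 + win)
    }
    props <- if (length(out)) do.call(rbind, out) else new_boxes()
  } else {
    props <- selective_search(tile, params)
  }
  if (nrow(props)) {
    props$x0 <- pmax(0, props$x0); props$y0 <- pmax(0, props$y0)
    props$x1 <- pmin(W, props$x1); props$y1 <- pmin(H, props$y1)
    props <- props[props$x1 > props$x0 & props$y1 > props$y0, ]
  }
  tibble::as_tibble(props)
}

# selective search: grid-seeded k-means over-segmentation + greedy merging
selective_search <- function(tile, params = list()) {
  d <- dim(tile)
  H <- d[1]; W <- d[2]
  step <- params$grid_step %||% 8L
  n_bins <- params$n_bins %||% 8L
  max_props <- params$max_proposals %||% 200L
  min_size <- params$min_size %||% 3L
  kmeans_iters <- params$kmeans_iters %||% 5L
  sw <- params$spatial_weight %||% (1 / step)

  ys <- seq(step / 2, H - step / 2, by = step)
  xs <- seq(step / 2, W - step / 2, by = step)
  cen <- as.matrix(expand.grid(y = ys, x = xs))
  px <- cbind(y = rep(seq_len(H) - 0.5, W), x = rep(seq_len(W) - 0.5, each = H))
  feat <- cbind(px * sw, matrix(tile, H * W, d[3]))
  centers <- cbind(cen * sw,
                   t(vapply(seq_len(nrow(cen)), function(i) {
                     tile[ceiling(cen[i, 1]), ceiling(cen[i, 2]), ]
                   }, numeric(d[3]))))
  lab <- integer(H * W)
  for (it in seq_len(kmeans_iters)) {
    # squared distances pixel x center
    d2 <- outer(rowSums(feat^2), rowSums(centers^2), "+") -
      2 * feat %*% t(centers)
    lab <- max.col(-d2, ties.method = "first")
    for (k in seq_len(nrow(centers))) {
      sel <- lab == k
      if (any(sel)) centers[k, ] <- colMeans(feat[sel, , drop = FALSE])
    }
  }
  keep <- sort(unique(lab))
  lab <- match(lab, keep)
  nreg <- length(keep)
  ycoord <- px[, 1] - 0.5; xcoord <- px[, 2] - 0.5
  # per-region state
  colmat <- matrix(tile, H * W, d[3])
  brk <- seq(0, 1, length.out = n_bins + 1L)
  hist_of <- function(idx) {
    h <- unlist(lapply(seq_len(d[3]), function(c) {
      tabulate(findInterval(colmat[idx, c], brk, rightmost.closed = TRUE),
               nbins = n_bins)
    }))
    h / sum(h)
  }
  regs <- lapply(seq_len(nreg), function(k) {
    idx <- which(lab == k)
    list(size = length(idx), hist = hist_of(idx),
         box = c(min(xcoord[idx]), min(ycoord[idx]),
                 max(xcoord[idx]) + 1, max(ycoord[idx]) + 1),
         alive = TRUE)
  })
  # region adjacency from pixel grid
  labm <- matrix(lab, H, W)
  adj <- unique(rbind(
    cbind(as.vector(labm[-H, ]), as.vector(labm[-1, ])),
    cbind(as.vector(labm[, -W]), as.vector(labm[, -1]))))
  adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
  adj <- unique(t(apply(adj, 1, sort)))
  pairs <- lapply(seq_len(nrow(adj)), function(i) adj[i, ])

  imsize <- H * W
  simfun <- function(a, b) {
    s_col <- sum(pmin(a$hist, b$hist))
    s_size <- 1 - (a$size + b$size) / imsize
    bb <- c(min(a$box[1], b$box[1]), min(a$box[2], b$box[2]),
            max(a$box[3], b$box[3]), max(a$box[4], b$box[4]))
    s_fill <- 1 - ((bb[3] - bb[1]) * (bb[4] - bb[2]) - a$size - b$size) / imsize
    s_col + s_size + s_fill
  }
  boxes <- lapply(regs, `[[`, "box")
  while (length(pairs)) {
    sims <- vapply(pairs, function(p) {
      if (!regs[[p[1]]]$alive || !regs[[p[2]]]$alive) return(-Inf)
      simfun(regs[[p[1]]], regs[[p[2]]])
    }, numeric(1))
    best <- which.max(sims)
    if (!is.finite(sims[best])) break
    p <- pairs[[best]]
    a <- regs[[p[1]]]; b <- regs[[p[2]]]
    merged <- list(
      size = a$size + b$size,
      hist = (a$hist * a$size + b$hist * b$size) / (a$size + b$size),
      box = c(min(a$box[1], b$box[1]), min(a$box[2], b$box[2]),
              max(a$box[3], b$box[3]), max(a$box[4], b$box[4])),
      alive = TRUE)
    regs[[p[1]]]$alive <- FALSE
    regs[[p[2]]]$alive <- FALSE
    regs[[length(regs) + 1L]] <- merged
    newid <- length(regs)
    boxes[[length(boxes) + 1L]] <- merged$box
    # rewire adjacency to the merged region
    touched <- unique(unlist(lapply(pairs, function(q) {
      if (any(q %in% p)) setdiff(q, p) else NULL
    })))
    pairs <- Filter(function(q) !any(q %in% p), pairs)
    for (tch in touched) {
      if (regs[[tch]]$alive) pairs[[length(pairs) + 1L]] <- c(tch, newid)
    }
  }
  bm <- do.call(rbind, boxes)
  props <- new_boxes(x0 = floor(bm[, 1]), y0 = floor(bm[, 2]),
                     x1 = ceiling(bm[, 3]), y1 = ceiling(bm[, 4]))
  props <- props[(props$x1 - props$x0) >= min_size &
                 (props$y1 - props$y0) >= min_size, ]
  props <- props[!duplicated(props), ]
  # prefer later (larger, merged) regions? keep scan order, cap the count
  if (nrow(props) > max_props) props <- props[seq_len(max_props), ]
  props
}

#' Partition proposals into positives and negatives by IoU
#'
#' A proposal is positive if its maximum IoU against any ground-truth box is
#' `>= pos_iou`, negative if `< neg_iou`, and discarded otherwise.
#'
#' @param proposals tibble of proposal boxes.
#' @param gt_boxes tibble of ground-truth (positive) boxes.
#' @param pos_iou,neg_iou thresholds (defaults 0.5 / 0.3).
#' @return list with `positives` (tibble, plus `gt_index` of the best-IoU
#'   ground-truth box) and `negatives` (tibble).
#' @export
label_proposals <- function(proposals, gt_boxes, pos_iou = 0.5, neg_iou = 0.3) {
  if (!(pos_iou > neg_iou)) stop("need pos_iou > neg_iou")
  proposals <- tibble::as_tibble(proposals)
  if (nrow(proposals) == 0L) {
    return(list(positives = proposals, negatives = proposals))
  }
  if (NROW(gt_boxes) == 0L) {
    neg <- proposals
    pos <- proposals[0, ]
    pos$gt_index <- integer(0)
    return(list(positives = pos, negatives = neg))
  }
  M <- iou_matrix(proposals, tibble::as_tibble(gt_boxes))
  best <- apply(M, 1, max)
  besti <- apply(M, 1, which.max)
  pos <- proposals[best >= pos_iou, ]
  pos$gt_index <- besti[best >= pos_iou]
  list(positives = pos, negatives = proposals[best < neg_iou, ])
}

#' Minibatch composition specification
#'
#' The detector composes each minibatch from 32 positive and 96 negative
#' region samples.
#'
#' @param n_pos,n_neg quota of positive / negative samples (32 / 96).
#' @param seed RNG seed; `NA` draws from the ambient RNG stream.
#' @return a `minibatch_spec` list.
#' @export
minibatch_spec <- function(n_pos = 32L, n_neg = 96L, seed = NA_integer_) {
  if (n_pos <= 0L || n_neg <= 0L) stop("both quotas must be positive")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seed = seed), class = "minibatch_spec")
}

pool_sample <- function(n_avail, quota) {
  if (n_avail >= quota) sample.int(n_avail, quota)
  else sample.int(n_avail, quota, replace = TRUE)
}

#' Sample a 32/96 minibatch from proposal pools
#'
#' Sampling is without replacement when a pool covers its quota, with
#' replacement otherwise, and always returns exactly `n_pos + n_neg`
#' samples.
#'
#' @param positives,negatives pools (tibbles or vectors/lists); must be
#'   non-empty.
#' @param spec a [minibatch_spec()].
#' @return list with `positives` and `negatives`, of sizes `n_pos` and
#'   `n_neg`.
#' @export
sample_minibatch <- function(positives, negatives, spec = minibatch_spec()) {
  np <- NROW(positives); nn <- NROW(negatives)
  if (np == 0L) stop("positive pool is empty; cannot compose a minibatch")
  if (nn == 0L) stop("negative pool is empty; cannot compose a minibatch")
  if (!is.na(spec$seed)) set.seed(spec$seed)
  pi <- pool_sample(np, spec$n_pos)
  ni <- pool_sample(nn, spec$n_neg)
  take <- function(pool, i) {
    if (is.data.frame(pool)) pool[i, , drop = FALSE] else pool[i]
  }
  list(positives = take(positives, pi), negatives = take(negatives, ni))
}

#' Bounding-box regression targets
#'
#' Standard center/log-size parametrization:
#' `(dx, dy, dw, dh) = ((gx-px)/pw, (gy-py)/ph, log(gw/pw), log(gh/ph))`
#' from proposal centers/sizes `(px, py, pw, ph)` to ground-truth
#' `(gx, gy, gw, gh)`. [apply_bbox_regression()] is its exact inverse.
#'
#' @param proposal,gt boxes as `c(x0, y0, x1, y1)` or one-row data frames.
#' @return numeric `c(dx, dy, dw, dh)`.
#' @export
bbox_regression_targets <- function(proposal, gt) {
  p <- box_vec(proposal)
  g <- box_vec(gt)
  pw <- p[3] - p[1]; ph <- p[4] - p[2]
  if (pw <= 0 || ph <= 0) stop("zero-size proposal has no regression target")
  gw <- g[3] - g[1]; gh <- g[4] - g[2]
  c(dx = ((g[1] + g[3]) / 2 - (p[1] + p[3]) / 2) / pw,
    dy = ((g[2] + g[4]) / 2 - (p[2] + p[4]) / 2) / ph,
    dw = log(gw / pw), dh = log(gh / ph))
}

#' Apply bounding-box regression offsets to a proposal
#'
#' @param proposal box `c(x0, y0, x1, y1)` or one-row data frame.
#' @param deltas numeric `c(dx, dy, dw, dh)`.
#' @return numeric box `c(x0, y0, x1, y1)`.
#' @export
apply_bbox_regression <- function(proposal, deltas) {
  p <- box_vec(proposal)
  pw <- p[3] - p[1]; ph <- p[4] - p[2]
  cx <- (p[1] + p[3]) / 2 + deltas[1] * pw
  cy <- (p[2] + p[4]) / 2 + deltas[2] * ph
  w <- pw * exp(deltas[3]); h <- ph * exp(deltas[4])
  c(x0 = cx - w / 2, y0 = cy - h / 2, x1 = cx + w / 2, y1 = cy + h / 2)
}

#' Greedy non-maximum suppression
#'
#' @param detections tibble with box columns and `confidence`.
#' @param nms_iou overlap threshold (default 0.3): a detection is suppressed
#'   if its IoU with an already-kept higher-confidence detection exceeds it.
#' @return the surviving detections, sorted by descending confidence.
#' @export
nms <- function(detections, nms_iou = 0.3) {
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) <= 1L) return(detections)
  ord <- order(-detections$confidence)
  detections <- detections[ord, ]
  keep <- logical(nrow(detections))
  for (i in seq_len(nrow(detections))) {
    if (any(keep)) {
      kept <- detections[keep, ]
      if (max(iou_matrix(detections[i, ], kept)) > nms_iou) next
    }
    keep[i] <- TRUE
  }
  detections[keep, ]
}

# bilinear resize of an (H, W, C) array to (out_h, out_w)
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  dim(img) <- c(H, W, C)
  sy <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(pmax(floor(sx), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(out_h, out_w, C))
  for (c in seq_len(C)) {
    ch <- img[, , c]
    a <- ch[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- ch[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    e <- ch[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    f <- ch[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    WX <- rep(wx, each = out_h); WY <- rep(wy, out_w)
    out[, , c] <- matrix((a * (1 - WX) + b * WX) * (1 - WY) +
                         (e * (1 - WX) + f * WX) * WY, out_h, out_w)
  }
  out
}

# crop a (possibly fractional) box from a tile and warp to warp x warp px
warp_crop <- function(tile, box, warp) {
  d <- dim(tile)
  x0 <- max(0L, floor(box[["x0"]])); y0 <- max(0L, floor(box[["y0"]]))
  x1 <- min(d[2], ceiling(box[["x1"]])); y1 <- min(d[1], ceiling(box[["y1"]]))
  if (x1 <= x0) x1 <- min(d[2], x0 + 1L)
  if (y1 <= y0) y1 <- min(d[1], y0 + 1L)
  crop <- tile[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  resize_bilinear(crop, warp, warp)
}

#' Detector configuration
#'
#' @param warp_size side of the square region crop fed to the CNN
#'   (default 64).
#' @param channels backbone channel widths, one conv/BN/ReLU + 2x2 pooling
#'   stage each (default `c(8, 16, 32, 32)`).
#' @param steps minibatch iterations for CNN training (default 100).
#' @param lr_start,lr_end log-linear learning-rate schedule endpoints.
#' @param pos_iou,neg_iou proposal labelling thresholds (0.5 / 0.3).
#' @param nms_iou non-maximum-suppression threshold (0.3).
#' @param score_threshold minimum confidence of an emitted detection.
#' @param classifier `"svm"` (linear SVM on frozen CNN features, default) or
#'   `"softmax"` (the CNN head itself).
#' @param svm_cost linear-SVM cost parameter.
#' @param ridge_lambda ridge penalty of the bbox regressor.
#' @param use_bbox_regression apply regression offsets at inference
#'   (default TRUE).
#' @param proposal_method,proposal_params see [propose_regions()].
#' @param n_pos,n_neg minibatch quotas (32 / 96).
#' @param seed RNG seed.
#' @return a `detector_config` list.
#' @export
detector_config <- function(warp_size = 64L, channels = c(8L, 16L, 32L, 32L),
                            steps = 100L, lr_start = 1e-3, lr_end = 1e-6,
                            pos_iou = 0.5, neg_iou = 0.3, nms_iou = 0.3,
                            score_threshold = 0.5,
                            classifier = c("svm", "softmax"),
                            svm_cost = 1, ridge_lambda = 1,
                            use_bbox_regression = TRUE,
                            proposal_method = "sliding_window",
                            proposal_params = list(),
                            n_pos = 32L, n_neg = 96L, seed = 1L) {
  classifier <- match.arg(classifier)
  if (log2(warp_size) < length(channels)) {
    stop("warp_size too small for ", length(channels), " pooling stages")
  }
  structure(list(warp_size = as.integer(warp_size),
                 channels = as.integer(channels), steps = as.integer(steps),
                 lr_start = lr_start, lr_end = lr_end,
                 pos_iou = pos_iou, neg_iou = neg_iou, nms_iou = nms_iou,
                 score_threshold = score_threshold, classifier = classifier,
                 svm_cost = svm_cost, ridge_lambda = ridge_lambda,
                 use_bbox_regression = use_bbox_regression,
                 proposal_method = proposal_method,
                 proposal_params = proposal_params,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seed = as.integer(seed)),
            class = "detector_config")
}

detector_backbone <- function(cfg) {
  layers <- list()
  cin <- 3L
  for (c in cfg$channels) {
    layers <- c(layers, nn_block(cin, c, 1L, 3L), list(nn_layer_pool2()))
    cin <- c
  }
  layers
}

backbone_features <- function(layers, crops, train = FALSE) {
  r <- nn_seq_forward(layers, crops, train)
  d <- dim(r$y)
  m <- matrix(r$y, d[1] * d[2], d[3] * d[4])
  feats <- matrix(colMeans(m), d[3], d[4])  # (N, C) global average pool
  list(feats = feats, fw = r, outdim = d)
}

#' Train the R-CNN-style detector
#'
#' Proposals are generated on every training tile and partitioned against
#' the positive strong-label boxes; ground-truth boxes join the positive
#' pool. A small CNN is trained with softmax cross entropy on 32/96
#' minibatches of warped crops; a linear SVM is then fitted on the frozen
#' CNN features, and a ridge regressor maps positive-proposal features to
#' box offsets.
#'
#' @param tiles list of `(H, W, 3)` arrays.
#' @param labeled_boxes list (same length) of labelled box tibbles from
#'   [generate_strong_labels()]; only rows with `positive == TRUE` are used
#'   as ground truth.
#' @param cfg a [detector_config()].
#' @return an object of class `mito_detector` with a `history` tibble of
#'   per-step classification loss.
#' @export
train_detector <- function(tiles, labeled_boxes, cfg = detector_config()) {
  stopifnot(length(tiles) == length(labeled_boxes))
  set.seed(cfg$seed)
  pos_crates <- list(); neg_crates <- list(); pos_targets <- list()
  for (i in seq_along(tiles)) {
    gt <- tibble::as_tibble(labeled_boxes[[i]])
    if ("positive" %in% names(gt)) gt <- gt[gt$positive, ]
    gt <- gt[, c("x0", "y0", "x1", "y1")]
    props <- propose_regions(tiles[[i]], cfg$proposal_method,
                             cfg$proposal_params)
    lab <- label_proposals(props, gt, cfg$pos_iou, cfg$neg_iou)
    pos <- lab$positives
    if (nrow(gt)) {  # ground-truth boxes are positives of their own right
      gtp <- gt; gtp$gt_index <- seq_len(nrow(gt))
      pos <- rbind(pos, gtp)
    }
    if (nrow(pos)) {
      pos_crates[[length(pos_crates) + 1L]] <-
        cbind(tile = i, pos[, c("x0", "y0", "x1", "y1")])
      pos_targets[[length(pos_targets) + 1L]] <- t(vapply(
        seq_len(nrow(pos)),
        function(j) bbox_regression_targets(pos[j, ], gt[pos$gt_index[j], ]),
        numeric(4)))
    }
    if (nrow(lab$negatives)) {
      neg_crates[[length(neg_crates) + 1L]] <-
        cbind(tile = i, lab$negatives[, c("x0", "y0", "x1", "y1")])
    }
  }
  if (length(pos_crates) == 0L) {
    stop("no positive boxes in any tile; cannot train the detector")
  }
  pos_pool <- do.call(rbind, pos_crates)
  neg_pool <- do.call(rbind, neg_crates)
  pos_t <- do.call(rbind, pos_targets)
  if (NROW(neg_pool) == 0L) stop("no negative proposals; widen the proposal set")

  crop_of <- function(row) warp_crop(tiles[[row$tile]], row, cfg$warp_size)
  crops_tensor <- function(pool_rows) {
    x <- array(0, c(cfg$warp_size, cfg$warp_size, nrow(pool_rows), 3L))
    for (j in seq_len(nrow(pool_rows))) x[, , j, ] <- crop_of(pool_rows[j, ])
    x
  }

  layers <- detector_backbone(cfg)
  C <- cfg$channels[length(cfg$channels)]
  headW <- matrix(stats::rnorm(C * 2L, sd = sqrt(2 / C)), C, 2L)
  headb <- numeric(2L)
  opt <- nn_adam_init(layers)
  hm <- list(W = headW * 0, b = headb * 0)
  hv <- list(W = headW * 0, b = headb * 0)
  spec <- minibatch_spec(cfg$n_pos, cfg$n_neg, seed = NA_integer_)
  history <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  for (step in seq_len(cfg$steps)) {
    lr <- nn_lr_schedule(step, cfg$steps, cfg$lr_start, cfg$lr_end)
    mb <- sample_minibatch(pos_pool, neg_pool, spec)
    batch <- rbind(mb$positives, mb$negatives)
    y <- c(rep(2L, cfg$n_pos), rep(1L, cfg$n_neg))  # 2 = mitosis
    x <- crops_tensor(batch)
    bf <- backbone_features(layers, x, train = TRUE)
    layers <- bf$fw$layers
    logits <- bf$feats %*% headW + matrix(headb, nrow(bf$feats), 2L,
                                          byrow = TRUE)
    ce <- nn_softmax_ce(logits, y)
    n <- nrow(logits)
    dlog <- ce$dlogits / n
    dW <- crossprod(bf$feats, dlog)
    db <- colSums(dlog)
    dfeats <- dlog %*% t(headW)
    d <- bf$outdim
    dgap <- array(0, d)
    for (j in seq_len(d[3])) {
      dgap[, , j, ] <- rep(dfeats[j, ] / (d[1] * d[2]), each = d[1] * d[2])
    }
    bk <- nn_seq_backward(layers, bf$fw$caches, dgap)
    upd <- nn_adam_step(layers, bk$grads, opt, lr, step)
    layers <- upd$layers; opt <- upd$state
    # Adam on the dense head
    for (p in c("W", "b")) {
      g <- if (p == "W") dW else db
      hm[[p]] <- 0.9 * hm[[p]] + 0.1 * g
      hv[[p]] <- 0.999 * hv[[p]] + 0.001 * g^2
      mhat <- hm[[p]] / (1 - 0.9^step)
      vhat <- hv[[p]] / (1 - 0.999^step)
      if (p == "W") headW <- headW - lr * mhat / (sqrt(vhat) + 1e-8)
      else headb <- headb - lr * mhat / (sqrt(vhat) + 1e-8)
    }
    history <- rbind(history,
                     data.frame(step = step, loss = ce$loss / n, lr = lr))
  }

  # frozen features for the SVM and the ridge bbox regressor
  feats_of <- function(pool_rows) {
    out <- matrix(0, nrow(pool_rows), C)
    bs <- 64L
    for (s in seq(1L, nrow(pool_rows), by = bs)) {
      idx <- s:min(s + bs - 1L, nrow(pool_rows))
      out[idx, ] <- backbone_features(layers, crops_tensor(pool_rows[idx, ]),
                                      train = FALSE)$feats
    }
    out
  }
  fpos <- feats_of(pos_pool)
  fneg <- feats_of(neg_pool)
  X <- rbind(fpos, fneg)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  yf <- factor(c(rep("pos", nrow(fpos)), rep("neg", nrow(fneg))),
               levels = c("neg", "pos"))
  svm_fit <- NULL; svm_sign <- 1
  if (cfg$classifier == "svm") {
    svm_fit <- e1071::svm(Xs, yf, kernel = "linear", cost = cfg$svm_cost,
                          scale = FALSE)
    dv <- attr(stats::predict(svm_fit, Xs, decision.values = TRUE),
               "decision.values")[, 1]
    svm_sign <- if (mean(dv[yf == "pos"]) >= mean(dv[yf == "neg"])) 1 else -1
  }
  # ridge regression (with intercept) from positive features to box offsets
  Xp <- cbind(1, sweep(sweep(fpos, 2, mu), 2, sdv, "/"))
  lam <- diag(cfg$ridge_lambda, ncol(Xp)); lam[1, 1] <- 0
  bbox_B <- solve(crossprod(Xp) + lam, crossprod(Xp, pos_t))

  structure(list(cfg = cfg, layers = layers, headW = headW, headb = headb,
                 feat_mu = mu, feat_sd = sdv, svm = svm_fit,
                 svm_sign = svm_sign, bbox_B = bbox_B,
                 history = tibble::as_tibble(history)),
            class = "mito_detector")
}

#' @export
print.mito_detector <- function(x, ...) {
  cat("<mito_detector> backbone channels:",
      paste(x$cfg$channels, collapse = "/"),
      " classifier:", x$cfg$classifier,
      " steps:", nrow(x$history), "\n")
  invisible(x)
}

#' Run the detector on a tile
#'
#' Proposals are scored by the region classifier, positively scored boxes are
#' refined by the ridge regressor, thresholded, and reduced by greedy
#' non-maximum suppression.
#'
#' @param detector a trained [mito_detector][train_detector()].
#' @param tile `(H, W, 3)` array.
#' @param score_threshold,nms_iou override the config values.
#' @return tibble of detections `(x0, y0, x1, y1, confidence)`, sorted by
#'   descending confidence; possibly empty.
#' @export
detect <- function(detector, tile, score_threshold = NULL, nms_iou = NULL) {
  cfg <- detector$cfg
  score_threshold <- score_threshold %||% cfg$score_threshold
  nms_iou <- nms_iou %||% cfg$nms_iou
  props <- propose_regions(tile, cfg$proposal_method, cfg$proposal_params)
  empty <- new_boxes(confidence = numeric(0))
  if (nrow(props) == 0L) return(empty)
  x <- array(0, c(cfg$warp_size, cfg$warp_size, nrow(props), 3L))
  for (j in seq_len(nrow(props))) {
    x[, , j, ] <- warp_crop(tile, props[j, ], cfg$warp_size)
  }
  bf <- backbone_features(detector$layers, x, train = FALSE)
  if (cfg$classifier == "svm") {
    Xs <- sweep(sweep(bf$feats, 2, detector$feat_mu), 2, detector$feat_sd, "/")
    dv <- attr(stats::predict(detector$svm, Xs, decision.values = TRUE),
               "decision.values")[, 1]
    conf <- 1 / (1 + exp(-detector$svm_sign * dv))
  } else {
    logits <- bf$feats %*% detector$headW +
      matrix(detector$headb, nrow(bf$feats), 2L, byrow = TRUE)
    conf <- nn_softmax_ce(logits, rep(1L, nrow(logits)))$p[, 2]
  }
  keep <- conf >= score_threshold
  if (!any(keep)) return(empty)
  boxes <- props[keep, ]
  conf <- conf[keep]
  if (cfg$use_bbox_regression) {
    Xs <- sweep(sweep(bf$feats[keep, , drop = FALSE], 2, detector$feat_mu),
                2, detector$feat_sd, "/")
    deltas <- cbind(1, Xs) %*% detector$bbox_B
    d <- dim(tile)
    for (j in seq_len(nrow(boxes))) {
      nb <- apply_bbox_regression(boxes[j, ], deltas[j, ])
      boxes$x0[j] <- max(0, nb[1]); boxes$y0[j] <- max(0, nb[2])
      boxes$x1[j] <- min(d[2], nb[3]); boxes$y1[j] <- min(d[1], nb[4])
    }
    ok <- boxes$x1 > boxes$x0 & boxes$y1 > boxes$y0
    boxes <- boxes[ok, ]; conf <- conf[ok]
  }
  if (nrow(boxes) == 0L) return(empty)
  boxes$confidence <- conf
  nms(boxes, nms_iou)
}
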