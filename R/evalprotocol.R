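#' @title Center-distance detection scoring
#' @name evalprotocol
#' @description
#' ICPR-contest-style evaluation: a detection counts as a true positive if
#' its center (the diagonal intersection of its bounding box) lies within
#' 8 micrometers of an unclaimed ground-truth mitosis center; precision,
#' recall and F1 are computed from the resulting confusion counts.
NULL

#' Resolution specification
#'
#' Converts the physical 8 um match criterion into pixels:
#' `pixel radius = match_radius_um / microns_per_pixel`.
#'
#' @param microns_per_pixel scan resolution, microns per pixel (> 0); e.g.
#'   0.25 for an Aperio Scanscope XT, 0.2455 for a Hamamatsu Nanozoomer.
#' @param match_radius_um matching radius in micrometers (default 8).
#' @return a `resolution_spec` list with the derived `radius_px`.
#' @export
resolution_spec <- function(microns_per_pixel, match_radius_um = 8) {
  if (!(microns_per_pixel > 0)) stop("`microns_per_pixel` must be > 0")
  if (!(match_radius_um > 0)) stop("`match_radius_um` must be > 0")
  structure(list(microns_per_pixel = microns_per_pixel,
                 match_radius_um = match_radius_um,
                 radius_px = match_radius_um / microns_per_pixel),
            class = "resolution_spec")
}

#' Center of a bounding box
#'
#' The diagonal intersection of the box, in continuous pixel coordinates.
#'
#' @param box box as `c(x0, y0, x1, y1)` or a data frame of boxes.
#' @return `c(x, y)` for a single box, or a tibble `(x, y)` for several.
#' @export
box_center <- function(box) {
  if (is.data.frame(box) && nrow(box) != 1L) {
    return(tibble::tibble(x = (box$x0 + box$x1) / 2,
                          y = (box$y0 + box$y1) / 2))
  }
  b <- box_vec(box)
  c(x = (b[1] + b[3]) / 2, y = (b[2] + b[4]) / 2)
}

#' Match detections to ground-truth mitosis centers
#'
#' Greedy one-to-one matching: detections are visited in descending
#' confidence order and each claims the nearest unclaimed ground-truth point
#' within the match radius. Matched detections are true positives, the rest
#' false positives; unclaimed ground-truth points are false negatives, so
#' `tp + fn = |gt|` and `tp + fp = |detections|` always.
#'
#' @param detections tibble with `x0, y0, x1, y1` (and optionally
#'   `confidence`; missing confidence ranks in input order) or with center
#'   columns `x, y`.
#' @param gt_points tibble of ground-truth centers `(x, y)`.
#' @param res a [resolution_spec()].
#' @return list with `counts` (tibble `tp, fp, fn`) and `matches` (tibble:
#'   one row per detection with its matched gt index, distance in px and um,
#'   and `matched` flag).
#' @export
match_detections <- function(detections, gt_points, res) {
  if (!inherits(res, "resolution_spec")) {
    stop("`res` must be a resolution_spec()")
  }
  detections <- tibble::as_tibble(detections)
  nd <- nrow(detections)
  if (nd > 0L && !all(c("x", "y") %in% names(detections))) {
    cen <- box_center(detections[, c("x0", "y0", "x1", "y1")])
    if (nd == 1L) cen <- tibble::tibble(x = cen[["x"]], y = cen[["y"]])
    detections$x <- cen$x
    detections$y <- cen$y
  }
  col_or <- function(nm, default) {
    if (nm %in% names(detections)) detections[[nm]] else default
  }
  conf <- col_or("confidence", rep(NA_real_, nd))
  ord <- if (all(is.na(conf))) seq_len(nd) else order(-conf)
  ng <- NROW(gt_points)
  claimed <- logical(ng)
  match_idx <- rep(NA_integer_, nd)
  dist_px <- rep(NA_real_, nd)
  for (i in ord) {
    if (ng == 0L) break
    dd <- sqrt((gt_points$x - detections$x[i])^2 +
               (gt_points$y - detections$y[i])^2)
    dd[claimed] <- Inf
    j <- which.min(dd)
    if (length(j) && is.finite(dd[j]) && dd[j] <= res$radius_px) {
      claimed[j] <- TRUE
      match_idx[i] <- j
      dist_px[i] <- dd[j]
    }
  }
  tp <- sum(!is.na(match_idx))
  counts <- tibble::tibble(tp = tp, fp = nd - tp, fn = ng - tp)
  matches <- tibble::tibble(
    detection = seq_len(nd),
    confidence = conf,
    x = col_or("x", numeric(0)), y = col_or("y", numeric(0)),
    gt_index = match_idx,
    dist_px = dist_px,
    dist_um = dist_px * res$microns_per_pixel,
    matched = !is.na(match_idx))
  list(counts = counts, matches = matches)
}

#' Precision, recall and F1 from confusion counts
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2 * Recall * Precision / (Recall + Precision)`.
#' With no detections (TP+FP = 0) precision is undefined and reported as 0
#' with `precision_defined = FALSE`, so batch evaluation never aborts.
#'
#' @param counts tibble or list with `tp`, `fp`, `fn`.
#' @return a one-row tibble of class `mito_metrics`:
#'   `tp, fp, fn, precision, recall, f1, precision_defined`.
#' @examples
#' compute_metrics(list(tp = 3, fp = 1, fn = 2))  # P=0.75 R=0.6 F1=2/3
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp == 0 && fp == 0 && fn == 0) {
    stop("all counts are zero; metrics are undefined")
  }
  prec_def <- (tp + fp) > 0
  precision <- if (prec_def) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  out <- tibble::tibble(tp = tp, fp = fp, fn = fn,
                        precision = precision, recall = recall,
                        f1 = f1_from_pr(recall, precision),
                        precision_defined = prec_def)
  class(out) <- c("mito_metrics", class(out))
  if (!prec_def) {
    warning("no detections: precision undefined, reported as 0")
  }
  out
}

#' F1 score from recall and precision
#'
#' Harmonic combination `2 * R * P / (R + P)`; symmetric in its arguments;
#' defined as 0 when both are 0.
#'
#' @param recall,precision scalars in `[0, 1]`.
#' @return scalar F1 in `[0, 1]`.
#' @examples
#' f1_from_pr(0.766, 0.843)  # 0.803 at 3 decimals
#' @export
f1_from_pr <- function(recall, precision) {
  stopifnot(recall >= 0, recall <= 1, precision >= 0, precision <= 1)
  ifelse(recall + precision == 0, 0,
         2 * recall * precision / (recall + precision))
}

#' Evaluate detections against weak-label ground truth
#'
#' Convenience wrapper: [match_detections()] then [compute_metrics()].
#' With lists of per-tile detections/ground truth, counts are pooled across
#' tiles before computing metrics (`aggregate = "pooled"`), or per-tile
#' metrics are macro-averaged (`aggregate = "macro"`).
#'
#' @param detections tibble, or list of tibbles (one per tile).
#' @param gt_points tibble `(x, y)`, or list of tibbles.
#' @param res a [resolution_spec()].
#' @param aggregate `"pooled"` (default) or `"macro"`.
#' @return a `mito_metrics` tibble (for macro: mean precision/recall/f1 with
#'   summed counts).
#' @export
evaluate_detections <- function(detections, gt_points, res,
                                aggregate = c("pooled", "macro")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(detections)) detections <- list(detections)
  if (is.data.frame(gt_points)) gt_points <- list(gt_points)
  stopifnot(length(detections) == length(gt_points))
  per <- mapply(function(d, g) match_detections(d, g, res)$counts,
                detections, gt_points, SIMPLIFY = FALSE)
  counts <- do.call(rbind, per)
  if (aggregate == "pooled") {
    return(compute_metrics(list(tp = sum(counts$tp), fp = sum(counts$fp),
                                fn = sum(counts$fn))))
  }
  ms <- lapply(seq_len(nrow(counts)), function(i) {
    suppressWarnings(compute_metrics(counts[i, ]))
  })
  m <- do.call(rbind, ms)
  out <- tibble::tibble(tp = sum(counts$tp), fp = sum(counts$fp),
                        fn = sum(counts$fn),
                        precision = mean(m$precision), recall = mean(m$recall),
                        f1 = mean(m$f1),
                        precision_defined = all(m$precision_defined))
  class(out) <- c("mito_metrics", class(out))
  out
}
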