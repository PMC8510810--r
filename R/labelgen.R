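#' @title Weak-to-strong label generation
#' @name labelgen
#' @description
#' Converts a predicted mitosis probability map plus weak centre-point
#' annotations into bounding-box "strong" labels: the map is thresholded,
#' 8-connected components are extracted, each component's minimum
#' circumscribed (axis-aligned) rectangle becomes a candidate box, and a box
#' is positive iff a weak label falls inside it.
#'
#' Coordinate convention (package-wide): 0-based, `x` = column, `y` = row;
#' boxes are half-open `[x0, x1) x [y0, y1)`.
NULL

new_boxes <- function(x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), ...) {
  tibble::tibble(x0 = x0, y0 = y0, x1 = x1, y1 = y1, ...)
}

validate_boxes <- function(boxes, where = "boxes") {
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(boxes))) {
    stop(where, " must have columns x0, y0, x1, y1")
  }
  bad <- which(boxes$x1 <= boxes$x0 | boxes$y1 <= boxes$y0)
  if (length(bad)) {
    stop(where, ": degenerate box (x1 <= x0 or y1 <= y0) at row ",
         bad[1])
  }
  invisible(boxes)
}

#' Threshold a probability map into a binary mitosis mask
#'
#' @param probmap a [probability_map][softmax_pixelwise()] or `(H, W, K)`
#'   array; the mitosis class is channel 2 (class index 1).
#' @param threshold scalar in (0, 1); pixels with mitosis probability
#'   `>= threshold` become foreground.
#' @return logical `(H, W)` matrix.
#' @export
binarize_probmap <- function(probmap, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  probs <- if (inherits(probmap, "probability_map")) probmap$probs else probmap
  p_mit <- if (length(dim(probs)) == 3L) probs[, , 2L] else probs
  p_mit >= threshold
}

#' Extract 8-connected components from a binary mask
#'
#' Components smaller than `min_area` pixels are dropped.
#'
#' @param mask logical or 0/1 matrix, `mask[y + 1, x + 1]` indexing.
#' @param min_area minimum pixel count for a component to be kept
#'   (default 5).
#' @return list of tibbles with 0-based integer columns `x`, `y`, ordered by
#'   first (row-major) pixel.
#' @export
extract_components <- function(mask, min_area = 5L) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  id <- matrix(NA_integer_, H, W)
  id[fg] <- seq_along(fg)
  edges <- list()
  # neighbour offsets covering the 8-neighbourhood once: (dr, dc)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    r1 <- max(1L, 1L - o[1]):min(H, H - o[1])
    c1 <- max(1L, 1L - o[2]):min(W, W - o[2])
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + o[1], c1 + o[2], drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_along(fg)]
  } else {
    memb <- seq_along(fg)
  }
  rows <- ((fg - 1L) %% H)       # 0-based y
  cols <- ((fg - 1L) %/% H)      # 0-based x
  comps <- split(seq_along(fg), memb)
  out <- lapply(comps, function(i) {
    tibble::tibble(x = as.integer(cols[i]), y = as.integer(rows[i]))
  })
  out <- unname(out[vapply(out, nrow, 0L) >= min_area])
  # deterministic order: by first pixel in column-major scan
  firsts <- vapply(out, function(d) min(d$y + d$x * H), numeric(1))
  out[order(firsts)]
}

#' Minimum circumscribed rectangle of a pixel component
#'
#' The tightest axis-aligned box containing every pixel of the component.
#'
#' @param component tibble/data.frame with 0-based `x`, `y` pixel columns.
#' @return one-row tibble `(x0, y0, x1, y1)`, half-open.
#' @examples
#' min_bounding_rect(data.frame(x = c(0, 0, 0, 1), y = c(0, 1, 2, 2)))
#' @export
min_bounding_rect <- function(component) {
  if (NROW(component) == 0L) stop("empty component has no bounding rectangle")
  new_boxes(x0 = min(component$x), y0 = min(component$y),
            x1 = max(component$x) + 1L, y1 = max(component$y) + 1L)
}

box_contains_point <- function(boxes, px, py) {
  # boundary-inclusive on the closed pixel extent [x0, x1-1] x [y0, y1-1]
  px >= boxes$x0 & px <= boxes$x1 - 1 & py >= boxes$y0 & py <= boxes$y1 - 1
}

#' Assign weak centre-point labels to candidate boxes
#'
#' A box is positive iff at least one weak label lies within it
#' (boundary-inclusive on the box's pixel extent). Each point matches at most
#' one box: among boxes containing it, the one with the nearest centre, ties
#' broken by smaller area then lower row order. Boxes claimed by no point are
#' negative candidates; points inside no box are reported unmatched.
#'
#' @param boxes tibble with columns `x0, y0, x1, y1`.
#' @param points tibble with columns `x`, `y` (weak labels).
#' @return the `boxes` tibble with added columns `positive` (logical),
#'   `point_x`, `point_y` (first matched weak label, NA when negative), and
#'   attribute `unmatched_points`: tibble of points inside no box.
#' @export
assign_weak_labels <- function(boxes, points) {
  boxes <- tibble::as_tibble(boxes)
  nb <- nrow(boxes)
  res <- boxes
  res$positive <- logical(nb)
  res$point_x <- rep(NA_real_, nb)
  res$point_y <- rep(NA_real_, nb)
  unmatched <- tibble::tibble(x = numeric(0), y = numeric(0))
  np <- NROW(points)
  if (nb > 0L && np > 0L) {
    cx <- (boxes$x0 + boxes$x1) / 2
    cy <- (boxes$y0 + boxes$y1) / 2
    area <- (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)
    for (i in seq_len(np)) {
      px <- points$x[i]; py <- points$y[i]
      inside <- which(box_contains_point(boxes, px, py))
      if (length(inside) == 0L) {
        unmatched <- tibble::add_row(unmatched, x = px, y = py)
        next
      }
      d2 <- (cx[inside] - px)^2 + (cy[inside] - py)^2
      best <- inside[order(d2, area[inside], inside)][1]
      if (!res$positive[best]) {
        res$positive[best] <- TRUE
        res$point_x[best] <- px
        res$point_y[best] <- py
      }
    }
  } else if (np > 0L) {
    unmatched <- tibble::as_tibble(points[, c("x", "y")])
  }
  attr(res, "unmatched_points") <- unmatched
  res
}

#' Generate bounding-box strong labels from a probability map
#'
#' The full phase-1 output: threshold the map, extract 8-connected
#' components, take each component's minimum circumscribed rectangle, and
#' mark rectangles containing a weak label as positive.
#'
#' @param probmap a [probability_map][softmax_pixelwise()] or binary mask
#'   matrix (already thresholded).
#' @param weak_labels tibble with `x`, `y` columns.
#' @param threshold binarization threshold (default 0.5).
#' @param min_area minimum component area in pixels (default 5).
#' @return list with `boxes` (labelled boxes tibble, see
#'   [assign_weak_labels()]) and `unmatched_points` (weak labels the
#'   segmentation missed).
#' @export
generate_strong_labels <- function(probmap, weak_labels,
                                   threshold = 0.5, min_area = 5L) {
  mask <- if (is.matrix(probmap) && (is.logical(probmap) ||
                                     all(probmap %in% c(0, 1)))) {
    probmap > 0
  } else {
    binarize_probmap(probmap, threshold)
  }
  comps <- extract_components(mask, min_area)
  boxes <- if (length(comps)) {
    do.call(rbind, lapply(comps, min_bounding_rect))
  } else {
    new_boxes()
  }
  labelled <- assign_weak_labels(boxes, weak_labels)
  list(boxes = labelled,
       unmatched_points = attr(labelled, "unmatched_points"))
}
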