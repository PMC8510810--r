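# Independent brute-force oracles used across test files. These deliberately
# re-derive results from first principles rather than calling package code.

# full n x n periodized orthonormal analysis matrix built directly from the
# filter definition (rows: low-pass then high-pass, stride-2 placement)
oracle_wavelet_matrix <- function(n, lo) {
  m <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(m) - 1)
  W <- matrix(0, n, n)
  for (k in seq_len(n %/% 2)) {
    for (j in seq_len(m)) {
      col <- ((2 * k - 2 + j - 1) %% n) + 1
      W[k, col] <- W[k, col] + lo[j]
      W[n %/% 2 + k, col] <- W[n %/% 2 + k, col] + hi[j]
    }
  }
  W
}

oracle_haar_subbands <- function(X) {
  n <- nrow(X); w <- ncol(X)
  Wh <- oracle_wavelet_matrix(n, c(1, 1) / sqrt(2))
  Ww <- oracle_wavelet_matrix(w, c(1, 1) / sqrt(2))
  Y <- Wh %*% X %*% t(Ww)
  h <- n %/% 2; v <- w %/% 2
  list(ll = Y[1:h, 1:v, drop = FALSE], lh = Y[1:h, (v + 1):w, drop = FALSE],
       hl = Y[(h + 1):n, 1:v, drop = FALSE],
       hh = Y[(h + 1):n, (v + 1):w, drop = FALSE])
}

# stack-based 8-connected flood fill; returns label matrix (0 = background)
oracle_flood_fill <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- nxt
      r <- ((p - 1L) %% H) + 1L; c <- ((p - 1L) %/% H) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          stack <- c(stack, (cc - 1L) * H + rr)
        }
      }
    }
  }
  lab
}

# exhaustive maximum one-to-one matching within a radius (branch and bound)
oracle_optimal_tp <- function(det_xy, gt_xy, radius) {
  nd <- nrow(det_xy); ng <- nrow(gt_xy)
  if (nd == 0 || ng == 0) return(0L)
  D <- outer(seq_len(nd), seq_len(ng), function(i, j) {
    sqrt((det_xy$x[i] - gt_xy$x[j])^2 + (det_xy$y[i] - gt_xy$y[j])^2)
  })
  ok <- D <= radius
  best <- 0L
  rec <- function(i, used, cnt) {
    if (cnt + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, cnt); return() }
    rec(i + 1L, used, cnt)
    for (j in which(ok[i, ])) {
      if (!used[j]) { u <- used; u[j] <- TRUE; rec(i + 1L, u, cnt + 1L) }
    }
  }
  rec(1L, rep(FALSE, ng), 0L)
  best
}

# IoU by counting covered integer pixel cells on a discrete grid
oracle_pixel_iou <- function(a, b) {
  lim <- max(a, b) + 1
  g <- expand.grid(x = 0:lim, y = 0:lim)
  ina <- g$x >= a[1] & g$x < a[3] & g$y >= a[2] & g$y < a[4]
  inb <- g$x >= b[1] & g$x < b[3] & g$y >= b[2] & g$y < b[4]
  sum(ina & inb) / sum(ina | inb)
}

# naive elementwise cross-entropy loop
oracle_cross_entropy <- function(probs, labels) {
  total <- 0
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      total <- total - log(probs[i, j, labels[i, j] + 1])
    }
  }
  total
}

# brute-force greedy NMS written as an explicit pairwise suppression table
oracle_nms_keep <- function(boxes, conf, thr) {
  ord <- order(-conf)
  keep <- integer(0)
  for (i in ord) {
    suppressed <- FALSE
    for (k in keep) {
      if (oracle_pixel_iou_cont(boxes[i, ], boxes[k, ]) > thr) {
        suppressed <- TRUE
        break
      }
    }
    if (!suppressed) keep <- c(keep, i)
  }
  sort(keep)
}

oracle_pixel_iou_cont <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / un
}

# small synthetic training set shared by the slower fixtures
make_tiny_tiles <- function(n, tile_size = 48, seed0 = 0, n_mitoses = c(2, 3),
                            ...) {
  tiles <- list(); masks <- list(); weak <- list(); boxes <- list()
  for (i in seq_len(n)) {
    tl <- generate_tile(synth_config(tile_size = tile_size,
                                     n_mitoses = n_mitoses,
                                     seed = seed0 + i, ...))
    tiles[[i]] <- tl$image; masks[[i]] <- tl$mask
    weak[[i]] <- tl$weak_labels; boxes[[i]] <- tl$boxes
  }
  list(tiles = tiles, masks = masks, weak = weak, boxes = boxes)
}
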