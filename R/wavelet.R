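#' @title Single-level 2-D discrete wavelet transform
#' @name wavelet
#' @description
#' Orthonormal single-level 2-D DWT/IWT used as the down- and up-sampling
#' operators of the segmentation network. The transform splits a plane into
#' four half-resolution subbands (ll, lh, hl, hh) and reconstructs exactly.
#' Filters are periodized, so input spatial dimensions must be even.
NULL

# registered orthonormal filter pairs (analysis low-pass; high-pass by QMF)
.wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
)

wavelet_lowpass <- function(wavelet_name) {
  lo <- .wavelet_filters[[wavelet_name]]
  if (is.null(lo)) {
    stop("unknown wavelet '", wavelet_name, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  lo
}

# n x n orthogonal analysis matrix for a periodized filter bank:
# rows 1..n/2 are the low-pass rows, rows n/2+1..n the high-pass rows.
# Cached per (n, wavelet) since training re-applies the same sizes.
.wavelet_cache <- new.env(parent = emptyenv())

wavelet_matrix <- function(n, wavelet_name = "haar") {
  key <- paste0(wavelet_name, ":", n)
  W <- .wavelet_cache[[key]]
  if (!is.null(W)) return(W)
  lo <- wavelet_lowpass(wavelet_name)
  m <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(m) - 1)  # quadrature mirror filter
  half <- n %/% 2L
  W <- matrix(0, n, n)
  for (k in seq_len(half)) {
    idx <- ((2L * k - 2L + seq_len(m) - 1L) %% n) + 1L
    for (j in seq_len(m)) {
      W[k, idx[j]] <- W[k, idx[j]] + lo[j]
      W[half + k, idx[j]] <- W[half + k, idx[j]] + hi[j]
    }
  }
  .wavelet_cache[[key]] <- W
  W
}

.check_even <- function(d, axis) {
  if (d %% 2L != 0L) {
    stop("spatial dimension along ", axis, " axis is odd (", d,
         "); pad to even size before the transform", call. = FALSE)
  }
}

# core 2-D transform of an (H, W) plane stacked over trailing dims:
# x is (H, W, ...) flattened to (H, W, S); returns same shape transformed.
.wt2_core <- function(x, Wh, Ww, inverse = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; S <- prod(d[-(1:2)])
  if (inverse) { Ah <- t(Wh); Aw <- t(Ww) } else { Ah <- Wh; Aw <- Ww }
  y <- Ah %*% matrix(x, H, W * S)                 # rows (vertical axis)
  dim(y) <- c(H, W, S)
  y <- aperm(y, c(2L, 1L, 3L))
  y <- Aw %*% matrix(y, W, H * S)                 # columns (horizontal axis)
  dim(y) <- c(W, H, S)
  y <- aperm(y, c(2L, 1L, 3L))
  dim(y) <- d
  y
}

#' Single-level 2-D DWT
#'
#' Decomposes a 2-D or 3-D (multi-channel, `(H, W, C)`) real array into four
#' half-resolution subbands with an orthonormal periodized filter bank.
#' Orthonormal scaling is used, so the sum of squared coefficients equals the
#' sum of squared inputs.
#'
#' Subband naming: the first letter is the filter applied along rows
#' (vertical, y), the second along columns (horizontal, x); `lh` is therefore
#' vertically smooth / horizontally detailed.
#'
#' @param plane 2-D `(H, W)` or 3-D `(H, W, C)` numeric array; `H` and `W`
#'   must be even.
#' @param wavelet_name registered filter name, `"haar"` (default) or `"db2"`.
#' @return An object of class `subband_set`: list with `ll`, `lh`, `hl`, `hh`
#'   (each `(H/2, W/2[, C])`) and `wavelet_name`.
#' @examples
#' s <- dwt2(matrix(1:16, 4, 4))
#' max(abs(iwt2(s) - matrix(1:16, 4, 4)))  # ~1e-16
#' @seealso [iwt2()]
#' @export
dwt2 <- function(plane, wavelet_name = "haar") {
  stopifnot(is.numeric(plane))
  twod <- length(dim(plane)) < 3L
  if (is.null(dim(plane))) stop("`plane` must be a matrix or 3-D array")
  if (twod) dim(plane) <- c(dim(plane), 1L)
  d <- dim(plane)
  .check_even(d[1], "row (y)")
  .check_even(d[2], "column (x)")
  Wh <- wavelet_matrix(d[1], wavelet_name)
  Ww <- wavelet_matrix(d[2], wavelet_name)
  y <- .wt2_core(plane, Wh, Ww)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  sub <- function(ri, ci) {
    out <- y[ri, ci, , drop = FALSE]
    if (twod) dim(out) <- c(h2, w2)
    out
  }
  structure(
    list(ll = sub(1:h2, 1:w2),
         lh = sub(1:h2, (w2 + 1):d[2]),
         hl = sub((h2 + 1):d[1], 1:w2),
         hh = sub((h2 + 1):d[1], (w2 + 1):d[2]),
         wavelet_name = wavelet_name),
    class = "subband_set")
}

#' Single-level 2-D inverse DWT
#'
#' Exact inverse of [dwt2()]: reassembles the four subbands and reconstructs
#' the plane at doubled spatial resolution.
#'
#' @param subbands a `subband_set` as returned by [dwt2()], or a list with
#'   elements `ll`, `lh`, `hl`, `hh` (and optionally `wavelet_name`).
#' @param wavelet_name filter name; defaults to the one recorded in
#'   `subbands`.
#' @return numeric array of shape `(2H, 2W[, C])`.
#' @export
iwt2 <- function(subbands, wavelet_name = NULL) {
  need <- c("ll", "lh", "hl", "hh")
  if (!all(need %in% names(subbands))) {
    stop("`subbands` must contain ll, lh, hl and hh planes")
  }
  if (is.null(wavelet_name)) {
    wavelet_name <- subbands$wavelet_name %||% "haar"
  }
  dims <- lapply(subbands[need], function(p) dim(p) %||% length(p))
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("subband shapes differ: ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
               collapse = ", "))
  }
  ll <- subbands$ll
  twod <- length(dim(ll)) < 3L
  planes <- subbands[need]
  if (twod) planes <- lapply(planes, function(p) {
    if (is.null(dim(p))) stop("subbands must be matrices or 3-D arrays")
    array(p, c(dim(p), 1L))
  })
  d <- dim(planes$ll)
  H <- 2L * d[1]; W <- 2L * d[2]
  y <- array(0, c(H, W, d[3]))
  y[1:d[1], 1:d[2], ] <- planes$ll
  y[1:d[1], (d[2] + 1):W, ] <- planes$lh
  y[(d[1] + 1):H, 1:d[2], ] <- planes$hl
  y[(d[1] + 1):H, (d[2] + 1):W, ] <- planes$hh
  Wh <- wavelet_matrix(H, wavelet_name)
  Ww <- wavelet_matrix(W, wavelet_name)
  out <- .wt2_core(y, Wh, Ww, inverse = TRUE)
  if (twod) dim(out) <- c(H, W)
  out
}

#' @export
print.subband_set <- function(x, ...) {
  d <- dim(x$ll) %||% length(x$ll)
  cat("<subband_set> wavelet:", x$wavelet_name,
      " subband shape:", paste(d, collapse = "x"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tensor variants used inside the network (layout H, W, N, C) ----------

# DWT that stacks the four subbands channel-wise: (H,W,N,C) -> (H/2,W/2,N,4C)
# channel order: [ll(1..C), lh(1..C), hl(1..C), hh(1..C)]
dwt2_stack <- function(x, wavelet_name = "haar") {
  d <- dim(x)
  Wh <- wavelet_matrix(d[1], wavelet_name)
  Ww <- wavelet_matrix(d[2], wavelet_name)
  y <- .wt2_core(x, Wh, Ww)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  out <- array(0, c(h2, w2, d[3], 4L * d[4]))
  C <- d[4]
  out[, , , 1:C]             <- y[1:h2, 1:w2, , , drop = FALSE]
  out[, , , (C + 1):(2 * C)] <- y[1:h2, (w2 + 1):d[2], , , drop = FALSE]
  out[, , , (2 * C + 1):(3 * C)] <- y[(h2 + 1):d[1], 1:w2, , , drop = FALSE]
  out[, , , (3 * C + 1):(4 * C)] <- y[(h2 + 1):d[1], (w2 + 1):d[2], , , drop = FALSE]
  out
}

# inverse of dwt2_stack: (H,W,N,4C) -> (2H,2W,N,C)
iwt2_stack <- function(x, wavelet_name = "haar") {
  d <- dim(x)
  C <- d[4] %/% 4L
  H <- 2L * d[1]; W <- 2L * d[2]
  y <- array(0, c(H, W, d[3], C))
  y[1:d[1], 1:d[2], , ]           <- x[, , , 1:C, drop = FALSE]
  y[1:d[1], (d[2] + 1):W, , ]     <- x[, , , (C + 1):(2 * C), drop = FALSE]
  y[(d[1] + 1):H, 1:d[2], , ]     <- x[, , , (2 * C + 1):(3 * C), drop = FALSE]
  y[(d[1] + 1):H, (d[2] + 1):W, , ] <- x[, , , (3 * C + 1):(4 * C), drop = FALSE]
  Wh <- wavelet_matrix(H, wavelet_name)
  Ww <- wavelet_matrix(W, wavelet_name)
  .wt2_core(y, Wh, Ww, inverse = TRUE)
}
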