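#' @title File formats
#' @name io
#' @description
#' Readers and writers for the CSV dialects shared by all stages. All
#' coordinates in files are 0-based with `x` = column and `y` = row; boxes
#' are half-open. Weak-label CSVs follow the ICPR contest dialect: one
#' mitosis per line, `x,y[,...]`, no header; extra columns are ignored.
NULL

.split_csv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  list(lines = lines[keep], numbers = keep)
}

#' Read ICPR-style weak-label CSV
#'
#' @param path CSV file: `x,y` per row (extra columns ignored, blank lines
#'   skipped, no header expected).
#' @return tibble with numeric `x`, `y`.
#' @export
read_weak_labels <- function(path) {
  p <- .split_csv_lines(path)
  if (length(p$lines) == 0L) return(tibble::tibble(x = numeric(0),
                                                   y = numeric(0)))
  xs <- numeric(length(p$lines)); ys <- numeric(length(p$lines))
  for (i in seq_along(p$lines)) {
    parts <- strsplit(p$lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("line ", p$numbers[i], " of ", path,
           ": expected at least 2 comma-separated values")
    }
    v <- suppressWarnings(as.numeric(parts[1:2]))
    if (any(is.na(v))) {
      stop("line ", p$numbers[i], " of ", path,
           ": non-numeric coordinate '", p$lines[i], "'")
    }
    xs[i] <- v[1]; ys[i] <- v[2]
  }
  tibble::tibble(x = xs, y = ys)
}

#' Write weak labels in the ICPR dialect
#' @param path output CSV path.
#' @param points tibble with `x`, `y`.
#' @export
write_weak_labels <- function(path, points) {
  writeLines(sprintf("%s,%s", format(points$x, trim = TRUE, digits = 15),
                     format(points$y, trim = TRUE, digits = 15)), path)
  invisible(path)
}

#' Write bounding boxes as CSV
#'
#' Columns `x0,y0,x1,y1` plus, when present, `positive` (0/1) or
#' `confidence`; a header row names the columns.
#'
#' @param path output CSV path.
#' @param boxes box tibble.
#' @export
write_boxes <- function(path, boxes) {
  validate_boxes(boxes)
  cols <- c("x0", "y0", "x1", "y1",
            intersect(c("positive", "confidence"), names(boxes)))
  df <- as.data.frame(boxes)[, cols, drop = FALSE]
  if ("positive" %in% cols) df$positive <- as.integer(df$positive)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bounding-box CSV
#'
#' Accepts the dialect of [write_boxes()] (with header) or headerless
#' `x0,y0,x1,y1[,positive|confidence]` rows. Box invariants (`x1 > x0`,
#' `y1 > y0`) are enforced with the offending line number.
#'
#' @param path CSV path.
#' @return box tibble; `positive` back-converted to logical when present.
#' @export
read_boxes <- function(path) {
  p <- .split_csv_lines(path)
  if (length(p$lines) == 0L) return(new_boxes())
  first <- strsplit(p$lines[1], ",", fixed = TRUE)[[1]]
  has_header <- all(is.na(suppressWarnings(as.numeric(first))))
  header <- NULL
  if (has_header) {
    header <- trimws(first)
    p$lines <- p$lines[-1]; p$numbers <- p$numbers[-1]
  }
  if (length(p$lines) == 0L) return(new_boxes())
  rows <- lapply(seq_along(p$lines), function(i) {
    parts <- strsplit(p$lines[i], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) < 4L || any(is.na(v[1:4]))) {
      stop("line ", p$numbers[i], " of ", path, ": malformed box row '",
           p$lines[i], "'")
    }
    v
  })
  ncols <- max(vapply(rows, length, 0L))
  m <- t(vapply(rows, function(v) c(v, rep(NA_real_, ncols - length(v))),
                numeric(ncols)))
  out <- new_boxes(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4])
  bad <- which(out$x1 <= out$x0 | out$y1 <= out$y0)
  if (length(bad)) {
    stop("line ", p$numbers[bad[1]], " of ", path,
         ": invalid box (x1 <= x0 or y1 <= y0)")
  }
  if (ncols >= 5L) {
    extra <- if (!is.null(header) && length(header) >= 5L) header[5] else NULL
    if (identical(extra, "positive")) {
      out$positive <- m[, 5] != 0
    } else if (identical(extra, "confidence")) {
      out$confidence <- m[, 5]
    } else if (all(m[, 5] %in% c(0, 1))) {
      out$positive <- m[, 5] != 0
    } else {
      out$confidence <- m[, 5]
    }
  }
  out
}

#' Write detections as CSV
#'
#' Writes both the box dialect (`x0,y0,x1,y1,confidence`) and, optionally,
#' the ICPR-style center dialect (`x,y,confidence` from box centers).
#'
#' @param path output CSV path (box dialect).
#' @param detections tibble with boxes and `confidence`.
#' @param centers_path optional path for the center dialect.
#' @export
write_detections <- function(path, detections, centers_path = NULL) {
  write_boxes(path, detections)
  if (!is.null(centers_path)) {
    cen <- box_center(detections[, c("x0", "y0", "x1", "y1")])
    if (!is.data.frame(cen)) cen <- tibble::tibble(x = cen[1], y = cen[2])
    writeLines(sprintf("%s,%s,%s",
                       format(cen$x, trim = TRUE, digits = 15),
                       format(cen$y, trim = TRUE, digits = 15),
                       format(detections$confidence, trim = TRUE,
                              digits = 15)),
               centers_path)
  }
  invisible(path)
}

#' Write a metrics JSON file
#' @param path output path.
#' @param metrics a `mito_metrics` row ([compute_metrics()]).
#' @export
write_metrics <- function(path, metrics) {
  jsonlite::write_json(
    list(tp = metrics$tp, fp = metrics$fp, fn = metrics$fn,
         precision = metrics$precision, recall = metrics$recall,
         f1 = metrics$f1),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
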