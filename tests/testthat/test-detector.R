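test_that("IoU matches a pixel-counting oracle and is symmetric", {
  expect_equal(iou(c(0, 0, 4, 4), c(0, 0, 4, 4)), 1)
  expect_equal(iou(c(0, 0, 4, 4), c(10, 10, 12, 12)), 0)
  expect_equal(iou(c(0, 0, 4, 4), c(2, 2, 6, 6)), 1 / 7)
  expect_equal(iou(c(0, 0, 4, 4), c(2, 2, 6, 6)),
               oracle_pixel_iou(c(0, 0, 4, 4), c(2, 2, 6, 6)))
  set.seed(3)
  for (rep in 1:10) {
    a <- c(sample(0:10, 1), sample(0:10, 1))
    a <- c(a, a + sample(1:8, 2))
    b <- c(sample(0:10, 1), sample(0:10, 1))
    b <- c(b, b + sample(1:8, 2))
    expect_equal(iou(a, b), iou(b, a))
    expect_equal(iou(a, b), oracle_pixel_iou(a, b), tolerance = 1e-12)
  }
})

test_that("sliding-window proposals follow closed-form grid arithmetic", {
  tile <- array(0.5, c(32, 32, 3))
  p <- propose_regions(tile, "sliding_window",
                       list(windows = 16, stride = 8))
  expect_equal(nrow(p), (floor((32 - 16) / 8) + 1)^2)  # 9
  expect_true(all(p$x0 >= 0 & p$x1 <= 32 & p$y0 >= 0 & p$y1 <= 32))
  p2 <- propose_regions(tile, "sliding_window",
                        list(windows = 16, stride = 8))
  expect_identical(p, p2)
  expect_error(propose_regions(tile, "voronoi"), "arg")
})

test_that("selective search is capped, deterministic and finds a dark blob", {
  tile <- array(0.8, c(32, 32, 3))
  p <- propose_regions(tile, "selective_search",
                       list(max_proposals = 30, grid_step = 8))
  expect_lte(nrow(p), 30)
  expect_identical(p, propose_regions(tile, "selective_search",
                                      list(max_proposals = 30, grid_step = 8)))
  # one dark square on light background: some proposal overlaps it well
  tile[10:17, 12:19, ] <- 0.1
  p <- propose_regions(tile, "selective_search", list(grid_step = 4))
  gt <- tibble::tibble(x0 = 11, y0 = 9, x1 = 19, y1 = 17)
  ious <- vapply(seq_len(nrow(p)), function(i) iou(p[i, ], gt), numeric(1))
  expect_gt(max(ious), 0.5)
})

test_that("proposal labelling agrees with an exhaustive max-IoU oracle", {
  gt <- tibble::tibble(x0 = c(2, 20), y0 = c(2, 20), x1 = c(10, 28),
                       y1 = c(10, 28))
  lab <- label_proposals(gt[1, ], gt, 0.5, 0.3)
  expect_equal(nrow(lab$positives), 1)

  far <- tibble::tibble(x0 = 40, y0 = 40, x1 = 44, y1 = 44)
  lab <- label_proposals(far, gt, 0.5, 0.3)
  expect_equal(nrow(lab$negatives), 1)

  set.seed(8)
  props <- tibble::tibble(x0 = runif(10, 0, 24), y0 = runif(10, 0, 24))
  props$x1 <- props$x0 + runif(10, 2, 10)
  props$y1 <- props$y0 + runif(10, 2, 10)
  lab <- label_proposals(props, gt, 0.5, 0.3)
  for (i in seq_len(10)) {
    best <- max(iou(props[i, ], gt[1, ]), iou(props[i, ], gt[2, ]))
    inpos <- any(lab$positives$x0 == props$x0[i] &
                 lab$positives$y0 == props$y0[i])
    inneg <- any(lab$negatives$x0 == props$x0[i] &
                 lab$negatives$y0 == props$y0[i])
    expect_equal(inpos, best >= 0.5)
    expect_equal(inneg, best < 0.3)
  }
  expect_error(label_proposals(props, gt, 0.3, 0.5), "pos_iou > neg_iou")
})

test_that("minibatches always contain exactly 32 positives and 96 negatives", {
  set.seed(10)
  for (rep in 1:20) {
    np <- sample(c(1, 3, 5, 31, 32, 100, 500), 1)
    nn <- sample(c(1, 50, 96, 1000), 1)
    mb <- sample_minibatch(seq_len(np), 1000 + seq_len(nn),
                           minibatch_spec(seed = rep))
    expect_length(mb$positives, 32)
    expect_length(mb$negatives, 96)
    expect_true(all(mb$positives %in% seq_len(np)))
    expect_true(all(mb$negatives %in% (1000 + seq_len(nn))))
  }
  # replacement only when the pool is short
  mb <- sample_minibatch(1:5, 1:200, minibatch_spec(seed = 1))
  expect_setequal(unique(mb$positives), 1:5)
  mb96 <- sample_minibatch(1:100, 1:96, minibatch_spec(seed = 2))
  expect_equal(sort(mb96$negatives), 1:96)  # exact cover, no replacement
  # determinism and errors
  expect_identical(sample_minibatch(1:9, 1:9, minibatch_spec(seed = 5)),
                   sample_minibatch(1:9, 1:9, minibatch_spec(seed = 5)))
  expect_error(sample_minibatch(integer(0), 1:5, minibatch_spec()),
               "positive pool")
  expect_error(sample_minibatch(1:5, integer(0), minibatch_spec()),
               "negative pool")
})

test_that("box regression encode/decode form an exact inverse pair", {
  expect_equal(unname(bbox_regression_targets(c(0, 0, 10, 10),
                                              c(0, 0, 10, 10))),
               c(0, 0, 0, 0))
  t <- bbox_regression_targets(c(0, 0, 10, 10), c(0, 0, 20, 20))
  expect_equal(unname(t), c(0.5, 0.5, log(2), log(2)))
  expect_equal(unname(apply_bbox_regression(c(0, 0, 10, 10), t)),
               c(0, 0, 20, 20), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:20) {
    p <- c(runif(2, 0, 30), 0, 0); p[3:4] <- p[1:2] + runif(2, 1, 20)
    g <- c(runif(2, 0, 30), 0, 0); g[3:4] <- g[1:2] + runif(2, 1, 20)
    expect_equal(unname(apply_bbox_regression(p, bbox_regression_targets(p, g))),
                 unname(g), tolerance = 1e-9)
  }
  expect_error(bbox_regression_targets(c(0, 0, 0, 10), c(0, 0, 5, 5)),
               "zero-size")
})

test_that("greedy NMS matches an explicit suppression-table oracle", {
  two <- tibble::tibble(x0 = c(0, 0), y0 = c(0, 0), x1 = c(8, 8), y1 = c(8, 8),
                        confidence = c(0.9, 0.8))
  out <- nms(two, 0.3)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)

  set.seed(19)
  cand <- tibble::tibble(x0 = runif(6, 0, 20), y0 = runif(6, 0, 20))
  cand$x1 <- cand$x0 + runif(6, 4, 12)
  cand$y1 <- cand$y0 + runif(6, 4, 12)
  cand$confidence <- runif(6)
  out <- nms(cand, 0.3)
  keep <- oracle_nms_keep(as.matrix(cand[, 1:4]), cand$confidence, 0.3)
  expect_equal(nrow(out), length(keep))
  expect_setequal(out$confidence, cand$confidence[keep])
  expect_true(all(diff(out$confidence) <= 0))
})

test_that("a tiny detector trains deterministically and its loss decreases", {
  d <- make_tiny_tiles(6, tile_size = 32, seed0 = 40, n_mitoses = 2,
                       min_separation_px = 10)
  gt <- lapply(d$boxes, function(b) { b$positive <- TRUE; b })
  cfg <- detector_config(warp_size = 16, channels = c(4, 8), steps = 8,
                         lr_start = 1e-3, lr_end = 1e-4, seed = 3,
                         proposal_params = list(windows = c(8, 12),
                                                stride = 4))
  det1 <- train_detector(d$tiles, gt, cfg)
  det2 <- train_detector(d$tiles, gt, cfg)
  expect_identical(det1$layers, det2$layers)
  expect_identical(det1$bbox_B, det2$bbox_B)
  expect_lt(mean(tail(det1$history$loss, 3)), det1$history$loss[1])

  out <- detect(det1, d$tiles[[1]], score_threshold = 0.999)
  expect_true(all(c("x0", "y0", "x1", "y1", "confidence") %in% names(out)))
  blank <- array(0.85, c(32, 32, 3))
  expect_equal(nrow(detect(det1, blank, score_threshold = 0.9999)), 0)

  nogt <- lapply(gt, function(b) { b$positive <- FALSE; b })
  expect_error(train_detector(d$tiles, nogt, cfg), "no positive boxes")
})
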