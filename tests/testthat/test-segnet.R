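test_that("pixelwise softmax matches direct scalar evaluation", {
  a <- array(0, c(2, 2, 2))
  pm <- softmax_pixelwise(a)
  expect_s3_class(pm, "probability_map")
  expect_true(all(pm$probs == 0.5))

  a[1, 1, ] <- c(1, 0)
  pm <- softmax_pixelwise(a)
  expect_equal(pm$probs[1, 1, 1], exp(1) / (1 + exp(1)), tolerance = 1e-10)
  expect_equal(pm$probs[1, 1, 1], 0.7311, tolerance = 1e-4)

  set.seed(1)
  b <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_equal(softmax_pixelwise(b + 100)$probs, softmax_pixelwise(b)$probs,
               tolerance = 1e-6)
  expect_equal(apply(softmax_pixelwise(b)$probs, c(1, 2), sum),
               matrix(1, 3, 3), tolerance = 1e-12)
  b[2, 2, 1] <- NaN
  expect_error(softmax_pixelwise(b), "NaN")
})

test_that("pixelwise cross entropy matches closed form and a summation oracle", {
  K2 <- function(H, W, p) array(p, c(H, W, 2))
  expect_equal(pixelwise_cross_entropy(K2(4, 4, 1), matrix(0L, 4, 4)) +
                 pixelwise_cross_entropy(K2(4, 4, 1), matrix(1L, 4, 4)), 0)
  expect_equal(pixelwise_cross_entropy(K2(4, 4, 0.5), matrix(0L, 4, 4)),
               16 * log(2), tolerance = 1e-12)

  set.seed(5)
  raw <- array(runif(3 * 3 * 2), c(3, 3, 2))
  probs <- raw / array(rep(apply(raw, c(1, 2), sum), 2), dim(raw))
  labels <- matrix(sample(0:1, 9, TRUE), 3, 3)
  expect_equal(pixelwise_cross_entropy(probs, labels),
               oracle_cross_entropy(probs, labels), tolerance = 1e-10)

  expect_error(pixelwise_cross_entropy(probs, matrix(2L, 3, 3)), "labels")
  expect_error(pixelwise_cross_entropy(probs, matrix(0L, 2, 2)), "shape|match")
})

test_that("softmax followed by cross entropy equals log-sum-exp form", {
  set.seed(9)
  logits <- array(rnorm(4 * 6 * 3, sd = 3), c(4, 6, 3))
  labels <- matrix(sample(0:2, 24, TRUE), 4, 6)
  via_softmax <- pixelwise_cross_entropy(softmax_pixelwise(logits), labels)
  direct <- 0
  for (i in 1:4) for (j in 1:6) {
    a <- logits[i, j, ]
    direct <- direct + (log(sum(exp(a - max(a)))) + max(a) -
                          (a[labels[i, j] + 1] - max(a)) - max(a))
  }
  expect_equal(via_softmax, direct, tolerance = 1e-8)
})

test_that("network construction is shape-correct, seeded and auditable", {
  cfg <- segnet_config(levels = 1, channels = 4, classes = 2, seed = 11)
  m1 <- build_segnet(cfg)
  m2 <- build_segnet(cfg)
  expect_identical(m1$blocks, m2$blocks)

  # manual parameter audit (conv has no bias under BN; BN has gamma+beta):
  #  encoder block 3->4,4->4,4->4,4->4:  (9*3*4+8) + 3*(9*16+8)   =   572
  #  bottom block 16->16 x4:              4*(9*256+32)            =  9344
  #  decoder block 8->4,4->4,4->4,4->4:  (9*32+8) + 3*(9*16+8)    =   752
  #  1x1 head 4->2 with bias:             8 + 2                   =    10
  expect_equal(segnet_n_params(m1), 572 + 9344 + 752 + 10)

  tile <- array(runif(8 * 8 * 3), c(8, 8, 3))
  pm <- predict_probmap(m1, tile)
  expect_equal(dim(pm$probs), c(8, 8, 2))

  expect_error(segnet_config(levels = 2, channels = c(1, 2, 3)),
               "one entry per level")
  expect_warning(segnet_config(block_depth = 3), "4-layer")
})

test_that("prediction preserves arbitrary spatial shapes and is deterministic", {
  m <- build_segnet(segnet_config(levels = 2, channels = c(2, 4), seed = 2))
  for (sz in list(c(7, 9), c(63, 65), c(16, 16), c(33, 12))) {
    tile <- array(runif(prod(sz) * 3), c(sz, 3))
    pm <- predict_probmap(m, tile)
    expect_equal(dim(pm$probs), c(sz, 2))
    expect_equal(apply(pm$probs, c(1, 2), sum),
                 matrix(1, sz[1], sz[2]), tolerance = 1e-6)
  }
  tile <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_identical(predict_probmap(m, tile)$probs,
                   predict_probmap(m, tile)$probs)
  expect_error(predict_probmap(m, array(0, c(8, 8, 4))), "channels")
})

test_that("training reduces the objective, is reproducible, and segments blobs", {
  d <- make_tiny_tiles(8, tile_size = 48, seed0 = 0)
  cfg <- train_config(epochs = 25, batch_size = 4,
                      lr_start = 2e-3, lr_end = 2e-4, seed = 1)
  ncfg <- segnet_config(levels = 1, channels = 8, seed = 1)
  seg <- train_segmentation(d$tiles, d$masks, cfg, ncfg)
  expect_lt(seg$history$loss[nrow(seg$history)], seg$history$loss[1])
  # learning-rate schedule hits both endpoints, log-linearly
  expect_equal(seg$history$lr[1], 2e-3)
  expect_equal(seg$history$lr[nrow(seg$history)], 2e-4, tolerance = 1e-12)
  mid <- seg$history$lr[13]
  expect_equal(log(mid), log(2e-3) + (12 / 24) * (log(2e-4) - log(2e-3)),
               tolerance = 1e-9)

  dice <- vapply(seq_along(d$tiles), function(i) {
    pm <- predict_probmap(seg, d$tiles[[i]])
    dice_coefficient(binarize_probmap(pm, 0.5), d$masks[[i]])
  }, numeric(1))
  expect_gt(mean(dice), 0.7)

  seg2 <- train_segmentation(d$tiles, d$masks, cfg, ncfg)
  expect_equal(seg2$history$loss, seg$history$loss)

  expect_error(train_segmentation(list(), list(), cfg, ncfg), "empty")
  expect_error(train_segmentation(d$tiles[1], list(matrix(0L, 3, 3)),
                                  cfg, ncfg), "mismatch")
})
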