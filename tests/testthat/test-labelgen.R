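test_that("binarization uses the >= convention and matches elementwise compare", {
  p <- array(0, c(4, 4, 2))
  p[, , 1] <- 1
  expect_false(any(binarize_probmap(p, 0.5)))
  p[2, 3, 2] <- 0.5; p[2, 3, 1] <- 0.5
  m <- binarize_probmap(p, 0.5)
  expect_true(m[2, 3])
  expect_equal(sum(m), 1)

  set.seed(21)
  q <- array(runif(16 * 16), c(16, 16, 1))
  pm <- array(0, c(16, 16, 2)); pm[, , 2] <- q[, , 1]; pm[, , 1] <- 1 - q[, , 1]
  got <- binarize_probmap(pm, 0.3)
  for (i in 1:16) for (j in 1:16) {
    expect_identical(got[i, j], q[i, j, 1] >= 0.3)
  }
  expect_error(binarize_probmap(pm, 1.5), "threshold")
})

test_that("8-connected components match a flood-fill oracle on seeded masks", {
  # diagonal touching pixels form one component
  m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
  comps <- extract_components(m, min_area = 1)
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]), 2)

  expect_length(extract_components(matrix(0L, 5, 5)), 0)

  set.seed(33)
  for (rep in 1:25) {
    mask <- matrix(rbinom(16 * 16, 1, 0.25), 16, 16)
    lab <- oracle_flood_fill(mask)
    sizes <- tabulate(lab[lab > 0])
    comps <- extract_components(mask, min_area = 1)
    expect_length(comps, max(lab))
    expect_equal(sort(vapply(comps, nrow, 0L)), sort(sizes))
    # membership agreement: every component maps onto one oracle label
    for (cc in comps) {
      labs <- lab[cbind(cc$y + 1, cc$x + 1)]
      expect_length(unique(labs), 1)
    }
  }

  # min_area drops small components
  m2 <- matrix(0L, 8, 8); m2[1:2, 1:3] <- 1L; m2[7, 7] <- 1L
  expect_length(extract_components(m2, min_area = 5), 1)
})

test_that("minimum circumscribed rectangles are tight, by coordinate min/max", {
  b <- min_bounding_rect(data.frame(x = 3, y = 5))
  expect_equal(as.numeric(b[1, ]), c(3, 5, 4, 6))
  expect_equal((b$x1 - b$x0) * (b$y1 - b$y0), 1)

  L <- data.frame(x = c(0, 0, 0, 1), y = c(0, 1, 2, 2))
  expect_equal(as.numeric(min_bounding_rect(L)[1, ]), c(0, 0, 2, 3))

  full <- expand.grid(x = 0:3, y = 0:3)
  expect_equal(as.numeric(min_bounding_rect(full)[1, ]), c(0, 0, 4, 4))

  expect_error(min_bounding_rect(data.frame(x = numeric(0), y = numeric(0))),
               "empty")

  set.seed(44)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    comp <- data.frame(x = sample(0:31, n, TRUE), y = sample(0:31, n, TRUE))
    b <- min_bounding_rect(comp)
    expect_equal(as.numeric(b[1, ]),
                 c(min(comp$x), min(comp$y), max(comp$x) + 1, max(comp$y) + 1))
  }
})

test_that("weak labels mark boxes positive under the inclusive boundary rule", {
  boxes <- tibble::tibble(x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  r <- assign_weak_labels(boxes, tibble::tibble(x = 5, y = 5))
  expect_true(r$positive)
  r <- assign_weak_labels(boxes, tibble::tibble(x = 9, y = 9))
  expect_true(r$positive)  # last covered pixel counts
  r <- assign_weak_labels(boxes, tibble::tibble(x = 10, y = 5))
  expect_false(r$positive)  # half-open: x = 10 is outside
  expect_equal(nrow(attr(r, "unmatched_points")), 1)
})

test_that("nested-box ties resolve to the nearest centre, matching enumeration", {
  boxes <- tibble::tibble(x0 = c(0, 2, 20), y0 = c(0, 2, 20),
                          x1 = c(12, 8, 24), y1 = c(12, 8, 24))
  pts <- tibble::tibble(x = c(4, 21), y = c(4, 21))
  r <- assign_weak_labels(boxes, pts)
  # point (4,4): inside boxes 1 and 2; centres (6,6) and (5,5) -> box 2 wins
  expect_equal(r$positive, c(FALSE, TRUE, TRUE))
  # exhaustive check: the chosen box among containers has minimal distance
  centres <- cbind((boxes$x0 + boxes$x1) / 2, (boxes$y0 + boxes$y1) / 2)
  d <- sqrt((centres[, 1] - 4)^2 + (centres[, 2] - 4)^2)
  containers <- c(1, 2)
  expect_equal(which(r$positive & seq_len(3) %in% containers),
               containers[which.min(d[containers])])
  # bijection: every positive box contains its matched point
  pos <- r[r$positive, ]
  expect_true(all(pos$point_x >= pos$x0 & pos$point_x <= pos$x1 - 1 &
                  pos$point_y >= pos$y0 & pos$point_y <= pos$y1 - 1))
})

test_that("labelgen on a ground-truth mask reproduces the generator's boxes", {
  tl <- generate_tile(synth_config(seed = 12, n_mitoses = 4,
                                   min_separation_px = 18))
  comps <- extract_components(tl$mask, min_area = 1)
  expect_length(comps, 4)
  sl <- generate_strong_labels(tl$mask, tl$weak_labels)
  got <- sl$boxes[order(sl$boxes$y0, sl$boxes$x0), c("x0", "y0", "x1", "y1")]
  want <- tl$boxes[order(tl$boxes$y0, tl$boxes$x0), ]
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
  expect_true(all(sl$boxes$positive))
  expect_equal(nrow(sl$unmatched_points), 0)
})
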