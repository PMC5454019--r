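test_that("all automated methods separate a clean bimodal image", {
  set.seed(31)
  px <- matrix(10, 50, 50)
  fg <- disc_mask(50, 50, c(25, 25), 12)
  px[fg] <- 1000
  img <- channel_image(px, 12, "donor")
  for (method in c("moments", "otsu", "mean", "triangle")) {
    mask <- auto_threshold(img, method)
    expect_identical(mask$pixels, fg)
  }
})

test_that("otsu threshold maximizes between-class variance (exhaustive oracle)", {
  set.seed(32)
  px <- matrix(pmin(pmax(round(c(rnorm(700, 80, 20), rnorm(300, 700, 60))), 0), 4095),
               40, 25)
  img <- channel_image(px, 12, "donor")
  got <- auto_threshold(img, "otsu")$threshold_value
  # brute-force sweep over all candidate thresholds
  v <- as.numeric(px)
  obj_value <- function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }
  best_t <- -1; best_v <- -Inf
  for (t in 0:4094) {
    bcv <- obj_value(t)
    if (bcv > best_v) { best_v <- bcv; best_t <- t }
  }
  expect_equal(obj_value(got), obj_value(best_t))
  # cross-check against the EBImage implementation: the objective can
  # plateau across empty histogram gaps, so compare the induced masks
  eb <- EBImage::otsu(EBImage::Image(px / 4095), range = c(0, 1), levels = 4096) * 4095
  expect_identical(px > got, px > eb)
})

test_that("manual and degenerate thresholds follow their contracts", {
  px <- matrix(c(0, 3, 5, 9), 2, 2)
  img <- channel_image(px, 12, "donor")
  expect_identical(auto_threshold(img, "manual", manual_value = 0)$pixels, px > 0)
  expect_error(auto_threshold(img, "manual"), class = "fretcoloc_config_error")
  expect_error(auto_threshold(img, "frobnicate"), class = "fretcoloc_config_error")

  flat <- channel_image(const_mat(0, 5, 5), 12, "donor")
  expect_warning(empty <- auto_threshold(flat, "otsu"), "constant image")
  expect_false(any(empty$pixels))
})

test_that("watershed splits two overlapping discs with a one-pixel line", {
  m <- disc_mask(60, 60, c(30, 21), 10) | disc_mask(60, 60, c(30, 39), 10)
  obj <- watershed_split(binary_mask(m))
  expect_equal(obj$n_objects, 2L)
  lab <- obj$labels
  # separation: no two 4-adjacent pixels carry different positive labels
  horiz <- lab[, -ncol(lab)] * lab[, -1]
  vert <- lab[-nrow(lab), ] * lab[-1, ]
  expect_false(any(horiz == 2))  # labels 1*2 adjacency would multiply to 2
  expect_false(any(vert == 2))
  # conservation: no new foreground; every lost pixel lies between the labels
  expect_true(all(lab[!m] == 0))
  lost <- m & lab == 0
  expect_gt(sum(lost), 0)
  expect_lt(sum(lost), 30)
})

test_that("watershed leaves a single disc intact and handles empty masks", {
  m <- disc_mask(40, 40, c(20, 20), 9)
  obj <- watershed_split(binary_mask(m))
  expect_equal(obj$n_objects, 1L)
  expect_identical(obj$labels > 0, m)

  empty <- watershed_split(binary_mask(matrix(FALSE, 10, 10)))
  expect_equal(empty$n_objects, 0L)
})

test_that("watershed labeling is deterministic", {
  set.seed(33)
  m <- matrix(runif(2500) > 0.6, 50, 50)
  a <- watershed_split(binary_mask(m))
  b <- watershed_split(binary_mask(m))
  expect_identical(a$labels, b$labels)
})

test_that("union/intersection obey mask algebra on random pairs", {
  set.seed(34)
  for (i in 1:100) {
    a <- binary_mask(matrix(runif(400) > runif(1, 0.3, 0.9), 20, 20))
    b <- binary_mask(matrix(runif(400) > runif(1, 0.3, 0.9), 20, 20))
    u <- combine_union(a, b)
    x <- combine_intersection(a, b)
    expect_equal(sum(u$pixels) + sum(x$pixels), sum(a$pixels) + sum(b$pixels))
  }
  a <- binary_mask(disc_mask(20, 20, c(6, 6), 3))
  expect_identical(combine_union(a, a)$pixels, a$pixels)
  expect_identical(combine_intersection(a, a)$pixels, a$pixels)
  none <- binary_mask(matrix(FALSE, 20, 20))
  expect_identical(combine_union(a, none)$pixels, a$pixels)
  expect_false(any(combine_intersection(a, none)$pixels))
  small <- binary_mask(matrix(FALSE, 5, 5))
  expect_error(combine_union(a, small), class = "fretcoloc_shape_error")
})

test_that("component labeling is 8-connected, size-filtered, raster-ordered", {
  m <- matrix(FALSE, 30, 30)
  m[2:3, 2:3] <- TRUE                      # size 4
  m[10:13, 10:14] <- TRUE                  # size 20
  m[20:29, 20:29] <- TRUE                  # size 100
  obj <- label_objects(binary_mask(m), min_size = 10)
  expect_equal(obj$n_objects, 2L)
  expect_equal(sort(tabulate(obj$labels[obj$labels > 0])), c(20L, 100L))
  expect_equal(label_objects(binary_mask(m), min_size = 0)$n_objects, 3L)

  # diagonal-only contact is one 8-connected object
  d <- matrix(FALSE, 6, 6)
  d[1, 1] <- TRUE; d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(label_objects(binary_mask(d), min_size = 0)$n_objects, 1L)

  # isolated single-pixel specks disappear below min_size 2
  sp <- matrix(FALSE, 10, 10)
  sp[cbind(seq(2, 10, 2), seq(2, 10, 2))] <- TRUE
  sp[2, 8] <- TRUE
  expect_equal(label_objects(binary_mask(sp), min_size = 0)$n_objects, 6L)
  expect_equal(label_objects(binary_mask(sp), min_size = 2)$n_objects, 0L)

  # raster-scan order of top-left pixels
  two <- matrix(FALSE, 10, 10)
  two[8:9, 1:2] <- TRUE   # lower-left
  two[1:2, 7:8] <- TRUE   # upper-right: first in raster order
  lab <- label_objects(binary_mask(two), min_size = 0)$labels
  expect_equal(lab[1, 7], 1L)
  expect_equal(lab[8, 1], 2L)
})
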