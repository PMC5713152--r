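# Mask cleaning, circle Hough transform, dedup, labels and OR fusion.

test_that("clean_mask fills holes and removes specks", {
  m <- disk_mask(200, 200, 100, 100, 28)
  m[96:100, 96:100] <- 0L # a hole
  out <- clean_mask(m)
  expect_equal(out[100 + 1, 100 + 1], 1L) # hole filled
  # scale restored by the closing: area close to the original disk
  expect_equal(sum(out), sum(disk_mask(200, 200, 100, 100, 28)),
               tolerance = 0.05)

  empty <- matrix(0L, 50, 50)
  expect_equal(clean_mask(empty), empty)

  # a 5-px speck is far below the minimum component area
  speck <- disk_mask(100, 100, 50, 50, 3)
  expect_equal(sum(clean_mask(speck)), 0)
})

test_that("dilation without scale restoration never shrinks a mask", {
  set.seed(30)
  for (i in 1:5) {
    m <- disk_mask(120, 120, runif(1, 40, 80), runif(1, 40, 80),
                   runif(1, 16, 25))
    out <- clean_mask(m, restore_scale = FALSE, min_area = 0)
    expect_true(all(out >= m))
    expect_gte(sum(out), sum(m))
  }
})

test_that("canny edges of a binary disk form a thin boundary ring", {
  m <- disk_mask(120, 120, 60, 60, 35)
  e <- canny_edges(m)
  ys <- which(e == 1L, arr.ind = TRUE)
  r <- sqrt((ys[, 2] - 1 - 60)^2 + (ys[, 1] - 1 - 60)^2)
  expect_true(all(abs(r - 35) < 4))
  expect_gt(nrow(ys), 100)
})

test_that("the Hough transform recovers an ideal disk to within 2 px", {
  m <- disk_mask(240, 240, 100, 100, 40)
  got <- hough_circles(m)
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$x - 100), 2)
  expect_lt(abs(got$y - 100), 2)
  expect_lt(abs(got$r - 40), 2)

  expect_equal(nrow(hough_circles(matrix(0L, 100, 100))), 0)
  expect_error(hough_circles(m, r_min = 50, r_max = 30), "r_min")
})

test_that("two disjoint disks are both recovered and match a dense accumulator oracle", {
  m <- disk_mask(300, 420, 100, 150, 32) | disk_mask(300, 420, 300, 150, 48)
  storage.mode(m) <- "integer"
  got <- hough_circles(m)
  got <- dplyr::arrange(got, x)
  expect_equal(nrow(got), 2)
  expect_lt(max(abs(got$x - c(100, 300))), 2)
  expect_lt(max(abs(got$r - c(32, 48))), 2)

  # brute-force accumulator oracle for the strongest circle: vote every
  # edge pixel over all radii in a dense R-side accumulator
  e <- canny_edges(m)
  ep <- which(e == 1L, arr.ind = TRUE) # row, col (1-based)
  best <- c(-1, 0, 0, 0)
  for (r in 30:50) {
    acc <- matrix(0L, 300, 420)
    th <- seq(0, 2 * pi, length.out = round(2 * pi * r))
    cx <- as.integer(round(outer(ep[, 2] - 1, r * cos(th), `-`)))
    cy <- as.integer(round(outer(ep[, 1] - 1, r * sin(th), `-`)))
    ok <- cx >= 0 & cx < 420 & cy >= 0 & cy < 300
    idx <- cy[ok] + 1L + cx[ok] * 300L
    tab <- tabulate(idx, 300L * 420L)
    mx <- max(tab)
    if (mx / r > best[1] / max(best[4], 1)) {
      wi <- which.max(tab)
      best <- c(mx, (wi - 1) %/% 300, (wi - 1) %% 300, r)
    }
  }
  # the strongest oracle peak coincides with one detected circle
  d_or <- sqrt((got$x - best[2])^2 + (got$y - best[3])^2)
  expect_lt(min(d_or), 3)
  expect_lt(abs(got$r[which.min(d_or)] - best[4]), 3)
})

test_that("dedupe merges centres closer than 15 px by single linkage", {
  expect_equal(nrow(dedupe_circles(make_circles(c(0, 10), c(0, 0)))), 1)
  expect_equal(nrow(dedupe_circles(make_circles(c(0, 20), c(0, 0)))), 2)
  # chains merge transitively even though the ends are 24 px apart
  chain <- dedupe_circles(make_circles(c(0, 12, 24), c(0, 0, 0)))
  expect_equal(nrow(chain), 1)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    circ <- make_circles(runif(n, 0, 120), runif(n, 0, 120),
                         r = runif(n, 30, 50), score = runif(n, 0.5, 2))
    out <- dedupe_circles(circ)
    if (nrow(out) > 1) {
      expect_gte(min(stats::dist(cbind(out$x, out$y))), 15)
    }
    # idempotence
    expect_equal(nrow(dedupe_circles(out)), nrow(out))
    # brute-force transitive closure bounds the component count
    comp <- litchistereo:::graph_components(
      as.matrix(stats::dist(cbind(circ$x, circ$y))) < 15
    )
    expect_lte(nrow(out), max(comp))
  }
})

test_that("labels are the minimum circumscribed squares, clipped at borders", {
  lab <- circle_to_label(make_circles(100, 100, r = 40))
  expect_equal(c(lab$xmin, lab$ymin, lab$xmax, lab$ymax), c(60, 60, 140, 140))
  verts <- label_vertices(lab)
  expect_equal(nrow(verts), 4)

  clipped <- circle_to_label(make_circles(10, 10, r = 30),
                             image_size = c(640, 480))
  expect_equal(c(clipped$xmin, clipped$ymin), c(0, 0))

  set.seed(32)
  circ <- make_circles(runif(10, 100, 500), runif(10, 100, 380),
                       r = runif(10, 30, 50))
  lab <- circle_to_label(circ)
  expect_equal((lab$xmax - lab$xmin) * (lab$ymax - lab$ymin), (2 * circ$r)^2)
})

test_that("OR fusion keeps a fruit found by any single classifier", {
  a <- make_circles(100, 100, source = "bayes")
  empty <- a[0, ]
  fused <- fuse_detections(list(empty, a, empty, empty))
  expect_equal(nrow(fused), 1)
  expect_equal(fused$source, "fused")

  # four agreeing detections collapse to one
  four <- lapply(c(0, 4, -4, 6), function(dx) make_circles(100 + dx, 100))
  expect_equal(nrow(fuse_detections(four)), 1)

  set.seed(33)
  lists <- lapply(1:4, function(i) {
    n <- sample(0:5, 1)
    make_circles(runif(n, 0, 300), runif(n, 0, 300), r = runif(n, 30, 50),
                 score = runif(n, 0.5, 1))
  })
  fused <- fuse_detections(lists)
  oracle <- dedupe_circles(dplyr::bind_rows(lists))
  expect_equal(nrow(fused), nrow(oracle))
  expect_equal(fused[order(fused$x), c("x", "y", "r")],
               oracle[order(oracle$x), c("x", "y", "r")])
})
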