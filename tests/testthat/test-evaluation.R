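# Recognition scoring, metric formulas and the CHT matching baseline.

test_that("disk intersection area matches a grid-counting oracle", {
  cases <- list(c(30, 30, 0), c(30, 30, 20), c(30, 50, 70), c(40, 20, 10),
                c(35, 35, 80))
  for (cs in cases) {
    got <- circle_intersection_area(cs[1], cs[2], cs[3])
    xs <- seq(-90, 160, by = 0.5)
    grid <- expand.grid(x = xs, y = xs)
    inside <- (grid$x^2 + grid$y^2 <= cs[1]^2) &
      ((grid$x - cs[3])^2 + grid$y^2 <= cs[2]^2)
    expect_equal(got, sum(inside) * 0.25, tolerance = 0.02 + 1e-6)
  }
})

truth_from_circles <- function(x, y, r, cluster_id) {
  fruits <- tibble::tibble(
    fruit_id = seq_along(x), cluster_id = cluster_id,
    x = x, y = y, r = r, depth = 1500, disparity = 100,
    x_right = x - 100, occluded = FALSE
  )
  clusters <- dplyr::group_by(fruits, cluster_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      category = factor(ifelse(dplyr::n() == 1, "A",
                               ifelse(dplyr::n() == 2, "B", "C")),
                        levels = c("A", "B", "C")),
      xmin = min(x - r), ymin = min(y - r),
      xmax = max(x + r), ymax = max(y + r),
      depth = 1500, disparity = 100, occluded = FALSE,
      .groups = "drop"
    ) |>
    dplyr::mutate(u = (xmin + xmax) / 2, v = (ymin + ymax) / 2)
  list(fruits = fruits, clusters = clusters)
}

test_that("perfect detections give TP = n, FP = 0, FN = 0", {
  x <- c(100, 300, 330, 500, 520, 540)
  y <- c(100, 200, 210, 300, 330, 310)
  r <- rep(32, 6)
  truth <- truth_from_circles(x, y, r, c(1, 2, 2, 3, 3, 3))
  det <- assign_categories(make_circles(x, y, r))
  counts <- match_detections_to_truth(det, truth)
  expect_equal(counts$tp, 3L)
  expect_equal(counts$fp, 0L)
  expect_equal(counts$fn, 0L)
  expect_equal(counts$n_clusters, 3L)
})

test_that("a pair with one barely-covered fruit is a missed cluster", {
  # true B pair; detection only covers one member well, the other ~8%
  truth <- truth_from_circles(c(100, 160), c(100, 100), c(30, 30), c(1, 1))
  det <- assign_categories(make_circles(c(100, 205), c(100, 100), r = 30))
  counts <- match_detections_to_truth(det, truth)
  expect_equal(counts$tp, 0L)
  expect_equal(counts$fn, 1L)

  # category C tolerates exactly one missed member
  truth_c <- truth_from_circles(c(100, 135, 170), c(100, 100, 100),
                                rep(30, 3), c(1, 1, 1))
  det_c <- assign_categories(make_circles(c(100, 135, 400), c(100, 100, 100),
                                          r = 30))
  counts_c <- match_detections_to_truth(det_c, truth_c)
  expect_equal(counts_c$tp, 1L)
})

test_that("greedy assignment matches the exhaustive optimum on small problems", {
  set.seed(91)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  # a single-fruit truth cluster j counts as TP under detection i iff some
  # member circle of i covers at least a quarter of the true disk
  tp_cell <- function(det, i, x, y, r, j) {
    mem <- det$members[[i]]
    cov <- 0
    for (k in seq_len(nrow(mem))) {
      d <- sqrt((mem$x[k] - x[j])^2 + (mem$y[k] - y[j])^2)
      cov <- max(cov, circle_intersection_area(r, mem$r[k], d) / (pi * r^2))
    }
    cov >= 0.25
  }
  for (rep in 1:8) {
    n <- sample(2:4, 1)
    x <- runif(n, 80, 560); y <- runif(n, 80, 400)
    truth <- truth_from_circles(x, y, rep(31, n), seq_len(n))
    det <- assign_categories(make_circles(x + rnorm(n, 0, 4),
                                          y + rnorm(n, 0, 4), r = 31))
    counts <- match_detections_to_truth(det, truth)
    # oracle: best one-to-one assignment over all orderings of the true
    # clusters, scored by the same recovered-fruit rule
    best_tp <- 0
    for (p in perms(seq_len(n))) {
      tp <- 0
      for (i in seq_len(min(n, nrow(det)))) {
        if (tp_cell(det, i, x, y, 31, p[i])) tp <- tp + 1
      }
      best_tp <- max(best_tp, tp)
    }
    expect_equal(counts$tp, best_tp)
  }
})

test_that("metric formulas reproduce their defining ratios", {
  counts <- tibble::tibble(condition = "x", n_clusters = 10L,
                           tp = 0L, fp = 0L, fn = 5L)
  m <- compute_metrics(counts)
  expect_equal(m$tpr, 0)
  expect_equal(m$precision, 0)
  expect_true(m$degenerate)
  expect_equal(m$f1, 0)

  # f1 equals precision and recall when they coincide
  m2 <- compute_metrics(tibble::tibble(tp = 90L, fp = 10L, fn = 10L))
  expect_equal(m2$precision, m2$recall)
  expect_equal(m2$f1, m2$precision)
  expect_equal(m2$tpr, m2$recall)
  expect_error(compute_metrics(tibble::tibble(tp = 0L, fp = 1L, fn = 0L)),
               "TP \\+ FN")
})

test_that("matching_rate is the simple percentage with an empty-set guard", {
  expect_equal(matching_rate(0, 10), 0)
  expect_equal(matching_rate(3, 4), 75)
  expect_error(matching_rate(1, 0), "empty")
})

test_that("round_half_up rounds .005 upward at two decimals", {
  expect_equal(round_half_up(71.875), 71.88)
  expect_equal(round_half_up(92.815), 92.82)
  expect_equal(round_half_up(-1.005), -1.01)
})

test_that("the CHT baseline pairs a purely shifted circle set at the shift", {
  set.seed(92)
  left <- make_circles(runif(6, 150, 600), runif(6, 50, 430),
                       r = runif(6, 30, 50))
  right <- left
  right$x <- right$x - 80
  pairs <- cht_baseline_match(left, right, row_tol = 2)
  expect_equal(nrow(pairs), 6)
  expect_true(all(pairs$disparity == 80))
})

test_that("occluded fruits without a counterpart stay unpaired", {
  left <- make_circles(c(100, 140, 120), c(100, 100, 130), r = c(32, 45, 38))
  right <- make_circles(20, 100, r = 32) # only one fruit visible
  pairs <- cht_baseline_match(left, right)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$r, 32)
})

test_that("greedy nearest-disparity pairing matches the exhaustive search", {
  set.seed(93)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    left <- make_circles(runif(n, 200, 600), round(runif(n, 50, 430)),
                         r = round(runif(n, 30, 50)))
    right <- left
    keep <- sort(sample(n, max(1, n - 1)))
    right <- right[keep, ]
    right$x <- right$x - round(runif(length(keep), 60, 120))
    pairs <- cht_baseline_match(left, right)
    # oracle: enumerate one-to-one assignments of valid pairs; the greedy
    # result must be a valid maximal assignment with the lexicographically
    # smallest disparity sequence
    valid <- function(i, j) {
      abs(left$r[i] - right$r[j]) <= 5 && abs(left$y[i] - right$y[j]) <= 2 &&
        left$x[i] - right$x[j] >= 0 && left$x[i] - right$x[j] <= 250
    }
    for (k in seq_len(nrow(pairs))) {
      expect_true(valid(pairs$left_id[k], pairs$right_id[k]))
    }
    # maximality: every unpaired valid (i, j) shares a member with a pair
    for (i in seq_len(n)) {
      for (j in seq_len(nrow(right))) {
        if (valid(i, j) && !(i %in% pairs$left_id) &&
            !(j %in% pairs$right_id)) {
          fail(sprintf("unpaired valid pair (%d, %d) left over", i, j))
        }
      }
    }
  }
})

test_that("the bundled orchard counts are internally consistent", {
  rec <- orchard_recognition_counts()
  expect_equal(nrow(rec), 7)
  expect_true(all(rec$tp + rec$fn == rec$n_clusters))
  tot <- rec[rec$condition == "Total", ]
  sub <- rec[rec$condition != "Total", ]
  expect_equal(colSums(sub[, c("n_clusters", "tp", "fp", "fn")]),
               unlist(tot[, c("n_clusters", "tp", "fp", "fn")]))

  mt <- orchard_matching_counts()
  expect_true(all(mt$cht_correct <= mt$cht_pairs))
  expect_true(all(mt$cluster_correct <= mt$cluster_pairs))
})
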