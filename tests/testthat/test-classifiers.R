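# The four supervised classifiers.

two_feature_set <- function(n = 10, seed = 12, gap = 4) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
    cbind(rnorm(n, gap, 1), rnorm(n, gap, 1))
  )
  colnames(X) <- c("f1", "f2")
  out <- tibble::as_tibble(X)
  out$label <- factor(rep(c("fruit", "non_fruit"), each = n),
                      levels = c("fruit", "non_fruit"))
  out
}

# ---------------------------------------------------------------- bayes ---

test_that("bayes posteriors are symmetric when the classes are indistinguishable", {
  s <- two_feature_set(gap = 0, seed = 13)
  # identical class likelihoods: mirror the fruit rows into the non-fruit class
  s[11:20, 1:2] <- s[1:10, 1:2]
  m <- train_bayes(s)
  at_mean <- colMeans(as.matrix(s[1:10, 1:2]))
  p <- classify_bayes(m, at_mean)
  expect_equal(p$posterior_fruit, 0.5, tolerance = 1e-12)
})

test_that("bayes classifies the fruit-class mean as fruit and posteriors sum to one", {
  s <- two_feature_set()
  m <- train_bayes(s)
  p <- classify_bayes(m, c(0, 0))
  expect_equal(as.character(p$class), "fruit")
  X <- as.matrix(s[, 1:2])
  p <- classify_bayes(m, X)
  expect_true(all(abs(p$posterior_fruit + (1 - p$posterior_fruit) - 1) < 1e-12))
})

test_that("bayes posteriors match an independent naive-Bayes implementation", {
  s <- two_feature_set(n = 10, seed = 14, gap = 2)
  m <- train_bayes(s)
  nb <- e1071::naiveBayes(label ~ ., data = as.data.frame(s))
  new <- as.data.frame(two_feature_set(n = 5, seed = 15, gap = 2)[, 1:2])
  p_ref <- stats::predict(nb, new, type = "raw")[, "fruit"]
  p_got <- classify_bayes(m, as.matrix(new))$posterior_fruit
  expect_equal(p_got, unname(p_ref), tolerance = 1e-9)
})

test_that("zero-variance features are floored, not fatal", {
  s <- two_feature_set()
  s$f2 <- 1 # constant in both classes
  expect_silent(m <- train_bayes(s))
  expect_true(all(m$var[, "f2"] >= 1e-9))
})

# ------------------------------------------------------------------ knn ---

test_that("cosine similarity follows the sum formula", {
  expect_equal(cosine_similarity(c(3, 4), c(3, 4)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  set.seed(16)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    ref <- sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
    expect_equal(cosine_similarity(x, y), ref, tolerance = 1e-12)
  }
  expect_error(cosine_similarity(rep(0, 3), c(1, 2, 3)), "zero vector")
})

test_that("knn recalls a stored sample at k = 1 and is forced by a global majority", {
  s <- two_feature_set()
  m <- train_knn(s, k = 1)
  expect_equal(as.character(classify_knn(m, as.numeric(s[1, 1:2]))), "fruit")

  # 60% non-fruit, k = all: majority forced regardless of the query
  s2 <- two_feature_set()[c(1:8, 9:20, 11:18), ]
  m2 <- train_knn(s2, k = nrow(s2))
  expect_true(mean(s2$label == "non_fruit") > 0.5)
  expect_equal(as.character(classify_knn(m2, c(0.1, -0.2))), "non_fruit")
})

test_that("knn agrees with an exhaustive sort-and-vote oracle", {
  set.seed(17)
  s <- two_feature_set(n = 15, seed = 18, gap = 2)
  m <- train_knn(s, k = 5)
  X <- as.matrix(s[, 1:2])
  for (i in 1:10) {
    q <- rnorm(2, 1, 2)
    sims <- apply(X, 1, function(r) cosine_similarity(r, q))
    top <- order(-sims)[1:5]
    n_fruit <- sum(s$label[top] == "fruit")
    want <- if (n_fruit > 5 - n_fruit) "fruit" else "non_fruit"
    expect_equal(as.character(classify_knn(m, q)), want)
  }
})

test_that("knn cosine decisions are invariant to a global feature scaling", {
  s <- two_feature_set(n = 12, seed = 19, gap = 2)
  m1 <- train_knn(s, k = 5)
  s2 <- s
  s2[, 1:2] <- s2[, 1:2] * 37.5
  m2 <- train_knn(s2, k = 5)
  set.seed(20)
  Q <- matrix(rnorm(20, 1, 2), 10, 2)
  expect_equal(classify_knn(m1, Q), classify_knn(m2, Q * 37.5))
  expect_error(classify_knn(m1, Q, k = 0), "positive")
  expect_error(classify_knn(m1, Q, k = 99), "exceeds")
})

# ------------------------------------------------------------------- bp ---

test_that("the hidden-layer sizing rule reproduces the working value J = 7", {
  expect_equal(hidden_size(9, 1, 4), 7L)
  expect_equal(hidden_size(9, 1, 1), 4L)
  expect_equal(hidden_size(9, 1, 10), 13L)
  expect_error(hidden_size(9, 1, 0), "between 1 and 10")
  expect_error(hidden_size(9, 1, 11), "between 1 and 10")
})

test_that("the sigmoid activation passes through one half at zero", {
  expect_equal(litchistereo:::sigmoid(0), 0.5)
})

test_that("bp training loss is non-increasing and fits an XOR-style set exactly", {
  set.seed(22)
  n <- 30
  cl <- sample(0:3, n, replace = TRUE)
  X <- cbind(ifelse(cl %% 2 == 0, 0.15, 0.85) + runif(n, -0.07, 0.07),
             ifelse(cl %/% 2 == 0, 0.15, 0.85) + runif(n, -0.07, 0.07))
  colnames(X) <- c("f1", "f2")
  s <- tibble::as_tibble(X)
  s$label <- factor(ifelse(cl %in% c(1, 2), "fruit", "non_fruit"),
                    levels = c("fruit", "non_fruit"))
  m <- train_bp(s, J = 4, seed = 99, epochs = 4000, lr = 5)
  expect_true(all(diff(m$loss) <= 1e-12))
  expect_equal(m$training_accuracy, 1)
})

test_that("bp training is reproducible for a fixed seed", {
  s <- two_feature_set()
  m1 <- train_bp(s, J = 3, seed = 7, epochs = 50)
  m2 <- train_bp(s, J = 3, seed = 7, epochs = 50)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$loss, m2$loss)
})

# ------------------------------------------------------------------ svm ---

test_that("the symmetric 1-D problem yields the unit-margin discriminant", {
  s <- tibble::tibble(f1 = c(1, -1), label = factor(c("fruit", "non_fruit"),
                                                    levels = c("fruit", "non_fruit")))
  m <- train_svm(s, scale = FALSE)
  expect_equal(unname(m$w), 1, tolerance = 1e-3)
  expect_equal(unname(m$b), 0, tolerance = 1e-3)
})

test_that("support vectors sit on the unit margin in the separable case", {
  set.seed(23)
  s <- two_feature_set(n = 15, seed = 23, gap = 6)
  m <- train_svm(s, scale = FALSE)
  X <- as.matrix(s[, 1:2])
  f <- X %*% m$w + m$b
  sv <- m$support
  expect_true(length(sv) >= 2)
  expect_equal(unname(abs(f[sv, 1])), rep(1, length(sv)), tolerance = 1e-3)
})

test_that("svm labels agree with a generic quadratic-programming solve of the dual", {
  set.seed(24)
  s <- two_feature_set(n = 12, seed = 24, gap = 6)
  m <- train_svm(s, scale = FALSE)
  X <- as.matrix(s[, 1:2])
  y <- ifelse(s$label == "fruit", 1, -1)
  K <- X %*% t(X)
  Hm <- (y %*% t(y)) * K + diag(1e-8, nrow(X))
  qp <- kernlab::ipop(c = rep(-1, nrow(X)), H = Hm,
                      A = matrix(y, 1), b = 0, r = 0,
                      l = rep(0, nrow(X)), u = rep(10, nrow(X)))
  alpha <- kernlab::primal(qp)
  w_qp <- as.numeric(t(X) %*% (alpha * y))
  on_margin <- which(alpha > 1e-5 & alpha < 10 - 1e-5)
  b_qp <- mean(y[on_margin] - X[on_margin, , drop = FALSE] %*% w_qp)
  lab_qp <- as.vector(ifelse(X %*% w_qp + b_qp > 0, "fruit", "non_fruit"))
  expect_equal(as.character(classify_svm(m, X)), lab_qp)
  expect_equal(unname(m$w), w_qp, tolerance = 0.05)
})

test_that("the separable svm is invariant to duplicating a training sample", {
  s <- two_feature_set(n = 12, seed = 25, gap = 6)
  m1 <- train_svm(s)
  m2 <- train_svm(dplyr::bind_rows(s, s[3, ]))
  set.seed(26)
  Q <- matrix(rnorm(40, 2, 3), 20, 2)
  colnames(Q) <- c("f1", "f2")
  expect_equal(classify_svm(m1, Q), classify_svm(m2, Q))
})

test_that("a single-class training set is a degenerate svm problem", {
  s <- two_feature_set()[1:10, ]
  expect_error(train_svm(s), "degenerate")
})

# ------------------------------------------------- cross-cutting checks ---

test_that("all four classifiers reach 100% training accuracy on a well-separated set", {
  s <- separated_features()
  expect_equal(train_bayes(s)$training_accuracy, 1)
  expect_equal(train_knn(s, k = 5)$training_accuracy, 1)
  expect_equal(train_svm(s)$training_accuracy, 1)
  s01 <- s
  s01[, 1:10] <- s01[, 1:10] / 20 # BP works on a [0, 1]-ish input scale
  expect_equal(train_bp(s01, J = 7, seed = 1234, epochs = 1500)$training_accuracy, 1)
})

test_that("models survive a save/load round trip with bit-identical predictions", {
  s <- separated_features(n_per_class = 15)
  set.seed(27)
  Q <- as.matrix(s[, 1:10]) + rnorm(150)
  models <- list(
    train_bayes(s), train_knn(s, k = 3), train_svm(s),
    train_bp(s, J = 3, seed = 5, epochs = 100)
  )
  for (m in models) {
    path <- tempfile(fileext = ".json")
    litchi_save_model(m, path)
    back <- litchi_load_model(path)
    expect_identical(predict(back, Q), predict(m, Q))
    if (m$kind == "bayes") {
      expect_identical(classify_bayes(back, Q)$posterior_fruit,
                       classify_bayes(m, Q)$posterior_fruit)
    }
  }
})

test_that("tidy and glance summarize models", {
  s <- separated_features(n_per_class = 10)
  m <- train_svm(s)
  td <- tidy(m)
  expect_equal(nrow(td), 11) # ten coefficients + bias
  gl <- glance(m)
  expect_equal(gl$kind, "svm")
  expect_equal(gl$training_accuracy, 1)
})
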