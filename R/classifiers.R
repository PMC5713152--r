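# The four supervised fruit / non-fruit classifiers. Class c1 is "fruit",
# class c2 is "non_fruit"; every trainer takes a tidy feature table
# (feature columns + `label`) and returns a `litchi_model`.

litchi_classes <- c("fruit", "non_fruit")

split_samples <- function(samples) {
  stopifnot("label" %in% names(samples))
  y <- factor(as.character(samples$label), levels = litchi_classes)
  if (any(is.na(y))) stop("labels must be 'fruit' or 'non_fruit'")
  X <- as.matrix(samples[setdiff(names(samples), "label")])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must be finite")
  list(X = X, y = y)
}

new_litchi_model <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "litchi_model")
}

# run expr with a fixed RNG state, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# ---------------------------------------------------------------- bayes ---

#' Gaussian naive Bayes fruit classifier
#'
#' Posterior class probabilities follow Bayes' rule with class priors equal
#' to the class frequencies and class-conditional likelihoods modelled as a
#' product of per-feature Gaussians. A zero-variance feature has its
#' variance floored at 1e-9 rather than failing.
#'
#' @param samples Tidy feature table: feature columns plus `label`
#'   (`"fruit"` / `"non_fruit"`), at least two samples per class.
#' @return A `litchi_model` of kind `"bayes"`.
#' @export
train_bayes <- function(samples) {
  s <- split_samples(samples)
  if (any(table(s$y) < 2)) stop("need at least 2 samples per class")
  stats_by <- function(cl) {
    Xc <- s$X[s$y == cl, , drop = FALSE]
    list(mu = colMeans(Xc), var = pmax(apply(Xc, 2, stats::var), 1e-9))
  }
  st <- lapply(litchi_classes, stats_by)
  names(st) <- litchi_classes
  m <- new_litchi_model("bayes", list(
    priors = as.numeric(table(s$y) / length(s$y)),
    mu = rbind(fruit = st$fruit$mu, non_fruit = st$non_fruit$mu),
    var = rbind(fruit = st$fruit$var, non_fruit = st$non_fruit$var),
    features = colnames(s$X), n_train = nrow(s$X)
  ))
  m$training_accuracy <- mean(classify_bayes(m, s$X)$class == s$y)
  m
}

#' @rdname train_bayes
#' @param model A trained bayes `litchi_model`.
#' @param X Feature vector, matrix or tibble of new observations.
#' @return `classify_bayes` returns a tibble with `class` (factor) and
#'   `posterior` (posterior probability of the predicted class; the two
#'   class posteriors sum to one).
#' @export
classify_bayes <- function(model, X) {
  X <- as_feature_matrix(X, model$features)
  loglik <- function(cl) {
    mu <- model$mu[cl, ]; v <- model$var[cl, ]
    rowSums(-0.5 * log(2 * pi * matrix(v, nrow(X), ncol(X), byrow = TRUE)) -
              sweep(X, 2, mu)^2 / (2 * matrix(v, nrow(X), ncol(X), byrow = TRUE))) +
      log(model$priors[match(cl, litchi_classes)])
  }
  l1 <- loglik("fruit"); l2 <- loglik("non_fruit")
  mx <- pmax(l1, l2)
  p1 <- exp(l1 - mx) / (exp(l1 - mx) + exp(l2 - mx))
  cls <- factor(ifelse(p1 > 0.5, "fruit", "non_fruit"), levels = litchi_classes)
  tibble(class = cls, posterior = ifelse(p1 > 0.5, p1, 1 - p1),
         posterior_fruit = p1)
}

as_feature_matrix <- function(X, features = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "label")])
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  storage.mode(X) <- "double"
  if (!is.null(features) && !is.null(colnames(X)) &&
      all(features %in% colnames(X))) {
    X <- X[, features, drop = FALSE]
  }
  X
}

# ------------------------------------------------------------------ knn ---

#' Cosine similarity between two vectors
#'
#' `sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`; undefined for a zero
#' vector.
#'
#' @param x,y Nonzero numeric vectors of equal length.
#' @return A value in \[-1, 1\].
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' k-nearest-neighbour classifier with cosine similarity
#'
#' Stores the training samples; a query is ranked against all stored
#' samples by descending cosine similarity and the majority class among the
#' top `k` wins, with ties broken toward non-fruit.
#'
#' @inheritParams train_bayes
#' @param k Number of neighbours (default 5).
#' @return A `litchi_model` of kind `"knn"`.
#' @export
train_knn <- function(samples, k = 5) {
  s <- split_samples(samples)
  if (k <= 0 || k > nrow(s$X)) stop("k must be in 1..n_samples")
  m <- new_litchi_model("knn", list(
    X = s$X, y = s$y, k = as.integer(k),
    features = colnames(s$X), n_train = nrow(s$X)
  ))
  m$training_accuracy <- mean(classify_knn(m, s$X) == s$y)
  m
}

#' @rdname train_knn
#' @param model A trained knn `litchi_model`.
#' @param Y Query feature vector or matrix.
#' @return `classify_knn` returns a factor of predicted classes.
#' @export
classify_knn <- function(model, Y, k = model$k) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(model$X)) stop("k exceeds the number of stored samples")
  Y <- as_feature_matrix(Y, model$features)
  nX <- sqrt(rowSums(model$X^2)); nY <- sqrt(rowSums(Y^2))
  if (any(nX == 0) || any(nY == 0)) {
    stop("cosine similarity undefined for a zero vector")
  }
  sims <- (Y / nY) %*% t(model$X / nX)
  cls <- apply(sims, 1, function(s) {
    top <- order(-s)[seq_len(k)]
    n_fruit <- sum(model$y[top] == "fruit")
    if (n_fruit > k - n_fruit) "fruit" else "non_fruit"
  })
  factor(cls, levels = litchi_classes)
}

# ------------------------------------------------------------------- bp ---

#' Hidden-layer size of the BP network
#'
#' `J = round(sqrt(m + n)) + a` for `m` input neurons, `n` output neurons
#' and an integer adjustment `a` in 1..10. With the working configuration
#' `m = 9`, `n = 1`, this spans 4..13; `a = 4` gives the default `J = 7`.
#'
#' @param m,n Input / output neuron counts.
#' @param a Integer in 1..10.
#' @return Integer hidden-layer size.
#' @export
hidden_size <- function(m, n, a) {
  if (length(a) != 1 || a != round(a) || a < 1 || a > 10) {
    stop("a must be an integer between 1 and 10")
  }
  as.integer(round(sqrt(m + n)) + a)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Three-layer sigmoid back-propagation classifier
#'
#' A fully connected `m -> J -> 1` network with logistic activations
#' `f(x) = 1 / (1 + exp(-x))` everywhere, trained by full-batch gradient
#' descent on the squared error with a halving line search (so the recorded
#' training loss is non-increasing). The fruit class is coded 1, non-fruit
#' 0; prediction thresholds the output at 0.5.
#'
#' @param samples Tidy table of input columns (typically the nine 3x3
#'   neighbourhood intensities scaled to \[0, 1\]) plus `label`.
#' @param J Hidden-layer size (default 7, see [hidden_size()]).
#' @param seed RNG seed for the weight initialization.
#' @param epochs Training epochs.
#' @param lr Initial learning rate.
#' @return A `litchi_model` of kind `"bp"` with a `loss` history.
#' @export
train_bp <- function(samples, J = 7, seed = 1234, epochs = 2000, lr = 2) {
  s <- split_samples(samples)
  X <- s$X
  t_out <- as.numeric(s$y == "fruit")
  m <- ncol(X); n1 <- nrow(X)

  par <- with_local_seed(seed, list(
    W1 = matrix(runif(J * m, -0.5, 0.5), J, m),
    b1 = runif(J, -0.5, 0.5),
    W2 = matrix(runif(J, -0.5, 0.5), 1, J),
    b2 = runif(1, -0.5, 0.5)
  ))

  fwd <- function(p) {
    A1 <- sigmoid(X %*% t(p$W1) + matrix(p$b1, n1, J, byrow = TRUE))
    out <- sigmoid(A1 %*% t(p$W2) + p$b2)[, 1]
    list(A1 = A1, out = out, loss = mean((out - t_out)^2) / 2)
  }

  st <- fwd(par)
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    delta2 <- (st$out - t_out) * st$out * (1 - st$out) / n1 # n1-vector
    gW2 <- matrix(delta2 %*% st$A1, 1, J)
    gb2 <- sum(delta2)
    delta1 <- (matrix(delta2, ncol = 1) %*% par$W2) * st$A1 * (1 - st$A1) # n1 x J
    gW1 <- t(delta1) %*% X
    gb1 <- colSums(delta1)

    step <- lr
    for (try in 1:25) {
      cand <- list(W1 = par$W1 - step * gW1, b1 = par$b1 - step * gb1,
                   W2 = par$W2 - step * gW2, b2 = par$b2 - step * gb2)
      st2 <- fwd(cand)
      if (st2$loss <= st$loss) break
      step <- step / 2
    }
    if (st2$loss <= st$loss) {
      par <- cand
      st <- st2
      lr <- min(step * 1.5, 50)
    }
    losses[e] <- st$loss
  }

  md <- new_litchi_model("bp", list(
    W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
    J = as.integer(J), seed = seed, loss = losses,
    features = colnames(X), n_train = n1
  ))
  md$training_accuracy <- mean(classify_bp(md, X)$class == s$y)
  md
}

#' @rdname train_bp
#' @param model A trained bp `litchi_model`.
#' @param X Input vector or matrix (same columns as training).
#' @return `classify_bp` returns a tibble with `class` and the raw network
#'   `output` in (0, 1).
#' @export
classify_bp <- function(model, X) {
  X <- as_feature_matrix(X, model$features)
  A1 <- sigmoid(X %*% t(model$W1) + matrix(model$b1, nrow(X), model$J,
                                           byrow = TRUE))
  out <- sigmoid(A1 %*% t(model$W2) + model$b2)[, 1]
  tibble(
    class = factor(ifelse(out > 0.5, "fruit", "non_fruit"),
                   levels = litchi_classes),
    output = out
  )
}

# ------------------------------------------------------------------ svm ---

#' Linear support vector machine
#'
#' Maximum-margin linear discriminant `f(x) = sgn(w* . x + b*)`, minimizing
#' `phi(w) = ||w||^2 / 2` subject to `c_j (w . x_j + b) >= 1`, relaxed to a
#' soft margin with penalty `C` when the classes are inseparable. The fruit
#' class is coded +1. Features are z-scored internally by default; the
#' reported `w`/`b` are mapped back to the original feature units. The
#' quadratic program is solved by libsvm (via e1071).
#'
#' @inheritParams train_bayes
#' @param C Soft-margin penalty (default 10).
#' @param scale Standardize features internally (default TRUE).
#' @return A `litchi_model` of kind `"svm"` with fields `w`, `b` (original
#'   units) and `w_scaled`, `b_scaled`, `center`, `scale`.
#' @export
train_svm <- function(samples, C = 10, scale = TRUE) {
  s <- split_samples(samples)
  if (length(unique(s$y)) < 2) {
    stop("degenerate problem: both classes must be present")
  }
  ctr <- if (scale) colMeans(s$X) else rep(0, ncol(s$X))
  scl <- if (scale) apply(s$X, 2, stats::sd) else rep(1, ncol(s$X))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(s$X, 2, ctr), 2, scl, "/")

  fit <- e1071::svm(Xs, s$y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-6)
  w_s <- as.numeric(t(fit$coefs) %*% fit$SV)
  b_s <- -fit$rho
  # orient the discriminant so that fruit maps to +1
  pred <- factor(ifelse(Xs %*% w_s + b_s > 0, "fruit", "non_fruit"),
                 levels = litchi_classes)
  lib <- stats::predict(fit, Xs)
  if (mean(pred == lib) < 0.5) {
    w_s <- -w_s
    b_s <- -b_s
  }
  w <- w_s / scl
  b <- b_s - sum(w_s * ctr / scl)

  m <- new_litchi_model("svm", list(
    w = w, b = b, w_scaled = w_s, b_scaled = b_s,
    center = ctr, scale = scl, C = C,
    support = as.integer(fit$index),
    features = colnames(s$X), n_train = nrow(s$X)
  ))
  m$training_accuracy <- mean(classify_svm(m, s$X) == s$y)
  m
}

#' @rdname train_svm
#' @param model A trained svm `litchi_model`.
#' @param X Feature vector or matrix.
#' @return `classify_svm` returns a factor of predicted classes
#'   (`sign(w . x + b) = +1` maps to fruit).
#' @export
classify_svm <- function(model, X) {
  X <- as_feature_matrix(X, model$features)
  f <- as.numeric(X %*% model$w + model$b)
  factor(ifelse(f > 0, "fruit", "non_fruit"), levels = litchi_classes)
}

#' @export
predict.litchi_model <- function(object, newdata, ...) {
  switch(object$kind,
    bayes = classify_bayes(object, newdata)$class,
    knn = classify_knn(object, newdata),
    bp = classify_bp(object, newdata)$class,
    svm = classify_svm(object, newdata),
    stop("unknown model kind")
  )
}

#' @export
print.litchi_model <- function(x, ...) {
  cat(sprintf("<litchi_model: %s>  %d features, %d training samples", x$kind,
              length(x$features), x$n_train))
  if (!is.null(x$training_accuracy)) {
    cat(sprintf(", training accuracy %.1f%%", 100 * x$training_accuracy))
  }
  cat("\n")
  invisible(x)
}

# -------------------------------------------------------- serialization ---

#' Save / load a classifier as JSON
#'
#' Models round-trip with bit-identical predictions (numbers are written at
#' full precision).
#'
#' @param model A `litchi_model`.
#' @param path File path (`.json`).
#' @return `litchi_load_model` returns the model; `litchi_save_model`
#'   returns `path` invisibly.
#' @export
litchi_save_model <- function(model, path) {
  enc <- function(v) {
    if (is.matrix(v)) {
      list(.matrix = TRUE, dim = dim(v), data = as.numeric(v),
           rownames = rownames(v))
    } else if (is.factor(v)) {
      list(.factor = TRUE, levels = levels(v), data = as.character(v))
    } else {
      v
    }
  }
  obj <- lapply(unclass(model), enc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname litchi_save_model
#' @export
litchi_load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(v) {
    if (is.list(v) && isTRUE(v$.matrix)) {
      m <- matrix(v$data, v$dim[1], v$dim[2])
      if (!is.null(v$rownames) && length(v$rownames)) rownames(m) <- v$rownames
      m
    } else if (is.list(v) && isTRUE(v$.factor)) {
      factor(v$data, levels = v$levels)
    } else {
      v
    }
  }
  out <- lapply(obj, dec)
  structure(out, class = "litchi_model")
}

# --------------------------------------------------------------- tidiers ---

#' Tidy a litchi classifier
#'
#' @param x A `litchi_model`.
#' @param ... Unused.
#' @return A tibble of model parameters: per-feature Gaussian moments
#'   (bayes), the stored-sample summary (knn), layer weights (bp) or the
#'   discriminant coefficients (svm).
#' @export
tidy.litchi_model <- function(x, ...) {
  switch(x$kind,
    bayes = tibble(
      feature = rep(x$features, 2),
      class = rep(litchi_classes, each = length(x$features)),
      mean = c(x$mu["fruit", ], x$mu["non_fruit", ]),
      variance = c(x$var["fruit", ], x$var["non_fruit", ])
    ),
    knn = tibble(feature = x$features,
                 mean_fruit = colMeans(x$X[x$y == "fruit", , drop = FALSE]),
                 mean_non_fruit = colMeans(x$X[x$y == "non_fruit", , drop = FALSE])),
    bp = tibble(
      layer = c(rep("hidden", length(x$W1)), rep("hidden_bias", length(x$b1)),
                rep("output", length(x$W2)), "output_bias"),
      weight = c(as.numeric(x$W1), x$b1, as.numeric(x$W2), x$b2)
    ),
    svm = tibble(term = c(x$features, "(bias)"), estimate = c(x$w, x$b))
  )
}

#' Model-level summary of a litchi classifier
#'
#' @inheritParams tidy.litchi_model
#' @return A one-row tibble with `kind`, `n_train` and
#'   `training_accuracy`.
#' @export
glance.litchi_model <- function(x, ...) {
  tibble(kind = x$kind, n_train = x$n_train,
         training_accuracy = x$training_accuracy %||% NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
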