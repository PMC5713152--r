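# shared fixtures: training patches and trained models are built once per
# test run; everything is generated in code from fixed seeds

litchi_fixtures <- new.env(parent = emptyenv())

fixture_patches <- function() {
  if (is.null(litchi_fixtures$patches)) {
    litchi_fixtures$patches <- generate_training_patches(150, seed = 42)
  }
  litchi_fixtures$patches
}

fixture_models <- function() {
  if (is.null(litchi_fixtures$models)) {
    litchi_fixtures$models <- train_classifiers(fixture_patches())
  }
  litchi_fixtures$models
}

# a linearly well-separated two-class feature set (10-dimensional, like X);
# the class means differ in direction, not just scale, so that the
# scale-invariant cosine classifier can also separate them
separated_features <- function(n_per_class = 30, seed = 7, gap = 8) {
  set.seed(seed)
  p <- 10
  mu1 <- c(rep(2 + gap, p / 2), rep(2, p / 2))
  mu2 <- c(rep(2, p / 2), rep(2 + gap, p / 2))
  X <- rbind(
    matrix(rep(mu1, each = n_per_class) + rnorm(n_per_class * p, 0, 0.5),
           n_per_class, p),
    matrix(rep(mu2, each = n_per_class) + rnorm(n_per_class * p, 0, 0.5),
           n_per_class, p)
  )
  colnames(X) <- paste0("f", seq_len(p))
  out <- tibble::as_tibble(X)
  out$label <- factor(rep(c("fruit", "non_fruit"), each = n_per_class),
                      levels = c("fruit", "non_fruit"))
  out
}

random_rotation <- function() {
  rotation_matrix(runif(1, -pi / 3, pi / 3), runif(1, -pi / 3, pi / 3),
                  runif(1, -pi, pi))
}

random_pose <- function(t_scale = 500) {
  camera_pose(random_rotation(), runif(3, -t_scale, t_scale))
}

# points guaranteed to sit in front of both cameras in the tests below
random_world_points <- function(n, depth = c(1500, 4000)) {
  cbind(runif(n, -300, 300), runif(n, -300, 300), runif(n, depth[1], depth[2]))
}

# a flat colour image (H x W x 3)
flat_image <- function(H, W, rgb) {
  array(rep(rgb, each = H * W), c(H, W, 3))
}

# draw an ideal binary disk mask
disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1), H, W)
  m <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  storage.mode(m) <- "integer"
  m
}

make_circles <- function(x, y, r = 40, score = 1, source = "test") {
  tibble::tibble(x = x, y = y, r = r, score = score, source = source)
}
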