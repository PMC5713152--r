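# Turning a trained classifier into a binary fruit mask.

#' Segment an image into a binary fruit mask
#'
#' For the window classifiers (bayes, knn, svm) a 40x40 window slides over
#' the image at the given stride; each positive window votes for all its
#' pixels and a pixel is foreground iff at least half of the windows
#' covering it vote positive. The BP network classifies pixels directly on
#' their 3x3 intensity neighbourhoods, restricted to pixels passing a
#' fruit-colour gate (`R - B > gate`).
#'
#' @param image H x W x 3 array, values in \[0, 255\], at least 40 x 40.
#' @param model A `litchi_model`.
#' @param stride Sliding-window stride in pixels (default 8).
#' @param size Window side (default 40).
#' @param gate Colour gate for the per-pixel BP path (default 20).
#' @param features Optional precomputed [window_feature_grid()] result for
#'   this image/stride, to share feature extraction across classifiers.
#' @return H x W binary (0/1) matrix.
#' @export
segment_image <- function(image, model, stride = 8, size = 40, gate = 50,
                          features = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < size || W < size) stop("image smaller than the sliding window")
  if (model$kind == "bp") {
    return(segment_bp(image, model, gate = gate))
  }
  if (is.null(features)) features <- window_feature_grid(image, stride, size)
  pos <- predict(model, features$X) == "fruit"

  votes <- matrix(0, H, W)
  cover <- matrix(0, H, W)
  # rectangle accumulation via a difference matrix + double cumsum
  dv <- matrix(0, H + 1, W + 1)
  dc <- matrix(0, H + 1, W + 1)
  for (i in seq_along(pos)) {
    y0 <- features$y0[i] + 1; x0 <- features$x0[i] + 1
    dc[y0, x0] <- dc[y0, x0] + 1
    dc[y0 + size, x0] <- dc[y0 + size, x0] - 1
    dc[y0, x0 + size] <- dc[y0, x0 + size] - 1
    dc[y0 + size, x0 + size] <- dc[y0 + size, x0 + size] + 1
    if (pos[i]) {
      dv[y0, x0] <- dv[y0, x0] + 1
      dv[y0 + size, x0] <- dv[y0 + size, x0] - 1
      dv[y0, x0 + size] <- dv[y0, x0 + size] - 1
      dv[y0 + size, x0 + size] <- dv[y0 + size, x0 + size] + 1
    }
  }
  acc2 <- function(d) {
    m <- apply(d, 2, cumsum)
    m <- t(apply(m, 1, cumsum))
    m[1:H, 1:W]
  }
  votes <- acc2(dv)
  cover <- acc2(dc)
  mask <- (votes >= cover / 2) & (votes > 0)
  storage.mode(mask) <- "integer"
  mask
}

# per-pixel BP segmentation on gated pixels
segment_bp <- function(image, model, gate = 50) {
  H <- dim(image)[1]; W <- dim(image)[2]
  g <- as_gray(image) / 255
  rb <- image[, , 1] - image[, , 3]
  cand <- which(rb > gate)
  mask <- matrix(0L, H, W)
  if (length(cand) == 0) return(mask)

  # replicate-padded shifted copies give each pixel its 3x3 neighbourhood
  pad <- rbind(g[1, , drop = FALSE], g, g[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  X <- matrix(0, length(cand), 9)
  k <- 1
  for (dy in 0:2) {
    for (dx in 0:2) {
      X[, k] <- pad[(dy + 1):(dy + H), (dx + 1):(dx + W), drop = FALSE][cand]
      k <- k + 1
    }
  }
  colnames(X) <- paste0("p", 1:9)
  out <- classify_bp(model, X)
  mask[cand[out$class == "fruit"]] <- 1L
  mask
}
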