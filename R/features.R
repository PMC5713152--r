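# The 10-dimensional feature vector X used by all four classifiers:
# four effective colour components (R-B, HSI intensity, Cb of YCbCr,
# b* of CIE L*a*b*) and the six Tamura texture features.
#
# Images are numeric arrays H x W x 3 with channel values in [0, 255];
# grayscale images are H x W matrices on the same scale.

#' Convert a colour image to grayscale
#'
#' BT.601 luminance: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img H x W x 3 array with values in \[0, 255\].
#' @return H x W matrix in \[0, 255\].
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Effective colour components
#'
#' Computes the four colour components that best separate mature litchi
#' fruit from orchard background:
#' * `rb` — the raw channel difference R - B;
#' * `intensity` — the I channel of HSI, `(R + G + B) / 3`;
#' * `cb` — blue chrominance of YCbCr (BT.601 full range, +128 offset, so
#'   an achromatic pixel maps to 128);
#' * `bstar` — b* of CIE L*a*b* (sRGB primaries, D65 white).
#'
#' @param img H x W x 3 array (values in \[0, 255\]), or a length-3 RGB
#'   vector, or an n x 3 matrix of pixels.
#' @return For an image, an H x W x 4 array (last dimension named);
#'   otherwise an n x 4 matrix (or named length-4 vector for one pixel).
#' @examples
#' color_components(c(128, 128, 128)) # achromatic: rb 0, I 128, Cb 128, b* 0
#' @export
color_components <- function(img) {
  single <- is.numeric(img) && is.null(dim(img)) && length(img) == 3
  if (single) img <- matrix(img, ncol = 3)
  if (is.matrix(img)) {
    if (ncol(img) != 3) stop("pixel input must have 3 channels")
    R <- img[, 1]; G <- img[, 2]; B <- img[, 3]
  } else {
    if (length(dim(img)) != 3 || dim(img)[3] != 3) {
      stop("image input must have 3 channels")
    }
    R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  }

  rb <- R - B
  intensity <- (R + G + B) / 3
  cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B

  # sRGB -> XYZ (D65) -> b*
  lin <- function(v) {
    v <- v / 255
    ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  }
  Rl <- lin(R); Gl <- lin(G); Bl <- lin(B)
  Y <- 0.2126729 * Rl + 0.7151522 * Gl + 0.0721750 * Bl
  Z <- 0.0193339 * Rl + 0.1191920 * Gl + 0.9503041 * Bl
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  bstar <- 200 * (f(Y / 1) - f(Z / 1.08883))

  if (is.matrix(img) || single) {
    out <- cbind(rb = rb, intensity = intensity, cb = cb, bstar = bstar)
    if (single) out <- out[1, ]
    return(out)
  }
  out <- array(c(rb, intensity, cb, bstar),
               dim = c(dim(img)[1:2], 4),
               dimnames = list(NULL, NULL,
                               c("rb", "intensity", "cb", "bstar")))
  out
}

#' Tamura texture features
#'
#' The six perceptual texture statistics of a grayscale patch: coarseness
#' (mean best dyadic window size, capped at 32 px), contrast
#' (`sigma / kurtosis^(1/4)`), directionality (sharpness of the 16-bin
#' gradient-direction histogram, Prewitt gradients), line-likeness
#' (direction co-occurrence along the edge direction), regularity
#' (1 minus the normalized spread of the first four features over the
#' patch quadrants) and roughness (coarseness + contrast).
#'
#' @param patch H x W grayscale matrix, H and W at least 8, values in
#'   \[0, 255\].
#' @return Named numeric vector of length 6.
#' @export
tamura_features <- function(patch) {
  stopifnot(is.matrix(patch))
  if (nrow(patch) < 8 || ncol(patch) < 8) {
    stop("patch must be at least 8x8 for Tamura features")
  }
  tamura_cpp(patch)
}

#' Feature vector of a square window
#'
#' Colour components are averaged over the window; the Tamura features are
#' computed on the window's grayscale. Together they form the
#' 10-dimensional feature vector X.
#'
#' @param image H x W x 3 array (values in \[0, 255\]).
#' @param x,y Top-left corner of the window (0-based pixel coordinates).
#' @param size Window side length (default 40).
#' @return Named numeric vector of length 10.
#' @export
window_features <- function(image, x, y, size = 40) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (x < 0 || y < 0 || x + size > W || y + size > H) {
    stop("window out of image bounds")
  }
  rows <- (y + 1):(y + size)
  cols <- (x + 1):(x + size)
  sub <- image[rows, cols, , drop = FALSE]
  cc <- color_components(sub)
  col4 <- apply(cc, 3, mean)
  tam <- tamura_features(as_gray(sub))
  stats::setNames(c(col4, tam), litchi_feature_names)
}

#' Per-pixel feature vector from a 3x3 neighbourhood
#'
#' Colour components are averaged over the 3x3 neighbourhood of the pixel
#' (borders handled by reflection). A 3x3 neighbourhood cannot support
#' texture statistics, so the six Tamura components are taken from the
#' `context`-sized window centred on the pixel (shifted inside the image
#' near borders), keeping X 10-dimensional.
#'
#' @param image H x W x 3 array.
#' @param x,y Pixel (0-based).
#' @param context Side of the texture context window (default 40).
#' @return Named numeric vector of length 10.
#' @export
pixel_neighborhood_features <- function(image, x, y, context = 40) {
  H <- dim(image)[1]; W <- dim(image)[2]
  stopifnot(x >= 0, y >= 0, x < W, y < H)
  refl <- function(i, n) {
    i[i < 0] <- -i[i < 0]
    i[i > n - 1] <- 2 * (n - 1) - i[i > n - 1]
    i
  }
  rows <- refl(y + (-1:1), H) + 1
  cols <- refl(x + (-1:1), W) + 1
  sub <- image[rows, cols, , drop = FALSE]
  col4 <- apply(color_components(sub), 3, mean)

  cx <- min(max(x - context %/% 2, 0), W - context)
  cy <- min(max(y - context %/% 2, 0), H - context)
  g <- as_gray(image)[(cy + 1):(cy + context), (cx + 1):(cx + context)]
  tam <- tamura_features(g)
  stats::setNames(c(col4, tam), litchi_feature_names)
}

#' Feature table for labelled training patches
#'
#' Runs [window_features()] over every 40x40 patch and returns a tidy
#' feature table, one row per patch.
#'
#' @param patches A tibble with a list-column `patch` (40x40x3 arrays) and
#'   a `label` column, as produced by [generate_training_patches()].
#' @return A tibble with the ten feature columns and `label`.
#' @export
patch_features <- function(patches) {
  feats <- purrr::map(patches$patch, function(p) {
    window_features(p, 0, 0, size = dim(p)[1])
  })
  out <- as_tibble(do.call(rbind, feats))
  out$label <- patches$label
  out
}

# --- fast window-grid features used by the sliding-window classifiers ----

# integral image: S[i+1, j+1] = sum of m[1:i, 1:j]
integral_image <- function(m) {
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  S
}

box_sums <- function(S, x0, y0, size) {
  # x0, y0 0-based vectors; sums over size x size boxes
  S[cbind(y0 + size + 1, x0 + size + 1)] - S[cbind(y0 + 1, x0 + size + 1)] -
    S[cbind(y0 + size + 1, x0 + 1)] + S[cbind(y0 + 1, x0 + 1)]
}

# features for every sliding window position; returns list(x0, y0, X)
window_feature_grid <- function(image, stride = 8, size = 40) {
  H <- dim(image)[1]; W <- dim(image)[2]
  xs <- unique(c(seq(0, W - size, by = stride), W - size))
  ys <- unique(c(seq(0, H - size, by = stride), H - size))
  grid <- expand.grid(x0 = xs, y0 = ys)

  cc <- color_components(image)
  Sr <- integral_image(cc[, , 1])
  Si <- integral_image(cc[, , 2])
  Sc <- integral_image(cc[, , 3])
  Sb <- integral_image(cc[, , 4])
  n <- size * size
  col4 <- cbind(
    rb = box_sums(Sr, grid$x0, grid$y0, size) / n,
    intensity = box_sums(Si, grid$x0, grid$y0, size) / n,
    cb = box_sums(Sc, grid$x0, grid$y0, size) / n,
    bstar = box_sums(Sb, grid$x0, grid$y0, size) / n
  )

  g <- as_gray(image)
  tam <- tamura_windows_cpp(g, as.integer(grid$x0), as.integer(grid$y0),
                            as.integer(size))
  X <- cbind(col4, tam)
  colnames(X) <- litchi_feature_names
  list(x0 = grid$x0, y0 = grid$y0, X = X)
}
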