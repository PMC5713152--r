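# Single-fruit detection: mask cleaning, Canny edges, circle Hough
# transform over radii 30-50 px, centre deduplication, rectangular labels
# and OR fusion of the four classifiers' detections.
#
# Detections are tibbles with columns x, y (centre, 0-based pixels),
# r (radius, px), score (normalized accumulator support) and source.

#' Morphological cleaning of a fruit mask
#'
#' Dilation by a disk structuring element (radius 10), hole filling, then
#' removal of connected components smaller than `min_area` (default
#' `pi * 15^2`, below the smallest plausible fruit). With
#' `restore_scale = TRUE` (the default) the mask is eroded by the same
#' disk after hole filling — a morphological closing — so that blob sizes,
#' and hence the Hough radius estimates, are not inflated by the
#' structuring element.
#'
#' @param mask H x W binary matrix.
#' @param dilate_radius Disk radius of the structuring element (default 10).
#' @param min_area Minimum surviving component area in px.
#' @param restore_scale Erode back after filling (default TRUE).
#' @return H x W binary (0/1 integer) matrix.
#' @export
clean_mask <- function(mask, dilate_radius = 10, min_area = pi * 15^2,
                       restore_scale = TRUE) {
  m <- mask
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("mask must be binary")
  if (sum(m) == 0) return(m)
  if (dilate_radius > 0) {
    brush <- EBImage::makeBrush(2 * dilate_radius + 1, shape = "disc")
    m <- EBImage::dilate(m, brush)
  }
  m <- EBImage::fillHull(m)
  if (restore_scale && dilate_radius > 0) {
    brush <- EBImage::makeBrush(2 * dilate_radius + 1, shape = "disc")
    m <- EBImage::erode(m, brush)
  }
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_area)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  storage.mode(m) <- "integer"
  unname(m)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction and hysteresis thresholding (high threshold
#' by Otsu on the gradient magnitudes, low = 0.4 x high). On a binary mask
#' this reduces to the region boundary.
#'
#' @param img H x W grayscale matrix (any scale) or binary mask.
#' @param sigma Gaussian smoothing sd in px.
#' @param low_frac Low threshold as a fraction of the high threshold.
#' @return H x W binary (0/1 integer) edge map.
#' @export
canny_edges <- function(img, sigma = 1, low_frac = 0.4) {
  m <- img
  storage.mode(m) <- "double"
  H <- nrow(m); W <- ncol(m)
  if (sigma > 0) {
    ks <- 2 * ceiling(3 * sigma) + 1
    kern <- outer(
      stats::dnorm(seq(-ceiling(3 * sigma), ceiling(3 * sigma)), sd = sigma),
      stats::dnorm(seq(-ceiling(3 * sigma), ceiling(3 * sigma)), sd = sigma)
    )
    kern <- kern / sum(kern)
    m <- EBImage::filter2(m, kern, boundary = "replicate")
  }
  sx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- EBImage::filter2(m, sx, boundary = "replicate")
  gy <- EBImage::filter2(m, t(sx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  # the FFT-based convolution leaves ~1e-13 residue on flat regions; kill
  # everything far below the image's dynamic range (a constant image has
  # no edges at all)
  rng <- diff(range(img))
  if (rng == 0) return(matrix(0L, H, W))
  mag[mag < 1e-6 * rng] <- 0
  if (max(mag) == 0) return(matrix(0L, H, W))

  # non-max suppression: compare against the two neighbours along the
  # quantized gradient direction
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4 # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift <- function(m2, dy, dx) {
    out <- matrix(0, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy)
    xs <- max(1, 1 + dx):min(W, W + dx)
    out[ys, xs] <- m2[ys - dy, xs - dx]
    out
  }
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nms <- matrix(FALSE, H, W)
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- shift(mag, o[1], o[2])
    n2 <- shift(mag, -o[1], -o[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  thin <- mag * nms

  hi <- otsu_threshold(thin[thin > 0])
  lo <- low_frac * hi
  strong <- thin >= hi
  weak <- thin >= lo
  if (!any(strong)) return(matrix(0L, H, W))
  lab <- EBImage::bwlabel(weak * 1L)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  edge <- matrix(0L, H, W)
  edge[lab %in% keep] <- 1L
  edge
}

# Otsu threshold of a numeric vector (256-bin histogram)
otsu_threshold <- function(v) {
  if (length(v) == 0) return(0)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((v - rng[1]) / diff(rng) * 256)) + 1L,
                256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (1:256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Circle Hough transform fruit detection
#'
#' Canny edges of the (cleaned) mask vote in a circular Hough accumulator
#' over integer radii `r_min..r_max`. Peaks are extracted strongest-first
#' with iterative edge claiming; a peak is kept when its normalized
#' accumulator support reaches `1 - sensitivity` and at least
#' `support_min` of its perimeter lies on unclaimed edge pixels.
#'
#' @param mask H x W binary matrix (a cleaned classifier mask), or an edge
#'   map if `edges = TRUE`.
#' @param r_min,r_max Radius search range in px (defaults 30 and 50).
#' @param sensitivity Detection sensitivity in (0, 1) (default 0.97); the
#'   accumulator threshold is `1 - sensitivity` of the theoretical maximum
#'   edge support per circle.
#' @param support_min Minimum verified perimeter-support fraction.
#' @param max_circles Upper bound on extracted circles.
#' @param edges Set TRUE if `mask` is already an edge map.
#' @param source Value for the `source` column of the result.
#' @return A tibble of detected circles: `x`, `y`, `r`, `score`, `source`,
#'   strongest first.
#' @export
hough_circles <- function(mask, r_min = 30, r_max = 50, sensitivity = 0.97,
                          support_min = 0.35, max_circles = 100,
                          edges = FALSE, source = "mask") {
  if (r_min > r_max) stop("r_min must not exceed r_max")
  edge <- if (edges) {
    e <- mask
    storage.mode(e) <- "integer"
    e
  } else {
    canny_edges(mask, sigma = 1)
  }
  res <- hough_circles_cpp(edge, as.integer(r_min), as.integer(r_max),
                           1 - sensitivity, support_min,
                           as.integer(max_circles))
  out <- as_tibble(res)
  out$source <- rep(source, nrow(out))
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Merge duplicate circle detections
#'
#' Circles whose centres lie strictly closer than `threshold` px are the
#' same fruit: connected components of the centre-distance graph (single
#' linkage) are replaced by one circle at the support-weighted mean centre
#' and radius. Merging repeats until all pairwise centre distances are at
#' least `threshold`.
#'
#' @param circles A detections tibble (`x`, `y`, `r`, `score`, ...).
#' @param threshold Centre-distance threshold in px (default 15).
#' @return A deduplicated detections tibble.
#' @export
dedupe_circles <- function(circles, threshold = 15) {
  if (nrow(circles) < 2) return(circles)
  cur <- circles
  repeat {
    n <- nrow(cur)
    d <- as.matrix(stats::dist(cbind(cur$x, cur$y)))
    comp <- graph_components(d < threshold)
    if (max(comp) == n) break
    cur <- dplyr::group_by(cur, comp = comp) |>
      dplyr::summarise(
        x = stats::weighted.mean(.data$x, .data$score),
        y = stats::weighted.mean(.data$y, .data$score),
        r = stats::weighted.mean(.data$r, .data$score),
        score = sum(.data$score),
        source = if (dplyr::n_distinct(.data$source) == 1) {
          .data$source[1]
        } else {
          "fused"
        },
        .groups = "drop"
      ) |>
      dplyr::select(-"comp")
    if (nrow(cur) == n) break
  }
  dplyr::arrange(cur, dplyr::desc(.data$score))
}

# connected components of a logical adjacency matrix (single linkage)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Rectangular label of a detected circle
#'
#' The minimum circumscribed axis-aligned square of each circle: corners at
#' `(x - r, y - r)` and `(x + r, y + r)`, optionally clipped to the image.
#'
#' @param circles Detections tibble.
#' @param image_size Optional `c(width, height)`; when given, labels are
#'   clipped to `[0, width-1] x [0, height-1]`.
#' @return The input tibble with label columns `xmin`, `ymin`, `xmax`,
#'   `ymax` added.
#' @export
circle_to_label <- function(circles, image_size = NULL) {
  out <- dplyr::mutate(circles,
    xmin = .data$x - .data$r, ymin = .data$y - .data$r,
    xmax = .data$x + .data$r, ymax = .data$y + .data$r
  )
  if (!is.null(image_size)) {
    out <- dplyr::mutate(out,
      xmin = pmax(.data$xmin, 0), ymin = pmax(.data$ymin, 0),
      xmax = pmin(.data$xmax, image_size[1] - 1),
      ymax = pmin(.data$ymax, image_size[2] - 1)
    )
  }
  out
}

#' Corner vertices of fruit labels
#'
#' @param labels Tibble with `xmin`, `ymin`, `xmax`, `ymax`.
#' @return A tibble in long form: one row per vertex (`vertex` 1..4,
#'   clockwise from the top-left).
#' @export
label_vertices <- function(labels) {
  labels$label_id <- seq_len(nrow(labels))
  tidyr::pivot_longer(
    dplyr::transmute(labels,
      label_id = .data$label_id,
      `1_x` = .data$xmin, `1_y` = .data$ymin,
      `2_x` = .data$xmax, `2_y` = .data$ymin,
      `3_x` = .data$xmax, `3_y` = .data$ymax,
      `4_x` = .data$xmin, `4_y` = .data$ymax
    ),
    cols = -"label_id",
    names_to = c("vertex", ".value"), names_sep = "_"
  )
}

#' Fuse the detections of the four classifiers (OR rule)
#'
#' A fruit found by any one classifier survives: the union of all detection
#' lists is deduplicated with [dedupe_circles()].
#'
#' @param detections A list of detection tibbles (one per classifier; any
#'   may be empty).
#' @param threshold Dedup centre-distance threshold in px.
#' @return A fused detections tibble with `source = "fused"`.
#' @export
fuse_detections <- function(detections, threshold = 15) {
  all <- dplyr::bind_rows(detections)
  if (nrow(all) == 0) {
    return(tibble(x = double(), y = double(), r = double(),
                  score = double(), source = character()))
  }
  out <- dedupe_circles(all, threshold)
  out$source <- "fused"
  out
}

#' Run the full single-image detection stage
#'
#' Stage 2 of the pipeline for one image: segment with each of the four
#' classifiers, clean each mask, extract circles by the Hough transform,
#' deduplicate per classifier, then fuse with the OR rule.
#'
#' @param image H x W x 3 array (values in \[0, 255\]).
#' @param models A list of trained models (`bayes`, `knn`, `bp`, `svm`).
#' @param config A [litchi_config()].
#' @return A list with `masks` (cleaned binary masks per classifier),
#'   `per_classifier` (detection tibbles) and `fused` (fused detections).
#' @export
detect_fruits <- function(image, models, config = litchi_config()) {
  feats <- NULL
  masks <- list()
  dets <- list()
  for (kind in c("bayes", "knn", "bp", "svm")) {
    if (is.null(models[[kind]])) stop("missing model: ", kind)
    if (kind != "bp" && is.null(feats)) {
      feats <- window_feature_grid(image, config$stride, config$patch_size)
    }
    raw <- segment_image(image, models[[kind]], stride = config$stride,
                         size = config$patch_size, gate = config$bp_gate,
                         features = feats)
    m <- clean_mask(raw, config$dilate_radius, config$min_component_area)
    circ <- hough_circles(m, config$r_min, config$r_max, config$sensitivity,
                          config$support_min, source = kind)
    masks[[kind]] <- m
    dets[[kind]] <- dedupe_circles(circ, config$dedupe_threshold)
  }
  list(masks = masks, per_classifier = dets,
       fused = fuse_detections(dets, config$dedupe_threshold))
}
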