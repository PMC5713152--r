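# Seeded synthetic stereo litchi scenes with full ground truth.
#
# A scene is a pair of 640 x 480 colour images: red, speckle-textured,
# roughly circular fruits (radius 30-50 px) growing singly or in clusters
# spaced around the 40-px category threshold, over green leaf blobs, brown
# branch strokes and a sky gradient, under one of three illumination modes.
# The right image renders every element shifted by its own pinhole
# disparity at a 200 mm baseline, so matching and triangulation have exact
# ground truth.

#' Specification of a synthetic stereo scene
#'
#' @param width,height Image size in px (default 640 x 480).
#' @param clusters Integer vector of intended cluster sizes (1 = category
#'   A, 2 = B, >= 3 = C).
#' @param radius_range Radius range for single fruits (px).
#' @param cluster_radius_range Radius range for clustered fruits (px);
#'   kept in the lower half of the fruit range so overlapping fruits in a
#'   cluster remain individually visible.
#' @param spacing_range Centre spacing of clustered fruits (px), strictly
#'   below the 40-px category threshold.
#' @param depth_range Fruit depth range in mm.
#' @param illumination One of `"sunny_front"`, `"sunny_back"`, `"cloudy"`.
#' @param occlusion_fraction Probability that a cluster is partially
#'   occluded by a foreground leaf (each occluded fruit loses roughly a
#'   third of its disk).
#' @param n_leaves,n_branches Background clutter density.
#' @param seed RNG seed; a fixed seed reproduces the scene byte for byte.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 640, height = 480,
                       clusters = c(1, 1, 2, 2, 3),
                       radius_range = c(30, 50),
                       cluster_radius_range = c(30, 38),
                       spacing_range = c(28, 38),
                       depth_range = c(1200, 2400),
                       illumination = c("cloudy", "sunny_front", "sunny_back"),
                       occlusion_fraction = 0,
                       n_leaves = 140, n_branches = 8,
                       seed = 1) {
  illumination <- match.arg(illumination)
  stopifnot(all(clusters >= 1), occlusion_fraction >= 0,
            occlusion_fraction <= 1,
            spacing_range[2] < 40)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    clusters = as.integer(clusters),
    radius_range = radius_range, cluster_radius_range = cluster_radius_range,
    spacing_range = spacing_range, depth_range = depth_range,
    illumination = illumination, occlusion_fraction = occlusion_fraction,
    n_leaves = as.integer(n_leaves), n_branches = as.integer(n_branches),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

illum_factors <- function(mode) {
  switch(mode,
    sunny_front = list(fruit = 1.05, leaf = 1.00, sky_lo = c(150, 190, 235),
                       sky_hi = c(210, 225, 245), specular = TRUE, flat = 0),
    # back-lighting: leaves are translucent and glow, opaque fruit turns
    # into a dark silhouette against the bright canopy
    sunny_back = list(fruit = 0.45, leaf = 1.15, sky_lo = c(245, 247, 250),
                      sky_hi = c(255, 255, 255), specular = FALSE, flat = 0),
    cloudy = list(fruit = 0.80, leaf = 0.75, sky_lo = c(200, 205, 210),
                  sky_hi = c(225, 228, 232), specular = FALSE, flat = 0.35)
  )
}

smooth3 <- function(m, times = 2) {
  n <- nrow(m)
  for (t in seq_len(times)) {
    p <- rbind(m[1, ], m, m[n, ])
    p <- cbind(p[, 1], p, p[, ncol(p)])
    m <- (p[1:n, 1:n] + p[1:n, 2:(n + 1)] + p[1:n, 3:(n + 2)] +
          p[2:(n + 1), 1:n] + p[2:(n + 1), 2:(n + 1)] + p[2:(n + 1), 3:(n + 2)] +
          p[3:(n + 2), 1:n] + p[3:(n + 2), 2:(n + 1)] + p[3:(n + 2), 3:(n + 2)]) / 9
  }
  m
}

# ---- element samplers (all randomness happens here, before rendering) ----

sample_scene_elements <- function(spec, rig) {
  W <- spec$width; H <- spec$height
  ax <- rig$left$intrinsics$ax
  bmm <- rig$baseline
  # canopy foliage spans a range of depths behind the fruit, so the
  # background exhibits real parallax rather than a rigid shift
  bg_depth_range <- c(2600, 3800)
  d_bg <- round(ax * bmm / mean(bg_depth_range))

  # dense-foliage base: low-contrast mottle over a deep-green field, with
  # bright sky showing only through a few upper-canopy gaps
  mw <- W + 260
  mottle <- smooth3(matrix(runif((H %/% 4) * (mw %/% 4), -1, 1),
                           H %/% 4, mw %/% 4), 2)
  mottle <- 1 + 0.18 * mottle / max(abs(mottle))
  # a few large open-sky regions high in the canopy (small bright holes
  # scattered through the crown would put a high-contrast background edge
  # into almost every fruit template, which field imagery does not show)
  n_gaps <- 3
  sky_gaps <- tibble(
    x = runif(n_gaps, 0, W),
    y = runif(n_gaps, 0, 0.22 * H),
    a = runif(n_gaps, 80, 150),
    b = runif(n_gaps, 45, 80),
    angle = runif(n_gaps, 0, pi),
    d = d_bg
  )

  leaves <- if (spec$n_leaves > 0) {
    z_leaf <- runif(spec$n_leaves, bg_depth_range[1], bg_depth_range[2])
    tibble(
      x = runif(spec$n_leaves, -20, W + 20),
      y = runif(spec$n_leaves, -20, H + 20),
      a = runif(spec$n_leaves, 18, 45),
      b = runif(spec$n_leaves, 9, 22),
      angle = runif(spec$n_leaves, 0, pi),
      r_col = pmax(20, 60 + rnorm(spec$n_leaves, 0, 18)),
      g_col = pmax(50, 128 + rnorm(spec$n_leaves, 0, 22)),
      b_col = pmax(15, 58 + rnorm(spec$n_leaves, 0, 15)),
      z = z_leaf,
      d = round(ax * bmm / z_leaf)
    ) |>
      dplyr::arrange(dplyr::desc(.data$z)) # paint far foliage first
  } else {
    tibble(x = double(), y = double(), a = double(), b = double(),
           angle = double(), r_col = double(), g_col = double(),
           b_col = double(), z = double(), d = double())
  }

  branches <- if (spec$n_branches > 0) {
    x0 <- runif(spec$n_branches, 0, W)
    y0 <- runif(spec$n_branches, 0, H)
    ang <- runif(spec$n_branches, 0, pi)
    len <- runif(spec$n_branches, 120, 320)
    z_br <- runif(spec$n_branches, bg_depth_range[1], bg_depth_range[2])
    tibble(
      x0 = x0, y0 = y0,
      x1 = x0 + len * cos(ang), y1 = y0 + len * sin(ang),
      w = runif(spec$n_branches, 5, 12),
      r_col = 110 + rnorm(spec$n_branches, 0, 12),
      g_col = 78 + rnorm(spec$n_branches, 0, 10),
      b_col = 48 + rnorm(spec$n_branches, 0, 8),
      d = round(ax * bmm / z_br)
    )
  } else {
    tibble(x0 = double(), y0 = double(), x1 = double(), y1 = double(),
           w = double(), r_col = double(), g_col = double(),
           b_col = double(), d = double())
  }

  # cluster layout: members stay within `ext - 10` px of the cluster anchor
  # and anchors stay >= 2*ext + 25 apart, so cross-cluster fruit centres are
  # always > 40 px apart and the intended categories are exactly the 40-px
  # single-linkage components of the true centres
  ext <- 55
  sep <- 2 * ext + 25
  d_max_scene <- round(ax * bmm / spec$depth_range[1])
  margin <- 62
  anchors <- NULL
  for (restart in 1:40) {
    anchors <- matrix(numeric(0), 0, 2)
    done <- TRUE
    for (ci in seq_along(spec$clusters)) {
      ok <- FALSE
      for (try in 1:400) {
        cx <- runif(1, d_max_scene + margin, W - 1 - margin)
        cy <- runif(1, margin, H - 1 - margin)
        if (nrow(anchors) == 0 ||
            min(sqrt((anchors[, 1] - cx)^2 + (anchors[, 2] - cy)^2)) >= sep) {
          anchors <- rbind(anchors, c(cx, cy))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  if (!done) stop("layout failure: cluster plan not placeable in image")

  fruits <- list()
  occluders <- list()
  fid <- 0
  for (ci in seq_along(spec$clusters)) {
    size <- spec$clusters[ci]
    z <- runif(1, spec$depth_range[1], spec$depth_range[2])
    d <- round(ax * bmm / z)
    rr <- if (size == 1) spec$radius_range else spec$cluster_radius_range
    pts <- matrix(anchors[ci, ], 1, 2)
    while (nrow(pts) < size) {
      anchor <- pts[sample.int(nrow(pts), 1), ]
      placed <- FALSE
      for (try in 1:80) {
        th <- runif(1, 0, 2 * pi)
        sp <- runif(1, spec$spacing_range[1], spec$spacing_range[2])
        cand <- anchor + sp * c(cos(th), sin(th))
        dctr <- sqrt(sum((cand - anchors[ci, ])^2))
        dmin <- min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2))
        if (dctr <= ext - 10 && dmin >= 22) {
          pts <- rbind(pts, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("layout failure: cluster plan not placeable in image")
    }
    occluded_cluster <- runif(1) < spec$occlusion_fraction
    occ_member <- if (occluded_cluster) sample.int(size, 1) else 0L
    for (k in seq_len(size)) {
      fid <- fid + 1
      r <- runif(1, rr[1], rr[2])
      base <- c(150 + runif(1, 20, 70), 30 + runif(1, 0, 30),
                45 + runif(1, 0, 30))
      n <- 2 * ceiling(r) + 5
      speck <- smooth3(matrix(runif(n * n, -1, 1), n, n), 2)
      speck <- 1 + 0.45 * speck / max(abs(speck))
      fruits[[fid]] <- list(
        fruit_id = fid, cluster_id = ci, x = pts[k, 1], y = pts[k, 2],
        r = r, depth = z, d = d, base = base, speckle = speck,
        occluded = occluded_cluster && k == occ_member
      )
      if (occluded_cluster && k == occ_member) {
        oth <- runif(1, 0, 2 * pi)
        z_occ <- max(z - 250, 400)
        occluders[[length(occluders) + 1]] <- tibble(
          x = pts[k, 1] + 0.75 * r * cos(oth),
          y = pts[k, 2] + 0.75 * r * sin(oth),
          a = 0.95 * r, b = 0.62 * r,
          angle = runif(1, 0, pi),
          r_col = pmax(20, 55 + rnorm(1, 0, 12)),
          g_col = pmax(50, 120 + rnorm(1, 0, 15)),
          b_col = pmax(15, 52 + rnorm(1, 0, 10)),
          z = z_occ,
          d = round(ax * bmm / z_occ)
        )
      }
    }
  }
  list(leaves = leaves, branches = branches, fruits = fruits,
       occluders = dplyr::bind_rows(occluders), d_bg = d_bg,
       mottle = mottle, sky_gaps = sky_gaps)
}

# ---- rasterisers --------------------------------------------------------

blank_canvas <- function(W, H, il) {
  t_row <- seq(0, 1, length.out = H)
  canvas <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    canvas[, , ch] <- matrix(il$sky_lo[ch] + t_row * (il$sky_hi[ch] - il$sky_lo[ch]),
                             H, W)
  }
  canvas
}

foliage_rgb <- c(48, 88, 46)

# dense-foliage base of a full scene; the coarse mottle field is part of
# the sampled elements so both views index the same texture, the right
# view shifted by the background disparity
foliage_canvas <- function(spec, el, il, shift_bg) {
  H <- spec$height; W <- spec$width
  mi <- pmin(nrow(el$mottle), pmax(1, ceiling((1:H) / 4)))
  mj <- pmin(ncol(el$mottle), pmax(1, ceiling(((1:W) + 130 + shift_bg) / 4)))
  m <- el$mottle[mi, mj]
  canvas <- array(0, c(H, W, 3))
  for (ch in 1:3) canvas[, , ch] <- foliage_rgb[ch] * il$leaf * m
  canvas
}

# small foliage tile used by the training-patch generator
foliage_tile <- function(s, il) {
  m <- smooth3(matrix(runif(s * s, -1, 1), s, s), 2)
  m <- 1 + 0.18 * m / max(abs(m))
  canvas <- array(0, c(s, s, 3))
  for (ch in 1:3) canvas[, , ch] <- foliage_rgb[ch] * il$leaf * m
  canvas
}

draw_ellipse <- function(canvas, x, y, a, b, angle, col3, shift = 0) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  x <- x - shift
  ex <- ceiling(max(a, b))
  x0 <- max(0, floor(x - ex)); x1 <- min(W - 1, ceiling(x + ex))
  y0 <- max(0, floor(y - ex)); y1 <- min(H - 1, ceiling(y + ex))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  lx <- outer(rep(1, length(ys)), xs - x)
  ly <- outer(ys - y, rep(1, length(xs)))
  u <- lx * cos(angle) + ly * sin(angle)
  v <- -lx * sin(angle) + ly * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(canvas)
  # soft interior shading keeps leaves from being flat colour fields
  shade <- 1 - 0.25 * ((u / a)^2 + (v / b)^2)
  for (ch in 1:3) {
    block <- canvas[ys + 1, xs + 1, ch]
    block[inside] <- pmin(255, pmax(0, col3[ch] * shade[inside]))
    canvas[ys + 1, xs + 1, ch] <- block
  }
  canvas
}

draw_branch <- function(canvas, x0, y0, x1, y1, w, col3, shift = 0) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  x0 <- x0 - shift; x1 <- x1 - shift
  bx0 <- max(0, floor(min(x0, x1) - w)); bx1 <- min(W - 1, ceiling(max(x0, x1) + w))
  by0 <- max(0, floor(min(y0, y1) - w)); by1 <- min(H - 1, ceiling(max(y0, y1) + w))
  if (bx0 > bx1 || by0 > by1) return(canvas)
  xs <- bx0:bx1; ys <- by0:by1
  px <- outer(rep(1, length(ys)), xs)
  py <- outer(ys, rep(1, length(xs)))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  dx <- px - (x0 + t * vx); dy <- py - (y0 + t * vy)
  inside <- dx^2 + dy^2 <= (w / 2)^2
  if (!any(inside)) return(canvas)
  shade <- 1 - 0.5 * sqrt(dx^2 + dy^2) / (w / 2)
  for (ch in 1:3) {
    block <- canvas[ys + 1, xs + 1, ch]
    block[inside] <- pmin(255, pmax(0, col3[ch] * (0.7 + 0.5 * shade[inside])))
    canvas[ys + 1, xs + 1, ch] <- block
  }
  canvas
}

draw_fruit <- function(canvas, fr, il, shift = 0) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  x <- fr$x - shift; y <- fr$y; r <- fr$r
  x0 <- max(0, floor(x - r)); x1 <- min(W - 1, ceiling(x + r))
  y0 <- max(0, floor(y - r)); y1 <- min(H - 1, ceiling(y + r))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  lx <- outer(rep(1, length(ys)), xs - x)
  ly <- outer(ys - y, rep(1, length(xs)))
  rho2 <- (lx^2 + ly^2) / r^2
  inside <- rho2 <= 1
  if (!any(inside)) return(canvas)

  shade <- 0.72 + 0.48 * sqrt(pmax(0, 1 - rho2))
  if (il$flat > 0) shade <- (1 - il$flat) * shade + il$flat * mean(shade[inside])
  n <- nrow(fr$speckle)
  si <- pmin(n, pmax(1, round(ly + (n + 1) / 2)))
  sj <- pmin(n, pmax(1, round(lx + (n + 1) / 2)))
  speck <- matrix(fr$speckle[cbind(as.vector(si), as.vector(sj))],
                  nrow(lx), ncol(lx))
  glow <- if (il$specular) {
    hx <- -0.35 * r; hy <- -0.35 * r
    230 * exp(-(((lx - hx)^2 + (ly - hy)^2) / (0.18 * r^2)))
  } else {
    0
  }
  for (ch in 1:3) {
    val <- fr$base[ch] * il$fruit * shade * speck + glow
    block <- canvas[ys + 1, xs + 1, ch]
    block[inside] <- pmin(255, pmax(0, val[inside]))
    canvas[ys + 1, xs + 1, ch] <- block
  }
  canvas
}

render_view <- function(spec, el, side = c("left", "right")) {
  side <- match.arg(side)
  il <- illum_factors(spec$illumination)
  leaf_scale <- il$leaf
  sh <- function(d) if (side == "right") d else 0
  canvas <- foliage_canvas(spec, el, il, sh(el$d_bg))
  if (nrow(el$sky_gaps)) {
    for (i in seq_len(nrow(el$sky_gaps))) {
      g <- el$sky_gaps[i, ]
      canvas <- draw_ellipse(canvas, g$x, g$y, g$a, g$b, g$angle,
                             il$sky_hi, shift = sh(g$d))
    }
  }

  if (nrow(el$branches)) {
    for (i in seq_len(nrow(el$branches))) {
      b <- el$branches[i, ]
      canvas <- draw_branch(canvas, b$x0, b$y0, b$x1, b$y1, b$w,
                            c(b$r_col, b$g_col, b$b_col) * leaf_scale,
                            shift = sh(b$d))
    }
  }
  if (nrow(el$leaves)) {
    for (i in seq_len(nrow(el$leaves))) {
      l <- el$leaves[i, ]
      canvas <- draw_ellipse(canvas, l$x, l$y, l$a, l$b, l$angle,
                             c(l$r_col, l$g_col, l$b_col) * leaf_scale,
                             shift = sh(l$d))
    }
  }
  # fruits and occluding leaves painted in one far-to-near pass so nearer
  # objects correctly cover farther ones in both views
  items <- c(
    lapply(el$fruits, function(f) list(kind = "fruit", z = f$depth, obj = f)),
    if (nrow(el$occluders)) {
      lapply(seq_len(nrow(el$occluders)), function(i) {
        list(kind = "occluder", z = el$occluders$z[i], obj = el$occluders[i, ])
      })
    }
  )
  for (i in order(-vapply(items, function(it) it$z, numeric(1)))) {
    it <- items[[i]]
    if (it$kind == "fruit") {
      canvas <- draw_fruit(canvas, it$obj, il, shift = sh(it$obj$d))
    } else {
      o <- it$obj
      canvas <- draw_ellipse(canvas, o$x, o$y, o$a, o$b, o$angle,
                             c(o$r_col, o$g_col, o$b_col) * leaf_scale,
                             shift = sh(o$d))
    }
  }
  canvas
}

#' Generate a synthetic stereo scene with ground truth
#'
#' Renders the left and right views of a litchi-like scene described by a
#' [scene_spec()]. Every element (background clutter, fruit, occluder)
#' carries a depth and is shifted in the right view by its own rounded
#' pinhole disparity, so the rendered pair is geometrically consistent
#' with the rig.
#'
#' @param spec A [scene_spec()].
#' @param rig A rectified [stereo_rig()] (default: 800 px focal scale,
#'   200 mm baseline).
#' @return A `litchi_scene`: list with `left`, `right` (H x W x 3 arrays,
#'   0-255), `truth` (list of tibbles `fruits` and `clusters`), `spec` and
#'   `rig`.
#' @export
generate_scene <- function(spec, rig = rectified_rig()) {
  el <- with_local_seed(spec$seed, sample_scene_elements(spec, rig))
  left <- render_view(spec, el, "left")
  right <- render_view(spec, el, "right")

  fruits <- dplyr::bind_rows(lapply(el$fruits, function(f) {
    tibble(fruit_id = f$fruit_id, cluster_id = f$cluster_id,
           x = f$x, y = f$y, r = f$r, depth = f$depth, disparity = f$d,
           x_right = f$x - f$d, occluded = f$occluded)
  }))
  clusters <- if (nrow(fruits)) {
    dplyr::group_by(fruits, .data$cluster_id) |>
      dplyr::summarise(
        n = dplyr::n(),
        category = factor(if (dplyr::n() == 1) "A" else if (dplyr::n() == 2) "B" else "C",
                          levels = c("A", "B", "C")),
        xmin = min(.data$x - .data$r), ymin = min(.data$y - .data$r),
        xmax = max(.data$x + .data$r), ymax = max(.data$y + .data$r),
        depth = .data$depth[1], disparity = .data$disparity[1],
        occluded = any(.data$occluded),
        .groups = "drop"
      ) |>
      dplyr::mutate(u = (.data$xmin + .data$xmax) / 2,
                    v = (.data$ymin + .data$ymax) / 2)
  } else {
    tibble(cluster_id = integer(), n = integer(),
           category = factor(levels = c("A", "B", "C")),
           xmin = double(), ymin = double(), xmax = double(), ymax = double(),
           depth = double(), disparity = double(), occluded = logical(),
           u = double(), v = double())
  }
  # a cluster counts as occluded if any occluding leaf overlaps its box in
  # either view (an occluder can slide over a different cluster in the
  # right view because it carries its own disparity)
  if (nrow(clusters) && nrow(el$occluders)) {
    for (j in seq_len(nrow(clusters))) {
      bx <- c(clusters$xmin[j], clusters$ymin[j],
              clusters$xmax[j], clusters$ymax[j])
      dj <- clusters$disparity[j]
      for (i in seq_len(nrow(el$occluders))) {
        o <- el$occluders[i, ]
        rb <- 0.8 * max(o$a, o$b)
        hit_left <- o$x > bx[1] - rb && o$x < bx[3] + rb &&
          o$y > bx[2] - rb && o$y < bx[4] + rb
        xr <- o$x - o$d + dj # occluder position in left-box coordinates
        hit_right <- xr > bx[1] - rb && xr < bx[3] + rb &&
          o$y > bx[2] - rb && o$y < bx[4] + rb
        if (hit_left || hit_right) clusters$occluded[j] <- TRUE
      }
    }
  }
  structure(list(left = left, right = right,
                 truth = list(fruits = fruits, clusters = clusters),
                 spec = spec, rig = rig),
            class = "litchi_scene")
}

#' Generate labelled 40x40 training patches
#'
#' Fruit patches are rendered fruits (random radius, colour, texture and
#' illumination mode) cropped to their circumscribed square and resized to
#' 40 x 40; non-fruit patches are crops of leaf, branch and sky background.
#'
#' @param n_per_class Patches per class (default 150).
#' @param illumination Illumination modes cycled through while rendering.
#' @param seed RNG seed.
#' @return A tibble with list-column `patch` (40 x 40 x 3 arrays, 0-255),
#'   `label` (`"fruit"` / `"non_fruit"`) and `illumination`.
#' @export
generate_training_patches <- function(n_per_class = 150,
                                      illumination = c("cloudy", "sunny_front",
                                                       "sunny_back"),
                                      seed = 1) {
  stopifnot(n_per_class >= 2)
  with_local_seed(seed, {
    modes <- rep(illumination, length.out = n_per_class)
    fruit <- lapply(seq_len(n_per_class), function(i) {
      il <- illum_factors(modes[i])
      r <- runif(1, 30, 50)
      s <- 2 * ceiling(r) + 9
      canvas <- foliage_tile(s, il)
      for (j in 1:3) {
        canvas <- draw_ellipse(canvas, runif(1, 0, s), runif(1, 0, s),
                               runif(1, 15, 30), runif(1, 8, 16),
                               runif(1, 0, pi),
                               c(55 + rnorm(1, 0, 12), 125 + rnorm(1, 0, 18),
                                 55 + rnorm(1, 0, 10)) * il$leaf)
      }
      n <- 2 * ceiling(r) + 5
      speck <- smooth3(matrix(runif(n * n, -1, 1), n, n), 2)
      speck <- 1 + 0.45 * speck / max(abs(speck))
      fr <- list(x = (s - 1) / 2, y = (s - 1) / 2, r = r,
                 base = c(150 + runif(1, 20, 70), 30 + runif(1, 0, 30),
                          45 + runif(1, 0, 30)),
                 speckle = speck)
      canvas <- draw_fruit(canvas, fr, il)
      crop <- floor((s - 2 * r) / 2)
      sub <- canvas[(crop + 1):(crop + floor(2 * r)),
                    (crop + 1):(crop + floor(2 * r)), , drop = FALSE]
      resize_image(sub, 40, 40)
    })
    # background patches are crops of rendered fruit-free scenes, so the
    # non-fruit class is sampled from the same canopy distribution the
    # classifiers will face (foliage, branches, sky gaps and their edges)
    bg_modes <- unique(modes)
    bg_scenes <- lapply(bg_modes, function(mode) {
      generate_scene(scene_spec(clusters = integer(0), illumination = mode,
                                seed = sample.int(1e6, 1)))$left
    })
    names(bg_scenes) <- bg_modes
    bg <- lapply(seq_len(n_per_class), function(i) {
      img <- bg_scenes[[modes[i]]]
      x0 <- sample.int(dim(img)[2] - 40, 1)
      y0 <- sample.int(dim(img)[1] - 40, 1)
      img[(y0 + 1):(y0 + 40), (x0 + 1):(x0 + 40), , drop = FALSE]
    })
    tibble(
      patch = c(fruit, bg),
      label = factor(rep(c("fruit", "non_fruit"), each = n_per_class),
                     levels = litchi_classes),
      illumination = rep(modes, 2)
    )
  })
}

#' Resize an image by bilinear interpolation
#'
#' @param img H x W x 3 array or H x W matrix.
#' @param width,height Target size in px.
#' @return Resized array/matrix on the same intensity scale.
#' @export
resize_image <- function(img, width, height) {
  out <- EBImage::resize(img, w = height, h = width, filter = "bilinear")
  if (is.matrix(img)) as.matrix(out) else {
    a <- as.array(out)
    dim(a) <- c(height, width, dim(img)[3])
    a
  }
}

#' Sample 3x3 neighbourhood training inputs for the BP network
#'
#' Draws pixel neighbourhoods from labelled patches: fruit inputs come
#' from the central fruit region, non-fruit inputs preferentially from
#' pixels that pass the fruit-colour gate (hard negatives such as brown
#' branches).
#'
#' @param patches Patch tibble from [generate_training_patches()].
#' @param n_per_patch Neighbourhoods sampled per patch.
#' @param gate Colour gate `R - B` threshold.
#' @param seed RNG seed.
#' @return Tibble with columns `p1..p9` (intensities in \[0, 1\]) and
#'   `label`.
#' @export
bp_training_samples <- function(patches, n_per_patch = 3, gate = 50,
                                seed = 1234) {
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(patches)), function(i) {
      p <- patches$patch[[i]]
      lab <- patches$label[i]
      g <- as_gray(p) / 255
      s <- nrow(g)
      if (lab == "fruit") {
        ctr <- (s + 1) / 2
        xs <- round(ctr + runif(n_per_patch, -s / 5, s / 5))
        ys <- round(ctr + runif(n_per_patch, -s / 5, s / 5))
      } else {
        rb <- p[, , 1] - p[, , 3]
        hard <- which(rb > gate, arr.ind = TRUE)
        hard <- hard[hard[, 1] > 1 & hard[, 1] < s & hard[, 2] > 1 &
                       hard[, 2] < s, , drop = FALSE]
        if (nrow(hard) >= n_per_patch) {
          pick <- hard[sample.int(nrow(hard), n_per_patch), , drop = FALSE]
          ys <- pick[, 1]; xs <- pick[, 2]
        } else {
          xs <- round(runif(n_per_patch, 2, s - 1))
          ys <- round(runif(n_per_patch, 2, s - 1))
        }
      }
      X <- matrix(0, n_per_patch, 9)
      for (k in seq_len(n_per_patch)) {
        X[k, ] <- as.numeric(g[(ys[k] - 1):(ys[k] + 1),
                               (xs[k] - 1):(xs[k] + 1)])
      }
      colnames(X) <- paste0("p", 1:9)
      out <- as_tibble(X)
      out$label <- lab
      out
    })
    dplyr::bind_rows(rows)
  })
}

#' Write / read a scene bundle
#'
#' A scene directory holds `left.png`, `right.png`, `truth.json` and
#' `spec.yaml`.
#'
#' @param scene A `litchi_scene`.
#' @param dir Directory path (created if needed).
#' @return `read_scene` returns the scene (without the rig, which is
#'   stored in `spec.yaml` as baseline/intrinsics); `write_scene` returns
#'   `dir` invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(scene$left / 255, file.path(dir, "left.png"))
  png::writePNG(scene$right / 255, file.path(dir, "right.png"))
  jsonlite::write_json(
    list(fruits = scene$truth$fruits, clusters = scene$truth$clusters),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA
  )
  sp <- unclass(scene$spec)
  yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  left <- png::readPNG(file.path(dir, "left.png")) * 255
  right <- png::readPNG(file.path(dir, "right.png")) * 255
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  sp <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  spec <- do.call(scene_spec, sp[setdiff(names(sp), c())])
  truth <- list(fruits = as_tibble(tr$fruits), clusters = as_tibble(tr$clusters))
  if (nrow(truth$clusters)) {
    truth$clusters$category <- factor(truth$clusters$category,
                                      levels = c("A", "B", "C"))
  }
  structure(list(left = left, right = right, truth = truth, spec = spec,
                 rig = rectified_rig()),
            class = "litchi_scene")
}
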