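# Stereo matching of recognized clusters: normalized cross-correlation of
# the cluster label template along the epipolar row, ordering/row
# constraints, and 3-D localization by triangulation.

#' Normalized cross-correlation at one disparity
#'
#' Zero-mean cross-correlation of the left template (the cluster label box)
#' with the right-image window shifted left by `d` pixels, normalized by
#' both root sums of squares. Invariant to positive linear gray-level
#' transforms of either window.
#'
#' @param left,right Grayscale matrices (same size, values on any scale).
#' @param box Template box `c(xmin, ymin, xmax, ymax)` (0-based, inclusive).
#' @param d Candidate disparity in px (>= 0).
#' @return The correlation value in \[-1, 1\].
#' @export
ncc <- function(left, right, box, d) {
  b <- round(box)
  H <- nrow(left); W <- ncol(left)
  if (b[1] < 0 || b[2] < 0 || b[3] > W - 1 || b[4] > H - 1) {
    stop("template box outside the left image")
  }
  if (b[1] - d < 0 || b[3] - d > ncol(right) - 1) {
    stop("shifted window outside the right image")
  }
  rows <- (b[2] + 1):(b[4] + 1)
  t1 <- left[rows, (b[1] + 1):(b[3] + 1), drop = FALSE]
  t2 <- right[rows, (b[1] - d + 1):(b[3] - d + 1), drop = FALSE]
  t1 <- t1 - mean(t1)
  t2 <- t2 - mean(t2)
  s1 <- sum(t1^2); s2 <- sum(t2^2)
  if (s1 == 0 || s2 == 0) stop("undefined correlation: window has zero variance")
  sum(t1 * t2) / sqrt(s1 * s2)
}

#' Match recognized clusters into the right image
#'
#' Each left-image cluster label is used as an NCC template and searched
#' along its epipolar row over disparities `d_range`; the best-scoring
#' disparity wins and a match is kept iff its score reaches `threshold`
#' (default 0.6). Disparities whose shifted window leaves the right image
#' are skipped rather than zero-padded.
#'
#' @param left_img,right_img H x W x 3 arrays (or grayscale matrices) of a
#'   rectified stereo pair.
#' @param clusters Cluster tibble from [assign_categories()].
#' @param d_range Integer disparity candidates (default `0:200`).
#' @param threshold NCC acceptance threshold (default 0.6).
#' @return A tibble of matches: `cluster_id`, `category`, left centre
#'   `u`, `v`, `right_u`, `right_v`, `disparity`, `score`.
#' @export
match_clusters <- function(left_img, right_img, clusters, d_range = 0:200,
                           threshold = 0.6) {
  gl <- as_gray(left_img)
  gr <- as_gray(right_img)
  empty <- tibble(cluster_id = integer(), category = factor(levels = c("A", "B", "C")),
                  u = double(), v = double(), right_u = double(),
                  right_v = double(), disparity = double(), score = double())
  if (nrow(clusters) == 0) return(empty)

  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    box <- round(c(cl$xmin, cl$ymin, cl$xmax, cl$ymax))
    best_d <- NA_real_; best_s <- -Inf
    for (d in d_range) {
      if (box[1] - d < 0 || box[3] - d > ncol(gr) - 1) next
      s <- tryCatch(ncc(gl, gr, box, d), error = function(e) NA_real_)
      if (!is.na(s) && s > best_s) {
        best_s <- s
        best_d <- d
      }
    }
    if (!is.finite(best_s) || best_s < threshold) return(NULL)
    tibble(cluster_id = cl$cluster_id, category = cl$category,
           u = cl$u, v = cl$v,
           right_u = cl$u - best_d, right_v = cl$v,
           disparity = best_d, score = best_s)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Enforce the ordering and epipolar constraints
#'
#' Matches whose left/right rows differ by more than `row_tol` px are
#' discarded. The ordering constraint (left-to-right order of clusters must
#' agree between the two views) applies to clusters sharing an epipolar
#' band — their rows must lie within `order_band` px, since ordering along
#' epipolar lines carries no information for objects in different rows —
#' and is enforced by repeatedly discarding the lowest-scoring match
#' involved in any order violation. Clusters flagged by the caller as
#' having no left-side anchor in the right image are dropped.
#'
#' @param matches Match tibble from [match_clusters()].
#' @param row_tol Epipolar row tolerance in px (default 1; set 0 for the
#'   strict same-row rule).
#' @param order_band Row distance within which two matches are subject to
#'   the ordering constraint (default 40 px, the nominal fruit diameter;
#'   `Inf` applies it globally).
#' @param no_anchor Optional vector of `cluster_id`s to drop (no left-side
#'   anchor).
#' @return The surviving matches, ordered by `u`.
#' @export
enforce_constraints <- function(matches, row_tol = 1, order_band = 40,
                                no_anchor = NULL) {
  m <- matches
  if (!is.null(no_anchor)) m <- m[!(m$cluster_id %in% no_anchor), ]
  if (nrow(m) == 0) return(m)
  m <- m[abs(m$v - m$right_v) <= row_tol, ]
  # iteratively drop the lowest-scoring participant in an order violation
  repeat {
    if (nrow(m) < 2) break
    viol <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        if (abs(m$v[i] - m$v[j]) > order_band) next
        if (sign(m$u[i] - m$u[j]) * sign(m$right_u[i] - m$right_u[j]) < 0) {
          viol[i] <- TRUE
          viol[j] <- TRUE
        }
      }
    }
    if (!any(viol)) break
    worst <- which(viol)[which.min(m$score[viol])]
    m <- m[-worst, ]
  }
  # restoration pass: a match dropped early may have conflicted only with
  # matches that were themselves dropped later; re-admit (strongest first)
  # whatever no longer violates the ordering
  dropped <- matches[!(matches$cluster_id %in% m$cluster_id) &
                       abs(matches$v - matches$right_v) <= row_tol &
                       !(matches$cluster_id %in% no_anchor), , drop = FALSE]
  if (nrow(dropped)) {
    ok_with <- function(mm, cand) {
      sel <- abs(mm$v - cand$v) <= order_band
      if (!any(sel)) return(TRUE)
      all((mm$u[sel] - cand$u) * (mm$right_u[sel] - cand$right_u) >= 0)
    }
    for (i in order(-dropped$score)) {
      if (ok_with(m, dropped[i, ])) m <- dplyr::bind_rows(m, dropped[i, ])
    }
  }
  dplyr::arrange(m, .data$u)
}

#' Localize matched clusters in 3-D
#'
#' Triangulates each matched cluster centre with its disparity on a
#' rectified rig; world coordinates are in the left-camera frame (mm).
#'
#' @param rig A rectified [stereo_rig()].
#' @param matches Match tibble.
#' @return The matches with `xw`, `yw`, `zw` columns added (mm).
#' @export
localize_matches <- function(rig, matches) {
  if (nrow(matches) == 0) {
    matches$xw <- double()
    matches$yw <- double()
    matches$zw <- double()
    return(matches)
  }
  wp <- tibble(xw = rep(NA_real_, nrow(matches)), yw = NA_real_, zw = NA_real_)
  ok <- matches$disparity > 0
  if (any(ok)) {
    wp[ok, ] <- triangulate(rig, cbind(matches$u, matches$v)[ok, , drop = FALSE],
                            matches$disparity[ok])
  }
  dplyr::bind_cols(matches, wp)
}
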