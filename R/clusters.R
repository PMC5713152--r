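# Cluster-category recognition: the 40-px geometric-centre rule.
#
# Categories: A = single fruit, B = two clustered fruits, C = more than
# two clustered fruits, where "clustered" means geometric centres strictly
# closer than the average single-fruit diameter (40 px), chained by single
# linkage.

#' Assign fruit detections to cluster categories
#'
#' Connected components of the strict `< diameter` centre-distance graph
#' (single linkage): component size 1 is category A, size 2 category B and
#' size 3 or more category C. Centres at exactly `diameter` px do not
#' cluster. The labels of the member circles are merged into one large
#' label whose corners take the extreme abscissas/ordinates, and the
#' cluster centre is the diagonal intersection (midpoint) of that label;
#' for merged clusters the member circle centres are dropped from the
#' public geometry (they remain available in the `members` list-column).
#'
#' @param circles Deduplicated detections tibble (`x`, `y`, `r`, ...).
#' @param diameter Centre-distance threshold in px (default 40).
#' @param image_size Optional `c(width, height)` used to clip the merged
#'   label; cluster geometry itself uses unclipped member labels.
#' @return A tibble of clusters: `cluster_id`, `category` (factor A/B/C),
#'   `n`, label box `xmin..ymax`, centre `u`, `v`, and `members`
#'   (list-column of member detection rows).
#' @export
assign_categories <- function(circles, diameter = 40, image_size = NULL) {
  if (nrow(circles) == 0) {
    return(tibble(cluster_id = integer(), category = factor(levels = c("A", "B", "C")),
                  n = integer(), xmin = double(), ymin = double(),
                  xmax = double(), ymax = double(), u = double(), v = double(),
                  members = list()))
  }
  d <- as.matrix(stats::dist(cbind(circles$x, circles$y)))
  comp <- graph_components(d < diameter) # strict inequality
  labs <- circle_to_label(circles) # unclipped geometry for merging

  rows <- lapply(sort(unique(comp)), function(ci) {
    idx <- which(comp == ci)
    box <- merge_labels(labs[idx, , drop = FALSE])
    if (!is.null(image_size)) {
      box <- c(
        max(box[1], 0), max(box[2], 0),
        min(box[3], image_size[1] - 1), min(box[4], image_size[2] - 1)
      )
    }
    ctr <- cluster_center(box)
    tibble(
      n = length(idx),
      category = factor(if (length(idx) == 1) "A" else if (length(idx) == 2) "B" else "C",
                        levels = c("A", "B", "C")),
      xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4],
      u = ctr[1], v = ctr[2],
      members = list(circles[idx, , drop = FALSE])
    )
  })
  out <- dplyr::bind_rows(rows)
  # deterministic order regardless of input permutation
  out <- dplyr::arrange(out, .data$u, .data$v)
  out$cluster_id <- seq_len(nrow(out))
  dplyr::select(out, "cluster_id", "category", "n", "xmin", "ymin",
                "xmax", "ymax", "u", "v", "members")
}

#' Merge fruit labels into one box
#'
#' The merged label's corners are the minimum and maximum abscissas and
#' ordinates over all member label vertices.
#'
#' @param labels Tibble (or data frame) with `xmin`, `ymin`, `xmax`,
#'   `ymax`; at least one row.
#' @return Numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
merge_labels <- function(labels) {
  if (is.null(nrow(labels)) || nrow(labels) == 0) {
    stop("empty cluster: at least one label is required")
  }
  c(min(labels$xmin), min(labels$ymin), max(labels$xmax), max(labels$ymax))
}

#' Geometric centre of a cluster label
#'
#' The diagonal intersection point of the (axis-aligned) label box, i.e.
#' its midpoint.
#'
#' @param box Numeric `c(xmin, ymin, xmax, ymax)`.
#' @return Numeric `c(u, v)` in pixels.
#' @export
cluster_center <- function(box) {
  c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
}
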