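# Scoring recognition and matching against ground truth: the
# missed-cluster definitions, the recognition-rate formulas, the matching
# rate and a single-fruit CHT matching baseline for comparison.

#' Area of intersection of two disks
#'
#' Closed-form lens area of two circles with radii `r1`, `r2` and centre
#' distance `d`.
#'
#' @param r1,r2 Radii.
#' @param d Centre distance.
#' @return Intersection area (same squared units).
#' @export
circle_intersection_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

box_overlap <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

#' Score detected clusters against ground truth
#'
#' Detected clusters are assigned one-to-one to true clusters greedily by
#' descending label-box overlap. An assigned true cluster counts as
#' detected (TP) unless it is "missed" under the recovered-fruit rule: a
#' member fruit is recovered when some detected circle of the assigned
#' cluster covers at least `fraction` (default 25%) of the true fruit
#' disk; a single fruit (A) is missed if its fruit is not recovered, a
#' pair (B) is missed if one or two members are not recovered, and a
#' multiple cluster (C) is missed if two or more members are not
#' recovered. Unassigned true clusters are FN; unassigned detections are
#' FP.
#'
#' @param clusters Detected cluster tibble from [assign_categories()]
#'   (with the `members` list-column).
#' @param truth Scene truth: a list with tibbles `fruits` and `clusters`
#'   (as in `litchi_scene$truth`).
#' @param fraction Minimum recovered-area fraction of a fruit (default
#'   0.25).
#' @param condition Condition tag recorded in the output.
#' @return A one-row tibble of recognition counts: `condition`,
#'   `n_clusters`, `tp`, `fp`, `fn`.
#' @export
match_detections_to_truth <- function(clusters, truth, fraction = 0.25,
                                      condition = "synthetic") {
  tc <- truth$clusters
  tf <- truth$fruits
  n_det <- nrow(clusters)
  n_true <- nrow(tc)
  if (n_true == 0) {
    return(tibble(condition = condition, n_clusters = 0L,
                  tp = 0L, fp = n_det, fn = 0L))
  }

  ov <- matrix(0, max(n_det, 1), n_true)
  if (n_det > 0) {
    for (i in seq_len(n_det)) {
      for (j in seq_len(n_true)) {
        ov[i, j] <- box_overlap(
          c(clusters$xmin[i], clusters$ymin[i], clusters$xmax[i], clusters$ymax[i]),
          c(tc$xmin[j], tc$ymin[j], tc$xmax[j], tc$ymax[j])
        )
      }
    }
  }

  assign <- rep(NA_integer_, n_true) # detected index per true cluster
  if (n_det > 0) {
    ow <- ov
    repeat {
      m <- which(ow == max(ow), arr.ind = TRUE)[1, , drop = TRUE]
      if (ow[m[1], m[2]] <= 0) break
      assign[m[2]] <- m[1]
      ow[m[1], ] <- -1
      ow[, m[2]] <- -1
      if (all(ow <= 0)) break
    }
  }

  tp <- 0L
  for (j in seq_len(n_true)) {
    if (is.na(assign[j])) next
    mem <- clusters$members[[assign[j]]]
    fr <- tf[tf$cluster_id == tc$cluster_id[j], , drop = FALSE]
    recovered <- vapply(seq_len(nrow(fr)), function(k) {
      area <- pi * fr$r[k]^2
      cov <- 0
      for (i in seq_len(nrow(mem))) {
        d <- sqrt((mem$x[i] - fr$x[k])^2 + (mem$y[i] - fr$y[k])^2)
        cov <- max(cov, circle_intersection_area(fr$r[k], mem$r[i], d) / area)
      }
      cov >= fraction
    }, logical(1))
    n_missed <- sum(!recovered)
    missed <- switch(as.character(tc$category[j]),
      A = n_missed >= 1,
      B = n_missed >= 1,
      C = n_missed >= 2
    )
    if (!missed) tp <- tp + 1L
  }
  fn <- n_true - tp
  # detections assigned to a true cluster correspond to a real cluster
  # region; only unassigned detections count as false positives
  tibble(condition = condition, n_clusters = as.integer(n_true),
         tp = tp, fp = as.integer(n_det - sum(!is.na(assign))), fn = as.integer(fn))
}

#' Recognition metrics from counts
#'
#' True/false positive/negative rates, precision, recall and F1 (percent):
#' `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TP)`, `fnr = FN/(FN+TP)`,
#' `precision = TP/(FP+TP)`, `recall = tpr`,
#' `f1 = 2 * precision * recall / (precision + recall)`. Values are kept
#' at full precision; round only at report formatting.
#'
#' @param counts Tibble with columns `tp`, `fp`, `fn` (and optionally
#'   `condition`, `n_clusters`), one row per condition.
#' @return The input with metric columns `tpr`, `fpr`, `fnr`, `precision`,
#'   `recall`, `f1` (percent) and a `degenerate` flag (TRUE when
#'   `TP + FP = 0` forces precision to 0).
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp + counts$fn <= 0)) {
    stop("TP + FN must be positive to define the recognition rates")
  }
  out <- dplyr::mutate(counts,
    tpr = 100 * .data$tp / (.data$tp + .data$fn),
    fnr = 100 * .data$fn / (.data$fn + .data$tp),
    degenerate = (.data$tp + .data$fp) == 0,
    fpr = ifelse(.data$degenerate, 0, 100 * .data$fp / (.data$fp + .data$tp)),
    precision = ifelse(.data$degenerate, 0,
                       100 * .data$tp / (.data$fp + .data$tp)),
    recall = .data$tpr,
    f1 = ifelse(.data$precision + .data$recall == 0, 0,
                2 * .data$precision * .data$recall /
                  (.data$precision + .data$recall))
  )
  dplyr::relocate(out, "degenerate", .after = dplyr::last_col())
}

#' Format a recognition-metrics report table
#'
#' Rounds every rate to two decimals (half up). The F1 column is computed
#' from the *rounded* precision and recall, matching the convention of the
#' reference report tables this layout mirrors.
#'
#' @param metrics Output of [compute_metrics()].
#' @return A tibble with 2-decimal `tpr`, `fpr`, `fnr`, `precision`,
#'   `recall` and `f1` columns (percent).
#' @export
format_metrics_report <- function(metrics) {
  out <- dplyr::mutate(metrics,
    tpr = round_half_up(.data$tpr), fpr = round_half_up(.data$fpr),
    fnr = round_half_up(.data$fnr),
    precision = round_half_up(.data$precision),
    recall = round_half_up(.data$recall),
    f1 = ifelse(.data$precision + .data$recall == 0, 0,
                round_half_up(2 * round_half_up(.data$precision) *
                                round_half_up(.data$recall) /
                                (round_half_up(.data$precision) +
                                   round_half_up(.data$recall))))
  )
  dplyr::select(out, -"degenerate")
}

#' Matching success rate
#'
#' @param n_correct,n_total Correctly matched and total pair counts.
#' @return The rate `100 * n_correct / n_total` (percent).
#' @export
matching_rate <- function(n_correct, n_total) {
  if (any(n_total <= 0)) stop("matching rate undefined for an empty set")
  100 * n_correct / n_total
}

#' Round half away from zero
#'
#' Report-formatting rounding used for the printed rate tables (base R
#' `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the epsilon absorbs binary representation error in x * p (e.g.
  # 1.005 * 100 = 100.4999...)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Single-fruit CHT matching baseline
#'
#' The comparison method: individual circles detected in the left and
#' right images are paired when their radii differ by at most
#' `radius_tol`, their rows by at most `row_tol`, and the implied
#' disparity lies in `[0, d_max]`; candidate pairs are accepted greedily
#' nearest-disparity first, one-to-one.
#'
#' @param left_circles,right_circles Detection tibbles (`x`, `y`, `r`).
#' @param radius_tol Radius agreement tolerance in px (default 5).
#' @param row_tol Row agreement tolerance in px (default 2).
#' @param d_max Largest admissible disparity (default 250).
#' @return A tibble of pairs: `left_id`, `right_id`, left `x`, `y`, `r`,
#'   and `disparity`.
#' @export
cht_baseline_match <- function(left_circles, right_circles, radius_tol = 5,
                               row_tol = 2, d_max = 250) {
  nl <- nrow(left_circles); nr <- nrow(right_circles)
  empty <- tibble(left_id = integer(), right_id = integer(), x = double(),
                  y = double(), r = double(), disparity = double())
  if (nl == 0 || nr == 0) return(empty)
  cand <- list()
  for (i in seq_len(nl)) {
    for (j in seq_len(nr)) {
      d <- left_circles$x[i] - right_circles$x[j]
      if (abs(left_circles$r[i] - right_circles$r[j]) <= radius_tol &&
          abs(left_circles$y[i] - right_circles$y[j]) <= row_tol &&
          d >= 0 && d <= d_max) {
        cand[[length(cand) + 1]] <- c(i, j, d)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used_l <- logical(nl); used_r <- logical(nr)
  keep <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_l[i] || used_r[j]) next
    used_l[i] <- TRUE
    used_r[j] <- TRUE
    keep[[length(keep) + 1]] <- tibble(
      left_id = as.integer(i), right_id = as.integer(j),
      x = left_circles$x[i], y = left_circles$y[i], r = left_circles$r[i],
      disparity = cand[k, 3]
    )
  }
  dplyr::bind_rows(keep)
}

#' Bundled orchard evaluation counts
#'
#' Reference per-condition counts from a 432-cluster orchard evaluation of
#' this pipeline under six illumination/occlusion conditions (SFP/SFN =
#' sunny front-lighting with partial/no occlusion, SBP/SBN = sunny
#' back-lighting, CP/CN = cloudy day), bundled so the metric formulas can
#' be exercised against published rates. `orchard_recognition_counts()`
#' returns cluster recognition counts (TP/FP/FN per condition);
#' `orchard_matching_counts()` returns matched-pair counts for the
#' cluster matcher and the single-fruit CHT baseline.
#'
#' @return A tibble.
#' @export
orchard_recognition_counts <- function() {
  path <- system.file("extdata", "orchard_recognition_counts.csv",
                      package = "litchistereo", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}

#' @rdname orchard_recognition_counts
#' @export
orchard_matching_counts <- function() {
  path <- system.file("extdata", "orchard_matching_counts.csv",
                      package = "litchistereo", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}

#' Evaluate the full pipeline on one synthetic scene
#'
#' Runs detection, categorization and matching on a generated scene and
#' scores the result against the scene truth: recognition counts
#' ([match_detections_to_truth()]), cluster-match disparity correctness
#' (within `disp_tol` px of the rendered disparity) and the single-fruit
#' CHT baseline ([cht_baseline_match()]) on circles detected independently
#' in both views.
#'
#' @param scene A `litchi_scene`.
#' @param models Trained classifier list (see [train_classifiers()]).
#' @param config A [litchi_config()].
#' @param disp_tol Disparity tolerance in px (default 1).
#' @param baseline Also run the CHT single-fruit baseline (default TRUE;
#'   requires a second detection pass on the right image).
#' @return A list with `result` (the [run_pipeline()] output), `counts`,
#'   and a one-row `summary` tibble: recognition counts, numbers of
#'   non-occluded true clusters matched correctly, and baseline fruit
#'   matching counts.
#' @export
evaluate_scene <- function(scene, models, config = litchi_config(),
                           disp_tol = 1, baseline = TRUE) {
  res <- run_pipeline(scene$left, scene$right, models, config,
                      rig = scene$rig)
  counts <- match_detections_to_truth(res$clusters, scene$truth,
                                      condition = scene$spec$illumination)

  tc <- scene$truth$clusters
  match_ok <- 0L
  match_ok_all <- 0L
  n_nonocc <- sum(!tc$occluded)
  if (nrow(res$matches) > 0 && nrow(tc) > 0) {
    for (j in seq_len(nrow(tc))) {
      # a match belongs to this truth cluster when its left centre falls
      # inside the (slightly expanded) truth label box — a partial
      # detection of a cluster centres on the members it did find
      inside <- res$matches$u >= tc$xmin[j] - 20 &
        res$matches$u <= tc$xmax[j] + 20 &
        res$matches$v >= tc$ymin[j] - 20 &
        res$matches$v <= tc$ymax[j] + 20
      hit <- any(inside &
                   abs(res$matches$disparity - tc$disparity[j]) <= disp_tol)
      if (hit) {
        match_ok_all <- match_ok_all + 1L
        if (!tc$occluded[j]) match_ok <- match_ok + 1L
      }
    }
  }

  cht_correct <- NA_integer_
  n_fruits <- nrow(scene$truth$fruits)
  if (baseline) {
    det_r <- detect_fruits(scene$right, models, config)
    pairs <- cht_baseline_match(res$detections$fused, det_r$fused,
                                d_max = config$d_max + 50)
    cht_correct <- 0L
    tf <- scene$truth$fruits
    if (nrow(pairs) > 0 && n_fruits > 0) {
      for (k in seq_len(nrow(tf))) {
        dd <- sqrt((pairs$x - tf$x[k])^2 + (pairs$y - tf$y[k])^2)
        if (length(dd) && min(dd) <= 20) {
          j <- which.min(dd)
          if (abs(pairs$disparity[j] - tf$disparity[k]) <= disp_tol) {
            cht_correct <- cht_correct + 1L
          }
        }
      }
    }
  }

  summary <- tibble(
    illumination = scene$spec$illumination,
    n_clusters = counts$n_clusters, tp = counts$tp, fp = counts$fp,
    fn = counts$fn,
    n_nonoccluded = as.integer(n_nonocc),
    matched_nonoccluded = match_ok,
    matched_all = match_ok_all,
    n_fruits = as.integer(n_fruits),
    cht_correct = cht_correct
  )
  list(result = res, counts = counts, summary = summary)
}
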