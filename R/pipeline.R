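# Pipeline configuration and the end-to-end runner binding stage 2
# (recognition) and stage 3 (matching and localization) together.

#' Pipeline configuration
#'
#' All tunable constants of the pipeline with their working defaults:
#' 40 x 40 patches, 40-px cluster diameter, Hough radii 30-50 px at
#' sensitivity 0.97, 15-px dedup threshold, disk-10 dilation, NCC
#' threshold 0.6 and a 200 mm baseline. Any field can be overridden by
#' name; unknown fields are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `litchi_config` list.
#' @examples
#' litchi_config(stride = 16, ncc_threshold = 0.7)$stride
#' @export
litchi_config <- function(...) {
  defaults <- list(
    image_size = c(640L, 480L),
    patch_size = 40L,
    cluster_diameter = 40,
    r_min = 30L, r_max = 50L,
    sensitivity = 0.97,
    support_min = 0.35,
    dedupe_threshold = 15,
    dilate_radius = 10L,
    min_component_area = pi * 15^2,
    ncc_threshold = 0.6,
    d_max = 200L,
    knn_k = 5L,
    bp_hidden = 7L,
    bp_seed = 1234L,
    bp_gate = 50,
    stride = 8L,
    row_tol = 1,
    order_band = 40,
    baseline = 200
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "litchi_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A `litchi_config`.
#' @param path File path (`.yaml`).
#' @return `load_config` returns a `litchi_config`; `save_config` returns
#'   `path` invisibly.
#' @export
save_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(litchi_config, vals)
}

#' Train the four fruit classifiers
#'
#' Extracts the 10-dimensional feature vector from every labelled patch
#' and trains the Gaussian naive Bayes, cosine-KNN and linear SVM window
#' classifiers, plus the per-pixel BP network on sampled 3x3
#' neighbourhoods.
#'
#' @param patches Patch tibble from [generate_training_patches()] (or any
#'   tibble with a `patch` list-column of 40x40x3 arrays and `label`).
#' @param config A [litchi_config()].
#' @return A `litchi_models` list with elements `bayes`, `knn`, `bp`,
#'   `svm`.
#' @export
train_classifiers <- function(patches, config = litchi_config()) {
  feats <- patch_features(patches)
  bp_samples <- bp_training_samples(patches, gate = config$bp_gate,
                                    seed = config$bp_seed)
  structure(list(
    bayes = train_bayes(feats),
    knn = train_knn(feats, k = config$knn_k),
    bp = train_bp(bp_samples, J = config$bp_hidden, seed = config$bp_seed),
    svm = train_svm(feats)
  ), class = "litchi_models")
}

#' Save / load the four classifiers
#'
#' One JSON file per classifier inside `dir`.
#'
#' @param models A `litchi_models` list.
#' @param dir Directory path.
#' @return `load_classifiers` returns a `litchi_models` list;
#'   `save_classifiers` returns `dir` invisibly.
#' @export
save_classifiers <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in names(models)) {
    litchi_save_model(models[[kind]], file.path(dir, paste0(kind, ".json")))
  }
  invisible(dir)
}

#' @rdname save_classifiers
#' @export
load_classifiers <- function(dir) {
  kinds <- c("bayes", "knn", "bp", "svm")
  out <- lapply(kinds, function(k) {
    litchi_load_model(file.path(dir, paste0(k, ".json")))
  })
  names(out) <- kinds
  structure(out, class = "litchi_models")
}

#' Run the full recognition-and-matching pipeline on a stereo pair
#'
#' Stage 2: each of the four classifiers segments the left image, masks
#' are cleaned, circles extracted by the Hough transform, deduplicated and
#' fused with the OR rule, and fused fruits are grouped into cluster
#' categories. Stage 3: each cluster label is matched into the right image
#' by NCC along its epipolar row, the ordering/row constraints are
#' enforced, and surviving matches are triangulated. Images larger than
#' `config$image_size` are first resized to it (bilinear); images already
#' at or below that size pass through.
#'
#' @param left,right H x W x 3 arrays of a rectified stereo pair
#'   (values in \[0, 255\]).
#' @param models A `litchi_models` list (all four classifiers required).
#' @param config A [litchi_config()].
#' @param rig A rectified [stereo_rig()]; defaults to the standard rig
#'   with `config$baseline`.
#' @param verbose Print per-stage counts.
#' @return A `litchi_result`: list with `detections` (per-classifier masks
#'   and circles plus the fused set), `clusters`, `matches` (with world
#'   coordinates in mm), `config` and `rig`.
#' @export
run_pipeline <- function(left, right, models, config = litchi_config(),
                         rig = NULL, verbose = FALSE) {
  if (is.null(rig)) rig <- rectified_rig(baseline = config$baseline)
  for (kind in c("bayes", "knn", "bp", "svm")) {
    if (is.null(models[[kind]])) stop("missing model: ", kind)
  }
  tgt <- config$image_size
  if (dim(left)[2] > tgt[1] || dim(left)[1] > tgt[2]) {
    left <- resize_image(left, tgt[1], tgt[2])
    right <- resize_image(right, tgt[1], tgt[2])
  }
  det <- detect_fruits(left, models, config)
  if (verbose) {
    for (k in names(det$masks)) {
      message(sprintf("%-5s: foreground %.1f%%, %d circles", k,
                      100 * mean(det$masks[[k]]),
                      nrow(det$per_classifier[[k]])))
    }
    message(sprintf("fused: %d circles", nrow(det$fused)))
  }
  clusters <- assign_categories(det$fused, config$cluster_diameter,
                                image_size = c(dim(left)[2], dim(left)[1]))
  matches <- match_clusters(left, right, clusters,
                            d_range = 0:config$d_max,
                            threshold = config$ncc_threshold)
  n_raw <- nrow(matches)
  matches <- enforce_constraints(matches, row_tol = config$row_tol,
                                 order_band = config$order_band)
  matches <- localize_matches(rig, matches)
  if (verbose) {
    tab <- table(clusters$category)
    message(sprintf("clusters: %d (A %d, B %d, C %d); matches kept %d of %d",
                    nrow(clusters), tab["A"], tab["B"], tab["C"],
                    nrow(matches), n_raw))
  }
  structure(list(detections = det, clusters = clusters, matches = matches,
                 config = config, rig = rig),
            class = "litchi_result")
}

#' @export
print.litchi_result <- function(x, ...) {
  tab <- table(x$clusters$category)
  cat(sprintf("<litchi_result> %d fused circles -> %d clusters (A %d, B %d, C %d), %d matched\n",
              nrow(x$detections$fused), nrow(x$clusters),
              tab["A"], tab["B"], tab["C"], nrow(x$matches)))
  invisible(x)
}

#' Tidy the pipeline result
#'
#' @param x A `litchi_result`.
#' @param ... Unused.
#' @return The matched-cluster table: one row per recognized cluster with
#'   its category, label box, centre, disparity, NCC score and world
#'   coordinates (mm) where matched.
#' @export
tidy.litchi_result <- function(x, ...) {
  cl <- dplyr::select(x$clusters, "cluster_id", "category", "n",
                      "xmin", "ymin", "xmax", "ymax", "u", "v")
  m <- dplyr::select(x$matches, "cluster_id", "disparity", "score",
                     "xw", "yw", "zw")
  dplyr::left_join(cl, m, by = "cluster_id")
}

#' @rdname tidy.litchi_result
#' @export
glance.litchi_result <- function(x, ...) {
  tab <- table(x$clusters$category)
  tibble(
    n_circles = nrow(x$detections$fused),
    n_clusters = nrow(x$clusters),
    n_A = as.integer(tab["A"]), n_B = as.integer(tab["B"]),
    n_C = as.integer(tab["C"]),
    n_matched = nrow(x$matches),
    mean_score = if (nrow(x$matches)) mean(x$matches$score) else NA_real_,
    mean_depth_mm = if (nrow(x$matches)) mean(x$matches$zw) else NA_real_
  )
}
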