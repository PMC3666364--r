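# End-to-end segmentation pipeline:
# extract features -> train SOM -> FCM on prototypes -> voxel membership
# inheritance -> PVE thresholding -> tissue identification.

#' Pipeline configuration
#'
#' @param window A [window_spec()].
#' @param som_shape SOM lattice dimensions (default `c(10, 10)`).
#' @param lattice `"hexagonal"` or `"rectangular"`.
#' @param som A [som_config()].
#' @param k Number of tissue clusters (default 3).
#' @param m FCM fuzzifier (default 2).
#' @param eps FCM convergence tolerance (default 1e-5).
#' @param tau PVE membership-difference threshold (default 0.02).
#' @param fcm_seed Seed for the FCM initialization.
#' @param selected_features Optional feature-name subset.
#' @param standardize Z-score features before the SOM (default `TRUE`).
#' @return An object of class `somseg_config`.
#' @export
pipeline_config <- function(window = window_spec(),
                            som_shape = c(10L, 10L),
                            lattice = "hexagonal",
                            som = som_config(),
                            k = 3L, m = 2, eps = 1e-5, tau = 0.02,
                            fcm_seed = 1L, selected_features = NULL,
                            standardize = TRUE) {
  stopifnot(inherits(window, "somseg_window"),
            inherits(som, "somseg_som_config"))
  if (!is.null(selected_features))
    selected_features <- resolve_feature_names(selected_features)
  structure(list(window = window, som_shape = as.integer(som_shape),
                 lattice = lattice, som = som, k = as.integer(k), m = m,
                 eps = eps, tau = tau, fcm_seed = as.integer(fcm_seed),
                 selected_features = selected_features,
                 standardize = standardize),
            class = "somseg_config")
}

#' Segment a volume into CSF, GM and WM
#'
#' Runs the full unsupervised pipeline on a skull-stripped, masked volume:
#' per-voxel descriptors, SOM vector quantization, fuzzy c-means on the
#' prototypes, BMU membership inheritance, maximum-membership
#' defuzzification with tau-threshold PVE multi-labels, and tissue naming
#' by ascending mean intensity. Deterministic for fixed seeds.
#'
#' @param vol A `somseg_volume` with a nonempty brain mask.
#' @param config A [pipeline_config()].
#' @param features Optionally, a precomputed `somseg_features` (cache);
#'   when supplied, extraction is skipped and the matrix is used as is.
#' @return An object of class `somseg_result`: `segmentation` (a
#'   `somseg_fuzzyseg` in tissue space), `labels` (tissue `somseg_labelmap`),
#'   `som`, `fcm`, and `meta` (configs, seeds, quantization error, FCM
#'   iterations).
#' @export
segment_volume <- function(vol, config = pipeline_config(), features = NULL) {
  stopifnot(is_volume(vol), inherits(config, "somseg_config"))
  if (!any(vol$mask)) stop("stage features: brain mask is empty")
  if (is.null(features))
    features <- extract_features(vol, config$window,
                                 selected = config$selected_features,
                                 standardize = config$standardize)
  model <- train_som(features, shape = config$som_shape,
                     config = config$som, lattice = config$lattice)
  fcmres <- fcm_cluster(model$prototypes, k = config$k, m = config$m,
                        eps = config$eps, seed = config$fcm_seed)
  seg <- assign_voxels(model, fcmres, features)
  seg <- pve_assign(seg, config$tau)
  labels <- identify_tissues(seg, vol)
  map <- attr(labels, "cluster_to_tissue")
  if (all(sort(map) == seq_len(config$k)))
    seg <- relabel_segmentation(seg, map)
  else
    warning("empty cluster: segmentation left in cluster space")
  structure(list(segmentation = seg, labels = labels, som = model,
                 fcm = fcmres,
                 meta = list(config = config,
                             n_voxels = length(seg$crisp),
                             quantization_error = model$quantization_error,
                             fcm_iterations = fcmres$iterations,
                             fcm_converged = fcmres$converged,
                             cluster_to_tissue = map)),
            class = "somseg_result")
}

#' @export
print.somseg_result <- function(x, ...) {
  cat("<somseg_result> ", x$meta$n_voxels, " voxels | SOM qe = ",
      signif(x$meta$quantization_error, 4), " | FCM ",
      x$meta$fcm_iterations, " iters | tau = ", x$segmentation$tau,
      "\n", sep = "")
  invisible(x)
}

#' Write per-tissue membership probability volumes
#'
#' One float32 NIfTI probability image per tissue, values in `[0, 1]`.
#'
#' @param result A `somseg_result`.
#' @param prefix Output path prefix; files are named
#'   `<prefix>_<tissue>.nii.gz`.
#' @return Paths written, invisibly.
#' @export
write_memberships <- function(result, prefix) {
  seg <- result$segmentation
  paths <- character(0)
  for (t in seq_len(ncol(seg$memberships))) {
    prob <- array(0, dim = seg$dim)
    prob[seg$voxel_index] <- seg$memberships[, t]
    p <- paste0(prefix, "_", names(tissue_labels())[t], ".nii.gz")
    write_nifti(prob, p, seg$affine, datatype = "float32")
    paths <- c(paths, p)
  }
  invisible(paths)
}
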