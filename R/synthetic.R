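# Synthetic three-tissue brain phantoms and feature-space toys.
#
# The phantom emulates a skull-stripped T1-weighted volume: nested
# ellipsoidal shells (WM core, GM shell, CSF rim) with tissue means ordered
# CSF < GM < WM, additive Gaussian noise that is spatially smoothed with a
# per-tissue scale (distinct local texture), and an optional smooth
# multiplicative bias field mimicking scanner inhomogeneity.

#' Phantom specification
#'
#' @param shape Grid dimensions, each >= 16 (default 64^3).
#' @param tissue_means Mean intensities for (CSF, GM, WM), strictly
#'   increasing; default `c(30, 100, 180)` approximates skull-stripped T1
#'   tissue contrast.
#' @param noise_sigma Additive Gaussian noise SD (default 10, i.e. tissue
#'   separation of 7 sigma).
#' @param bias_amplitude Amplitude of the smooth multiplicative bias field
#'   in `[0, 1)`; 0 disables it.
#' @param geometry `"nested_ellipsoids"` (default) or `"blobs"` (three
#'   spatially coherent random regions from a thresholded smooth field).
#' @param texture_sigma Per-tissue Gaussian smoothing scale (voxels) of the
#'   noise field, giving each tissue a distinct local texture; default
#'   `c(0.5, 1, 1.5)`.
#' @param seed Random seed; all outputs are reproducible from it.
#' @return An object of class `somseg_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         tissue_means = c(30, 100, 180),
                         noise_sigma = 10, bias_amplitude = 0,
                         geometry = c("nested_ellipsoids", "blobs"),
                         texture_sigma = c(0.5, 1, 1.5), seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must be 3 dimensions, each >= 16")
  if (length(tissue_means) != 3L || any(diff(tissue_means) <= 0))
    stop("tissue_means must be 3 strictly increasing values")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must lie in [0, 1)")
  texture_sigma <- rep_len(texture_sigma, 3L)
  structure(list(shape = as.integer(shape), tissue_means = tissue_means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 geometry = geometry, texture_sigma = texture_sigma,
                 seed = as.integer(seed)),
            class = "somseg_phantom_spec")
}

# Separable Gaussian smoothing along the three axes (kernel-sum normalized
# at the edges). sigma <= 0 returns the input unchanged.
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-k:k, sd = sigma)
  smooth_dim1 <- function(a) {
    n <- dim(a)[1L]
    B <- matrix(0, n, n)
    for (o in -k:k) {
      i <- seq.int(max(1L, 1L + o), min(n, n + o))
      B[cbind(i, i - o)] <- B[cbind(i, i - o)] + kern[o + k + 1L]
    }
    B <- B / rowSums(B)
    array(B %*% matrix(a, n), dim = dim(a))
  }
  for (ax in 1:3) {
    arr <- aperm(smooth_dim1(aperm(arr, c(ax, setdiff(1:3, ax)))),
                 order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

#' Generate a three-tissue phantom with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a `somseg_volume` whose mask is
#'   the brain region) and `truth` (a `somseg_labelmap` with 1 = CSF,
#'   2 = GM, 3 = WM).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "somseg_phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$shape
  centre <- (dm + 1) / 2
  semi <- 0.45 * dm
  ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - centre[a]) / semi[a])^2)
  rho2 <- outer(outer(ax[[1L]], ax[[2L]], "+"), ax[[3L]], "+")
  rho <- sqrt(rho2)
  brain <- rho <= 1

  labels <- array(0L, dm)
  if (spec$geometry == "nested_ellipsoids") {
    labels[brain] <- 1L                       # CSF rim
    labels[rho <= 0.80] <- 2L                 # GM shell
    labels[rho <= 0.55] <- 3L                 # WM core
  } else {
    field <- gauss_smooth3(array(stats::rnorm(prod(dm)), dm), sigma = 4)
    qs <- stats::quantile(field[brain], c(1 / 3, 2 / 3))
    lab <- 1L + (field > qs[1L]) + (field > qs[2L])
    labels[brain] <- lab[brain]
  }

  intens <- array(0, dm)
  intens[labels > 0L] <- spec$tissue_means[labels[labels > 0L]]
  if (spec$bias_amplitude > 0) {
    hat <- lapply(1:3, function(a) (seq_len(dm[a]) - 1) / (dm[a] - 1) - 0.5)
    bias <- outer(outer(hat[[1L]], hat[[2L]], "+"), hat[[3L]], "+") / 1.5
    intens <- intens * (1 + spec$bias_amplitude * bias)
  }
  if (spec$noise_sigma > 0) {
    for (t in 1:3) {
      noise <- gauss_smooth3(array(stats::rnorm(prod(dm)), dm),
                             spec$texture_sigma[t])
      noise <- noise / stats::sd(noise)
      sel <- labels == t
      intens[sel] <- intens[sel] + spec$noise_sigma * noise[sel]
    }
  }
  list(volume = as_volume(intens, mask = labels > 0L),
       truth = label_map(labels))
}

#' Three-cluster feature-space toy
#'
#' Gaussian clusters (unit SD) in 3 informative dimensions, placed at
#' pairwise distance `separation`, plus pure-noise N(0, 1) columns. Used to
#' exercise the SOM, FCM and GA modules without imaging data.
#'
#' @param n_per_cluster Points per cluster.
#' @param separation Pairwise Euclidean distance between cluster centres.
#' @param noise_dims Number of uninformative columns appended.
#' @param seed Random seed.
#' @return A list with `features` (a `somseg_features` with columns
#'   `info1..info3, noise1..`) and integer `labels` (1..3).
#' @export
make_feature_toy <- function(n_per_cluster = 100L, separation = 6,
                             noise_dims = 3L, seed = 1L) {
  if (n_per_cluster < 1L) stop("n_per_cluster must be >= 1")
  set.seed(seed)
  n <- 3L * n_per_cluster
  centers <- diag(3L) * separation / sqrt(2)  # pairwise distance = separation
  labels <- rep(1:3, each = n_per_cluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * 3L), n, 3L)
  nm <- paste0("info", 1:3)
  if (noise_dims > 0L) {
    X <- cbind(X, matrix(stats::rnorm(n * noise_dims), n, noise_dims))
    nm <- c(nm, paste0("noise", seq_len(noise_dims)))
  }
  fm <- feature_matrix(X, nm, seq_len(n), dim = c(n, 1L, 1L))
  list(features = fm, labels = labels)
}
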