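# Per-voxel 23-dimensional statistical descriptors.
#
# Each brain voxel is described by the features of its w x w x w window
# (default 3x3x3): 12 Haralick statistics averaged over the 13 independent
# 3D co-occurrence directions, 3 first-order statistics, 7 local-histogram
# moments, and the voxel's global intensity probability. Gray levels are
# requantized to a small number of equal-width bins (default 16) over the
# masked intensity range before any histogram/GLCM computation.

haralick_feature_names <- c(
  "energy", "entropy", "correlation", "contrast", "homogeneity",
  "variance", "sum_average", "dissimilarity", "cluster_shade",
  "cluster_tendency", "maximum_probability", "difference_variance")

first_order_names <- c("central_intensity", "window_mean", "window_variance")

local_hist_names <- c("hist_mean", "hist_variance", "hist_energy",
                      "hist_entropy", "hist_skewness", "hist_kurtosis",
                      "hist_mode")

#' Canonical feature names
#'
#' The 23 descriptor names in registry order: 12 Haralick texture features,
#' 3 first-order window features, 7 local-histogram features and the global
#' intensity probability. `"inverse_variance"` (the homogeneity variant
#' restricted to off-diagonal cells) is accepted everywhere feature names are
#' resolved, as a selectable extra beyond the canonical 23.
#'
#' @return Character vector of length 23.
#' @export
somseg_feature_names <- function() {
  c(haralick_feature_names, first_order_names, local_hist_names,
    "global_probability")
}

#' Feature subset reported as most discriminative
#'
#' The 11-feature subset found by the reference genetic-algorithm selection
#' on real data: five texture features (with inverse variance in place of
#' difference variance), the three first-order features, and histogram
#' energy, skewness and kurtosis.
#'
#' @return Character vector of length 11.
#' @export
optimized_feature_set <- function() {
  c("energy", "contrast", "homogeneity", "cluster_shade", "inverse_variance",
    "central_intensity", "window_mean", "window_variance",
    "hist_energy", "hist_skewness", "hist_kurtosis")
}

resolve_feature_names <- function(selected) {
  known <- c(somseg_feature_names(), "inverse_variance")
  norm <- tolower(gsub("[ -]", "_", selected))
  bad <- norm[!norm %in% known]
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(norm)) stop("duplicated feature names in selection")
  norm
}

#' Window specification for feature extraction
#'
#' @param size Odd window edge length, >= 3 (default 3: a 3x3x3 cube, the
#'   trade-off between texture capture and resolution).
#' @param levels Number of quantized gray levels N_g >= 2 (default 16).
#' @param border `"pad_reflect"` (mirror the volume at its faces so every
#'   masked voxel keeps a descriptor) or `"skip"` (drop voxels whose window
#'   leaves the grid or the brain mask).
#' @param distance Co-occurrence offset radius d (default 1).
#' @return An object of class `somseg_window`.
#' @export
window_spec <- function(size = 3L, levels = 16L,
                        border = c("pad_reflect", "skip"), distance = 1L) {
  size <- as.integer(size); levels <- as.integer(levels)
  if (size < 3L || size %% 2L == 0L) stop("window size must be odd and >= 3")
  if (levels < 2L) stop("quantization levels must be >= 2")
  if (distance < 1L) stop("distance must be a positive integer")
  structure(list(size = size, levels = levels, border = match.arg(border),
                 distance = as.integer(distance)),
            class = "somseg_window")
}

#' Quantize a volume to equal-width gray-level bins
#'
#' Maps intensities to integers in `[0, levels - 1]` by equal-width binning
#' over the masked min-max range (monotone non-decreasing). Voxels outside
#' the mask are binned with the same rule and clamped into range so that
#' windows overlapping the mask border stay defined.
#'
#' @param vol A `somseg_volume`.
#' @param levels Number of gray levels, >= 2.
#' @return A `somseg_volume` whose data are integer levels, carrying a
#'   `"levels"` attribute.
#' @export
quantize_volume <- function(vol, levels = 16L) {
  stopifnot(is_volume(vol))
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (!any(vol$mask)) stop("mask has no voxels")
  vals <- vol$data[vol$mask]
  mn <- min(vals); mx <- max(vals)
  if (mx == mn) {
    warning("constant image: all voxels quantized to level 0")
    q <- array(0L, dim = dim(vol$data))
  } else {
    q <- floor((vol$data - mn) / (mx - mn) * levels)
    q <- array(as.integer(pmin(pmax(q, 0), levels - 1L)), dim = dim(vol$data))
  }
  attr(q, "levels") <- levels
  out <- as_volume(q, vol$affine, vol$mask)
  out
}

ensure_quantized <- function(vol, levels) {
  lv <- attr(vol$data, "levels")
  if (!is.null(lv) && lv == levels) vol else quantize_volume(vol, levels)
}

#' The 13 independent 3D co-occurrence directions
#'
#' Of the 27 offsets with components in {-d, 0, d}, removing the null offset
#' and folding antipodal pairs (G_d = t(G_-d)) leaves 13 independent
#' directions, enumerated here in the conventional spherical-angle order.
#'
#' @param d Offset radius (default 1).
#' @return A 13 x 3 integer matrix; no row is the negation of another.
#' @export
glcm_offsets <- function(d = 1L) {
  base <- rbind(
    c(0, 1, 0), c(-1, 1, 0), c(-1, 0, 0), c(-1, -1, 0),
    c(0, 1, -1), c(0, 0, 1), c(0, -1, -1), c(-1, 0, -1), c(1, 0, -1),
    c(-1, 1, -1), c(1, -1, -1), c(-1, -1, -1), c(1, 1, -1))
  storage.mode(base) <- "integer"
  base * as.integer(d)
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts ordered voxel pairs `(p, p + offset)` inside a window with gray
#' values `(i, j)`. By default the transpose is folded in (symmetric GLCM),
#' doubling every pair and counting both orientations.
#'
#' @param window 3D integer array with values in `[0, levels - 1]`.
#' @param offset Integer offset vector `(dx, dy, dz)`.
#' @param levels Number of gray levels N.
#' @param symmetric Fold in the transpose (default `TRUE`).
#' @param normalize Divide by the total count to get probabilities.
#' @return An object of class `somseg_glcm` with fields `counts` (N x N),
#'   `offset`, `levels`, `distance`.
#' @export
compute_glcm <- function(window, offset, levels, symmetric = TRUE,
                         normalize = FALSE) {
  stopifnot(length(dim(window)) == 3L, length(offset) == 3L)
  if (any(window < 0L | window > levels - 1L))
    stop("window values must lie in [0, levels - 1]")
  dm <- dim(window)
  off <- as.integer(offset)
  lo <- pmax(1L, 1L - off)
  hi <- pmin(dm, dm - off)
  counts <- matrix(0, levels, levels)
  if (all(lo <= hi)) {
    rng <- lapply(1:3, function(a) seq.int(lo[a], hi[a]))
    i <- window[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    j <- window[rng[[1]] + off[1L], rng[[2]] + off[2L], rng[[3]] + off[3L],
                drop = FALSE]
    counts <- matrix(as.double(tabulate(as.vector(i) * levels +
                                          as.vector(j) + 1L,
                                        nbins = levels * levels)),
                     levels, levels, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  structure(list(counts = counts, offset = off, levels = levels,
                 distance = max(abs(off))),
            class = "somseg_glcm")
}

#' Haralick texture features of a GLCM
#'
#' Computes the 12 canonical texture statistics of a normalized symmetric
#' co-occurrence matrix, in registry order: energy, entropy (bits),
#' correlation, contrast, homogeneity, variance, sum average, dissimilarity,
#' cluster shade, cluster tendency, maximum probability, difference variance
#' (variance of the difference histogram `p_{x-y}`). Gray levels are indexed
#' `0..N-1`. A zero matrix (no valid pairs) yields an all-zero vector; a
#' non-normalized matrix is normalized internally with a warning.
#'
#' @param glcm A `somseg_glcm` or a square nonnegative matrix.
#' @param extra Also return `inverse_variance`
#'   (`sum_{i != j} p / (1 + (i - j)^2)`).
#' @return Named numeric vector of length 12 (13 with `extra`).
#' @export
haralick_features <- function(glcm, extra = FALSE) {
  p <- if (inherits(glcm, "somseg_glcm")) glcm$counts else as.matrix(glcm)
  stopifnot(nrow(p) == ncol(p))
  nm <- if (extra) c(haralick_feature_names, "inverse_variance")
        else haralick_feature_names
  s <- sum(p)
  if (s == 0) return(stats::setNames(numeric(length(nm)), nm))
  if (abs(s - 1) > 1e-8) {
    warning("GLCM not normalized; normalizing internally")
  }
  p <- p / s
  n <- nrow(p)
  I <- row(p) - 1; J <- col(p) - 1; D <- I - J
  mux <- sum(I * p); muy <- sum(J * p)
  varx <- sum((I - mux)^2 * p); vary <- sum((J - muy)^2 * p)
  sdx <- sqrt(varx); sdy <- sqrt(vary)
  corr <- if (sdx > 1e-12 && sdy > 1e-12)
    (sum(I * J * p) - mux * muy) / (sdx * sdy) else 0
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  # difference histogram p_{x-y}(k), k = |i - j|
  pd <- as.vector(rowsum(as.vector(p), group = as.vector(abs(D))))
  kd <- sort(unique(as.vector(abs(D))))
  mud <- sum(kd * pd)
  out <- c(
    energy = sum(p^2),
    entropy = entropy,
    correlation = corr,
    contrast = sum(D^2 * p),
    homogeneity = sum(p / (1 + D^2)),
    variance = varx,
    sum_average = sum((I + J) * p),
    dissimilarity = sum(abs(D) * p),
    cluster_shade = sum((I + J - mux - muy)^3 * p),
    cluster_tendency = sum((I + J - mux - muy)^2 * p),
    maximum_probability = max(p),
    difference_variance = sum((kd - mud)^2 * pd))
  if (extra)
    out <- c(out, inverse_variance = sum((p / (1 + D^2))[D != 0]))
  out
}

# --- sliding-window machinery ------------------------------------------------

pad_indices <- function(n, r) {
  if (n <= r) stop("volume dimension ", n, " too small for window radius ", r)
  c(seq(r + 1L, 2L), seq_len(n), seq(n - 1L, n - r))
}

pad_reflect <- function(arr, r) {
  dm <- dim(arr)
  arr[pad_indices(dm[1L], r), pad_indices(dm[2L], r), pad_indices(dm[3L], r)]
}

shift_mask <- function(mask, off) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= dm[a]) return(out)
    dst[[a]] <- seq.int(max(1L, 1L + o), min(dm[a], dm[a] + o))
    src[[a]] <- dst[[a]] - o
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# Voxels retained under the border policy, as sorted linear indices.
kept_voxels <- function(vol, spec) {
  keep <- vol$mask
  if (spec$border == "skip") {
    r <- (spec$size - 1L) %/% 2L
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      if (dx == 0L && dy == 0L && dz == 0L) next
      keep <- keep & shift_mask(vol$mask, c(dx, dy, dz))
    }
  }
  which(keep)
}

feature_matrix <- function(values, names, voxel_index, dim, affine = diag(4)) {
  values <- as.matrix(values)
  colnames(values) <- names
  if (any(!is.finite(values)))
    stop("non-finite feature values after extraction")
  structure(list(values = values, feature_names = names,
                 voxel_index = as.integer(voxel_index), dim = dim,
                 affine = affine),
            class = "somseg_features")
}

is_features <- function(x) inherits(x, "somseg_features")

#' @export
print.somseg_features <- function(x, ...) {
  cat("<somseg_features> ", nrow(x$values), " voxels x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

# One C++ pass over all requested groups; global probability in R.
window_features_internal <- function(vol, spec, haralick = FALSE,
                                     first = FALSE, hist = FALSE) {
  stopifnot(is_volume(vol), inherits(spec, "somseg_window"))
  r <- (spec$size - 1L) %/% 2L
  idx <- kept_voxels(vol, spec)
  if (!length(idx)) stop("no voxels retained under the border policy")
  coords0 <- voxel_coords(idx, dim(vol$data)) - 1L
  need_q <- haralick || hist
  qpad <- if (need_q) pad_reflect(ensure_quantized(vol, spec$levels)$data, r)
          else array(0L, dim(vol$data) + 2L * r)
  rawpad <- if (first) pad_reflect(vol$data, r) else qpad
  res <- cpp_window_features(
    as.integer(qpad), as.double(rawpad), dim(qpad), r,
    coords0, glcm_offsets(spec$distance), spec$levels,
    haralick, first, hist)
  res$voxel_index <- idx
  res
}

#' Direction-averaged Haralick descriptors for every brain voxel
#'
#' For each retained voxel, the 13 co-occurrence matrices of its window are
#' computed (one per independent 3D direction, symmetrized and normalized)
#' and every Haralick feature is averaged over the 13 directions for
#' rotation invariance.
#'
#' @param vol A `somseg_volume` (quantized internally if needed).
#' @param spec A [window_spec()].
#' @return A `somseg_features` with 12 columns.
#' @export
voxel_haralick <- function(vol, spec = window_spec()) {
  res <- window_features_internal(vol, spec, haralick = TRUE)
  feature_matrix(res$haralick[, 1:12, drop = FALSE], haralick_feature_names,
                 res$voxel_index, dim(vol$data), vol$affine)
}

#' First-order window features
#'
#' Central voxel intensity, window mean and window variance (population
#' variance) of the raw, unquantized intensities.
#'
#' @inheritParams voxel_haralick
#' @return A `somseg_features` with 3 columns.
#' @export
first_order_features <- function(vol, spec = window_spec()) {
  res <- window_features_internal(vol, spec, first = TRUE)
  feature_matrix(res$first_order, first_order_names,
                 res$voxel_index, dim(vol$data), vol$affine)
}

#' Local-histogram window features
#'
#' Moments of the normalized gray-level histogram of each voxel's window:
#' mean, variance, energy, entropy (bits), skewness, kurtosis and the level
#' of maximum probability (mode; lowest level on ties). Skewness and
#' kurtosis of a zero-variance window are defined as 0.
#'
#' @inheritParams voxel_haralick
#' @return A `somseg_features` with 7 columns.
#' @export
local_histogram_features <- function(vol, spec = window_spec()) {
  res <- window_features_internal(vol, spec, hist = TRUE)
  feature_matrix(res$local_hist, local_hist_names,
                 res$voxel_index, dim(vol$data), vol$affine)
}

#' Global intensity probability
#'
#' For each brain voxel, the relative frequency of its quantized gray level
#' over all masked voxels.
#'
#' @inheritParams voxel_haralick
#' @return A `somseg_features` with 1 column.
#' @export
global_intensity_probability <- function(vol, spec = window_spec()) {
  stopifnot(is_volume(vol))
  idx <- kept_voxels(vol, spec)
  qvol <- ensure_quantized(vol, spec$levels)
  q <- qvol$data[vol$mask]
  # frequencies over the full mask, reported at the retained voxels
  tab <- tabulate(q + 1L, nbins = spec$levels)
  p <- tab[qvol$data[idx] + 1L] / length(q)
  feature_matrix(matrix(p, ncol = 1L), "global_probability",
                 idx, dim(vol$data), vol$affine)
}

#' Extract the full per-voxel descriptor matrix
#'
#' Concatenates the four feature groups in registry order (Haralick,
#' first-order, local histogram, global probability), optionally restricted
#' to a named subset, and z-scores every column over the retained voxels
#' (so that Euclidean distances in the map are not dominated by intensity
#' magnitude).
#'
#' @param vol A `somseg_volume`.
#' @param spec A [window_spec()].
#' @param selected Optional character vector of feature names (see
#'   [somseg_feature_names()]; `"inverse_variance"` is accepted as an extra,
#'   ordered after `"difference_variance"`).
#' @param standardize Z-score columns (default `TRUE`); constant columns
#'   become all-zero.
#' @return A `somseg_features` with one row per retained brain voxel.
#' @export
extract_features <- function(vol, spec = window_spec(), selected = NULL,
                             standardize = TRUE) {
  stopifnot(is_volume(vol))
  full_order <- append(somseg_feature_names(), "inverse_variance",
                       after = match("difference_variance",
                                     somseg_feature_names()))
  selected <- if (is.null(selected)) somseg_feature_names()
              else resolve_feature_names(selected)
  selected <- full_order[full_order %in% selected]

  want_har <- any(selected %in% c(haralick_feature_names, "inverse_variance"))
  want_first <- any(selected %in% first_order_names)
  want_hist <- any(selected %in% local_hist_names)
  want_glob <- "global_probability" %in% selected

  res <- window_features_internal(vol, spec, haralick = want_har,
                                  first = want_first, hist = want_hist)
  blocks <- list()
  if (want_har) {
    har <- res$haralick
    colnames(har) <- c(haralick_feature_names, "inverse_variance")
    blocks <- c(blocks, list(har))
  }
  if (want_first) {
    fo <- res$first_order; colnames(fo) <- first_order_names
    blocks <- c(blocks, list(fo))
  }
  if (want_hist) {
    lh <- res$local_hist; colnames(lh) <- local_hist_names
    blocks <- c(blocks, list(lh))
  }
  if (want_glob) {
    gp <- global_intensity_probability(vol, spec)
    stopifnot(identical(gp$voxel_index, res$voxel_index))
    blocks <- c(blocks, list(gp$values))
  }
  values <- do.call(cbind, blocks)[, selected, drop = FALSE]
  if (standardize) {
    mu <- colMeans(values)
    sd <- apply(values, 2L, stats::sd)
    values <- sweep(values, 2L, mu, "-")
    nz <- sd > 0
    values[, nz] <- sweep(values[, nz, drop = FALSE], 2L, sd[nz], "/")
    values[, !nz] <- 0
  }
  fm <- feature_matrix(values, selected, res$voxel_index, dim(vol$data),
                       vol$affine)
  attr(fm, "standardized") <- standardize
  fm
}

#' Write / read a feature matrix as tab-separated text
#'
#' One row per voxel: the linear voxel index followed by the feature
#' columns, with a header line. Used to cache features between pipeline
#' stages.
#'
#' @param fm A `somseg_features`.
#' @param path Output (input) path.
#' @param dim Grid dimensions to attach on read (optional).
#' @return `write_features`: `path` invisibly; `read_features`: a
#'   `somseg_features`.
#' @export
write_features <- function(fm, path) {
  stopifnot(is_features(fm))
  df <- data.frame(voxel_index = fm$voxel_index, fm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, dim = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  feature_matrix(as.matrix(df[, -1L, drop = FALSE]),
                 colnames(df)[-1L], df[[1L]],
                 dim = dim %||% rep(NA_integer_, 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
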