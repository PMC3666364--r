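# Fuzzy c-means clustering of SOM prototypes and voxel tissue assignment.
#
# FCM minimizes J_m = sum_k sum_i u_ki^m ||v_k - c_i||^2 by alternating the
# membership update u_ki = d_ki^(-2/(m-1)) / sum_l d_kl^(-2/(m-1)) and the
# center update c_i = sum_k u_ki^m v_k / sum_k u_ki^m, stopping when the
# largest membership change drops below eps. Voxels inherit the membership
# row of their BMU; the crisp label is the maximum membership, and clusters
# whose membership lies within tau of the maximum are added as partial
# volume (PVE) multi-labels.

#' Fuzzy c-means clustering
#'
#' @param x Data matrix (rows = points; here, SOM prototypes).
#' @param k Number of clusters (>= 2; 3 for tissue segmentation).
#' @param m Fuzzifier, > 1 (default 2).
#' @param eps Convergence tolerance on the membership change, in (0, 1).
#' @param seed Seed for the random membership initialization.
#' @param max_iter Iteration cap (default 1000).
#' @return An object of class `somseg_fcm`: `memberships` (rows sum to 1),
#'   `centers` (k x F), `iterations`, `converged`, and the per-iteration
#'   `objective` trace (non-increasing).
#' @export
fcm_cluster <- function(x, k = 3L, m = 2, eps = 1e-5, seed = 1L,
                        max_iter = 1000L) {
  x <- feature_values(x)
  n <- nrow(x)
  if (n < k || k < 2L) stop("need at least k >= 2 data points, got n = ", n)
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (eps <= 0 || eps >= 1) stop("eps must be in (0, 1)")

  set.seed(seed)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    centers <- crossprod(um, x) / colSums(um)
    d2 <- cross_dist2(x, centers)
    # singularity rule: a point coinciding with a center gets a one-hot row
    sing <- d2 < 1e-12
    u_new <- matrix(0, n, k)
    has_sing <- rowSums(sing) > 0L
    if (any(has_sing))
      u_new[cbind(which(has_sing),
                  max.col(sing[has_sing, , drop = FALSE],
                          ties.method = "first"))] <- 1
    if (any(!has_sing)) {
      tmp <- d2[!has_sing, , drop = FALSE]^(-1 / (m - 1))
      u_new[!has_sing, ] <- tmp / rowSums(tmp)
    }
    obj <- c(obj, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < eps) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  structure(list(memberships = u, centers = centers, iterations = iter,
                 converged = converged, objective = obj, m = m, k = k),
            class = "somseg_fcm")
}

#' @export
print.somseg_fcm <- function(x, ...) {
  cat("<somseg_fcm> k = ", x$k, ", ", x$iterations, " iterations",
      if (x$converged) " (converged)", " | J_m = ",
      signif(utils::tail(x$objective, 1L), 6), "\n", sep = "")
  invisible(x)
}

fuzzy_segmentation <- function(crisp, memberships, pve, voxel_index, dim,
                               affine, tau) {
  structure(list(crisp = crisp, memberships = memberships, pve = pve,
                 voxel_index = voxel_index, dim = dim, affine = affine,
                 tau = tau),
            class = "somseg_fuzzyseg")
}

#' @export
print.somseg_fuzzyseg <- function(x, ...) {
  cat("<somseg_fuzzyseg> ", length(x$crisp), " voxels x ",
      ncol(x$memberships), " clusters | tau = ", x$tau, " | ",
      sum(rowSums(x$pve) > 1L), " multi-label voxels\n", sep = "")
  invisible(x)
}

#' Map voxels to fuzzy tissue memberships through their BMU
#'
#' Every voxel inherits the FCM membership row of its best matching unit;
#' the crisp label is the maximum membership (lowest cluster index on
#' ties). The result starts with crisp-only PVE labels (`tau = 0`); apply
#' [pve_assign()] to expand them.
#'
#' @param model A trained `somseg_som`.
#' @param fcmres A `somseg_fcm` computed on `model$prototypes`.
#' @param features The `somseg_features` the model quantizes.
#' @return An object of class `somseg_fuzzyseg` with per-voxel `crisp`
#'   cluster labels, `memberships` (V x k), logical PVE matrix `pve`,
#'   `voxel_index`, grid `dim` and `affine`.
#' @export
assign_voxels <- function(model, fcmres, features) {
  stopifnot(inherits(model, "somseg_som"), inherits(fcmres, "somseg_fcm"),
            is_features(features))
  if (nrow(fcmres$memberships) != nrow(model$prototypes))
    stop("FCM result does not match the number of SOM units")
  b <- bmu(model, features)
  memb <- fcmres$memberships[b, , drop = FALSE]
  crisp <- max.col(memb, ties.method = "first")
  pve <- matrix(FALSE, nrow(memb), ncol(memb))
  pve[cbind(seq_along(crisp), crisp)] <- TRUE
  fuzzy_segmentation(crisp, memb, pve, features$voxel_index, features$dim,
                     features$affine, tau = 0)
}

#' Partial-volume multi-label assignment
#'
#' A voxel is additionally assigned to every cluster whose membership
#' differs from its maximum membership by less than `tau`; with `tau = 0`
#' this reduces to the crisp maximum-membership labeling. The crisp label
#' is always included.
#'
#' @param seg A `somseg_fuzzyseg`.
#' @param tau Membership-difference threshold in `[0, 1]` (0.02 in the
#'   reference experiments).
#' @return The segmentation with updated `pve` and `tau`.
#' @export
pve_assign <- function(seg, tau = 0.02) {
  stopifnot(inherits(seg, "somseg_fuzzyseg"))
  if (!is.numeric(tau) || tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]")
  mx <- seg$memberships[cbind(seq_along(seg$crisp), seg$crisp)]
  pve <- (mx - seg$memberships) < tau
  pve[cbind(seq_along(seg$crisp), seg$crisp)] <- TRUE
  seg$pve <- pve
  seg$tau <- tau
  seg
}

#' Name clusters as tissues by mean intensity
#'
#' Ranks clusters by the mean raw intensity of their member voxels,
#' ascending; on T1 contrast this orders CSF (darkest) < GM < WM
#' (brightest), giving tissue labels 1, 2, 3. Empty clusters produce a
#' warning and their tissue label is absent from the output; exact mean
#' ties keep the cluster-index order (stable) with a warning.
#'
#' @param seg A `somseg_fuzzyseg` with crisp labels in cluster space.
#' @param vol The raw intensity `somseg_volume`.
#' @return A `somseg_labelmap` of tissue labels (0 outside the segmented
#'   voxels) with attribute `"cluster_to_tissue"` (integer permutation).
#' @export
identify_tissues <- function(seg, vol) {
  stopifnot(inherits(seg, "somseg_fuzzyseg"), is_volume(vol))
  k <- ncol(seg$memberships)
  intens <- vol$data[seg$voxel_index]
  means <- vapply(seq_len(k), function(cl) {
    v <- intens[seg$crisp == cl]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(means))
    warning("empty cluster(s): ", paste(which(is.na(means)), collapse = ", "),
            "; their tissue label is absent")
  if (anyDuplicated(stats::na.omit(means)))
    warning("tied cluster mean intensities; keeping cluster-index order")
  cluster_to_tissue <- integer(k)
  ord <- order(means, na.last = TRUE)          # stable for ties
  present <- which(!is.na(means))
  cluster_to_tissue[ord[seq_along(present)]] <- seq_along(present)
  labels <- array(0L, dim = seg$dim)
  labels[seg$voxel_index] <- cluster_to_tissue[seg$crisp]
  out <- label_map(labels, seg$affine)
  attr(out, "cluster_to_tissue") <- cluster_to_tissue
  out
}

# Reorder a fuzzy segmentation from cluster space to tissue space, so that
# column t of memberships/pve corresponds to tissue label t.
relabel_segmentation <- function(seg, cluster_to_tissue) {
  k <- ncol(seg$memberships)
  stopifnot(length(cluster_to_tissue) == k)
  perm <- order(cluster_to_tissue)             # perm[t] = cluster of tissue t
  seg$memberships <- seg$memberships[, perm, drop = FALSE]
  seg$pve <- seg$pve[, perm, drop = FALSE]
  seg$crisp <- cluster_to_tissue[seg$crisp]
  seg
}

# Crisp labels of a fuzzy segmentation as a LabelMap (tissue space).
crisp_labelmap <- function(seg) {
  labels <- array(0L, dim = seg$dim)
  labels[seg$voxel_index] <- seg$crisp
  label_map(labels, seg$affine)
}
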