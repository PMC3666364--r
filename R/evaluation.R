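# Per-tissue Jaccard overlap against reference segmentations.

label_array <- function(x) {
  if (is_labelmap(x)) x$labels else x
}

#' Jaccard index of one tissue between two label maps
#'
#' `|S1 intersect S2| / |S1 union S2|` over the voxel sets carrying the
#' tissue label. When the tissue is absent from both maps the index is
#' defined as 1 (trivial perfect agreement) with a warning; absent from
#' only one map gives 0.
#'
#' @param a,b `somseg_labelmap`s or integer arrays of equal shape.
#' @param tissue Tissue label (1 = CSF, 2 = GM, 3 = WM).
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b, tissue) {
  a <- label_array(a); b <- label_array(b)
  if (!identical(dim(a), dim(b)))
    stop("label map shapes differ: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  sa <- a == tissue; sb <- b == tissue
  uni <- sum(sa | sb)
  if (uni == 0L) {
    warning("tissue ", tissue, " absent from both maps; Jaccard defined as 1")
    return(1)
  }
  sum(sa & sb) / uni
}

#' Score a segmentation against a reference
#'
#' Per-tissue Jaccard indices of a fuzzy segmentation versus a reference
#' label map, restricted to the intersection of the two brain masks (the
#' segmented voxels and the reference's nonzero voxels), since differences
#' in brain extraction otherwise contaminate the overlap. With
#' `use_pve = TRUE` a voxel counts as a tissue whenever that tissue is in
#' its PVE label set (multi-assignments enter each tissue's intersection
#' and union independently); with `tau = 0` this equals crisp scoring.
#'
#' @param pred A `somseg_fuzzyseg` in tissue space (as returned by
#'   [segment_volume()]) or a `somseg_labelmap`.
#' @param ref Reference `somseg_labelmap`.
#' @param use_pve Score the PVE multi-labels instead of crisp labels
#'   (ignored when `pred` is a plain label map).
#' @return An object of class `somseg_score`: `per_tissue` (named Jaccard
#'   values), `mean`, and `counts` (per-tissue voxel counts in both maps).
#' @export
score_segmentation <- function(pred, ref, use_pve = FALSE) {
  stopifnot(is_labelmap(ref))
  tissues <- tissue_labels()
  refl <- ref$labels
  if (is_labelmap(pred)) {
    if (!identical(dim(pred$labels), dim(refl))) stop("shape mismatch")
    domain <- pred$labels > 0L & refl > 0L
    in_tissue <- function(t) pred$labels == t
  } else {
    stopifnot(inherits(pred, "somseg_fuzzyseg"))
    if (prod(pred$dim) != length(refl)) stop("shape mismatch")
    predmask <- array(FALSE, dim = pred$dim)
    predmask[pred$voxel_index] <- TRUE
    domain <- predmask & refl > 0L
    in_tissue <- function(t) {
      m <- array(FALSE, dim = pred$dim)
      m[pred$voxel_index] <- if (use_pve) pred$pve[, t] else pred$crisp == t
      m
    }
  }
  per <- counts <- stats::setNames(numeric(length(tissues)), names(tissues))
  cnt <- list()
  for (t in seq_along(tissues)) {
    sa <- in_tissue(tissues[t]) & domain
    sb <- (refl == tissues[t]) & domain
    uni <- sum(sa | sb)
    if (uni == 0L) {
      warning("tissue ", names(tissues)[t],
              " absent from both maps; Jaccard defined as 1")
      per[t] <- 1
    } else per[t] <- sum(sa & sb) / uni
    cnt[[names(tissues)[t]]] <- c(pred = sum(sa), ref = sum(sb))
  }
  structure(list(per_tissue = per, mean = mean(per), counts = cnt,
                 use_pve = use_pve),
            class = "somseg_score")
}

#' @export
print.somseg_score <- function(x, ...) {
  cat("<somseg_score>", if (x$use_pve) "(PVE)" else "(crisp)", "Jaccard:",
      paste(names(x$per_tissue), signif(x$per_tissue, 4), sep = "=",
            collapse = " "),
      "| mean =", signif(x$mean, 4), "\n")
  invisible(x)
}

#' Tabular score report
#'
#' @param scores A named list of `somseg_score` objects (one per volume).
#' @return A data frame with one row per volume x tissue.
#' @export
score_table <- function(scores) {
  if (inherits(scores, "somseg_score")) scores <- list(volume = scores)
  do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    data.frame(volume = nm, tissue = names(s$per_tissue),
               jaccard = as.numeric(s$per_tissue),
               pred_voxels = vapply(s$counts, `[[`, 0, "pred"),
               ref_voxels = vapply(s$counts, `[[`, 0, "ref"),
               row.names = NULL)
  }))
}
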