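# Independent brute-force oracles, deliberately naive: explicit loops over
# voxel pairs / matrix cells, no shared code with the package paths.

oracle_glcm <- function(window, offset, levels, symmetric = TRUE) {
  dm <- dim(window)
  counts <- matrix(0, levels, levels)
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    p2 <- c(x, y, z) + offset
    if (all(p2 >= 1) && all(p2 <= dm)) {
      i <- window[x, y, z] + 1L
      j <- window[p2[1], p2[2], p2[3]] + 1L
      counts[i, j] <- counts[i, j] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

oracle_haralick <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  n <- nrow(p)
  mux <- muy <- 0
  for (i in 1:n) for (j in 1:n) {
    mux <- mux + (i - 1) * p[i, j]
    muy <- muy + (j - 1) * p[i, j]
  }
  energy <- entropy <- contrast <- homog <- varx <- vary <- 0
  sumavg <- dissim <- cshade <- ctend <- maxp <- sij <- 0
  pd <- numeric(n)  # difference histogram over k = |i-j| (index k+1)
  for (i in 1:n) for (j in 1:n) {
    pij <- p[i, j]
    d <- (i - 1) - (j - 1)
    energy <- energy + pij^2
    if (pij > 0) entropy <- entropy - pij * log2(pij)
    contrast <- contrast + d^2 * pij
    homog <- homog + pij / (1 + d^2)
    varx <- varx + ((i - 1) - mux)^2 * pij
    vary <- vary + ((j - 1) - muy)^2 * pij
    sumavg <- sumavg + ((i - 1) + (j - 1)) * pij
    dissim <- dissim + abs(d) * pij
    cshade <- cshade + ((i - 1) + (j - 1) - mux - muy)^3 * pij
    ctend <- ctend + ((i - 1) + (j - 1) - mux - muy)^2 * pij
    if (pij > maxp) maxp <- pij
    sij <- sij + (i - 1) * (j - 1) * pij
    pd[abs(d) + 1] <- pd[abs(d) + 1] + pij
  }
  corr <- if (varx > 1e-24 && vary > 1e-24)
    (sij - mux * muy) / sqrt(varx * vary) else 0
  mud <- dv <- 0
  for (k in 0:(n - 1)) mud <- mud + k * pd[k + 1]
  for (k in 0:(n - 1)) dv <- dv + (k - mud)^2 * pd[k + 1]
  c(energy = energy, entropy = entropy, correlation = corr,
    contrast = contrast, homogeneity = homog, variance = varx,
    sum_average = sumavg, dissimilarity = dissim, cluster_shade = cshade,
    cluster_tendency = ctend, maximum_probability = maxp,
    difference_variance = dv)
}

oracle_hist_features <- function(window, levels) {
  h <- numeric(levels)
  for (v in as.vector(window)) h[v + 1] <- h[v + 1] + 1
  h <- h / length(window)
  mean_ <- var_ <- energy <- entropy <- m3 <- m4 <- 0
  for (l in 0:(levels - 1)) mean_ <- mean_ + l * h[l + 1]
  for (l in 0:(levels - 1)) {
    var_ <- var_ + (l - mean_)^2 * h[l + 1]
    m3 <- m3 + (l - mean_)^3 * h[l + 1]
    m4 <- m4 + (l - mean_)^4 * h[l + 1]
    energy <- energy + h[l + 1]^2
    if (h[l + 1] > 0) entropy <- entropy - h[l + 1] * log2(h[l + 1])
  }
  skew <- if (var_ > 1e-12) m3 / var_^1.5 else 0
  kurt <- if (var_ > 1e-12) m4 / var_^2 else 0
  mode <- which.max(h) - 1
  c(hist_mean = mean_, hist_variance = var_, hist_energy = energy,
    hist_entropy = entropy, hist_skewness = skew, hist_kurtosis = kurt,
    hist_mode = mode)
}

# Mirror-without-edge padding, written independently of the package helper.
oracle_pad <- function(arr, r) {
  ix <- function(n) c((r + 1):2, 1:n, (n - 1):(n - r))
  dm <- dim(arr)
  arr[ix(dm[1]), ix(dm[2]), ix(dm[3])]
}

# Small fully-masked random volume, pre-quantized to `levels`.
toy_qvolume <- function(dm = c(6, 6, 6), levels = 6L, seed = 1L) {
  set.seed(seed)
  data <- array(sample.int(levels, prod(dm), replace = TRUE) - 1L, dm)
  attr(data, "levels") <- levels
  as_volume(data, mask = array(TRUE, dm))
}

# Best label permutation accuracy between predicted and true labels (k = 3).
match_accuracy <- function(pred, truth) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  max(vapply(perms, function(p) mean(p[pred] == truth), numeric(1)))
}
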