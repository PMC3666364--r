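# Self-organizing map vector quantization of the feature space.
#
# Units live on a 2D (or 3D) hexagonal or rectangular lattice; each stores a
# prototype vector in feature space. Training shrinks a Gaussian
# neighbourhood around each sample's best matching unit (BMU). The default
# trainer is the deterministic batch rule; an online trainer implementing
# the classical stochastic update with exponentially decaying learning rate
# is available for small data.

#' SOM training configuration
#'
#' @param epochs Training iterations (batch) or data passes (online),
#'   default 200.
#' @param alpha0 Initial learning rate for the online rule,
#'   `alpha(t) = alpha0 * exp(-t / epochs)`; unused by the batch rule.
#' @param sigma0 Initial neighbourhood radius; default (`NULL`) is half the
#'   lattice diameter. Decays as `sigma(t) = sigma0 * exp(-t / lambda)`.
#' @param lambda Decay time constant for `alpha` and `sigma`; default
#'   (`NULL`) is `epochs`, so sigma anneals to `sigma0 / e` over the run.
#'   Smaller values push sigma towards 0 (exact vector quantization limit).
#' @param seed Seed for prototype initialization and subsampling.
#' @param mode `"batch"` (default, deterministic, order-independent) or
#'   `"online"`.
#' @param max_samples Training subsample cap; larger feature sets are
#'   subsampled uniformly (seeded) before training. BMU mapping afterwards
#'   always covers all voxels.
#' @return An object of class `somseg_som_config`.
#' @export
som_config <- function(epochs = 200L, alpha0 = 0.5, sigma0 = NULL,
                       lambda = NULL, seed = 1L,
                       mode = c("batch", "online"), max_samples = 100000L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (alpha0 <= 0 || alpha0 > 1) stop("alpha0 must be in (0, 1]")
  if (!is.null(sigma0) && sigma0 <= 0) stop("sigma0 must be > 0")
  if (!is.null(lambda) && lambda <= 0) stop("lambda must be > 0")
  structure(list(epochs = as.integer(epochs), alpha0 = alpha0,
                 sigma0 = sigma0, lambda = lambda, seed = as.integer(seed),
                 mode = match.arg(mode),
                 max_samples = as.integer(max_samples)),
            class = "somseg_som_config")
}

# Unit positions for a lattice of the given shape (length 2 or 3).
# Hexagonal: odd rows shifted half a unit, row spacing sqrt(3)/2.
lattice_coords <- function(shape, lattice = c("hexagonal", "rectangular")) {
  lattice <- match.arg(lattice)
  shape <- as.integer(shape)
  if (!length(shape) %in% 2:3 || any(shape < 1L))
    stop("shape must be 2 or 3 positive lattice dimensions")
  grid <- as.matrix(expand.grid(lapply(shape, seq_len)))[, , drop = FALSE]
  coords <- matrix(0, nrow(grid), length(shape))
  if (lattice == "hexagonal") {
    coords[, 1L] <- grid[, 1L] + 0.5 * ((grid[, 2L] - 1L) %% 2L)
    coords[, 2L] <- (grid[, 2L] - 1L) * sqrt(3) / 2
  } else {
    coords[, 1L] <- grid[, 1L]
    coords[, 2L] <- grid[, 2L] - 1L
  }
  if (length(shape) == 3L) coords[, 3L] <- grid[, 3L] - 1L
  coords
}

feature_values <- function(features) {
  if (is_features(features)) features$values
  else as.matrix(features)
}

# Squared Euclidean distances between rows of x and rows of w.
cross_dist2 <- function(x, w) {
  d2 <- outer(rowSums(x^2), rowSums(w^2), "+") - 2 * tcrossprod(x, w)
  d2[d2 < 0] <- 0
  d2
}

#' Train a self-organizing map
#'
#' @param features A `somseg_features` or a numeric matrix (samples x
#'   features); rows must be finite.
#' @param shape Lattice dimensions, default `c(10, 10)` (100 units).
#' @param config A [som_config()].
#' @param lattice `"hexagonal"` (default) or `"rectangular"`.
#' @return An object of class `somseg_som`: `prototypes` (U x F),
#'   `lattice_coords`, `shape`, `lattice`, `config`, and the final training
#'   `quantization_error`.
#' @export
train_som <- function(features, shape = c(10L, 10L), config = som_config(),
                      lattice = c("hexagonal", "rectangular")) {
  lattice <- match.arg(lattice)
  X <- feature_values(features)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty feature matrix")
  if (any(!is.finite(X))) stop("non-finite feature values")
  U <- prod(shape)
  coords <- lattice_coords(shape, lattice)
  latd2 <- cross_dist2(coords, coords)
  sigma0 <- config$sigma0 %||% (sqrt(max(latd2)) / 2)
  lambda <- config$lambda %||% config$epochs

  set.seed(config$seed)
  if (nrow(X) > config$max_samples)
    X <- X[sample.int(nrow(X), config$max_samples), , drop = FALSE]
  n <- nrow(X)
  W <- X[sample.int(n, U, replace = U > n), , drop = FALSE]

  if (config$mode == "batch") {
    for (t in seq_len(config$epochs)) {
      sigma <- max(sigma0 * exp(-t / lambda), 1e-3)
      H <- exp(-latd2 / (2 * sigma^2))
      b <- max.col(-cross_dist2(X, W), ties.method = "first")
      rs <- rowsum(X, b)
      sums <- matrix(0, U, ncol(X))
      sums[as.integer(rownames(rs)), ] <- rs
      cnt <- tabulate(b, nbins = U)
      num <- H %*% sums
      den <- as.numeric(H %*% cnt)
      upd <- den > 1e-12
      W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
  } else {
    for (t in seq_len(config$epochs)) {
      alpha <- config$alpha0 * exp(-t / lambda)
      sigma <- max(sigma0 * exp(-t / lambda), 1e-3)
      ord <- sample.int(n)
      for (k in ord) {
        v <- X[k, ]
        d2 <- rowSums(sweep(W, 2L, v)^2)
        i <- which.min(d2)
        h <- exp(-latd2[i, ] / (2 * sigma^2))
        W <- W + alpha * h * (rep(1, U) %o% v - W)
      }
    }
  }
  dimnames(W) <- list(NULL, colnames(X))
  model <- structure(list(prototypes = W, lattice_coords = coords,
                          shape = as.integer(shape), lattice = lattice,
                          config = config),
                     class = "somseg_som")
  model$quantization_error <- quantization_error(model, X)
  model
}

#' @export
print.somseg_som <- function(x, ...) {
  cat("<somseg_som> ", paste(x$shape, collapse = " x "), " ", x$lattice,
      " lattice | ", ncol(x$prototypes), " features | qe = ",
      signif(x$quantization_error, 4), "\n", sep = "")
  invisible(x)
}

#' Best matching unit(s)
#'
#' Index of the prototype nearest (Euclidean) to each input vector; ties are
#' broken by the lowest unit index.
#'
#' @param model A `somseg_som`.
#' @param x A feature vector, matrix of row vectors, or `somseg_features`.
#' @return Integer vector of unit indices.
#' @export
bmu <- function(model, x) {
  X <- if (is.numeric(x) && is.null(dim(x))) matrix(x, nrow = 1L)
       else feature_values(x)
  if (ncol(X) != ncol(model$prototypes))
    stop("feature dimension ", ncol(X), " does not match model (",
         ncol(model$prototypes), ")")
  if (any(!is.finite(X))) stop("non-finite input to bmu()")
  max.col(-cross_dist2(X, model$prototypes), ties.method = "first")
}

#' Mean quantization error
#'
#' Mean Euclidean distance from each sample to its BMU prototype — the SOM
#' reconstruction-fit diagnostic used to choose the map size.
#'
#' @param model A `somseg_som`.
#' @param features Samples (matrix or `somseg_features`).
#' @return Nonnegative scalar.
#' @export
quantization_error <- function(model, features) {
  X <- feature_values(features)
  if (nrow(X) == 0L) stop("empty feature matrix")
  d2 <- cross_dist2(X, model$prototypes)
  mean(sqrt(d2[cbind(seq_len(nrow(X)),
                     max.col(-d2, ties.method = "first"))]))
}

#' Save / load a SOM model as plain text
#'
#' Serializes prototypes, lattice coordinates, shape and configuration into
#' a single tab-separated archive for pipeline caching.
#'
#' @param model A `somseg_som`.
#' @param path File path.
#' @return `save_som`: `path` invisibly; `load_som`: a `somseg_som`.
#' @export
save_som <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  writeLines(c(
    paste("#somseg_som", paste(model$shape, collapse = "x"), model$lattice,
          cfg$epochs, cfg$alpha0, cfg$sigma0 %||% "NULL",
          cfg$lambda %||% "NULL", cfg$seed,
          cfg$mode, cfg$max_samples, sep = "\t")), con)
  utils::write.table(model$prototypes, con, sep = "\t", row.names = FALSE,
                     col.names = !is.null(colnames(model$prototypes)))
  invisible(path)
}

#' @rdname save_som
#' @export
load_som <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  stopifnot(hdr[1L] == "#somseg_som")
  shape <- as.integer(strsplit(hdr[2L], "x")[[1L]])
  cfg <- som_config(epochs = as.integer(hdr[4L]), alpha0 = as.numeric(hdr[5L]),
                    sigma0 = if (hdr[6L] == "NULL") NULL
                             else as.numeric(hdr[6L]),
                    lambda = if (hdr[7L] == "NULL") NULL
                             else as.numeric(hdr[7L]),
                    seed = as.integer(hdr[8L]), mode = hdr[9L],
                    max_samples = as.integer(hdr[10L]))
  W <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                   header = TRUE, check.names = FALSE))
  model <- structure(list(prototypes = W,
                          lattice_coords = lattice_coords(shape, hdr[3L]),
                          shape = shape, lattice = hdr[3L], config = cfg),
                     class = "somseg_som")
  model
}
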