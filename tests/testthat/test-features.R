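test_that("quantization maps the masked range onto [0, levels-1] monotonely", {
  v <- as_volume(array(rep(0:255, length.out = 8^3), c(8, 8, 8)),
                 mask = array(TRUE, c(8, 8, 8)))
  q <- quantize_volume(v, 16)
  expect_setequal(unique(as.vector(q$data)), 0:15)
  expect_equal(q$data[v$data == 255][1], 15L)
  expect_equal(q$data[v$data == 0][1], 0L)

  expect_warning(qc <- quantize_volume(
    as_volume(array(5, c(4, 4, 4)), mask = array(TRUE, c(4, 4, 4))), 8),
    "constant")
  expect_true(all(qc$data == 0L))

  set.seed(2)
  vr <- as_volume(array(runif(8^3, -3, 40), c(8, 8, 8)),
                  mask = array(TRUE, c(8, 8, 8)))
  qr <- quantize_volume(vr, 4)
  # brute-force pairwise monotonicity on a subsample
  i <- sample(length(vr$data), 300, replace = TRUE)
  j <- sample(length(vr$data), 300, replace = TRUE)
  lt <- vr$data[i] <= vr$data[j]
  expect_true(all(qr$data[i][lt] <= qr$data[j][lt]))
})

test_that("the 13 offsets cover all 27 directions once antipodes are folded", {
  offs <- glcm_offsets()
  expect_equal(nrow(offs), 13)
  expect_true(all(offs %in% -1:1))
  keys <- apply(offs, 1, paste, collapse = ",")
  neg <- apply(-offs, 1, paste, collapse = ",")
  expect_length(intersect(keys, neg), 0)       # no antipodal pair present
  expect_length(unique(c(keys, neg, "0,0,0")), 27)
  expect_true(all(abs(glcm_offsets(2)) %in% c(0, 2)))
})

test_that("compute_glcm matches brute-force pair enumeration", {
  # constant window: 18 ordered pairs for offset (0,0,-1), 36 symmetrized
  g <- compute_glcm(array(2L, c(3, 3, 3)), c(0, 0, -1), 4)
  expect_equal(g$counts[3, 3], 36)
  expect_equal(sum(g$counts), 36)
  raw <- compute_glcm(array(2L, c(3, 3, 3)), c(0, 0, -1), 4,
                      symmetric = FALSE)
  expect_equal(sum(raw$counts), 3^2 * (3 - 1))   # w^2 (w-1) valid pairs

  for (seed in 1:3) {
    set.seed(seed)
    w <- array(sample(0:3, 4 * 3 * 5, replace = TRUE), c(4, 3, 5))
    for (k in c(1, 5, 13)) {
      off <- glcm_offsets()[k, ]
      got <- compute_glcm(w, off, 4)
      expect_equal(got$counts, oracle_glcm(w, off, 4))
      expect_identical(got$counts, t(got$counts))
    }
  }

  # offset longer than the window extent: empty matrix, not an error
  expect_true(all(compute_glcm(array(1L, c(3, 3, 3)),
                               c(0, 0, -4), 4)$counts == 0))
  expect_error(compute_glcm(array(9L, c(3, 3, 3)), c(0, 0, 1), 4), "levels")
})

test_that("haralick_features matches closed forms and the double-loop oracle", {
  # degenerate one-cell matrix
  p <- matrix(0, 8, 8); p[4, 4] <- 1
  h <- haralick_features(p)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["dissimilarity"]], 0)
  expect_equal(h[["maximum_probability"]], 1)
  expect_equal(h[["homogeneity"]], 1)

  # uniform 4x4 matrix
  hu <- haralick_features(matrix(1 / 16, 4, 4))
  expect_equal(hu[["energy"]], 1 / 16)
  expect_equal(hu[["entropy"]], 4)

  # random GLCMs vs the naive oracle, to 1e-10
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rexp(6 * 6), 6, 6)
    m <- m + t(m)
    m <- m / sum(m)
    expect_equal(haralick_features(m), oracle_haralick(m), tolerance = 1e-10)
  }

  # non-normalized input is normalized with a warning; empty GLCM is zeros
  expect_warning(hn <- haralick_features(matrix(2, 2, 2)), "normaliz")
  expect_equal(hn[["energy"]], 0.25)
  expect_equal(unname(haralick_features(matrix(0, 3, 3))), numeric(12))

  # inverse variance extra: off-diagonal homogeneity
  set.seed(9)
  m <- matrix(runif(16), 4, 4); m <- (m + t(m)) / (2 * sum(m))
  he <- haralick_features(m, extra = TRUE)
  expect_equal(he[["inverse_variance"]],
               he[["homogeneity"]] - sum(diag(m) / sum(m)))
})

test_that("voxel_haralick equals the per-window R path (vectorization contract)", {
  vol <- toy_qvolume(c(6, 6, 6), levels = 5, seed = 4)
  spec <- window_spec(levels = 5, border = "skip")
  fm <- voxel_haralick(vol, spec)
  offs <- glcm_offsets()
  for (row in c(1L, 17L, nrow(fm$values))) {
    xyz <- voxel_coords(fm$voxel_index[row], dim(vol$data))
    win <- vol$data[xyz[1] + (-1:1), xyz[2] + (-1:1), xyz[3] + (-1:1)]
    per_dir <- sapply(seq_len(13), function(d)
      haralick_features(compute_glcm(win, offs[d, ], 5, normalize = TRUE)))
    expect_equal(unname(fm$values[row, ]), unname(rowMeans(per_dir)),
                 tolerance = 1e-12)
  }
})

test_that("constant volumes give degenerate texture columns", {
  v <- as_volume(array(7, c(6, 6, 6)), mask = array(TRUE, c(6, 6, 6)))
  suppressWarnings(q <- quantize_volume(v, 8))
  fm <- voxel_haralick(q, window_spec(levels = 8))
  expect_true(all(fm$values[, "energy"] == 1))
  expect_true(all(fm$values[, "entropy"] == 0))
  lh <- local_histogram_features(q, window_spec(levels = 8))
  expect_true(all(lh$values[, "hist_energy"] == 1))
  expect_true(all(lh$values[, "hist_entropy"] == 0))
  expect_true(all(lh$values[, "hist_variance"] == 0))
  expect_true(all(lh$values[, "hist_skewness"] == 0))
  expect_true(all(lh$values[, "hist_kurtosis"] == 0))
  expect_true(all(lh$values[, "hist_mode"] == 0))
  fo <- first_order_features(v, window_spec())
  expect_true(all(fo$values[, "central_intensity"] == 7))
  expect_true(all(fo$values[, "window_mean"] == 7))
  expect_true(all(fo$values[, "window_variance"] == 0))
})

test_that("first-order features match direct arithmetic", {
  # one window holding 0..26: mean 13, population variance 60.666...
  d <- array(0, c(3, 3, 3)); d[] <- 0:26
  v <- as_volume(d, mask = array(TRUE, c(3, 3, 3)))
  fo <- first_order_features(v, window_spec(border = "skip"))
  expect_equal(nrow(fo$values), 1)
  expect_equal(unname(fo$values[1, "window_mean"]), 13)
  expect_equal(unname(fo$values[1, "window_variance"]), sum((0:26 - 13)^2) / 27)
  expect_equal(unname(fo$values[1, "central_intensity"]), d[2, 2, 2])
})

test_that("local histogram features match the scalar oracle", {
  # 27 distinct levels in one window: entropy log2(27)
  d <- array(0L, c(3, 3, 3)); d[] <- 0:26
  attr(d, "levels") <- 27L
  v <- as_volume(d, mask = array(TRUE, c(3, 3, 3)))
  lh <- local_histogram_features(v, window_spec(levels = 27, border = "skip"))
  expect_equal(unname(lh$values[1, "hist_entropy"]), log2(27))
  expect_equal(unname(lh$values[1, "hist_energy"]), 1 / 27)

  vol <- toy_qvolume(c(7, 6, 5), levels = 6, seed = 8)
  spec <- window_spec(levels = 6, border = "skip")
  lh <- local_histogram_features(vol, spec)
  for (row in c(2L, nrow(lh$values))) {
    xyz <- voxel_coords(lh$voxel_index[row], dim(vol$data))
    win <- vol$data[xyz[1] + (-1:1), xyz[2] + (-1:1), xyz[3] + (-1:1)]
    expect_equal(lh$values[row, ], oracle_hist_features(win, 6),
                 tolerance = 1e-12)
  }
})

test_that("global intensity probability is the masked level frequency", {
  d <- array(0L, c(4, 4, 4)); d[1:32] <- 1L
  attr(d, "levels") <- 2L
  v <- as_volume(d, mask = array(TRUE, c(4, 4, 4)))
  gp <- global_intensity_probability(v, window_spec(levels = 2))
  expect_true(all(gp$values == 0.5))           # half level 0, half level 1

  vol <- toy_qvolume(c(6, 6, 6), levels = 4, seed = 5)
  gp <- global_intensity_probability(vol, window_spec(levels = 4))
  tab <- table(factor(vol$data, levels = 0:3))
  expect_equal(as.vector(gp$values),
               as.vector(tab[vol$data[gp$voxel_index] + 1] / sum(tab)))
})

test_that("extract_features assembles 23 named, finite, standardized columns", {
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 16), seed = 2))
  fm <- extract_features(ph$volume)
  expect_equal(ncol(fm$values), 23)
  expect_identical(fm$feature_names, somseg_feature_names())
  expect_true(all(is.finite(fm$values)))
  expect_equal(unname(colMeans(fm$values)), rep(0, 23), tolerance = 1e-8)

  # the 11-name published subset resolves, with inverse_variance in place
  fm11 <- extract_features(ph$volume, selected = optimized_feature_set())
  expect_equal(ncol(fm11$values), 11)
  expect_setequal(fm11$feature_names, optimized_feature_set())

  # projection consistency: single-column extraction equals the full column
  fm1 <- extract_features(ph$volume, selected = "energy")
  expect_equal(fm1$values[, "energy"], fm$values[, "energy"])

  expect_error(extract_features(ph$volume, selected = "no_such"), "unknown")
})

test_that("direction averaging is rotation invariant about the z axis", {
  vol <- toy_qvolume(c(8, 8, 8), levels = 4, seed = 6)
  rot <- function(a) {            # 90 deg about z: (x, y) -> (n + 1 - y, x)
    b <- aperm(a, c(2, 1, 3))
    b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
  }
  rd <- rot(vol$data); attr(rd, "levels") <- 4L
  vrot <- as_volume(rd, mask = array(TRUE, c(8, 8, 8)))
  spec <- window_spec(levels = 4, border = "skip")
  f1 <- voxel_haralick(vol, spec)
  f2 <- voxel_haralick(vrot, spec)
  # match voxels through the rotation
  xyz <- voxel_coords(f1$voxel_index, c(8, 8, 8))
  rxyz <- cbind(8 + 1 - xyz[, 2], xyz[, 1], xyz[, 3])
  m <- match(voxel_index(rxyz, c(8, 8, 8)), f2$voxel_index)
  expect_equal(f2$values[m, ], f1$values, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("border policies agree on interior voxels and differ at the faces", {
  vol <- toy_qvolume(c(6, 6, 6), levels = 4, seed = 3)
  fa <- voxel_haralick(vol, window_spec(levels = 4))
  fs <- voxel_haralick(vol, window_spec(levels = 4, border = "skip"))
  expect_equal(nrow(fa$values), 6^3)
  expect_equal(nrow(fs$values), 4^3)
  m <- match(fs$voxel_index, fa$voxel_index)
  expect_equal(fa$values[m, ], fs$values, ignore_attr = TRUE)
})

test_that("feature matrices round-trip through the TSV cache", {
  vol <- toy_qvolume(c(5, 5, 5), levels = 4, seed = 1)
  fm <- extract_features(vol, window_spec(levels = 4),
                         selected = c("energy", "window_mean", "hist_mode"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "features.tsv")
  write_features(fm, p)
  back <- read_features(p, dim = fm$dim)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_identical(back$voxel_index, fm$voxel_index)
  expect_identical(back$feature_names, fm$feature_names)
})
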