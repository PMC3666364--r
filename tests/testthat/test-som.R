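test_that("training is deterministic and prototypes stay in the data box", {
  toy <- make_feature_toy(60, separation = 8, noise_dims = 2, seed = 3)
  cfg <- som_config(epochs = 30, seed = 5)
  m1 <- train_som(toy$features, shape = c(4, 4), config = cfg)
  m2 <- train_som(toy$features, shape = c(4, 4), config = cfg)
  expect_identical(m1$prototypes, m2$prototypes)

  X <- toy$features$values
  expect_true(all(m1$prototypes >= rep(apply(X, 2, min), each = 16) - 1e-9))
  expect_true(all(m1$prototypes <= rep(apply(X, 2, max), each = 16) + 1e-9))
  expect_true(all(is.finite(m1$prototypes)))

  expect_error(train_som(X[0, , drop = FALSE]), "empty")
})

test_that("with as many units as distinct points the map quantizes exactly", {
  set.seed(4)
  X <- matrix(rnorm(9 * 4, sd = 5), 9, 4)    # 9 well-spread points
  cfg <- som_config(epochs = 100, sigma0 = 0.3, lambda = 10, seed = 2)
  model <- train_som(X, shape = c(3, 3), config = cfg)
  expect_lt(quantization_error(model, X), 1e-3)
  expect_equal(sort(unique(bmu(model, X))), 1:9)  # each point its own unit
})

test_that("bmu matches a linear-scan oracle, with lowest-index ties", {
  set.seed(7)
  W <- matrix(rnorm(100 * 6), 100, 6)
  model <- structure(list(prototypes = W,
                          lattice_coords = lattice_coords(c(10, 10)),
                          shape = c(10L, 10L), lattice = "hexagonal",
                          config = som_config()),
                     class = "somseg_som")
  expect_equal(bmu(model, W[37, ]), 37)      # zero-distance identity
  for (i in 1:50) {
    v <- rnorm(6)
    scan <- which.min(apply(W, 1, function(w) sqrt(sum((v - w)^2))))
    expect_equal(bmu(model, v), scan)
  }
  # an exact tie: duplicate prototypes at indices 2 and 7
  W2 <- W; W2[7, ] <- W2[2, ]
  model$prototypes <- W2
  expect_equal(bmu(model, W2[2, ]), 2)
  expect_error(bmu(model, rep(NA_real_, 6)), "non-finite")
  expect_error(bmu(model, 1:3), "dimension")
})

test_that("quantization error matches closed forms and the loop oracle", {
  W <- matrix(c(0, 0), 1, 2)
  model <- structure(list(prototypes = W, lattice_coords = matrix(1, 1, 2),
                          shape = c(1L, 1L), lattice = "rectangular",
                          config = som_config()), class = "somseg_som")
  # samples on a circle of radius r around the single prototype
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  X <- cbind(3 * cos(th), 3 * sin(th))
  expect_equal(quantization_error(model, X), 3)
  expect_equal(quantization_error(model, W), 0)

  set.seed(1)
  W <- matrix(rnorm(20 * 3), 20, 3)
  X <- matrix(rnorm(50 * 3), 50, 3)
  model$prototypes <- W
  loop <- mean(apply(X, 1, function(v)
    min(apply(W, 1, function(w) sqrt(sum((v - w)^2))))))
  expect_equal(quantization_error(model, X), loop, tolerance = 1e-12)
  expect_error(quantization_error(model, X[0, ]), "empty")
})

test_that("quantization error is non-increasing in the number of units", {
  toy <- make_feature_toy(250, separation = 5, noise_dims = 5, seed = 11)
  sides <- c(2, 4, 6, 8, 10)
  qe <- vapply(sides, function(s)
    train_som(toy$features, shape = c(s, s),
              config = som_config(epochs = 40, seed = 3))$quantization_error,
    numeric(1))
  expect_true(all(diff(qe) <= 1e-6))
})

test_that("well separated clusters map to contiguous lattice regions", {
  toy <- make_feature_toy(150, separation = 20, noise_dims = 0, seed = 9)
  model <- train_som(toy$features, shape = c(6, 6),
                     config = som_config(epochs = 60, seed = 1))
  b <- bmu(model, toy$features)
  # label each used unit by the majority cluster of its hits; purity ~ 1
  purity <- vapply(sort(unique(b)), function(u) {
    tt <- table(toy$labels[b == u]); max(tt) / sum(tt)
  }, numeric(1))
  expect_gt(mean(purity), 0.99)
  # contiguity: every unit's nearest distinct-label unit is farther than
  # its nearest same-label unit on the lattice, for most units
  lab <- vapply(sort(unique(b)), function(u)
    as.integer(names(which.max(table(toy$labels[b == u])))), integer(1))
  coords <- model$lattice_coords[sort(unique(b)), , drop = FALSE]
  frac_ok <- mean(vapply(seq_along(lab), function(i) {
    d <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
    same <- lab == lab[i]
    same[i] <- FALSE
    if (!any(same) || all(same[-i])) return(TRUE)
    min(d[same]) <= min(d[!same & seq_along(lab) != i])
  }, logical(1)))
  expect_gt(frac_ok, 0.9)
})

test_that("the online trainer follows the update rule and also learns", {
  toy <- make_feature_toy(40, separation = 10, noise_dims = 0, seed = 2)
  cfg <- som_config(epochs = 20, alpha0 = 0.5, seed = 4, mode = "online")
  m <- train_som(toy$features, shape = c(3, 3), config = cfg)
  expect_true(all(is.finite(m$prototypes)))
  expect_gt(m$quantization_error, 0)
  expect_lt(m$quantization_error, 10)
  m2 <- train_som(toy$features, shape = c(3, 3), config = cfg)
  expect_identical(m$prototypes, m2$prototypes)
})

test_that("hexagonal and 3D lattices have distinct, correctly spaced units", {
  hexc <- lattice_coords(c(3, 4), "hexagonal")
  expect_equal(nrow(unique(hexc)), 12)
  d1 <- sqrt(sum((hexc[1, ] - hexc[4, ])^2))   # neighbours across rows
  expect_equal(d1, 1, tolerance = 1e-9)
  l3 <- lattice_coords(c(3, 3, 2), "hexagonal")
  expect_equal(dim(l3), c(18, 3))
  expect_equal(nrow(unique(l3)), 18)
  expect_error(lattice_coords(c(0, 3)), "positive")
})

test_that("SOM models round-trip through the text archive", {
  toy <- make_feature_toy(30, separation = 6, seed = 8)
  model <- train_som(toy$features, shape = c(3, 3),
                     config = som_config(epochs = 10, seed = 1))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "som.tsv")
  save_som(model, p)
  back <- load_som(p)
  expect_equal(back$prototypes, model$prototypes, tolerance = 1e-12)
  expect_identical(back$shape, model$shape)
  expect_equal(back$lattice_coords, model$lattice_coords)
  expect_equal(quantization_error(back, toy$features),
               quantization_error(model, toy$features), tolerance = 1e-9)
})
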