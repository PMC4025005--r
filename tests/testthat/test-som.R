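test_that("normalization z-scores columns and round-trips", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  nz <- somNormalize(X)
  expect_equal(colMeans(nz$z), c(a = 0, b = 0))
  expect_equal(apply(nz$z, 2, sd), c(a = 1, b = 1))
  expect_equal(somDenormalize(nz$z, nz$center, nz$scale), X,
               tolerance = 1e-10)
  # constant columns: zeroed and flagged
  Xc <- cbind(a = c(1, 2, 3), k = c(4, 4, 4))
  expect_warning(nc <- somNormalize(Xc), "constant")
  expect_true(nc$constant[["k"]])
  expect_equal(nc$z[, "k"], rep(0, 3))
  expect_error(somNormalize(data.frame(a = 1:3, b = letters[1:3])),
               "non-numeric.*b")
  expect_error(somNormalize(cbind(a = c(1, NA, 3), b = 1:3)),
               "row 2, column a")
})

test_that("training on identical cases collapses the codebook to them", {
  v <- c(3, -1, 7)
  X <- matrix(rep(v, each = 20), 20, 3)
  m <- suppressWarnings(trainSOM(X, 2, 2))
  cb <- codebookDenormalized(m)
  for (u in seq_len(4)) expect_equal(unname(cb[u, ]), v,
                                     tolerance = 1e-6)
})

test_that("at vanishing radius training reaches the k-means limit", {
  set.seed(3)
  mu1 <- c(0, 0); mu2 <- c(30, 30)
  X <- rbind(sweep(matrix(rnorm(60, sd = 1), 30), 2, mu1, "+"),
             sweep(matrix(rnorm(60, sd = 1), 30), 2, mu2, "+"))
  m <- trainSOM(X, 2, 1, roughEpochs = 30L, finetuneEpochs = 0L,
                radiusStart = 0.02, radiusEnd = 0.02)
  cb <- codebookDenormalized(m)
  cloudMeans <- rbind(colMeans(X[1:30, ]), colMeans(X[31:60, ]))
  # each codebook vector within 0.1 within-cloud SD of a cloud mean
  d <- pracma::distmat(cb, cloudMeans)
  expect_lt(max(apply(d, 2, min)), 0.1)
})

test_that("training is deterministic and translation-equivariant", {
  set.seed(11)
  X <- matrix(rnorm(200), 50, 4)
  m1 <- trainSOM(X, 3, 3, init = "random", seed = 42)
  m2 <- trainSOM(X, 3, 3, init = "random", seed = 42)
  expect_identical(codebook(m1), codebook(m2))
  # translating inputs translates the (denormalized) codebook; probed
  # on well-separated data so BMU decisions are stable under the
  # rounding that the translation itself introduces
  X <- makeBlobs(48, 4, 4, sep = 8, seed = 2)$X
  t0 <- c(5, -2, 0.5, 100)
  m3 <- trainSOM(sweep(X, 2, t0, "+"), 3, 3)
  m0 <- trainSOM(X, 3, 3)
  expect_equal(codebookDenormalized(m3),
               sweep(codebookDenormalized(m0), 2, t0, "+"),
               tolerance = 1e-8)
})

test_that("BMU search matches brute force and breaks ties low", {
  set.seed(4)
  X <- matrix(rnorm(120), 30, 4)
  m <- trainSOM(X, 4, 3)
  probe <- matrix(rnorm(400), 100, 4)
  b <- bmu(m, probe)
  cb <- codebook(m)
  zp <- sweep(sweep(probe, 2, m@normCenter, "-"), 2, m@normScale, "/")
  for (i in 1:100) {
    d <- sqrt(colSums((t(cb) - zp[i, ])^2))
    expect_equal(unname(b[i, "best"]), which.min(d))
    expect_equal(unname(d[b[i, "second"]]), sort(d)[2], tolerance = 1e-12)
  }
  # exact codebook vector maps to its own unit
  x5 <- somDenormalize(cb[5, , drop = FALSE], m@normCenter, m@normScale)
  expect_equal(unname(bmu(m, as.vector(x5))[["best"]]), 5)
  # tie rule: identical codebook rows 2 and 7, probe equal to both
  mt <- m
  mt@codebook[7, ] <- mt@codebook[2, ]
  x2 <- somDenormalize(mt@codebook[2, , drop = FALSE], m@normCenter,
                       m@normScale)
  bt <- bmu(mt, as.vector(x2))
  expect_equal(unname(bt[["best"]]), 2)
  expect_equal(unname(bt[["second"]]), 7)
  expect_error(bmu(m, 1:3), "dimension mismatch")
})

test_that("quantization and topographic errors equal brute-force oracles", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40, 5)
  for (lat in c("hexagonal", "rectangular")) {
    m <- trainSOM(X, 5, 6, lattice = lat)
    z <- sweep(sweep(X, 2, m@normCenter, "-"), 2, m@normScale, "/")
    expect_equal(quantizationError(m, X), oracleQE(codebook(m), z),
                 tolerance = 1e-12)
    expect_equal(topographicError(m, X),
                 oracleTE(codebook(m), m@unitXY, z), tolerance = 1e-12)
    expect_gte(topographicError(m, X), 0)
    expect_lte(topographicError(m, X), 1)
  }
  # codebook containing every data vector: QE = 0
  mx <- suppressWarnings(trainSOM(X[1:6, ], 3, 2))
  mx@codebook <- sweep(sweep(X[1:6, ], 2, mx@normCenter, "-"), 2,
                       mx@normScale, "/")
  expect_lt(quantizationError(mx, X[1:6, ]), 1e-12)
  # a 2-unit map has TE identically 0
  m2 <- trainSOM(X, 2, 1)
  expect_equal(topographicError(m2, X), 0)
  expect_error(quantizationError(m2, X[0, , drop = FALSE]), "empty")
})

test_that("U-matrix reports adjacent codebook distances", {
  set.seed(2)
  X <- matrix(rnorm(30 * 3), 30, 3)
  m <- trainSOM(X, 3, 4)
  # identical codebook: all zeros
  m0 <- m; m0@codebook[] <- 1
  um0 <- uMatrix(m0)
  expect_true(all(um0$edges$distance == 0))
  expect_true(all(um0$unit == 0))
  # 3-4-5 triangle on a 2-unit map
  m2 <- trainSOM(X[, 1:2], 2, 1)
  m2@codebook <- rbind(c(0, 0), c(3, 4))
  um2 <- uMatrix(m2)
  expect_equal(um2$edges$distance, 5)
  # permuting variable order leaves the U-matrix unchanged
  perm <- c(3, 1, 2)
  mp <- m; mp@codebook <- m@codebook[, perm]
  expect_equal(uMatrix(mp)$unit, uMatrix(m)$unit, tolerance = 1e-12)
  expect_true(all(uMatrix(m)$edges$distance >= 0))
})

test_that("component planes are per-variable, convex and denormalized", {
  set.seed(6)
  X <- cbind(a = rnorm(60, 10, 2), b = runif(60), k = rep(5, 60))
  m <- suppressWarnings(trainSOM(X, 4, 6))
  pl <- componentPlanes(m)
  expect_equal(length(pl), 3)
  expect_equal(names(pl), c("a", "b", "k"))
  expect_equal(dim(pl$a), c(4, 6))
  # constant input variable: constant plane at its value
  expect_equal(as.vector(pl$k), rep(5, 24))
  # batch updates are convex combinations of cases: planes stay within
  # the data range (small tolerance for the linear initialization)
  for (v in c("a", "b")) {
    span <- diff(range(X[, v]))
    expect_gte(min(pl[[v]]), min(X[, v]) - 0.1 * span)
    expect_lte(max(pl[[v]]), max(X[, v]) + 0.1 * span)
  }
})

test_that("map-size scan records QE/TE per candidate and selects argmin", {
  set.seed(5)
  X <- matrix(rnorm(50 * 4), 50, 4)
  one <- mapSizeScan(X, cbind(3, 3))
  expect_equal(one$scan$units, 9)
  expect_equal(one$selected, 1)
  sc <- suppressWarnings(mapSizeScan(X, rbind(c(1, 2), c(20, 20))))
  expect_lt(sc$scan$qe[2], sc$scan$qe[1])  # capacity lowers QE
  expect_error(mapSizeScan(X, cbind(1, 1)), "fewer than 2 units")
  # selection rule: argmin QE, ties broken by min TE
  expect_equal(sc$selected, order(sc$scan$qe, sc$scan$te)[1])
  # the nine standard sizes produce nine records, incl. 12 x 7 = 84
  sizes <- defaultMapSizes()
  expect_equal(nrow(sizes), 9)
  expect_equal(unname(sizes[4, "nRows"] * sizes[4, "nCols"]), 84)
})
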