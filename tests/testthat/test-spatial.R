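test_that("empirical variogram handles degenerate and tiny inputs", {
  # constant field: zero semivariance in every nonempty lag
  set.seed(1)
  x <- runif(30); y <- runif(30)
  ev <- empiricalVariogram(x, y, rep(3.7, 30))
  expect_true(all(ev$gamma[ev$npairs > 0] == 0))
  # two points differing by d: one pair, semivariance d^2/2
  ev2 <- empiricalVariogram(c(0, 1), c(0, 0), c(2, 5), nLags = 4L,
                            maxDist = 2)
  expect_equal(sum(ev2$npairs), 1)
  expect_equal(ev2$gamma[ev2$npairs > 0], (5 - 2)^2 / 2)
  expect_error(empiricalVariogram(c(1, 1), c(2, 2), c(0, 1)),
               "degenerate geometry")
})

test_that("variogram fit recovers exact model parameters from clean lags", {
  truth <- new("VariogramModel", family = "spherical", nugget = 0.3,
               partialSill = 2.1, rangeParam = 0.6)
  lag <- seq(0.05, 1.2, length.out = 12)
  tab <- data.frame(lag = lag, gamma = variogramValue(truth, lag),
                    npairs = rep(50L, 12))
  fit <- fitVariogram(tab, family = "spherical")
  expect_equal(fit@nugget, 0.3, tolerance = 1e-6)
  expect_equal(fit@partialSill, 2.1, tolerance = 1e-6)
  expect_equal(fit@rangeParam, 0.6, tolerance = 1e-6)
  # an empty lag is ignored
  tab2 <- tab; tab2$gamma[5] <- NA; tab2$npairs[5] <- 0L
  fit2 <- fitVariogram(tab2)
  expect_equal(fit2@rangeParam, 0.6, tolerance = 1e-6)
  # flat table: pure nugget, range pinned low, vanishing partial sill
  flat <- data.frame(lag = lag, gamma = 1.5, npairs = 40L)
  fitF <- fitVariogram(flat)
  expect_lt(fitF@partialSill, 1e-8)
  expect_equal(fitF@nugget, 1.5, tolerance = 1e-8)
  expect_lt(fitF@rangeParam, max(lag) * 1e-3)
  expect_error(fitVariogram(tab[1:2, ]), "insufficient lags")
})

test_that("fitted sill is close to truth for simulated spatial fields", {
  # simulate Gaussian fields with known spherical covariance; the
  # re-estimated sill should land within 25% of truth (median over seeds)
  truth <- new("VariogramModel", family = "spherical", nugget = 0.2,
               partialSill = 1.0, rangeParam = 0.4)
  sillTruth <- truth@nugget + truth@partialSill
  rel <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 200
    x <- runif(n); y <- runif(n)
    D <- as.matrix(dist(cbind(x, y)))
    C <- sillTruth - variogramValue(truth, D)
    diag(C) <- sillTruth
    z <- t(chol(C + diag(1e-10, n))) %*% rnorm(n)
    fit <- fitVariogram(empiricalVariogram(x, y, as.vector(z)))
    abs((fit@nugget + fit@partialSill) - sillTruth) / sillTruth
  }, numeric(1))
  expect_lt(median(rel), 0.25)
})

test_that("ordinary kriging is unbiased, exact and beats the mean", {
  set.seed(7)
  n <- 60
  x <- runif(n); y <- runif(n)
  vm <- new("VariogramModel", family = "spherical", nugget = 0,
            partialSill = 1, rangeParam = 0.5)
  # constant field reproduced everywhere (unbiasedness)
  gC <- krigeGrid(x, y, rep(4.2, n), vm, cellSize = 0.2)
  expect_equal(gridValues(gC), rep(4.2, length(gridValues(gC))),
               tolerance = 1e-8)
  # weights sum to 1 at every prediction node
  W <- krigingWeights(x, y, vm, px = runif(25), py = runif(25))
  expect_equal(rowSums(W), rep(1, 25), tolerance = 1e-8)
  # nugget 0: prediction at a sample location equals the observation
  z <- sin(4 * x) + cos(3 * y)
  grid <- GridField(x[1] - 0.05, y[1] - 0.05, 0.1, 1L, 1L)
  gE <- krigeGrid(x, y, z, vm, grid = grid)  # single cell centered on x1
  expect_equal(gridValues(gE), z[1], tolerance = 1e-6)
  # hold-one-out predictions outperform the global-mean predictor
  pred <- vapply(seq_len(n), function(i) {
    w <- krigingWeights(x[-i], y[-i], vm, x[i], y[i])
    sum(w * z[-i])
  }, numeric(1))
  rmseKrige <- sqrt(mean((pred - z)^2))
  rmseMean <- sqrt(mean((mean(z) - z)^2))
  expect_lt(rmseKrige, rmseMean)
})

test_that("duplicate sample coordinates are averaged with a warning", {
  vm <- new("VariogramModel", family = "exponential", nugget = 0,
            partialSill = 1, rangeParam = 0.3)
  x <- c(0, 0, 1); y <- c(0, 0, 1); z <- c(1, 3, 5)
  expect_warning(g <- krigeGrid(x, y, z, vm, cellSize = 0.5),
                 "duplicate")
  # the duplicated location behaves as a single point with value 2
  grid <- GridField(-0.25, -0.25, 0.5, 1L, 1L)
  expect_warning(g0 <- krigeGrid(x, y, z, vm, grid = grid))
  expect_equal(gridValues(g0), 2, tolerance = 1e-8)
})

test_that("zonal means follow the cell-center rule and conserve mass", {
  # 6 x 6 grid, values 1..36
  g <- GridField(0, 0, 1, 6L, 6L, values = as.numeric(1:36))
  sq <- function(x0, y0, x1, y1)
    list(list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1),
                    c(x0, y0))))
  # constant grid: every unit mean equals the constant
  gc <- GridField(0, 0, 1, 6L, 6L, values = rep(7, 36))
  u2 <- UnitPolygonSet(c("a", "b"), list(sq(0, 0, 3, 6), sq(3, 0, 6, 6)))
  expect_equal(as.vector(zonalMean(gc, u2)), c(7, 7))
  # unit covering exactly two cells valued 1 and 3
  u1 <- UnitPolygonSet("two", list(sq(-0.2, -0.2, 1.8, 1.2)))
  zm1 <- zonalMean(GridField(0, 0, 1, 6L, 6L,
                             values = c(1, 3, rep(100, 34))), u1)
  expect_equal(as.vector(zm1), 2)
  # tessellation: cell-count-weighted mean of unit means = grid mean
  units <- list(); ids <- character(0)
  for (i in 0:1) for (j in 0:2) {
    ids <- c(ids, sprintf("u%d%d", i, j))
    units <- c(units, list(sq(j * 2, i * 3, j * 2 + 2, i * 3 + 3)))
  }
  tess <- UnitPolygonSet(ids, units)
  zm <- zonalMean(g, tess)
  nc <- attr(zm, "ncells")
  expect_equal(sum(nc), 36)
  expect_equal(sum(zm * nc) / sum(nc), mean(gridValues(g)),
               tolerance = 1e-12)
  # unit with no covered cell centers: flagged missing
  far <- UnitPolygonSet("far", list(sq(50, 50, 50.4, 50.4)))
  expect_true(is.na(zonalMean(g, far)))
})

test_that("GeoJSON polygons round-trip losslessly", {
  tw <- generateTowns(nTowns = 12L, seed = 3L)
  f <- tempfile(fileext = ".geojson")
  writeUnitsGeoJSON(tw$towns, f)
  # RFC 7946 structural checks
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 12)
  expect_true(all(vapply(gj$features, function(ft)
    ft$type == "Feature" &&
      ft$geometry$type %in% c("Polygon", "MultiPolygon"), logical(1))))
  back <- readUnitsGeoJSON(f)
  expect_equal(unitIds(back), unitIds(tw$towns))
  for (i in seq_along(back@geometry))
    expect_equal(back@geometry[[i]][[1]][[1]],
                 tw$towns@geometry[[i]][[1]][[1]], tolerance = 1e-12)
  expect_equal(unname(unitAreas(back)), unname(unitAreas(tw$towns)),
               tolerance = 1e-12)
})

test_that("multipolygon and holed geometries are measured correctly", {
  ring <- function(x0, y0, s) rbind(c(x0, y0), c(x0 + s, y0),
                                    c(x0 + s, y0 + s), c(x0, y0 + s),
                                    c(x0, y0))
  holed <- list(list(ring(0, 0, 4), ring(1, 1, 1)))   # area 16 - 1
  multi <- list(list(ring(0, 0, 1)), list(ring(5, 5, 2)))  # 1 + 4
  u <- UnitPolygonSet(c("holed", "multi"), list(holed, multi))
  expect_equal(unname(unitAreas(u)), c(15, 5))
  g <- GridField(0, 0, 1, 8L, 8L, values = rep(2, 64))
  zm <- zonalMean(g, u)
  expect_equal(as.vector(zm), c(2, 2))
  # the hole's cell center (1.5, 1.5) is excluded
  expect_equal(attr(zm, "ncells")[["holed"]], 15)
})
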