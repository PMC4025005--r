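#' Z-score normalization for SOM training
#'
#' Centers and scales each column to zero mean and unit variance.
#' Constant columns cannot be scaled: they are mapped to zeros and
#' flagged, which removes them from all SOM distance computations (a
#' warning is emitted).
#'
#' @param data numeric matrix or data.frame, cases in rows.
#' @return list with \code{z} (normalized matrix), \code{center},
#'   \code{scale} and logical \code{constant} flags.
#' @export
somNormalize <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) {
    bad <- which(!vapply(as.data.frame(data), is.numeric, logical(1)))
    stop(sprintf("non-numeric column(s): %s",
                 paste(colnames(data)[bad], collapse = ", ")))
  }
  if (nrow(x) < 2L) stop("at least 2 cases are required")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    stop(sprintf("non-finite value(s) at row %d, column %s (and %d more)",
                 bad[1L, 1L],
                 colnames(x)[bad[1L, 2L]] %||% bad[1L, 2L],
                 nrow(bad) - 1L))
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  const <- scl == 0
  if (any(const)) {
    warning(sprintf("constant column(s) mapped to zero: %s",
                    paste(colnames(x)[const], collapse = ", ")))
    scl[const] <- 1
  }
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  list(z = z, center = ctr, scale = scl, constant = const)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Undo SOM normalization
#'
#' @param z normalized matrix.
#' @param center,scale parameters from [somNormalize()].
#' @return matrix on the original scale.
#' @export
somDenormalize <- function(z, center, scale) {
  sweep(sweep(z, 2L, scale, "*"), 2L, center, "+")
}

# lattice coordinates, row-major from the top-left; hexagonal rows are
# offset so all 6 neighbors sit at unit distance
.latticeCoords <- function(nRows, nCols, lattice) {
  r <- rep(seq_len(nRows), each = nCols)
  c <- rep(seq_len(nCols), times = nRows)
  if (lattice == "hexagonal") {
    cbind(x = c + ifelse(r %% 2 == 0, 0.5, 0), y = r * sqrt(3) / 2)
  } else {
    cbind(x = as.numeric(c), y = as.numeric(r))
  }
}

.latticeDist <- function(unitXY) {
  as.matrix(stats::dist(unitXY))
}

# squared Euclidean distances between case rows and codebook rows
.caseUnitDist2 <- function(z, M) {
  d2 <- outer(rowSums(z^2), rowSums(M^2), "+") - 2 * tcrossprod(z, M)
  pmax(d2, 0)
}

.linearInit <- function(z, unitXY, nRows, nCols) {
  nu <- nrow(unitXY)
  d <- ncol(z)
  cv <- stats::cov(z)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  # canonicalize eigenvector signs (largest component positive) so the
  # initialization is stable under tiny perturbations of the input
  for (j in seq_len(ncol(eg$vectors))) {
    big <- which.max(abs(eg$vectors[, j]))
    if (eg$vectors[big, j] < 0) eg$vectors[, j] <- -eg$vectors[, j]
  }
  # span the lattice along the two leading principal directions, the
  # longer lattice side on the larger eigenvalue
  s1 <- if (max(unitXY[, 1L]) > min(unitXY[, 1L]))
    2 * (unitXY[, 1L] - min(unitXY[, 1L])) /
      (max(unitXY[, 1L]) - min(unitXY[, 1L])) - 1 else rep(0, nu)
  s2 <- if (max(unitXY[, 2L]) > min(unitXY[, 2L]))
    2 * (unitXY[, 2L] - min(unitXY[, 2L])) /
      (max(unitXY[, 2L]) - min(unitXY[, 2L])) - 1 else rep(0, nu)
  if (nCols < nRows) { tmp <- s1; s1 <- s2; s2 <- tmp }
  M <- matrix(rep(colMeans(z), each = nu), nu, d)
  M <- M + outer(s1, eg$vectors[, 1L] * sqrt(ev[1L]))
  if (d >= 2L) M <- M + outer(s2, eg$vectors[, 2L] * sqrt(ev[2L]))
  M
}

#' Train a batch self-organizing map
#'
#' Batch SOM training on z-scored data: each epoch assigns every case to
#' its best matching unit (BMU, minimum Euclidean distance) and replaces
#' each codebook vector with the Gaussian-neighborhood-weighted mean of
#' all cases, weights \eqn{h_{uj} = \exp(-d_{lattice}^2 / (2\sigma^2))}
#' evaluated at each case's BMU. The neighborhood radius \eqn{\sigma}
#' shrinks linearly over a rough phase (default
#' \code{max(nRows, nCols)/4} down to 1) and a fine-tune phase (1 down to
#' 0.5). Training is deterministic given the seed and init mode; linear
#' (principal-plane) initialization needs no randomness at all.
#'
#' @param data cases x variables matrix or data.frame (original units;
#'   normalization is handled internally and stored in the model).
#' @param nRows,nCols lattice dimensions.
#' @param lattice "hexagonal" (default) or "rectangular".
#' @param init "linear" (default) or "random" (codebook seeded from
#'   sampled cases).
#' @param roughEpochs,finetuneEpochs epochs per phase (defaults 10, 20).
#' @param radiusStart,radiusEnd rough-phase radius limits; default
#'   \code{max(nRows, nCols)/4} and 1.
#' @param seed integer seed (used by random init only).
#' @return a [SOMModel-class].
#' @export
trainSOM <- function(data, nRows, nCols,
                     lattice = c("hexagonal", "rectangular"),
                     init = c("linear", "random"),
                     roughEpochs = 10L, finetuneEpochs = 20L,
                     radiusStart = NULL, radiusEnd = 1,
                     seed = NULL) {
  lattice <- match.arg(lattice)
  init <- match.arg(init)
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (nRows * nCols < 2L) stop("lattice must have at least 2 units")
  nrm <- somNormalize(data)
  z <- nrm$z
  if (nrow(z) < nRows * nCols)
    warning(sprintf("fewer cases (%d) than map units (%d)",
                    nrow(z), nRows * nCols))
  unitXY <- .latticeCoords(nRows, nCols, lattice)
  L <- .latticeDist(unitXY)
  if (is.null(radiusStart)) radiusStart <- max(nRows, nCols) / 4
  radiusStart <- max(radiusStart, radiusEnd)
  M <- if (init == "linear") .linearInit(z, unitXY, nRows, nCols)
  else .withSeed(seed, z[sample.int(nrow(z), nRows * nCols,
                                    replace = nrow(z) < nRows * nCols),
                         , drop = FALSE])
  sched <- function(from, to, n)
    if (n <= 1L) rep(to, n) else seq(from, to, length.out = n)
  radii <- c(sched(radiusStart, radiusEnd, roughEpochs),
             sched(min(1, radiusEnd), 0.5, finetuneEpochs))
  for (sigma in radii) {
    d2 <- .caseUnitDist2(z, M)
    bmuIdx <- max.col(-d2, ties.method = "first")
    H <- exp(-L^2 / (2 * sigma^2))
    S <- matrix(0, nrow(z), nrow(M))
    S[cbind(seq_len(nrow(z)), bmuIdx)] <- 1
    sums <- crossprod(S, z)          # per-unit case sums
    counts <- colSums(S)
    numer <- H %*% sums
    denom <- as.vector(H %*% counts)
    upd <- denom > 1e-12
    M[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
  }
  colnames(M) <- colnames(z)
  new("SOMModel", nRows = nRows, nCols = nCols, lattice = lattice,
      codebook = M, unitXY = unitXY, normCenter = nrm$center,
      normScale = nrm$scale, constantVars = nrm$constant,
      varNames = colnames(z) %||% paste0("V", seq_len(ncol(z))),
      config = list(init = init, roughEpochs = roughEpochs,
                    finetuneEpochs = finetuneEpochs,
                    radiusStart = radiusStart, radiusEnd = radiusEnd,
                    seed = seed))
}

#' @rdname SOMModel-class
#' @export
setMethod("codebook", "SOMModel", function(object) object@codebook)

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %d x %d %s lattice (%d units), %d variables\n",
              object@nRows, object@nCols, object@lattice,
              object@nRows * object@nCols, ncol(object@codebook)))
  cat(" variables:", paste(utils::head(object@varNames, 8L),
                           collapse = ", "),
      if (length(object@varNames) > 8L) "..." else "", "\n")
})

# normalize new data with a model's stored parameters
.normalizeWith <- function(model, data) {
  x <- as.matrix(data)
  if (ncol(x) != ncol(model@codebook))
    stop(sprintf("dimension mismatch: model has %d variables, data has %d",
                 ncol(model@codebook), ncol(x)))
  sweep(sweep(x, 2L, model@normCenter, "-"), 2L, model@normScale, "/")
}

#' Denormalized codebook
#'
#' @param model a [SOMModel-class].
#' @return the codebook mapped back to original variable units.
#' @export
codebookDenormalized <- function(model) {
  stopifnot(is(model, "SOMModel"))
  somDenormalize(model@codebook, model@normCenter, model@normScale)
}
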