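# one k-means++ seeding + Lloyd descent; returns labels/centroids/inertia
.lloydOnce <- function(X, k, maxIter = 100L) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  if (k > 1L) for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  labels <- rep(1L, n)
  for (it in seq_len(maxIter)) {
    D <- .caseUnitDist2(X, centers)
    newLabels <- max.col(-D, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(newLabels == j)) {
        # empty cluster: reseed at the point farthest from its centroid
        far <- which.max(D[cbind(seq_len(n), newLabels)])
        centers[j, ] <- X[far, ]
        newLabels[far] <- j
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[newLabels == j, , drop = FALSE])
    if (all(newLabels == labels) && it > 1L) break
    labels <- newLabels
  }
  D <- .caseUnitDist2(X, centers)
  labels <- max.col(-D, ties.method = "first")
  inertia <- sum(D[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = centers, inertia = inertia)
}

#' k-means clustering of codebook vectors
#'
#' Lloyd's algorithm with k-means++ seeding, run \code{nRestarts} times;
#' the solution with the smallest within-cluster sum of squares wins.
#' Empty clusters arising during iteration are re-seeded at the point
#' farthest from its current centroid. Deterministic given \code{seed}.
#'
#' @param X vectors to cluster (rows), e.g. [codebook()] of a trained
#'   SOM.
#' @param k number of clusters, at most \code{nrow(X)}.
#' @param seed integer seed.
#' @param nRestarts number of restarts (default 10).
#' @return list with \code{labels}, \code{centroids} and \code{inertia}.
#' @export
kmeansCodebook <- function(X, k, seed = NULL, nRestarts = 10L) {
  X <- as.matrix(X)
  if (k > nrow(X))
    stop(sprintf("k = %d exceeds the number of vectors (%d)", k, nrow(X)))
  if (k < 1L) stop("k must be >= 1")
  .withSeed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      fit <- .lloydOnce(X, k)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best
  })
}

#' Davies-Bouldin index
#'
#' \deqn{DBI = \frac{1}{k} \sum_i \max_{j \ne i} \frac{S_i + S_j}{M_{ij}}}
#' where \eqn{S_i} is the mean Euclidean distance of cluster \eqn{i}'s
#' members to their centroid and \eqn{M_{ij}} the distance between
#' centroids. Lower is better; a partition into singletons scores 0.
#'
#' @param X clustered vectors (rows).
#' @param labels integer cluster labels (all clusters nonempty).
#' @return the DBI.
#' @export
daviesBouldin <- function(X, labels) {
  X <- as.matrix(X)
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2L) stop("at least 2 clusters are required")
  centroids <- t(vapply(labs, function(l)
    colMeans(X[labels == l, , drop = FALSE]), numeric(ncol(X))))
  S <- vapply(seq_len(k), function(i) {
    mem <- X[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(mem, 2L, centroids[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(centroids))
  if (any(M[upper.tri(M)] == 0))
    stop("coincident centroids: Davies-Bouldin ratio undefined")
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Select the number of clusters by minimum Davies-Bouldin index
#'
#' Runs [kmeansCodebook()] for every k in \code{kRange}, scores each
#' partition with [daviesBouldin()], and returns the k with the smallest
#' index (ties resolved toward the smaller, more parsimonious k),
#' together with the full scan table.
#'
#' @param X vectors to cluster (rows).
#' @param kRange candidate cluster numbers (default 2:10).
#' @param seed integer seed (fanned out per k so the scan is
#'   reproducible).
#' @param nRestarts restarts per k.
#' @return list with \code{k} (selected), \code{dbi} (its index),
#'   \code{labels}, \code{centroids}, and \code{scan} (data.frame
#'   \code{k}, \code{dbi}).
#' @export
selectK <- function(X, kRange = 2:10, seed = NULL, nRestarts = 10L) {
  X <- as.matrix(X)
  kRange <- as.integer(kRange)
  if (any(kRange < 2L) || any(kRange > nrow(X)))
    stop("kRange must lie within [2, number of vectors]")
  fits <- vector("list", length(kRange))
  dbi <- numeric(length(kRange))
  for (i in seq_along(kRange)) {
    s <- if (is.null(seed)) NULL else seed + kRange[i]
    fits[[i]] <- kmeansCodebook(X, kRange[i], seed = s,
                                nRestarts = nRestarts)
    dbi[i] <- daviesBouldin(X, fits[[i]]$labels)
  }
  best <- order(dbi, kRange)[1L]
  list(k = kRange[best], dbi = dbi[best], labels = fits[[best]]$labels,
       centroids = fits[[best]]$centroids,
       scan = data.frame(k = kRange, dbi = dbi))
}

#' Project unit-level cluster labels onto cases
#'
#' Cases inherit the cluster of their best matching unit, carrying a
#' clustering of the SOM codebook back to the original observations.
#'
#' @param model a [SOMModel-class].
#' @param labels integer vector of cluster labels, one per map unit.
#' @param data cases x variables matrix or data.frame (original units).
#' @return integer vector of case labels.
#' @export
projectLabels <- function(model, labels, data) {
  stopifnot(is(model, "SOMModel"))
  if (length(labels) != nrow(model@codebook))
    stop("labels must cover all map units")
  b <- bmu(model, as.matrix(data))
  labels[b[, "best"]]
}
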