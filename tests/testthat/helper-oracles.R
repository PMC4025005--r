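# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, enumeration) and never call the
# implementation paths they check.

# reference values giving a well-formed panel for unit tests
testReference <- function() {
  c(Cr = 250, Ni = 60, Zn = 300, Hg = 1, Cu = 100, As = 30,
    Cd = 0.6, Pb = 350)
}

testPanel <- function() MetalPanel(reference = testReference())

# brute-force mean minimum distance between cases and codebook rows
oracleQE <- function(M, X) {
  tot <- 0
  for (i in seq_len(nrow(X))) {
    dmin <- Inf
    for (u in seq_len(nrow(M)))
      dmin <- min(dmin, sqrt(sum((X[i, ] - M[u, ])^2)))
    tot <- tot + dmin
  }
  tot / nrow(X)
}

# brute-force TE: fraction of cases whose two nearest codebook rows are
# not adjacent on the lattice (adjacency = unit distance on unitXY)
oracleTE <- function(M, unitXY, X) {
  bad <- 0
  for (i in seq_len(nrow(X))) {
    d <- sqrt(colSums((t(M) - X[i, ])^2))
    ord <- order(d)
    dl <- sqrt(sum((unitXY[ord[1L], ] - unitXY[ord[2L], ])^2))
    if (dl > 1 + 1e-9) bad <- bad + 1
  }
  bad / nrow(X)
}

# direct per-pair Davies-Bouldin evaluation
oracleDBI <- function(X, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cen <- lapply(labs, function(l) colMeans(X[labels == l, , drop = FALSE]))
  S <- vapply(seq_len(k), function(i) {
    mem <- X[labels == labs[i], , drop = FALSE]
    mean(apply(mem, 1L, function(r) sqrt(sum((r - cen[[i]])^2))))
  }, numeric(1))
  tot <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    tot <- tot + worst
  }
  tot / k
}

# all permutations of seq_len(n), list form (independent of the package's
# internal permutation builder)
oraclePerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oraclePerms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# two-sided permutation p-value for Spearman's rho by full enumeration
oracleSpearmanP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  hits <- 0L; tot <- 0L
  for (p in oraclePerms(length(x))) {
    tot <- tot + 1L
    if (abs(cor(rx, ry[p])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / tot
}

# mean of a normal clamped to [lo, hi] (closed form)
clampedNormalMean <- function(mu, sigma, lo, hi) {
  if (sigma == 0) return(min(max(mu, lo), hi))
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  loTerm <- if (is.finite(lo)) lo * pnorm(a) else 0
  hiTerm <- if (is.finite(hi)) hi * pnorm(b, lower.tail = FALSE) else 0
  loTerm + hiTerm +
    mu * (pnorm(b) - pnorm(a)) - sigma * (dnorm(b) - dnorm(a))
}

# is the compact letter display a valid clique cover of the
# non-significance graph? sig: logical "significantly different" matrix
validLetters <- function(letters, sig) {
  k <- length(letters)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    share <- length(intersect(strsplit(letters[i], "")[[1L]],
                              strsplit(letters[j], "")[[1L]])) > 0
    if (sig[i, j] && share) return(FALSE)      # different groups joined
    if (!sig[i, j] && !share) return(FALSE)    # equal groups split
  }
  TRUE
}

# k well-separated Gaussian blobs in d >= k dimensions: center i sits at
# sep on axis i, so every pair is sep * sqrt(2) apart with within-SD 1
makeBlobs <- function(n, k, d, sep = 8, seed = 1) {
  stopifnot(d >= k)
  set.seed(seed)
  centers <- matrix(0, k, d)
  centers[cbind(seq_len(k), seq_len(k))] <- sep
  lab <- rep(seq_len(k), length.out = n)
  X <- centers[lab, , drop = FALSE] + matrix(rnorm(n * d), n, d)
  list(X = X, labels = lab, centers = centers)
}

# a small synthetic scene shared by slower tests (built once per run)
smallScene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateScene(nTowns = 60L, nSamples = 200L, seed = 5L)
    cache
  }
})
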