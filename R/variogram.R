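#' Semivariogram model value
#'
#' Evaluates a semivariogram at lag distance \code{h}. By convention
#' \eqn{\gamma(0) = 0}; for \eqn{h > 0} the nugget applies:
#' spherical \eqn{\gamma(h) = c_0 + c [1.5 h/a - 0.5 (h/a)^3]} for
#' \eqn{h \le a} and \eqn{c_0 + c} beyond; exponential
#' \eqn{\gamma(h) = c_0 + c [1 - \exp(-3h/a)]} (practical range a).
#'
#' @param model a [VariogramModel-class].
#' @param h nonnegative lag distance(s).
#' @return semivariance value(s).
#' @export
variogramValue <- function(model, h) {
  stopifnot(is(model, "VariogramModel"))
  g <- .vgramShape(h, model@rangeParam, model@family)
  out <- model@nugget + model@partialSill * g
  out[h == 0] <- 0
  out
}

.vgramShape <- function(h, a, family) {
  if (family == "spherical") {
    r <- pmin(h / a, 1)
    1.5 * r - 0.5 * r^3
  } else {
    1 - exp(-3 * h / a)
  }
}

#' Empirical semivariogram
#'
#' Bins all point pairs by separation distance and averages the squared
#' half-differences: \eqn{\gamma_l = mean_{(i,j) \in l} (v_i - v_j)^2 / 2}.
#'
#' @param x,y point coordinates.
#' @param values observed values at the points.
#' @param nLags number of distance bins (default 12).
#' @param maxDist maximum pair distance considered; defaults to half the
#'   bounding-box diagonal.
#' @return data.frame with columns \code{lag} (bin center), \code{gamma}
#'   (mean semivariance, \code{NA} for empty bins) and \code{npairs}.
#' @export
empiricalVariogram <- function(x, y, values, nLags = 12L, maxDist = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n)
  if (n < 2L) stop("at least 2 points are required")
  d <- as.vector(stats::dist(cbind(x, y)))
  if (all(d == 0)) stop("degenerate geometry: all points are coincident")
  if (is.null(maxDist))
    maxDist <- sqrt(diff(range(x))^2 + diff(range(y))^2) / 2
  if (maxDist <= 0) stop("maxDist must be > 0")
  vd <- as.vector(stats::dist(matrix(values, ncol = 1L)))^2 / 2
  keep <- d > 0 & d <= maxDist
  d <- d[keep]; vd <- vd[keep]
  width <- maxDist / nLags
  bin <- pmin(pmax(ceiling(d / width), 1L), nLags)
  gamma <- rep(NA_real_, nLags)
  np <- integer(nLags)
  agg <- tapply(vd, bin, mean)
  cnt <- tapply(vd, bin, length)
  idx <- as.integer(names(agg))
  gamma[idx] <- agg
  np[idx] <- cnt
  data.frame(lag = (seq_len(nLags) - 0.5) * width, gamma = gamma,
             npairs = np)
}

# pair-count-weighted least squares for (nugget, psill) at fixed range;
# nonnegativity enforced by coordinate clamping (2 parameters only)
.wlsAtRange <- function(lag, gamma, w, a, family) {
  g <- .vgramShape(lag, a, family)
  X <- cbind(1, g)
  W <- sqrt(w)
  fit <- tryCatch(stats::lm.fit(X * W, gamma * W)$coefficients,
                  error = function(e) c(0, 0))
  nug <- fit[1L]; ps <- fit[2L]
  if (is.na(ps)) ps <- 0
  if (is.na(nug)) nug <- 0
  if (nug < 0) {
    nug <- 0
    ps <- sum(w * g * gamma) / sum(w * g^2)
    if (!is.finite(ps) || ps < 0) ps <- 0
  } else if (ps < 0) {
    ps <- 0
    nug <- sum(w * gamma) / sum(w)
  }
  sse <- sum(w * (gamma - (nug + ps * g))^2)
  list(nugget = nug, psill = ps, sse = sse)
}

#' Fit a semivariogram model to an empirical lag table
#'
#' Weighted least squares with pair-count weights: minimizes
#' \eqn{\sum_l n_l (\hat\gamma_l - \gamma(h_l))^2}. The nugget and partial
#' sill enter the model linearly, so they are profiled out exactly at each
#' candidate range and only the range is searched (dense scan plus golden-
#' section refinement), making the fit deterministic. Empty lags are
#' ignored. A flat (pure-nugget) table pins the range at its lower bound
#' with a vanishing partial sill.
#'
#' @param lagTable output of [empiricalVariogram()].
#' @param family "spherical" (default) or "exponential".
#' @return a [VariogramModel-class].
#' @export
fitVariogram <- function(lagTable, family = c("spherical", "exponential")) {
  family <- match.arg(family)
  ok <- is.finite(lagTable$gamma) & lagTable$npairs > 0
  lag <- lagTable$lag[ok]; gamma <- lagTable$gamma[ok]
  w <- lagTable$npairs[ok]
  if (length(lag) < 3L)
    stop("insufficient lags: need at least 3 nonempty lags")
  aMin <- max(lag) * 1e-4
  aMax <- max(lag) * 2
  grid <- exp(seq(log(aMin), log(aMax), length.out = 200L))
  sse <- vapply(grid, function(a)
    .wlsAtRange(lag, gamma, w, a, family)$sse, numeric(1))
  i <- which.min(sse)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(a)
    .wlsAtRange(lag, gamma, w, a, family)$sse,
    lower = lo, upper = hi, tol = aMax * 1e-10)
  a <- opt$minimum
  # a flat table leaves the range unidentified; pin it at the lower bound
  if (.wlsAtRange(lag, gamma, w, aMin, family)$sse <= opt$objective +
      1e-12 * max(1, opt$objective))
    a <- aMin
  best <- .wlsAtRange(lag, gamma, w, a, family)
  new("VariogramModel", family = family, nugget = unname(best$nugget),
      partialSill = unname(best$psill), rangeParam = a)
}

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf("VariogramModel (%s): nugget %.4g, partial sill %.4g, range %.4g\n",
              object@family, object@nugget, object@partialSill,
              object@rangeParam))
})
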