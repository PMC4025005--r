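# all permutations of 1..n as an n! x n matrix (n <= 9)
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permMatrix(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with significance flag
#'
#' Rank correlation on midranks (tied observations get average ranks),
#' with a two-tailed p-value: exact by full permutation enumeration for
#' \eqn{n \le 9}, and the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} otherwise. If either variable
#' is constant the correlation is undefined and the cell is flagged
#' \code{not_computable} (the "a" marker in exported tables).
#'
#' @param x,y paired observation vectors.
#' @return list with \code{rho}, \code{p} and \code{flag} (one of
#'   "none", "p<0.05", "p<0.01", "not_computable").
#' @export
spearmanCell <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flag = "not_computable"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    P <- .permMatrix(n)
    ryP <- matrix(ry[P], nrow(P), n)
    S <- as.vector(ryP %*% rx)
    rhoAll <- (S - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  flag <- if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05" else "none"
  list(rho = rho, p = p, flag = flag)
}

#' Per-cluster correlation of covariates with the risk index
#'
#' Computes, within every cluster, the Spearman correlation between each
#' covariate and the town risk index, with two-tailed significance flags
#' at 0.05 and 0.01. Cells where either variable is constant within the
#' cluster, or where the cluster holds fewer than 3 towns, are flagged
#' \code{not_computable}.
#'
#' @param townData data.frame of covariates (numeric columns only are
#'   used; an optional \code{unit_id} column is ignored).
#' @param ri numeric risk index, one value per row of \code{townData}.
#' @param clusterLabels cluster assignment per row.
#' @return list of matrices \code{rho}, \code{p} and \code{flag}
#'   (covariates x clusters).
#' @export
correlationTable <- function(townData, ri, clusterLabels) {
  townData <- as.data.frame(townData)
  townData <- townData[, setdiff(names(townData), "unit_id"),
                       drop = FALSE]
  stopifnot(nrow(townData) == length(ri),
            nrow(townData) == length(clusterLabels))
  clusters <- sort(unique(clusterLabels))
  vars <- names(townData)
  dims <- list(vars, as.character(clusters))
  rho <- p <- matrix(NA_real_, length(vars), length(clusters),
                     dimnames = dims)
  flag <- matrix("not_computable", length(vars), length(clusters),
                 dimnames = dims)
  for (ci in seq_along(clusters)) {
    sel <- clusterLabels == clusters[ci]
    if (sum(sel) < 3L) next
    for (vi in seq_along(vars)) {
      cell <- spearmanCell(townData[[vi]][sel], ri[sel])
      rho[vi, ci] <- cell$rho
      p[vi, ci] <- cell$p
      flag[vi, ci] <- cell$flag
    }
  }
  list(rho = rho, p = p, flag = flag)
}

#' Format a correlation table for export
#'
#' Renders the output of [correlationTable()] in the conventional style:
#' the coefficient with "*" (p < 0.05) or "**" (p < 0.01) suffixes, and
#' the marker "a" for cells that cannot be computed because a variable is
#' constant within the cluster.
#'
#' @param ct output of [correlationTable()].
#' @param digits coefficient digits (default 3).
#' @return character data.frame, covariates x clusters.
#' @export
formatCorrelationTable <- function(ct, digits = 3L) {
  out <- matrix("", nrow(ct$rho), ncol(ct$rho),
                dimnames = dimnames(ct$rho))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- if (ct$flag[i, j] == "not_computable") "a"
    else paste0(format(round(ct$rho[i, j], digits), nsmall = digits),
                switch(ct$flag[i, j], "p<0.01" = " **",
                       "p<0.05" = " *", ""))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
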