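#' One-way analysis of variance
#'
#' Classical between/within mean-square F test with degrees of freedom
#' \eqn{(k - 1, N - k)}, fitted with [stats::aov()]. Groups with fewer
#' than 2 observations are dropped with a warning.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return list with \code{F}, \code{p}, \code{df1}, \code{df2} and
#'   \code{fit} (the underlying \code{aov} object).
#' @export
anovaOneway <- function(values, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("group(s) with < 2 observations dropped: %s",
                    paste(small, collapse = ", ")))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2L)
    stop("need at least 2 groups with at least 2 observations each")
  fit <- stats::aov(values ~ factor(groups))
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df1 = tab[1L, "Df"], df2 = tab[2L, "Df"], fit = fit)
}

# pairwise significance decisions (logical "different" matrix) at alpha
.pairwiseSignificance <- function(values, groups, method, alpha) {
  groups <- factor(groups)
  levs <- levels(groups)
  k <- length(levs)
  sig <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  if (method == "tukey") {
    fit <- stats::aov(values ~ groups)
    hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
    pairNames <- strsplit(rownames(hsd), "-", fixed = TRUE)
    for (i in seq_len(nrow(hsd))) {
      a <- pairNames[[i]][1L]; b <- pairNames[[i]][2L]
      sig[a, b] <- sig[b, a] <- hsd[i, "p adj"] < alpha
    }
    return(sig)
  }
  # Duncan's multiple range test: studentized-range tests over ordered
  # means with the protection level 1 - (1 - alpha)^(p - 1) for a span
  # of p means; a non-significant span declares all enclosed pairs
  # non-significant (unequal n handled by the harmonic pair mean)
  fit <- stats::aov(values ~ groups)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  dfe <- stats::df.residual(fit)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ord <- order(means)
  ns <- ns[ord]; means <- means[ord]; levsOrd <- levs[ord]
  diffPair <- matrix(TRUE, k, k)   # in ordered index space
  nsPair <- matrix(FALSE, k, k)
  for (span in k:2) {
    crit <- stats::qtukey((1 - alpha)^(span - 1), span, dfe)
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (nsPair[i, j]) next
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- (means[j] - means[i]) / se
      if (q < crit) nsPair[i:j, i:j] <- TRUE
    }
  }
  diffPair <- !nsPair
  diag(diffPair) <- FALSE
  sig[levsOrd, levsOrd] <- diffPair
  sig
}

# compact letter display by insert-and-absorb (Piepho-style) from a
# logical "significantly different" matrix
.cldFromSig <- function(sig, means = NULL) {
  k <- nrow(sig)
  cols <- list(seq_len(k))   # each column: set of group indices
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    newCols <- list()
    for (cl in cols) {
      if (i %in% cl && j %in% cl) {
        newCols <- c(newCols, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else newCols <- c(newCols, list(cl))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(newCols))
    for (a in seq_along(newCols)) for (b in seq_along(newCols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newCols[[a]] %in% newCols[[b]]) &&
          (length(newCols[[a]]) < length(newCols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- newCols[keep]
  }
  # order letters so 'a' goes to the column holding the largest mean
  if (!is.null(means)) {
    colScore <- vapply(cols, function(cl) max(means[cl]), numeric(1))
    cols <- cols[order(-colScore)]
  }
  letterOf <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, function(cl) g %in% cl,
                               logical(1)))], collapse = ""),
    character(1))
  stats::setNames(letterOf, rownames(sig))
}

#' Post-hoc compact letter display
#'
#' All-pairs comparisons at level \code{alpha} followed by an
#' insert-and-absorb compact letter display: groups sharing any letter
#' are not significantly different. Methods: Tukey's HSD (default) or
#' Duncan's multiple range test.
#'
#' @param values numeric response.
#' @param groups group labels (each group needs >= 2 observations).
#' @param method "tukey" or "duncan".
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter codes, one per group;
#'   letters are assigned in decreasing order of group means.
#' @export
posthocLetters <- function(values, groups, method = c("tukey", "duncan"),
                           alpha = 0.05) {
  method <- match.arg(method)
  groups <- factor(as.character(groups))
  if (stats::sd(values) == 0) {
    # no variation at all: nothing can differ
    return(stats::setNames(rep("a", nlevels(groups)), levels(groups)))
  }
  sig <- .pairwiseSignificance(values, groups, method, alpha)
  means <- tapply(values, groups, mean)
  .cldFromSig(sig, means = means[rownames(sig)])
}

#' Per-cluster summary table with post-hoc letters
#'
#' For every covariate: the per-cluster mean and standard deviation plus
#' a compact-letter post-hoc grouping from a one-way ANOVA across
#' clusters (letters shared between clusters mean no significant
#' difference at \code{alpha}). Clusters without data (allowed, e.g. a
#' map cluster that captured no towns) yield missing-value cells.
#'
#' @param townData data.frame of numeric covariates (optional
#'   \code{unit_id} ignored).
#' @param labels cluster label per row of \code{townData}.
#' @param clusters cluster set to tabulate (defaults to the labels seen;
#'   pass explicitly to include empty clusters).
#' @param method post-hoc method, "tukey" or "duncan".
#' @param alpha significance level.
#' @return list of matrices \code{mean}, \code{sd}, \code{letters}
#'   (variables x clusters) and \code{formatted} (character data.frame
#'   of "mean (sd) letter" cells, "-" for empty clusters).
#' @export
clusterSummary <- function(townData, labels, clusters = NULL,
                           method = c("tukey", "duncan"), alpha = 0.05) {
  method <- match.arg(method)
  townData <- as.data.frame(townData)
  townData <- townData[, setdiff(names(townData), "unit_id"),
                       drop = FALSE]
  stopifnot(nrow(townData) == length(labels))
  if (is.null(clusters)) clusters <- sort(unique(labels))
  clusters <- as.character(clusters)
  labels <- as.character(labels)
  vars <- names(townData)
  dims <- list(vars, clusters)
  mn <- sdm <- matrix(NA_real_, length(vars), length(clusters),
                      dimnames = dims)
  let <- matrix("", length(vars), length(clusters), dimnames = dims)
  for (vi in seq_along(vars)) {
    v <- townData[[vi]]
    for (ci in seq_along(clusters)) {
      sel <- labels == clusters[ci]
      if (!any(sel)) next
      mn[vi, ci] <- mean(v[sel])
      sdm[vi, ci] <- stats::sd(v[sel])
      if (sum(sel) == 1L) sdm[vi, ci] <- 0
    }
    usable <- names(which(table(labels) >= 2L))
    if (length(usable) >= 2L) {
      sel <- labels %in% usable
      lt <- tryCatch(
        suppressWarnings(posthocLetters(v[sel], labels[sel],
                                        method = method, alpha = alpha)),
        error = function(e) NULL)
      if (!is.null(lt)) {
        hit <- intersect(names(lt), clusters)
        let[vi, hit] <- lt[hit]
      }
    }
  }
  fmt <- matrix("-", length(vars), length(clusters), dimnames = dims)
  for (vi in seq_along(vars)) for (ci in seq_along(clusters)) {
    if (is.finite(mn[vi, ci]))
      fmt[vi, ci] <- trimws(sprintf("%.2f (%.2f) %s", mn[vi, ci],
                                    sdm[vi, ci], let[vi, ci]))
  }
  list(mean = mn, sd = sdm, letters = let,
       formatted = as.data.frame(fmt, stringsAsFactors = FALSE))
}
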