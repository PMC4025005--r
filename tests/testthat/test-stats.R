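test_that("Spearman rho is exact on ranks and monotone-invariant", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 0.3, 2.9, 4.4)
  expect_equal(spearmanCell(x, x)$rho, 1)
  expect_equal(spearmanCell(x, exp(x))$rho, 1)
  expect_equal(spearmanCell(x, -x^3)$rho, -1)
  # constant input: not computable (the exported "a" marker)
  expect_equal(spearmanCell(rep(2, 8), x)$flag, "not_computable")
  expect_equal(spearmanCell(x, rep(0, 8))$flag, "not_computable")
  expect_error(spearmanCell(x, x[-1]), "equal length")
  # midrank rho agrees with the Pearson-on-ranks / cor.test reference,
  # including ties
  set.seed(20)
  for (rep in 1:8) {
    a <- sample(1:6, 15, replace = TRUE) + rnorm(15, sd = 0.01 * (rep %% 2))
    b <- sample(1:5, 15, replace = TRUE)
    expect_equal(spearmanCell(a, b)$rho,
                 suppressWarnings(cor.test(a, b,
                                           method = "spearman"))$estimate[[1]],
                 tolerance = 1e-10)
    expect_equal(spearmanCell(a, b)$rho, cor(rank(a), rank(b)),
                 tolerance = 1e-12)
  }
})

test_that("small-sample Spearman p-values equal full enumeration", {
  set.seed(30)
  for (n in c(5, 6)) {
    for (rep in 1:3) {
      x <- rnorm(n); y <- rnorm(n)
      expect_equal(spearmanCell(x, y)$p, oracleSpearmanP(x, y),
                   tolerance = 1e-12)
    }
    # with ties
    x <- sample(1:3, n, replace = TRUE) + 0
    y <- rnorm(n)
    if (sd(x) > 0)
      expect_equal(spearmanCell(x, y)$p, oracleSpearmanP(x, y),
                   tolerance = 1e-12)
  }
  # large-sample t approximation matches the textbook formula
  set.seed(31)
  x <- rnorm(40); y <- x + rnorm(40)
  cell <- spearmanCell(x, y)
  tval <- cell$rho * sqrt((40 - 2) / (1 - cell$rho^2))
  expect_equal(cell$p, 2 * pt(-abs(tval), 38), tolerance = 1e-12)
})

test_that("correlation table flags clusters and constants per cell", {
  set.seed(21)
  n <- 30
  td <- data.frame(unit_id = sprintf("u%02d", 1:n),
                   v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n))
  ri <- td$v1 + rnorm(n, sd = 0.01)
  lab <- rep(1:2, each = 15)
  td$v3[lab == 2] <- 7  # constant within cluster 2 only
  ct <- correlationTable(td, ri, lab)
  expect_equal(dim(ct$rho), c(3, 2))
  expect_equal(ct$flag["v3", ], c("1" = "none", "2" = "not_computable")
               [colnames(ct$flag)], ignore_attr = TRUE)
  expect_true(all(ct$flag["v1", ] == "p<0.01"))
  # a covariate identical to RI in a single cluster: rho 1, p < 0.01
  # already at n = 8 (exact permutation: 2/8! two-sided)
  td8 <- data.frame(v = 1:8)
  ct8 <- correlationTable(td8, as.numeric(1:8), rep(1, 8))
  expect_equal(ct8$rho[1, 1], 1)
  expect_equal(ct8$p[1, 1], 2 / factorial(8))
  expect_equal(ct8$flag[1, 1], "p<0.01")
  # clusters of fewer than 3 towns are entirely not computable
  ct2 <- correlationTable(td, ri, c(rep(1, 28), 2, 2))
  expect_true(all(ct2$flag[, "2"] == "not_computable"))
  # formatted export uses the "a" marker and significance stars
  fmt <- formatCorrelationTable(ct)
  expect_equal(fmt["v3", "2"], "a")
  expect_match(fmt["v1", "1"], "\\*\\*$")
})

test_that("one-way ANOVA matches direct sums and the t-test identity", {
  set.seed(22)
  g <- rep(c("a", "b", "c"), times = c(8, 10, 12))
  y <- rnorm(30) + as.integer(factor(g))
  out <- anovaOneway(y, g)
  # direct between/within mean square computation
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fdirect <- (ssb / 2) / (ssw / 27)
  expect_equal(out$F, Fdirect, tolerance = 1e-10)
  expect_equal(c(out$df1, out$df2), c(2, 27))
  # two groups: F = t^2 of the pooled-variance t test
  g2 <- rep(c("a", "b"), each = 12)
  y2 <- rnorm(24) + (g2 == "b")
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(anovaOneway(y2, g2)$F, tt$statistic[[1]]^2,
               tolerance = 1e-10)
  expect_equal(anovaOneway(y2, g2)$p, tt$p.value, tolerance = 1e-10)
  # identical group means with nonzero within-variance: F near 0
  y0 <- rep(c(-1, 1), 12)
  expect_lt(anovaOneway(y0, g2)$F, 1e-20)
  # scale invariance
  expect_equal(anovaOneway(100 * y, g)$F, out$F, tolerance = 1e-10)
  # undersized groups are dropped with a warning
  expect_warning(out3 <- anovaOneway(c(y2, 5), c(g2, "c")), "dropped")
  expect_equal(out3$F, anovaOneway(y2, g2)$F, tolerance = 1e-12)
  expect_error(suppressWarnings(anovaOneway(c(1, 2, 3), c("a", "a", "b"))),
               "at least 2 groups")
})

test_that("post-hoc letters reflect the pairwise significance graph", {
  set.seed(23)
  # identical distributions: one shared letter
  y <- rnorm(60); g <- rep(letters[1:3], each = 20)
  expect_equal(unname(posthocLetters(y, g)), rep("a", 3))
  # two groups 10 SDs apart: distinct letters
  y2 <- c(rnorm(10), rnorm(10, 10)); g2 <- rep(c("lo", "hi"), each = 10)
  lt2 <- posthocLetters(y2, g2)
  expect_equal(unname(lt2[c("hi", "lo")]), c("a", "b"))
  # degenerate: zero variance everywhere
  expect_equal(unname(posthocLetters(rep(1, 12), rep(1:3, 4))),
               rep("a", 3))
  expect_error(posthocLetters(y, g, method = "scheffe"))
})

test_that("letter displays are valid clique covers for both methods", {
  set.seed(24)
  for (rep in 1:6) {
    k <- sample(3:5, 1)
    n <- 12
    g <- rep(letters[1:k], each = n)
    y <- rnorm(k * n) + rep(runif(k, 0, 3), each = n)
    for (method in c("tukey", "duncan")) {
      lt <- posthocLetters(y, g, method = method)
      sig <- riskSOM:::.pairwiseSignificance(y, factor(g), method, 0.05)
      expect_true(validLetters(unname(lt[colnames(sig)]), sig),
                  label = sprintf("%s rep %d", method, rep))
    }
  }
})

test_that("letters permute consistently under cluster relabeling", {
  set.seed(25)
  y <- rnorm(45) + rep(c(0, 0.2, 5), each = 15)
  g <- rep(c("x", "y", "z"), each = 15)
  lt <- posthocLetters(y, g)
  # relabel groups: the induced partition of groups must be unchanged
  map <- c(x = "q", y = "r", z = "p")
  lt2 <- posthocLetters(y, map[g])
  expect_equal(unname(lt2[map[names(lt)]]), unname(lt))
})

test_that("cluster summary tables aggregate and format correctly", {
  set.seed(26)
  n <- 40
  td <- data.frame(unit_id = sprintf("u%02d", 1:n),
                   a = rnorm(n, 10), b = runif(n))
  lab <- rep(1:4, each = 10)
  cs <- clusterSummary(td, lab)
  # means match a direct group-by oracle
  for (cl in 1:4) {
    expect_equal(cs$mean["a", as.character(cl)],
                 mean(td$a[lab == cl]), tolerance = 1e-12)
    expect_equal(cs$sd["b", as.character(cl)],
                 sd(td$b[lab == cl]), tolerance = 1e-12)
  }
  # permuting town order leaves the table unchanged
  p <- sample(n)
  cs2 <- clusterSummary(td[p, ], lab[p])
  expect_equal(cs2$mean, cs$mean, tolerance = 1e-12)
  expect_equal(cs2$letters, cs$letters)
  # single-town clusters: sd reported as 0, letters unavailable
  cs1 <- clusterSummary(td[1:3, ], 1:3)
  expect_true(all(cs1$sd == 0))
  # an empty cluster yields missing markers
  csE <- clusterSummary(td, lab, clusters = 1:5)
  expect_true(all(csE$formatted[, "5"] == "-"))
  expect_true(all(is.na(csE$mean[, "5"])))
  # formatted cells carry "mean (sd) letter"
  expect_match(csE$formatted["a", "1"], "^[0-9.]+ \\([0-9.]+\\) [a-z]+$")
})
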