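# helper: block-diagonal consensus TOM with two planted blocks
blockTOM <- function(sizes = c(5, 5), within = 0.9, between = 0.1,
                     nNoise = 0) {
  n <- sum(sizes) + nNoise
  m <- matrix(between, n, n)
  start <- 1
  for (s in sizes) {
    idx <- start:(start + s - 1)
    m[idx, idx] <- within
    start <- start + s
  }
  diag(m) <- 1
  dimnames(m) <- list(sprintf("f%02d", 1:n), sprintf("f%02d", 1:n))
  m
}

test_that("clustering groups block-diagonal TOM into clean subtrees", {
  tom <- blockTOM(c(5, 5))
  dend <- clusterFeatures(tom)
  lab <- stats::cutree(dend, k = 2)
  expect_equal(length(unique(lab[1:5])), 1)
  expect_equal(length(unique(lab[6:10])), 1)
  expect_false(lab[1] == lab[6])
  # identical features merge at height 0
  tom2 <- blockTOM(c(2, 3), within = 1)
  d2 <- clusterFeatures(tom2)
  expect_equal(min(d2$height), 0)
  # permuting feature order yields an isomorphic tree
  set.seed(61)
  perm <- sample(10)
  dp <- clusterFeatures(tom[perm, perm])
  coph <- as.matrix(stats::cophenetic(dend))
  cophp <- as.matrix(stats::cophenetic(dp))
  expect_equal(cophp[rownames(coph), colnames(coph)], coph,
               tolerance = 1e-12)
  expect_error(clusterFeatures(matrix(1, 1, 1)), "at least 2")
})

test_that("the static cut respects height bounds and the minimum size", {
  tom <- blockTOM(c(4, 3), nNoise = 1, between = 0.05)
  dend <- clusterFeatures(tom)
  lab <- cutTree(dend, minSize = 2)
  expect_equal(unname(lab[1:4]), rep(lab[[1]], 4))
  expect_equal(unname(lab[5:7]), rep(lab[[5]], 3))
  expect_gt(lab[1], 0); expect_gt(lab[5], 0)
  expect_false(lab[1] == lab[5])
  # the isolated singleton goes to grey
  expect_equal(unname(lab[8]), 0L)
  # all features identical -> one module containing all
  d1 <- clusterFeatures(blockTOM(c(6), within = 1, between = 1))
  expect_equal(unname(cutTree(d1)), rep(1L, 6))
  expect_error(cutTree(dend, hCut = 2), "max merge height")
  expect_error(cutTree(dend, hCut = 0), "max merge height")
})

test_that("eigengenes are leading principal components with fixed sign", {
  set.seed(67)
  x <- rnorm(25)
  z <- toyZ(cbind(f1 = x, f2 = 2 * x + 5, f3 = -x, f4 = rnorm(25),
                  f5 = rnorm(25)))
  # identical (up to affine) columns: eigengene = standardized column
  eg <- moduleEigengene(z, c("f1", "f2"))
  expect_equal(unname(eg$eigengene), as.numeric(scale(x)), tolerance = 1e-12)
  expect_equal(eg$varExplained, 1)
  # sign convention: non-negative correlation with the member mean
  for (members in list(c("f1", "f4"), c("f3", "f4", "f5"), c("f1", "f3", "f4"))) {
    e <- moduleEigengene(z, members)
    xm <- scale(zValues(z)[, e$members])
    expect_gte(stats::cor(e$eigengene, rowMeans(xm)), 0)
  }
  # var_explained against the eigendecomposition of the correlation matrix
  members <- c("f1", "f2", "f3", "f4", "f5")
  e <- moduleEigengene(z, members)
  lam <- eigen(stats::cor(zValues(z)[, members]), symmetric = TRUE)$values
  expect_equal(e$varExplained, lam[1] / sum(lam), tolerance = 1e-10)
  # zero-variance member dropped with a warning
  z2 <- toyZ(cbind(f1 = x, f2 = rep(1, 25)))
  expect_warning(e2 <- moduleEigengene(z2, c("f1", "f2")), "zero-variance")
  expect_equal(e2$members, "f1")
})

test_that("modules merge iff consensus eigengene similarity exceeds 0.8", {
  set.seed(71)
  n <- 60
  f <- rnorm(n)
  mk <- function(cor_target) {
    # two 3-feature modules whose eigengenes correlate ~ cor_target
    g <- cor_target * f + sqrt(1 - cor_target^2) * rnorm(n)
    cbind(a1 = f + 0.01 * rnorm(n), a2 = f + 0.01 * rnorm(n),
          a3 = f + 0.01 * rnorm(n),
          b1 = g + 0.01 * rnorm(n), b2 = g + 0.01 * rnorm(n),
          b3 = g + 0.01 * rnorm(n))
  }
  asn <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                         c("a1", "a2", "a3", "b1", "b2", "b3"))
  high <- toyZ(mk(0.95))
  merged <- mergeModules(asn, list(d1 = high, d2 = high), mergeCut = 0.2)
  expect_equal(length(unique(merged)), 1)
  low <- toyZ(mk(0.5))
  kept <- mergeModules(asn, list(d1 = low, d2 = low), mergeCut = 0.2)
  expect_equal(length(unique(kept)), 2)
  # consensus = worst dataset: similar in one dataset only -> no merge
  mixed <- mergeModules(asn, list(d1 = high, d2 = low), mergeCut = 0.2)
  expect_equal(length(unique(mixed)), 2)
})

test_that("colors follow the size-ordered standard sequence", {
  asn <- stats::setNames(c(2L, 2L, 2L, 0L, 1L, 1L, 0L),
                         sprintf("f%d", 1:7))
  col <- assignColors(asn)
  expect_equal(unname(col[1:3]), rep("turquoise", 3))  # largest first
  expect_equal(unname(col[5:6]), rep("blue", 2))
  expect_equal(unname(col[c(4, 7)]), rep("grey", 2))
  # relabelling is a bijection on non-grey modules
  tab <- table(asn[col != "grey"], col[col != "grey"])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("module-trait correlation flags grey and matches direct tests", {
  set.seed(73)
  n <- 40
  eg <- cbind(turquoise = rnorm(n), grey = rnorm(n))
  rownames(eg) <- sprintf("S%02d", 1:n)
  traits <- data.frame(t1 = eg[, "turquoise"], t2 = rnorm(n),
                       row.names = rownames(eg))
  tab <- moduleTraitCorrelation(eg, traits, "baseline")
  expect_equal(tab$rho[tab$module == "turquoise" & tab$trait == "t1"], 1)
  expect_true(all(tab$is_grey[tab$module == "grey"]))
  ct <- stats::cor.test(eg[, "grey"], traits$t2, method = "spearman",
                        exact = FALSE)
  row <- tab[tab$module == "grey" & tab$trait == "t2", ]
  expect_equal(row$rho, unname(ct$estimate))
  expect_equal(row$p, ct$p.value)
  tabAdj <- moduleTraitCorrelation(eg, traits, adjust = TRUE)
  expect_true("fdr" %in% names(tabAdj))
  expect_equal(tabAdj$fdr[tabAdj$trait == "t2"],
               bhAdjust(tabAdj$p[tabAdj$trait == "t2"]))
  traits$t3 <- NA_real_
  expect_warning(moduleTraitCorrelation(eg, traits), "all-missing")
})

test_that("eigengene-trait null keeps its size", {
  set.seed(79)
  n <- 50; reps <- 1000
  e <- rnorm(n)
  p <- replicate(reps, stats::cor.test(e, rnorm(n), method = "spearman",
                                       exact = FALSE)$p.value)
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("recovery score is 1 for identity and 0 in expectation for noise", {
  truth <- stats::setNames(rep(c("a", "b", "grey"), c(8, 8, 24)),
                           sprintf("f%02d", 1:40))
  expect_equal(recoveryScore(truth, truth), 1)
  set.seed(83)
  aris <- replicate(100, recoveryScore(
    stats::setNames(sample(truth), names(truth)), truth))
  expect_lt(abs(mean(aris)), 0.05)
  bad <- truth; names(bad)[1] <- "zzz"
  expect_error(recoveryScore(bad, truth), "same features")
})
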