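# minimal effect table covering the global/hierarchy analyses for toy states
mockEffects <- function(dMatrix, metrics = "FC",
                        analyses = list(c("global", "whole_brain"))) {
  rows <- list()
  for (m in metrics) for (k in seq_along(analyses)) {
    a <- analyses[[k]]
    rows[[paste(m, k)]] <- data.frame(
      state = rownames(dMatrix), class = "psychedelic", metric = m,
      level = a[1], contrast = a[2],
      d = dMatrix[, min(k, ncol(dMatrix))], undefined = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

test_that("states are ranked by signed effect size with average-rank ties", {
  d <- matrix(c(-0.5, 0.1, 0.9), 3, dimnames = list(c("a", "b", "c"), NULL))
  rt <- rankStates(mockEffects(d))
  expect_equal(setNames(rt$rank, rt$state), c(a = 1, b = 2, c = 3))
  dt <- matrix(c(0.2, 0.2, 0.7), 3, dimnames = list(c("a", "b", "c"), NULL))
  rtt <- rankStates(mockEffects(dt))
  expect_equal(sort(rtt$rank), c(1.5, 1.5, 3))
  # sign, not magnitude: a large negative effect ranks below a small positive
  dm <- matrix(c(-2, 1), 2, dimnames = list(c("deep", "mild"), NULL))
  rtm <- rankStates(mockEffects(dm))
  expect_equal(rtm$rank[rtm$state == "deep"], 1)
  expect_equal(rtm$rank[rtm$state == "mild"], 2)
})

test_that("rank tables must cover every state and be defined", {
  d <- matrix(c(-1, 0, 1), 3, dimnames = list(c("a", "b", "c"), NULL))
  tab <- mockEffects(d, metrics = c("FC", "EFF"))
  # state b missing from the FC analysis but present in EFF
  expect_error(rankStates(tab[!(tab$state == "b" & tab$metric == "FC"), ]),
               "every state")
  tab$undefined[2] <- TRUE
  expect_error(rankStates(tab), "undefined")
})

test_that("composite ranks average across analysis-metric pairs", {
  d <- matrix(c(-1, 0, 1), 3, dimnames = list(c("a", "b", "c"), NULL))
  analyses <- list(c("global", "whole_brain"), c("global", "between_network"),
                   c("hierarchy", "U-U"))
  rt <- rankStates(mockEffects(d, metrics = c("FC", "EFF", "CPLX"),
                               analyses = analyses))
  comp <- compositeRank(rt)
  expect_equal(setNames(comp$meanRank, comp$state)[c("a", "b", "c")],
               c(a = 1, b = 2, c = 3))          # identical rankings everywhere
  # 13/14 split between rank 1 and rank 9 averages to 139/27
  rt2 <- data.frame(metric = rep("FC", 27),
                    analysis = paste0("an", 1:27),
                    state = "s", d = 0, rank = c(rep(1, 13), rep(9, 14)))
  other <- do.call(rbind, lapply(1:8, function(i)
    data.frame(metric = "FC", analysis = paste0("an", 1:27),
               state = paste0("o", i), d = 0, rank = i)))
  comp2 <- compositeRank(rbind(rt2, other))
  expect_equal(comp2$meanRank[comp2$state == "s"], 139 / 27)
  expect_error(compositeRank(rbind(rt2, other)[-1, ]), "incomplete")
})

test_that("rank agreement reproduces hand-counted Kendall tau-b", {
  mk <- function(r) data.frame(metric = "FC", analysis = "a1",
                               state = paste0("s", seq_along(r)), d = 0,
                               rank = r)
  comp <- data.frame(state = paste0("s", 1:4), meanRank = 1:4)
  expect_equal(rankAgreement(mk(1:4), comp)$tau, 1)
  expect_equal(rankAgreement(mk(4:1), comp)$tau, -1)
  expect_equal(rankAgreement(mk(c(1, 3, 2, 4)), comp)$tau, 2 / 3)
  # cross-check the tie-corrected statistic against a pair-count oracle
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:5, 6, replace = TRUE)
    y <- sample(1:5, 6, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(cor(x, y, method = "kendall"), oracleTauB(x, y),
                 tolerance = 1e-12)
  }
  constant <- mk(rep(2.5, 4))
  expect_true(rankAgreement(constant, comp)$undefined)
})

test_that("feature matrices have the fixed 84-feature layout", {
  states <- paste0("st", 1:9)
  nets <- networkNames()
  cells <- expand.grid(i = 1:7, j = 1:7)
  cells <- cells[cells$i <= cells$j, ]
  rows <- list()
  for (m in c("FC", "EFF", "CPLX")) for (s in states)
    rows[[paste(m, s)]] <- data.frame(
      state = s, class = "sleep", metric = m, level = "network",
      contrast = paste(nets[cells$i], nets[cells$j], sep = "-"),
      d = rnorm(28), undefined = FALSE)
  tab <- do.call(rbind, rows)
  X <- buildFeatureMatrix(tab)
  expect_equal(dim(X), c(84, 9))
  expect_equal(colnames(X), states)
  info <- attr(X, "featureInfo")
  expect_equal(info$metric, rep(c("FC", "EFF", "CPLX"), each = 28))
  # permuting state rows permutes columns identically
  tabP <- tab[sample(nrow(tab)), ]
  XP <- buildFeatureMatrix(tabP)
  expect_equal(XP[, states], X[, states])
  expect_error(buildFeatureMatrix(tab[-1, ]), "missing network-level")
})

test_that("uncentered PCA decomposes, reconstructs, and fixes signs", {
  set.seed(10)
  v <- rnorm(84)
  scale9 <- seq(-2, 2, length.out = 9)
  X <- outer(v, scale9)
  rownames(X) <- paste0("f", 1:84); colnames(X) <- paste0("s", 1:9)
  p <- pcaUncentered(X)
  expect_equal(p@varExplained[1], 1)           # rank-1: PC1 is everything
  # largest-magnitude loading is positive by convention
  expect_gt(p@loadings[which.max(abs(p@loadings[, 1])), 1], 0)
  # two opposite state groups separate with opposite PC1 signs
  grp <- sign(p@scores[, 1])
  expect_equal(grp[scale9 > 0], -grp[scale9 < 0], ignore_attr = TRUE)
  # full reconstruction of a generic matrix
  Y <- matrix(rnorm(84 * 9), 84, dimnames = dimnames(X))
  q <- pcaUncentered(Y)
  expect_equal(q@scores %*% t(q@loadings), t(Y), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(q@loadings), diag(9), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaUncentered(matrix(0, 4, 3)), "all-zero")
})

test_that("negating the input flips scores but not explained variance", {
  set.seed(12)
  X <- matrix(rnorm(84 * 9), 84,
              dimnames = list(paste0("f", 1:84), paste0("s", 1:9)))
  a <- pcaUncentered(X)
  b <- pcaUncentered(-X)
  expect_equal(a@varExplained, b@varExplained, tolerance = 1e-10)
  expect_equal(abs(a@scores), abs(b@scores), tolerance = 1e-8)
})

test_that("PC1 loading maps invert the feature layout", {
  set.seed(77)
  states <- paste0("st", 1:9)
  nets <- networkNames()
  cells <- expand.grid(i = 1:7, j = 1:7)
  cells <- cells[cells$i <= cells$j, ]
  rows <- list()
  for (m in c("FC", "EFF", "CPLX")) for (s in states)
    rows[[paste(m, s)]] <- data.frame(
      state = s, class = "sleep", metric = m, level = "network",
      contrast = paste(nets[cells$i], nets[cells$j], sep = "-"),
      d = rnorm(28), undefined = FALSE)
  tab <- do.call(rbind, rows)
  X <- buildFeatureMatrix(tab)
  p <- pcaUncentered(X)
  maps <- pc1LoadingMatrices(p)
  expect_named(maps, c("FC", "EFF", "CPLX"))
  info <- p@featureInfo
  for (k in sample(84, 12)) {
    expect_equal(maps[[info$metric[k]]][info$net1[k], info$net2[k]],
                 p@loadings[k, 1])
  }
  # lower triangle stays empty
  expect_true(all(is.na(maps$FC[lower.tri(maps$FC)])))
  # a one-hot loading pattern lights exactly one cell across the three maps
  Xoh <- outer(replace(rep(0, 84), 30, 1), 1:9)
  rownames(Xoh) <- rownames(X); colnames(Xoh) <- states
  attr(Xoh, "featureInfo") <- info
  mapsOh <- pc1LoadingMatrices(pcaUncentered(Xoh))
  nz <- vapply(mapsOh, function(m) sum(abs(m) > 1e-12, na.rm = TRUE), 0L)
  expect_equal(sum(nz), 1L)
})
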