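test_that("weight-to-distance transform follows the log contract", {
  w <- matrix(c(1, 1 / exp(1), 0.5, 1 / exp(1), 1, -0.4, 0.5, -0.4, 1), 3)
  d <- weightsToDistances(w)
  expect_equal(d[1, 2], 1)                     # -log(1/e)
  expect_equal(d[1, 3], log(2))                # -log(0.5)
  expect_identical(d[2, 3], Inf)               # negative edges are removed
  expect_equal(diag(d), rep(0, 3))
  # weights at/above 1 are clipped just below 1
  w1 <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_equal(weightsToDistances(w1)[1, 2], -log(1 - 1e-10))
})

test_that("Floyd-Warshall equals per-source Dijkstra on random graphs", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    d <- weightsToDistances(randomFC(n, lo = -0.5, hi = 0.95))
    # agreement up to summation order of multi-hop path lengths
    expect_equal(shortestPaths(d), oracleDijkstra(d), tolerance = 1e-12)
  }
})

test_that("relay paths and disconnection are handled", {
  d <- matrix(Inf, 3, 3); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1; d[2, 3] <- d[3, 2] <- 1
  sp <- shortestPaths(d)
  expect_equal(sp[1, 3], 2)                    # through the middle node
  dAll <- matrix(Inf, 4, 4); diag(dAll) <- 0
  expect_identical(shortestPaths(dAll)[1, 2], Inf)
  expect_equal(globalEfficiency(shortestPaths(dAll)), 0)  # edgeless graph
})

test_that("efficiency closed forms and the exhaustive-path oracle agree", {
  wUnif <- matrix(0.5, 6, 6); diag(wUnif) <- 1
  eg <- globalEfficiency(shortestPaths(weightsToDistances(wUnif)))
  expect_equal(eg, 1 / log(2), tolerance = 1e-12)
  set.seed(55)
  for (i in 1:10) {
    d <- weightsToDistances(randomFC(5, lo = -0.4, hi = 0.9))
    expect_equal(shortestPaths(d), oracleAllPaths(d), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases efficiency", {
  set.seed(77)
  for (i in 1:20) {
    w <- randomFC(12, lo = -0.6, hi = 0.9)
    absent <- which(w <= 0 & upper.tri(w), arr.ind = TRUE)
    if (!nrow(absent)) next
    e0 <- globalEfficiency(shortestPaths(weightsToDistances(w)))
    k <- absent[sample(nrow(absent), 1), ]
    w[k[1], k[2]] <- w[k[2], k[1]] <- runif(1, 0.05, 0.9)
    e1 <- globalEfficiency(shortestPaths(weightsToDistances(w)))
    expect_gte(e1, e0)
  }
})

test_that("weight shuffling preserves the multiset and is seed-deterministic", {
  set.seed(9)
  w <- randomFC(15)
  s1 <- withr::with_seed(4, shuffleWeights(w))
  s2 <- withr::with_seed(4, shuffleWeights(w))
  expect_identical(s1, s2)
  expect_identical(sort(s1[upper.tri(s1)]), sort(w[upper.tri(w)]))
  expect_identical(s1, t(s1))
  # uniform weights: any permutation is the identity
  wu <- matrix(0.3, 8, 8); diag(wu) <- 1
  expect_identical(shuffleWeights(wu), wu)
  w2 <- matrix(c(1, 0.4, 0.4, 1), 2)           # single off-diagonal weight
  expect_identical(shuffleWeights(w2), w2)
})

test_that("uniform graphs have exactly unit normalized efficiency", {
  w <- matrix(0.6, 12, 12); diag(w) <- 1
  for (spec in list(list(NULL, NULL), list(1:5, NULL), list(1:5, 6:12))) {
    r <- normalizedEfficiency(w, spec[[1]], spec[[2]], nNull = 5)
    expect_equal(egNorm(r), 1, tolerance = 1e-12)
  }
})

test_that("raw efficiency is independent of the null ensemble", {
  set.seed(12)
  w <- randomFC(15)
  r1 <- withr::with_seed(1, normalizedEfficiency(w, nNull = 1))
  r2 <- withr::with_seed(99, normalizedEfficiency(w, nNull = 40))
  expect_identical(r1@eg, r2@eg)
  expect_equal(r1@nNull, 1L)
  expect_length(r2@egRand, 40)
})

test_that("the C++ efficiency path equals the composed R operations", {
  set.seed(3)
  for (i in 1:5) {
    w <- randomFC(12, lo = -0.4, hi = 0.9)
    r <- normalizedEfficiency(w, nNull = 2)
    expect_equal(r@eg,
                 globalEfficiency(shortestPaths(weightsToDistances(w))),
                 tolerance = 1e-12)
    # between-set analysis: cross-set pairs only, relays allowed
    s1 <- 1:5; s2 <- 6:12
    rb <- normalizedEfficiency(w, s1, s2, nNull = 2)
    sub <- w[c(s1, s2), c(s1, s2)]
    spl <- shortestPaths(weightsToDistances(sub))
    mask <- outer(rep(c(1, 2), c(5, 7)), rep(c(1, 2), c(5, 7)), `!=`)
    expect_equal(rb@eg, globalEfficiency(spl, mask), tolerance = 1e-12)
  }
})

test_that("null normalization of an already-shuffled graph is unity within noise", {
  set.seed(41)
  w <- shuffleWeights(randomFC(20, lo = -0.2, hi = 0.9))
  r <- normalizedEfficiency(w, nNull = 60)
  # the observed graph is itself one draw from the null ensemble
  expect_lt(abs(r@eg - mean(r@egRand)), 4 * sd(r@egRand))
  expect_lt(abs(egNorm(r) - 1), 4 * sd(r@egRand) / mean(r@egRand))
})

test_that("between-set normalization tracks relative cross-block coupling", {
  set.seed(19)
  n <- 20
  mkBlock <- function(cross) {
    w <- matrix(cross, n, n)
    w[1:10, 1:10] <- 0.7
    w[11:20, 11:20] <- 0.7
    w <- w + matrix(rnorm(n * n, 0, 0.02), n); w <- (w + t(w)) / 2
    diag(w) <- 1
    w
  }
  segregated <- normalizedEfficiency(mkBlock(0.15), 1:10, 11:20, nNull = 60)
  integrated <- normalizedEfficiency(mkBlock(0.60), 1:10, 11:20, nNull = 60)
  # weak cross-edges: data cross-pair efficiency falls short of the null
  expect_lt(egNorm(segregated), 1)
  # strengthening cross-coupling raises the normalized value
  expect_gt(egNorm(integrated), egNorm(segregated))
})

test_that("efficiency levels match an independent per-spec recomputation", {
  set.seed(47)
  p <- makePartition(14, rep(2, 7))
  fc <- randomFC(14, lo = 0.05, hi = 0.9)
  ls <- withr::with_seed(8, efficiencyLevels(fc, p, nNull = 3))
  # same seed, same spec order: whole brain, 6 hierarchy, 28 network
  withr::with_seed(8, {
    wb <- egNorm(normalizedEfficiency(fc, nNull = 3))
    hcs <- list(c("unimodal", "unimodal"), c("attention", "attention"),
                c("transmodal", "transmodal"), c("unimodal", "attention"),
                c("unimodal", "transmodal"), c("attention", "transmodal"))
    hv <- vapply(hcs, function(hc) {
      a <- hierarchyMembers(p, hc[1]); b <- hierarchyMembers(p, hc[2])
      if (hc[1] == hc[2]) egNorm(normalizedEfficiency(fc, a, nNull = 3))
      else egNorm(normalizedEfficiency(fc, a, b, nNull = 3))
    }, 0)
    nets <- networkNames()
    nv <- matrix(NA_real_, 7, 7)
    for (i in 1:7) for (j in i:7) {
      a <- networkMembers(p, nets[i]); b <- networkMembers(p, nets[j])
      nv[i, j] <- nv[j, i] <-
        if (i == j) egNorm(normalizedEfficiency(fc, a, nNull = 3))
        else egNorm(normalizedEfficiency(fc, a, b, nNull = 3))
    }
    expect_equal(globalLevel(ls)[["whole_brain"]], wb, tolerance = 1e-10)
    expect_equal(unname(hierarchyLevel(ls)), hv, tolerance = 1e-10)
    expect_equal(unname(networkLevel(ls)), nv, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(globalLevel(ls)[["within_network"]], mean(diag(nv)),
                 tolerance = 1e-10)
    expect_equal(globalLevel(ls)[["between_network"]],
                 mean(nv[upper.tri(nv)]), tolerance = 1e-10)
  })
})

test_that("raw efficiencies are invariant to relabeling network blocks", {
  set.seed(29)
  p <- makePartition(14, rep(2, 7))
  fc <- randomFC(14, lo = 0.05, hi = 0.9)
  # swap the VIS and DMN blocks in both data and partition
  perm <- c(13:14, 3:12, 1:2)
  fcP <- fc[perm, perm]
  egs <- function(f, a, b) normalizedEfficiency(f, a, b, nNull = 1)@eg
  expect_equal(egs(fc, 1:2, 3:4), egs(fcP, 13:14, 3:4), tolerance = 1e-12)
  expect_equal(egs(fc, 13:14, NULL), egs(fcP, 1:2, NULL), tolerance = 1e-12)
})
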