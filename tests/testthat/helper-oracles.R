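# Independent oracles used across the suite. Each is a deliberately naive,
# loop-based implementation kept separate from the package's code paths.

# per-source Dijkstra on a distance matrix (0 diagonal, Inf = no edge)
oracleDijkstra <- function(dist) {
  n <- nrow(dist)
  out <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    d <- rep(Inf, n)
    d[src] <- 0
    visited <- rep(FALSE, n)
    repeat {
      cand <- which(!visited & is.finite(d))
      if (!length(cand)) break
      u <- cand[which.min(d[cand])]
      visited[u] <- TRUE
      for (v in seq_len(n)) {
        if (!visited[v] && is.finite(dist[u, v])) {
          alt <- d[u] + dist[u, v]
          if (alt < d[v]) d[v] <- alt
        }
      }
    }
    out[src, ] <- d
  }
  out
}

# exhaustive shortest paths by enumerating every simple path (tiny n only)
oracleAllPaths <- function(dist) {
  n <- nrow(dist)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  paths <- function(from, to, visited, len) {
    if (len >= best[from0, to0]) return()
    if (from == to) {
      best[from0, to0] <<- len
      return()
    }
    for (v in seq_len(n)) {
      if (!visited[v] && is.finite(dist[from, v]))
        paths(v, to, `[<-`(visited, v, TRUE), len + dist[from, v])
    }
  }
  for (from0 in seq_len(n)) for (to0 in seq_len(n)) {
    if (from0 == to0) next
    paths(from0, to0, `[<-`(rep(FALSE, n), from0, TRUE), 0)
  }
  best
}

# Benjamini-Hochberg step-up, written from the definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m / seq_len(m)) * p[o]
  # step-up: enforce monotonicity from the largest p downwards
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# block mean over unordered pairs by explicit double loop
oracleBlockMean <- function(fc, rows, cols) {
  seen <- matrix(FALSE, nrow(fc), ncol(fc))
  vals <- numeric()
  for (i in rows) for (j in cols) {
    if (i == j) next
    a <- min(i, j); b <- max(i, j)
    if (seen[a, b]) next
    seen[a, b] <- TRUE
    vals <- c(vals, fc[a, b])
  }
  mean(vals)
}

# interaction matrix by triple loop
oracleInteraction <- function(x1, x2, center = TRUE) {
  M <- matrix(0, ncol(x1), ncol(x2))
  for (i in seq_len(ncol(x1)))
    for (j in seq_len(ncol(x2)))
      for (t in seq_len(nrow(x1)))
        M[i, j] <- M[i, j] + x1[t, i] * x2[t, j]
  if (center) M <- M - mean(M)
  M
}

# Kendall tau-b from concordant/discordant pair counts
oracleTauB <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# reference level summary by classifying every unique pair
oracleSummarize <- function(fc, partition, pooling = "block") {
  net <- networkOf(partition)
  hier <- hierarchyOf(partition)
  n <- nrow(fc)
  nets <- networkNames()
  netMat <- matrix(NA_real_, 7, 7, dimnames = list(nets, nets))
  for (a in seq_len(7)) for (b in a:7) {
    ia <- which(net == nets[a]); ib <- which(net == nets[b])
    netMat[a, b] <- netMat[b, a] <- oracleBlockMean(fc, ia, ib)
  }
  hcs <- list(`U-U` = c("unimodal", "unimodal"),
              `A-A` = c("attention", "attention"),
              `T-T` = c("transmodal", "transmodal"),
              `U-A` = c("unimodal", "attention"),
              `U-T` = c("unimodal", "transmodal"),
              `A-T` = c("attention", "transmodal"))
  hvals <- vapply(hcs, function(hc) {
    ia <- which(!is.na(hier) & hier == hc[1])
    ib <- which(!is.na(hier) & hier == hc[2])
    oracleBlockMean(fc, ia, ib)
  }, 0)
  off <- upper.tri(netMat)
  if (pooling == "block") {
    wi <- mean(diag(netMat)); be <- mean(netMat[off])
  } else {
    wiv <- c(); bev <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (net[i] == net[j]) wiv <- c(wiv, fc[i, j]) else bev <- c(bev, fc[i, j])
    }
    wi <- mean(wiv); be <- mean(bev)
  }
  list(global = c(whole_brain = oracleBlockMean(fc, 1:n, 1:n),
                  within_network = wi, between_network = be),
       hierarchy = hvals, network = netMat)
}

# small random symmetric weight matrix with unit diagonal
randomFC <- function(n, lo = -0.3, hi = 0.9) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, lo, hi)
  w <- w + t(w)
  diag(w) <- 1
  w
}

# tiny but non-degenerate simulated cohort for integration-style tests
tinyConfig <- function(seed, nSubjects = 4, nFrames = 60,
                       states = defaultStates()[c(1, 9), ])
  simulationConfig(seed = seed, nRois = 28, networkSizes = rep(4, 7),
                   nFrames = nFrames, nSubjects = nSubjects, states = states)
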