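# brute-force oracles, independent of the package's implementation paths:
# all-pairs shortest paths by Floyd-Warshall, Katz by truncated power series,
# current-flow quantities by explicit per-pair solves with a Moore-Penrose
# pseudoinverse

oracleWeightMatrix <- function(tg, scenario) {
  cd <- cellData(tg)
  wd <- wallData(tg)
  n <- nrow(cd)
  W <- matrix(0, n, n, dimnames = list(cd$id, cd$id))
  for (k in seq_len(nrow(wd))) {
    u <- wd$u[k]; v <- wd$v[k]
    w <- switch(scenario,
      unweighted = 1,
      area = 2 / (cd$area[cd$id == u] + cd$area[cd$id == v]),
      wall = 1 / wd$sharedWall[k],
      distance = {
        iu <- which(cd$id == u); iv <- which(cd$id == v)
        1 / sqrt((cd$x[iu] - cd$x[iv])^2 + (cd$y[iu] - cd$y[iv])^2 +
                 (cd$z[iu] - cd$z[iv])^2)
      })
    W[u, v] <- w; W[v, u] <- w
  }
  W
}

# Floyd-Warshall on lengths = 1/weight
oracleDistances <- function(W) {
  n <- nrow(W)
  D <- 1 / W
  D[W == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracleHarmonic <- function(W) {
  D <- oracleDistances(W)
  sapply(seq_len(nrow(W)), function(v) sum(1 / D[v, -v]))
}

oracleCloseness <- function(W) {
  D <- oracleDistances(W)
  sapply(seq_len(nrow(W)), function(v) 1 / sum(D[v, -v]))
}

# shortest-path betweenness via path counting on the length graph
oracleBetweenness <- function(W, tol = 1e-10) {
  n <- nrow(W)
  L <- 1 / W; L[W == 0] <- Inf; diag(L) <- 0
  D <- oracleDistances(W)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (v in order(D[s, ])) {
      if (v == s) next
      pred <- which(is.finite(L[, v]) & L[, v] > 0 &
                    abs(D[s, ] + L[, v] - D[s, v]) < tol)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  bw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) for (v in seq_len(n)) {
    if (v == s || v == t) next
    if (abs(D[s, v] + D[v, t] - D[s, t]) < tol)
      bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  }
  bw
}

oracleKatz <- function(W, attenuationFactor = 0.9, beta = 1) {
  lmax <- max(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  alpha <- attenuationFactor / lmax
  n <- nrow(W)
  x <- rep(beta, n)
  term <- rep(beta, n)
  for (k in 1:5000) {
    term <- alpha * (W %*% term)
    x <- x + term
    if (max(abs(term)) < 1e-14) break
  }
  as.numeric(x)
}

oracleEigenvector <- function(W) {
  v <- eigen(W, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  v / max(v)
}

oracleCurrentFlowCloseness <- function(W) {
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  G <- MASS::ginv(L)
  sapply(seq_len(n), function(v) {
    sumR <- sum(sapply(seq_len(n), function(t)
      G[v, v] + G[t, t] - 2 * G[v, t]))
    (n - 1) / sumR
  })
}

oracleCurrentFlowBetweenness <- function(W) {
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  G <- MASS::ginv(L)
  cfb <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    b <- numeric(n); b[s] <- 1; b[t] <- -1
    p <- G %*% b
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thr <- 0
      for (u in which(W[v, ] > 0))
        thr <- thr + W[v, u] * abs(p[v] - p[u])
      cfb[v] <- cfb[v] + thr / 2
    }
  }
  cfb
}

oracleStrength <- function(W) rowSums(W)

oracleClusteringBarrat <- function(W) {
  n <- nrow(W)
  A <- W > 0
  s <- rowSums(W)
  deg <- rowSums(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    tot <- 0
    for (j in nb) for (h in nb)
      if (j != h && A[j, h]) tot <- tot + (W[i, j] + W[i, h]) / 2
    tot / (s[i] * (deg[i] - 1))
  })
}

oracleAvgNeighborDegree <- function(W) {
  deg <- rowSums(W > 0)
  as.numeric((W %*% deg) / rowSums(W))
}

# neighborhood features by explicit induced subgraphs
oracleNeighborhood <- function(W, k) {
  n <- nrow(W)
  A <- W > 0
  hop1 <- lapply(seq_len(n), function(v) which(A[v, ]))
  members <- lapply(seq_len(n), function(v) {
    m <- hop1[[v]]
    if (k == 2) m <- union(m, unlist(hop1[m]))
    setdiff(m, v)
  })
  t(sapply(seq_len(n), function(v) {
    m <- members[[v]]
    N <- length(m)
    E <- sum(A[m, m, drop = FALSE]) / 2
    mp <- 0
    if (N >= 2) {
      Wm <- W[m, m, drop = FALSE]
      D <- oracleDistances(Wm)
      d <- D[upper.tri(D)]
      d <- d[is.finite(d)]
      if (length(d)) mp <- mean(d)
    }
    c(size = N,
      absDensity = if (N > 1) 2 * E / (N * (N - 1)) else 0,
      relDensity = if (N > 0) 2 * E / N else 0,
      meanPath = mp)
  }))
}

# rank-sum (Mann-Whitney) AUC
oracleAUC <- function(labels, scores, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# full oracle feature matrix in catalogue column order
oracleAllFeatures <- function(tg, scenario) {
  W <- oracleWeightMatrix(tg, scenario)
  nb1 <- oracleNeighborhood(W, 1)
  nb2 <- oracleNeighborhood(W, 2)
  cbind(degree = oracleStrength(W),
        clustering = oracleClusteringBarrat(W),
        avgNeighborDegree = oracleAvgNeighborDegree(W),
        harmonic = oracleHarmonic(W),
        closeness = oracleCloseness(W),
        betweenness = oracleBetweenness(W),
        currentFlowCloseness = oracleCurrentFlowCloseness(W),
        katz = oracleKatz(W),
        eigenvector = oracleEigenvector(W),
        currentFlowBetweenness = oracleCurrentFlowBetweenness(W),
        nbSize1 = nb1[, "size"], nbAbsDensity1 = nb1[, "absDensity"],
        nbRelDensity1 = nb1[, "relDensity"],
        nbSize2 = nb2[, "size"], nbAbsDensity2 = nb2[, "absDensity"],
        nbRelDensity2 = nb2[, "relDensity"], nbMeanPath2 = nb2[, "meanPath"])
}
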