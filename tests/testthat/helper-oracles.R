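# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately use naive enumeration (Floyd-Warshall triple loop, explicit
# triangle counting, explicit subgraph + full sort) so they share no code
# path with the package implementations they check.

# Floyd-Warshall all-pairs shortest paths on edge lengths 1/w
oracleDistances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracleEg <- function(w) {
  n <- nrow(w)
  d <- oracleDistances(w)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracleNodalEfficiency <- function(w) {
  n <- nrow(w)
  d <- oracleDistances(w)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (n - 1)
  }, 1)
}

oracleLp <- function(w) {
  d <- oracleDistances(w)
  vals <- d[row(d) != col(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

# Onnela weighted clustering by explicit triangle enumeration
oracleCp <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- w / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

oracleEloc <- function(w) {
  n <- nrow(w)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracleEg(w[nb, nb, drop = FALSE])
  }, 1))
}

# Weighted rich-club coefficient by explicit subgraph + full weight sort
oraclePhi <- function(w, k) {
  n <- nrow(w)
  deg <- vapply(seq_len(n), function(i) sum(w[i, ] > 0), 1)
  S <- which(deg > k)
  clubW <- c()
  for (i in S) for (j in S) if (i < j && w[i, j] > 0)
    clubW <- c(clubW, w[i, j])
  e <- length(clubW)
  if (e == 0) return(NA_real_)
  allW <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j && w[i, j] > 0)
    allW <- c(allW, w[i, j])
  sum(clubW) / sum(sort(allW, decreasing = TRUE)[seq_len(e)])
}

# Per-edge consensus counting oracle
oracleConsensusMask <- function(ws, prevalence) {
  n <- nrow(ws[[1]])
  mask <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    cnt <- sum(vapply(ws, function(w) w[i, j] > 0, TRUE))
    if (cnt / length(ws) >= prevalence) mask[i, j] <- 1
  }
  mask
}

# Normal-equations least squares (independent of qr.resid)
oracleResiduals <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# ---- fixture builders ----

symMatrix <- function(n, fill = 0) matrix(fill, n, n)

# Build a symmetric weight matrix from an edge list: list of c(i, j, w)
edgesToMatrix <- function(n, edges) {
  w <- symMatrix(n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  w
}

randomWeightedGraph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- symMatrix(n)
  up <- which(upper.tri(w), arr.ind = TRUE)
  on <- runif(nrow(up)) < density
  vals <- ifelse(on, runif(nrow(up), 0.1, 5), 0)
  w[up] <- vals
  w[up[, c(2, 1)]] <- vals
  w
}

# Ring lattice: each node tied to `neigh` neighbors on each side, unit
# weights; optionally rewire a fraction of edges at random (Watts-Strogatz
# style) while keeping the graph simple.
ringLattice <- function(n, neigh = 3, rewireFrac = 0, seed = 1) {
  w <- symMatrix(n)
  for (i in seq_len(n)) for (s in seq_len(neigh)) {
    j <- ((i + s - 1) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  if (rewireFrac > 0) {
    set.seed(seed)
    up <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    pick <- sample(nrow(up), round(rewireFrac * nrow(up)))
    for (r in pick) {
      i <- up[r, 1]; j <- up[r, 2]
      cand <- setdiff(which(w[i, ] == 0), c(i, j))
      if (!length(cand)) next
      jn <- cand[sample.int(length(cand), 1)]
      w[i, j] <- w[j, i] <- 0
      w[i, jn] <- w[jn, i] <- 1
    }
  }
  w
}

net <- function(w) weightedNetwork(w)

rawConnectome <- function(fn, fa, volumes, atlas = NULL) {
  new("RawConnectome", fn = fn, fa = fa, volumes = volumes, atlas = atlas)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# Small, fast simulation config for tests (overridable defaults)
testConfig <- function(...) {
  args <- utils::modifyList(list(nNodes = 30, nHubs = 8, nGroup1 = 6,
                                 nGroup2 = 6, fnBase = 6), list(...))
  do.call(simulationConfig, args)
}
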