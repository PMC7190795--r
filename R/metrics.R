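## Graph metrics on weighted networks. Edge length is the reciprocal weight
## (the usual convention for structural connectomes); shortest paths are
## delegated to igraph's Dijkstra implementation.

asIgraph <- function(network) {
  igraph::graph_from_adjacency_matrix(edgeWeights(network),
                                      mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' All-pairs shortest-path distances of a weighted network
#'
#' Edge length = 1 / weight; distances are Dijkstra shortest paths;
#' unreachable pairs are +Inf; the diagonal is 0.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @return N x N numeric distance matrix.
#' @export
distanceMatrix <- function(network) {
  w <- edgeWeights(network)
  n <- nrow(w)
  g <- asIgraph(network)
  if (igraph::ecount(g) == 0L) {
    d <- matrix(Inf, n, n); diag(d) <- 0
    return(d)
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

## Onnela weighted clustering coefficient per node: geometric mean of
## triangle weights, normalized by the network maximum; reduces to the
## binary triangle fraction on 0/1 weights. Nodes with degree < 2 get 0.
onnelaClustering <- function(w) {
  n <- nrow(w)
  k <- colSums(w > 0)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  cr <- (w / mx)^(1 / 3)
  tri <- diag(cr %*% cr %*% cr)
  ci <- numeric(n)
  ok <- k >= 2
  ci[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  ci
}

#' Global metrics of a weighted network
#'
#' Computes the raw global metrics: mean Onnela weighted clustering (Cp),
#' characteristic path length (Lp, mean over finite ordered-pair
#' distances), global efficiency (Eg, mean inverse distance with 0 for
#' disconnected pairs), local efficiency (Eloc, mean over nodes of the
#' global efficiency of each node's neighbor-induced subgraph), plus nodal
#' efficiency and the per-node degree and strength.
#'
#' @param network a \linkS4class{WeightedNetwork} with >= 2 nodes.
#' @return list with elements Cp, Lp, Eg, Eloc (scalars) and
#'   nodalEfficiency, degree, strength (length-N vectors).
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
#' computeGlobalMetrics(weightedNetwork(w))$Eg   # (1 + 1 + 0.5)/3
#' @export
computeGlobalMetrics <- function(network) {
  w <- edgeWeights(network)
  n <- nrow(w)
  stopIfNot(n >= 2, "network must have at least 2 nodes")
  d <- distanceMatrix(network)
  off <- !diag(n)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  eg <- sum(inv[off]) / (n * (n - 1))
  finite <- is.finite(d) & off
  lp <- if (any(finite)) mean(d[finite]) else NA_real_
  nodalEff <- rowSums(inv) / (n - 1)
  ci <- onnelaClustering(w)
  k <- colSums(w > 0)
  eloc <- mean(vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    subgraphEg(w[nb, nb, drop = FALSE])
  }, 1))
  list(Cp = mean(ci), Lp = lp, Eg = eg, Eloc = eloc,
       nodalEfficiency = nodalEff, degree = k, strength = colSums(w))
}

subgraphEg <- function(w) {
  m <- nrow(w)
  if (m < 2L) return(0)
  computeGlobalMetricsFast_Eg(w)
}

## Eg of a plain weight matrix without re-wrapping into S4 (hot path of
## Eloc): Dijkstra over the subgraph.
computeGlobalMetricsFast_Eg <- function(w) {
  m <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (m * (m - 1))
}

#' Nodal metrics of a weighted network
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @return data.frame with node, label (if an atlas is attached), degree,
#'   strength and nodalEfficiency.
#' @export
nodalMetrics <- function(network) {
  gm <- computeGlobalMetrics(network)
  lab <- nodeLabels(network)
  out <- data.frame(node = seq_len(nNodes(network)),
                    degree = gm$degree, strength = gm$strength,
                    nodalEfficiency = gm$nodalEfficiency)
  if (!is.null(lab)) out <- cbind(out[1], label = lab, out[-1])
  out
}

#' Degree-preserving random network (Maslov-Sneppen rewiring)
#'
#' Rewires the binary topology by double-edge swaps that preserve every
#' node's degree exactly, then randomly reassigns the original multiset of
#' edge weights to the rewired edges. This is the matched null model used
#' to normalize clustering, path length and the rich-club coefficient.
#'
#' @param network a \linkS4class{WeightedNetwork} with >= 2 edges
#'   (fewer: the input is returned with a warning).
#' @param nSwapsPerEdge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return a \linkS4class{WeightedNetwork} with identical degree sequence
#'   and weight multiset.
#' @export
rewireNull <- function(network, nSwapsPerEdge = 10, seed = 1) {
  w <- edgeWeights(network)
  n <- nrow(w)
  up <- upperPairs(n)
  wts <- w[up][w[up] > 0]
  ne <- length(wts)
  if (ne < 2L) {
    warning("too few edges to rewire; returning the input network")
    return(network)
  }
  g <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected",
                                           diag = FALSE)
  out <- matrix(0, n, n)
  withSeed(seed, {
    rg <- igraph::rewire(g, igraph::keeping_degseq(niter = nSwapsPerEdge * ne))
    el <- igraph::as_edgelist(rg, names = FALSE)
    wperm <- sample(wts)
  })
  out[el] <- wperm
  out[el[, c(2, 1), drop = FALSE]] <- wperm
  weightedNetwork(out, network@atlas)
}

## Clustering and path length only (the quantities the small-world null
## loop needs); skips the expensive per-node local-efficiency pass.
cpLpOnly <- function(network) {
  w <- edgeWeights(network)
  n <- nrow(w)
  d <- distanceMatrix(network)
  finite <- is.finite(d) & !diag(n)
  lp <- if (any(finite)) mean(d[finite]) else NA_real_
  list(Cp = mean(onnelaClustering(w)), Lp = lp)
}

#' Small-world indices against a degree-preserving null ensemble
#'
#' gamma = Cp / mean(Cp_null), lambda = Lp / mean(Lp_null),
#' sigma = gamma / lambda, over \code{nNull} rewired random networks.
#' A degenerate ensemble (mean null Cp or Lp of 0) yields NA indices.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param nNull number of null networks (the reference analysis uses 1000;
#'   smaller values are appropriate for exploration).
#' @param seed integer seed; null b uses \code{childSeed(seed, b)}.
#' @param nSwapsPerEdge swaps per edge for each null.
#' @return list with gamma, lambda, sigma, Cp, Lp, and null summaries
#'   (CpNullMean, CpNullSd, LpNullMean, LpNullSd, nNull).
#' @export
smallWorldIndices <- function(network, nNull = 1000, seed = 1,
                              nSwapsPerEdge = 10) {
  stopIfNot(nNull >= 1, "nNull must be >= 1")
  gm <- cpLpOnly(network)
  nulls <- vapply(seq_len(nNull), function(b) {
    nb <- rewireNull(network, nSwapsPerEdge, seed = childSeed(seed, b))
    nm <- cpLpOnly(nb)
    c(nm$Cp, nm$Lp)
  }, c(0, 0))
  cpn <- mean(nulls[1, ]); lpn <- mean(nulls[2, ], na.rm = TRUE)
  gamma <- if (is.finite(cpn) && cpn > 0) gm$Cp / cpn else NA_real_
  lambda <- if (is.finite(lpn) && lpn > 0) gm$Lp / lpn else NA_real_
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = gm$Cp, Lp = gm$Lp,
       CpNullMean = cpn, CpNullSd = stats::sd(nulls[1, ]),
       LpNullMean = lpn, LpNullSd = stats::sd(nulls[2, ]),
       nNull = as.integer(nNull))
}

.metricNames <- c("Cp", "Lp", "Eg", "Eloc")

#' Metric-versus-sparsity curve with area under the curve
#'
#' Evaluates a global metric on \code{\link{applySparsity}}(network, s) for
#' every s on the grid and integrates the curve with the trapezoid rule.
#' The conventional grid is sparsity 0.10 to 0.40 in steps of 0.01.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param metric one of "Cp", "Lp", "Eg", "Eloc".
#' @param grid strictly ascending sparsities within (0, 1].
#' @return a \linkS4class{MetricCurve}.
#' @export
sparsityAUC <- function(network, metric = .metricNames,
                        grid = seq(0.10, 0.40, by = 0.01)) {
  metric <- match.arg(metric)
  stopIfNot(!is.unsorted(grid, strictly = TRUE) && all(grid > 0) &&
              all(grid <= 1), "grid must be ascending within (0, 1]")
  vals <- vapply(grid, function(s)
    computeGlobalMetrics(applySparsity(network, s))[[metric]], 1)
  new("MetricCurve", metric = metric, sparsity = as.numeric(grid),
      values = vals, auc = trapezoid(grid, vals))
}
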