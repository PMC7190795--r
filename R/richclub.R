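#' Binary degree of every node
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @return integer vector: number of nonzero connections per node.
#' @export
binaryDegree <- function(network) {
  as.integer(colSums(edgeWeights(network) > 0))
}

#' Weighted rich-club coefficient at a single degree level
#'
#' Let S be the nodes with binary degree > k, E the number of edges with
#' both ends in S and W their summed weight. Phi^w(k) = W divided by the
#' sum of the E largest edge weights anywhere in the network, so
#' Phi^w(k) <= 1 wherever defined. Returns NA when the club has no edges.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param k degree threshold (>= 0); club membership uses strict >.
#' @return Phi^w(k) in [0, 1], or NA if undefined.
#' @export
richClubCoefficient <- function(network, k) {
  stopIfNot(length(k) == 1L && k >= 0, "k must be a single degree >= 0")
  phiCurve(edgeWeights(network), as.integer(k))
}

## Vectorized Phi^w over a k grid: degrees, the sorted weight vector and
## its cumulative sums are computed once.
phiCurve <- function(w, kGrid) {
  n <- nrow(w)
  up <- upperPairs(n)
  wv <- w[up]
  pos <- wv > 0
  deg <- colSums(w > 0)
  sortedW <- sort(wv[pos], decreasing = TRUE)
  csum <- cumsum(sortedW)
  vapply(kGrid, function(k) {
    inS <- deg > k
    club <- pos & inS[up[, 1]] & inS[up[, 2]]
    e <- sum(club)
    if (e == 0L) return(NA_real_)
    sum(wv[club]) / csum[e]
  }, 1)
}

#' Normalized weighted rich-club curve
#'
#' Computes Phi^w(k) across a degree grid and normalizes each value by the
#' mean Phi^w_null(k) over \code{nNull} degree-preserving random networks
#' (\code{\link{rewireNull}}). phi_norm(k) > 1 across a k interval is the
#' signature of rich-club organization. Undefined values (empty club in the
#' observed network, or every null undefined at that k) are NA.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param kGrid integer degrees; default 1 .. max(degree) - 1.
#' @param nNull number of null networks (reference analysis: 1000).
#' @param seed integer seed; null b uses \code{childSeed(seed, b)}.
#' @param nSwapsPerEdge swaps per edge for each null.
#' @return a \linkS4class{RichClubCurve}.
#' @export
normalizedRichClub <- function(network, kGrid = NULL, nNull = 1000,
                               seed = 1, nSwapsPerEdge = 10) {
  stopIfNot(nNull >= 1, "nNull must be >= 1")
  w <- edgeWeights(network)
  deg <- colSums(w > 0)
  if (is.null(kGrid)) {
    kmax <- max(deg)
    stopIfNot(kmax >= 2, "network too sparse for a default k grid")
    kGrid <- seq_len(kmax - 1L)
  }
  kGrid <- as.integer(kGrid)
  phi <- phiCurve(w, kGrid)
  nullPhi <- vapply(seq_len(nNull), function(b) {
    nb <- rewireNull(network, nSwapsPerEdge, seed = childSeed(seed, b))
    phiCurve(edgeWeights(nb), kGrid)
  }, numeric(length(kGrid)))
  nullPhi <- matrix(nullPhi, nrow = length(kGrid))
  nm <- rowMeans(nullPhi, na.rm = TRUE)
  nm[!is.finite(nm)] <- NA_real_
  nsd <- apply(nullPhi, 1, stats::sd, na.rm = TRUE)
  norm <- ifelse(!is.na(phi) & !is.na(nm) & nm > 0, phi / nm, NA_real_)
  new("RichClubCurve", k = kGrid, phi = phi, phiNullMean = nm,
      phiNullSd = nsd, phiNorm = norm, nNull = as.integer(nNull),
      seed = as.integer(seed))
}

#' Identify rich-club nodes
#'
#' Either every node with binary degree strictly above \code{k} (the
#' reference analysis used k = 7), or the \code{topN} highest-degree nodes
#' (the reference analysis reported the top 32 regions); ties on degree are
#' broken by strength, then by node index, so the selection is
#' deterministic. Exactly one selector must be given.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param k degree threshold (strict >), or NULL.
#' @param topN number of nodes to select, or NULL.
#' @return sorted integer vector of node ids.
#' @export
identifyRichNodes <- function(network, k = NULL, topN = NULL) {
  stopIfNot(xor(is.null(k), is.null(topN)),
            "provide exactly one of k / topN")
  w <- edgeWeights(network)
  deg <- colSums(w > 0)
  if (!is.null(k)) {
    stopIfNot(k >= 0, "k must be >= 0")
    return(which(deg > k))
  }
  stopIfNot(topN >= 1 && topN <= nrow(w), "topN out of range")
  strength <- colSums(w)
  ord <- order(-deg, -strength, seq_along(deg))
  sort(ord[seq_len(topN)])
}

#' Classify edges into rich-club, feeder and local connections
#'
#' Edges with both ends in the rich-node set are rich-club connections,
#' edges with exactly one end in it are feeder connections, and edges
#' between two non-rich nodes are local connections. Class strengths sum
#' the edge weights per class and always partition the total strength.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param richNodes integer ids of rich-club nodes (possibly empty).
#' @return an \linkS4class{EdgeClassification}.
#' @export
classifyEdges <- function(network, richNodes) {
  w <- edgeWeights(network)
  n <- nrow(w)
  richNodes <- as.integer(richNodes)
  stopIfNot(all(richNodes >= 1 & richNodes <= n) && !anyDuplicated(richNodes),
            "richNodes must be unique node ids within the network")
  up <- upperPairs(n)
  wv <- w[up]
  pos <- wv > 0
  isRich <- logical(n); isRich[richNodes] <- TRUE
  nrich <- isRich[up[, 1]] + isRich[up[, 2]]
  cls <- c("local", "feeder", "rich")[nrich + 1L]
  edges <- data.frame(i = up[pos, 1], j = up[pos, 2], weight = wv[pos],
                      class = cls[pos], stringsAsFactors = FALSE)
  cs <- c(rich = sum(edges$weight[edges$class == "rich"]),
          feeder = sum(edges$weight[edges$class == "feeder"]),
          local = sum(edges$weight[edges$class == "local"]))
  ratios <- c(richFeeder = if (cs["feeder"] > 0) cs[["rich"]] / cs[["feeder"]]
                           else NA_real_,
              richLocal = if (cs["local"] > 0) cs[["rich"]] / cs[["local"]]
                          else NA_real_)
  new("EdgeClassification", richNodes = sort(richNodes), edges = edges,
      classStrength = cs, ratios = ratios)
}

#' Per-subject connection-class strengths
#'
#' Applies \code{\link{classifyEdges}} with one (group-level) rich-node set
#' to every subject network, returning the three per-subject strength sums
#' used in group comparisons and clinical correlations.
#'
#' @param networks list of same-size \linkS4class{WeightedNetwork}s.
#' @param richNodes integer rich-node ids on the shared atlas.
#' @return data.frame with columns rich, feeder, local (one row per
#'   network, named after the list).
#' @export
subjectClassStrengths <- function(networks, richNodes) {
  ns <- vapply(networks, nNodes, 1L)
  stopIfNot(all(ns == ns[1]), "all networks must have the same size")
  out <- t(vapply(networks, function(x)
    classifyEdges(x, richNodes)@classStrength,
    c(rich = 0, feeder = 0, local = 0)))
  as.data.frame(out)
}

#' Export a network for BrainNet Viewer
#'
#' Writes \code{<prefix>.node} (six whitespace-delimited columns:
#' x y z color size label, color 1 for rich nodes and 2 otherwise, size =
#' nodal strength) and \code{<prefix>.edge} (the N x N weight matrix,
#' whitespace-delimited).
#'
#' @param network a \linkS4class{WeightedNetwork} with an atlas.
#' @param richNodes integer rich-node ids.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
exportBrainNet <- function(network, richNodes, prefix) {
  atl <- atlas(network)
  stopIfNot(!is.null(atl), "BrainNet export needs an atlas with coordinates")
  w <- edgeWeights(network)
  n <- nrow(w)
  color <- rep(2L, n); color[richNodes] <- 1L
  nodeFile <- paste0(prefix, ".node")
  edgeFile <- paste0(prefix, ".edge")
  nodeTab <- data.frame(atl@coords[, 1], atl@coords[, 2], atl@coords[, 3],
                        color, colSums(w), atl@label)
  utils::write.table(nodeTab, nodeFile, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(w, edgeFile, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node = nodeFile, edge = edgeFile))
}
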