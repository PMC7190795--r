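#' Construct a WeightedNetwork from raw values
#'
#' @param weights symmetric non-negative matrix with zero diagonal.
#' @param atlas optional \linkS4class{NodeAtlas}.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
weightedNetwork <- function(weights, atlas = NULL) {
  new("WeightedNetwork", weights = unname(as.matrix(weights)), atlas = atlas)
}

#' Build a subject's weighted network from raw ingredients
#'
#' Edge weights follow w_ij = FN_ij * FA_ij / ((vol_i + vol_j) / 2): the
#' streamline count times the mean FA along the bundle, normalized by the
#' arithmetic mean volume of the two connected regions. Edges with fewer
#' than \code{fnThreshold} streamlines are removed.
#'
#' @param raw a \linkS4class{RawConnectome}.
#' @param fnThreshold minimum streamline count for an edge to survive
#'   (>= 1); typical sensitivity values are 1, 2, 3, 5 and 10.
#' @return a \linkS4class{WeightedNetwork}.
#' @examples
#' fn <- matrix(0, 2, 2); fn[1, 2] <- fn[2, 1] <- 10
#' fa <- matrix(0, 2, 2); fa[1, 2] <- fa[2, 1] <- 0.5
#' raw <- new("RawConnectome", fn = fn, fa = fa, volumes = c(4, 6),
#'            atlas = NULL)
#' edgeWeights(buildNetwork(raw))[1, 2]   # 10 * 0.5 / 5 = 1
#' @export
buildNetwork <- function(raw, fnThreshold = 1) {
  stopIfNot(is(raw, "RawConnectome"), "raw must be a RawConnectome")
  stopIfNot(length(fnThreshold) == 1L && fnThreshold >= 1,
            "fnThreshold must be >= 1")
  validObject(raw)
  vol <- raw@volumes
  denom <- outer(vol, vol, `+`) / 2
  w <- raw@fn * raw@fa / denom
  w[raw@fn < fnThreshold] <- 0
  diag(w) <- 0
  weightedNetwork(w, raw@atlas)
}

#' Group-consensus backbone
#'
#' Retains an edge iff the fraction of subjects in which it is present
#' (weight > 0) is at least \code{prevalence}; the retained edge weight is
#' the mean weight over the subjects where the edge is present.
#'
#' @param networks non-empty list of same-size
#'   \linkS4class{WeightedNetwork}s.
#' @param prevalence required subject fraction in (0, 1]; the study's
#'   levels are 0.50, 0.75 and 0.90.
#' @return a \linkS4class{ConsensusBackbone}.
#' @export
groupConsensus <- function(networks, prevalence = 0.75) {
  stopIfNot(length(networks) >= 1L, "need at least one network")
  stopIfNot(prevalence > 0 && prevalence <= 1,
            "prevalence must lie in (0, 1]")
  ns <- vapply(networks, nNodes, 1L)
  stopIfNot(all(ns == ns[1]), "all networks must have the same size")
  nsub <- length(networks)
  presence <- Reduce(`+`, lapply(networks, function(x) x@weights > 0))
  wsum <- Reduce(`+`, lapply(networks, edgeWeights))
  mask <- (presence / nsub >= prevalence) * 1
  diag(mask) <- 0
  w <- matrix(0, ns[1], ns[1])
  keep <- mask == 1 & presence > 0
  w[keep] <- wsum[keep] / presence[keep]
  new("ConsensusBackbone", weights = w, atlas = networks[[1]]@atlas,
      mask = mask, prevalence = prevalence, nSubjects = as.integer(nsub))
}

#' Threshold a network to a target sparsity
#'
#' Keeps the \code{round(s * N(N-1)/2)} largest-weight edges (half-up
#' rounding) and zeroes the rest. Ties at the cut are broken by the lowest
#' (i, j) lexicographic edge index, so the result is deterministic. If the
#' network has fewer nonzero edges than the target count, all are kept.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param s target sparsity (fraction of possible edges) in (0, 1].
#' @return a \linkS4class{WeightedNetwork} at the requested sparsity.
#' @export
applySparsity <- function(network, s) {
  stopIfNot(length(s) == 1L && s > 0 && s <= 1, "s must lie in (0, 1]")
  w <- edgeWeights(network)
  n <- nrow(w)
  up <- upperPairs(n)
  wv <- w[up]
  target <- floor(s * n * (n - 1) / 2 + 0.5)   # round half away from zero
  ## order by weight desc, then (i, j) lexicographic for tie determinism
  ord <- order(-wv, up[, 1], up[, 2])
  keepIdx <- ord[seq_len(min(target, length(ord)))]
  keepIdx <- keepIdx[wv[keepIdx] > 0]          # never promote absent edges
  out <- matrix(0, n, n)
  sel <- up[keepIdx, , drop = FALSE]
  out[sel] <- wv[keepIdx]
  out[sel[, c(2, 1), drop = FALSE]] <- wv[keepIdx]
  weightedNetwork(out, network@atlas)
}
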