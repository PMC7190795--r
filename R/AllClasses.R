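#' NodeAtlas: region definitions of a parcellation
#'
#' Holds the node set of a brain parcellation: unique region labels,
#' hemisphere assignment, centroid coordinates in mm, and regional volumes
#' (voxel counts). Volumes enter the denominator of the connectome
#' edge-weight formula; centroids are used only for node-file export.
#'
#' @slot name short atlas identifier (e.g. "synth90").
#' @slot label character vector of unique region abbreviations.
#' @slot hemisphere character vector, "L" or "R" per node.
#' @slot coords numeric N x 3 matrix of centroid coordinates (mm).
#' @slot volume numeric vector of strictly positive regional volumes.
#' @export
setClass("NodeAtlas",
  representation(name = "character", label = "character",
                 hemisphere = "character", coords = "matrix",
                 volume = "numeric"),
  validity = function(object) {
    n <- length(object@label)
    if (n < 2L) return("an atlas needs at least 2 nodes")
    if (anyDuplicated(object@label)) return("node labels must be unique")
    if (length(object@hemisphere) != n || !all(object@hemisphere %in% c("L", "R")))
      return("hemisphere must be 'L'/'R' for every node")
    if (!is.numeric(object@coords) || nrow(object@coords) != n ||
        ncol(object@coords) != 3L)
      return("coords must be an N x 3 numeric matrix")
    if (length(object@volume) != n || any(!is.finite(object@volume)) ||
        any(object@volume <= 0))
      return("volumes must be strictly positive")
    TRUE
  })

setClassUnion("NodeAtlasOrNULL", c("NodeAtlas", "NULL"))

#' RawConnectome: per-subject network ingredients
#'
#' The tractography-derived ingredients of a subject's structural network:
#' a symmetric streamline-count (FN) matrix, a symmetric mean-FA matrix with
#' the same support, and per-node volumes. These are combined into edge
#' weights by \code{\link{buildNetwork}}.
#'
#' @slot fn symmetric non-negative integer-valued N x N matrix, zero diagonal.
#' @slot fa symmetric N x N matrix in [0, 1]; positive exactly where fn > 0.
#' @slot volumes length-N strictly positive numeric vector.
#' @slot atlas a \linkS4class{NodeAtlas} or NULL.
#' @export
setClass("RawConnectome",
  representation(fn = "matrix", fa = "matrix", volumes = "numeric",
                 atlas = "NodeAtlasOrNULL"),
  validity = function(object) {
    n <- nrow(object@fn)
    if (!isSymmetricZeroDiag(object@fn))
      return("fn must be symmetric with zero diagonal")
    if (any(object@fn < 0) || any(object@fn != round(object@fn)))
      return("fn must hold non-negative integer counts")
    if (!identical(dim(object@fa), dim(object@fn)))
      return("fa and fn must have identical shape")
    if (!isSymmetricZeroDiag(object@fa))
      return("fa must be symmetric with zero diagonal")
    if (any(object@fa < 0) || any(object@fa > 1))
      return("fa entries must lie in [0, 1]")
    if (any((object@fa > 0) != (object@fn > 0)))
      return("fa must be positive exactly where fn is positive")
    if (length(object@volumes) != n || any(object@volumes <= 0))
      return("volumes must be strictly positive, one per node")
    if (!is.null(object@atlas) && length(object@atlas@label) != n)
      return("atlas size does not match matrices")
    TRUE
  })

#' WeightedNetwork: a symmetric weighted structural network
#'
#' The unit of all graph computation: a symmetric non-negative N x N weight
#' matrix with zero diagonal, optionally tied to a \linkS4class{NodeAtlas}.
#'
#' @slot weights symmetric non-negative numeric matrix, zero diagonal.
#' @slot atlas a \linkS4class{NodeAtlas} or NULL.
#' @export
setClass("WeightedNetwork",
  representation(weights = "matrix", atlas = "NodeAtlasOrNULL"),
  validity = function(object) {
    if (!isSymmetricZeroDiag(object@weights))
      return("weights must be symmetric with zero diagonal")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (!is.null(object@atlas) &&
        length(object@atlas@label) != nrow(object@weights))
      return("atlas size does not match weight matrix")
    TRUE
  })

#' ConsensusBackbone: group-level network
#'
#' A \linkS4class{WeightedNetwork} restricted to edges present in at least a
#' stated fraction of subjects; retained edge weights are the mean weight
#' over the subjects in which the edge is present.
#'
#' @slot mask binary N x N matrix of retained edges.
#' @slot prevalence fraction in (0, 1] of subjects required per edge.
#' @slot nSubjects number of subjects the backbone summarizes.
#' @export
setClass("ConsensusBackbone", contains = "WeightedNetwork",
  representation(mask = "matrix", prevalence = "numeric",
                 nSubjects = "integer"),
  validity = function(object) {
    if (!identical(dim(object@mask), dim(object@weights)))
      return("mask and weights must have identical shape")
    if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
    if (any(object@weights[object@mask == 0] != 0))
      return("weights must be zero off the mask")
    if (object@prevalence <= 0 || object@prevalence > 1)
      return("prevalence must lie in (0, 1]")
    TRUE
  })

#' SimulationConfig: parameters of the synthetic-cohort generator
#'
#' Defines a two-group cohort of synthetic connectomes with planted hub
#' (rich-club) organization: a block of \code{nHubs} hub nodes whose edges
#' are both more probable (densityHubGain) and carry more streamlines
#' (fnHubGain) than the rest, a multiplicative patient-group deficit on all
#' hub-attached streamline counts, and clinical scores rank-coupled to
#' subject-level connection-class strengths through a Gaussian copula.
#'
#' @slot nNodes,nHubs,nGroup1,nGroup2 cohort dimensions (patients = group1).
#' @slot density expected fraction of realized edges over the whole network.
#' @slot densityHubGain length-2 presence-probability multipliers for
#'   hub-hub and hub-nonhub edges relative to nonhub-nonhub edges.
#' @slot presenceConcentration concentration of the cohort-level per-edge
#'   presence propensities around their block probability: each cohort
#'   draws one Beta(c p, c (1 - p)) propensity per potential edge, shared
#'   by all subjects. Small values give a U-shaped (anatomically
#'   consistent) edge template in which an edge is either present in most
#'   subjects or in few, as in real tractography cohorts.
#' @slot fnBase expected streamline count on a present nonhub-nonhub edge.
#' @slot fnHubGain multiplicative FN enrichment on hub-hub edges (> 1);
#'   hub-nonhub edges get the geometric midpoint \code{sqrt(fnHubGain)}.
#' @slot fnDispersion negative-binomial size (overdispersion) parameter.
#' @slot groupDeficit multiplicative factor in (0, 1] applied to the
#'   expected FN of hub-hub and hub-nonhub edges in the patient group.
#' @slot faShape Beta shape parameters of the FA distribution.
#' @slot faRange FA support (tractography masks FA below 0.2).
#' @slot volumeMeanlog,volumeSdlog lognormal node-volume parameters.
#' @slot durationMeanlog,durationSdlog lognormal illness-duration (months)
#'   parameters for patients; controls get duration 0.
#' @slot couplings data.frame(scale, class, rho): per-scale target Spearman
#'   correlation with a named connection-class strength
#'   ("rich", "feeder" or "local"), applied within each group.
#' @slot scoreMarginals data.frame(scale, group, mean, sd): truncated-normal
#'   score marginals per group.
#' @slot covariateModel list(ageMean, ageSd, ageRange, eduMean, eduSd,
#'   pMale, confound, confoundShift); with \code{confound = TRUE} the
#'   patient ages are shifted by \code{confoundShift} years (for testing
#'   covariate removal), otherwise covariates are group-independent.
#' @slot seed master integer seed.
#' @export
setClass("SimulationConfig",
  representation(nNodes = "integer", nHubs = "integer",
                 nGroup1 = "integer", nGroup2 = "integer",
                 density = "numeric", densityHubGain = "numeric",
                 presenceConcentration = "numeric",
                 fnBase = "numeric", fnHubGain = "numeric",
                 fnDispersion = "numeric", groupDeficit = "numeric",
                 faShape = "numeric", faRange = "numeric",
                 volumeMeanlog = "numeric", volumeSdlog = "numeric",
                 durationMeanlog = "numeric", durationSdlog = "numeric",
                 couplings = "data.frame", scoreMarginals = "data.frame",
                 covariateModel = "list", seed = "integer"),
  validity = function(object) {
    if (object@nNodes < 2L) return("nNodes must be >= 2")
    if (object@nHubs < 1L || object@nHubs >= object@nNodes)
      return("nHubs must satisfy 1 <= nHubs < nNodes")
    if (object@nGroup1 < 1L || object@nGroup2 < 1L)
      return("both groups need at least one subject")
    if (object@density <= 0 || object@density > 1)
      return("density must lie in (0, 1]")
    if (length(object@densityHubGain) != 2L || any(object@densityHubGain < 1))
      return("densityHubGain must be two multipliers >= 1")
    if (object@presenceConcentration <= 0)
      return("presenceConcentration must be positive")
    if (object@groupDeficit <= 0 || object@groupDeficit > 1)
      return("groupDeficit must lie in (0, 1]")
    if (object@fnHubGain <= 1) return("fnHubGain must exceed 1")
    if (object@fnBase * object@groupDeficit < 1)
      return("fnBase * groupDeficit must be >= 1 (counts are >= 1 on edges)")
    p <- presenceProbs(object)
    if (any(p > 1)) return("density/densityHubGain imply probabilities > 1")
    if (nrow(object@couplings) &&
        (any(abs(object@couplings$rho) >= 1) ||
         !all(object@couplings$class %in% c("rich", "feeder", "local")) ||
         anyDuplicated(object@couplings$scale)))
      return("couplings need |rho| < 1, a known class, one row per scale")
    TRUE
  })

#' RichClubCurve: weighted rich-club coefficients across degree
#'
#' Phi^w(k) with its null-ensemble mean/SD over degree-preserving random
#' networks and the normalized curve phi_norm(k) = Phi^w(k) / mean null.
#' Undefined values (empty club, or all-null undefined) are NA.
#'
#' @slot k integer degree grid.
#' @slot phi weighted rich-club coefficient per k (NA where undefined).
#' @slot phiNullMean,phiNullSd null-ensemble summaries per k.
#' @slot phiNorm normalized coefficient per k.
#' @slot nNull number of null networks used.
#' @slot seed seed used for the null ensemble.
#' @export
setClass("RichClubCurve",
  representation(k = "integer", phi = "numeric", phiNullMean = "numeric",
                 phiNullSd = "numeric", phiNorm = "numeric",
                 nNull = "integer", seed = "integer"),
  validity = function(object) {
    len <- length(object@k)
    if (any(vapply(list(object@phi, object@phiNullMean, object@phiNullSd,
                        object@phiNorm), length, 1L) != len))
      return("all curve slots must have the length of k")
    if (is.unsorted(object@k, strictly = TRUE))
      return("k grid must be strictly ascending")
    if (any(object@phi < -1e-12 | object@phi > 1 + 1e-12, na.rm = TRUE))
      return("phi must lie in [0, 1] where defined")
    TRUE
  })

#' EdgeClassification: rich-club / feeder / local decomposition
#'
#' Partition of a network's edges by rich-node membership of their
#' endpoints, with per-class strength sums and strength ratios.
#'
#' @slot richNodes integer ids of rich-club nodes.
#' @slot edges data.frame(i, j, weight, class) over existing edges.
#' @slot classStrength named numeric: summed weight per class.
#' @slot ratios named numeric: rich/feeder and rich/local strength ratios
#'   (NA on zero denominators).
#' @export
setClass("EdgeClassification",
  representation(richNodes = "integer", edges = "data.frame",
                 classStrength = "numeric", ratios = "numeric"),
  validity = function(object) {
    if (!all(c("rich", "feeder", "local") %in% names(object@classStrength)))
      return("classStrength must name rich, feeder and local")
    tot <- sum(object@edges$weight)
    if (abs(sum(object@classStrength) - tot) > 1e-8 * max(1, tot))
      return("class strengths must sum to total strength")
    TRUE
  })

#' Cohort: a generated two-group study population
#'
#' @slot atlas the \linkS4class{NodeAtlas} shared by all subjects.
#' @slot phenotypes data.frame: subjectId, group, age, sex, education,
#'   duration, PSQI, ISI, SAS, SDS.
#' @slot connectomes named list of \linkS4class{RawConnectome}, parallel to
#'   the phenotype rows.
#' @slot config the \linkS4class{SimulationConfig} that produced it.
#' @export
setClass("Cohort",
  representation(atlas = "NodeAtlas", phenotypes = "data.frame",
                 connectomes = "list", config = "SimulationConfig"),
  validity = function(object) {
    if (nrow(object@phenotypes) != length(object@connectomes))
      return("one connectome per phenotype row required")
    if (!identical(names(object@connectomes), object@phenotypes$subjectId))
      return("connectome names must match subjectId order")
    TRUE
  })

#' PermutationTestResult: permutation group comparison
#'
#' @slot observed group mean difference of the tested quantity after
#'   covariate removal (group1 minus group2).
#' @slot nullMean,nullSd summaries of the permutation null.
#' @slot nPerm number of permutations.
#' @slot pRaw two-tailed permutation p (add-one estimator, always > 0).
#' @slot pAdjusted corrected p (NA until a correction is applied).
#' @slot method correction name ("none" when unadjusted).
#' @slot seed permutation seed.
#' @export
setClass("PermutationTestResult",
  representation(observed = "numeric", nullMean = "numeric",
                 nullSd = "numeric", nPerm = "integer", pRaw = "numeric",
                 pAdjusted = "numeric", method = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@pRaw <= 0 || object@pRaw > 1) return("pRaw must lie in (0, 1]")
    if (!is.na(object@pAdjusted) && object@pAdjusted < object@pRaw - 1e-12)
      return("adjusted p cannot be below raw p")
    TRUE
  })

#' CorrelationResult: covariate-adjusted Spearman correlation
#'
#' @slot rho Spearman coefficient of the covariate residuals.
#' @slot p two-tailed p from the t approximation.
#' @slot n sample size.
#' @slot covariates names of the removed covariates.
#' @export
setClass("CorrelationResult",
  representation(rho = "numeric", p = "numeric", n = "integer",
                 covariates = "character"),
  validity = function(object) {
    if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
      return("|rho| cannot exceed 1")
    TRUE
  })

#' MetricCurve: a graph metric across sparsity thresholds
#'
#' @slot metric metric name.
#' @slot sparsity ascending sparsity grid in (0, 1].
#' @slot values metric value at each sparsity.
#' @slot auc trapezoidal area under the curve.
#' @export
setClass("MetricCurve",
  representation(metric = "character", sparsity = "numeric",
                 values = "numeric", auc = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@sparsity, strictly = TRUE))
      return("sparsity grid must be strictly ascending")
    if (length(object@values) != length(object@sparsity))
      return("values must match the grid length")
    TRUE
  })

## ---- accessors ----

#' @describeIn NodeAtlas number of nodes
#' @param x object.
#' @export
setMethod("nNodes", "NodeAtlas", function(x) length(x@label))
#' @describeIn WeightedNetwork number of nodes
#' @param x object.
#' @export
setMethod("nNodes", "WeightedNetwork", function(x) nrow(x@weights))
#' @export
#' @describeIn RawConnectome number of nodes
setMethod("nNodes", "RawConnectome", function(x) nrow(x@fn))

#' @export
#' @describeIn NodeAtlas region labels
setMethod("nodeLabels", "NodeAtlas", function(x) x@label)
#' @export
#' @describeIn WeightedNetwork region labels (NULL without an atlas)
setMethod("nodeLabels", "WeightedNetwork",
          function(x) if (is.null(x@atlas)) NULL else x@atlas@label)
#' @export
#' @describeIn NodeAtlas region volumes
setMethod("nodeVolumes", "NodeAtlas", function(x) x@volume)

#' @export
#' @describeIn WeightedNetwork weight matrix
setMethod("edgeWeights", "WeightedNetwork", function(x) x@weights)

#' @export
#' @describeIn WeightedNetwork attached atlas
setMethod("atlas", "WeightedNetwork", function(x) x@atlas)
#' @export
#' @describeIn RawConnectome attached atlas
setMethod("atlas", "RawConnectome", function(x) x@atlas)
#' @export
#' @describeIn Cohort attached atlas
setMethod("atlas", "Cohort", function(x) x@atlas)

#' @export
#' @describeIn Cohort phenotype table
setMethod("phenotypes", "Cohort", function(x) x@phenotypes)
#' @export
#' @describeIn Cohort raw connectome list
setMethod("connectomes", "Cohort", function(x) x@connectomes)

#' Coerce a NodeAtlas to a data.frame
#' @param x a \linkS4class{NodeAtlas}.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return data.frame with node_id, label, hemisphere, x, y, z, volume.
#' @export
as.data.frame.NodeAtlas <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(node_id = seq_along(x@label), label = x@label,
             hemisphere = x@hemisphere,
             x = x@coords[, 1], y = x@coords[, 2], z = x@coords[, 3],
             volume = x@volume, stringsAsFactors = FALSE)
}

#' Coerce a RichClubCurve to a data.frame
#' @param x a \linkS4class{RichClubCurve}.
#' @param row.names,optional,... S3 compatibility, unused.
#' @return data.frame with k, phi, phiNullMean, phiNullSd, phiNorm.
#' @export
as.data.frame.RichClubCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(k = x@k, phi = x@phi, phiNullMean = x@phiNullMean,
             phiNullSd = x@phiNullSd, phiNorm = x@phiNorm)
}

## ---- show methods ----

setMethod("show", "NodeAtlas", function(object) {
  cat(sprintf("NodeAtlas '%s': %d nodes (%d L / %d R)\n", object@name,
              nNodes(object), sum(object@hemisphere == "L"),
              sum(object@hemisphere == "R")))
})

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@weights
  ne <- sum(w[upper.tri(w)] > 0)
  cat(sprintf("%s: %d nodes, %d edges, density %.3f\n", class(object),
              nrow(w), ne, ne / choose(nrow(w), 2)))
})

setMethod("show", "ConsensusBackbone", function(object) {
  callNextMethod()
  cat(sprintf("  consensus of %d subjects at prevalence >= %.2f\n",
              object@nSubjects, object@prevalence))
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@phenotypes$group)
  cat(sprintf("Cohort: %d subjects (%s), %d nodes, seed %d\n",
              nrow(object@phenotypes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nNodes(object@atlas), object@config@seed))
})

setMethod("show", "RichClubCurve", function(object) {
  ok <- !is.na(object@phiNorm)
  cat(sprintf("RichClubCurve: k in [%d, %d], %d nulls; phi_norm > 1 at %d/%d k\n",
              min(object@k), max(object@k), object@nNull,
              sum(object@phiNorm[ok] > 1), sum(ok)))
})

setMethod("show", "EdgeClassification", function(object) {
  cs <- object@classStrength
  cat(sprintf("EdgeClassification: %d rich nodes; strengths rich=%.4g feeder=%.4g local=%.4g\n",
              length(object@richNodes), cs["rich"], cs["feeder"], cs["local"]))
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("Permutation test: observed diff %.4g, %d permutations, p = %.4g%s\n",
              object@observed, object@nPerm, object@pRaw,
              if (is.na(object@pAdjusted)) "" else
                sprintf(" (%s-adjusted %.4g)", object@method, object@pAdjusted)))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman (partial on %s): rho = %.3f, p = %.4g, n = %d\n",
              if (length(object@covariates)) paste(object@covariates, collapse = ",")
              else "none", object@rho, object@p, object@n))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d nodes (%d hubs), groups %d/%d, ",
                     "density %.2f, deficit %.2f, seed %d\n"),
              object@nNodes, object@nHubs, object@nGroup1, object@nGroup2,
              object@density, object@groupDeficit, object@seed))
})
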