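#' @import methods
NULL

#' Number of nodes of an object
#' @param x an object with a node dimension.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Node labels of an object
#' @param x an object carrying an atlas.
#' @return character vector of region labels.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Node volumes of an atlas
#' @param x a \linkS4class{NodeAtlas}.
#' @return numeric vector of region volumes.
#' @export
setGeneric("nodeVolumes", function(x) standardGeneric("nodeVolumes"))

#' Edge-weight matrix of a network
#' @param x a \linkS4class{WeightedNetwork} or object containing one.
#' @return symmetric numeric matrix of weights.
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' Atlas attached to an object
#' @param x an object carrying a \linkS4class{NodeAtlas} (or NULL).
#' @return a \linkS4class{NodeAtlas} or NULL.
#' @export
setGeneric("atlas", function(x) standardGeneric("atlas"))

#' Phenotype table of a cohort
#' @param x a \linkS4class{Cohort}.
#' @return data.frame with one row per subject.
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' Raw connectomes of a cohort
#' @param x a \linkS4class{Cohort}.
#' @return named list of \linkS4class{RawConnectome} objects.
#' @export
setGeneric("connectomes", function(x) standardGeneric("connectomes"))
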