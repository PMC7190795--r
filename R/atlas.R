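## AAL-90 cortical/subcortical abbreviations (45 bilateral regions); used to
## label synthetic 90-node atlases so exports read like real parcellations.
.aal45 <- c(
  "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
  "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS", "ACG",
  "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING", "SOG", "MOG",
  "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG", "PCUN", "PCL", "CAU",
  "PUT", "PAL", "THA", "HES", "STG", "TPOsup", "MTG", "TPOmid", "ITG")

#' Construct a NodeAtlas
#'
#' @param label character vector of unique region labels.
#' @param hemisphere "L"/"R" per node.
#' @param coords N x 3 numeric matrix of centroids (mm).
#' @param volume strictly positive volumes per node.
#' @param name atlas identifier.
#' @return a \linkS4class{NodeAtlas}.
#' @export
nodeAtlas <- function(label, hemisphere, coords, volume, name = "atlas") {
  new("NodeAtlas", name = name, label = as.character(label),
      hemisphere = as.character(hemisphere),
      coords = as.matrix(coords), volume = as.numeric(volume))
}

#' Generate a synthetic parcellation atlas
#'
#' Creates a reproducible atlas of \code{nNodes} regions with unique labels,
#' hemispheres alternating L/R (so both hemispheres get
#' \code{floor(nNodes/2)} or \code{ceiling(nNodes/2)} nodes), mirrored
#' centroid coordinates, and lognormal regional volumes. For
#' \code{nNodes = 90} the labels are the AAL-90 abbreviations
#' (\code{<abbrev>.L} / \code{<abbrev>.R}); otherwise generic
#' \code{N###.L/R} labels are used.
#'
#' @param nNodes number of regions (>= 2).
#' @param seed integer seed; identical seeds give identical atlases.
#' @param volumeMeanlog,volumeSdlog lognormal volume parameters
#'   (defaults give a median regional volume of 1500 voxels).
#' @return a \linkS4class{NodeAtlas}.
#' @examples
#' a <- generateAtlas(90, seed = 1)
#' table(a@hemisphere)
#' @export
generateAtlas <- function(nNodes, seed, volumeMeanlog = log(1500),
                          volumeSdlog = 0.4) {
  stopIfNot(length(nNodes) == 1L && nNodes >= 2, "nNodes must be >= 2")
  nNodes <- as.integer(nNodes)
  hemi <- rep(c("L", "R"), length.out = nNodes)
  if (nNodes == 90L) {
    base <- rep(.aal45, each = 2L)
  } else {
    base <- rep(sprintf("N%03d", seq_len(ceiling(nNodes / 2))), each = 2L)[seq_len(nNodes)]
  }
  label <- paste(base, hemi, sep = ".")
  withSeed(seed, {
    ## mirrored centroids: left hemisphere x < 0, right x > 0
    xmag <- runif(nNodes, 5, 70)
    coords <- cbind(x = ifelse(hemi == "L", -xmag, xmag),
                    y = runif(nNodes, -100, 70),
                    z = runif(nNodes, -45, 80))
    volume <- stats::rlnorm(nNodes, volumeMeanlog, volumeSdlog)
  })
  nodeAtlas(label, hemi, coords, volume,
            name = sprintf("synth%d", nNodes))
}
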