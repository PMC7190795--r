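## Synthetic-cohort generator: plants rich-club organization (a hub block
## with enriched edge presence and streamline counts), a patient-group
## deficit on hub-attached connections, and clinical scores rank-coupled to
## connection-class strengths.

.scales <- c("PSQI", "ISI", "SAS", "SDS", "duration")

.defaultScoreMarginals <- function() {
  ## group-specific truncated-normal marginals of the clinical instruments
  data.frame(
    scale = rep(c("PSQI", "ISI", "SAS", "SDS"), each = 2L),
    group = rep(c("patient", "control"), 4L),
    mean  = c(16.32, 2.55, 20.72, 2.63, 47.66, 5.91, 52.40, 6.97),
    sd    = c(3.76, 2.47, 3.75, 2.65, 8.59, 10.87, 8.75, 11.97),
    stringsAsFactors = FALSE)
}

.defaultCouplings <- function() {
  data.frame(scale = c("ISI", "SDS"), class = c("rich", "rich"),
             rho = c(0.58, -0.31), stringsAsFactors = FALSE)
}

#' Build a SimulationConfig
#'
#' All arguments default to the emulated study conditions: a 90-node atlas
#' with a 32-node hub block, 43 patients vs 42 controls, a 30% patient
#' deficit on hub-attached streamline counts, and clinical couplings
#' ISI~rich-club +0.58 and SDS~rich-club -0.31 within each group.
#'
#' @param nNodes,nHubs,nGroup1,nGroup2 cohort dimensions
#'   (group1 = patients, group2 = controls).
#' @param density expected overall edge density.
#' @param densityHubGain presence-probability multipliers (hub-hub,
#'   hub-nonhub) relative to nonhub-nonhub edges.
#' @param presenceConcentration Beta concentration of the cohort-level
#'   per-edge presence propensities (small = anatomically consistent,
#'   U-shaped edge template shared by all subjects).
#' @param fnBase expected streamline count on a present local edge.
#' @param fnHubGain FN enrichment factor on hub-hub edges.
#' @param fnDispersion negative-binomial size parameter.
#' @param groupDeficit multiplicative patient-group factor on hub-attached
#'   expected FN.
#' @param faShape,faRange Beta shape parameters and support of the FA draw.
#' @param volumeMeanlog,volumeSdlog lognormal node-volume parameters.
#' @param durationMeanlog,durationSdlog lognormal patient illness-duration
#'   (months) parameters.
#' @param couplings data.frame(scale, class, rho) of target within-group
#'   Spearman couplings; \code{NULL} for the defaults above,
#'   \code{data.frame()} for none.
#' @param scoreMarginals data.frame(scale, group, mean, sd); \code{NULL}
#'   for defaults.
#' @param covariateModel list of covariate-generation parameters; see
#'   \linkS4class{SimulationConfig}.
#' @param seed master seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nNodes = 90, nHubs = 32, nGroup1 = 43,
                             nGroup2 = 42, density = 0.35,
                             densityHubGain = c(3, 2),
                             presenceConcentration = 1.0, fnBase = 8,
                             fnHubGain = 3, fnDispersion = 2,
                             groupDeficit = 0.7, faShape = c(4, 4),
                             faRange = c(0.2, 0.9),
                             volumeMeanlog = log(1500), volumeSdlog = 0.4,
                             durationMeanlog = log(24), durationSdlog = 0.6,
                             couplings = NULL, scoreMarginals = NULL,
                             covariateModel = list(), seed = 1) {
  cm <- utils::modifyList(
    list(ageMean = 40.4, ageSd = 10.4, ageRange = c(18, 60),
         eduMean = 7.8, eduSd = 4.0, pMale = 38 / 85,
         confound = FALSE, confoundShift = 8),
    covariateModel)
  new("SimulationConfig",
      nNodes = as.integer(nNodes), nHubs = as.integer(nHubs),
      nGroup1 = as.integer(nGroup1), nGroup2 = as.integer(nGroup2),
      density = density, densityHubGain = as.numeric(densityHubGain),
      presenceConcentration = presenceConcentration,
      fnBase = fnBase, fnHubGain = fnHubGain, fnDispersion = fnDispersion,
      groupDeficit = groupDeficit, faShape = as.numeric(faShape),
      faRange = as.numeric(faRange), volumeMeanlog = volumeMeanlog,
      volumeSdlog = volumeSdlog, durationMeanlog = durationMeanlog,
      durationSdlog = durationSdlog,
      couplings = if (is.null(couplings)) .defaultCouplings() else couplings,
      scoreMarginals = if (is.null(scoreMarginals)) .defaultScoreMarginals()
                       else scoreMarginals,
      covariateModel = cm, seed = as.integer(seed))
}

#' Planted hub node ids of a configuration
#' @param config a \linkS4class{SimulationConfig}.
#' @return integer vector of hub node ids (the first \code{nHubs} nodes).
#' @export
plantedHubs <- function(config) seq_len(config@nHubs)

## Per-block edge presence probabilities (hub-hub, hub-nonhub,
## nonhub-nonhub) solved so that the expected overall density is met.
presenceProbs <- function(config) {
  n <- config@nNodes; h <- config@nHubs
  ehh <- choose(h, 2); ehn <- h * (n - h); ell <- choose(n - h, 2)
  g <- config@densityHubGain
  pll <- config@density * choose(n, 2) / (ehh * g[1] + ehn * g[2] + ell)
  c(hh = g[1] * pll, hn = g[2] * pll, ll = pll)
}

#' Cohort-level per-edge presence propensities
#'
#' Deterministic in the config seed: one Beta(c p_block, c (1 - p_block))
#' draw per potential edge, shared by every subject of the cohort. This is
#' the anatomical edge template: with small concentration c the propensity
#' distribution is U-shaped, so an edge tends to be present in most
#' subjects or in few, which is what gives the group-consensus backbone
#' its cross-subject consistency. The mean propensity per block equals the
#' block presence probability, so the expected density is unchanged.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return numeric vector of propensities over upper-triangle edges.
#' @export
edgePropensities <- function(config) {
  p <- presenceProbs(config)[edgeBlocks(config)]
  cc <- config@presenceConcentration
  withSeed(childSeed(config@seed, 999983L),
           stats::rbeta(length(p), cc * p, cc * (1 - p)))
}

## Block label per upper-triangle edge: 1 = hub-hub, 2 = hub-nonhub,
## 3 = nonhub-nonhub
edgeBlocks <- function(config) {
  hubs <- plantedHubs(config)
  up <- upperPairs(config@nNodes)
  ih <- up[, 1] %in% hubs
  jh <- up[, 2] %in% hubs
  ifelse(ih & jh, 1L, ifelse(ih | jh, 2L, 3L))
}

## Expected FN per block for a given group (patients get the deficit on
## hub-attached blocks).
blockMeans <- function(config, group) {
  m <- c(config@fnBase * config@fnHubGain,
         config@fnBase * sqrt(config@fnHubGain),
         config@fnBase)
  if (group == "patient") m[1:2] <- m[1:2] * config@groupDeficit
  m
}

#' Generate one synthetic subject
#'
#' Draws a subject's raw connectome: edges are present with the cohort's
#' shared \code{\link{edgePropensities}} template (identical in both
#' groups and across subjects of a cohort), streamline counts on
#' present edges are 1 + NegBin(mu = m - 1) so the expected FN equals the
#' block mean m exactly, and FA is Beta-distributed on the configured range
#' with the same support as FN. For patients the expected FN of hub-hub and
#' hub-nonhub edges is multiplied by \code{groupDeficit}. Clinical scores
#' are drawn from the group marginals; cohort-level rank couplings are
#' imposed afterwards by \code{\link{generateCohort}}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param atlas the cohort's \linkS4class{NodeAtlas}
#'   (must have \code{config@nNodes} nodes).
#' @param group "patient" or "control".
#' @param seed integer seed.
#' @param subjectId subject identifier.
#' @return list with elements \code{record} (one-row phenotype data.frame)
#'   and \code{connectome} (a \linkS4class{RawConnectome}).
#' @export
generateSubject <- function(config, atlas, group = c("patient", "control"),
                            seed, subjectId = "S001") {
  group <- match.arg(group)
  stopIfNot(nNodes(atlas) == config@nNodes,
            "atlas node count must equal config@nNodes")
  n <- config@nNodes
  blocks <- edgeBlocks(config)
  p <- edgePropensities(config)
  mu <- blockMeans(config, group)[blocks]
  withSeed(seed, {
    present <- stats::rbinom(length(p), 1L, p) == 1L
    fnUp <- integer(length(p))
    if (any(present))
      fnUp[present] <- 1L + stats::rnbinom(sum(present),
                                           size = config@fnDispersion,
                                           mu = mu[present] - 1)
    faUp <- numeric(length(p))
    if (any(present))
      faUp[present] <- config@faRange[1] +
        diff(config@faRange) * stats::rbeta(sum(present), config@faShape[1],
                                            config@faShape[2])
    cm <- config@covariateModel
    age <- min(max(stats::rnorm(1, cm$ageMean +
                                  if (isTRUE(cm$confound) && group == "patient")
                                    cm$confoundShift else 0,
                                cm$ageSd), cm$ageRange[1]), cm$ageRange[2])
    sex <- if (stats::runif(1) < cm$pMale) "male" else "female"
    education <- max(stats::rnorm(1, cm$eduMean, cm$eduSd), 0)
    duration <- if (group == "patient")
      stats::rlnorm(1, config@durationMeanlog, config@durationSdlog) else 0
    scores <- vapply(c("PSQI", "ISI", "SAS", "SDS"), function(s)
      drawTruncScore(1, config, s, group), numeric(1))
  })
  fn <- matrix(0, n, n); fn[upper.tri(fn)] <- fnUp; fn <- fn + t(fn)
  fa <- matrix(0, n, n); fa[upper.tri(fa)] <- faUp; fa <- fa + t(fa)
  record <- data.frame(subjectId = subjectId, group = group,
                       age = round(age, 1), sex = sex,
                       education = round(education, 1),
                       duration = round(duration, 1),
                       PSQI = scores[["PSQI"]], ISI = scores[["ISI"]],
                       SAS = scores[["SAS"]], SDS = scores[["SDS"]],
                       stringsAsFactors = FALSE)
  conn <- new("RawConnectome", fn = fn, fa = fa,
              volumes = nodeVolumes(atlas), atlas = atlas)
  list(record = record, connectome = conn)
}

## Marginal machinery for scores: normal truncated at 0 (scores are
## non-negative), integer-rounded.
marginalFor <- function(config, scale, group) {
  sm <- config@scoreMarginals
  row <- sm[sm$scale == scale & sm$group == group, ]
  stopIfNot(nrow(row) == 1L,
            sprintf("no score marginal for %s/%s", scale, group))
  row
}

truncQuantile <- function(u, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

drawTruncScore <- function(n, config, scale, group) {
  row <- marginalFor(config, scale, group)
  round(truncQuantile(stats::runif(n), row$mean, row$sd))
}

## Impose the configured within-group rank couplings between clinical
## scales and connection-class strengths via a Gaussian copula: normal
## scores of the strength ranks are mixed with independent noise at the
## Pearson equivalent r = 2 sin(pi rho / 6) of the target Spearman rho,
## then mapped through the group's marginal.
applyCouplings <- function(config, phen, classStrengths, seed) {
  if (!nrow(config@couplings)) return(phen)
  withSeed(seed, {
    for (ci in seq_len(nrow(config@couplings))) {
      cp <- config@couplings[ci, ]
      rPearson <- 2 * sin(pi * cp$rho / 6)
      for (grp in unique(phen$group)) {
        idx <- which(phen$group == grp)
        ng <- length(idx)
        if (ng < 2L) next
        s <- classStrengths[idx, cp$class]
        zs <- stats::qnorm((rank(s, ties.method = "average") - 0.5) / ng)
        z <- rPearson * zs + sqrt(1 - rPearson^2) * stats::rnorm(ng)
        u <- stats::pnorm(z)
        if (cp$scale == "duration") {
          val <- if (grp == "patient")
            round(stats::qlnorm(u, config@durationMeanlog,
                                config@durationSdlog), 1) else 0
        } else {
          row <- marginalFor(config, cp$scale, grp)
          val <- round(truncQuantile(u, row$mean, row$sd))
        }
        phen[idx, cp$scale] <- val
      }
    }
  })
  phen
}

#' Generate a full synthetic cohort
#'
#' Generates the atlas, every subject's raw connectome and the phenotype
#' table, then imposes the configured clinical-score couplings on
#' subject-level connection-class strengths (computed against the planted
#' hub set on networks built at FN >= 1). Fully reproducible from
#' \code{config@seed}; writes nothing.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{Cohort}.
#' @examples
#' cfg <- simulationConfig(nNodes = 30, nHubs = 8, nGroup1 = 5, nGroup2 = 5)
#' generateCohort(cfg)
#' @export
generateCohort <- function(config) {
  validObject(config)
  atl <- generateAtlas(config@nNodes, seed = childSeed(config@seed, 0),
                       volumeMeanlog = config@volumeMeanlog,
                       volumeSdlog = config@volumeSdlog)
  groups <- rep(c("patient", "control"), c(config@nGroup1, config@nGroup2))
  ## stable ids: PI001.. for patients, HC001.. for controls, in cohort order
  ids <- character(length(groups))
  ids[groups == "patient"] <- sprintf("PI%03d", seq_len(config@nGroup1))
  ids[groups == "control"] <- sprintf("HC%03d", seq_len(config@nGroup2))
  subs <- lapply(seq_along(groups), function(i)
    generateSubject(config, atl, groups[i], seed = childSeed(config@seed, i),
                    subjectId = ids[i]))
  phen <- do.call(rbind, lapply(subs, `[[`, "record"))
  conns <- lapply(subs, `[[`, "connectome")
  names(conns) <- phen$subjectId
  ## class strengths against the planted hub set drive the couplings
  hubs <- plantedHubs(config)
  cs <- t(vapply(conns, function(rc) {
    net <- buildNetwork(rc, fnThreshold = 1)
    classifyEdges(net, hubs)@classStrength
  }, c(rich = 0, feeder = 0, local = 0)))
  phen <- applyCouplings(config, phen, cs,
                         seed = childSeed(config@seed, length(groups) + 1L))
  rownames(phen) <- NULL
  new("Cohort", atlas = atl, phenotypes = phen, connectomes = conns,
      config = config)
}
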