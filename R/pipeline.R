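## End-to-end orchestration: simulate -> build -> consensus -> metrics ->
## rich club -> group inference -> correlations -> report.

## Cheap content fingerprint for the provenance log (first bytes of the
## serialized object folded into 32 bits).
fingerprint <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2L)[-(1:14)])  # skip header
  acc <- 0
  for (i in seq_along(b)) acc <- (acc * 31 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(acc))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param sim a \linkS4class{SimulationConfig} describing the cohort (or
#'   NULL when \code{dataDir} points to an existing cohort on disk).
#' @param dataDir optional directory readable by \code{\link{readCohortDir}}.
#' @param fnThresholds streamline-count thresholds for the sensitivity
#'   grid (default 1, 2, 3, 5, 10).
#' @param prevalence consensus prevalence levels (default 0.50, 0.75, 0.90).
#' @param sparsityGrid grid for metric-versus-sparsity AUCs.
#' @param topN rich-node count for edge classification (default 32).
#' @param kDegree degree threshold variant reported alongside topN
#'   (default 7).
#' @param richSet "pooled" (one shared rich set from the all-subject
#'   backbone; the exchangeable default), "intersection", or "own"
#'   (descriptive; see \code{\link{compareClassStrengths}}).
#' @param nNull null networks for rich-club and small-world normalization.
#' @param nPerm label permutations per group test.
#' @param correction "holm" (FWE, default) or "BH" (FDR).
#' @param computeGlobal also run the per-subject global-metric AUC and
#'   small-world comparisons (the slowest stage).
#' @param seed master seed for every stochastic stage.
#' @return a validated list of class \code{richconnRunConfig}.
#' @export
runConfig <- function(sim = simulationConfig(), dataDir = NULL,
                      fnThresholds = c(1, 2, 3, 5, 10),
                      prevalence = c(0.50, 0.75, 0.90),
                      sparsityGrid = seq(0.10, 0.40, by = 0.01),
                      topN = 32, kDegree = 7,
                      richSet = c("pooled", "intersection", "own"),
                      nNull = 100, nPerm = 10000,
                      correction = c("holm", "BH"),
                      computeGlobal = TRUE, seed = 1) {
  richSet <- match.arg(richSet)
  correction <- match.arg(correction)
  stopIfNot(all(fnThresholds >= 1), "fnThresholds must all be >= 1")
  stopIfNot(all(prevalence > 0 & prevalence <= 1),
            "prevalence levels must lie in (0, 1]")
  stopIfNot(length(seed) == 1L && is.finite(seed), "a seed is required")
  if (!is.null(sim)) validObject(sim)
  structure(list(sim = sim, dataDir = dataDir,
                 fnThresholds = fnThresholds, prevalence = prevalence,
                 sparsityGrid = sparsityGrid, topN = as.integer(topN),
                 kDegree = as.integer(kDegree), richSet = richSet,
                 nNull = as.integer(nNull), nPerm = as.integer(nPerm),
                 correction = correction, computeGlobal = computeGlobal,
                 seed = as.integer(seed)),
            class = "richconnRunConfig")
}

adjustFamily <- function(p, method, alpha = 0.05) {
  if (method == "holm") holmBonferroni(p, alpha) else benjaminiHochberg(p, alpha)
}

#' Compare connection-class strengths between groups
#'
#' For one FN threshold and one prevalence level: builds each group's
#' consensus backbone, selects the top-N rich nodes per backbone, computes
#' per-subject rich/feeder/local strengths (each group against its own
#' rich set, or against the shared intersection), and runs the
#' covariate-removed permutation test per class with the chosen
#' multiple-comparison correction over the three classes.
#'
#' @param netsByGroup named list with elements \code{patient} and
#'   \code{control}, each a list of \linkS4class{WeightedNetwork}s.
#' @param covariates data.frame of per-subject covariates in
#'   (patient, control) row order.
#' @param prevalence consensus prevalence level.
#' @param topN rich-node count.
#' @param richSet "pooled" (default: one shared rich set from the
#'   all-subject consensus backbone — the only variant whose permutation
#'   test is exchangeable under the null), "intersection" (shared nodes of
#'   the two group sets), or "own" (each group against its own set;
#'   descriptive only, as group-specific set-selection noise inflates the
#'   test's type-I error).
#' @param nPerm,correction,seed inference settings.
#' @return list with the two backbones, rich sets, per-subject strengths
#'   and the test table.
#' @export
compareClassStrengths <- function(netsByGroup, covariates,
                                  prevalence = 0.75, topN = 32,
                                  richSet = c("pooled", "intersection", "own"),
                                  nPerm = 10000,
                                  correction = "holm", seed = 1) {
  richSet <- match.arg(richSet)
  bbP <- groupConsensus(netsByGroup$patient, prevalence)
  bbC <- groupConsensus(netsByGroup$control, prevalence)
  richP <- identifyRichNodes(bbP, topN = topN)
  richC <- identifyRichNodes(bbC, topN = topN)
  shared <- intersect(richP, richC)
  if (richSet == "pooled") {
    bbAll <- groupConsensus(c(netsByGroup$patient, netsByGroup$control),
                            prevalence)
    pooled <- identifyRichNodes(bbAll, topN = topN)
    setP <- pooled; setC <- pooled
  } else if (richSet == "intersection") {
    setP <- shared; setC <- shared
  } else {
    setP <- richP; setC <- richC
  }
  sP <- subjectClassStrengths(netsByGroup$patient, setP)
  sC <- subjectClassStrengths(netsByGroup$control, setC)
  tests <- lapply(c("rich", "feeder", "local"), function(cl)
    permutationGroupTest(sP[[cl]], sC[[cl]], covariates, nPerm,
                         seed = childSeed(seed, match(cl, c("rich", "feeder", "local")))))
  praw <- vapply(tests, slot, 1, "pRaw")
  adj <- adjustFamily(praw, correction)
  tab <- data.frame(class = c("rich", "feeder", "local"),
                    observed = vapply(tests, slot, 1, "observed"),
                    pRaw = praw, pAdjusted = adj$adjusted,
                    reject = adj$reject)
  list(backbonePatient = bbP, backboneControl = bbC,
       richPatient = richP, richControl = richC, sharedRich = shared,
       strengthsPatient = sP, strengthsControl = sC, tests = tab)
}

#' Demographics and clinical-characteristics table
#'
#' Group mean +/- SD (or male/female counts for sex) with a Mann-Whitney U
#' p-value per quantitative variable and a chi-square p for sex, in the
#' conventional row order: age, sex, education, PSQI, ISI, SAS, SDS.
#'
#' @param subjects phenotype data.frame with columns group, age, sex,
#'   education, PSQI, ISI, SAS, SDS.
#' @return data.frame with characteristic, patient, control, p, test.
#' @export
demographicsTable <- function(subjects) {
  stopIfNot(length(unique(subjects$group)) == 2L,
            "two groups are required")
  pat <- subjects[subjects$group == "patient", ]
  ctl <- subjects[subjects$group == "control", ]
  fmt <- function(v) sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
  quant <- c("age", "education", "PSQI", "ISI", "SAS", "SDS")
  rows <- list()
  for (v in quant) {
    mw <- mannWhitneyU(pat[[v]], ctl[[v]])
    rows[[v]] <- data.frame(characteristic = v, patient = fmt(pat[[v]]),
                            control = fmt(ctl[[v]]), p = mw$p,
                            test = "Mann-Whitney U",
                            stringsAsFactors = FALSE)
  }
  sexTab <- rbind(c(sum(pat$sex == "male"), sum(pat$sex == "female")),
                  c(sum(ctl$sex == "male"), sum(ctl$sex == "female")))
  chis <- chiSquare2x2(sexTab)
  sexRow <- data.frame(characteristic = "sex (male/female)",
                       patient = sprintf("%d/%d", sexTab[1, 1], sexTab[1, 2]),
                       control = sprintf("%d/%d", sexTab[2, 1], sexTab[2, 2]),
                       p = chis$p, test = "chi-square",
                       stringsAsFactors = FALSE)
  out <- rbind(rows$age, sexRow, rows$education, rows$PSQI, rows$ISI,
               rows$SAS, rows$SDS)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, builds per-subject weighted networks at
#' every FN threshold, computes group-consensus backbones at every
#' prevalence level, compares rich/feeder/local connection strengths
#' between groups with covariate-removed permutation tests at every
#' (threshold x prevalence) combination, computes normalized rich-club
#' curves for both group backbones, optionally compares per-subject
#' global-metric sparsity-AUCs and small-world indices, and correlates the
#' patient-group clinical scores with connection-class strengths
#' (covariates removed). All randomness derives from \code{config$seed}.
#'
#' @param config a \code{\link{runConfig}} list.
#' @param outDir optional output directory; when given, report.json, CSV
#'   tables and BrainNet Viewer node/edge exports are written there.
#'   On any stage failure, partially written outputs are removed.
#' @param verbose log one line per stage with input fingerprints.
#' @return the report list (invisibly identical to report.json).
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
  stopIfNot(inherits(config, "richconnRunConfig"),
            "config must come from runConfig()")
  createdOut <- FALSE
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
    createdOut <- TRUE
  }
  log1 <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (createdOut) unlink(outDir, recursive = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(config$dataDir)) {
      cd <- readCohortDir(config$dataDir)
      new("Cohort", atlas = cd$atlas, phenotypes = cd$phenotypes,
          connectomes = cd$connectomes,
          config = if (is.null(config$sim)) simulationConfig() else config$sim)
    } else generateCohort(config$sim)
  })
  log1("simulate", "cohort ", fingerprint(phenotypes(cohort)))

  phen <- phenotypes(cohort)
  isPat <- phen$group == "patient"
  ord <- c(which(isPat), which(!isPat))
  covariates <- data.frame(age = phen$age,
                           sex = ifelse(phen$sex == "male", 1, 0),
                           education = phen$education)[ord, ]

  demo <- stage("demographics", demographicsTable(phen))

  richBlocks <- list()
  primary <- NULL
  for (fi in seq_along(config$fnThresholds)) {
    fn <- config$fnThresholds[fi]
    nets <- stage("build", lapply(connectomes(cohort), buildNetwork,
                                  fnThreshold = fn))
    byGroup <- list(patient = nets[isPat], control = nets[!isPat])
    for (pi in seq_along(config$prevalence)) {
      prev <- config$prevalence[pi]
      blockSeed <- childSeed(config$seed, 1000L + 10L * fi + pi)
      blk <- stage("richclub", compareClassStrengths(
        byGroup, covariates, prevalence = prev, topN = config$topN,
        richSet = config$richSet, nPerm = config$nPerm,
        correction = config$correction, seed = blockSeed))
      log1("richclub", sprintf("fn>=%g prev=%.2f shared=%d", fn, prev,
                               length(blk$sharedRich)))
      key <- sprintf("fn%g_prev%g", fn, prev)
      richBlocks[[key]] <- c(list(fnThreshold = fn, prevalence = prev), blk)
      if (is.null(primary) ||
          (fn == config$fnThresholds[1] && abs(prev - 0.75) < 1e-9))
        primary <- richBlocks[[key]]
    }
  }

  curves <- stage("richclub-curves", list(
    patient = normalizedRichClub(primary$backbonePatient,
                                 nNull = config$nNull,
                                 seed = childSeed(config$seed, 2001L)),
    control = normalizedRichClub(primary$backboneControl,
                                 nNull = config$nNull,
                                 seed = childSeed(config$seed, 2002L))))

  globalCmp <- NULL
  if (isTRUE(config$computeGlobal)) {
    globalCmp <- stage("global-metrics", {
      nets <- lapply(connectomes(cohort), buildNetwork,
                     fnThreshold = config$fnThresholds[1])
      aucs <- lapply(.metricNames, function(m)
        vapply(nets, function(x) sparsityAUC(x, m, config$sparsityGrid)@auc, 1))
      names(aucs) <- paste0(.metricNames, "_auc")
      sw <- lapply(seq_along(nets), function(i)
        smallWorldIndices(nets[[i]], nNull = config$nNull,
                          seed = childSeed(config$seed, 3000L + i)))
      vals <- c(aucs, list(gamma = vapply(sw, `[[`, 1, "gamma"),
                           lambda = vapply(sw, `[[`, 1, "lambda"),
                           sigma = vapply(sw, `[[`, 1, "sigma")))
      tests <- lapply(seq_along(vals), function(vi)
        permutationGroupTest(vals[[vi]][isPat], vals[[vi]][!isPat],
                             covariates, config$nPerm,
                             seed = childSeed(config$seed, 4000L + vi)))
      praw <- vapply(tests, slot, 1, "pRaw")
      adj <- adjustFamily(praw, config$correction)
      data.frame(metric = names(vals),
                 meanPatient = vapply(vals, function(v) mean(v[isPat]), 1),
                 meanControl = vapply(vals, function(v) mean(v[!isPat]), 1),
                 observed = vapply(tests, slot, 1, "observed"),
                 pRaw = praw, pAdjusted = adj$adjusted, reject = adj$reject,
                 row.names = NULL)
    })
  }

  correlations <- stage("correlate", {
    pat <- phen[isPat, ]
    covP <- data.frame(age = pat$age, sex = ifelse(pat$sex == "male", 1, 0),
                       education = pat$education)
    sP <- primary$strengthsPatient
    rows <- list()
    for (scale in c("PSQI", "ISI", "SAS", "SDS", "duration"))
      for (cl in c("rich", "feeder", "local")) {
        cr <- spearmanPartial(pat[[scale]], sP[[cl]], covP)
        rows[[length(rows) + 1L]] <- data.frame(
          scale = scale, class = cl, rho = cr@rho, p = cr@p, n = cr@n)
      }
    do.call(rbind, rows)
  })

  report <- list(
    provenance = list(package = "richconn",
                      version = as.character(utils::packageVersion("richconn")),
                      rVersion = paste(R.version$major, R.version$minor, sep = "."),
                      seed = config$seed,
                      configHash = fingerprint(config)),
    nSubjects = nrow(phen),
    demographics = demo,
    richClub = lapply(richBlocks, function(b) list(
      fnThreshold = b$fnThreshold, prevalence = b$prevalence,
      richPatient = b$richPatient, richControl = b$richControl,
      nSharedRich = length(b$sharedRich), tests = b$tests)),
    richClubCurves = lapply(curves, as.data.frame),
    globalMetrics = globalCmp,
    correlations = correlations)

  if (!is.null(outDir)) {
    stage("report", {
      json <- jsonlite::toJSON(report, dataframe = "columns", digits = 10,
                               auto_unbox = TRUE, na = "null")
      writeLines(json, file.path(outDir, "report.json"))
      utils::write.csv(demo, file.path(outDir, "demographics.csv"),
                       row.names = FALSE)
      utils::write.csv(correlations, file.path(outDir, "correlations.csv"),
                       row.names = FALSE)
      if (!is.null(globalCmp))
        utils::write.csv(globalCmp, file.path(outDir, "global_metrics.csv"),
                         row.names = FALSE)
      allTests <- do.call(rbind, lapply(names(richBlocks), function(k)
        cbind(block = k, richBlocks[[k]]$tests)))
      utils::write.csv(allTests, file.path(outDir, "richclub_tests.csv"),
                       row.names = FALSE)
      if (!is.null(atlas(primary$backbonePatient))) {
        exportBrainNet(primary$backbonePatient, primary$richPatient,
                       file.path(outDir, "backbone_patient"))
        exportBrainNet(primary$backboneControl, primary$richControl,
                       file.path(outDir, "backbone_control"))
      }
    })
  }
  invisible(report)
}
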