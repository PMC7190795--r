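test_that("generated atlases have the promised structure and determinism", {
  a <- generateAtlas(90, seed = 1)
  expect_s4_class(a, "NodeAtlas")
  expect_equal(nNodes(a), 90)
  expect_equal(as.vector(table(a@hemisphere)[c("L", "R")]), c(45L, 45L))
  expect_false(anyDuplicated(nodeLabels(a)) > 0)
  expect_true(all(nodeVolumes(a) > 0))
  # left-hemisphere centroids sit at negative x, right at positive
  expect_true(all(a@coords[a@hemisphere == "L", 1] < 0))
  expect_true(all(a@coords[a@hemisphere == "R", 1] > 0))

  expect_identical(generateAtlas(90, seed = 1), a)
  expect_false(identical(generateAtlas(90, seed = 2)@volume, a@volume))

  tiny <- generateAtlas(2, seed = 7)
  expect_equal(nNodes(tiny), 2)
  expect_false(tiny@label[1] == tiny@label[2])

  expect_error(generateAtlas(1, seed = 1), "nNodes")
})

test_that("subject connectomes satisfy the structural invariants", {
  cfg <- testConfig()
  atl <- generateAtlas(cfg@nNodes, seed = childSeed(cfg@seed, 0))
  for (s in 1:5) {
    sub <- generateSubject(cfg, atl, "patient", seed = s)
    fn <- sub$connectome@fn
    fa <- sub$connectome@fa
    expect_identical(fn, t(fn))
    expect_true(all(diag(fn) == 0))
    expect_true(all(fn >= 0 & fn == round(fn)))
    expect_identical((fa > 0), (fn > 0))           # FA support == FN support
    on <- fa[fn > 0]
    expect_true(all(on > cfg@faRange[1] & on < cfg@faRange[2]))
    rec <- sub$record
    expect_true(all(unlist(rec[c("PSQI", "ISI", "SAS", "SDS")]) >= 0))
    expect_true(rec$group %in% c("patient", "control"))
  }
  badAtlas <- generateAtlas(10, seed = 1)
  expect_error(generateSubject(cfg, badAtlas, "patient", seed = 1), "atlas")
})

test_that("the planted group deficit scales hub-attached streamline counts", {
  # Monte-Carlo check of the generator's own expectation: patient hub-hub
  # FN means should be groupDeficit times the control mean.
  cfg <- simulationConfig(nNodes = 40, nHubs = 12, nGroup1 = 2, nGroup2 = 2,
                          groupDeficit = 0.7)
  atl <- generateAtlas(cfg@nNodes, seed = childSeed(cfg@seed, 0))
  hubIdx <- plantedHubs(cfg)
  hubhubMean <- function(group, seeds) {
    vals <- unlist(lapply(seeds, function(s) {
      fn <- generateSubject(cfg, atl, group, seed = s)$connectome@fn
      hh <- fn[hubIdx, hubIdx]
      hh[upper.tri(hh) & hh > 0]
    }))
    mean(vals)
  }
  mPat <- hubhubMean("patient", 1:200)
  mCtl <- hubhubMean("control", 201:400)
  expect_lt(abs(mPat / mCtl - 0.7), 0.05)

  cfg1 <- simulationConfig(nNodes = 40, nHubs = 12, nGroup1 = 2, nGroup2 = 2,
                           groupDeficit = 1.0)
  atl1 <- generateAtlas(cfg1@nNodes, seed = childSeed(cfg1@seed, 0))
  hubhubMean1 <- function(group, seeds) {
    vals <- unlist(lapply(seeds, function(s) {
      fn <- generateSubject(cfg1, atl1, group, seed = s)$connectome@fn
      hh <- fn[hubIdx, hubIdx]
      hh[upper.tri(hh) & hh > 0]
    }))
    mean(vals)
  }
  expect_lt(abs(hubhubMean1("patient", 1:150) /
                hubhubMean1("control", 151:300) - 1), 0.05)
})

test_that("cohorts have the configured size, grouping and determinism", {
  cfg <- testConfig(seed = 11)
  co <- generateCohort(cfg)
  phe <- phenotypes(co)
  expect_equal(nrow(phe), 12)
  expect_equal(sum(phe$group == "patient"), 6)
  expect_equal(sum(phe$group == "control"), 6)
  expect_identical(names(connectomes(co)), phe$subjectId)

  co2 <- generateCohort(cfg)
  expect_identical(phenotypes(co2), phe)
  expect_identical(connectomes(co2)[[3]]@fn, connectomes(co)[[3]]@fn)

  expect_error(generateCohort(testConfig(nGroup1 = 0)), "group")

  # default configuration reproduces the 43 + 42 study layout
  defCfg <- simulationConfig()
  expect_equal(defCfg@nGroup1 + defCfg@nGroup2, 85L)
})

test_that("serialized cohorts round-trip and are byte-identical per seed", {
  cfg <- testConfig(seed = 3)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  writeCohort(generateCohort(cfg), d1)
  writeCohort(generateCohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- readCohortDir(d1)
  expect_equal(back$phenotypes$subjectId, phenotypes(generateCohort(cfg))$subjectId)
  expect_equal(back$connectomes[[1]]@fn, connectomes(generateCohort(cfg))[[1]]@fn)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("clinical-score couplings are recovered at the configured strength", {
  cfg <- simulationConfig(
    nNodes = 40, nHubs = 12, nGroup1 = 200, nGroup2 = 2,
    couplings = data.frame(scale = "ISI", class = "rich", rho = 0.6),
    seed = 21)
  co <- generateCohort(cfg)
  phe <- phenotypes(co)
  pat <- phe$group == "patient"
  nets <- lapply(connectomes(co)[pat], buildNetwork)
  s <- subjectClassStrengths(nets, plantedHubs(cfg))
  rho <- cor(phe$ISI[pat], s$rich, method = "spearman")
  expect_lt(abs(rho - 0.6), 0.1)
})

test_that("planted hubs dominate the expected-degree ranking", {
  # expected degree estimated by the cohort-mean binary degree; the top
  # 32 nodes must coincide with the planted hub block in >= 95% of
  # cohort draws at the default (90-node, 32-hub) conditions
  hits <- vapply(1:15, function(s) {
    cfg <- simulationConfig(seed = 500 + s)
    co <- generateCohort(cfg)
    degs <- vapply(connectomes(co),
                   function(rc) binaryDegree(buildNetwork(rc)),
                   integer(cfg@nNodes))
    md <- rowMeans(degs)
    top <- order(-md, seq_along(md))[seq_len(cfg@nHubs)]
    setequal(top, plantedHubs(cfg))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
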