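test_that("binary degree counts nonzero connections regardless of weight", {
  star <- edgesToMatrix(5, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1)))
  expect_equal(binaryDegree(net(star)), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(binaryDegree(net(symMatrix(4))), rep(0L, 4))
  w <- edgesToMatrix(3, list(c(1, 2, 0.1), c(1, 3, 9)))
  expect_equal(binaryDegree(net(w))[1], 2L)
})

test_that("the weighted rich-club coefficient matches hand enumeration", {
  # complete uniform K6: every club's edges are the top-ranked weights
  k6 <- symMatrix(6, 2); diag(k6) <- 0
  for (k in 0:4) expect_equal(richClubCoefficient(net(k6), k), 1)

  # 4-node hand example: S = {b, d}... degrees a=2, b=3, c=3, d=2;
  # k=2 club = {b, c}, club weight 2, top-1 network weight 5 -> 0.4
  w <- edgesToMatrix(4, list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 2),
                             c(3, 4, 1), c(2, 4, 5)))
  expect_equal(richClubCoefficient(net(w), 2), 0.4)

  # star: only the center exceeds k=1, no club edges -> undefined
  star <- edgesToMatrix(5, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1)))
  expect_true(is.na(richClubCoefficient(net(star), 1)))

  expect_error(richClubCoefficient(net(w), -1), "k must")
})

test_that("phi agrees with the subgraph + full-sort oracle on random graphs", {
  for (s in 1:30) {
    n <- sample(4:10, 1)
    w <- randomWeightedGraph(n, runif(1, 0.3, 0.9), seed = 2000 + s)
    kmax <- max(binaryDegree(net(w)))
    for (k in 0:max(0, kmax - 1)) {
      expect_equal(richClubCoefficient(net(w), k), oraclePhi(w, k),
                   tolerance = 1e-12, info = sprintf("seed %d k %d", s, k))
    }
    # phi <= 1 wherever defined
    phis <- vapply(0:max(1, kmax), function(k)
      richClubCoefficient(net(w), k), 1)
    expect_true(all(phis <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("weight transfers move phi in the expected direction", {
  w <- randomWeightedGraph(12, 0.5, seed = 77)
  k <- 5
  deg <- binaryDegree(net(w))
  S <- which(deg > k)
  club <- outer(seq_len(12) %in% S, seq_len(12) %in% S, `&`) & w > 0
  clubUp <- which(club & upper.tri(w), arr.ind = TRUE)
  expect_gt(nrow(clubUp), 0)
  phi0 <- richClubCoefficient(net(w), k)
  # draining weight from a club edge (keeping it present) lowers phi
  e <- clubUp[1, ]
  w1 <- w
  w1[e[1], e[2]] <- w1[e[2], e[1]] <- w[e[1], e[2]] * 0.1
  expect_lt(richClubCoefficient(net(w1), k), phi0)
  # shrinking a weak non-club edge that sits outside the top-E ranks
  # leaves phi unchanged
  outUp <- which(!club & upper.tri(w) & w > 0, arr.ind = TRUE)
  wts <- w[outUp]
  weakest <- outUp[which.min(wts), ]
  w2 <- w
  w2[weakest[1], weakest[2]] <- w2[weakest[2], weakest[1]] <-
    min(wts) * 0.5
  expect_equal(richClubCoefficient(net(w2), k), phi0)
})

test_that("normalized rich-club curves carry sane null summaries", {
  # degenerate ensemble: one null equals that draw exactly
  w <- randomWeightedGraph(12, 0.5, seed = 55)
  crv1 <- normalizedRichClub(net(w), kGrid = 2:6, nNull = 1, seed = 4)
  oneNull <- rewireNull(net(w), seed = childSeed(4, 1))
  for (i in seq_along(crv1@k)) {
    expect_equal(crv1@phiNullMean[i],
                 richClubCoefficient(oneNull, crv1@k[i]))
  }

  # self-normalization: a null draw against its own ensemble gives ~1
  x <- rewireNull(net(w), seed = 9)
  crv <- normalizedRichClub(x, kGrid = 2:6, nNull = 40, seed = 6)
  ok <- !is.na(crv@phiNorm) & crv@phiNullSd > 0
  expect_true(all(abs(crv@phi[ok] - crv@phiNullMean[ok]) <=
                    3 * crv@phiNullSd[ok]))

  # planted-hub backbone shows rich-club organization over a k interval
  cfg <- testConfig(seed = 41)
  co <- generateCohort(cfg)
  ctl <- phenotypes(co)$group == "control"
  bb <- groupConsensus(lapply(connectomes(co)[ctl], buildNetwork), 0.75)
  crvB <- normalizedRichClub(bb, nNull = 30, seed = 7)
  above <- which(!is.na(crvB@phiNorm) & crvB@phiNorm > 1)
  runs <- rle(diff(above) == 1)
  expect_gte(max(c(0, runs$lengths[runs$values])) + 1, 3)
})

test_that("rich-node identification follows degree with deterministic ties", {
  # degrees [5,4,4,2,1]-like pattern, tie on degree broken by strength
  w <- edgesToMatrix(6, list(
    c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1), c(1, 6, 1),  # deg(1)=5
    c(2, 3, 5), c(2, 4, 1), c(2, 6, 1),                          # deg(2)=4
    c(3, 4, 1), c(3, 5, 1)))                                     # deg(3)=4
  deg <- binaryDegree(net(w))
  expect_equal(deg[1:3], c(5L, 4L, 4L))
  expect_equal(identifyRichNodes(net(w), topN = 3), c(1L, 2L, 3L))
  # node 2 outranks node 3 on strength at equal degree
  expect_equal(identifyRichNodes(net(w), topN = 2), c(1L, 2L))

  # degrees [9,8,2,1] with k = 7 -> exactly the two high-degree nodes
  hub <- symMatrix(10)
  hub[1, 2:10] <- hub[2:10, 1] <- 1          # deg(1) = 9
  hub[2, 3:9] <- hub[3:9, 2] <- 1            # deg(2) = 8
  expect_equal(identifyRichNodes(net(hub), k = 7), c(1L, 2L))

  expect_equal(length(identifyRichNodes(net(hub), k = max(binaryDegree(net(hub))))), 0)
  expect_error(identifyRichNodes(net(hub)), "exactly one")
  expect_error(identifyRichNodes(net(hub), k = 2, topN = 3), "exactly one")
})

test_that("edge classification partitions strength into the three classes", {
  w <- edgesToMatrix(4, list(c(1, 2, 3), c(1, 3, 2), c(3, 4, 1)))
  ec <- classifyEdges(net(w), c(1L, 2L))
  expect_equal(unname(ec@classStrength),
               c(3, 2, 1))                     # rich, feeder, local
  expect_equal(unname(ec@ratios), c(1.5, 3))

  ecAll <- classifyEdges(net(w), 1:4)
  expect_equal(unname(ecAll@classStrength["rich"]), 6)
  expect_equal(unname(ecAll@classStrength["feeder"]), 0)
  expect_true(is.na(ecAll@ratios["richFeeder"]))

  ecNone <- classifyEdges(net(w), integer(0))
  expect_equal(unname(ecNone@classStrength["local"]), 6)

  expect_error(classifyEdges(net(w), c(1L, 9L)), "node ids")

  # partition conservation on random graphs and random rich sets
  for (s in 1:10) {
    wr <- randomWeightedGraph(9, 0.6, seed = 300 + s)
    rich <- sample(9, sample(0:9, 1))
    ec <- classifyEdges(net(wr), rich)
    expect_equal(sum(ec@classStrength), sum(wr) / 2, tolerance = 1e-12)
  }
})

test_that("subject class strengths use one rich set across a cohort", {
  w <- randomWeightedGraph(8, 0.6, seed = 12)
  nets <- list(a = net(w), b = net(w), c = net(w))
  s <- subjectClassStrengths(nets, c(1L, 2L, 3L))
  expect_equal(nrow(s), 3)
  expect_true(all(apply(s, 2, stats::sd) == 0))  # identical subjects
  # strengths sum to each subject's total strength
  expect_equal(unname(rowSums(s)), rep(sum(w) / 2, 3), tolerance = 1e-12)

  cfg <- testConfig(seed = 13, groupDeficit = 0.7)
  co <- generateCohort(cfg)
  isPat <- phenotypes(co)$group == "patient"
  nets2 <- lapply(connectomes(co), buildNetwork)
  ss <- subjectClassStrengths(nets2, plantedHubs(cfg))
  expect_lt(mean(ss$rich[isPat]), mean(ss$rich[!isPat]))
})

test_that("BrainNet Viewer exports have the documented column layout", {
  cfg <- testConfig(seed = 17)
  co <- generateCohort(cfg)
  bb <- groupConsensus(lapply(connectomes(co), buildNetwork), 0.75)
  rich <- identifyRichNodes(bb, topN = 5)
  pre <- file.path(tempdir(), "bnv")
  files <- exportBrainNet(bb, rich, pre)
  nodeTab <- read.table(files["node"])
  expect_equal(ncol(nodeTab), 6)
  expect_true(all(nodeTab[[4]] %in% c(1, 2)))
  expect_equal(which(nodeTab[[4]] == 1), rich)
  expect_equal(nodeTab[[5]], unname(colSums(edgeWeights(bb))))
  edgeTab <- as.matrix(read.table(files["edge"]))
  expect_equal(unname(edgeTab), edgeWeights(bb))
  unlink(files)
})
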