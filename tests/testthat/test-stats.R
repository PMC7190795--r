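test_that("residualization removes covariate effects exactly", {
  set.seed(1)
  n <- 50
  covs <- data.frame(age = runif(n, 20, 60),
                     sex = rbinom(n, 1, 0.5),
                     education = runif(n, 0, 16))
  # values exactly linear in age leave no residual
  y <- 3 + 0.5 * covs$age
  expect_equal(residualize(y, covs["age"]), rep(0, n), tolerance = 1e-10)

  # covariates orthogonal to the values: residuals are the centered values
  x <- rep(c(-1, 1), 25)
  orth <- data.frame(z = rep(c(1, 1, -1, -1), length.out = n))
  expect_equal(residualize(x, orth), x - mean(x), tolerance = 1e-10)

  # random case against the normal-equations oracle
  y2 <- rnorm(n)
  X <- model.matrix(~ ., data = covs)
  expect_equal(residualize(y2, covs), oracleResiduals(y2, X),
               tolerance = 1e-10)
  expect_equal(sum(residualize(y2, covs)), 0, tolerance = 1e-8)

  # rank-deficient designs are rejected
  covs$age2 <- covs$age * 2
  expect_error(residualize(y2, covs), "rank deficient")
  expect_error(residualize(c(y2, NA), NULL), "missing")
})

test_that("permutation group test calibrates against hand-derived cases", {
  set.seed(2)
  # identical samples: observed difference 0, p at the top of its range
  g <- rnorm(12)
  r0 <- permutationGroupTest(g, g, nPerm = 500, seed = 3)
  expect_equal(r0@observed, 0, tolerance = 1e-12)
  expect_gt(r0@pRaw, 0.95)

  # full separation with nPerm = 999: add-one estimator gives 1/1000
  g1 <- rnorm(10, 100, 0.1); g2 <- rnorm(10, 0, 0.1)
  r1 <- permutationGroupTest(g1, g2, nPerm = 999, seed = 4)
  expect_equal(r1@pRaw, 0.001)
  expect_gt(r1@observed, 99)

  # invariance under monotone affine rescaling of the pooled values
  a <- 3.7; b <- -12
  r2 <- permutationGroupTest(a * g1 + b, a * g2 + b, nPerm = 999, seed = 4)
  expect_equal(r2@pRaw, r1@pRaw)

  # covariate removal recovers the truth under confounding:
  # group difference fully explained by age
  n <- 40
  age <- c(runif(n, 40, 60), runif(n, 20, 40))
  y <- 0.1 * age + rnorm(2 * n, sd = 0.01)
  covs <- data.frame(age = age)
  radj <- permutationGroupTest(y[1:n], y[(n + 1):(2 * n)], covs,
                               nPerm = 499, seed = 5)
  expect_gt(radj@pRaw, 0.05)

  expect_error(permutationGroupTest(numeric(0), g), "non-empty")
})

test_that("permutation test attains nominal type-I error on null data", {
  set.seed(6)
  rej <- vapply(1:200, function(i) {
    x <- rnorm(15); y <- rnorm(15)
    permutationGroupTest(x, y, nPerm = 199, seed = i)@pRaw <= 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("Holm and Benjamini-Hochberg adjustments match hand calculations", {
  h <- holmBonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_equal(h$adjusted, c(0.003, 0.04, 0.04), tolerance = 1e-12)
  expect_true(all(h$reject))

  expect_equal(holmBonferroni(0.031)$adjusted, 0.031)
  h2 <- holmBonferroni(c(0.5, 0.6))
  expect_equal(h2$adjusted, c(1.0, 1.0))
  expect_false(any(h2$reject))

  b <- benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(b$adjusted, rep(0.04, 4), tolerance = 1e-12)
  expect_equal(benjaminiHochberg(rep(1, 3))$adjusted, rep(1, 3))
  expect_equal(benjaminiHochberg(0.02)$adjusted, 0.02)

  # adjusted >= raw and order-monotone for both procedures
  set.seed(7)
  p <- runif(8)
  for (f in list(holmBonferroni, benjaminiHochberg)) {
    adj <- f(p)$adjusted
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holmBonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney U handles exact and approximate branches", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)           # 2 / choose(6, 3)
  expect_true(r$exact)

  r1 <- mannWhitneyU(1, 2)
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 1.0)          # both orderings equally extreme

  # exact p agrees with complete enumeration of group assignments
  enumP <- function(x, y) {
    pooled <- c(x, y)
    n <- length(x)
    combos <- combn(length(pooled), n)
    uOf <- function(idx) {
      rk <- rank(pooled)
      sum(rk[idx]) - n * (n + 1) / 2
    }
    uObs <- uOf(seq_len(n))
    us <- apply(combos, 2, uOf)
    mu <- length(x) * length(y) / 2
    mean(abs(us - mu) >= abs(uObs - mu))
  }
  set.seed(8)
  for (i in 1:5) {
    x <- round(rnorm(5), 6); y <- round(rnorm(4) + 0.5, 6)
    expect_equal(mannWhitneyU(x, y)$p, enumP(x, y), tolerance = 1e-12,
                 info = paste("rep", i))
  }

  # ties force the approximate branch
  rt <- mannWhitneyU(c(1, 1, 2), c(1, 2, 3))
  expect_false(rt$exact)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("chi-square on 2x2 tables matches the closed form", {
  expect_equal(chiSquare2x2(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chiSquare2x2(rbind(c(10, 10), c(10, 10)))$p, 1)

  t2 <- rbind(c(20, 0), c(0, 20))
  r2 <- chiSquare2x2(t2)
  expect_equal(r2$statistic, 40, tolerance = 1e-12)
  expect_lt(r2$p, 1e-9)

  closedForm <- function(t) {
    N <- sum(t)
    N * (t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1])^2 /
      (sum(t[1, ]) * sum(t[2, ]) * sum(t[, 1]) * sum(t[, 2]))
  }
  t3 <- rbind(c(21, 22), c(17, 25))   # study-sized sex table
  expect_equal(chiSquare2x2(t3)$statistic, closedForm(t3), tolerance = 1e-12)
  # the continuity-corrected variant differs and is available by flag
  expect_gt(chiSquare2x2(t3, correct = TRUE)$p, chiSquare2x2(t3)$p)

  expect_error(chiSquare2x2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("partial Spearman correlation recovers monotone couplings", {
  x <- 1:20
  y <- x^3                                   # strictly monotone
  r <- spearmanPartial(x, y)
  expect_equal(r@rho, 1)
  expect_equal(r@p, 0)

  set.seed(9)
  rhos <- vapply(1:50, function(i) {
    spearmanPartial(rnorm(200), rnorm(200))@rho
  }, 1)
  expect_gte(mean(abs(rhos) < 0.15), 0.9)   # ~2 SE band at n = 200
  expect_lt(abs(mean(rhos)), 0.03)

  # covariate removal: correlation induced purely by age disappears
  n <- 60
  age <- runif(n, 20, 60)
  x2 <- age + rnorm(n, sd = 1)
  y2 <- 2 * age + rnorm(n, sd = 1)
  raw <- spearmanPartial(x2, y2)
  prt <- spearmanPartial(x2, y2, data.frame(age = age))
  expect_gt(raw@rho, 0.9)
  expect_lt(abs(prt@rho), 0.35)

  cst <- spearmanPartial(rep(1, 10), rnorm(10))
  expect_true(is.na(cst@rho))
  expect_error(spearmanPartial(1:3, 1:3), "n >= 4")
})
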