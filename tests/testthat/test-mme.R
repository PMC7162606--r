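test_that("single-trait MME equals the dense GLS oracle", {
  ped <- toyPed()
  A <- relValues(buildA(ped))
  Ainv <- buildAinv(ped)
  ## records on animals 2..5 only; animal 1 predicted via relationships
  set.seed(4)
  dat <- data.frame(id = 2:5, y = c(1.2, -0.4, 0.7, 2.1),
                    sex = factor(c(1, 2, 1, 2)))
  s2u <- 0.4; s2e <- 0.6
  sol <- solveSingleTrait(dat, Ainv, list(sigma2u = s2u, sigma2e = s2e),
                          fixed = ~sex)
  X <- model.matrix(~sex, dat)
  Z <- matrix(0, 4, 5); Z[cbind(1:4, 2:5)] <- 1
  ref <- glsSingleTrait(dat$y, X, Z, A, s2u, s2e)
  expect_equal(unname(sol@gebv[, 1]), ref$u, tolerance = 1e-7)
  expect_equal(unname(sol@fixed), ref$b, tolerance = 1e-7)
  expect_lt(sol@residualNorm, 1e-8)
})

test_that("shrinkage limits behave correctly", {
  ped <- data.frame(id = 1, sire = 0, dam = 0)
  Ainv <- buildAinv(ped)
  dat <- data.frame(id = 1, y = 5)
  ## lambda -> infinity: full shrinkage to zero
  solBig <- solveSingleTrait(dat, Ainv, list(sigma2u = 1e-9, sigma2e = 1),
                             fixed = ~1)
  expect_lt(abs(solBig@gebv[1, 1]), 1e-6)
  ## noiseless limit on a family: phenotypes are true breeding values, so
  ## recorded animals' GEBVs converge to y minus the fitted mean
  ped5 <- toyPed()
  set.seed(2)
  tbvv <- as.numeric(t(chol(relValues(buildA(ped5)))) %*% rnorm(5))
  dat5 <- data.frame(id = 1:5, y = tbvv)
  sol <- solveSingleTrait(dat5, buildAinv(ped5),
                          list(sigma2u = 1, sigma2e = 1e-9), fixed = ~1)
  expect_equal(unname(sol@gebv[, 1]), tbvv - sol@fixed[[1]], tolerance = 1e-3)
  expect_gt(cor(sol@gebv[, 1], tbvv), 0.999)
})

test_that("zero additive variance yields equal (zero) breeding values", {
  ped <- toyPed()
  dat <- data.frame(id = 1:5, y = rnorm(5), sex = factor(c(1, 2, 1, 2, 1)))
  ebv <- pedigreeBlupEbv(dat, ped, list(sigma2u = 0, sigma2e = 1))
  expect_true(all(ebv == 0))
})

test_that("solutions are invariant to animal ordering", {
  set.seed(6)
  ped <- data.frame(id = 1:12, sire = c(rep(0, 4), sample(1:2, 8, TRUE)),
                    dam = c(rep(0, 4), sample(3:4, 8, TRUE)))
  dat <- data.frame(id = 5:12, y = rnorm(8), sex = factor(rep(1:2, 4)))
  vc <- list(sigma2u = 0.3, sigma2e = 0.7)
  s1 <- pedigreeBlupEbv(dat, ped, vc)
  perm <- sample(nrow(dat))
  s2 <- pedigreeBlupEbv(dat[perm, ], ped, vc)
  expect_equal(s1, s2[names(s1)], tolerance = 1e-9)
})

test_that("multi-trait MME equals the dense GLS oracle", {
  ped <- data.frame(id = 1:6, sire = c(0, 0, 1, 1, 3, 0),
                    dam = c(0, 0, 2, 2, 4, 0))
  A <- relValues(buildA(ped))
  Ainv <- buildAinv(ped)
  G0 <- matrix(c(0.5, 0.3, 0.3, 0.4), 2)
  r0 <- c(0.6, 0.8)
  set.seed(10)
  dat <- data.frame(id = c(2, 3, 4, 5, 6), y = rnorm(5),
                    trait = factor(c("t1", "t1", "t2", "t2", "t2"),
                                   levels = c("t1", "t2")))
  sol <- solveMultiTrait(dat, Ainv, G0, r0, fixed = ~1)
  tidx <- as.integer(dat$trait)
  X <- matrix(0, 5, 2); X[cbind(1:5, tidx)] <- 1
  Z <- matrix(0, 5, 6); Z[cbind(1:5, c(2, 3, 4, 5, 6))] <- 1
  ref <- glsMultiTrait(dat$y, X, Z, A, tidx, G0, r0)
  expect_equal(unname(sol@gebv), ref$u, tolerance = 1e-6)
  expect_lt(sol@residualNorm, 1e-8)
})

test_that("diagonal G0 decouples the multi-trait model into single-trait solves", {
  ped <- toyPed()
  Ainv <- buildAinv(ped)
  set.seed(12)
  dat <- data.frame(id = c(1:5, 1:5), y = rnorm(10),
                    trait = factor(rep(c("a", "b"), each = 5)))
  G0 <- diag(c(0.5, 0.3))
  r0 <- c(0.7, 0.9)
  solM <- solveMultiTrait(dat, Ainv, G0, r0, fixed = ~1)
  for (t in 1:2) {
    dt <- dat[as.integer(dat$trait) == t, ]
    solS <- solveSingleTrait(dt, Ainv,
                             list(sigma2u = G0[t, t], sigma2e = r0[t]),
                             fixed = ~1)
    expect_equal(solM@gebv[, t], solS@gebv[, 1], tolerance = 1e-7)
  }
})

test_that("unit genetic correlation with equal variances gives proportional GEBVs", {
  ped <- toyPed()
  Ainv <- buildAinv(ped)
  set.seed(14)
  dat <- data.frame(id = 1:5, y = rnorm(5),
                    trait = factor(rep("a", 5), levels = c("a", "b")))
  ## correlation ~1 (bent slightly by the solver for invertibility)
  G0 <- matrix(c(0.5, 0.5 - 1e-9, 0.5 - 1e-9, 0.5), 2)
  solM <- solveMultiTrait(dat, Ainv, G0, c(0.7, 0.7), fixed = ~1)
  expect_equal(solM@gebv[, 1], solM@gebv[, 2], tolerance = 1e-3)
})
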