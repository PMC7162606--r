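# REML is checked against data generated directly from the animal model
# (u ~ N(0, sigma2u * A) via the Cholesky factor of A), independently of the
# mixed-model machinery under test.

simFromModel <- function(ped, s2u, s2e, mu = 0) {
  A <- relValues(buildA(ped))
  u <- as.numeric(t(chol(A)) %*% rnorm(nrow(A))) * sqrt(s2u)
  data.frame(id = ped$id, y = mu + u + rnorm(nrow(A), 0, sqrt(s2e)))
}

halfSibPed <- function(nSire = 25, nOff = 16) {
  nDam <- nSire * nOff
  founders <- data.frame(id = 1:(nSire + nDam), sire = 0L, dam = 0L)
  off <- data.frame(id = nSire + nDam + 1:nDam,
                    sire = rep(1:nSire, each = nOff),
                    dam = nSire + 1:nDam)
  rbind(founders, off)
}

test_that("single-trait REML recovers the simulated heritability", {
  ped <- halfSibPed()
  h2hat <- vphat <- numeric(3)
  set.seed(101)
  for (r in 1:3) {
    dat <- simFromModel(ped, s2u = 0.33 * 0.13, s2e = 0.67 * 0.13)
    dat <- dat[ped$sire > 0 | ped$id <= 25, ]  # records on sires + offspring
    vc <- remlEstimate(dat, ped, model = "single", fixed = ~1)
    h2hat[r] <- vc@h2
    vphat[r] <- vc@sigma2u + vc@sigma2e
    expect_true(vc@converged)
  }
  ## replicate-spread bands around the simulated truth
  expect_gt(mean(h2hat), 0.20)
  expect_lt(mean(h2hat), 0.46)
  expect_equal(mean(vphat), 0.13, tolerance = 0.1)
})

test_that("pure-noise data drives the additive variance to the boundary", {
  ped <- halfSibPed(30, 10)
  set.seed(33)
  h2s <- sapply(1:2, function(r) {
    dat <- data.frame(id = ped$id, y = rnorm(nrow(ped)))
    remlEstimate(dat, ped, model = "single", fixed = ~1)@h2
  })
  expect_lt(mean(h2s), 0.1)
})

test_that("three-trait REML recovers a high genetic correlation", {
  ## two purebred-like groups and a crossbred-like group measured on
  ## different animals, all driven by one shared genetic factor (rg ~ 0.9)
  ped <- halfSibPed(24, 12)
  set.seed(55)
  A <- relValues(buildA(ped))
  L <- t(chol(A))
  G0 <- 0.0429 * matrix(c(1, .9, .9, .9, 1, .9, .9, .9, 1), 3)
  r0 <- rep(0.0871, 3)
  cG <- chol(G0)
  U <- (L %*% matrix(rnorm(3 * nrow(A)), ncol = 3)) %*% cG
  rec <- ped$id[ped$sire > 0]
  tidx <- rep(1:3, length.out = length(rec))
  dat <- data.frame(id = rec,
                    y = U[cbind(match(rec, ped$id), tidx)] +
                        rnorm(length(rec), 0, sqrt(r0[tidx])),
                    trait = factor(c("Line1", "Line2", "F1")[tidx],
                                   levels = c("Line1", "Line2", "F1")))
  vc <- remlEstimate(dat, ped, model = "multi", fixed = ~1)
  expect_true(all(dim(vc@G0) == 3))
  expect_true(all(diag(vc@R0) > 0))
  expect_gt(vc@rg["Line1", "F1"], 0.5)
  expect_gt(vc@rg["Line2", "F1"], 0.5)
  expect_equal(mean(vc@h2), 0.33, tolerance = 0.5)
})

test_that("multi-trait REML with unrelated groups stays near zero correlation", {
  ped <- halfSibPed(16, 10)
  set.seed(77)
  A <- relValues(buildA(ped))
  L <- t(chol(A))
  ## independent genetic factors per trait
  U <- L %*% matrix(rnorm(2 * nrow(A)), ncol = 2) * sqrt(0.4)
  rec <- ped$id[ped$sire > 0]
  tidx <- rep(1:2, length.out = length(rec))
  dat <- data.frame(id = rec,
                    y = U[cbind(match(rec, ped$id), tidx)] +
                        rnorm(length(rec), 0, sqrt(0.6)),
                    trait = factor(c("a", "b")[tidx]))
  vc <- remlEstimate(dat, ped, model = "multi", fixed = ~1)
  expect_lt(abs(vc@rg[1, 2]), 0.55)
})
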