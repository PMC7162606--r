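test_that("SNP-effect back-solving equals the dense matrix product", {
  set.seed(17)
  M <- matrix(rbinom(12, 2, 0.5), 3, 4, dimnames = list(letters[1:3], paste0("s", 1:4)))
  p <- c(0.4, 0.5, 0.3, 0.6)
  gebv <- c(a = 0.5, b = -0.2, c = 0.9)
  u <- backsolveSnpEffects(gebv, M, p = p)
  ## independent dense assembly: u = (1/k) D Z' G^-1 g
  Z <- sweep(M, 2, 2 * p, "-")
  k <- 2 * sum(p * (1 - p))
  G <- Z %*% t(Z) / k
  uref <- as.numeric((1 / k) * t(Z) %*% solve(G, gebv))
  expect_equal(unname(u), uref, tolerance = 1e-9)
  ## Eq-consistency: Z u reconstructs the genomic GEBVs exactly
  expect_equal(as.numeric(Z %*% u), unname(gebv), tolerance = 1e-9)
  ## zero GEBVs give zero effects
  expect_true(all(backsolveSnpEffects(gebv * 0, M, p = p) == 0))
})

test_that("SNP weights follow d = u^2 2p(1-p) with mean-1 normalization", {
  raw <- snpWeights(c(1, 0), c(0.5, 0.3), normalize = FALSE)
  expect_equal(raw@weights, c(0.5, 0))        # 1^2 * 2 * 0.5 * 0.5
  expect_equal(snpWeights(c(0, 2), c(0.5, 0.5), normalize = FALSE)@weights[1], 0)
  ## equal effects and frequencies normalize to all ones
  w <- snpWeights(rep(0.3, 6), rep(0.25, 6))
  expect_equal(w@weights, rep(1, 6))
  expect_identical(w@iteration, 2L)
  ## boundary frequencies get weight zero with a warning
  expect_warning(wb <- snpWeights(c(1, 1), c(0, 0.5)), "boundary")
  expect_equal(wb@weights[1], 0)
  ## normalization removes any constant scaling of the effects
  w1 <- snpWeights(c(0.1, 0.4, 0.2), c(0.3, 0.4, 0.2))
  w2 <- snpWeights(10 * c(0.1, 0.4, 0.2), c(0.3, 0.4, 0.2))
  expect_equal(w1@weights, w2@weights, tolerance = 1e-12)
})

test_that("weighted G with unit weights equals plain G", {
  set.seed(19)
  M <- matrix(rbinom(40, 2, 0.4), 5, 8, dimnames = list(letters[1:5], NULL))
  p <- runif(8, 0.2, 0.8)
  expect_equal(relValues(buildG(M, p = p)),
               relValues(buildG(M, p = p, weights = rep(1, 8))))
})

test_that("one weighting iteration reproduces plain single-step GBLUP", {
  pop <- microPop("SIM5", 1)
  set.seed(23)
  asc <- assembleScenario(pop, "SC1")
  kept <- crossBLUP:::.popQc(pop)$kept
  geno <- genotypes(pop, asc$genotypedIds, snps = kept)
  rownames(geno) <- as.character(asc$genotypedIds)
  ped <- pop@pedigree[, c("id", "sire", "dam")]
  vc <- list(sigma2u = 0.33 * 0.13, sigma2e = 0.67 * 0.13)
  res1 <- wssgblupRun(asc$train, ped, geno, varcomp = vc, nIterations = 1)
  ## manual plain ssGBLUP with the same pieces
  Ainv <- buildAinv(ped)
  A22m <- relSubset(ped, asc$genotypedIds)
  A22 <- new("RelationshipMatrix", labels = rownames(geno), values = A22m,
             kind = "A22", provenance = list())
  pP <- alleleFreqs(geno)
  nP <- nrow(geno)
  pP <- pmin(pmax(pP, 1 / (4 * nP)), 1 - 1 / (4 * nP))
  G <- buildG(geno, p = pP)
  H <- blendHinv(Ainv, A22, G, tau = 2.2, omega = 0.5)
  solRef <- solveSingleTrait(asc$train, H, vc)
  expect_equal(res1$solution@gebv, solRef@gebv, tolerance = 1e-6)

  ## two iterations with a strong-LD trait change the weights but keep
  ## the constant-weight invariance: re-running with weights scaled by c
  ## inside snpWeights has no effect (normalization), checked above; here
  ## check the full loop returns normalized weights and valid solutions
  res2 <- wssgblupRun(asc$train, ped, geno, varcomp = vc, nIterations = 2)
  expect_s4_class(res2$weights, "SnpWeightSet")
  expect_equal(mean(res2$weights@weights), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(res2$solution@gebv, res1$solution@gebv)))
  ## iteration-1 component of the two-iteration run equals the plain run
  expect_equal(res2$iteration1@gebv, res1$solution@gebv, tolerance = 1e-9)
})

test_that("a large simulated QTL ranks among the top back-solved effects", {
  ## one strong QTL in complete LD with a marker: its marker's squared
  ## effect should rank at the top
  set.seed(29)
  n <- 120; m <- 40
  M <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(seq_len(n), paste0("s", 1:m)))
  tbvv <- 2 * (M[, 7] - 1)  # marker 7 is the causal locus
  gebv <- tbvv + rnorm(n, 0, 0.3)
  names(gebv) <- rownames(M)
  ## more animals than markers: invert through the pedigree blend
  u <- backsolveSnpEffects(gebv, M, A22 = diag(n))
  expect_equal(which.max(abs(u)), 7L, ignore_attr = TRUE)
})
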