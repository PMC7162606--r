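test_that("pairwise LD matches hand-computed haplotype frequencies", {
  ## perfect coupling: AB/AB/ab/ab
  h <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  ld <- ldR2(h, 1, 2)
  expect_equal(ld$r, 1)
  expect_equal(ld$r2, 1)
  ## equilibrium: all four haplotypes equally frequent
  h2 <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  expect_equal(ldR2(h2, 1, 2)$D, 0)
  expect_equal(ldR2(h2, 1, 2)$r, 0)
  ## 8-haplotype fixture: f(A)=5/8, f(B)=4/8, f(AB)=3/8
  h8 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 0), c(1, 0),
              c(0, 1), c(0, 0), c(0, 0))
  ld8 <- ldR2(h8, 1, 2)
  D <- 3 / 8 - (5 / 8) * (4 / 8)
  expect_equal(ld8$D, D)
  expect_equal(ld8$r2, D^2 / ((5 / 8) * (3 / 8) * (4 / 8) * (4 / 8)))
  expect_equal(ld8$r, D / sqrt((5 / 8) * (3 / 8) * (4 / 8) * (4 / 8)))
  expect_error(ldR2(rbind(c(1, 1), c(1, 0)), 1, 2), "monomorphic")
})

test_that("signed r is antisymmetric under allele relabeling, r2 invariant", {
  set.seed(41)
  h <- matrix(rbinom(200, 1, 0.5), 100, 2)
  h[, 2] <- ifelse(runif(100) < 0.7, h[, 1], h[, 2])  # induce LD
  a <- ldR2(h, 1, 2)
  hf <- h; hf[, 1] <- 1 - hf[, 1]
  b <- ldR2(hf, 1, 2)
  expect_equal(a$r, -b$r)
  expect_equal(a$r2, b$r2)
})

test_that("adjacent LD profile averages r2 over qualifying pairs", {
  map <- data.frame(chrom = c(1, 1, 1, 2, 2), pos = c(0.025, 0.075, 0.2, 0.025, 0.075))
  set.seed(43)
  h <- matrix(rbinom(500, 1, 0.5), 100, 5)
  prof <- adjacentLdProfile(h, map, maxDistCM = 0.05)
  ## qualifying pairs: (1,2) and (4,5); (2,3) too far, (3,4) crosses chroms
  expect_equal(prof$nPairs + prof$nExcluded, 2L)
  r12 <- ldR2(h, 1, 2)$r2; r45 <- ldR2(h, 4, 5)$r2
  expect_equal(prof$meanR2, mean(c(r12, r45)))
})

test_that("phase consistency is 1 for identical populations and -1 for anti-phase", {
  set.seed(47)
  m <- 30
  map <- data.frame(chrom = 1L, pos = seq(0.05, by = 0.05, length.out = m))
  base <- matrix(rbinom(60 * m, 1, 0.5), 60, m)
  for (j in 2:m) base[, j] <- ifelse(runif(60) < 0.6, base[, j - 1], base[, j])
  pc <- phaseConsistency(base, base, map, orient = "asIs")
  expect_equal(pc$correlation[pc$nPairs >= 3],
               rep(1, sum(pc$nPairs >= 3)), tolerance = 1e-9)
  ## minor-allele orientation cannot break self-consistency
  pcm <- phaseConsistency(base, base, map, orient = "minor")
  expect_equal(pcm$correlation[pcm$nPairs >= 3],
               rep(1, sum(pcm$nPairs >= 3)), tolerance = 1e-9)
  ## flipping alleles at alternating loci reverses the sign of r for
  ## adjacent pairs: correlation -1 in the first bin
  flip <- seq(1, m, by = 2)
  anti <- base; anti[, flip] <- 1 - anti[, flip]
  pca <- phaseConsistency(base, anti, map, orient = "asIs")
  expect_equal(pca$correlation[1], -1, tolerance = 1e-9)
  ## symmetry in the population pair
  pab <- phaseConsistency(base, anti, map, orient = "asIs")
  pba <- phaseConsistency(anti, base, map, orient = "asIs")
  expect_equal(pab$correlation, pba$correlation)
})

test_that("PCA of G matches the characteristic polynomial on a 3x3 matrix", {
  M <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3)
  pc <- pcaOfG(M, nComp = 3)
  ## roots of the characteristic polynomial as the independent oracle:
  ## det(M - x I) = -x^3 + tr(M) x^2 - c2 x + det(M)
  c2 <- M[1, 1] * M[2, 2] - M[1, 2]^2 +
        M[1, 1] * M[3, 3] - M[1, 3]^2 +
        M[2, 2] * M[3, 3] - M[2, 3]^2
  roots <- sort(Re(polyroot(c(det(M), -c2, sum(diag(M)), -1))),
                decreasing = TRUE)
  expect_equal(pc$values, roots, tolerance = 1e-9)
  expect_equal(sum(pc$varExplained), 1)
  ## two identical animals get identical scores
  G <- matrix(c(1, 1, 0.2, 1, 1, 0.2, 0.2, 0.2, 1), 3)
  pc2 <- pcaOfG(G)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], tolerance = 1e-9)
  expect_error(pcaOfG(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("allele-frequency correlation behaves at its fixed points", {
  set.seed(51)
  g <- matrix(rbinom(300, 2, 0.3), 30, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  expect_equal(alleleFreqCorrelation(g, g), 1)
  pa <- runif(200, 0.05, 0.95); pb <- runif(200, 0.05, 0.95)
  names(pa) <- names(pb) <- paste0("x", 1:200)
  expect_lt(abs(alleleFreqCorrelation(pa, pb, orient = "asIs")), 0.25)
  expect_error(alleleFreqCorrelation(g[, 1:2], g[, 3:4]), "common")
})
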