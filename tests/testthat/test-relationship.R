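test_that("tabular A reproduces textbook relationships", {
  ## two unrelated founders
  A0 <- relValues(buildA(data.frame(id = 1:2, sire = 0, dam = 0)))
  expect_equal(unname(A0), diag(2))
  ## trio: parent-offspring 0.5, non-inbred offspring diagonal 1
  At <- relValues(buildA(data.frame(id = 1:3, sire = c(0, 0, 1),
                                    dam = c(0, 0, 2))))
  expect_equal(At[3, 1], 0.5)
  expect_equal(At[3, 3], 1)
  ## offspring of full sibs: F = 0.25
  A5 <- relValues(buildA(toyPed()))
  expect_equal(A5[5, 5], 1.25)
  expect_equal(A5[3, 4], 0.5)
  ## parent-offspring mating
  Ax <- relValues(buildA(data.frame(id = 1:3, sire = c(0, 1, 1),
                                    dam = c(0, 0, 2))))
  expect_equal(Ax[3, 3], 1.25)
  expect_equal(unname(inbreeding(data.frame(id = 1:3, sire = c(0, 1, 1),
                                            dam = c(0, 0, 2)))),
               c(0, 0, 0.25))
})

test_that("A matches Monte-Carlo gene-dropping on a small pedigree", {
  ped <- data.frame(id = 1:7, sire = c(0, 0, 1, 1, 3, 3, 5),
                    dam = c(0, 0, 2, 2, 4, 4, 6))
  A <- relValues(buildA(ped))
  set.seed(99)
  Ag <- geneDropRelationship(ped, nrep = 8000)
  expect_lt(max(abs(A - Ag)), 0.05)
})

test_that("sparse A-inverse and subset extraction agree with dense algebra", {
  set.seed(21)
  ped <- data.frame(id = 1:40, sire = 0L, dam = 0L)
  for (i in 11:40) {
    ped$sire[i] <- sample(1:(i - 1), 1)
    ped$dam[i] <- sample(1:(i - 1), 1)
  }
  ## avoid selfing
  same <- ped$sire == ped$dam & ped$sire > 0
  ped$dam[same] <- 0L
  A <- relValues(buildA(ped))
  Ainv <- as.matrix(relValues(buildAinv(ped)))
  expect_lt(max(abs(Ainv %*% A - diag(40))), 1e-8)
  ids <- c(3, 17, 40, 25)
  expect_equal(relSubset(ped, ids), A[as.character(ids), as.character(ids)],
               tolerance = 1e-10)
  ## extractA22 is plain principal-submatrix selection
  A22 <- extractA22(buildA(ped), ids)
  expect_equal(relValues(A22), A[as.character(ids), as.character(ids)])
  expect_equal(relValues(extractA22(buildA(ped), ped$id)), A)
  expect_equal(unname(relValues(extractA22(buildA(ped), 1L))),
               matrix(1, 1, 1))
  expect_error(extractA22(buildA(ped), 99), "not present")
})

test_that("VanRaden G matches the elementwise double-loop oracle", {
  set.seed(5)
  M <- matrix(rbinom(24, 2, 0.5), 4, 6)
  rownames(M) <- letters[1:4]
  p <- c(0.3, 0.5, 0.4, 0.6, 0.2, 0.5)
  G <- relValues(buildG(M, p = p))
  k <- 2 * sum(p * (1 - p))
  Gref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    s <- 0
    for (l in 1:6) s <- s + (M[i, l] - 2 * p[l]) * (M[j, l] - 2 * p[l])
    Gref[i, j] <- s / k
  }
  expect_equal(unname(G), Gref, tolerance = 1e-12)
})

test_that("G degenerate and symmetry cases behave as specified", {
  ## one animal heterozygous everywhere at p = 0.5: Z = 0
  M <- matrix(1L, 1, 5, dimnames = list("a", NULL))
  expect_equal(unname(relValues(buildG(M, p = rep(0.5, 5)))),
               matrix(0, 1, 1))
  ## duplicated genotypes give identical rows/columns
  M2 <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  G2 <- relValues(buildG(M2, p = rep(0.5, 4)))
  expect_equal(G2["a", "a"], G2["a", "b"])
  expect_equal(G2["a", "a"], G2["b", "b"])
  ## coding-flip invariance with identity weights
  set.seed(8)
  M3 <- matrix(rbinom(30, 2, 0.4), 5, 6, dimnames = list(letters[1:5], NULL))
  p3 <- runif(6, 0.2, 0.8)
  expect_equal(relValues(buildG(M3, p = p3)),
               relValues(buildG(2L - M3, p = 1 - p3)), tolerance = 1e-12)
  ## fixed loci are rejected
  expect_error(buildG(M3, p = c(0, p3[-1])), "degenerate")
})

test_that("H-inverse blending collapses to A-inverse when G = A22, tau = omega", {
  ped <- toyPed()
  A <- buildA(ped)
  Ainv <- buildAinv(ped)
  gids <- c(3, 4, 5)
  A22 <- extractA22(A, gids)
  Gfake <- new("RelationshipMatrix", labels = as.character(gids),
               values = relValues(A22), kind = "G", provenance = list())
  H <- blendHinv(Ainv, A22, Gfake, tau = 1, omega = 1)
  expect_lt(max(abs(as.matrix(relValues(H)) - as.matrix(relValues(Ainv)))),
            1e-10)
})

test_that("H-inverse equals the dense textbook assembly", {
  ped <- data.frame(id = 1:6, sire = c(0, 0, 1, 1, 3, 0),
                    dam = c(0, 0, 2, 2, 4, 0))
  A <- relValues(buildA(ped))
  gids <- c(4, 5, 6)
  gidx <- match(gids, ped$id)
  set.seed(31)
  geno <- matrix(rbinom(3 * 8, 2, 0.5), 3, 8, dimnames = list(gids, NULL))
  G <- buildG(geno, p = rep(0.5, 8))
  A22 <- extractA22(buildA(ped), gids)
  for (prm in list(c(1, 1), c(2.2, 0.5))) {
    H <- blendHinv(buildAinv(ped), A22, G, tau = prm[1], omega = prm[2])
    ## independent dense construction
    Gb <- 0.95 * relValues(G) + 0.05 * A[gidx, gidx]
    corr <- prm[1] * solve(Gb) - prm[2] * solve(A[gidx, gidx])
    Href <- solve(A)
    Href[gidx, gidx] <- Href[gidx, gidx] + corr
    expect_lt(max(abs(as.matrix(relValues(H)) - Href)), 1e-8)
  }
})

test_that("scaling factors outside the tested grid are rejected", {
  ped <- toyPed()
  A <- buildA(ped)
  A22 <- extractA22(A, c(3, 4, 5))
  Gfake <- new("RelationshipMatrix", labels = as.character(c(3, 4, 5)),
               values = relValues(A22), kind = "G", provenance = list())
  Ainv <- buildAinv(ped)
  expect_silent(blendHinv(Ainv, A22, Gfake, tau = 2.2, omega = 0.5))
  expect_error(blendHinv(Ainv, A22, Gfake, tau = 0, omega = 1), "outside")
  expect_error(blendHinv(Ainv, A22, Gfake, tau = 1, omega = 0.2), "outside")
})

test_that("pedigree errors are caught", {
  bad <- data.frame(id = 1:3, sire = c(0, 3, 2), dam = c(0, 0, 0))
  expect_error(buildA(bad), "sorted|cycle")
  expect_error(buildAinv(data.frame(id = 1:2, sire = c(0, 9), dam = 0)),
               "unknown")
})
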