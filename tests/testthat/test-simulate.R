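test_that("simulation is deterministic under a fixed seed", {
  a <- simulatePopulation(microGenome(), "SIM5", microParams(), seed = 7)
  b <- simulatePopulation(microGenome(), "SIM5", microParams(), seed = 7)
  expect_identical(a@pedigree, b@pedigree)
  expect_identical(a@hap1, b@hap1)
  expect_identical(a@phenotype, b@phenotype)
})

test_that("pedigree and cohort invariants hold", {
  pop <- microPop("SIM5", 1)
  ped <- pedigree(pop)
  n <- nrow(ped)
  ## parents precede offspring
  expect_true(all(ped$sire < ped$id | ped$sire == 0))
  expect_true(all(ped$dam < ped$id | ped$dam == 0))
  ## founders have unknown parents
  f <- pop@cohorts$founders
  expect_true(all(ped$sire[f] == 0 & ped$dam[f] == 0))
  ## F1 animals have a Line1 dam and a Line2 sire
  for (ch in paste0("F1-", 1:4)) {
    ids <- pop@cohorts[[ch]]
    expect_true(all(ped$population[ped$id %in% ped$dam[ids]] == "Line1"))
    expect_true(all(ped$population[ped$id %in% ped$sire[ids]] == "Line2"))
  }
  ## F1 parental generations follow the crossing calendar
  pg <- microParams()$f1$parentGens
  for (j in 1:4) {
    ids <- pop@cohorts[[paste0("F1-", j)]]
    expect_true(all(ped$generation[ped$dam[ids]] == pg[1, j]))
    expect_true(all(ped$generation[ped$sire[ids]] == pg[2, j]))
  }
  ## training and validation cohorts are disjoint
  expect_length(intersect(pop@cohorts[["F1-3"]], pop@cohorts[["F1-1"]]), 0)
  expect_length(intersect(pop@cohorts$Line1_train, pop@cohorts$Line2_train), 0)
})

test_that("variance bookkeeping matches the trait architecture", {
  pop5 <- microPop("SIM5", 1)
  f <- pop5@cohorts$founders
  ## all-QTL trait: founder TBV variance is scaled exactly to h2 * vp
  expect_equal(var(as.numeric(tbv(pop5)[f])), 0.33 * 0.13, tolerance = 1e-10)
  expect_true(all(pop5@tbvPoly == 0))
  ## fully polygenic trait: founder TBV variance is a random draw around it
  pop1 <- microPop("SIM1", 1)
  expect_true(all(pop1@tbvQtl == 0))
  expect_equal(var(as.numeric(tbv(pop1)[pop1@cohorts$founders])), 0.33 * 0.13,
               tolerance = 0.5)
  ## founder phenotypic variance close to vp
  expect_equal(var(as.numeric(phenotypes(pop5)[f])), 0.13, tolerance = 0.35)
})

test_that("selection for low EBV decreases the line mean over generations", {
  pop <- microPop("SIM5", 1)
  ped <- pedigree(pop)
  tb <- as.numeric(tbv(pop))
  m2 <- tapply(tb[ped$population == "Line2"],
               ped$generation[ped$population == "Line2"], mean)
  expect_lt(m2[[length(m2)]], m2[[1]])
  ## the line with the longer selection history ends lower
  m1 <- tapply(tb[ped$population == "Line1"],
               ped$generation[ped$population == "Line1"], mean)
  expect_lt(m2[[length(m2)]], m1[[length(m1)]])
})

test_that("every transmitted allele traces to a parental haplotype", {
  pop <- microPop("SIM5", 1)
  ped <- pedigree(pop)
  f1 <- unlist(pop@cohorts[paste0("F1-", 1:4)], use.names = FALSE)
  h <- haplotypes(pop, ids = f1)
  hs <- haplotypes(pop, ids = ped$sire[f1])
  hd <- haplotypes(pop, ids = ped$dam[f1])
  ## hap1 comes from the sire, hap2 from the dam (mutations excepted)
  okS <- h$hap1 == hs$hap1 | h$hap1 == hs$hap2
  okD <- h$hap2 == hd$hap1 | h$hap2 == hd$hap2
  expect_gt(mean(okS), 1 - 1e-3)
  expect_gt(mean(okD), 1 - 1e-3)
})

test_that("redrawing phenotypes preserves the residual variance law", {
  pop <- microPop("SIM5", 1)
  set.seed(99)
  pop2 <- assignPhenotypes(pop, mu = 1, sexEffect = 0)
  resid <- pop2@phenotype - 1 - as.numeric(tbv(pop2))
  expect_equal(var(resid), (1 - 0.33) * 0.13, tolerance = 0.05)
  expect_equal(mean(resid), 0, tolerance = 0.02)
})

test_that("scaled design parameters keep the breeding structure feasible", {
  p <- simParams(scaleFactor = 0.05)
  expect_identical(p$popTarget, 3200L)
  expect_identical(p$line1$dams, 1600L)
  ## sires are floored, never scaled below the drift-preserving minimum
  expect_gte(p$line2$sires, 25)
  expect_lte(p$line2$sires, 64)
  ## replacement feasibility: candidates cover the demand
  expect_lte(0.6 * p$line1$sires, p$line1$dams / 2)
  expect_lte(0.2 * p$line1$dams, p$line1$dams / 2)
  expect_error(simParams(scaleFactor = 0), "scaleFactor")
})
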