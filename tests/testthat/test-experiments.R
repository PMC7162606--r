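test_that("scenario table encodes the five training designs", {
  sc1 <- scenarioSpec("SC1")
  expect_identical(sc1@model, "single")
  expect_identical(sc1@method, "ssGBLUP")
  expect_true(all(c("F1-1", "F1-2") %in% sc1@training))
  sc2 <- scenarioSpec("SC2")
  expect_identical(sc2@model, "multi")
  sc4 <- scenarioSpec("SC4")
  expect_false(any(c("F1-1", "F1-2") %in% sc4@training))
  expect_identical(sc4@weightSource, "crossbred")
  expect_identical(scenarioSpec("SC5")@weightSource, "purebred")
  expect_identical(scenarioSpec("SC3")@weightSource, "pooled")
})

test_that("scenario assembly respects training membership and genotype sets", {
  pop <- microPop("SIM5", 1)
  a1 <- assembleScenario(pop, "SC1")
  expTrain <- c(pop@cohorts$Line1_train, pop@cohorts$Line2_train,
                pop@cohorts[["F1-1"]], pop@cohorts[["F1-2"]])
  expect_setequal(a1$train$id, expTrain)
  ## validation cohorts never contribute phenotypes
  expect_length(intersect(a1$train$id, unlist(a1$validation)), 0)
  ## validation crossbreds stay genotyped in every scenario
  a5 <- assembleScenario(pop, "SC5")
  expect_true(all(unlist(a5$validation) %in% a5$genotypedIds))
  ## purebred-training scenarios exclude training crossbreds from G
  expect_length(intersect(a5$genotypedIds, pop@cohorts[["F1-1"]]), 0)
  expect_true(all(pop@cohorts[["F1-1"]] %in%
                  assembleScenario(pop, "SC3")$genotypedIds))
  ## SC4 weights come from the crossbred training animals
  a4 <- assembleScenario(pop, "SC4")
  expect_setequal(a4$weightSourceIds,
                  c(pop@cohorts[["F1-1"]], pop@cohorts[["F1-2"]]))
  ## balanced-size subsampling gives the requested count
  ab <- assembleScenario(pop, "SC1", balanceTo = nrow(a5$train))
  expect_identical(nrow(ab$train), nrow(a5$train))
})

test_that("validation metrics match their closed forms", {
  x <- c(0.4, -0.1, 0.3, 0.8, -0.5, 0.2)
  expect_equal(unname(validateGebv(x, x)[1:2]), c(1, 1))
  v <- validateGebv(2 * x, x)
  expect_equal(unname(v[1:2]), c(1, 0.5))
  set.seed(61)
  g <- rnorm(6); t <- 0.6 * g + rnorm(6, 0, 0.3)
  v2 <- validateGebv(g, t)
  expect_equal(v2[["accuracy"]], cor(g, t))
  expect_equal(v2[["slope"]], cov(t, g) / var(g))
  expect_error(validateGebv(rep(1, 6), x), "zero variance")
  expect_error(validateGebv(x[1:2], x[1:2]), "too small")
})

test_that("paired comparisons reproduce the t-test and flag degeneracy", {
  df <- data.frame(replicate = rep(1:5, 2),
                   scenario = rep(c("A", "B"), each = 5),
                   accuracy = c(0.50, 0.52, 0.47, 0.55, 0.49,
                                0.45, 0.50, 0.44, 0.50, 0.46))
  out <- pairedComparison(df)
  d <- df$accuracy[1:5] - df$accuracy[6:10]
  tref <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t, tref, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(tref), 4), tolerance = 1e-12)
  ## identical groups: no difference, p = 1 by convention
  df2 <- df; df2$accuracy[6:10] <- df2$accuracy[1:5]
  out2 <- pairedComparison(df2)
  expect_equal(out2$p, 1)
  ## constant shift: zero variance of differences, flagged degenerate
  df3 <- df; df3$accuracy[6:10] <- df3$accuracy[1:5] - 0.1
  out3 <- pairedComparison(df3)
  expect_true(grepl("degenerate", out3$note))
  expect_true(is.na(out3$p))
  ## unequal replicate sets are a pairing error
  df4 <- df[-1, ]
  expect_error(pairedComparison(df4), "pairing")
})

test_that("tau/omega grid enumerates 136 combinations and selects reproducibly", {
  pop <- microPop("SIM5", 1)
  vc <- list(sigma2u = 0.33 * 0.13, sigma2e = 0.67 * 0.13)
  set.seed(3)
  gr <- tauOmegaGrid(pop, varcomp = vc)
  expect_identical(nrow(gr$surface), 136L)
  expect_identical(length(unique(gr$surface$tau)), 17L)
  expect_identical(length(unique(gr$surface$omega)), 8L)
  ## the selected pair minimizes |1 - slope| among solved combinations
  ok <- !is.na(gr$surface$slope)
  expect_equal(min(abs(1 - gr$surface$slope[ok])), abs(1 - gr$best$slope))
  set.seed(3)
  gr2 <- tauOmegaGrid(pop, varcomp = vc)
  expect_identical(gr$best, gr2$best)
})

test_that("validation phenotypes are never read (no leakage)", {
  pop <- microPop("SIM5", 1)
  vc <- list(sigma2u = 0.33 * 0.13, sigma2e = 0.67 * 0.13)
  set.seed(5)
  ev1 <- runEvaluation(pop, "SC1", varcomp = vc)
  pop2 <- pop
  vids <- unlist(pop@cohorts[c("F1-3", "F1-4")])
  pop2@phenotype[vids] <- 999
  set.seed(5)
  ev2 <- runEvaluation(pop2, "SC1", varcomp = vc)
  expect_identical(ev1$metrics, ev2$metrics)
})

test_that("the experiment driver aggregates replicates deterministically", {
  g <- microGenome(); p <- microParams()
  ex <- runExperiment(g, p, sims = "SIM5", scenarios = c("SC1", "SC5"),
                      seeds = 1:2,
                      varcomp = list(sigma2u = 0.33 * 0.13,
                                     sigma2e = 0.67 * 0.13))
  expect_identical(nrow(ex$results), 8L)  # 2 seeds x 2 scenarios x 2 cohorts
  expect_true(all(c("accuracy", "slope", "sim", "replicate") %in%
                  names(ex$results)))
  expect_identical(nrow(ex$summary), 4L)
  ex2 <- runExperiment(g, p, sims = "SIM5", scenarios = c("SC1", "SC5"),
                       seeds = 1:2,
                       varcomp = list(sigma2u = 0.33 * 0.13,
                                      sigma2e = 0.67 * 0.13))
  expect_identical(ex$results, ex2$results)
  ## predictions carry real information at micro scale
  expect_gt(mean(ex$results$accuracy), 0)
})
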