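#' Training-population scenario definitions
#'
#' SC1: single-trait ssGBLUP, purebred + crossbred training. SC2: the same
#' training set under the three-trait model. SC3: single-trait WssGBLUP with
#' weights from the pooled purebred + crossbred set. SC4: purebred-only
#' training, weights from the crossbred animals. SC5: purebred-only training
#' and purebred-derived weights. Validation cohorts F1-3 and F1-4 never
#' contribute phenotypes, and their genotypes stay in the genomic matrix in
#' every scenario.
#'
#' @param id "SC1".."SC5".
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(id) {
  id <- match.arg(id, paste0("SC", 1:5))
  pc <- c("Line1_train", "Line2_train", "F1-1", "F1-2")
  pb <- c("Line1_train", "Line2_train")
  def <- switch(id,
    SC1 = list(training = pc, model = "single", method = "ssGBLUP",  ws = "none"),
    SC2 = list(training = pc, model = "multi",  method = "ssGBLUP",  ws = "none"),
    SC3 = list(training = pc, model = "single", method = "WssGBLUP", ws = "pooled"),
    SC4 = list(training = pb, model = "single", method = "WssGBLUP", ws = "crossbred"),
    SC5 = list(training = pb, model = "single", method = "WssGBLUP", ws = "purebred"))
  new("ScenarioSpec", id = id, training = def$training, model = def$model,
      method = def$method, weightSource = def$ws)
}

#' Assemble training/validation data for a scenario
#'
#' @param pop a [SimulatedPopulation-class].
#' @param scenario a [ScenarioSpec-class] or its id.
#' @param balanceTo optionally subsample the training records to this size
#'   (used for same-size training-population comparisons).
#' @return list with `train` (id, y, sex, population, trait), `genotypedIds`
#'   (animals entering the genomic matrix: training genotypes per the
#'   scenario plus the validation crossbreds), `validation` (named id lists
#'   for F1-3 and F1-4), `weightSourceIds`, `predFreqIds` (animals whose
#'   allele frequencies parameterize G).
#' @export
assembleScenario <- function(pop, scenario, balanceTo = NULL) {
  if (is.character(scenario)) scenario <- scenarioSpec(scenario)
  ch <- pop@cohorts
  need <- scenario@training
  if (!all(need %in% names(ch) | need %in% c("F1-1", "F1-2")))
    stop("missing cohort(s): ", paste(setdiff(need, names(ch)), collapse = ", "))
  trainIds <- unlist(lapply(need, function(nm) ch[[nm]]), use.names = FALSE)
  ped <- pop@pedigree
  popLabel <- function(ids) {
    p <- ped$population[ids]
    ifelse(startsWith(p, "F1"), "F1", p)
  }
  train <- data.frame(id = trainIds, y = pop@phenotype[trainIds],
                      sex = factor(ped$sex[trainIds], levels = 1:2),
                      population = factor(popLabel(trainIds),
                                          levels = c("Line1", "Line2", "F1")),
                      trait = factor(popLabel(trainIds),
                                     levels = c("Line1", "Line2", "F1")),
                      stringsAsFactors = FALSE)
  train$population <- droplevels(train$population)
  train$trait <- droplevels(train$trait)
  if (!is.null(balanceTo)) {
    if (balanceTo > nrow(train)) stop("balanceTo exceeds the training size")
    train <- train[sort(sample(nrow(train), balanceTo)), , drop = FALSE]
  }
  crossInTrain <- any(c("F1-1", "F1-2") %in% need)
  genotypedIds <- c(ch$Line1_train, ch$Line2_train,
                    if (crossInTrain) c(ch[["F1-1"]], ch[["F1-2"]]),
                    ch[["F1-3"]], ch[["F1-4"]])
  crossTrainIds <- c(ch[["F1-1"]], ch[["F1-2"]])
  pureTrainIds <- c(ch$Line1_train, ch$Line2_train)
  weightSourceIds <- switch(scenario@weightSource,
    none = integer(),
    pooled = c(pureTrainIds, crossTrainIds),
    crossbred = crossTrainIds,
    purebred = pureTrainIds)
  predFreqIds <- switch(scenario@weightSource,
    none = ,
    pooled = c(pureTrainIds, crossTrainIds),
    crossbred = crossTrainIds,
    purebred = pureTrainIds)
  list(train = train, genotypedIds = genotypedIds,
       validation = list(`F1-3` = ch[["F1-3"]], `F1-4` = ch[["F1-4"]]),
       weightSourceIds = weightSourceIds, predFreqIds = predFreqIds,
       scenario = scenario)
}

#' Validation accuracy and dispersion slope
#'
#' Accuracy is the Pearson correlation between GEBVs and true breeding
#' values; the dispersion slope is the regression coefficient of TBV on GEBV
#' (1 = unbiased, below 1 = inflated GEBVs).
#'
#' @param gebv,tbvv aligned numeric vectors over one validation cohort.
#' @return named vector c(accuracy, slope, n).
#' @export
validateGebv <- function(gebv, tbvv) {
  if (length(gebv) != length(tbvv)) stop("gebv/tbv length mismatch")
  if (length(gebv) <= 2L) stop("validation cohort too small")
  if (var(gebv) <= 0) stop("zero variance in GEBV: slope undefined")
  c(accuracy = cor(tbvv, gebv), slope = cov(tbvv, gebv) / var(gebv),
    n = length(gebv))
}

## QC over the three genotyped populations of a simulated system
.popQc <- function(pop, maf = 0.05, hweDev = 0.15) {
  ch <- pop@cohorts
  f1 <- unlist(ch[grep("^F1-", names(ch))], use.names = FALSE)
  genoList <- list(Line1 = genotypes(pop, ch$Line1_train),
                   Line2 = genotypes(pop, ch$Line2_train),
                   F1 = genotypes(pop, f1))
  qcPipeline(genoList, maf = maf, hweDev = hweDev)
}

#' Run one genomic evaluation
#'
#' Performs genotype QC, estimates variance components by REML with the
#' pedigree relationship matrix (unless supplied), builds the single-step
#' H-inverse with the requested tau/omega, fits the scenario's model
#' (plain or weighted, single- or three-trait) and validates against the
#' true breeding values of the F1-3 and F1-4 cohorts.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param scenario a [ScenarioSpec-class] or id.
#' @param tau,omega H-inverse scaling factors.
#' @param varcomp optional fixed variance components (list with
#'   sigma2u/sigma2e, or with G0/R0 for SC2); REML otherwise.
#' @param qcKept optional precomputed kept-SNP vector (reused across
#'   scenarios of one replicate).
#' @param remlMaxN records are subsampled to at most this many for REML.
#' @param balanceTo see [assembleScenario()].
#' @return list with `metrics` (data.frame scenario, cohort, accuracy,
#'   slope, n), `varcomp`, `solution`, `weights`, `kept`.
#' @export
runEvaluation <- function(pop, scenario, tau = 2.2, omega = 0.5,
                          varcomp = NULL, qcKept = NULL, remlMaxN = 1000,
                          balanceTo = NULL) {
  if (is.character(scenario)) scenario <- scenarioSpec(scenario)
  asc <- assembleScenario(pop, scenario, balanceTo = balanceTo)
  kept <- if (is.null(qcKept)) .popQc(pop)$kept else qcKept
  ped <- pop@pedigree[, c("id", "sire", "dam")]
  train <- asc$train
  if (is.null(varcomp)) {
    sub <- train
    if (nrow(sub) > remlMaxN) sub <- sub[sort(sample(nrow(sub), remlMaxN)), ]
    varcomp <- if (scenario@model == "multi")
      remlEstimate(sub, ped, model = "multi")
    else remlEstimate(sub, ped, model = "single")
  }
  geno <- genotypes(pop, asc$genotypedIds, snps = kept)
  rownames(geno) <- as.character(asc$genotypedIds)
  weights <- NULL
  if (scenario@method == "WssGBLUP") {
    vc <- .asVarcompList(varcomp)
    genoWeight <- genotypes(pop, asc$weightSourceIds, snps = kept)
    rownames(genoWeight) <- as.character(asc$weightSourceIds)
    ## frequency source for the prediction G per scenario (crossbred animals
    ## are not part of the genomic matrix in the purebred-training designs)
    genoFreq <- genotypes(pop, asc$predFreqIds, snps = kept)
    res <- wssgblupRun(train, ped, geno, genoWeight = genoWeight,
                       predFreq = alleleFreqs(genoFreq),
                       varcomp = vc, tau = tau, omega = omega,
                       freqSource = scenario@weightSource)
    sol <- res$solution
    weights <- res$weights
  } else {
    Ainv <- buildAinv(ped)
    A22m <- relSubset(ped, asc$genotypedIds)
    A22 <- new("RelationshipMatrix", labels = rownames(geno), values = A22m,
               kind = "A22", provenance = list(method = "henderson-subset"))
    pP <- alleleFreqs(geno[as.character(asc$predFreqIds), , drop = FALSE])
    nP <- length(asc$predFreqIds)
    pP <- pmin(pmax(pP, 1 / (4 * nP)), 1 - 1 / (4 * nP))
    G <- buildG(geno, p = pP, freqSource = "pooled-training")
    Hinv <- blendHinv(Ainv, A22, G, tau = tau, omega = omega)
    sol <- if (scenario@model == "multi") {
      solveMultiTrait(train, Hinv, G0 = varcomp@G0, R0 = varcomp@R0)
    } else {
      solveSingleTrait(train, Hinv, .asVarcompList(varcomp))
    }
  }
  gcol <- if (scenario@model == "multi") "F1" else 1
  metrics <- do.call(rbind, lapply(names(asc$validation), function(cohort) {
    ids <- asc$validation[[cohort]]
    v <- validateGebv(sol@gebv[as.character(ids), gcol], as.numeric(tbv(pop, ids)))
    data.frame(scenario = scenario@id, cohort = cohort,
               accuracy = v[["accuracy"]], slope = v[["slope"]], n = v[["n"]],
               tau = tau, omega = omega, stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, varcomp = varcomp, solution = sol,
       weights = weights, kept = kept)
}

.asVarcompList <- function(vc) {
  if (is(vc, "VarianceComponents")) {
    if (length(vc@h2) > 1L)
      list(sigma2u = mean(diag(vc@G0)), sigma2e = mean(diag(vc@R0)))
    else list(sigma2u = vc@sigma2u, sigma2e = vc@sigma2e)
  } else vc
}

#' Grid search over the H-inverse scaling factors
#'
#' Evaluates every (tau, omega) combination on the SC1 design and selects
#' the pair minimizing |1 - slope| (slope averaged over the two validation
#' cohorts), breaking ties by higher accuracy and then by lower tau.
#' Inversions of the blended genomic matrix and of A22 are computed once and
#' reused across the grid.
#'
#' @param pop a [SimulatedPopulation-class] (the selection of the published
#'   factors used the architecture with 4,500 QTLs and QTL heritability equal
#'   to the trait heritability).
#' @param tauValues,omegaValues grid definitions (defaults 0.9-2.5 and
#'   0.5-1.2 at steps of 0.1: 17 x 8 = 136 combinations).
#' @param varcomp optional fixed variance components.
#' @param qcKept optional precomputed kept-SNP set.
#' @param remlMaxN REML record cap.
#' @return list with `surface` (tau, omega, accuracy, slope per cohort mean)
#'   and `best` (selected tau/omega row).
#' @export
tauOmegaGrid <- function(pop, tauValues = seq(0.9, 2.5, by = 0.1),
                         omegaValues = seq(0.5, 1.2, by = 0.1),
                         varcomp = NULL, qcKept = NULL, remlMaxN = 600) {
  scenario <- scenarioSpec("SC1")
  asc <- assembleScenario(pop, scenario)
  kept <- if (is.null(qcKept)) .popQc(pop)$kept else qcKept
  ped <- pop@pedigree[, c("id", "sire", "dam")]
  train <- asc$train
  if (is.null(varcomp)) {
    sub <- train
    if (nrow(sub) > remlMaxN) sub <- sub[sort(sample(nrow(sub), remlMaxN)), ]
    varcomp <- remlEstimate(sub, ped, model = "single")
  }
  vc <- .asVarcompList(varcomp)
  geno <- genotypes(pop, asc$genotypedIds, snps = kept)
  rownames(geno) <- as.character(asc$genotypedIds)
  Ainv <- buildAinv(ped)
  A22m <- relSubset(ped, asc$genotypedIds)
  pP <- alleleFreqs(geno[as.character(asc$predFreqIds), , drop = FALSE])
  nP <- length(asc$predFreqIds)
  pP <- pmin(pmax(pP, 1 / (4 * nP)), 1 - 1 / (4 * nP))
  G <- buildG(geno, p = pP)
  Gb <- 0.95 * as.matrix(relValues(G)) + 0.05 * A22m
  Gbi <- .spdInverse(Gb, "blended G")
  A22i <- .spdInverse(A22m, "A22")
  gidx <- match(rownames(geno), Ainv@labels)
  nA <- length(Ainv@labels)
  At <- as(as(Matrix::forceSymmetric(Ainv@values), "generalMatrix"),
           "TsparseMatrix")
  keepA <- At@i <= At@j
  ai <- At@j[keepA] + 1L; aj <- At@i[keepA] + 1L; ax <- At@x[keepA]
  lt <- which(lower.tri(Gbi, diag = TRUE))
  bi <- gidx[((lt - 1L) %% nrow(Gbi)) + 1L]
  bj <- gidx[((lt - 1L) %/% nrow(Gbi)) + 1L]
  rows <- list()
  for (tu in tauValues) for (om in omegaValues) {
    corr <- tu * Gbi - om * A22i
    corr <- (corr + t(corr)) / 2
    H <- Matrix::sparseMatrix(i = c(ai, pmax(bi, bj)),
                              j = c(aj, pmin(bi, bj)),
                              x = c(ax, corr[lt]),
                              dims = c(nA, nA), symmetric = TRUE)
    dimnames(H) <- list(Ainv@labels, Ainv@labels)
    Hrm <- new("RelationshipMatrix", labels = Ainv@labels, values = H,
               kind = "Hinv", provenance = list(tau = tu, omega = om))
    row <- tryCatch({
      sol <- solveSingleTrait(train, Hrm, vc)
      vals <- vapply(names(asc$validation), function(cohort) {
        ids <- asc$validation[[cohort]]
        validateGebv(sol@gebv[as.character(ids), 1], as.numeric(tbv(pop, ids)))[1:2]
      }, numeric(2))
      data.frame(tau = tu, omega = om,
                 accuracy = mean(vals[1, ]), slope = mean(vals[2, ]))
    }, error = function(e) data.frame(tau = tu, omega = om,
                                      accuracy = NA_real_, slope = NA_real_))
    rows[[length(rows) + 1L]] <- row
  }
  surface <- do.call(rbind, rows)
  ok <- which(!is.na(surface$slope))
  if (!length(ok)) stop("no grid combination solved")
  crit <- abs(1 - surface$slope[ok])
  best <- ok[order(crit, -surface$accuracy[ok], surface$tau[ok])][1]
  list(surface = surface, best = surface[best, , drop = FALSE])
}

#' Paired comparison of scenarios across replicates
#'
#' Paired Student's t-tests between all pairs of groups, paired by
#' replicate. Zero-variance difference vectors are reported as degenerate:
#' p = 1 when the groups are identical, NA otherwise.
#'
#' @param df data.frame of per-replicate results.
#' @param value name of the value column (e.g. "accuracy" or "slope").
#' @param group,replicate column names defining groups and pairing.
#' @return data.frame groupA, groupB, meanDiff, t, df, p, note.
#' @export
pairedComparison <- function(df, value = "accuracy", group = "scenario",
                             replicate = "replicate") {
  gs <- unique(df[[group]])
  out <- list()
  for (a in seq_along(gs)) for (b in seq_along(gs)) {
    if (b <= a) next
    da <- df[df[[group]] == gs[a], c(replicate, value)]
    db <- df[df[[group]] == gs[b], c(replicate, value)]
    if (!setequal(da[[replicate]], db[[replicate]]) ||
        nrow(da) != nrow(db))
      stop("pairing error: replicate sets differ between groups")
    m <- match(da[[replicate]], db[[replicate]])
    d <- da[[value]] - db[[value]][m]
    if (var(d) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        groupA = gs[a], groupB = gs[b], meanDiff = mean(d), t = NA_real_,
        df = length(d) - 1L, p = if (all(d == 0)) 1 else NA_real_,
        note = "degenerate: zero variance of differences")
      next
    }
    tt <- t.test(da[[value]], db[[value]][m], paired = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      groupA = gs[a], groupB = gs[b], meanDiff = mean(d),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, note = "")
  }
  do.call(rbind, out)
}

#' Run a replicated scenario-comparison experiment
#'
#' Simulates each replicate under its own seed, runs every requested
#' scenario on the same simulated data (so scenario comparisons are paired
#' by replicate), and aggregates accuracies and dispersion slopes per
#' (architecture, scenario, validation cohort).
#'
#' @param genome a [GenomeSpec-class].
#' @param params design list from [simParams()].
#' @param sims architecture labels to simulate.
#' @param scenarios scenario ids to evaluate.
#' @param seeds one seed per replicate.
#' @param tau,omega scaling factors used for all runs.
#' @param remlMaxN REML record cap.
#' @param varcomp optional fixed variance components (skips REML).
#' @return list with `results` (per replicate) and `summary` (mean/sd).
#' @export
runExperiment <- function(genome, params = simParams(), sims = "SIM5",
                          scenarios = paste0("SC", 1:5), seeds = 1:3,
                          tau = 2.2, omega = 0.5, remlMaxN = 1000,
                          varcomp = NULL) {
  rows <- list()
  for (seed in seeds) {
    for (sim in sims) {
      pop <- simulatePopulation(genome, sim, params, seed = seed)
      kept <- .popQc(pop)$kept
      for (sc in scenarios) {
        ev <- runEvaluation(pop, sc, tau = tau, omega = omega,
                            varcomp = varcomp, qcKept = kept,
                            remlMaxN = remlMaxN)
        m <- ev$metrics
        m$sim <- sim
        m$replicate <- seed
        rows[[length(rows) + 1L]] <- m
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- aggregate(cbind(accuracy, slope) ~ sim + scenario + cohort, results,
                   function(x) c(mean = mean(x), sd = sd(x)))
  summary <- data.frame(agg[, 1:3],
                        accuracy = agg$accuracy[, "mean"],
                        accuracySd = agg$accuracy[, "sd"],
                        slope = agg$slope[, "mean"],
                        slopeSd = agg$slope[, "sd"])
  list(results = results, summary = summary)
}
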