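#' Simulation design parameters
#'
#' Collects the population-design constants: a 1,020-generation random-mating
#' history with two bottlenecks (2,000 -> 1,500 -> 200 sampled founders), an
#' expansion population grown to `popTarget` over `popGens` generations with
#' `litterSize` offspring per female, two selected lines bred with
#' lowest-EBV truncation selection (sire/dam replacement 0.60/0.20), and four
#' F1 cohorts from Line1 dams x Line2 sires taken at the stated parental
#' generations.
#'
#' `scaleFactor` divides dam counts, the expansion target and F1 cohort
#' sizes. Historical sizes are never scaled (ancestral linkage
#' disequilibrium at a given marker spacing is set by the historical
#' effective size, which the scaled design must preserve), and line sire
#' counts are scaled but floored at `sireFloor` because the sire pool
#' dominates a line's effective size: cutting it proportionally would
#' multiply per-generation drift roughly by the scale factor's inverse and
#' destroy the LD and inbreeding behaviour of the design.
#'
#' @param scaleFactor population reduction knob in (0, 1].
#' @param histSizes,histGens sizes and lengths of the random-mating phases.
#' @param nFounders males/females sampled from the last historical
#'   generation.
#' @param popTarget,popGens,litterSize expansion design.
#' @param line1,line2 lists with `dams`, `sires`, `gens` (full-scale).
#' @param f1 list with `dams`, `sires`, and `parentGens`, a 2 x 4 matrix of
#'   (Line1, Line2) parental generations per cohort.
#' @param sireReplacement,damReplacement per-generation replacement ratios.
#' @param sireFloor minimum number of sires per line after scaling.
#' @param mu,sexEffect phenotype intercept and additive male effect
#'   (defaults 0; the evaluation models still fit sex).
#' @return list of resolved (scaled) design parameters.
#' @export
simParams <- function(scaleFactor = 0.05,
                      histSizes = c(2000, 1500), histGens = c(1000, 20),
                      nFounders = c(male = 100, female = 100),
                      popTarget = 64000, popGens = 8, litterSize = 5,
                      line1 = list(dams = 32000, sires = 640, gens = 10),
                      line2 = list(dams = 3200, sires = 64, gens = 30),
                      f1 = list(dams = 3000, sires = 60,
                                parentGens = rbind(c(7, 8, 9, 10),
                                                   c(27, 28, 29, 30))),
                      sireReplacement = 0.6, damReplacement = 0.2,
                      sireFloor = 25, mu = 0, sexEffect = 0,
                      qtlDensityScaling = FALSE) {
  if (scaleFactor <= 0 || scaleFactor > 1) stop("scaleFactor must be in (0, 1]")
  sc <- function(x, minv = 2L) max(as.integer(round(x * scaleFactor)), minv)
  ## sire floor, capped so replacement stays feasible (half the candidates
  ## born each generation are male and 60% of sires are replaced)
  scSires <- function(x, dams) min(x, as.integer(dams / 2),
                                   max(as.integer(round(x * scaleFactor)),
                                       as.integer(sireFloor)))
  list(scaleFactor = scaleFactor,
       histSizes = as.integer(histSizes), histGens = as.integer(histGens),
       nFounders = c(male = as.integer(nFounders[["male"]]),
                     female = as.integer(nFounders[["female"]])),
       popTarget = sc(popTarget, minv = 20L), popGens = as.integer(popGens),
       litterSize = as.integer(litterSize),
       line1 = list(dams = sc(line1$dams, 10L),
                    sires = scSires(line1$sires, sc(line1$dams, 10L)),
                    gens = as.integer(line1$gens)),
       line2 = list(dams = sc(line2$dams, 10L),
                    sires = scSires(line2$sires, sc(line2$dams, 10L)),
                    gens = as.integer(line2$gens)),
       f1 = list(dams = sc(f1$dams, 2L),
                 sires = min(f1$sires,
                             as.integer(sc(line2$dams, 10L) / 2),
                             max(as.integer(round(f1$sires * scaleFactor)),
                                 as.integer(sireFloor))),
                 parentGens = f1$parentGens),
       sireReplacement = sireReplacement, damReplacement = damReplacement,
       mu = mu, sexEffect = sexEffect, qtlDensityScaling = qtlDensityScaling)
}

#' Single meiosis
#'
#' Produces gametes from phased parental haplotypes: crossover counts per
#' chromosome are Poisson(length/100) with uniform positions (no
#' interference); each transmitted allele flips with probability
#' `mutationRate`.
#'
#' @param hap1,hap2 parental strands: vectors, or matrices with one row per
#'   gamete to produce.
#' @param loci data.frame `chrom`, `pos` (cM), loci grouped by chromosome in
#'   increasing position order.
#' @param chromLengths chromosome lengths in cM.
#' @param mutationRate per-locus flip probability.
#' @return gamete(s) in the same shape as the input.
#' @export
meiosis <- function(hap1, hap2, loci, chromLengths, mutationRate = 0) {
  vec <- is.null(dim(hap1))
  if (vec) { hap1 <- matrix(hap1, 1); hap2 <- matrix(hap2, 1) }
  out <- .cpp_make_gametes(hap1, hap2, as.integer(loci$chrom),
                           as.numeric(chromLengths), as.numeric(loci$pos),
                           mutationRate)
  if (vec) out[1, ] else out
}

#' Random-mating historical population
#'
#' Simulates the discrete-generation history that accumulates linkage
#' disequilibrium by drift: all loci start at allele frequency exactly 0.50,
#' then `histGens[i]` generations of random mating at constant size
#' `histSizes[i]` per phase.
#'
#' @param loci data.frame `chrom`, `pos` over all loci (markers and QTLs).
#' @param chromLengths chromosome lengths (cM).
#' @param histSizes,histGens phase sizes and lengths.
#' @param mutationRate per-locus per-generation flip rate.
#' @return list with `hap1`, `hap2` (final generation) and `sex` (1/2).
#' @export
simulateHistory <- function(loci, chromLengths, histSizes = c(2000, 1500),
                            histGens = c(1000, 20), mutationRate = 1e-5) {
  stopifnot(length(histSizes) == length(histGens))
  .cpp_sim_history(as.integer(loci$chrom), as.numeric(chromLengths),
                   as.numeric(loci$pos), mutationRate,
                   as.integer(histSizes), as.integer(histGens))
}

## ---- expansion ----------------------------------------------------------

.simExpand <- function(st, founderIds, targetSize, nGens, litterSize) {
  cur <- founderIds
  for (g in seq_len(nGens)) {
    females <- cur[st$sex[cur] == 2L]
    males <- cur[st$sex[cur] == 1L]
    if (!length(females) || !length(males))
      stop("expansion population lost one sex entirely")
    capacity <- litterSize * length(females)
    nNext <- min(capacity, targetSize)
    if (g == nGens && nNext < targetSize)
      stop(sprintf("growth insufficient to reach %d in %d generations", targetSize, nGens))
    nLitters <- ceiling(nNext / litterSize)
    moms <- sample(females, nLitters)
    litterOf <- rep(seq_len(nLitters), each = litterSize)[seq_len(nNext)]
    dam <- moms[litterOf]
    sirePerLitter <- sample(males, nLitters, replace = TRUE)
    sire <- sirePerLitter[litterOf]
    ## alternate sexes within litters: guarantees an almost exact 1:1 ratio
    sex <- as.integer(1L + (ave(litterOf, litterOf, FUN = seq_along) %% 2L))
    g1 <- .stateGametes(st, sire)
    g2 <- .stateGametes(st, dam)
    ids <- .stateAdd(st, sire, dam, sex, g, "POP", g1, g2, retain = TRUE)
    if (g > 1L) .stateDrop(st, cur)  # founders stay retained
    cur <- ids
  }
  cur
}

## ---- line breeding ------------------------------------------------------

.simBreedLine <- function(st, lineName, initSires, initDams, nSires, nDams,
                          nGens, varcomp) {
  p <- st$params
  sires <- initSires; dams <- initDams
  lineIds <- c(initSires, initDams)
  for (g in seq_len(nGens)) {
    sire <- sample(sires, nDams, replace = TRUE)
    dam <- dams  # one offspring per female
    ## balanced sexes (each offspring male or female with probability 0.5
    ## marginally; exact 1:1 keeps replacement feasible in small cohorts)
    sex <- sample(rep(1:2, length.out = nDams))
    gS <- .stateGametes(st, sire)
    gD <- .stateGametes(st, dam)
    ids <- .stateAdd(st, sire, dam, sex, g, lineName, gS, gD, retain = TRUE)
    lineIds <- c(lineIds, ids)
    if (g == nGens) break
    ## EBVs from within-line records; line founders treated as base animals
    ebv <- .lineEbv(st, lineIds, varcomp)
    cand <- ids
    candM <- cand[st$sex[cand] == 1L]
    candF <- cand[st$sex[cand] == 2L]
    nNewS <- round(p$sireReplacement * nSires)
    nNewF <- round(p$damReplacement * nDams)
    if (length(candM) < nNewS || length(candF) < nNewF)
      stop(sprintf("replacement demand exceeds candidate pool in %s generation %d",
                   lineName, g))
    ## selection keeps lowest-EBV candidates; culling removes highest-EBV parents
    newS <- candM[order(ebv[as.character(candM)])][seq_len(nNewS)]
    keepS <- sires[order(ebv[as.character(sires)])][seq_len(nSires - nNewS)]
    newF <- candF[order(ebv[as.character(candF)])][seq_len(nNewF)]
    keepF <- dams[order(ebv[as.character(dams)])][seq_len(nDams - nNewF)]
    sires <- c(keepS, newS)
    dams <- c(keepF, newF)
  }
  invisible(lineIds)
}

.lineEbv <- function(st, lineIds, varcomp) {
  inLine <- rep(FALSE, st$n)
  inLine[lineIds] <- TRUE
  sire <- st$sire[lineIds]; dam <- st$dam[lineIds]
  localPed <- data.frame(id = lineIds,
                         sire = ifelse(sire > 0 & inLine[pmax(sire, 1L)], sire, 0L),
                         dam = ifelse(dam > 0 & inLine[pmax(dam, 1L)], dam, 0L))
  rec <- data.frame(id = lineIds, y = st$phen[lineIds],
                    sex = factor(st$sex[lineIds]))
  pedigreeBlupEbv(rec, localPed, varcomp)
}

## ---- F1 -----------------------------------------------------------------

.simMakeF1 <- function(st, cohortName, cohortGen, line1Gen, line2Gen,
                       nDams, nSires) {
  allIds <- seq_len(st$n)
  damPool <- allIds[st$popn == "Line1" & st$gen == line1Gen & st$sex == 2L]
  sirePool <- allIds[st$popn == "Line2" & st$gen == line2Gen & st$sex == 1L]
  if (length(damPool) < nDams || length(sirePool) < nSires)
    stop(sprintf("requested F1 parents absent from Line1 g%d / Line2 g%d",
                 line1Gen, line2Gen))
  dams <- sample(damPool, nDams)
  sires0 <- sample(sirePool, nSires)
  sire <- sample(sires0, nDams, replace = TRUE)
  sex <- as.integer(rbinom(nDams, 1, 0.5) + 1L)
  gS <- .stateGametes(st, sire)
  gD <- .stateGametes(st, dams)
  .stateAdd(st, sire, dams, sex, cohortGen, cohortName, gS, gD, retain = TRUE)
}

#' Simulate the full breeding system
#'
#' Runs history, founder sampling, expansion, the two selected lines and the
#' four F1 cohorts under one seed, returning a [SimulatedPopulation-class].
#' Line selection uses pedigree BLUP EBVs computed each generation with the
#' true additive genetic variance; selection is for the lowest EBV, and
#' culling removes the highest-EBV parents.
#'
#' @param genome a [GenomeSpec-class].
#' @param sim trait architecture label "SIM1".."SIM5" (see
#'   [simArchitecture()]).
#' @param params design list from [simParams()].
#' @param seed integer seed; identical seed and configuration reproduce the
#'   object exactly.
#' @return a [SimulatedPopulation-class].
#' @examples
#' \donttest{
#' g <- buildGenome(1, 10, 100)
#' p <- simParams(scaleFactor = 0.005, histSizes = c(100, 80),
#'                histGens = c(50, 10))
#' pop <- simulatePopulation(g, "SIM5", p, seed = 1)
#' pop
#' }
#' @export
simulatePopulation <- function(genome, sim = "SIM5", params = simParams(),
                               seed = 1L) {
  set.seed(seed)
  trait <- simArchitecture(sim, genome,
                           qtlDensityScaling = isTRUE(params$qtlDensityScaling))
  snp <- genome@map
  loci <- rbind(data.frame(id = snp$id, chrom = snp$chrom, pos = snp$pos,
                           type = "SNP", stringsAsFactors = FALSE),
                if (trait@nQtl > 0)
                  data.frame(id = sprintf("qtl%d", seq_len(trait@nQtl)),
                             chrom = trait@qtlMap$chrom, pos = trait@qtlMap$pos,
                             type = "QTL", stringsAsFactors = FALSE))
  loci <- loci[order(loci$chrom, loci$pos), ]
  rownames(loci) <- NULL

  hist <- simulateHistory(loci, genome@chromLengths, params$histSizes,
                          params$histGens, trait@mutationRate)
  nh <- nrow(hist$hap1)
  males <- which(hist$sex == 1L); females <- which(hist$sex == 2L)
  if (length(males) < params$nFounders[["male"]] ||
      length(females) < params$nFounders[["female"]])
    stop("historical pool too small to sample the founder set")
  fm <- sample(males, params$nFounders[["male"]])
  ff <- sample(females, params$nFounders[["female"]])
  pick <- c(fm, ff)
  founderSex <- c(rep(1L, length(fm)), rep(2L, length(ff)))

  ## QTL effects are scaled to the founder cohort
  qtlCols <- which(loci$type == "QTL")
  if (trait@nQtl > 0) {
    fg <- hist$hap1[pick, qtlCols, drop = FALSE] +
          hist$hap2[pick, qtlCols, drop = FALSE]
    trait <- sampleQtlEffects(trait, fg)
  }

  st <- .newState(genome, trait, loci, params)
  nF <- length(pick)
  founderIds <- .stateAdd(st, rep(0L, nF), rep(0L, nF), founderSex, 0L, "POP",
                          hist$hap1[pick, , drop = FALSE],
                          hist$hap2[pick, , drop = FALSE],
                          retain = TRUE, founderPoly = TRUE)
  rm(hist)

  popFinal <- .simExpand(st, founderIds, st$params$popTarget, params$popGens,
                         params$litterSize)

  ## draft line founders from the final expansion generation; sex is
  ## assigned at drafting time (expansion-final animals never breed in POP)
  need <- params$line1$sires + params$line2$sires +
          params$line1$dams + params$line2$dams
  if (need > length(popFinal))
    stop("expansion population too small to found both lines")
  draft <- sample(popFinal, need)
  i <- 0L
  takeN <- function(n) { out <- draft[i + seq_len(n)]; i <<- i + n; out }
  l1S <- takeN(params$line1$sires); l2S <- takeN(params$line2$sires)
  l1D <- takeN(params$line1$dams); l2D <- takeN(params$line2$dams)
  st$sex[c(l1S, l2S)] <- 1L
  st$sex[c(l1D, l2D)] <- 2L

  varcomp <- list(sigma2u = trait@h2Total * trait@vp,
                  sigma2e = (1 - trait@h2Total) * trait@vp)
  .simBreedLine(st, "Line1", l1S, l1D, params$line1$sires, params$line1$dams,
                params$line1$gens, varcomp)
  .simBreedLine(st, "Line2", l2S, l2D, params$line2$sires, params$line2$dams,
                params$line2$gens, varcomp)

  pg <- params$f1$parentGens
  f1ids <- list()
  for (j in seq_len(ncol(pg)))
    f1ids[[paste0("F1-", j)]] <-
      .simMakeF1(st, paste0("F1-", j), j, pg[1, j], pg[2, j],
                 params$f1$dams, params$f1$sires)

  g1 <- params$line1$gens; g2 <- params$line2$gens
  fin <- .stateFinish(st)
  ped <- fin$ped
  cohorts <- c(list(
    founders = founderIds,
    POP_final = popFinal,
    Line1_train = ped$id[ped$population == "Line1" &
                         ped$generation %in% (g1 - 4):(g1 - 2)],
    Line2_train = ped$id[ped$population == "Line2" &
                         ped$generation %in% (g2 - 4):(g2 - 2)]),
    f1ids)
  cohorts$genotyped <- c(cohorts$Line1_train, cohorts$Line2_train,
                         unlist(f1ids, use.names = FALSE))

  new("SimulatedPopulation", genome = genome, trait = trait,
      pedigree = ped, loci = fin$loci, hap1 = fin$hap1, hap2 = fin$hap2,
      hapRow = fin$hapRow, tbvQtl = st$tbvQtl, tbvPoly = st$tbvPoly,
      phenotype = st$phen, cohorts = cohorts, seed = as.integer(seed))
}

#' Redraw phenotypes for a simulated population
#'
#' Phenotype = mu + sex effect + TBV(QTL) + TBV(polygenic) + residual with
#' residual variance (1 - h2) * vp. Useful for noise-limit checks and for
#' attaching phenotypes under alternative fixed effects without re-running
#' the simulation.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param mu intercept; @param sexEffect additive effect of being male.
#' @return the population with new phenotype draws.
#' @export
assignPhenotypes <- function(pop, mu = 0, sexEffect = 0) {
  s2e <- (1 - pop@trait@h2Total) * pop@trait@vp
  n <- nrow(pop@pedigree)
  pop@phenotype <- mu + sexEffect * (pop@pedigree$sex == 1L) +
    pop@tbvQtl + pop@tbvPoly + rnorm(n, 0, sqrt(s2e))
  pop
}
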