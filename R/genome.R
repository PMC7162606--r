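## Relative autosome sizes (Mb, bovine BTA1-29); used only as an allocation
## ruler, normalized to whatever total genome length is requested.
.bovineAutosomeMb <- c(158.3, 137.1, 121.4, 120.8, 121.2, 119.2, 112.6, 113.4,
                       105.7, 104.3, 107.3, 91.2, 84.2, 84.6, 85.3, 81.7, 75.2,
                       66.0, 64.1, 72.0, 71.6, 61.4, 52.5, 62.7, 42.9, 51.7,
                       45.4, 46.3, 51.5)

#' Build an evenly spaced SNP map
#'
#' Distributes `totalSnps` biallelic SNPs over `nChrom` chromosomes. Per
#' chromosome counts are proportional to chromosome length (largest-remainder
#' rounding so the counts sum exactly to `totalSnps`); within a chromosome of
#' length L carrying n SNPs, positions sit on the midpoint grid
#' (i - 0.5) * L / n so the spacing is exactly L/n cM.
#'
#' @param nChrom number of chromosomes.
#' @param genomeLengthCM total map length in cM. The default full-scale bovine
#'   panel is `buildGenome(29, 2696.54, 52886)`.
#' @param totalSnps total SNP count (>= nChrom).
#' @param scaleFactor recorded in the object for provenance; it does not alter
#'   the map (population sizes, not marker maps, are scaled).
#' @param chromLengths optional explicit per-chromosome lengths in cM; by
#'   default lengths follow a bundled bovine-autosome ruler (for nChrom == 29)
#'   or equal lengths otherwise, normalized to `genomeLengthCM`.
#' @param snpCounts optional explicit per-chromosome SNP counts.
#' @return a [GenomeSpec-class].
#' @examples
#' g <- buildGenome(2, 100, 10)
#' snpMap(g)
#' @export
buildGenome <- function(nChrom, genomeLengthCM, totalSnps, scaleFactor = 1,
                        chromLengths = NULL, snpCounts = NULL) {
  nChrom <- as.integer(nChrom)
  if (nChrom < 1L) stop("nChrom must be >= 1")
  if (!is.finite(genomeLengthCM) || genomeLengthCM <= 0)
    stop("genome length must be positive")
  totalSnps <- as.integer(totalSnps)
  if (totalSnps < nChrom) stop("need at least one SNP per chromosome")
  if (is.null(chromLengths)) {
    ruler <- if (nChrom == 29L) .bovineAutosomeMb else rep(1, nChrom)
    chromLengths <- ruler / sum(ruler) * genomeLengthCM
  } else {
    if (length(chromLengths) != nChrom) stop("chromLengths length mismatch")
    if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
    chromLengths <- chromLengths / sum(chromLengths) * genomeLengthCM
  }
  if (is.null(snpCounts)) {
    snpCounts <- .largestRemainder(chromLengths / sum(chromLengths) * totalSnps,
                                   totalSnps, minEach = 1L)
  } else {
    snpCounts <- as.integer(snpCounts)
    if (sum(snpCounts) != totalSnps) stop("snpCounts must sum to totalSnps")
  }
  map <- do.call(rbind, lapply(seq_len(nChrom), function(c) {
    n <- snpCounts[c]
    data.frame(chrom = c, pos = (seq_len(n) - 0.5) * chromLengths[c] / n)
  }))
  map <- data.frame(id = sprintf("snp%d_%d", map$chrom,
                                 ave(map$chrom, map$chrom, FUN = seq_along)),
                    chrom = map$chrom, pos = map$pos,
                    stringsAsFactors = FALSE)
  new("GenomeSpec", nChrom = nChrom, chromLengths = as.numeric(chromLengths),
      snpCounts = as.integer(snpCounts), map = map,
      scaleFactor = as.numeric(scaleFactor))
}

## integer allocation with fixed total: floor + distribute remainders
.largestRemainder <- function(target, total, minEach = 0L) {
  k <- length(target)
  base <- pmax(floor(target), minEach)
  # if the floors over/undershoot adjust by remainder ranking
  n <- as.integer(base)
  deficit <- total - sum(n)
  if (deficit > 0) {
    ord <- order(target - floor(target), decreasing = TRUE)
    i <- 0L
    while (deficit > 0) {
      j <- ord[(i %% k) + 1L]
      n[j] <- n[j] + 1L
      deficit <- deficit - 1L
      i <- i + 1L
    }
  } else if (deficit < 0) {
    ord <- order(target - floor(target))
    i <- 0L
    while (deficit < 0) {
      j <- ord[(i %% k) + 1L]
      if (n[j] > minEach) { n[j] <- n[j] - 1L; deficit <- deficit + 1L }
      i <- i + 1L
    }
  }
  n
}

#' Define a trait architecture on a genome
#'
#' The five stock architectures vary the number of QTLs and the share of the
#' heritability they explain: SIM1 (0 QTL, fully polygenic), SIM2 (198 QTL,
#' QTL heritability 0.11), SIM3 (4500 QTL, 0.11), SIM4 (198 QTL, 0.33), SIM5
#' (4500 QTL, 0.33); total h2 = 0.33 and phenotypic variance 0.13 throughout.
#' The QTL count is an architecture constant: it is kept at its stated value
#' on a reduced genome, preserving the per-locus effect-size distribution and
#' hence the polygenic response of the trait variance to selection. Set
#' `qtlDensityScaling = TRUE` to scale the count with map length instead
#' (only sensible for very small structural-test genomes).
#'
#' QTL positions are drawn uniformly along each chromosome among non-SNP map
#' positions: QTLs are not part of the genotyping panel and are observed by
#' the markers only through linkage disequilibrium.
#'
#' @param sim "SIM1".."SIM5".
#' @param genome a [GenomeSpec-class].
#' @param h2Total,vp,gammaShape,mutationRate trait constants.
#' @param qtlDensityScaling scale the QTL count with map length (default
#'   FALSE).
#' @param fullGenomeLengthCM reference length when density scaling is on.
#' @return a [TraitArchitecture-class] (effects not yet sampled).
#' @export
simArchitecture <- function(sim, genome, h2Total = 0.33, vp = 0.13,
                            gammaShape = 0.40, mutationRate = 1e-5,
                            qtlDensityScaling = FALSE,
                            fullGenomeLengthCM = 2696.54) {
  stopifnot(is(genome, "GenomeSpec"))
  sim <- match.arg(sim, c("SIM1", "SIM2", "SIM3", "SIM4", "SIM5"))
  full <- switch(sim,
    SIM1 = list(nQtl = 0L, h2Qtl = 0),
    SIM2 = list(nQtl = 198L, h2Qtl = h2Total / 3),
    SIM3 = list(nQtl = 4500L, h2Qtl = h2Total / 3),
    SIM4 = list(nQtl = 198L, h2Qtl = h2Total),
    SIM5 = list(nQtl = 4500L, h2Qtl = h2Total))
  nQtl <- full$nQtl
  if (qtlDensityScaling && nQtl > 0L) {
    frac <- sum(genome@chromLengths) / fullGenomeLengthCM
    nQtl <- max(1L, as.integer(round(nQtl * frac)))
  }
  qtlMap <- if (nQtl > 0L) .placeQtl(genome, nQtl) else
    data.frame(chrom = integer(), pos = numeric())
  new("TraitArchitecture", nQtl = nQtl, h2Total = h2Total, h2Qtl = full$h2Qtl,
      vp = vp, gammaShape = gammaShape, mutationRate = mutationRate,
      qtlMap = qtlMap, qtlEffects = numeric(), sim = sim)
}

.placeQtl <- function(genome, nQtl) {
  counts <- .largestRemainder(genome@chromLengths / sum(genome@chromLengths) * nQtl,
                              nQtl, minEach = 0L)
  out <- do.call(rbind, lapply(seq_len(genome@nChrom), function(c) {
    if (counts[c] == 0L) return(NULL)
    snpPos <- genome@map$pos[genome@map$chrom == c]
    pos <- numeric(0)
    while (length(pos) < counts[c]) {
      cand <- runif(counts[c] - length(pos), 0, genome@chromLengths[c])
      cand <- cand[!cand %in% snpPos & !cand %in% pos]
      pos <- c(pos, cand)
    }
    data.frame(chrom = c, pos = sort(pos))
  }))
  rownames(out) <- NULL
  out
}

#' Sample and scale QTL effects
#'
#' Raw effects are drawn from a gamma distribution (shape `gammaShape`) with
#' random sign, then rescaled so that the variance of QTL breeding values in
#' the supplied founder cohort equals `h2Qtl * vp`.
#'
#' @param trait a [TraitArchitecture-class].
#' @param founderQtlGeno founder allele-dosage matrix at the QTLs
#'   (individuals x QTLs).
#' @return the trait object with `qtlEffects` filled in.
#' @export
sampleQtlEffects <- function(trait, founderQtlGeno) {
  stopifnot(is(trait, "TraitArchitecture"))
  if (trait@nQtl == 0L) {
    trait@qtlEffects <- numeric(0)
    return(trait)
  }
  if (ncol(founderQtlGeno) != trait@nQtl)
    stop("founder QTL genotype matrix has wrong number of columns")
  raw <- rgamma(trait@nQtl, shape = trait@gammaShape, rate = 1) *
    sample(c(-1, 1), trait@nQtl, replace = TRUE)
  target <- trait@h2Qtl * trait@vp
  v <- var(as.numeric(founderQtlGeno %*% raw))
  if (target > 0 && v <= 0)
    stop("all founders monomorphic at all QTLs: cannot scale to the QTL variance target")
  trait@qtlEffects <- if (target == 0) raw * 0 else raw * sqrt(target / v)
  trait
}
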