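#' Marker-panel layout of a simulated genome
#'
#' Holds the chromosome lengths (cM) and an evenly spaced SNP map. Positions
#' are in centimorgans; downstream linkage-disequilibrium binning converts
#' with the 1 cM = 1 Mb convention.
#'
#' @slot nChrom number of autosomes.
#' @slot chromLengths numeric vector of chromosome lengths in cM.
#' @slot snpCounts integer vector, SNPs per chromosome.
#' @slot map data.frame with columns `id`, `chrom`, `pos` (cM), one row per
#'   SNP, grouped by chromosome with strictly increasing positions.
#' @slot scaleFactor dimensionless reduction knob recorded for provenance.
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(nChrom = "integer", chromLengths = "numeric",
                 snpCounts = "integer", map = "data.frame",
                 scaleFactor = "numeric"))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@chromLengths) != object@nChrom)
    msg <- c(msg, "chromLengths length must equal nChrom")
  if (length(object@snpCounts) != object@nChrom)
    msg <- c(msg, "snpCounts length must equal nChrom")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (nrow(object@map) != sum(object@snpCounts))
    msg <- c(msg, "map rows must equal sum(snpCounts)")
  for (c in seq_len(object@nChrom)) {
    p <- object@map$pos[object@map$chrom == c]
    if (length(p) > 1L && any(diff(p) <= 0))
      msg <- c(msg, sprintf("positions not strictly increasing on chromosome %d", c))
  }
  if (length(msg)) msg else TRUE
})

#' Trait architecture: QTL set, effects and variance targets
#'
#' @slot nQtl number of QTLs actually placed on this genome.
#' @slot h2Total total narrow-sense heritability of the trait.
#' @slot h2Qtl fraction of phenotypic variance explained by the QTL set;
#'   the remainder of the heritability is infinitesimal polygenic.
#' @slot vp phenotypic variance.
#' @slot gammaShape shape of the gamma distribution of raw QTL effects.
#' @slot mutationRate per-locus, per-generation recurrent flip rate.
#' @slot qtlMap data.frame `chrom`, `pos` (cM) of QTLs.
#' @slot qtlEffects additive allele-substitution effects (may be empty until
#'   [sampleQtlEffects()] has been run).
#' @slot sim label of the architecture ("SIM1".."SIM5" or custom).
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(nQtl = "integer", h2Total = "numeric", h2Qtl = "numeric",
                 vp = "numeric", gammaShape = "numeric",
                 mutationRate = "numeric", qtlMap = "data.frame",
                 qtlEffects = "numeric", sim = "character"))

setValidity("TraitArchitecture", function(object) {
  msg <- character()
  if (object@h2Qtl < 0 || object@h2Total > 1 || object@h2Qtl > object@h2Total)
    msg <- c(msg, "need 0 <= h2Qtl <= h2Total <= 1")
  if (object@vp <= 0) msg <- c(msg, "vp must be positive")
  if (nrow(object@qtlMap) != object@nQtl)
    msg <- c(msg, "qtlMap rows must equal nQtl")
  if (length(object@qtlEffects) &&
      length(object@qtlEffects) != object@nQtl)
    msg <- c(msg, "qtlEffects length must equal nQtl (or be empty)")
  if (length(msg)) msg else TRUE
})

#' A simulated multi-population breeding system
#'
#' Container for the pedigree, phased haplotypes of retained animals, true
#' breeding values, phenotypes and cohort membership produced by
#' [simulatePopulation()]. Haplotypes are kept only for animals that are
#' parents of recorded cohorts or members of analysis cohorts; `hapRow` maps
#' pedigree rows to haplotype rows (NA when dropped).
#'
#' @slot genome a [GenomeSpec-class].
#' @slot trait a [TraitArchitecture-class] with realized effects.
#' @slot pedigree data.frame `id, sire, dam, sex, generation, population`
#'   (0 = unknown parent; sex 1 = male, 2 = female), parents before offspring.
#' @slot loci data.frame `id, chrom, pos, type` over SNPs and QTLs in map
#'   order (haplotype column order).
#' @slot hap1,hap2 integer matrices, one row per retained animal.
#' @slot hapRow integer vector, pedigree row -> haplotype row.
#' @slot tbvQtl,tbvPoly,phenotype numeric vectors along pedigree rows.
#' @slot cohorts named list of pedigree id vectors.
#' @slot seed the seed the run was generated under.
#' @exportClass SimulatedPopulation
setClass("SimulatedPopulation",
  representation(genome = "GenomeSpec", trait = "TraitArchitecture",
                 pedigree = "data.frame", loci = "data.frame",
                 hap1 = "matrix", hap2 = "matrix", hapRow = "integer",
                 tbvQtl = "numeric", tbvPoly = "numeric",
                 phenotype = "numeric", cohorts = "list", seed = "integer"))

setValidity("SimulatedPopulation", function(object) {
  ped <- object@pedigree
  msg <- character()
  n <- nrow(ped)
  idx <- match(ped$sire, ped$id)
  if (any(!is.na(idx) & idx >= seq_len(n))) msg <- c(msg, "sire after offspring")
  idx <- match(ped$dam, ped$id)
  if (any(!is.na(idx) & idx >= seq_len(n))) msg <- c(msg, "dam after offspring")
  if (length(object@hapRow) != n) msg <- c(msg, "hapRow length != pedigree rows")
  if (ncol(object@hap1) != nrow(object@loci))
    msg <- c(msg, "haplotype columns != loci rows")
  if (length(msg)) msg else TRUE
})

#' Labeled relationship matrix with provenance
#'
#' @slot labels ordered individual ids (as character).
#' @slot values dense base matrix or sparse [Matrix::Matrix] (for inverses).
#' @slot kind one of "A", "A22", "G", "Gblend", "Ainv", "Hinv".
#' @slot provenance list of construction parameters (allele-frequency source,
#'   weight source, tau, omega, blend shares, ...).
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(labels = "character", values = "ANY", kind = "character",
                 provenance = "list"))

setValidity("RelationshipMatrix", function(object) {
  d <- dim(object@values)
  if (d[1] != d[2]) return("matrix must be square")
  if (length(object@labels) != d[1]) return("labels must match dimension")
  if (!object@kind %in% c("A", "A22", "G", "Gblend", "Ainv", "Hinv"))
    return("unknown kind")
  TRUE
})

#' Variance components from REML
#'
#' For the single-trait model `sigma2u`/`sigma2e` are scalars; for the
#' three-trait (Line1, Line2, F1) model `G0` is the 3x3 additive covariance
#' matrix and `R0` the diagonal residual matrix (records are measured on
#' different animals, so residual covariances are structurally zero).
#'
#' @slot sigma2u,sigma2e numeric.
#' @slot G0,R0 matrices (possibly 1x1).
#' @slot h2 derived heritabilities per trait.
#' @slot rg genetic correlation matrix.
#' @slot converged logical; `iterations` count; `boundary` flag set when a
#'   variance was pinned at the lower bound; `logLik` restricted log-likelihood.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigma2u = "numeric", sigma2e = "numeric",
                 G0 = "matrix", R0 = "matrix", h2 = "numeric", rg = "matrix",
                 converged = "logical", iterations = "integer",
                 boundary = "logical", logLik = "numeric"))

#' Training-population scenario definition
#'
#' Encodes the five evaluated designs: which cohorts contribute training
#' phenotypes, the statistical model, the evaluation method, and (for
#' weighted runs) the population whose SNP solutions drive the weights.
#'
#' @slot id "SC1".."SC5".
#' @slot training character vector of cohort names contributing phenotypes.
#' @slot model "single" or "multi".
#' @slot method "ssGBLUP" or "WssGBLUP".
#' @slot weightSource "pooled", "crossbred", "purebred" or "none".
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(id = "character", training = "character", model = "character",
                 method = "character", weightSource = "character"))

#' Per-SNP weights for weighted single-step GBLUP
#'
#' @slot weights nonnegative per-SNP values (diagonal of D), mean 1 after
#'   normalization.
#' @slot snpIds SNP labels.
#' @slot sourcePopulation which animals' SNP solutions produced the weights.
#' @slot iteration 1 = identity, 2 = weighted.
#' @slot normalization note on the scaling applied.
#' @exportClass SnpWeightSet
setClass("SnpWeightSet",
  representation(weights = "numeric", snpIds = "character",
                 sourcePopulation = "character", iteration = "integer",
                 normalization = "character"))

setValidity("SnpWeightSet", function(object) {
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (length(object@snpIds) != length(object@weights))
    return("snpIds/weights length mismatch")
  TRUE
})
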