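#' SNP filters and cross-population intersection
#'
#' Quality control mirrors the standard pre-evaluation pipeline: per
#' population a SNP is kept when its minor allele frequency is strictly above
#' `maf` and its departure from Hardy-Weinberg equilibrium (absolute
#' difference between observed and expected heterozygote frequency) is
#' strictly below `hweDev`; only SNPs passing in every population are kept.
#'
#' @param geno dosage matrix (individuals x SNPs) for one population.
#' @param maf minor-allele-frequency threshold (strict, default 0.05).
#' @return character vector of kept SNP ids (colnames), in map order.
#' @export
mafFilter <- function(geno, maf = 0.05) {
  if (!nrow(geno) || !ncol(geno)) stop("empty genotype matrix")
  if (maf < 0 || maf >= 0.5) stop("maf threshold must be in [0, 0.5)")
  p <- alleleFreqs(geno)
  keep <- pmin(p, 1 - p) > maf
  .snpIds(geno)[keep]
}

#' @rdname mafFilter
#' @param hweDev maximum absolute deviation of the heterozygote frequency
#'   from 2p(1-p) (strict, default 0.15).
#' @export
hweDepartureFilter <- function(geno, hweDev = 0.15) {
  if (!nrow(geno) || !ncol(geno)) stop("empty genotype matrix")
  if (hweDev <= 0 || hweDev >= 1) stop("hweDev must be in (0, 1)")
  p <- alleleFreqs(geno)
  hObs <- colMeans(geno == 1L)
  keep <- abs(hObs - 2 * p * (1 - p)) < hweDev
  .snpIds(geno)[keep]
}

.snpIds <- function(geno) {
  if (is.null(colnames(geno))) as.character(seq_len(ncol(geno))) else colnames(geno)
}

#' @rdname mafFilter
#' @param ... two or more kept-SNP id vectors (or a single list of them).
#' @export
intersectPopulations <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2L) stop("need at least two populations to intersect")
  out <- Reduce(intersect, sets)
  if (!length(out)) warning("no SNPs common to all populations")
  out
}

#' Run per-population QC and intersect
#'
#' @param genoList named list of per-population dosage matrices (same SNP
#'   columns).
#' @param maf,hweDev thresholds, see [mafFilter()].
#' @return list with `kept` (common SNP ids, map order) and `report`
#'   (data.frame: population, nInput, nMafFail, nHweFail, nKept).
#' @export
qcPipeline <- function(genoList, maf = 0.05, hweDev = 0.15) {
  stopifnot(is.list(genoList), length(genoList) >= 1L)
  perPop <- lapply(names(genoList), function(nm) {
    g <- genoList[[nm]]
    ids <- .snpIds(g)
    keptMaf <- mafFilter(g, maf)
    keptHwe <- hweDepartureFilter(g, hweDev)
    kept <- intersect(keptMaf, keptHwe)
    ## a SNP failing both is counted once, MAF first
    nMafFail <- length(ids) - length(keptMaf)
    nHweFail <- length(setdiff(keptMaf, kept))
    data.frame(population = nm, nInput = length(ids), nMafFail = nMafFail,
               nHweFail = nHweFail, nKept = length(kept),
               stringsAsFactors = FALSE)
  })
  keptSets <- lapply(genoList, function(g)
    intersect(mafFilter(g, maf), hweDepartureFilter(g, hweDev)))
  kept <- if (length(keptSets) >= 2L) intersectPopulations(keptSets) else keptSets[[1]]
  ## preserve map (column) order of the first matrix
  ids0 <- .snpIds(genoList[[1]])
  kept <- ids0[ids0 %in% kept]
  list(kept = kept, report = do.call(rbind, perPop))
}
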