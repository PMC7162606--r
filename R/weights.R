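#' Back-solve SNP effects from GEBVs
#'
#' u_hat = lambda * D * Z' * Ginv * gebv with Z = M - 2p and lambda the
#' SNP-to-genetic variance ratio, which for the VanRaden scale parameter
#' k = 2 * sum p(1-p) is 1/k. With the same D and frequencies, Z %*% u_hat
#' reconstructs the genomic part of the GEBVs exactly.
#'
#' For numerical stability the inverse is taken of the blended matrix
#' 0.95 G + 0.05 A22 when `A22` is supplied (G itself is singular whenever
#' there are more animals than markers or duplicated genotypes). SNPs
#' monomorphic in the source population get effect 0 with a warning.
#'
#' @param gebv named GEBV vector of the (genotyped) weight-source animals.
#' @param geno dosage matrix for the same animals (rows aligned to `gebv`).
#' @param p allele frequencies (default: from `geno`).
#' @param weights current per-SNP weights (diagonal of D), default identity.
#' @param A22 optional pedigree relationship block for blending, labels
#'   aligned to `geno` rows.
#' @param lambda SNP-to-genetic variance ratio; default 1/k.
#' @return named vector of SNP effects.
#' @export
backsolveSnpEffects <- function(gebv, geno, p = NULL, weights = NULL,
                                A22 = NULL, lambda = NULL) {
  if (nrow(geno) != length(gebv)) stop("gebv/genotype dimension mismatch")
  if (is.null(p)) p <- alleleFreqs(geno)
  if (is.null(weights)) weights <- rep(1, ncol(geno))
  mono <- p <= 0 | p >= 1
  if (any(mono))
    warning(sprintf("%d SNP(s) monomorphic in the weight-source population; effects set to 0",
                    sum(mono)))
  use <- !mono
  k <- 2 * sum(p[use] * (1 - p[use]))
  if (k <= 0) stop("scale parameter k is zero")
  if (is.null(lambda)) lambda <- 1 / k
  Z <- sweep(geno[, use, drop = FALSE], 2L, 2 * p[use], "-")
  ZD <- sweep(Z, 2L, weights[use], "*")
  G <- tcrossprod(ZD, Z) / k
  M <- if (!is.null(A22)) {
    A22v <- if (is(A22, "RelationshipMatrix")) as.matrix(relValues(A22)) else A22
    0.95 * G + 0.05 * A22v
  } else G
  Gi <- .spdInverse((M + t(M)) / 2, "genomic relationship matrix for back-solving")
  u <- numeric(ncol(geno))
  u[use] <- lambda * weights[use] * as.numeric(crossprod(Z, Gi %*% gebv))
  names(u) <- colnames(geno)
  u
}

#' SNP variance weights from SNP effects
#'
#' d_j = u_hat_j^2 * 2 p_j (1 - p_j), normalized to mean 1 so the total
#' genetic variance scale is stable across weighting iterations.
#'
#' @param effects per-SNP effect estimates.
#' @param p allele frequencies aligned to `effects`.
#' @param sourcePopulation label stored in the result.
#' @param normalize normalize to mean 1 (default TRUE).
#' @return a [SnpWeightSet-class] (iteration 2).
#' @export
snpWeights <- function(effects, p, sourcePopulation = "unspecified",
                       normalize = TRUE) {
  if (length(effects) != length(p)) stop("effects/frequency length mismatch")
  bad <- p <= 0 | p >= 1
  if (any(bad)) warning(sprintf("%d SNP(s) with boundary allele frequency get weight 0",
                                sum(bad)))
  d <- effects^2 * 2 * p * (1 - p)
  d[bad] <- 0
  note <- "raw"
  if (normalize) {
    m <- mean(d)
    if (m > 0) { d <- d / m; note <- "mean-1" }
    else warning("all weights zero; normalization skipped")
  }
  ids <- names(effects)
  if (is.null(ids)) ids <- as.character(seq_along(effects))
  new("SnpWeightSet", weights = as.numeric(d), snpIds = ids,
      sourcePopulation = sourcePopulation, iteration = 2L,
      normalization = note)
}

#' Weighted single-step GBLUP with iterative SNP weights
#'
#' Iteration 1 is plain single-step GBLUP (identity SNP weights); iteration
#' 2 derives per-SNP variances from the back-solved SNP effects of the
#' designated weight-source animals, rebuilds G (and the blended H-inverse)
#' with those weights, and re-solves. The two-iteration schedule (identity
#' plus one weighted pass) is the default.
#'
#' @param train data.frame `id`, `y` and fixed-effect columns (training
#'   records only).
#' @param ped full pedigree.
#' @param geno post-QC dosage matrix over the genotyped animals entering the
#'   genomic matrix (rownames = ids).
#' @param genoWeight dosage matrix of the weight-source animals (rownames =
#'   ids); defaults to `geno`. The weight-source animals need not be part of
#'   the genomic matrix: in the purebred-training designs the crossbred
#'   weight animals receive their iteration-1 GEBVs through the pedigree.
#' @param predFreq allele frequencies parameterizing the prediction G (SC4
#'   uses crossbred frequencies, SC5 purebred, SC3 the pooled training set);
#'   default: frequencies of `geno` itself.
#' @param varcomp list/object with `sigma2u`, `sigma2e`.
#' @param tau,omega H-inverse scaling factors.
#' @param nIterations 1 (= plain ssGBLUP) or 2.
#' @param fixed fixed-effect formula for [solveSingleTrait()].
#' @param freqSource label recorded in provenance.
#' @return list with `solution` (final [MMESolution-class]), `weights`
#'   ([SnpWeightSet-class] or NULL), `iteration1` (the identity-weight
#'   solution).
#' @export
wssgblupRun <- function(train, ped, geno, genoWeight = geno, predFreq = NULL,
                        varcomp, tau = 2.2, omega = 0.5, nIterations = 2,
                        fixed = NULL, freqSource = "pooled") {
  if (!nIterations %in% 1:2) stop("nIterations must be 1 or 2")
  if (!nrow(genoWeight))
    stop("weight-source population has no genotyped animals")
  Ainv <- buildAinv(ped)
  gIds <- rownames(geno)
  A22m <- relSubset(ped, gIds)
  A22 <- new("RelationshipMatrix", labels = gIds, values = A22m, kind = "A22",
             provenance = list(method = "henderson-subset"))
  pPred <- if (is.null(predFreq)) alleleFreqs(geno) else predFreq
  ## guard against loci fixed in the frequency-source subset
  nFreq <- max(nrow(geno), nrow(genoWeight))
  pPred <- pmin(pmax(pPred, 1 / (4 * nFreq)), 1 - 1 / (4 * nFreq))
  G1 <- buildG(geno, p = pPred, freqSource = freqSource)
  H1 <- blendHinv(Ainv, A22, G1, tau = tau, omega = omega)
  sol1 <- solveSingleTrait(train, H1, varcomp, fixed = fixed)
  if (nIterations == 1L)
    return(list(solution = sol1, weights = NULL, iteration1 = sol1))
  weightIds <- rownames(genoWeight)
  gsrc <- sol1@gebv[weightIds, 1]
  pSrc <- alleleFreqs(genoWeight)
  A22src <- relSubset(ped, weightIds)
  u <- backsolveSnpEffects(gsrc, genoWeight, p = pSrc, A22 = A22src)
  w <- snpWeights(u, pSrc, sourcePopulation = freqSource)
  G2 <- buildG(geno, p = pPred, weights = w@weights, freqSource = freqSource)
  H2 <- blendHinv(Ainv, A22, G2, tau = tau, omega = omega)
  sol2 <- solveSingleTrait(train, H2, varcomp, fixed = fixed)
  list(solution = sol2, weights = w, iteration1 = sol1)
}
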