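#' Linkage disequilibrium between two loci from phased haplotypes
#'
#' D = f(AB) - f(A) f(B); r2 = D^2 / (f(A) f(a) f(B) f(b)); the signed r is
#' sqrt(r2) carrying the sign of D. Signed r flips sign when one locus's
#' allele labels flip; r2 is invariant.
#'
#' @param haps haplotype matrix (one row per haplotype, 0/1 alleles).
#' @param i,j column indices of the two loci.
#' @return list with `D`, `r`, `r2`.
#' @export
ldR2 <- function(haps, i, j) {
  pA <- mean(haps[, i]); pB <- mean(haps[, j])
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("LD undefined for a monomorphic locus")
  D <- mean(haps[, i] * haps[, j]) - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  r <- D / sqrt(den)
  list(D = D, r = r, r2 = r^2)
}

## vectorized signed r for a set of locus pairs; monomorphic pairs -> NA
.signedR <- function(haps, pairI, pairJ) {
  p <- colMeans(haps)
  num <- colMeans(haps[, pairI, drop = FALSE] * haps[, pairJ, drop = FALSE]) -
    p[pairI] * p[pairJ]
  den <- p[pairI] * (1 - p[pairI]) * p[pairJ] * (1 - p[pairJ])
  out <- rep(NA_real_, length(pairI))
  ok <- den > 0
  out[ok] <- num[ok] / sqrt(den[ok])
  out
}

#' Mean adjacent-SNP r2
#'
#' Average r2 over pairs of adjacent SNPs whose map distance does not exceed
#' `maxDistCM` (the design places SNPs 0.05 cM apart, so the default keeps
#' exactly the adjacent pairs). Monomorphic loci are excluded and counted.
#'
#' @param haps haplotype matrix over SNP columns.
#' @param map data.frame `chrom`, `pos` aligned to the columns of `haps`.
#' @param maxDistCM distance cap in cM.
#' @return list with `meanR2`, `nPairs`, `nExcluded`.
#' @export
adjacentLdProfile <- function(haps, map, maxDistCM = 0.05) {
  m <- ncol(haps)
  if (nrow(map) != m) stop("map/haplotype mismatch")
  i <- seq_len(m - 1L); j <- i + 1L
  same <- map$chrom[i] == map$chrom[j] &
    (map$pos[j] - map$pos[i]) <= maxDistCM + 1e-9
  i <- i[same]; j <- j[same]
  if (!length(i)) stop("no adjacent SNP pairs within the distance cap")
  r <- .signedR(haps, i, j)
  list(meanR2 = mean(r^2, na.rm = TRUE), nPairs = sum(!is.na(r)),
       nExcluded = sum(is.na(r)))
}

#' Consistency of gametic phase between two populations
#'
#' Signed r is computed per population for every SNP pair within the largest
#' bin, pairs are sorted into physical-distance bins (1 cM = 1 Mb), and the
#' per-bin Pearson correlation of signed r between the populations is
#' reported. Pairs monomorphic in either population are dropped; bins with
#' fewer than 3 pairs report NA.
#'
#' Allele orientation follows the standard genotype-analysis tooling the
#' published workflow relies on: with `orient = "minor"` (default) each
#' population labels its own minor allele as the counted allele before
#' signing r, so a locus whose minor allele differs between the populations
#' contributes with opposite sign. `orient = "asIs"` keeps the allele labels
#' of the input haplotypes (a shared, pedigree-consistent labeling).
#'
#' @param hapsA,hapsB haplotype matrices over the same SNP columns.
#' @param map data.frame `chrom`, `pos` (cM) aligned to columns.
#' @param binEdgesKb increasing bin edges in kb (default 60-kb bins to 1.02
#'   Mb, so the first bin is the 0-60 kb headline bin).
#' @param orient "minor" or "asIs", see above.
#' @return data.frame `binStartKb`, `binEndKb`, `correlation`, `nPairs`.
#' @export
phaseConsistency <- function(hapsA, hapsB, map,
                             binEdgesKb = seq(0, 1020, by = 60),
                             orient = c("minor", "asIs")) {
  orient <- match.arg(orient)
  m <- ncol(hapsA)
  if (ncol(hapsB) != m || nrow(map) != m)
    stop("populations must share the same SNP columns")
  if (orient == "minor") {
    hapsA <- .orientMinor(hapsA)
    hapsB <- .orientMinor(hapsB)
  }
  maxKb <- max(binEdgesKb)
  pairs <- .pairsWithin(map, maxKb / 1000)
  rA <- .signedR(hapsA, pairs$i, pairs$j)
  rB <- .signedR(hapsB, pairs$i, pairs$j)
  distKb <- (map$pos[pairs$j] - map$pos[pairs$i]) * 1000
  bin <- cut(distKb, breaks = binEdgesKb, include.lowest = TRUE, right = TRUE)
  ok <- !is.na(rA) & !is.na(rB)
  out <- data.frame(binStartKb = head(binEdgesKb, -1),
                    binEndKb = binEdgesKb[-1],
                    correlation = NA_real_, nPairs = 0L)
  for (b in seq_len(nrow(out))) {
    sel <- ok & as.integer(bin) == b
    out$nPairs[b] <- sum(sel)
    if (sum(sel) >= 3L) out$correlation[b] <- cor(rA[sel], rB[sel])
  }
  out
}

## flip columns so the counted allele is the population's minor allele
.orientMinor <- function(haps) {
  flip <- colMeans(haps) > 0.5
  if (any(flip)) haps[, flip] <- 1L - haps[, flip, drop = FALSE]
  haps
}

## all intra-chromosome pairs with distance <= maxDistCM
.pairsWithin <- function(map, maxDistCM) {
  i <- integer(); j <- integer()
  for (c in unique(map$chrom)) {
    idx <- which(map$chrom == c)
    pos <- map$pos[idx]
    for (off in seq_len(length(idx) - 1L)) {
      sel <- seq_len(length(idx) - off)
      keep <- (pos[sel + off] - pos[sel]) <= maxDistCM + 1e-9
      if (!any(keep)) break
      i <- c(i, idx[sel[keep]]); j <- c(j, idx[sel[keep] + off])
    }
  }
  list(i = i, j = j)
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of G; per-animal scores are eigenvectors scaled by the
#' square root of their (nonnegative part of the) eigenvalues, and the
#' variance-explained fractions are eigenvalues over their sum.
#'
#' @param G a [RelationshipMatrix-class] of kind "G" or a symmetric matrix.
#' @param nComp number of components to return scores for.
#' @return list with `scores` (animals x nComp), `varExplained` (all
#'   fractions, summing to 1), `values` (eigenvalues).
#' @export
pcaOfG <- function(G, nComp = 2) {
  M <- if (is(G, "RelationshipMatrix")) as.matrix(relValues(G)) else as.matrix(G)
  if (any(!is.finite(M))) stop("non-finite entries in G")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  nComp <- min(nComp, ncol(M))
  sc <- e$vectors[, seq_len(nComp), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(nComp)], 0)), nComp)
  rownames(sc) <- rownames(M)
  colnames(sc) <- paste0("PC", seq_len(nComp))
  list(scores = sc, varExplained = e$values / sum(e$values), values = e$values)
}

#' Allele-frequency correlation between two populations
#'
#' Pearson correlation of allele-A frequencies over the common SNPs. With
#' `orient = "minor"` (default, matching the per-population frequency
#' reports of the standard tooling) allele A is each population's own minor
#' allele; "asIs" correlates the counted-allele frequencies as given.
#'
#' @param genoA,genoB dosage matrices with SNP colnames (or plain frequency
#'   vectors with names).
#' @param orient "minor" or "asIs".
#' @return the correlation.
#' @export
alleleFreqCorrelation <- function(genoA, genoB, orient = c("minor", "asIs")) {
  orient <- match.arg(orient)
  pA <- if (is.matrix(genoA)) alleleFreqs(genoA) else genoA
  pB <- if (is.matrix(genoB)) alleleFreqs(genoB) else genoB
  common <- intersect(names(pA), names(pB))
  if (length(common) < 3L) stop("need at least 3 common SNPs")
  pA <- pA[common]; pB <- pB[common]
  if (orient == "minor") {
    pA <- pmin(pA, 1 - pA)
    pB <- pmin(pB, 1 - pB)
  }
  cor(pA, pB)
}
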