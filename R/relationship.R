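#' Allele frequencies of the counted allele
#'
#' @param geno allele-dosage matrix (individuals x SNPs, coded 0/1/2).
#' @return per-SNP frequency of the counted allele.
#' @export
alleleFreqs <- function(geno) colMeans(geno) / 2

#' VanRaden genomic relationship matrix
#'
#' G = Z D Z' / k with Z = M - P, P columns equal to twice the allele
#' frequency, and k = 2 * sum_j p_j (1 - p_j). Plain single-step GBLUP uses
#' identity SNP weights (D = I); weighted runs pass per-SNP variances.
#'
#' @param geno dosage matrix (individuals x SNPs), rownames = animal ids.
#' @param p allele frequencies of the counted allele; the source population
#'   is an analysis choice (training purebreds, crossbreds, or pooled) and is
#'   recorded in the provenance. Default: frequencies of `geno` itself.
#' @param weights per-SNP nonnegative weights (diagonal of D), default 1.
#' @param freqSource label recorded in provenance.
#' @return a [RelationshipMatrix-class] of kind "G".
#' @export
buildG <- function(geno, p = NULL, weights = NULL, freqSource = "self") {
  if (is.null(rownames(geno)))
    rownames(geno) <- as.character(seq_len(nrow(geno)))
  if (is.null(p)) p <- alleleFreqs(geno)
  if (length(p) != ncol(geno)) stop("allele frequency length mismatch")
  if (any(p <= 0 | p >= 1))
    stop("degenerate locus: allele frequencies must lie strictly in (0,1) after QC")
  if (is.null(weights)) weights <- rep(1, ncol(geno))
  if (length(weights) != ncol(geno)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  k <- 2 * sum(p * (1 - p))
  if (k <= 0) stop("scale parameter k is zero")
  Z <- sweep(geno, 2L, 2 * p, "-")
  G <- tcrossprod(sweep(Z, 2L, weights, "*"), Z) / k
  G <- (G + t(G)) / 2
  lab <- rownames(geno)
  dimnames(G) <- list(lab, lab)
  new("RelationshipMatrix", labels = lab, values = G, kind = "G",
      provenance = list(freqSource = freqSource, k = k,
                        weighted = !all(weights == 1)))
}

#' Blend G with A22 and assemble the single-step H-inverse
#'
#' The genotyped-block correction of the hybrid relationship matrix:
#' H^-1 = A^-1 + [0 0; 0 tau * (gShare*G + aShare*A22)^-1 - omega * A22^-1].
#' Blending (default 0.95 G + 0.05 A22) is applied before inversion; tau
#' scales the blended-G inverse and omega the A22 inverse, tuning the
#' compatibility of genomic and pedigree information.
#'
#' @param Ainv [RelationshipMatrix-class] "Ainv" over the full pedigree.
#' @param A22 [RelationshipMatrix-class] "A22" over genotyped animals.
#' @param G [RelationshipMatrix-class] "G" over the same animals (same order).
#' @param tau,omega scaling factors; accepted within `bounds`.
#' @param gShare,aShare blend shares (must sum to 1).
#' @param bounds list with `tau` and `omega` ranges; defaults to the grid
#'   limits tau in [0.9, 2.5], omega in [0.5, 1.2]. Pass NULL to skip the
#'   range check (used by algebraic identity tests).
#' @return a [RelationshipMatrix-class] of kind "Hinv" (sparse + dense block).
#' @export
blendHinv <- function(Ainv, A22, G, tau = 1, omega = 1,
                      gShare = 0.95, aShare = 0.05,
                      bounds = list(tau = c(0.9, 2.5), omega = c(0.5, 1.2))) {
  stopifnot(is(Ainv, "RelationshipMatrix"), is(A22, "RelationshipMatrix"),
            is(G, "RelationshipMatrix"))
  if (abs(gShare + aShare - 1) > 1e-12) stop("blend shares must sum to 1")
  if (!is.null(bounds)) {
    if (tau < bounds$tau[1] || tau > bounds$tau[2])
      stop(sprintf("tau = %g outside grid bounds [%g, %g]", tau,
                   bounds$tau[1], bounds$tau[2]))
    if (omega < bounds$omega[1] || omega > bounds$omega[2])
      stop(sprintf("omega = %g outside grid bounds [%g, %g]", omega,
                   bounds$omega[1], bounds$omega[2]))
  }
  if (!identical(A22@labels, G@labels))
    stop("A22 and G must be over the same animals in the same order")
  gidx <- match(G@labels, Ainv@labels)
  if (anyNA(gidx)) stop("genotyped animals missing from Ainv")
  Gb <- gShare * as.matrix(G@values) + aShare * as.matrix(A22@values)
  Gbi <- .spdInverse(Gb, "blended G")
  rm(Gb)
  A22i <- .spdInverse(as.matrix(A22@values), "A22")
  corr <- tau * Gbi - omega * A22i
  rm(Gbi, A22i)
  corr <- (corr + t(corr)) / 2
  n <- length(Ainv@labels)
  ## assemble the symmetric H directly from one triangle: the pedigree part
  ## plus the genotyped-block correction, duplicate entries summed
  At <- as(as(Matrix::forceSymmetric(Ainv@values), "generalMatrix"),
           "TsparseMatrix")
  keepA <- At@i <= At@j
  lt <- which(lower.tri(corr, diag = TRUE))
  bi <- gidx[((lt - 1L) %% nrow(corr)) + 1L]   # row index within the block
  bj <- gidx[((lt - 1L) %/% nrow(corr)) + 1L]  # column index
  H <- Matrix::sparseMatrix(
    i = c(At@j[keepA] + 1L, pmax(bi, bj)),
    j = c(At@i[keepA] + 1L, pmin(bi, bj)),
    x = c(At@x[keepA], corr[lt]),
    dims = c(n, n), symmetric = TRUE)
  rm(At, corr)
  dimnames(H) <- list(Ainv@labels, Ainv@labels)
  new("RelationshipMatrix", labels = Ainv@labels, values = H, kind = "Hinv",
      provenance = list(tau = tau, omega = omega, gShare = gShare,
                        aShare = aShare, genotyped = G@labels,
                        freqSource = G@provenance$freqSource))
}

## symmetric positive-definite inverse with a diagnostic fallback
.spdInverse <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3e)",
                 what, min(ev)))
  }
  chol2inv(ch)
}
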