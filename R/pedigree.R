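## Pedigree machinery. A pedigree is a data.frame with integer-like `id`,
## `sire`, `dam` (0 = unknown), parents appearing before offspring.

.checkPed <- function(ped) {
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree needs id, sire, dam columns")
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(ped$sire != 0 & is.na(si)) || any(ped$dam != 0 & is.na(di)))
    stop("pedigree refers to unknown parent ids")
  if (any(!is.na(si) & si >= seq_len(n)) || any(!is.na(di) & di >= seq_len(n)))
    stop("pedigree not sorted parents-before-offspring (possible cycle)")
  list(sire = ifelse(is.na(si), 0L, si), dam = ifelse(is.na(di), 0L, di))
}

#' Inbreeding coefficients from a pedigree
#'
#' Exact F from Henderson's decomposition A = T D T': the diagonal of A is
#' computed generation-batch-wise by sparse triangular solves, with the
#' Mendelian-sampling variances D updated level by level (an animal's D
#' needs only its parents' F). Founders get F = 0 and an animal with one
#' unknown parent is treated as having an unrelated, non-inbred phantom
#' parent. Scales to deep, fully recorded pedigrees where the classical
#' ancestor-list recursion degrades.
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`; 0 = unknown),
#'   parents before offspring.
#' @return numeric vector of F along pedigree rows, named by id.
#' @export
inbreeding <- function(ped) {
  p <- .checkPed(ped)
  n <- nrow(ped)
  lev <- integer(n)
  for (i in seq_len(n)) {
    ls <- if (p$sire[i] > 0) lev[p$sire[i]] else 0L
    ld <- if (p$dam[i] > 0) lev[p$dam[i]] else 0L
    lev[i] <- 1L + max(ls, ld)
  }
  ImP <- .imp(p, n)
  Tt <- as(Matrix::t(ImP), "triangularMatrix")
  F <- numeric(n)
  d <- numeric(n)
  for (l in sort(unique(lev))) {
    idx <- which(lev == l)
    Fs <- ifelse(p$sire[idx] > 0, F[pmax(p$sire[idx], 1L)], NA_real_)
    Fd <- ifelse(p$dam[idx] > 0, F[pmax(p$dam[idx], 1L)], NA_real_)
    d[idx] <- .mendelD(Fs, Fd)
    if (l == 1L) { F[idx] <- 0; next }
    E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                              dims = c(n, length(idx)))
    W <- as(Matrix::solve(Tt, E), "CsparseMatrix")
    ## column sums of d-weighted squared loadings, on the slots directly
    v <- W@x * W@x * d[W@i + 1L]
    cs <- c(0, cumsum(v))
    F[idx] <- (cs[W@p[-1L] + 1L] - cs[W@p[-length(W@p)] + 1L]) - 1
  }
  names(F) <- as.character(ped$id)
  F
}

.mendelD <- function(Fs, Fd) {
  ifelse(!is.na(Fs) & !is.na(Fd), 0.5 - 0.25 * (Fs + Fd),
  ifelse(!is.na(Fs), 0.75 - 0.25 * Fs,
  ifelse(!is.na(Fd), 0.75 - 0.25 * Fd, 1)))
}

.imp <- function(p, n) {
  i <- c(seq_len(n), which(p$sire > 0), which(p$dam > 0))
  j <- c(seq_len(n), p$sire[p$sire > 0], p$dam[p$dam > 0])
  x <- c(rep(1, n), rep(-0.5, sum(p$sire > 0) + sum(p$dam > 0)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

## Henderson decomposition A = T D T': returns sparse (I - P) with 0.5 parent
## coefficients, the Mendelian-sampling variances d, and F.
.pedLDL <- function(ped) {
  p <- .checkPed(ped)
  n <- nrow(ped)
  F <- inbreeding(ped)
  Fs <- ifelse(p$sire > 0, F[pmax(p$sire, 1L)], NA_real_)
  Fd <- ifelse(p$dam > 0, F[pmax(p$dam, 1L)], NA_real_)
  d <- .mendelD(Fs, Fd)
  list(ImP = .imp(p, n), d = d, F = F)
}

#' Pedigree relationship matrix A (dense)
#'
#' Henderson's tabular recursion. Intended for pedigrees small enough for a
#' dense result; use [relSubset()] to obtain the block of A for a set of
#' animals from a large pedigree without forming all of it.
#'
#' @param ped pedigree data.frame.
#' @return a [RelationshipMatrix-class] of kind "A".
#' @export
buildA <- function(ped) {
  p <- .checkPed(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$sire[i]; d <- p$dam[i]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (s > 0) a <- a + 0.5 * A[j, s]
        if (d > 0) a <- a + 0.5 * A[j, d]
        A[j, i] <- A[i, j] <- a
      }
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  lab <- as.character(ped$id)
  dimnames(A) <- list(lab, lab)
  new("RelationshipMatrix", labels = lab, values = A, kind = "A",
      provenance = list(method = "tabular"))
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with Mendelian-sampling variances adjusted for
#' inbreeding: A^-1 = (I-P)' D^-1 (I-P).
#'
#' @param ped pedigree data.frame.
#' @return a [RelationshipMatrix-class] of kind "Ainv" holding a sparse
#'   symmetric Matrix.
#' @export
buildAinv <- function(ped) {
  dec <- .pedLDL(ped)
  Ainv <- Matrix::crossprod(dec$ImP, (1 / dec$d) * dec$ImP)
  Ainv <- Matrix::forceSymmetric(Ainv)
  lab <- as.character(ped$id)
  dimnames(Ainv) <- list(lab, lab)
  new("RelationshipMatrix", labels = lab, values = Ainv, kind = "Ainv",
      provenance = list(method = "henderson", inbreeding = TRUE))
}

#' Relationship block among a subset of animals
#'
#' Computes A[ids, ids] from a large pedigree by sparse triangular solves on
#' Henderson's decomposition, avoiding the full dense A.
#'
#' @param ped pedigree data.frame.
#' @param ids animal ids (subset of `ped$id`).
#' @return dense matrix A[ids, ids] with ids as dimnames.
#' @export
relSubset <- function(ped, ids) {
  idx <- match(ids, ped$id)
  if (anyNA(idx)) stop("unknown ids in relSubset")
  dec <- .pedLDL(ped)
  n <- nrow(ped)
  k <- length(idx)
  E <- Matrix::sparseMatrix(i = idx, j = seq_len(k), x = 1, dims = c(n, k))
  ## column j of W holds the ancestor weights of ids[j]: W = (I-P)^-T e_j
  W <- as(Matrix::solve(as(Matrix::t(dec$ImP), "triangularMatrix"), E),
          "CsparseMatrix")
  Wd <- W
  Wd@x <- W@x * dec$d[W@i + 1L]
  Ab <- as.matrix(Matrix::crossprod(Wd, W))
  dimnames(Ab) <- list(as.character(ids), as.character(ids))
  Ab
}

#' Extract the genotyped block of a relationship matrix
#'
#' @param A a [RelationshipMatrix-class] of kind "A" (dense).
#' @param genotypedIds ids of genotyped animals, in the desired order.
#' @return a [RelationshipMatrix-class] of kind "A22".
#' @export
extractA22 <- function(A, genotypedIds) {
  stopifnot(is(A, "RelationshipMatrix"))
  idx <- match(as.character(genotypedIds), A@labels)
  if (anyNA(idx)) stop("genotyped ids not present in A")
  V <- as.matrix(A@values)[idx, idx, drop = FALSE]
  lab <- as.character(genotypedIds)
  dimnames(V) <- list(lab, lab)
  new("RelationshipMatrix", labels = lab, values = V, kind = "A22",
      provenance = c(A@provenance, list(subsetOf = A@kind)))
}

#' Gene-dropping expected relationships (Monte Carlo oracle)
#'
#' Replays independent meioses down a pedigree at a single unlinked locus and
#' estimates expected identity-by-descent relationships. Used as an
#' independent check of [buildA()] on small pedigrees.
#'
#' @param ped pedigree data.frame.
#' @param nrep number of gene-dropping replicates.
#' @return estimated numerator relationship matrix.
#' @export
geneDropRelationship <- function(ped, nrep = 20000) {
  p <- .checkPed(ped)
  n <- nrow(ped)
  acc <- matrix(0, n, n)
  for (r in seq_len(nrep)) {
    a1 <- integer(n); a2 <- integer(n)
    cnt <- 0L
    for (i in seq_len(n)) {
      s <- p$sire[i]; d <- p$dam[i]
      a1[i] <- if (s > 0) (if (runif(1) < 0.5) a1[s] else a2[s]) else { cnt <- cnt + 1L; cnt }
      a2[i] <- if (d > 0) (if (runif(1) < 0.5) a1[d] else a2[d]) else { cnt <- cnt + 1L; cnt }
    }
    H1 <- outer(a1, a1, "==") + outer(a1, a2, "==")
    H2 <- outer(a2, a1, "==") + outer(a2, a2, "==")
    acc <- acc + (H1 + H2) / 2
  }
  acc / nrep
}
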