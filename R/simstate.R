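## Internal mutable simulation state. Pedigree columns are kept as plain
## vectors (assembled into a data.frame once at the end); haplotypes live in
## per-batch chunks so the state never re-copies the full matrices while the
## population grows.

.newState <- function(genome, trait, loci, params) {
  e <- new.env(parent = emptyenv())
  e$genome <- genome; e$trait <- trait; e$loci <- loci; e$params <- params
  e$n <- 0L
  e$sire <- integer(); e$dam <- integer(); e$sex <- integer()
  e$gen <- integer(); e$popn <- character()
  e$tbvQtl <- numeric(); e$tbvPoly <- numeric(); e$phen <- numeric()
  e$chunk1 <- list(); e$chunk2 <- list()
  e$hapChunk <- integer(); e$hapOffset <- integer()
  e$qtlCols <- which(loci$type == "QTL")
  e$s2poly <- (trait@h2Total - trait@h2Qtl) * trait@vp
  e$s2e <- (1 - trait@h2Total) * trait@vp
  ## incremental Henderson decomposition: F and Mendelian-sampling d per
  ## animal, plus (I - P) triplets, updated batch by batch
  e$F <- numeric(); e$d <- numeric()
  e$ti <- integer(); e$tj <- integer(); e$tx <- numeric()
  e
}

## F for a new batch whose parents' F are already known: one sparse
## triangular solve against the accumulated (I - P)'
.batchF <- function(st, ids, dNew, bothKnown) {
  n <- st$n
  F <- numeric(length(ids))
  if (any(bothKnown)) {
    ImP <- Matrix::sparseMatrix(i = st$ti, j = st$tj, x = st$tx, dims = c(n, n))
    idx <- ids[bothKnown]
    E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                              dims = c(n, length(idx)))
    W <- as(Matrix::solve(as(Matrix::t(ImP), "triangularMatrix"), E),
            "CsparseMatrix")
    dAll <- c(st$d, dNew)
    ## colSums of d-weighted squared ancestor loadings, on the slots directly
    v <- W@x * W@x * dAll[W@i + 1L]
    F[bothKnown] <- vapply(seq_along(idx), function(j)
      sum(v[(W@p[j] + 1L):W@p[j + 1L]]), 0) - 1
  }
  F
}

## Append a block of animals. hap1/hap2 rows correspond to the new animals.
.stateAdd <- function(st, sire, dam, sex, generation, population,
                      hap1, hap2, retain = TRUE, founderPoly = FALSE) {
  n <- length(sex)
  ids <- st$n + seq_len(n)
  st$n <- st$n + n
  st$sire <- c(st$sire, as.integer(sire))
  st$dam <- c(st$dam, as.integer(dam))
  st$sex <- c(st$sex, as.integer(sex))
  st$gen <- c(st$gen, rep(as.integer(generation), n))
  st$popn <- c(st$popn, rep(population, n))
  tq <- if (length(st$qtlCols))
          as.numeric((hap1[, st$qtlCols, drop = FALSE] +
                      hap2[, st$qtlCols, drop = FALSE]) %*% st$trait@qtlEffects)
        else rep(0, n)
  ## update the incremental Henderson decomposition (F, d, I - P)
  FsNA <- ifelse(sire > 0, st$F[pmax(sire, 1L)], NA_real_)
  FdNA <- ifelse(dam > 0, st$F[pmax(dam, 1L)], NA_real_)
  dNew <- .mendelD(FsNA, FdNA)
  st$ti <- c(st$ti, ids, ids[sire > 0], ids[dam > 0])
  st$tj <- c(st$tj, ids, sire[sire > 0], dam[dam > 0])
  st$tx <- c(st$tx, rep(1, n), rep(-0.5, sum(sire > 0) + sum(dam > 0)))
  FNew <- .batchF(st, ids, dNew, sire > 0 & dam > 0)
  st$F <- c(st$F, FNew)
  st$d <- c(st$d, dNew)
  if (st$s2poly > 0) {
    if (founderPoly) {
      tp <- rnorm(n, 0, sqrt(st$s2poly))
    } else {
      Fs <- ifelse(is.na(FsNA), 0, FsNA)
      Fd <- ifelse(is.na(FdNA), 0, FdNA)
      up <- 0.5 * (ifelse(sire > 0, st$tbvPoly[pmax(sire, 1L)], 0) +
                   ifelse(dam > 0, st$tbvPoly[pmax(dam, 1L)], 0))
      tp <- up + rnorm(n, 0, sqrt(pmax(0.5 * st$s2poly * (1 - 0.5 * (Fs + Fd)), 0)))
    }
  } else tp <- rep(0, n)
  p <- st$params
  y <- p$mu + p$sexEffect * (sex == 1L) + tq + tp + rnorm(n, 0, sqrt(st$s2e))
  st$tbvQtl <- c(st$tbvQtl, tq)
  st$tbvPoly <- c(st$tbvPoly, tp)
  st$phen <- c(st$phen, y)
  if (retain) {
    ci <- length(st$chunk1) + 1L
    st$chunk1[[ci]] <- hap1
    st$chunk2[[ci]] <- hap2
    st$hapChunk <- c(st$hapChunk, rep(ci, n))
    st$hapOffset <- c(st$hapOffset, seq_len(n))
  } else {
    st$hapChunk <- c(st$hapChunk, rep(NA_integer_, n))
    st$hapOffset <- c(st$hapOffset, rep(NA_integer_, n))
  }
  ids
}

.stateHaps <- function(st, ids) {
  ch <- st$hapChunk[ids]
  if (anyNA(ch)) stop("haplotypes no longer retained for requested animals")
  m <- nrow(st$loci)
  h1 <- matrix(0L, length(ids), m)
  h2 <- matrix(0L, length(ids), m)
  for (ci in unique(ch)) {
    sel <- which(ch == ci)
    off <- st$hapOffset[ids[sel]]
    h1[sel, ] <- st$chunk1[[ci]][off, , drop = FALSE]
    h2[sel, ] <- st$chunk2[[ci]][off, , drop = FALSE]
  }
  list(h1 = h1, h2 = h2)
}

## gametes for a vector of parent ids (one gamete per entry)
.stateGametes <- function(st, parentIds) {
  h <- .stateHaps(st, parentIds)
  .cpp_make_gametes(h$h1, h$h2, as.integer(st$loci$chrom),
                    as.numeric(st$genome@chromLengths),
                    as.numeric(st$loci$pos), st$trait@mutationRate)
}

## drop haplotypes for ids (frees chunks once fully dropped)
.stateDrop <- function(st, ids) {
  ch <- unique(st$hapChunk[ids])
  st$hapChunk[ids] <- NA_integer_
  st$hapOffset[ids] <- NA_integer_
  for (ci in ch[!is.na(ch)]) {
    if (!any(st$hapChunk == ci, na.rm = TRUE)) {
      st$chunk1[ci] <- list(NULL)
      st$chunk2[ci] <- list(NULL)
    }
  }
  invisible(st)
}

## final assembly of pedigree + compact haplotype matrices; only marker
## columns are kept (QTL haplotypes are needed during breeding for TBV and
## transmission, but the finished object carries TBVs as values and exposes
## the genotyping panel)
.stateFinish <- function(st) {
  ped <- data.frame(id = seq_len(st$n), sire = st$sire, dam = st$dam,
                    sex = st$sex, generation = st$gen, population = st$popn,
                    stringsAsFactors = FALSE)
  snpCols <- which(st$loci$type == "SNP")
  keep <- which(!is.na(st$hapChunk))
  hapRow <- rep(NA_integer_, st$n)
  hapRow[keep] <- seq_along(keep)
  ord <- order(st$hapChunk[keep], st$hapOffset[keep])
  ## gather rows chunk by chunk in storage order, then map back
  h1 <- do.call(rbind, lapply(st$chunk1[!vapply(st$chunk1, is.null, TRUE)],
                              function(m) m[, snpCols, drop = FALSE]))
  h2 <- do.call(rbind, lapply(st$chunk2[!vapply(st$chunk2, is.null, TRUE)],
                              function(m) m[, snpCols, drop = FALSE]))
  ## rows of h1/h2 follow (chunk, offset) order; align to keep order
  pos <- integer(length(keep))
  pos[ord] <- seq_along(keep)
  h1 <- h1[pos, , drop = FALSE]
  h2 <- h2[pos, , drop = FALSE]
  lociOut <- st$loci[snpCols, , drop = FALSE]
  rownames(lociOut) <- NULL
  list(ped = ped, hap1 = h1, hap2 = h2, hapRow = hapRow, loci = lociOut)
}
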