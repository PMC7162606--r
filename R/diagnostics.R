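#' Connectedness and parameter-recovery diagnostics for one replicate
#'
#' Computes, on a simulated system, the replicate-level summaries used to
#' validate the scaled design against its full-scale behaviour: mean
#' adjacent-SNP r2 in the last generation of each line (pre-QC markers, the
#' panel's 0.05 cM spacing), the consistency of gametic phase between the
#' genotyped Line1 and Line2 cohorts in the 0-60 kb bin (post-QC markers),
#' the variance fraction of the first principal component of the pooled
#' genomic relationship matrix, and REML estimates (single-trait h2 and
#' phenotypic variance; three-trait genetic correlations of each line with
#' F1).
#'
#' @param pop a [SimulatedPopulation-class].
#' @param what subset of c("ld", "phase", "pca", "reml1", "reml3").
#' @param remlMaxN record cap for REML (records are subsampled, keeping all
#'   of the smaller cohorts).
#' @param pcaMaxPerGroup animals per population entering the PCA (the
#'   variance fraction is a population property; a subsample estimates it).
#' @return named list of the requested summaries.
#' @export
deskDiagnostics <- function(pop, what = c("ld", "phase", "pca"),
                            remlMaxN = 900, pcaMaxPerGroup = 200) {
  out <- list()
  ped <- pop@pedigree
  snpIdx <- which(pop@loci$type == "SNP")
  map <- pop@genome@map
  if ("ld" %in% what) {
    for (ln in c("Line1", "Line2")) {
      mx <- max(ped$generation[ped$population == ln])
      ids <- ped$id[ped$population == ln & ped$generation == mx]
      h <- haplotypes(pop, ids = ids, loci = snpIdx)
      out[[paste0("adjacentR2_", ln)]] <-
        adjacentLdProfile(rbind(h$hap1, h$hap2), map)$meanR2
    }
  }
  needQc <- any(c("phase", "pca") %in% what)
  if (needQc) kept <- .popQc(pop)$kept
  if ("phase" %in% what) {
    keptIdx <- snpIdx[match(kept, pop@loci$id[snpIdx])]
    h1 <- haplotypes(pop, ids = pop@cohorts$Line1_train, loci = keptIdx)
    h2 <- haplotypes(pop, ids = pop@cohorts$Line2_train, loci = keptIdx)
    pc <- phaseConsistency(rbind(h1$hap1, h1$hap2), rbind(h2$hap1, h2$hap2),
                           map[match(kept, map$id), ])
    out$phaseLe60kb <- pc$correlation[1]
  }
  if ("pca" %in% what) {
    grab <- function(ids) {
      if (length(ids) > pcaMaxPerGroup) ids <- sort(sample(ids, pcaMaxPerGroup))
      ids
    }
    f1 <- unlist(pop@cohorts[grep("^F1-", names(pop@cohorts))], use.names = FALSE)
    ids <- c(grab(pop@cohorts$Line1_train), grab(pop@cohorts$Line2_train),
             grab(f1))
    geno <- genotypes(pop, ids, snps = kept)
    G <- buildG(geno, freqSource = "pooled")
    pc <- pcaOfG(G)
    ## variance share among the leading 20 components, the convention of the
    ## standard PCA tooling's reported eigenvalues
    top <- pmax(pc$values[seq_len(min(20L, length(pc$values)))], 0)
    out$pc1VarPct <- 100 * top[1] / sum(top)
    out$pc1VarPctTotal <- 100 * pc$varExplained[1]
    out$pcaGroups <- ifelse(startsWith(ped$population[ids], "F1"), "F1",
                            ped$population[ids])
    out$pcaScores <- pc$scores
  }
  if (any(c("reml1", "reml3") %in% what)) {
    asc <- assembleScenario(pop, "SC1")
    train <- asc$train
    if (nrow(train) > remlMaxN) {
      ## subsample records but keep the crossbred trainers together with
      ## their recorded purebred parents: the across-population genetic
      ## covariances are identified by exactly these parent-offspring links
      f1ids <- train$id[train$trait == "F1"]
      par <- unique(c(ped$sire[match(f1ids, ped$id)],
                      ped$dam[match(f1ids, ped$id)]))
      must <- c(f1ids, intersect(par, train$id))
      rest <- setdiff(train$id, must)
      extra <- max(0L, remlMaxN - length(must))
      keepIds <- c(must, sort(sample(rest, min(extra, length(rest)))))
      train <- train[train$id %in% keepIds, ]
    }
    ped3 <- pop@pedigree[, c("id", "sire", "dam")]
    ## one pedigree decomposition serves every fit below
    Arec <- relSubset(ped3, train$id)
    if ("reml1" %in% what) {
      vc <- remlEstimate(train, ped3, model = "single", Arec = Arec)
      out$h2Single <- vc@h2
      out$vpSingle <- vc@sigma2u + vc@sigma2e
    }
    if ("reml3" %in% what) {
      ## two-stage fit, the standard multi-trait REML practice: bivariate
      ## analyses of the identifiable pairs (each purebred line with F1,
      ## linked by recorded parent-offspring pairs) provide starting values;
      ## the purebred-purebred covariance, which carries almost no direct
      ## information (the lines meet only generations back in the expansion
      ## population), starts at the product of the purebred-F1 correlations
      ## so that the full fit is not dragged onto the positive-definiteness
      ## boundary by a wandering nuisance parameter.
      biv <- function(lineName) {
        sub <- train[train$trait %in% c(lineName, "F1"), , drop = FALSE]
        bivMax <- 600L
        if (nrow(sub) > bivMax) {
          ## crossbred records are subsampled together with their recorded
          ## parents, preserving the informative pairs
          f1ids2 <- sub$id[sub$trait == "F1"]
          if (length(f1ids2) > 300L) f1ids2 <- sort(sample(f1ids2, 300L))
          par2 <- unique(c(ped$sire[match(f1ids2, ped$id)],
                           ped$dam[match(f1ids2, ped$id)]))
          must2 <- unique(c(f1ids2, intersect(par2, sub$id)))
          rest2 <- setdiff(sub$id, must2)
          extra2 <- max(0L, bivMax - length(must2))
          keep2 <- c(must2, sort(sample(rest2, min(extra2, length(rest2)))))
          sub <- sub[sub$id %in% keep2, , drop = FALSE]
        }
        sub$trait <- droplevels(sub$trait)
        ix <- match(sub$id, train$id)
        remlEstimate(sub, ped3, model = "multi",
                     Arec = Arec[ix, ix, drop = FALSE])
      }
      b1 <- biv("Line1")
      b2 <- biv("Line2")
      g11 <- b1@G0["Line1", "Line1"]; g22 <- b2@G0["Line2", "Line2"]
      g33 <- mean(c(b1@G0["F1", "F1"], b2@G0["F1", "F1"]))
      r13 <- b1@rg["Line1", "F1"]; r23 <- b2@rg["Line2", "F1"]
      G0init <- matrix(0, 3, 3)
      diag(G0init) <- c(g11, g22, g33)
      G0init[1, 3] <- G0init[3, 1] <- r13 * sqrt(g11 * g33)
      G0init[2, 3] <- G0init[3, 2] <- r23 * sqrt(g22 * g33)
      G0init[1, 2] <- G0init[2, 1] <- r13 * r23 * sqrt(g11 * g22)
      R0init <- diag(c(b1@R0["Line1", "Line1"], b2@R0["Line2", "Line2"],
                       mean(c(b1@R0["F1", "F1"], b2@R0["F1", "F1"]))))
      vc3 <- remlEstimate(train, ped3, model = "multi", Arec = Arec,
                          init = list(G0 = G0init, R0 = R0init))
      out$rgLine1F1 <- vc3@rg["Line1", "F1"]
      out$rgLine2F1 <- vc3@rg["Line2", "F1"]
      out$rgLine1Line2 <- vc3@rg["Line1", "Line2"]
      out$remlConverged <- vc3@converged
    }
  }
  out
}
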