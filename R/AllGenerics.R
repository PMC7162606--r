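#' @name accessors
#' @title Accessors for crossBLUP classes
#' @description Small accessor generics: `snpMap()` returns the SNP map of a
#'   genome or population, `pedigree()` the pedigree table, `cohortIds()` the
#'   ids of a named cohort, `genotypes()` an allele-dosage matrix,
#'   `haplotypes()` the pair of phased haplotype matrices, `tbv()` total true
#'   breeding values, `phenotypes()` the trait records, `relValues()` /
#'   `relLabels()` the payload of a [RelationshipMatrix-class].
#' @param x object.
#' @param ... passed to methods.
NULL

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x, ...) standardGeneric("snpMap"))
#' @rdname accessors
#' @export
setGeneric("pedigree", function(x, ...) standardGeneric("pedigree"))
#' @rdname accessors
#' @export
setGeneric("cohortIds", function(x, ...) standardGeneric("cohortIds"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x, ...) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("tbv", function(x, ...) standardGeneric("tbv"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))
#' @rdname accessors
#' @export
setGeneric("relLabels", function(x) standardGeneric("relLabels"))

setMethod("snpMap", "GenomeSpec", function(x, ...) x@map)
setMethod("snpMap", "SimulatedPopulation", function(x, ...) x@genome@map)
setMethod("pedigree", "SimulatedPopulation", function(x, ...) x@pedigree)

setMethod("cohortIds", "SimulatedPopulation", function(x, cohort, ...) {
  ped <- x@pedigree
  if (cohort %in% names(x@cohorts)) return(x@cohorts[[cohort]])
  # "Line1_g6" style lookups
  m <- regmatches(cohort, regexec("^(.*)_g(\\d+)$", cohort))[[1]]
  if (length(m) == 3L) {
    sel <- ped$population == m[2] & ped$generation == as.integer(m[3])
    return(ped$id[sel])
  }
  if (cohort %in% ped$population) return(ped$id[ped$population == cohort])
  stop("unknown cohort: ", cohort)
})

setMethod("haplotypes", "SimulatedPopulation", function(x, ids = NULL, loci = NULL, ...) {
  rows <- if (is.null(ids)) which(!is.na(x@hapRow)) else match(ids, x@pedigree$id)
  if (anyNA(rows)) stop("unknown ids requested")
  hr <- x@hapRow[rows]
  if (anyNA(hr)) stop("haplotypes not retained for some requested animals")
  cols <- if (is.null(loci)) seq_len(ncol(x@hap1)) else loci
  ids2 <- x@pedigree$id[rows]
  h1 <- x@hap1[hr, cols, drop = FALSE]
  h2 <- x@hap2[hr, cols, drop = FALSE]
  rownames(h1) <- rownames(h2) <- as.character(ids2)
  list(hap1 = h1, hap2 = h2)
})

setMethod("genotypes", "SimulatedPopulation", function(x, ids = NULL, snps = NULL, ...) {
  snpIdx <- which(x@loci$type == "SNP")
  if (!is.null(snps)) snpIdx <- snpIdx[match(snps, x@loci$id[snpIdx])]
  h <- haplotypes(x, ids = ids, loci = snpIdx)
  g <- h$hap1 + h$hap2
  colnames(g) <- x@loci$id[snpIdx]
  g
})

setMethod("tbv", "SimulatedPopulation", function(x, ids = NULL, ...) {
  v <- x@tbvQtl + x@tbvPoly
  names(v) <- as.character(x@pedigree$id)
  if (is.null(ids)) v else v[as.character(ids)]
})

setMethod("phenotypes", "SimulatedPopulation", function(x, ids = NULL, ...) {
  v <- x@phenotype
  names(v) <- as.character(x@pedigree$id)
  if (is.null(ids)) v else v[as.character(ids)]
})

setMethod("relValues", "RelationshipMatrix", function(x) x@values)
setMethod("relLabels", "RelationshipMatrix", function(x) x@labels)

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %d chromosome(s), %.2f cM, %d SNPs (scale %.3g)\n",
              object@nChrom, sum(object@chromLengths),
              sum(object@snpCounts), object@scaleFactor))
})

setMethod("show", "TraitArchitecture", function(object) {
  cat(sprintf("TraitArchitecture [%s]: %d QTL, h2 = %.3g (QTL part %.3g), Vp = %.3g\n",
              object@sim, object@nQtl, object@h2Total, object@h2Qtl, object@vp))
})

setMethod("show", "SimulatedPopulation", function(object) {
  ped <- object@pedigree
  cat(sprintf("SimulatedPopulation: %d animals, %d retained haplotypes, %d loci\n",
              nrow(ped), nrow(object@hap1), nrow(object@loci)))
  tab <- table(ped$population)
  cat("  populations:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  trait %s, seed %d\n", object@trait@sim, object@seed))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix[%s]: %d x %d\n", object@kind,
              length(object@labels), length(object@labels)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "VarianceComponents", function(object) {
  k <- length(object@h2)
  if (k == 1L) {
    cat(sprintf("VarianceComponents: sigma2u = %.4g, sigma2e = %.4g, h2 = %.3f\n",
                object@sigma2u, object@sigma2e, object@h2))
  } else {
    cat("VarianceComponents (multi-trait)\n  G0:\n")
    print(round(object@G0, 4))
    cat("  residuals:", paste(round(diag(object@R0), 4), collapse = ", "), "\n")
    cat("  h2:", paste(round(object@h2, 3), collapse = ", "), "\n")
    cat("  genetic correlations:\n")
    print(round(object@rg, 3))
  }
  cat(sprintf("  converged: %s (%d iterations)%s\n", object@converged,
              object@iterations, if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec %s: %s %s model; training = %s; weights = %s\n",
              object@id, object@method, object@model,
              paste(object@training, collapse = "+"), object@weightSource))
})

setMethod("show", "SnpWeightSet", function(object) {
  cat(sprintf("SnpWeightSet: %d SNPs, iteration %d, source = %s (%s)\n",
              length(object@weights), object@iteration,
              object@sourcePopulation, object@normalization))
})
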