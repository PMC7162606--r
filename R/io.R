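#' Write genotypes as PLINK text or a flat dosage matrix
#'
#' The PLINK dialect writes a .ped/.map pair with alleles coded 1/2 (allele
#' "2" is the counted allele of the 0/1/2 dosage); the flat dialect writes a
#' whitespace-separated table with a SNP-id header and animal ids in the
#' first column. Map positions are emitted in both cM and bp (1 cM = 1 Mb).
#'
#' @param geno dosage matrix (rownames = animal ids, colnames = SNP ids).
#' @param map data.frame `id`, `chrom`, `pos` (cM) aligned to columns.
#' @param prefix output path prefix (PLINK) or file path (flat).
#' @param dialect "plink" or "flat".
#' @return invisibly, the written file path(s).
#' @export
writeGenotypes <- function(geno, map, prefix, dialect = c("plink", "flat")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat") {
    df <- data.frame(id = rownames(geno), geno, check.names = FALSE)
    write.table(df, prefix, quote = FALSE, row.names = FALSE)
    return(invisible(prefix))
  }
  mapFile <- paste0(prefix, ".map")
  pedFile <- paste0(prefix, ".ped")
  write.table(data.frame(map$chrom, map$id, map$pos,
                         as.integer(round(map$pos * 1e6))),
              mapFile, quote = FALSE, row.names = FALSE, col.names = FALSE)
  a1 <- ifelse(geno >= 1L, "2", "1")
  a2 <- ifelse(geno >= 2L, "2", "1")
  body <- matrix("", nrow(geno), 2 * ncol(geno))
  body[, seq(1, 2 * ncol(geno), 2)] <- a1
  body[, seq(2, 2 * ncol(geno), 2)] <- a2
  lead <- cbind("0", rownames(geno), "0", "0", "0", "-9")
  write.table(cbind(lead, body), pedFile, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(pedFile, mapFile))
}

#' Read genotypes written by [writeGenotypes()]
#'
#' Returns the 0/1/2 dosage of the counted allele ("2" in the PLINK text
#' dialect; heterozygotes may be coded in either allele order).
#'
#' @param prefix path prefix (PLINK) or file (flat).
#' @param dialect "plink" or "flat".
#' @return list with `geno` (dosage matrix) and `map` (data.frame id, chrom,
#'   pos in cM; NULL for the flat dialect).
#' @export
readGenotypes <- function(prefix, dialect = c("plink", "flat")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat") {
    df <- read.table(prefix, header = TRUE, check.names = FALSE)
    geno <- as.matrix(df[, -1, drop = FALSE])
    rownames(geno) <- as.character(df[[1]])
    storage.mode(geno) <- "integer"
    return(list(geno = geno, map = NULL))
  }
  mapFile <- paste0(prefix, ".map")
  pedFile <- paste0(prefix, ".ped")
  map <- read.table(mapFile, header = FALSE,
                    col.names = c("chrom", "id", "pos", "bp"))
  ped <- read.table(pedFile, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(sprintf("ped file has %d columns; expected %d for %d SNPs",
                 ncol(ped), 6 + 2 * m, m))
  alle <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (!all(alle %in% c("1", "2")))
    stop("unknown allele codes in ped file (expected 1/2)")
  g <- (alle[, seq(1, 2 * m, 2), drop = FALSE] == "2") +
       (alle[, seq(2, 2 * m, 2), drop = FALSE] == "2")
  storage.mode(g) <- "integer"
  rownames(g) <- ped[[2]]
  colnames(g) <- map$id
  list(geno = g, map = map[, c("id", "chrom", "pos")])
}

#' Read and topologically order a pedigree CSV
#'
#' Expects columns id, sire, dam (0 = unknown) and optionally sex,
#' generation, population. Rows are reordered parents-before-offspring; a
#' cycle raises an error naming the ids involved.
#'
#' @param path CSV file.
#' @return validated, ordered pedigree data.frame.
#' @export
readPedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  orderPedigree(ped)
}

#' @rdname readPedigree
#' @param ped pedigree data.frame to order/validate in memory.
#' @export
orderPedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  si <- match(ped$sire, ped$id); si[is.na(si)] <- 0L
  di <- match(ped$dam, ped$id); di[is.na(di)] <- 0L
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- which(!placed & (si == 0L | placed[pmax(si, 1L)]) &
                   (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  if (length(order) < n)
    stop("pedigree cycle involving ids: ",
         paste(ped$id[!placed], collapse = ", "))
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname readPedigree
#' @param file output CSV path.
#' @export
writePedigree <- function(ped, file) {
  write.table(ped, file, quote = FALSE, row.names = FALSE, sep = ",")
  invisible(file)
}

#' Write a labeled relationship matrix as lower-triangle triplets
#'
#' @param rm a [RelationshipMatrix-class].
#' @param file output path (tab-separated id_i, id_j, value).
#' @export
writeRelTriplets <- function(rm, file) {
  M <- as.matrix(relValues(rm))
  lab <- relLabels(rm)
  idx <- which(lower.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  df <- data.frame(id_i = lab[idx[, 1]], id_j = lab[idx[, 2]],
                   value = M[idx])
  write.table(df, file, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(file)
}

#' @rdname writeRelTriplets
#' @param kind kind label for the reconstructed matrix.
#' @export
readRelTriplets <- function(file, kind = "A") {
  df <- read.table(file, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  lab <- unique(c(df$id_i, df$id_j))
  M <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  M[cbind(match(df$id_i, lab), match(df$id_j, lab))] <- df$value
  M[cbind(match(df$id_j, lab), match(df$id_i, lab))] <- df$value
  new("RelationshipMatrix", labels = lab, values = M, kind = kind,
      provenance = list(file = file))
}

#' Round-trippable run configuration
#'
#' Configurations are plain named lists serialized as YAML; reading back a
#' written configuration reproduces it. A short content hash is logged so a
#' run can be traced to its exact configuration.
#'
#' @param config named list.
#' @param path file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname writeRunConfig
#' @export
configHash <- function(config) {
  ## normalize through a serialization round trip so that equivalent
  ## configurations (e.g. written and re-read) hash identically
  txt <- yaml::as.yaml(yaml::yaml.load(yaml::as.yaml(config)))
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Export a simulated population to disk
#'
#' Writes pedigree.csv, phenotypes.csv (id, population, generation, sex,
#' phenotype, tbv), one PLINK .ped/.map pair per genotyped population, a
#' config.yaml and a run log recording seed and configuration hash.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param outdir output directory (created if needed).
#' @param config configuration list stored alongside.
#' @export
exportPopulation <- function(pop, outdir, config = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ped <- pop@pedigree
  writePedigree(ped, file.path(outdir, "pedigree.csv"))
  phen <- data.frame(id = ped$id, population = ped$population,
                     generation = ped$generation, sex = ped$sex,
                     phenotype = pop@phenotype, tbv = as.numeric(tbv(pop)))
  write.table(phen, file.path(outdir, "phenotypes.csv"), quote = FALSE,
              row.names = FALSE, sep = ",")
  map <- pop@genome@map
  ch <- pop@cohorts
  f1 <- unlist(ch[grep("^F1-", names(ch))], use.names = FALSE)
  sets <- list(Line1 = ch$Line1_train, Line2 = ch$Line2_train, F1 = f1)
  for (nm in names(sets)) {
    g <- genotypes(pop, sets[[nm]])
    rownames(g) <- as.character(sets[[nm]])
    writeGenotypes(g, map, file.path(outdir, paste0("genotypes_", nm)))
  }
  config$seed <- pop@seed
  writeRunConfig(config, file.path(outdir, "config.yaml"))
  writeLines(c(sprintf("seed: %d", pop@seed),
               sprintf("config_hash: %s", configHash(config)),
               sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(outdir, "run.log"))
  invisible(outdir)
}
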