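#' Stamp founder labels onto the base population
#'
#' Declares the population at t = 0 to be the founder generation: every
#' allele copy of founder i receives the label i, so all
#' 2 (Nm + Nf) nc nl allele copies are relabeled while states are left
#' untouched.  Downstream, a label names the founder family an allele copy
#' physically descends from; no new label is ever created after t = 0.
#'
#' @param population a \linkS4class{Population} at generation 0 (the burn-in
#'   output).
#' @return The same population with the label layer filled in.
#' @examples
#' cfg <- simConfig(nChromosomes = 1, nLociRaw = 50, tBurnin = 50,
#'                  Nm = 4, Nf = 8)
#' set.seed(1)
#' pop <- makeFounderLabels(runBurnin(cfg))
#' length(unique(as.vector(founderLabels(pop))))  # 12 distinct founders
#' @export
makeFounderLabels <- function(population) {
  stopifnot(is(population, "Population"))
  if (generation(population) != 0L)
    stop("founder labels are stamped on the t = 0 population only")
  n <- nIndividuals(population)
  lab <- matrix(rep(seq_len(n), each = 2L), nrow = nLoci(population),
                ncol = 2L * n, byrow = TRUE)
  storage.mode(lab) <- "integer"
  population@labels <- lab
  population@founderSex <- population@sex
  validObject(population)
  population
}

#' Per-locus allele frequencies
#'
#' Frequency of the state-2 allele at every locus: count of state-2 copies
#' divided by 2 (Nm + Nf).
#'
#' @param population a \linkS4class{Population}.
#' @return Numeric vector of length \code{nLoci(population)} in [0, 1].
#' @export
alleleFrequencies <- function(population) {
  stopifnot(is(population, "Population"), nIndividuals(population) > 0)
  rowMeans(population@states == 2L)
}

#' Apply the minor-allele-frequency marker filter
#'
#' Retains, per chromosome, loci whose minor allele frequency exceeds
#' \code{mafThreshold} (all genotypes are observed in silico, so a
#' call-rate clause is vacuous here).  When \code{nKeep} is given, a seeded
#' uniform random subset of exactly \code{nKeep} passing loci per
#' chromosome is retained, and chromosomes with fewer passing loci raise an
#' error naming the chromosome (rerun the burn-in with a new seed, or pass
#' \code{nKeep = NULL} to keep every passing locus).  Every retained locus
#' is biallelic in the filtered population (Ao = 2, Pp = 1).
#'
#' @param population a \linkS4class{Population}.
#' @param mafThreshold MAF threshold (strict inequality), default 0.05.
#' @param nKeep loci to keep per chromosome, or \code{NULL} for all passing.
#' @return A list with \code{population} (the filtered population) and
#'   \code{kept} (integer indices of retained loci in the input map).
#' @export
applyMarkerFilter <- function(population, mafThreshold = 0.05, nKeep = NULL) {
  stopifnot(is(population, "Population"))
  p <- alleleFrequencies(population)
  maf <- pmin(p, 1 - p)
  pass <- maf > mafThreshold
  map <- population@map
  kept <- integer(0)
  for (c in seq_len(map@nChromosomes)) {
    onC <- which(map@chrom == c & pass)
    if (!is.null(nKeep) && !is.na(nKeep)) {
      if (length(onC) < nKeep)
        stop(sprintf(
          "chromosome %d: only %d loci pass MAF > %g, %d required; rerun the burn-in with a new seed or use nKeep = NULL",
          c, length(onC), mafThreshold, nKeep))
      onC <- sort(sample(onC, nKeep))
    }
    kept <- c(kept, onC)
  }
  if (!length(kept)) stop("no locus passes the MAF filter")
  newMap <- new("MarkerMap", nChromosomes = map@nChromosomes,
                chrom = map@chrom[kept], pos = map@pos[kept],
                lociPerChrom = as.integer(tabulate(map@chrom[kept],
                                                   map@nChromosomes)))
  population@states <- population@states[kept, , drop = FALSE]
  if (isLabeled(population))
    population@labels <- population@labels[kept, , drop = FALSE]
  population@map <- newMap
  list(population = population, kept = kept)
}

## ---- genotype and label I/O -------------------------------------------

# integer base-pair coordinate of a locus: genetic position scaled to 1 Mb
bpPositions <- function(map) as.integer(round(map@pos * 1e6))

#' Export genotypes, labels and pedigree
#'
#' Writes the population as a phased VCF v4.2 (one record per locus, GT
#' "a|b", allele 1 mapped to REF = A and allele 2 to ALT = C) or as
#' PLINK-text ped/map.  A sidecar label track
#' (\code{<path>.labels.tsv}: individual, chromosome, locus, haplotype,
#' founder_id, founder_sex) and a pedigree table (\code{<path>.ped.tsv}:
#' id, sire, dam, sex, generation) are written alongside whenever the
#' population is labeled.
#'
#' @param population a \linkS4class{Population}.
#' @param path output path; \code{.vcf} / \code{.ped}+\code{.map} suffixes
#'   are appended as needed.
#' @param format "vcf" (default) or "plink".
#' @return Invisibly, the paths written.
#' @seealso [importGenotypes()] for the inverse.
#' @export
exportGenotypes <- function(population, path, format = c("vcf", "plink")) {
  format <- match.arg(format)
  stopifnot(is(population, "Population"))
  map <- population@map
  n <- nIndividuals(population)
  bp <- bpPositions(map)
  st <- population@states
  paths <- character(0)
  if (format == "vcf") {
    vcf <- if (grepl("\\.vcf$", path)) path else paste0(path, ".vcf")
    con <- file(vcf, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=founderTrace",
                 sprintf("##contig=<ID=%d>", seq_len(map@nChromosomes)),
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
               con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("ind", population@id)),
                     collapse = "\t"), con)
    gtA <- st[, seq(1, 2 * n, 2), drop = FALSE] - 1L
    gtB <- st[, seq(2, 2 * n, 2), drop = FALSE] - 1L
    gt <- matrix(paste0(gtA, "|", gtB), nrow = nLoci(population))
    body <- cbind(map@chrom, bp,
                  sprintf("snp%d_%d", map@chrom, bp),
                  "A", "C", ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
    paths <- vcf
  } else {
    pedf <- paste0(sub("\\.ped$", "", path), ".ped")
    mapf <- paste0(sub("\\.ped$", "", path), ".map")
    alle <- matrix("A", nrow = nLoci(population), ncol = 2 * n)
    alle[st == 2L] <- "C"
    rows <- vapply(seq_len(n), function(i) {
      paste(c("FAM", population@id[i],
              ifelse(is.na(population@sire[i]), 0L, population@sire[i]),
              ifelse(is.na(population@dam[i]), 0L, population@dam[i]),
              population@sex[i], -9,
              as.vector(rbind(alle[, 2 * i - 1], alle[, 2 * i]))),
            collapse = " ")
    }, character(1))
    writeLines(rows, pedf)
    write.table(data.frame(chrom = map@chrom,
                           id = sprintf("snp%d_%d", map@chrom, bp),
                           cm = map@pos * 100, bp = bp),
                mapf, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(pedf, mapf)
  }
  base <- sub("\\.(vcf|ped)$", "", paths[1])
  pedigree <- data.frame(id = population@id, sire = population@sire,
                         dam = population@dam, sex = population@sex,
                         generation = generation(population))
  write.table(pedigree, paste0(base, ".ped.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- c(paths, paste0(base, ".ped.tsv"))
  if (isLabeled(population)) {
    lb <- population@labels
    labTrack <- data.frame(
      individual = rep(population@id, each = 2 * nLoci(population)),
      chromosome = rep(map@chrom, 2 * n),
      locus = rep(bp, 2 * n),
      haplotype = rep(rep(0:1, each = nLoci(population)), n),
      founder_id = as.vector(lb),
      founder_sex = c("male", "female")[population@founderSex[as.vector(lb)]])
    write.table(labTrack, paste0(base, ".labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, paste0(base, ".labels.tsv"))
  }
  invisible(paths)
}

#' Import genotypes and labels
#'
#' Reads a phased VCF written by [exportGenotypes()] (any phased biallelic
#' VCF works) plus, optionally, its sidecar label and pedigree tables, and
#' rebuilds a \linkS4class{Population}.  Round-tripping a population
#' through export and import is lossless for states, labels and pedigree
#' fields.
#'
#' @param vcfPath path to the VCF.
#' @param labelsPath optional sidecar label TSV.
#' @param pedigreePath optional pedigree TSV.
#' @param generation generation index to assign when no pedigree is given.
#' @return A \linkS4class{Population}.
#' @export
importGenotypes <- function(vcfPath, labelsPath = NULL, pedigreePath = NULL,
                            generation = 0L) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("importGenotypes needs the vcfR package")
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  if (!nrow(gt)) stop("VCF contains no genotype records")
  n <- ncol(gt)
  chrom <- as.integer(fix[, "CHROM"])
  bp <- as.integer(fix[, "POS"])
  nChrom <- max(chrom)
  lociPer <- as.integer(tabulate(chrom, nChrom))
  map <- new("MarkerMap", nChromosomes = nChrom, chrom = chrom,
             pos = bp / 1e6, lociPerChrom = lociPer)
  a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
  states <- matrix(0L, nrow = nrow(gt), ncol = 2 * n)
  states[, seq(1, 2 * n, 2)] <- as.integer(a) + 1L
  states[, seq(2, 2 * n, 2)] <- as.integer(b) + 1L
  ids <- as.integer(sub("^ind", "", colnames(gt)))
  if (anyNA(ids)) ids <- seq_len(n)
  sex <- rep(NA_integer_, n); sire <- rep(NA_integer_, n)
  dam <- rep(NA_integer_, n); gen <- as.integer(generation)
  if (!is.null(pedigreePath)) {
    ped <- read.table(pedigreePath, header = TRUE, sep = "\t")
    m <- match(ids, ped$id)
    sex <- as.integer(ped$sex[m]); sire <- as.integer(ped$sire[m])
    dam <- as.integer(ped$dam[m]); gen <- as.integer(ped$generation[m[1]])
  }
  if (anyNA(sex)) sex <- rep(c(1L, 2L), length.out = n)
  labels <- matrix(integer(0), 0, 0); founderSex <- integer(0)
  if (!is.null(labelsPath)) {
    lt <- read.table(labelsPath, header = TRUE, sep = "\t")
    L <- nrow(gt)
    labels <- matrix(0L, nrow = L, ncol = 2 * n)
    ord <- order(match(lt$individual, ids), lt$haplotype,
                 match(lt$chromosome, seq_len(nChrom)), lt$locus)
    lt <- lt[ord, ]
    for (i in seq_len(n)) {
      block <- lt[lt$individual == ids[i], ]
      labels[, 2 * i - 1] <- block$founder_id[block$haplotype == 0]
      labels[, 2 * i] <- block$founder_id[block$haplotype == 1]
    }
    fs <- unique(lt[, c("founder_id", "founder_sex")])
    founderSex <- rep(NA_integer_, max(fs$founder_id))
    founderSex[fs$founder_id] <- ifelse(fs$founder_sex == "male", 1L, 2L)
    founderSex[is.na(founderSex)] <- 1L
  }
  newPopulation(gen, ids, sex, sire, dam, states, labels, founderSex, map)
}
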