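#' @useDynLib founderTrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor rbinom rpois runif setNames quantile sd
#' @importFrom utils write.table read.table head tail
NULL

#' MarkerMap: evenly spaced biallelic markers on unit-length chromosomes
#'
#' Describes the marker panel: loci grouped by chromosome, each chromosome
#' with genetic length 1 Morgan and loci at evenly spaced genetic positions.
#' Positions are retained through marker filtering, so a filtered map keeps
#' the original coordinates of the surviving loci.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chrom integer vector, chromosome index (1-based) of every locus.
#' @slot pos numeric vector, genetic position of every locus in Morgans,
#'   strictly increasing within a chromosome.
#' @slot lociPerChrom integer vector of locus counts per chromosome.
#' @exportClass MarkerMap
setClass("MarkerMap",
  representation(nChromosomes = "integer", chrom = "integer",
                 pos = "numeric", lociPerChrom = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@chrom) != length(object@pos))
      msg <- c(msg, "chrom and pos must have the same length")
    if (length(object@lociPerChrom) != object@nChromosomes)
      msg <- c(msg, "lociPerChrom must have one entry per chromosome")
    if (!identical(as.integer(tabulate(object@chrom, object@nChromosomes)),
                   object@lociPerChrom))
      msg <- c(msg, "lociPerChrom inconsistent with chrom")
    for (c in seq_len(object@nChromosomes)) {
      p <- object@pos[object@chrom == c]
      if (length(p) && any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on chromosome %d", c))
        break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a marker map
#'
#' Lays out \code{lociPerChrom} loci per chromosome, evenly spaced on a
#' 1-Morgan chromosome: locus \eqn{j} (1-based) sits at genetic position
#' \eqn{(j - 0.5)/n} Morgans.
#'
#' @param nChromosomes number of chromosomes.
#' @param lociPerChrom loci per chromosome (scalar, same count everywhere).
#' @return A \linkS4class{MarkerMap}.
#' @examples
#' map <- markerMap(2, 100)
#' nLoci(map)
#' @export
markerMap <- function(nChromosomes, lociPerChrom) {
  nChromosomes <- as.integer(nChromosomes)
  lociPerChrom <- as.integer(lociPerChrom)
  stopifnot(nChromosomes >= 1, lociPerChrom >= 1)
  new("MarkerMap",
      nChromosomes = nChromosomes,
      chrom = rep(seq_len(nChromosomes), each = lociPerChrom),
      pos = rep((seq_len(lociPerChrom) - 0.5) / lociPerChrom, nChromosomes),
      lociPerChrom = rep(lociPerChrom, nChromosomes))
}

#' SimConfig: simulation parameters
#'
#' Holds every tunable of the simulated conservation study.  Defaults are
#' the reference study conditions: 20 boars and 100 sows kept constant, 18
#' chromosomes of 1,200 evenly spaced SNPs each, burn-in mutation rate
#' 2.5e-4 per locus per generation for 5,000 generations, conservation
#' mutation rate 2.5e-6 for 50 generations, and a MAF > 0.05 marker filter
#' retaining 1,000 loci per chromosome.
#'
#' @slot Nm,Nf males and females per generation.
#' @slot nChromosomes,nLociRaw chromosomes and raw loci per chromosome.
#' @slot nLociKeep loci kept per chromosome after the MAF filter
#'   (\code{NA} means keep every passing locus).
#' @slot muBurnin,muConservation per-locus per-generation mutation rates.
#' @slot tBurnin,tConservation generation counts of the two phases.
#' @slot mafThreshold minor-allele-frequency threshold of the marker filter.
#' @slot litterSize offspring per dam per generation.
#' @slot nReplicates replicates of the full study.
#' @slot baseSeed base random seed; replicate r uses baseSeed + r.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(Nm = "integer", Nf = "integer", nChromosomes = "integer",
                 nLociRaw = "integer", nLociKeep = "integer",
                 muBurnin = "numeric", muConservation = "numeric",
                 tBurnin = "integer", tConservation = "integer",
                 mafThreshold = "numeric", litterSize = "integer",
                 nReplicates = "integer", baseSeed = "integer"),
  validity = function(object) {
    msg <- character()
    counts <- c(object@Nm, object@Nf, object@nChromosomes, object@nLociRaw,
                object@tBurnin + 1L, object@tConservation + 1L,
                object@litterSize, object@nReplicates)
    if (any(counts < 1L)) msg <- c(msg, "all counts must be positive")
    if (object@muBurnin < 0 || object@muBurnin > 1 ||
        object@muConservation < 0 || object@muConservation > 1)
      msg <- c(msg, "mutation rates must lie in [0, 1]")
    if (!is.na(object@nLociKeep) && object@nLociKeep > object@nLociRaw)
      msg <- c(msg, "nLociKeep cannot exceed nLociRaw")
    if (object@mafThreshold < 0 || object@mafThreshold >= 0.5)
      msg <- c(msg, "mafThreshold must lie in [0, 0.5)")
    if (length(msg)) msg else TRUE
  })

#' Construct a simulation configuration
#'
#' @param Nm,Nf numbers of males and females (defaults 20 and 100).
#' @param nChromosomes,nLociRaw marker panel dimensions (18 x 1,200).
#' @param nLociKeep loci kept per chromosome by the MAF filter; \code{NA}
#'   keeps all passing loci.
#' @param muBurnin,muConservation mutation rates per locus per generation.
#' @param tBurnin,tConservation generations of burn-in and management.
#' @param mafThreshold MAF threshold of the marker filter.
#' @param litterSize offspring per dam per generation.
#' @param nReplicates study replicates.
#' @param baseSeed base random seed.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nChromosomes = 2, tBurnin = 100)
#' effectiveSize(cfg)
#' @export
simConfig <- function(Nm = 20, Nf = 100, nChromosomes = 18, nLociRaw = 1200,
                      nLociKeep = 1000, muBurnin = 2.5e-4,
                      muConservation = 2.5e-6, tBurnin = 5000,
                      tConservation = 50, mafThreshold = 0.05,
                      litterSize = 10, nReplicates = 100, baseSeed = 1) {
  new("SimConfig", Nm = as.integer(Nm), Nf = as.integer(Nf),
      nChromosomes = as.integer(nChromosomes),
      nLociRaw = as.integer(nLociRaw), nLociKeep = as.integer(nLociKeep),
      muBurnin = muBurnin, muConservation = muConservation,
      tBurnin = as.integer(tBurnin), tConservation = as.integer(tConservation),
      mafThreshold = mafThreshold, litterSize = as.integer(litterSize),
      nReplicates = as.integer(nReplicates), baseSeed = as.integer(baseSeed))
}

#' ManagementPolicy: the equal-procedure replacement rule
#'
#' Describes the replacement scheme of the conservation program: every sire
#' family (the progeny group of one boar) contributes exactly one
#' replacement boar, and replacement gilts are drawn from distinct sows
#' wherever possible, equalising family contributions and so reducing the
#' variance of family size.
#'
#' @slot oneBoarPerSireFamily retain exactly one boar per sire family.
#' @slot giltsFromDistinctDams retain at most one gilt per dam while enough
#'   dams have female offspring; otherwise the constraint relaxes to fill
#'   the quota.
#' @slot litterSize offspring per dam (\code{NA}: taken from the config).
#' @exportClass ManagementPolicy
setClass("ManagementPolicy",
  representation(oneBoarPerSireFamily = "logical",
                 giltsFromDistinctDams = "logical",
                 litterSize = "integer"))

#' Construct a management policy
#'
#' @param oneBoarPerSireFamily keep one boar per sire family (default TRUE).
#' @param giltsFromDistinctDams keep at most one gilt per sow (default TRUE).
#' @param litterSize offspring per dam; \code{NA} defers to the config.
#' @return A \linkS4class{ManagementPolicy}.
#' @export
managementPolicy <- function(oneBoarPerSireFamily = TRUE,
                             giltsFromDistinctDams = TRUE,
                             litterSize = NA) {
  new("ManagementPolicy", oneBoarPerSireFamily = oneBoarPerSireFamily,
      giltsFromDistinctDams = giltsFromDistinctDams,
      litterSize = as.integer(litterSize))
}

#' Population: one generation of double-labeled diploid individuals
#'
#' The central container.  Individual i owns two haplotype columns
#' (2i - 1 and 2i) of the locus-by-haplotype \code{states} matrix (alleles
#' coded 1/2).  A labeled population carries a parallel \code{labels}
#' matrix whose entries name the founder individual each allele copy
#' descends from; the founder label set is stamped at t = 0 and can only
#' shrink afterwards.
#'
#' @slot generation generation index t (0 = end of burn-in).
#' @slot id integer individual ids, unique within the pedigree.
#' @slot sex 1 = male, 2 = female.
#' @slot sire,dam parent ids (\code{NA} for founders).
#' @slot states L x 2N integer matrix of allele states in \{1, 2\}.
#' @slot labels L x 2N integer matrix of founder labels, or 0 x 0 when the
#'   population is unlabeled.
#' @slot founderSex sex (1/2) of each founder label, or length 0 when
#'   unlabeled.
#' @slot map the \linkS4class{MarkerMap}.
#' @exportClass Population
setClass("Population",
  representation(generation = "integer", id = "integer", sex = "integer",
                 sire = "integer", dam = "integer", states = "matrix",
                 labels = "matrix", founderSex = "integer",
                 map = "MarkerMap"),
  validity = function(object) {
    msg <- character()
    n <- length(object@id)
    if (length(object@sex) != n || length(object@sire) != n ||
        length(object@dam) != n)
      msg <- c(msg, "id, sex, sire, dam must have equal length")
    if (ncol(object@states) != 2L * n)
      msg <- c(msg, "states must have two haplotype columns per individual")
    if (nrow(object@states) != length(object@map@chrom))
      msg <- c(msg, "states rows must match the marker map")
    r <- suppressWarnings(range(object@states))
    if (is.finite(r[1]) && (r[1] < 1L || r[2] > 2L))
      msg <- c(msg, "allele states must be 1 or 2")
    if (nrow(object@labels) > 0 &&
        !identical(dim(object@labels), dim(object@states)))
      msg <- c(msg, "labels must match states in dimension")
    if (nrow(object@labels) > 0 && length(object@founderSex) == 0)
      msg <- c(msg, "labeled population needs founderSex")
    if (anyDuplicated(object@id)) msg <- c(msg, "individual ids must be unique")
    if (length(msg)) msg else TRUE
  })

# internal constructor used by the simulators (skips redundant coercions)
newPopulation <- function(generation, id, sex, sire, dam, states, labels,
                          founderSex, map) {
  new("Population", generation = as.integer(generation), id = as.integer(id),
      sex = as.integer(sex), sire = as.integer(sire), dam = as.integer(dam),
      states = states, labels = labels,
      founderSex = as.integer(founderSex), map = map)
}
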