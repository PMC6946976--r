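#' @name accessors
#' @title Accessors for founderTrace objects
#'
#' @description Small accessor generics used across the package:
#' \code{nLoci} (locus count), \code{nIndividuals}, \code{generation}
#' (generation index t), \code{isLabeled} (does the population carry founder
#' labels), \code{alleleStates} and \code{founderLabels} (the two layers of
#' the double label), \code{chromosomes} (per-locus chromosome index), and
#' \code{effectiveSize} (variance effective size 4NmNf/(Nm + Nf)).
#'
#' @param x a \linkS4class{Population}, \linkS4class{MarkerMap} or
#'   \linkS4class{SimConfig}.
#' @return See the individual descriptions.
NULL

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))
#' @rdname accessors
#' @export
setGeneric("isLabeled", function(x) standardGeneric("isLabeled"))
#' @rdname accessors
#' @export
setGeneric("alleleStates", function(x) standardGeneric("alleleStates"))
#' @rdname accessors
#' @export
setGeneric("founderLabels", function(x) standardGeneric("founderLabels"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("effectiveSize", function(x) standardGeneric("effectiveSize"))

#' @rdname accessors
setMethod("nLoci", "MarkerMap", function(x) length(x@chrom))
#' @rdname accessors
setMethod("nLoci", "Population", function(x) nrow(x@states))
#' @rdname accessors
setMethod("nIndividuals", "Population", function(x) length(x@id))
#' @rdname accessors
setMethod("generation", "Population", function(x) x@generation)
#' @rdname accessors
setMethod("isLabeled", "Population", function(x) nrow(x@labels) > 0)
#' @rdname accessors
setMethod("alleleStates", "Population", function(x) x@states)
#' @rdname accessors
setMethod("founderLabels", "Population", function(x) {
  if (!isLabeled(x)) stop("population carries no founder labels")
  x@labels
})
#' @rdname accessors
setMethod("chromosomes", "MarkerMap", function(x) x@chrom)
#' @rdname accessors
setMethod("chromosomes", "Population", function(x) x@map@chrom)
#' @rdname accessors
setMethod("effectiveSize", "SimConfig", function(x)
  4 * x@Nm * x@Nf / (x@Nm + x@Nf))

#' @rdname accessors
#' @export
sexOf <- function(x) x@sex

#' @rdname accessors
#' @export
markerMapOf <- function(x) x@map

setMethod("show", "MarkerMap", function(object) {
  cat(sprintf("MarkerMap: %d chromosome(s), %d loci (%s per chromosome)\n",
              object@nChromosomes, length(object@chrom),
              paste(object@lociPerChrom, collapse = "/")))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  population      : %d males + %d females (Ne = %.2f)\n",
              object@Nm, object@Nf, effectiveSize(object)))
  cat(sprintf("  markers         : %d chromosomes x %d loci (keep %s at MAF > %g)\n",
              object@nChromosomes, object@nLociRaw,
              ifelse(is.na(object@nLociKeep), "all passing",
                     as.character(object@nLociKeep)),
              object@mafThreshold))
  cat(sprintf("  burn-in         : %d generations, mu = %g\n",
              object@tBurnin, object@muBurnin))
  cat(sprintf("  conservation    : %d generations, mu = %g, litter %d\n",
              object@tConservation, object@muConservation, object@litterSize))
  cat(sprintf("  replication     : %d replicates, base seed %d\n",
              object@nReplicates, object@baseSeed))
})

setMethod("show", "Population", function(object) {
  cat(sprintf("Population at t = %d: %d males + %d females, %d loci on %d chromosome(s), %s\n",
              object@generation, sum(object@sex == 1L), sum(object@sex == 2L),
              nLoci(object), object@map@nChromosomes,
              if (isLabeled(object)) "founder-labeled" else "unlabeled"))
})

setMethod("show", "ManagementPolicy", function(object) {
  cat(sprintf("ManagementPolicy: one boar per sire family = %s, gilts from distinct dams = %s\n",
              object@oneBoarPerSireFamily, object@giltsFromDistinctDams))
})

# chromosome row offsets (0-based, length nChrom + 1) for the C++ kernels
chromStarts <- function(map) {
  c(0L, cumsum(map@lociPerChrom))
}

# subset a population to a set of individuals (columns) by index
subsetIndividuals <- function(pop, idx) {
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  newPopulation(pop@generation, pop@id[idx], pop@sex[idx], pop@sire[idx],
                pop@dam[idx], pop@states[, cols, drop = FALSE],
                if (isLabeled(pop)) pop@labels[, cols, drop = FALSE]
                else pop@labels,
                pop@founderSex, pop@map)
}
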