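#' Expected genome-wide mutation count per generation
#'
#' Mean of the Poisson draw governing new mutations each generation:
#' 2 Ne nc mu nl, with Ne = 4NmNf/(Nm + Nf) the variance effective size,
#' nc the chromosome count and nl the loci per chromosome.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param mu mutation rate per locus per generation (defaults to the
#'   burn-in rate in \code{config}).
#' @param nLoci loci per chromosome entering the mean (defaults to the raw
#'   panel size).
#' @return The Poisson mean (numeric scalar).
#' @examples
#' expectedMutations(simConfig())  # 2 x 66.67 x 18 x 2.5e-4 x 1200 = 720
#' @export
expectedMutations <- function(config, mu = config@muBurnin,
                              nLoci = config@nLociRaw) {
  2 * effectiveSize(config) * config@nChromosomes * mu * nLoci
}

#' Apply random state-flip mutations
#'
#' Draws K ~ Poisson(2 Ne nc mu nl) and flips the allele state (1 to 2 or
#' 2 to 1) of K uniformly random (individual, haplotype, locus) targets.
#' Flipping makes reversion (2 to 1) automatically rare while allele 1
#' dominates.  Labels are never touched: a mutated copy still physically
#' descends from its founder, so a post-t0 mutation breaks IBD (which
#' requires matching state and label) but not ancestry.
#'
#' @param population a \linkS4class{Population}.
#' @param mu per-locus per-generation mutation rate.
#' @param config a \linkS4class{SimConfig} supplying Ne; the locus count of
#'   the population itself is used for nc x nl.
#' @param nEvents optional fixed number of mutation events (overrides the
#'   Poisson draw; used in tests).
#' @return The mutated population.
#' @export
mutatePopulation <- function(population, mu, config, nEvents = NULL) {
  stopifnot(is(population, "Population"))
  if (is.null(nEvents)) {
    if (mu == 0) return(population)
    mean <- 2 * effectiveSize(config) * mu * nLoci(population)
    nEvents <- rpois(1L, mean)
  }
  if (nEvents == 0L) return(population)
  H <- ncol(population@states)
  L <- nLoci(population)
  rows <- sample.int(L, nEvents, replace = TRUE)
  cols <- sample.int(H, nEvents, replace = TRUE)
  idx <- cbind(rows, cols)
  population@states[idx] <- 3L - population@states[idx]
  population
}

#' Draw one recombinant gamete from a parent
#'
#' Meiosis for one individual: per chromosome, the crossover count is
#' Poisson(1), crossover positions are uniform on the 1-Morgan chromosome,
#' the source haplotype starts from a fair coin and switches at every
#' crossover.  States and labels travel together, since a label is
#' physically attached to its allele copy.
#'
#' @param population a \linkS4class{Population}.
#' @param individual index (1-based) of the parent within the population.
#' @param chromosome optional chromosome index; \code{NULL} (default)
#'   returns a whole-genome gamete.
#' @param record if TRUE, also return the per-locus source haplotype
#'   (0 = first, 1 = second parental haplotype).
#' @return A list with \code{states}, \code{labels} (integer(0) when the
#'   population is unlabeled), \code{crossovers} (count per chromosome) and
#'   \code{source} (per-locus source haplotype when \code{record}).
#' @export
recombineGamete <- function(population, individual, chromosome = NULL,
                            record = FALSE) {
  stopifnot(is(population, "Population"),
            individual >= 1, individual <= nIndividuals(population))
  map <- population@map
  if (is.null(chromosome)) {
    st <- population@states
    lb <- population@labels
    starts <- chromStarts(map)
  } else {
    rows <- which(map@chrom == chromosome)
    st <- population@states[rows, , drop = FALSE]
    lb <- if (isLabeled(population))
      population@labels[rows, , drop = FALSE] else population@labels
    starts <- c(0L, length(rows))
  }
  cpp_gamete(st, lb, isLabeled(population), as.integer(individual) - 1L,
             as.integer(starts), record)
}

#' One generation of random mating
#'
#' Each of the Nm + Nf offspring draws a uniformly random sire among the
#' males and a uniformly random dam among the females (independently per
#' offspring), receives one recombinant gamete from each, and is assigned a
#' sex so that exactly Nm male and Nf female slots are filled.  Mutation is
#' applied after gamete formation.
#'
#' @param population a \linkS4class{Population}.
#' @param mu mutation rate per locus per generation (0 disables mutation).
#' @param config a \linkS4class{SimConfig} (supplies Ne for the mutation
#'   mean; defaults to the population's own sex counts).
#' @return The next-generation \linkS4class{Population}.
#' @export
randomMatingGeneration <- function(population, mu = 0,
                                   config = simConfigFromPopulation(population)) {
  stopifnot(is(population, "Population"))
  males <- which(population@sex == 1L)
  females <- which(population@sex == 2L)
  if (!length(males) || !length(females)) stop("both sexes must be present")
  Nm <- length(males); Nf <- length(females); n <- Nm + Nf
  sire <- sample(males, n, replace = TRUE)
  dam <- sample(females, n, replace = TRUE)
  off <- cpp_offspring(population@states, population@labels,
                       isLabeled(population), as.integer(sire) - 1L,
                       as.integer(dam) - 1L,
                       as.integer(chromStarts(population@map)))
  ids <- max(population@id) + seq_len(n)
  out <- newPopulation(generation(population) + 1L, ids,
                       rep(c(1L, 2L), c(Nm, Nf)),
                       population@id[sire], population@id[dam],
                       off$states, off$labels, population@founderSex,
                       population@map)
  if (mu > 0) out <- mutatePopulation(out, mu, config)
  out
}

# config mirroring a population's sex counts (for mutation means)
simConfigFromPopulation <- function(population) {
  simConfig(Nm = max(1L, sum(population@sex == 1L)),
            Nf = max(1L, sum(population@sex == 2L)),
            nChromosomes = population@map@nChromosomes,
            nLociRaw = max(population@map@lociPerChrom),
            nLociKeep = NA, tBurnin = 1, tConservation = 1)
}

#' Run the burn-in to mutation-drift equilibrium
#'
#' Starts every locus fixed at state 1 at t = -tBurnin and iterates random
#' mating with Poisson(2 Ne nc mu nl) state-flip mutations for tBurnin
#' generations, returning the t = 0 base population.  Founder labels are
#' not tracked during burn-in (they are stamped at t = 0 by
#' [makeFounderLabels()]).  A mean-He trace over all raw loci is recorded
#' (every \code{traceEvery} generations) so equilibrium can be checked
#' post hoc; retrieve it with [burninTrace()].
#'
#' @param config a \linkS4class{SimConfig}.
#' @param traceEvery cadence of the He trace in generations (0 disables).
#' @return The unlabeled t = 0 \linkS4class{Population}.
#' @export
runBurnin <- function(config, traceEvery = 10L) {
  stopifnot(is(config, "SimConfig"))
  res <- cpp_burnin(config@nLociRaw, config@nChromosomes, config@Nm,
                    config@Nf, config@tBurnin,
                    expectedMutations(config), as.integer(traceEvery))
  n <- config@Nm + config@Nf
  map <- markerMap(config@nChromosomes, config@nLociRaw)
  pop <- newPopulation(0L, seq_len(n), rep(c(1L, 2L), c(config@Nm, config@Nf)),
                       rep(NA_integer_, n), rep(NA_integer_, n),
                       res$states, matrix(integer(0), 0, 0), integer(0), map)
  attr(pop, "burninTrace") <- data.frame(generation = res$traceGeneration,
                                         He = res$traceHe)
  pop
}

#' Burn-in diversity trace
#'
#' @param population a population returned by [runBurnin()].
#' @return A data.frame with columns \code{generation} (relative to t = 0)
#'   and \code{He}, or \code{NULL} if no trace was recorded.
#' @export
burninTrace <- function(population) attr(population, "burninTrace")
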