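#' Assign dams to sires for one breeding season
#'
#' Randomly partitions the dams among the sires.  When Nf is divisible by
#' Nm every sire receives exactly Nf/Nm dams; otherwise the remainder is
#' spread round-robin so sire groups differ by at most one dam.  Every dam
#' is mated exactly once.
#'
#' @param population a \linkS4class{Population}.
#' @param policy a \linkS4class{ManagementPolicy} (reserved for future
#'   mating designs; the partition itself is policy-free).
#' @return A data.frame with one row per dam: \code{sire}, \code{dam}
#'   (individual ids).
#' @export
assignMatings <- function(population, policy = managementPolicy()) {
  males <- which(population@sex == 1L)
  females <- which(population@sex == 2L)
  if (!length(males) || !length(females))
    stop("cannot assign matings: a sex class is empty")
  Nm <- length(males); Nf <- length(females)
  dams <- sample(females)                        # random partition
  sires <- males[rep(seq_len(Nm), length.out = Nf)]  # round-robin counts
  data.frame(sire = population@id[sires], dam = population@id[dams])
}

#' Produce the offspring pool of one managed generation
#'
#' Every mated pair produces \code{litterSize} offspring; each offspring
#' receives one recombinant gamete from its sire and one from its dam, and
#' a fair-coin sex.
#'
#' @param population the parent \linkS4class{Population}.
#' @param matings data.frame from [assignMatings()].
#' @param litterSize offspring per dam.
#' @return The offspring-pool \linkS4class{Population} (generation t + 1,
#'   size Nf x litterSize).
#' @export
makeLitters <- function(population, matings, litterSize) {
  sireIdx <- match(matings$sire, population@id)
  damIdx <- match(matings$dam, population@id)
  sire0 <- rep(sireIdx, each = litterSize)
  dam0 <- rep(damIdx, each = litterSize)
  nOff <- length(sire0)
  off <- cpp_offspring(population@states, population@labels,
                       isLabeled(population), as.integer(sire0) - 1L,
                       as.integer(dam0) - 1L,
                       as.integer(chromStarts(population@map)))
  sex <- rbinom(nOff, 1L, 0.5) + 1L
  newPopulation(generation(population) + 1L,
                max(population@id) + seq_len(nOff), sex,
                population@id[sire0], population@id[dam0],
                off$states, off$labels, population@founderSex,
                population@map)
}

#' Select replacements by the equal procedure
#'
#' Implements the replacement rule of the conservation program: every sire
#' family (progeny group of one boar) retains exactly one boar, chosen
#' uniformly among its male offspring, giving Nm male lines that never
#' merge; Nf gilts are retained with at most one per dam while at least Nf
#' dams have female offspring, relaxing to fill the quota otherwise.
#'
#' @param pool the offspring-pool \linkS4class{Population} from
#'   [makeLitters()].
#' @param policy a \linkS4class{ManagementPolicy}.
#' @param Nm,Nf males and females to retain.
#' @return The next-generation \linkS4class{Population} (boars first).
#' @export
selectReplacements <- function(pool, policy, Nm, Nf) {
  isMale <- pool@sex == 1L
  boars <- integer(0)
  if (policy@oneBoarPerSireFamily) {
    for (s in unique(pool@sire)) {
      cand <- which(pool@sire == s & isMale)
      if (!length(cand))
        stop(sprintf(
          "sire family %d has no male offspring; increase litterSize", s))
      boars <- c(boars, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    if (length(boars) != Nm)
      stop("number of sire families does not match Nm")
  } else {
    boars <- sample(which(isMale), Nm)
  }
  gilts <- integer(0)
  if (policy@giltsFromDistinctDams) {
    byDam <- split(which(!isMale), pool@dam[!isMale])
    picks <- vapply(byDam, function(cand)
      if (length(cand) == 1L) cand else sample(cand, 1L), integer(1))
    if (length(picks) >= Nf) {
      gilts <- sample(picks, Nf)
    } else {  # not enough dams with daughters: relax to fill the quota
      gilts <- picks
      rest <- setdiff(which(!isMale), gilts)
      gilts <- c(gilts, sample(rest, Nf - length(gilts)))
    }
  } else {
    gilts <- sample(which(!isMale), Nf)
  }
  subsetIndividuals(pool, c(sort(boars), sort(gilts)))
}

#' Manage a labeled base population for tConservation generations
#'
#' Iterates assign matings, litters, mutation (at the conservation rate),
#' and equal-procedure replacement for \code{config@tConservation}
#' generations, recording per-generation summaries: diversity measures,
#' label-based IBD and state-based IBS (raw and baseline-adjusted),
#' genealogical F, parental genomic components, and (every
#' \code{spectrumEvery} generations) the allele-frequency spectrum and the
#' LD-based Ne estimate.
#'
#' @param base the labeled, filtered t = 0 \linkS4class{Population}.
#' @param config a \linkS4class{SimConfig}.
#' @param policy a \linkS4class{ManagementPolicy}.
#' @param spectrumEvery cadence (generations) of spectra and Ne estimates;
#'   0 disables them.
#' @param keepEvery keep full population snapshots every so many
#'   generations (0 = only the final one).
#' @return A \code{conservationTrace} list with elements
#'   \code{diversity} (data.frame, one row per generation),
#'   \code{identity} (data.frame: ibd, ibsRaw, ibsAdjusted, F),
#'   \code{pgc} (founder x generation matrix of shares),
#'   \code{spectra}, \code{ne}, \code{snapshots}, \code{final},
#'   \code{founderSex}, \code{config}.
#' @export
runConservation <- function(base, config, policy = managementPolicy(),
                            spectrumEvery = 5L, keepEvery = 0L) {
  stopifnot(is(base, "Population"), isLabeled(base), generation(base) == 0L)
  litter <- if (is.na(policy@litterSize)) config@litterSize
            else policy@litterSize
  Tc <- config@tConservation
  pop <- base
  divRows <- vector("list", Tc + 1L)
  idRows <- vector("list", Tc + 1L)
  pgcCols <- vector("list", Tc + 1L)
  spectra <- list(); neRows <- list(); snapshots <- list()
  baselineIbs <- NULL
  for (t in 0:Tc) {
    if (t > 0L) {
      matings <- assignMatings(pop, policy)
      pool <- makeLitters(pop, matings, litter)
      pool <- mutatePopulation(pool, config@muConservation, config)
      pop <- selectReplacements(pool, policy, config@Nm, config@Nf)
    }
    divRows[[t + 1L]] <- diversitySummary(pop, scope = "genome")
    ibd <- ibdProbability(pop)
    ibs <- ibsProbability(pop, baseline = baselineIbs)
    if (t == 0L) baselineIbs <- ibs
    idRows[[t + 1L]] <- data.frame(
      t = t, ibd = ibd$ibd, ibsRaw = ibs$ibsRaw,
      ibsAdjusted = ibs$ibsAdjusted,
      F = genealogicalF(t, config@Nm, config@Nf)$F)
    pgcCols[[t + 1L]] <- pgcTable(pop)
    if (spectrumEvery > 0L && t %% spectrumEvery == 0L) {
      spectra[[as.character(t)]] <-
        frequencySpectrum(alleleFrequencies(pop), t)
      Fnow <- genealogicalF(t, config@Nm, config@Nf)$F
      ld <- tryCatch(
        ldNe(genotypeDosage(pop), chromosomes(pop)),
        error = function(e) list(neLd = NA_real_, meanR2 = NA_real_))
      neRows[[as.character(t)]] <- data.frame(
        t = t, neTheoretical = theoreticalNe(config@Nm, config@Nf, Fnow)$ne,
        neLd = ld$neLd, meanR2 = ld$meanR2)
    }
    if (keepEvery > 0L && t %% keepEvery == 0L)
      snapshots[[as.character(t)]] <- pop
  }
  structure(list(
    diversity = do.call(rbind, divRows),
    identity = do.call(rbind, idRows),
    pgc = do.call(cbind, setNames(pgcCols, 0:Tc)),
    spectra = spectra,
    ne = if (length(neRows)) do.call(rbind, neRows) else NULL,
    snapshots = snapshots,
    final = pop,
    founderSex = base@founderSex,
    config = config), class = "conservationTrace")
}

#' @export
print.conservationTrace <- function(x, ...) {
  Tc <- max(x$diversity$t)
  cat(sprintf("conservationTrace: %d generations of equal-procedure management\n", Tc))
  cat(sprintf("  He: %.4f (t=0) -> %.4f (t=%d)\n",
              x$diversity$He[1], x$diversity$He[nrow(x$diversity)], Tc))
  cat(sprintf("  IBD: %.4f -> %.4f;  F: %.4f\n",
              x$identity$ibd[1], x$identity$ibd[nrow(x$identity)],
              x$identity$F[nrow(x$identity)]))
  surv <- familySurvival(x$pgc, "female", x$founderSex)
  cat(sprintf("  female families: %d -> %d\n",
              surv$surviving[1], surv$surviving[nrow(surv)]))
  invisible(x)
}
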