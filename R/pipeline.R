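#' Run one full replicate chain
#'
#' Burn-in to the base population, founder labeling, MAF marker filtering,
#' and managed conservation, under one seed.  All randomness flows through
#' R's RNG, so a given (config, policy, seed) triple is bit-reproducible.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param policy a \linkS4class{ManagementPolicy}.
#' @param seed integer seed for this replicate.
#' @param ... passed on to [runConservation()].
#' @return The \code{conservationTrace} of the replicate, with extra
#'   elements \code{seed}, \code{keptPerChrom}, and \code{burninTrace}.
#' @export
runReplicate <- function(config, policy = managementPolicy(), seed = 1L,
                         ...) {
  set.seed(seed)
  base <- runBurnin(config)
  labeled <- makeFounderLabels(base)
  nKeep <- if (is.na(config@nLociKeep)) NULL else config@nLociKeep
  filt <- applyMarkerFilter(labeled, config@mafThreshold, nKeep)
  trace <- runConservation(filt$population, config, policy, ...)
  trace$seed <- seed
  trace$keptPerChrom <- filt$population@map@lociPerChrom
  trace$burninTrace <- burninTrace(base)
  trace
}

#' Run the replicated conservation study
#'
#' Runs \code{nReplicates} independent chains (replicate r is seeded with
#' \code{baseSeed + r}, so replicates are independent and individually
#' reproducible), and aggregates replicate means and standard deviations
#' of every trajectory, the decline-interval table, and the
#' family-survival curves.  A failing replicate is logged and excluded;
#' more than 10\% failures aborts the study.
#'
#' @param config a \linkS4class{SimConfig} (supplies \code{nReplicates}
#'   and \code{baseSeed}).
#' @param policy a \linkS4class{ManagementPolicy}.
#' @param nReplicates,baseSeed optional overrides of the config values.
#' @param verbose print one progress line per replicate.
#' @param ... passed to [runReplicate()].
#' @return A \code{studyReport} list: \code{diversity} and \code{identity}
#'   (data.frames of per-generation replicate means and SDs),
#'   \code{declines} (decline-interval table including the analytic F
#'   column), \code{familySurvival} (mean surviving families per
#'   generation and sex), \code{replicates} (the individual traces),
#'   \code{config}, \code{nCompleted}.
#' @export
runStudy <- function(config, policy = managementPolicy(),
                     nReplicates = config@nReplicates,
                     baseSeed = config@baseSeed, verbose = FALSE, ...) {
  reps <- vector("list", nReplicates)
  failed <- 0L
  for (r in seq_len(nReplicates)) {
    res <- tryCatch(
      runReplicate(config, policy, seed = baseSeed + r, ...),
      error = function(e) {
        warning(sprintf("replicate %d (seed %d) failed: %s",
                        r, baseSeed + r, conditionMessage(e)))
        NULL
      })
    reps[r] <- list(res)
    if (is.null(res)) failed <- failed + 1L
    if (verbose)
      message(sprintf("replicate %d/%d %s", r, nReplicates,
                      if (is.null(res)) "FAILED" else "done"))
  }
  if (failed > 0.1 * nReplicates)
    stop(sprintf("%d of %d replicates failed", failed, nReplicates))
  reps <- Filter(Negate(is.null), reps)
  div <- aggregateTrajectories(lapply(reps, `[[`, "diversity"),
                               c("He", "Ho", "Ao", "Ae", "PIC", "Pp", "RA"))
  ident <- aggregateTrajectories(lapply(reps, `[[`, "identity"),
                                 c("ibd", "ibsRaw", "ibsAdjusted", "F"))
  surv <- lapply(c(female = "female", male = "male"), function(sx) {
    per <- sapply(reps, function(rp)
      familySurvival(rp$pgc, sx, rp$founderSex)$surviving)
    data.frame(t = 0:config@tConservation, mean = rowMeans(per),
               sd = apply(per, 1, sd))
  })
  meanTraj <- function(df, col) df[[paste0(col, "_mean")]]
  declines <- declineTable(
    list(IBD_complement = 1 - meanTraj(ident, "ibd"),
         He = meanTraj(div, "He"), Ho = meanTraj(div, "Ho"),
         Ao = meanTraj(div, "Ao"), Ae = meanTraj(div, "Ae"),
         Pp = meanTraj(div, "Pp")),
    deltaF = genealogicalF(0, config@Nm, config@Nf)$deltaF)
  structure(list(diversity = div, identity = ident, declines = declines,
                 familySurvival = surv, replicates = reps, config = config,
                 nCompleted = length(reps)),
            class = "studyReport")
}

aggregateTrajectories <- function(dfs, cols) {
  t <- dfs[[1]]$t
  out <- data.frame(t = t)
  for (col in cols) {
    m <- sapply(dfs, `[[`, col)
    out[[paste0(col, "_mean")]] <- rowMeans(m)
    out[[paste0(col, "_sd")]] <- apply(m, 1, sd)
  }
  out
}

#' @export
print.studyReport <- function(x, ...) {
  Tc <- max(x$diversity$t)
  cat(sprintf("studyReport: %d replicates, %d conservation generations\n",
              x$nCompleted, Tc))
  last <- nrow(x$diversity)
  cat(sprintf("  He  : %.4f -> %.4f   Ho: %.4f -> %.4f\n",
              x$diversity$He_mean[1], x$diversity$He_mean[last],
              x$diversity$Ho_mean[1], x$diversity$Ho_mean[last]))
  cat(sprintf("  Ao  : %.3f -> %.3f    Ae: %.3f -> %.3f   Pp: %.3f -> %.3f\n",
              x$diversity$Ao_mean[1], x$diversity$Ao_mean[last],
              x$diversity$Ae_mean[1], x$diversity$Ae_mean[last],
              x$diversity$Pp_mean[1], x$diversity$Pp_mean[last]))
  cat(sprintf("  IBD : %.4f -> %.4f   F(t=%d) = %.4f\n",
              x$identity$ibd_mean[1], x$identity$ibd_mean[last], Tc,
              x$identity$F_mean[last]))
  cat(sprintf("  female families: %.1f -> %.1f\n",
              x$familySurvival$female$mean[1],
              x$familySurvival$female$mean[last]))
  invisible(x)
}

#' Write a study report as TSV files
#'
#' @param report a \code{studyReport}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("diversity", "identity", "declines")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(report[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  for (sx in names(report$familySurvival)) {
    p <- file.path(dir, paste0("family_survival_", sx, ".tsv"))
    write.table(report$familySurvival[[sx]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Measurement-only mode for external genotypes
#'
#' Applies the measurement layer to externally supplied data: a phased VCF
#' plus (optionally) the sidecar founder-label track written by
#' [exportGenotypes()].  Diversity measures and the GRM are always
#' computed; IBD and parental genomic components are skipped with a
#' warning when no labels are available.
#'
#' @param vcfPath path to the VCF.
#' @param labelsPath optional sidecar label TSV.
#' @param pedigreePath optional pedigree TSV.
#' @param mafThreshold optional MAF filter applied before measurement
#'   (\code{NULL}: measure all loci as given).
#' @return A list with \code{population}, \code{diversity},
#'   \code{identity} (IBS always; IBD when labeled), \code{pgc} (or
#'   \code{NULL}), and \code{grm}.
#' @export
measureOnly <- function(vcfPath, labelsPath = NULL, pedigreePath = NULL,
                        mafThreshold = NULL) {
  pop <- importGenotypes(vcfPath, labelsPath, pedigreePath)
  if (!is.null(mafThreshold))
    pop <- applyMarkerFilter(pop, mafThreshold, nKeep = NULL)$population
  div <- diversitySummary(pop)
  ibs <- ibsProbability(pop)
  if (isLabeled(pop)) {
    ibd <- ibdProbability(pop)
    pgc <- pgcTable(pop)
  } else {
    warning("no label track supplied; IBD and PGC skipped")
    ibd <- NULL; pgc <- NULL
  }
  list(population = pop, diversity = div,
       identity = list(ibd = ibd, ibs = ibs), pgc = pgc,
       grm = grm(pop))
}
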