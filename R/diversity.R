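#' Gene-frequency diversity summary
#'
#' Standard biallelic diversity measures from per-locus allele frequencies
#' p (state-2 allele) and q = 1 - p:
#' \itemize{
#'   \item He (Nei's expected heterozygosity): mean of 2pq;
#'   \item Ho: observed heterozygote fraction;
#'   \item Ao: observed number of alleles (count with copies present);
#'   \item Ae (effective number of alleles): mean of 1/(p^2 + q^2);
#'   \item PIC (Botstein): mean of 1 - (p^2 + q^2) - 2 p^2 q^2;
#'   \item Pp: fraction of loci with both alleles segregating;
#'   \item RA: number of rare alleles, i.e. alleles with frequency in
#'     (0, 0.05), counted over alleles (a locus can contribute one).
#' }
#' Means are over the loci in scope; no sample-size correction is applied.
#'
#' @param population a \linkS4class{Population}.
#' @param scope "genome" for one genome-wide row, "chromosome" for one row
#'   per chromosome.
#' @return A data.frame with columns t, scope, nLoci, He, Ho, Ao, Ae, PIC,
#'   Pp, RA.
#' @examples
#' # a locus with p = 0.5 contributes He = 0.5, Ae = 2, PIC = 0.375
#' @export
diversitySummary <- function(population, scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  stopifnot(is(population, "Population"))
  p <- alleleFrequencies(population)
  st <- population@states
  n <- nIndividuals(population)
  het <- rowMeans(st[, seq(1, 2 * n, 2), drop = FALSE] !=
                  st[, seq(2, 2 * n, 2), drop = FALSE])
  oneScope <- function(rows, label) {
    pr <- p[rows]; qr <- 1 - pr
    poly <- pr > 0 & pr < 1
    hom <- pr^2 + qr^2
    data.frame(
      t = generation(population), scope = label, nLoci = length(rows),
      He = mean(2 * pr * qr), Ho = mean(het[rows]),
      Ao = mean(1 + poly), Ae = mean(1 / hom),
      PIC = mean(1 - hom - 2 * pr^2 * qr^2), Pp = mean(poly),
      RA = sum(pr > 0 & pr < 0.05) + sum(qr > 0 & qr < 0.05))
  }
  if (scope == "genome") {
    oneScope(seq_along(p), "genome")
  } else {
    do.call(rbind, lapply(seq_len(population@map@nChromosomes), function(c)
      oneScope(which(chromosomes(population) == c), as.character(c))))
  }
}

#' Allele-frequency spectrum
#'
#' Sorts the state-2 allele frequency of every locus into 12 bins: "lost"
#' (exactly 0), ten right-closed interior bins (0, 0.1], ..., (0.9, 1), and
#' "fixed" (exactly 1).  Counts sum to the locus count.
#'
#' @param frequencies per-locus frequencies in [0, 1].
#' @param t generation index to record.
#' @return A data.frame with columns t, bin, count.
#' @export
frequencySpectrum <- function(frequencies, t = NA_integer_) {
  if (any(frequencies < 0 | frequencies > 1))
    stop("frequencies must lie in [0, 1]")
  interior <- frequencies > 0 & frequencies < 1
  edges <- seq(0, 1, 0.1)
  labs <- paste0("(", head(edges, -1), ",", tail(edges, -1), "]")
  cuts <- cut(frequencies[interior], breaks = edges, right = TRUE,
              include.lowest = FALSE, labels = labs)
  data.frame(t = t, bin = c("lost", labs, "fixed"),
             count = c(sum(frequencies == 0), as.integer(table(cuts)),
                       sum(frequencies == 1)))
}

#' Genealogical inbreeding coefficient
#'
#' Closed form under the idealised unequal-sex-ratio pedigree:
#' deltaF = 1/(8 Nm) + 1/(8 Nf) per generation and
#' F(t) = 1 - (1 - deltaF)^t, with F(0) = 0 (founders assumed unrelated).
#'
#' @param t generation (vectorised).
#' @param Nm,Nf male and female numbers.
#' @return A data.frame with columns t, Nm, Nf, deltaF, F.
#' @examples
#' genealogicalF(50, 20, 100)  # deltaF = 0.0075, F = 0.3137
#' @export
genealogicalF <- function(t, Nm, Nf) {
  stopifnot(all(t >= 0), Nm >= 1, Nf >= 1)
  deltaF <- 1 / (8 * Nm) + 1 / (8 * Nf)
  data.frame(t = t, Nm = Nm, Nf = Nf, deltaF = deltaF,
             F = 1 - (1 - deltaF)^t)
}

#' Generations until a trajectory declines by a given fraction
#'
#' For a simulated per-generation trajectory starting at t = 0: the first
#' generation t with value_t <= (1 - declineFraction) x value_0, or
#' \code{NA} ("not reached") if the decline never occurs.
#'
#' @param trajectory per-generation values, first element at t = 0.
#' @param declineFraction fraction lost, in (0, 1).
#' @return Integer generation count, or \code{NA_integer_}.
#' @export
declineInterval <- function(trajectory, declineFraction) {
  stopifnot(declineFraction > 0, declineFraction < 1, length(trajectory) >= 1)
  hit <- which(trajectory <= (1 - declineFraction) * trajectory[1])
  if (!length(hit)) NA_integer_ else as.integer(hit[1] - 1L)
}

#' Analytic decline interval for the genealogical F trajectory
#'
#' The diversity retained under genealogical inbreeding is (1 - deltaF)^t,
#' so a decline by fraction d is reached at t = ln(1 - d)/ln(1 - deltaF),
#' rounded to the nearest integer generation.
#'
#' @param deltaF per-generation inbreeding increment.
#' @param declineFraction fraction lost, in (0, 1) (vectorised).
#' @return Integer generation counts.
#' @examples
#' declineIntervalF(0.0075, 0.05)  # 6.81 -> 7
#' declineIntervalF(0.0075, seq(0.05, 0.30, 0.05))  # 7 14 22 30 38 47
#' @export
declineIntervalF <- function(deltaF, declineFraction) {
  stopifnot(deltaF > 0, deltaF < 1,
            all(declineFraction > 0), all(declineFraction < 1))
  as.integer(round(log(1 - declineFraction) / log(1 - deltaF)))
}

#' Decline-interval table across measures
#'
#' Tabulates, for a set of decline fractions, the generation at which each
#' simulated trajectory first drops to (1 - d) of its t = 0 value, plus the
#' analytic column for genealogical F.
#'
#' @param trajectories named list of per-generation numeric vectors
#'   (element 1 = t = 0).
#' @param declineFractions fractions lost (default 5\% to 30\% in 5\% steps).
#' @param deltaF inbreeding increment for the analytic F column, or
#'   \code{NULL} to omit it.
#' @return A data.frame, one row per decline fraction.
#' @export
declineTable <- function(trajectories,
                         declineFractions = seq(0.05, 0.30, 0.05),
                         deltaF = NULL) {
  out <- data.frame(decline = declineFractions)
  for (nm in names(trajectories))
    out[[nm]] <- vapply(declineFractions, function(d)
      declineInterval(trajectories[[nm]], d), integer(1))
  if (!is.null(deltaF))
    out$F <- declineIntervalF(deltaF, declineFractions)
  out
}
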