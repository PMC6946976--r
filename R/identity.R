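#' Label-based IBD probability
#'
#' True identity by descent from the double label: two allele copies are
#' IBD when they match in allele state AND founder label.  The "two alleles
#' drawn randomly from two individuals" formulation is made exhaustive:
#' over all unordered pairs of distinct individuals, all loci in scope and
#' all four cross-individual allele pairings, the IBD probability is the
#' matching-pairing count divided by the total pairing count (the
#' per-comparison locus total realises the G-IBD/(G-hom + G-her)
#' normalisation).  In a freshly labeled founder population every label is
#' unique to one individual, so the IBD probability is exactly 0.
#'
#' @param population a labeled \linkS4class{Population}.
#' @param scope "genome" or "chromosome".
#' @return A data.frame with columns t, scope, ibd, nComparisons.
#' @export
ibdProbability <- function(population, scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  if (!isLabeled(population))
    stop("IBD requires founder labels; run makeFounderLabels() first")
  counts <- cpp_identity_counts(population@states, population@labels, TRUE)
  identityScope(population, counts, scope, "ibd")
}

#' State-based IBS probability
#'
#' Same exhaustive pairing scheme as [ibdProbability()] but matching on
#' allele state only.  The baseline-adjusted value subtracts the raw IBS of
#' the t = 0 population (so it is exactly 0 at t = 0); the raw value is
#' also reported.
#'
#' @param population a \linkS4class{Population}.
#' @param baseline the t = 0 result of this function (same scope), or
#'   \code{NULL} for no adjustment (then ibsAdjusted = 0 at face value
#'   only when the population itself is the baseline).
#' @param scope "genome" or "chromosome".
#' @return A data.frame with columns t, scope, ibsRaw, ibsAdjusted,
#'   nComparisons.
#' @export
ibsProbability <- function(population, baseline = NULL,
                           scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  counts <- cpp_identity_counts(population@states, population@labels, FALSE)
  out <- identityScope(population, counts, scope, "ibsRaw")
  if (!is.null(baseline)) {
    if (!identical(as.character(baseline$scope), as.character(out$scope)))
      stop("baseline scope does not match")
    out$ibsAdjusted <- out$ibsRaw - baseline$ibsRaw
  } else {
    out$ibsAdjusted <- out$ibsRaw - out$ibsRaw
  }
  out
}

# shared scoping for the identity measures
identityScope <- function(population, counts, scope, name) {
  n <- nIndividuals(population)
  perLocus <- (2 * n) * (2 * n - 1) / 2 - n  # cross-individual hap pairs
  agg <- function(rows, label) {
    df <- data.frame(t = generation(population), scope = label,
                     value = sum(counts[rows]) / (length(rows) * perLocus),
                     nComparisons = length(rows) * perLocus)
    names(df)[3] <- name
    df
  }
  if (scope == "genome") {
    agg(seq_along(counts), "genome")
  } else {
    do.call(rbind, lapply(seq_len(population@map@nChromosomes), function(c)
      agg(which(chromosomes(population) == c), as.character(c))))
  }
}

#' Genotype dosage matrix
#'
#' @param population a \linkS4class{Population}.
#' @return An N x L integer matrix of state-2 allele counts (0/1/2).
#' @export
genotypeDosage <- function(population) {
  st <- population@states == 2L
  n <- nIndividuals(population)
  X <- t(st[, seq(1, 2 * n, 2), drop = FALSE] +
         st[, seq(2, 2 * n, 2), drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- as.character(population@id)
  X
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: with dosage matrix X (N x L) and reference frequencies p
#' from the analysed generation, Z = X - 2p and G = ZZ' / (2 sum p(1-p)).
#' Monomorphic loci are excluded.  The diagonal is approximately 1 plus the
#' genomic inbreeding coefficient; the founder mean off-diagonal is
#' approximately 0 by centering.
#'
#' @param X N x L dosage matrix (see [genotypeDosage()]), or a
#'   \linkS4class{Population}.
#' @param p optional reference allele frequencies (defaults to column means
#'   of X divided by 2).
#' @return The N x N symmetric relationship matrix.
#' @export
grm <- function(X, p = NULL) {
  if (is(X, "Population")) X <- genotypeDosage(X)
  stopifnot(nrow(X) >= 2)
  if (is.null(p)) p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all loci are monomorphic")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  tcrossprod(Z) / denom
}

#' LD-based effective population size
#'
#' Mean squared genotypic (Burrows composite) correlation r2 over
#' inter-chromosomal locus pairs with MAF >= \code{mafMin}, corrected for
#' finite sample size as r2' = r2 - 1/S, and converted under the
#' random-mating (unlinked-locus) model to Ne = 1/(3 r2').  Only pairs on
#' different chromosomes enter, matching the model's free-recombination
#' assumption.  A non-positive corrected r2 yields an infinite estimate.
#'
#' @param X N x L dosage matrix.
#' @param chrom chromosome index per locus (length L).
#' @param S sample size (defaults to nrow(X)).
#' @param mafMin MAF threshold for qualifying loci.
#' @return A list with neLd, meanR2, correctedR2, nPairs, S.
#' @export
ldNe <- function(X, chrom, S = nrow(X), mafMin = 0.05) {
  stopifnot(ncol(X) == length(chrom), S >= 10)
  p <- colMeans(X) / 2
  ok <- pmin(p, 1 - p) >= mafMin
  X <- X[, ok, drop = FALSE]; chrom <- chrom[ok]
  if (length(unique(chrom)) < 2)
    stop("need qualifying loci on at least two chromosomes")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("degenerate sample: monomorphic dosage column")
  r2sum <- 0; nPairs <- 0
  chrs <- unique(chrom)
  for (i in seq_along(chrs)[-length(chrs)]) for (j in (i + 1):length(chrs)) {
    r <- cor(X[, chrom == chrs[i], drop = FALSE],
             X[, chrom == chrs[j], drop = FALSE])
    r2sum <- r2sum + sum(r^2)
    nPairs <- nPairs + length(r)
  }
  meanR2 <- r2sum / nPairs
  r2c <- meanR2 - 1 / S
  list(neLd = if (r2c > 0) 1 / (3 * r2c) else Inf,
       meanR2 = meanR2, correctedR2 = r2c, nPairs = nPairs, S = S)
}

#' Theoretical effective population size under inbreeding
#'
#' Ne = N/(1 + F) with N = 4 Nm Nf/(Nm + Nf); monotone decreasing in F.
#'
#' @param Nm,Nf male and female numbers.
#' @param F inbreeding coefficient in [0, 1) (vectorised).
#' @return A list with ne, N, F.
#' @examples
#' theoreticalNe(20, 100, 0)$N        # 66.67
#' theoreticalNe(20, 100, 0.3137)$ne  # 50.75
#' @export
theoreticalNe <- function(Nm, Nf, F = 0) {
  stopifnot(Nm >= 1, Nf >= 1, all(F >= 0), all(F < 1))
  N <- 4 * Nm * Nf / (Nm + Nf)
  list(ne = N / (1 + F), N = N, F = F)
}
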