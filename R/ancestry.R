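#' Parental genomic components
#'
#' Share of the population's genome contributed by each founder, computed
#' from the founder labels over both sexes' genomes: for founder f,
#' PGC_f = (allele copies labeled f) / (allele copies labeled by any
#' founder of the same sex).  With 20 male and 100 female founders every
#' male family starts at 5\% of the male genomic components and every
#' female family at 1\%; within each sex the shares sum to 1 at every
#' generation while any label of that sex remains.
#'
#' @param population a labeled \linkS4class{Population}.
#' @return A named numeric vector of shares, one per founder (names are
#'   founder ids); attribute \code{founderSex} carries the sex (1/2) of
#'   each founder.
#' @export
pgcTable <- function(population) {
  if (!isLabeled(population))
    stop("parental genomic components require founder labels")
  fs <- population@founderSex
  nFounders <- length(fs)
  counts <- tabulate(population@labels, nbins = nFounders)
  share <- numeric(nFounders)
  for (s in 1:2) {
    tot <- sum(counts[fs == s])
    if (tot > 0) share[fs == s] <- counts[fs == s] / tot
  }
  structure(setNames(share, seq_len(nFounders)), founderSex = fs)
}

#' Relative genomic components
#'
#' Change of a founder's genomic component relative to the base generation:
#' RGC = (PGC_t - PGC_0)/PGC_0.  RGC = 0 means unchanged, RGC = -1 means
#' the family's labels have vanished entirely (and cannot return).
#'
#' @param pgc founder x generation matrix of shares (the \code{pgc}
#'   element of a \code{conservationTrace}), or a numeric vector of PGC_t.
#' @param pgc0 base-generation shares (defaults to column "0" of the
#'   matrix).
#' @return A matrix (or vector) of RGC values; founders with PGC_0 = 0
#'   raise an error.
#' @export
rgc <- function(pgc, pgc0 = NULL) {
  if (is.matrix(pgc)) {
    if (is.null(pgc0)) pgc0 <- pgc[, 1]
    if (any(pgc0 == 0)) stop("RGC undefined for founders with PGC_0 = 0")
    sweep(sweep(pgc, 1, pgc0), 1, pgc0, "/")
  } else {
    if (is.null(pgc0)) stop("pgc0 required for vector input")
    if (any(pgc0 == 0)) stop("RGC undefined for founders with PGC_0 = 0")
    (pgc - pgc0) / pgc0
  }
}

#' Bin relative genomic components
#'
#' Sorts RGC values into 8 bins: (-Inf, -1], (-1, -0.5], (-0.5, 0] and five
#' right-closed bins above 0 (default width 0.5 with an open top).  A lost
#' family (RGC = -1) falls in the leftmost bin.
#'
#' @param rgcValues numeric RGC values at one generation.
#' @param edges bin edges; default
#'   \code{c(-Inf, -1, -0.5, 0, 0.5, 1, 1.5, 2, Inf)}.
#' @return A data.frame with columns bin and count; counts sum to
#'   \code{length(rgcValues)}.
#' @export
rgcHistogram <- function(rgcValues,
                         edges = c(-Inf, -1, -0.5, 0, 0.5, 1, 1.5, 2, Inf)) {
  cuts <- cut(rgcValues, breaks = edges, right = TRUE)
  data.frame(bin = levels(cuts), count = as.integer(table(cuts)))
}

#' Surviving founder families per generation
#'
#' Counts the founders of one sex whose genomic component is still positive
#' at each generation.  Labels can never reappear once lost, so the count
#' is monotone non-increasing.
#'
#' @param pgc founder x generation matrix of shares.
#' @param sex "male" or "female".
#' @param founderSex per-founder sex vector (1/2); defaults to the
#'   attribute attached by [pgcTable()]/[runConservation()].
#' @return A data.frame with columns t and surviving.
#' @export
familySurvival <- function(pgc, sex = c("female", "male"),
                           founderSex = attr(pgc, "founderSex")) {
  sex <- match.arg(sex)
  if (is.null(founderSex)) stop("founderSex not available")
  rows <- founderSex == (if (sex == "male") 1L else 2L)
  data.frame(t = as.integer(colnames(pgc)),
             surviving = colSums(pgc[rows, , drop = FALSE] > 0))
}

#' Founder-origin segments of an individual's genome
#'
#' Run-length encodes the founder labels along each haplotype of one
#' individual, yielding BED-like segments (0-based, half-open locus
#' coordinates) that tile every haplotype exactly.  A founder individual
#' yields one segment per chromosome per haplotype.
#'
#' @param population a labeled \linkS4class{Population}.
#' @param individual index (1-based) of the individual.
#' @return A data.frame with columns individual, chromosome, haplotype
#'   (0/1), start, end, founder, founderSex.
#' @export
ideogramSegments <- function(population, individual) {
  if (!isLabeled(population)) stop("ideogram requires founder labels")
  stopifnot(individual >= 1, individual <= nIndividuals(population))
  map <- population@map
  out <- list()
  for (h in 0:1) {
    lab <- population@labels[, 2L * individual - 1L + h]
    for (c in seq_len(map@nChromosomes)) {
      rows <- which(map@chrom == c)
      r <- rle(lab[rows])
      ends <- cumsum(r$lengths)
      out[[length(out) + 1L]] <- data.frame(
        individual = population@id[individual], chromosome = c,
        haplotype = h, start = c(0L, head(ends, -1)), end = ends,
        founder = r$values,
        founderSex = c("male", "female")[population@founderSex[r$values]])
    }
  }
  do.call(rbind, out)
}

#' Write ideogram segments as a BED-like file
#'
#' @param segments output of [ideogramSegments()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeIdeogram <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
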