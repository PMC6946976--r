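# Construct a population directly from matrices (bypassing the simulators)
# so closed-form examples can be asserted exactly.
makePop <- function(states, labels = NULL, sex = NULL, t = 0L,
                    nChrom = 1L, founderSex = NULL,
                    sire = NULL, dam = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  n <- ncol(states) / 2L
  L <- nrow(states)
  stopifnot(L %% nChrom == 0)
  map <- markerMap(nChrom, L / nChrom)
  if (is.null(sex)) sex <- rep(c(1L, 2L), length.out = n)
  if (is.null(labels)) {
    labels <- matrix(integer(0), 0, 0)
    founderSex <- integer(0)
  } else {
    labels <- as.matrix(labels)
    storage.mode(labels) <- "integer"
    if (is.null(founderSex))
      founderSex <- rep(c(1L, 2L), length.out = max(labels))
  }
  if (is.null(sire)) sire <- rep(NA_integer_, n)
  if (is.null(dam)) dam <- rep(NA_integer_, n)
  founderTrace:::newPopulation(t, seq_len(n), sex, sire, dam,
                               states, labels, founderSex, map)
}

# A small labeled base population produced by the real chain (burn-in,
# labeling, MAF filter); cheap enough for unit tests.
smallBase <- function(seed = 42, Nm = 6, Nf = 12, nl = 240, tBurnin = 600,
                      nChrom = 1, mu = 5e-3) {
  # mu is scaled up relative to the study conditions so that tiny test
  # populations (small Ne) still hold a useful number of polymorphic loci
  cfg <- simConfig(Nm = Nm, Nf = Nf, nChromosomes = nChrom, nLociRaw = nl,
                   nLociKeep = NA, tBurnin = tBurnin, tConservation = 5,
                   litterSize = 8, nReplicates = 1, muBurnin = mu)
  set.seed(seed)
  base <- makeFounderLabels(runBurnin(cfg))
  filt <- applyMarkerFilter(base, cfg@mafThreshold, NULL)
  list(config = cfg, population = filt$population, kept = filt$kept)
}

# Gene-dropping oracle: simulate generations with recorded transmissions,
# then re-derive every allele copy's founder of origin by replaying the
# pedigree + per-locus source records, independently of the package's
# label propagation.
dropWithRecords <- function(base, nGen, perGen) {
  pops <- list(base)
  records <- list()  # records[[g]][[k]] = list(sirePos, damPos, srcS, srcD)
  for (g in seq_len(nGen)) {
    pop <- pops[[g]]
    males <- which(sexOf(pop) == 1L)
    females <- which(sexOf(pop) == 2L)
    n <- perGen
    st <- matrix(0L, nLoci(pop), 2L * n)
    lb <- matrix(0L, nLoci(pop), 2L * n)
    rec <- vector("list", n)
    sire <- integer(n); dam <- integer(n)
    for (k in seq_len(n)) {
      sp <- sample(males, 1); dp <- sample(females, 1)
      gs <- recombineGamete(pop, sp, record = TRUE)
      gd <- recombineGamete(pop, dp, record = TRUE)
      st[, 2 * k - 1] <- gs$states; st[, 2 * k] <- gd$states
      lb[, 2 * k - 1] <- gs$labels; lb[, 2 * k] <- gd$labels
      rec[[k]] <- list(sirePos = sp, damPos = dp,
                       srcS = gs$source, srcD = gd$source)
      sire[k] <- pop@id[sp]; dam[k] <- pop@id[dp]
    }
    pops[[g + 1]] <- founderTrace:::newPopulation(
      generation(pop) + 1L, max(pop@id) + seq_len(n),
      rep(c(1L, 2L), length.out = n), sire, dam, st, lb,
      pop@founderSex, markerMapOf(pop))
    records[[g]] <- rec
  }
  list(pops = pops, records = records)
}

# replayed founder origin of generation g (1-based beyond base)
oracleLabels <- function(drop, g) {
  L <- nLoci(drop$pops[[1]])
  # origin matrices per generation, same layout as the labels matrix
  org <- founderLabels(drop$pops[[1]])
  for (gen in seq_len(g)) {
    rec <- drop$records[[gen]]
    n <- length(rec)
    cur <- matrix(0L, L, 2L * n)
    for (k in seq_len(n)) {
      r <- rec[[k]]
      for (l in seq_len(L)) {
        cur[l, 2 * k - 1] <- org[l, 2L * r$sirePos - 1L + r$srcS[l]]
        cur[l, 2 * k]     <- org[l, 2L * r$damPos  - 1L + r$srcD[l]]
      }
    }
    org <- cur
  }
  org
}

# brute-force IBD: loop over every pair of individuals, locus, and the
# 4 cross-individual allele pairings
bruteIbd <- function(states, labels) {
  n <- ncol(states) / 2
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (hi in 0:1) for (hj in 0:1) {
      ci <- 2 * i - 1 + hi; cj <- 2 * j - 1 + hj
      num <- num + sum(states[, ci] == states[, cj] &
                       labels[, ci] == labels[, cj])
      den <- den + nrow(states)
    }
  }
  num / den
}
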