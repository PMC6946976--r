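test_that("the expected mutation count follows the 2 Ne nc mu nl Poisson mean", {
  expect_equal(expectedMutations(simConfig()), 720)
  cfg <- simConfig(Nm = 10, Nf = 10, nChromosomes = 2, nLociRaw = 100,
                   nLociKeep = NA)
  expect_equal(expectedMutations(cfg), 2 * 20 * 2 * 2.5e-4 * 100)
})

test_that("mutation flips exactly the drawn number of allele copies and spares labels", {
  sb <- smallBase(seed = 3)
  pop <- sb$population
  expect_identical(mutatePopulation(pop, 0, sb$config), pop)
  set.seed(4)
  mut <- mutatePopulation(pop, 1e-3, sb$config, nEvents = 1L)
  expect_identical(sum(alleleStates(mut) != alleleStates(pop)), 1L)
  expect_identical(founderLabels(mut), founderLabels(pop))
  # flipped copy changed 1 <-> 2
  idx <- which(alleleStates(mut) != alleleStates(pop))
  expect_identical(alleleStates(mut)[idx], 3L - alleleStates(pop)[idx])
})

test_that("gametes are mosaics of the two parental haplotypes with Poisson(1) crossovers", {
  sb <- smallBase(seed = 6, Nm = 3, Nf = 5, nl = 200, tBurnin = 300)
  pop <- sb$population
  set.seed(12)
  ncross <- integer(0)
  for (r in 1:300) {
    i <- sample(nIndividuals(pop), 1)
    g <- recombineGamete(pop, i, record = TRUE)
    hapS <- alleleStates(pop)[, c(2 * i - 1, 2 * i)]
    hapL <- founderLabels(pop)[, c(2 * i - 1, 2 * i)]
    L <- nLoci(pop)
    # the recorded source reproduces the gamete exactly, states and labels
    # traveling together
    expect_identical(g$states, hapS[cbind(seq_len(L), g$source + 1L)])
    expect_identical(g$labels, hapL[cbind(seq_len(L), g$source + 1L)])
    # observed source switches cannot exceed the crossover count
    expect_lte(sum(diff(g$source) != 0), sum(g$crossovers))
    ncross <- c(ncross, sum(g$crossovers))
  }
  expect_gt(mean(ncross), 0.7)
  expect_lt(mean(ncross), 1.3)
})

test_that("crossover counts fit a Poisson(1) distribution", {
  sb <- smallBase(seed = 16, Nm = 3, Nf = 5, nl = 50, tBurnin = 100)
  pop <- sb$population
  set.seed(77)
  n <- 10000
  counts <- integer(n)
  for (r in seq_len(n))
    counts[r] <- recombineGamete(pop, 1L, record = FALSE)$crossovers
  obs <- tabulate(pmin(counts, 4) + 1L, 5)  # bins 0,1,2,3,>=4
  pr <- c(dpois(0:3, 1), 1 - ppois(3, 1))
  gof <- chisq.test(obs, p = pr)
  expect_gt(gof$p.value, 0.001)
  expect_equal(mean(counts), 1.0, tolerance = 0.05)
})

test_that("random mating fills the sex slots and draws parents from the current generation", {
  sb <- smallBase(seed = 8)
  pop <- sb$population
  set.seed(21)
  nxt <- randomMatingGeneration(pop)
  expect_identical(nIndividuals(nxt), nIndividuals(pop))
  expect_identical(sum(sexOf(nxt) == 1L), sum(sexOf(pop) == 1L))
  expect_identical(generation(nxt), generation(pop) + 1L)
  maleIds <- pop@id[sexOf(pop) == 1L]
  femaleIds <- pop@id[sexOf(pop) == 2L]
  expect_true(all(nxt@sire %in% maleIds))
  expect_true(all(nxt@dam %in% femaleIds))
  # paternal haplotype labels descend from the sire, maternal from the dam
  lb <- founderLabels(nxt)
  for (k in sample(nIndividuals(nxt), 5)) {
    sirePos <- match(nxt@sire[k], pop@id)
    sireLab <- unique(as.vector(founderLabels(pop)[, c(2 * sirePos - 1, 2 * sirePos)]))
    expect_true(all(lb[, 2 * k - 1] %in% sireLab))
  }
})

test_that("burn-in reaches a polymorphic quasi-equilibrium and records its trace", {
  cfg <- simConfig(Nm = 6, Nf = 12, nChromosomes = 1, nLociRaw = 300,
                   nLociKeep = NA, tBurnin = 600)
  set.seed(14)
  pop <- runBurnin(cfg, traceEvery = 10)
  expect_identical(generation(pop), 0L)
  expect_false(isLabeled(pop))
  tr <- burninTrace(pop)
  expect_identical(tail(tr$generation, 1), 0)
  expect_gt(tail(tr$He, 1), 0)
  # a zero-length burn-in leaves every locus fixed: the filter must fail
  cfg0 <- simConfig(Nm = 6, Nf = 12, nChromosomes = 1, nLociRaw = 50,
                    nLociKeep = NA, tBurnin = 0)
  pop0 <- runBurnin(cfg0)
  expect_identical(diversitySummary(pop0)$He, 0)
  expect_error(applyMarkerFilter(pop0, 0.05, NULL), "no locus")
})
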