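test_that("mating assignment partitions dams evenly among sires", {
  sb <- smallBase(seed = 13, Nm = 4, Nf = 20, nl = 100, tBurnin = 300)
  pop <- sb$population
  set.seed(2)
  m <- assignMatings(pop)
  expect_identical(nrow(m), 20L)
  expect_identical(sort(m$dam), pop@id[sexOf(pop) == 2L])  # every dam once
  expect_true(all(table(m$sire) == 5L))
  # non-divisible case: counts differ by at most one
  sb2 <- smallBase(seed = 14, Nm = 3, Nf = 7, nl = 100, tBurnin = 300)
  set.seed(3)
  m2 <- assignMatings(sb2$population)
  expect_identical(as.integer(sort(table(m2$sire), decreasing = TRUE)),
                   c(3L, 2L, 2L))
  expect_identical(anyDuplicated(m2$dam), 0L)
})

test_that("equal-procedure replacement keeps one boar per sire family and gilts from distinct dams", {
  sb <- smallBase(seed = 17, Nm = 5, Nf = 10, nl = 150, tBurnin = 400)
  pop <- sb$population
  policy <- managementPolicy()
  set.seed(5)
  matings <- assignMatings(pop, policy)
  pool <- makeLitters(pop, matings, litterSize = 12)
  expect_identical(nIndividuals(pool), 120L)
  nxt <- selectReplacements(pool, policy, Nm = 5, Nf = 10)
  expect_identical(sum(sexOf(nxt) == 1L), 5L)
  expect_identical(sum(sexOf(nxt) == 2L), 10L)
  boars <- which(sexOf(nxt) == 1L)
  expect_identical(anyDuplicated(nxt@sire[boars]), 0L)  # lines never merge
  gilts <- which(sexOf(nxt) == 2L)
  expect_identical(anyDuplicated(nxt@dam[gilts]), 0L)
  # replacements come from this generation's offspring only
  expect_true(all(nxt@id %in% pool@id))
  expect_identical(generation(nxt), generation(pop) + 1L)
})

test_that("a sire family without male offspring is reported as a litter-size problem", {
  sb <- smallBase(seed = 19, Nm = 3, Nf = 6, nl = 100, tBurnin = 300)
  pop <- sb$population
  set.seed(6)
  pool <- makeLitters(pop, assignMatings(pop), litterSize = 4)
  sires <- unique(pool@sire)
  pool@sex[pool@sire == sires[1]] <- 2L  # wipe out one family's males
  expect_error(selectReplacements(pool, managementPolicy(), 3, 6),
               "litterSize")
})

test_that("managed generations keep the census and sex counts constant", {
  sb <- smallBase(seed = 23, Nm = 4, Nf = 8, nl = 200, tBurnin = 500)
  cfg <- simConfig(Nm = 4, Nf = 8, nChromosomes = 1, nLociRaw = 200,
                   nLociKeep = NA, tBurnin = 500, tConservation = 6,
                   litterSize = 8)
  set.seed(31)
  tr <- runConservation(sb$population, cfg, spectrumEvery = 0, keepEvery = 1)
  expect_identical(nrow(tr$diversity), 7L)
  for (snap in tr$snapshots) {
    expect_identical(sum(sexOf(snap) == 1L), 4L)
    expect_identical(sum(sexOf(snap) == 2L), 8L)
  }
  # zero-length management yields only the t = 0 summaries
  cfg0 <- cfg; cfg0@tConservation <- 0L
  tr0 <- runConservation(sb$population, cfg0, spectrumEvery = 0)
  expect_identical(nrow(tr0$diversity), 1L)
  expect_identical(tr0$diversity$t, 0L)
  expect_identical(tr0$identity$ibd, 0)
})

test_that("equal-procedure management erodes He more slowly than random replacement", {
  cfg <- simConfig(Nm = 6, Nf = 18, nChromosomes = 4, nLociRaw = 400,
                   nLociKeep = NA, tBurnin = 600, tConservation = 15,
                   litterSize = 8, muBurnin = 4e-3)
  equal <- managementPolicy()
  random <- managementPolicy(oneBoarPerSireFamily = FALSE,
                             giltsFromDistinctDams = FALSE)
  ratios <- sapply(1:6, function(r) {
    set.seed(100 + r)
    base <- makeFounderLabels(runBurnin(cfg))
    filt <- applyMarkerFilter(base, cfg@mafThreshold, NULL)$population
    trE <- runConservation(filt, cfg, equal, spectrumEvery = 0)
    trR <- runConservation(filt, cfg, random, spectrumEvery = 0)
    last <- cfg@tConservation + 1L
    c(equal = trE$diversity$He[last] / trE$diversity$He[1],
      random = trR$diversity$He[last] / trR$diversity$He[1])
  })
  # paired replicates: the variance-reduction effect the program relies on
  expect_gt(mean(ratios["equal", ] - ratios["random", ]), 0)
})
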