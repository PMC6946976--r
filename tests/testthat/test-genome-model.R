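test_that("founder labeling gives every founder a distinct label and leaves states alone", {
  cfg <- simConfig(Nm = 4, Nf = 8, nChromosomes = 2, nLociRaw = 40,
                   nLociKeep = NA, tBurnin = 100)
  set.seed(1)
  base <- runBurnin(cfg)
  labeled <- makeFounderLabels(base)
  expect_true(isLabeled(labeled))
  expect_identical(alleleStates(labeled), alleleStates(base))
  lab <- founderLabels(labeled)
  expect_setequal(unique(as.vector(lab)), 1:12)
  # both haplotypes of founder i carry label i at every locus
  for (i in c(1L, 7L, 12L))
    expect_true(all(lab[, c(2 * i - 1, 2 * i)] == i))
  # two distinct founders share no label, so IBD is structurally zero
  expect_identical(ibdProbability(labeled)$ibd, 0)
  # stamping is only defined on the t = 0 population
  shifted <- labeled
  shifted@generation <- 3L
  expect_error(makeFounderLabels(shifted), "t = 0")
})

test_that("MAF filter applies the threshold per locus and honours nKeep", {
  # 50 diploids, 3 loci with allele-2 counts 1, 10, 40 of 100 copies
  st <- matrix(1L, nrow = 3, ncol = 100)
  st[1, 1] <- 2L
  st[2, 1:10] <- 2L
  st[3, 1:40] <- 2L
  pop <- makePop(st)
  expect_equal(alleleFrequencies(pop), c(0.01, 0.10, 0.40))
  filt <- applyMarkerFilter(pop, mafThreshold = 0.05, nKeep = 2)
  expect_identical(filt$kept, c(2L, 3L))
  # every retained locus is biallelic: Ao = 2, Pp = 1
  d <- diversitySummary(filt$population)
  expect_identical(d$Ao, 2)
  expect_identical(d$Pp, 1)
  # nKeep = NULL keeps all passing loci
  expect_identical(applyMarkerFilter(pop, 0.05, NULL)$kept, c(2L, 3L))
  # demanding more loci than pass names the chromosome
  expect_error(applyMarkerFilter(pop, 0.05, nKeep = 3), "chromosome 1")
  # a completely monomorphic population has nothing to keep
  expect_error(applyMarkerFilter(makePop(matrix(1L, 3, 100)), 0.05, NULL),
               "no locus")
})

test_that("nKeep subsampling retains exactly nKeep passing loci per chromosome", {
  # 40 diploids, 10 loci, alternating MAF 0.4 / 0.0125 (only evens pass)
  st <- matrix(1L, nrow = 10, ncol = 80)
  for (l in seq(2, 10, 2)) st[l, 1:32] <- 2L
  for (l in seq(1, 10, 2)) st[l, 1] <- 2L
  pop <- makePop(st)
  set.seed(9)
  f3 <- applyMarkerFilter(pop, 0.05, nKeep = 3)
  expect_identical(nLoci(f3$population), 3L)
  expect_true(all(f3$kept %in% seq(2, 10, 2)))
  expect_false(is.unsorted(f3$kept))
  # same seed, same subset
  set.seed(9)
  expect_identical(applyMarkerFilter(pop, 0.05, nKeep = 3)$kept, f3$kept)
})

test_that("VCF export writes phased REF/ALT genotypes and round-trips losslessly", {
  skip_if_not_installed("vcfR")
  sb <- smallBase(seed = 7, Nm = 3, Nf = 5, nl = 120, tBurnin = 400)
  pop <- sb$population
  base <- file.path(tempdir(), "ft_roundtrip")
  paths <- exportGenotypes(pop, base, format = "vcf")
  vcf <- paths[1]
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, nLoci(pop))
  # allele-1 -> REF convention: a phased het with states (1,2) reads "0|1"
  f <- strsplit(body[1], "\t")[[1]]
  gt <- f[10:length(f)]
  stRow <- alleleStates(pop)[1, ]
  expGt <- paste0(stRow[seq(1, length(stRow), 2)] - 1L, "|",
                  stRow[seq(2, length(stRow), 2)] - 1L)
  expect_identical(gt, expGt)
  back <- importGenotypes(vcf, labelsPath = paste0(base, ".labels.tsv"),
                          pedigreePath = paste0(base, ".ped.tsv"))
  expect_identical(alleleStates(back), alleleStates(pop))
  expect_identical(founderLabels(back), founderLabels(pop))
  expect_identical(sexOf(back), sexOf(pop))
  expect_identical(generation(back), generation(pop))
  # measurement layer sees identical statistics after the round trip
  expect_equal(diversitySummary(back)$He, diversitySummary(pop)$He)
  expect_equal(ibdProbability(back)$ibd, ibdProbability(pop)$ibd)
})

test_that("PLINK text export writes one ped row per individual plus a map", {
  sb <- smallBase(seed = 8, Nm = 3, Nf = 5, nl = 120, tBurnin = 400)
  base <- file.path(tempdir(), "ft_plink")
  paths <- exportGenotypes(sb$population, base, format = "plink")
  ped <- readLines(paths[1])
  expect_length(ped, nIndividuals(sb$population))
  map <- read.table(paths[2])
  expect_identical(nrow(map), nLoci(sb$population))
})

test_that("labels present after several generations form a subset of the founder set", {
  sb <- smallBase(seed = 11)
  pop <- sb$population
  set.seed(30)
  for (g in 1:4) pop <- randomMatingGeneration(pop)
  present <- unique(as.vector(founderLabels(pop)))
  expect_true(all(present %in% seq_len(nIndividuals(sb$population))))
  # without mutation, a label-f copy carries one of founder f's own states
  # at that locus (labels name the founder individual, whose two haplotypes
  # may differ in state)
  st <- alleleStates(pop); lb <- founderLabels(pop)
  st0 <- alleleStates(sb$population)
  for (l in sample(nLoci(pop), min(10, nLoci(pop)))) {
    for (f in unique(lb[l, ]))
      expect_true(all(st[l, lb[l, ] == f] %in% st0[l, c(2 * f - 1, 2 * f)]))
  }
})
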