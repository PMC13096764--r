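test_that("F2 segregation at an unlinked locus is 1:2:1", {
  cfg <- bsaSimConfig(chromLengths = c(chrA = 1e6), markerSpacing = 1e6,
                      popType = "F2", nIndividuals = 10000,
                      qtls = data.frame(), epistasis = "none", seed = 101)
  doses <- genotypeDoses(simulatePopulation(cfg))[, 1L]
  freq <- tabulate(doses + 1L, 3L) / 10000
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.02 / 0.25)
})

test_that("RIL(9) residual heterozygosity is 2^-8", {
  cfg <- bsaSimConfig(chromLengths = c(chrA = 1e6), markerSpacing = 1e6,
                      popType = "RIL", generation = 9, nIndividuals = 10000,
                      qtls = data.frame(), epistasis = "none", seed = 102)
  doses <- genotypeDoses(simulatePopulation(cfg))[, 1L]
  expect_lt(abs(mean(doses == 1L) - 2^-8), 0.003)
})

test_that("recombinant gamete fraction matches the Haldane closed form", {
  # two loci 10 cM apart (2.5 Mb at 4 cM/Mb): r = (1 - exp(-0.2)) / 2
  cfg <- bsaSimConfig(chromLengths = c(chrA = 3e6),
                      markerPositions = list(chrA = c(1000, 2501000)),
                      popType = "F2", nIndividuals = 20000,
                      qtls = data.frame(), epistasis = "none", seed = 103)
  pop <- simulatePopulation(cfg)
  rec <- mean(c(pop@h1[, 1L] != pop@h1[, 2L], pop@h2[, 1L] != pop@h2[, 2L]))
  expect_lt(abs(rec - 0.0906), 0.01)
})

test_that("complementary epistasis gates the phenotype", {
  # 4 individuals x 2 QTL loci: donor/donor, donor at locus 1 only,
  # double het, fully recurrent
  h1 <- rbind(c(1L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 0L))
  h2 <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L), c(0L, 0L))
  pop <- makePop(h1, h2, "chr1", c(1000L, 2000L))
  cfg <- bsaSimConfig(chromLengths = c(chr1 = 1e4),
                      markerPositions = list(chr1 = c(1000, 2000)),
                      nIndividuals = 4,
                      qtls = data.frame(chrom = "chr1", pos = c(1000, 2000),
                                        a = c(1.63, 1.04), d = c(0.60, 1.25)),
                      noiseSd = 0, phenotypeScale = c(1, 9))
  sc <- assignPhenotypes(pop, cfg)
  expect_equal(sc[1L], 9L)   # donor homozygous at both loci -> top score
  expect_equal(sc[2L], 1L)   # donor at one locus only -> no trait
  expect_equal(sc[4L], 1L)   # recurrent background -> no trait
  expect_true(sc[3L] > 1L && sc[3L] < 9L)  # double het: gated on, weaker
})

test_that("epistasis rule requiring two loci rejects single-QTL configs", {
  pop <- makePop(matrix(1L, 2, 1), matrix(1L, 2, 1), "chr1", 1000L)
  cfg <- bsaSimConfig(chromLengths = c(chr1 = 1e4),
                      markerPositions = list(chr1 = 1000), nIndividuals = 2,
                      qtls = data.frame(chrom = "chr1", pos = 1000,
                                        a = 1, d = 0),
                      epistasis = "complementary")
  expect_error(assignPhenotypes(pop, cfg), "two")
})

test_that("null trait (a = d = 0) is independent of genotype", {
  cfg <- bsaSimConfig(chromLengths = c(chrA = 1e6), markerSpacing = 1e6,
                      popType = "F2", nIndividuals = 5000,
                      qtls = data.frame(chrom = "chrA", pos = 1e6,
                                        a = 0, d = 0),
                      epistasis = "none", phenotypeScale = c(1, 9),
                      seed = 104)
  pop <- simulatePopulation(cfg)
  sc <- assignPhenotypes(pop, cfg)
  expect_lt(abs(cor(sc, genotypeDoses(pop)[, 1L])), 0.05)
})

test_that("rank-rule bulks are disjoint with deterministic tie-breaking", {
  set.seed(1)
  phen <- sample(1:3, 49, replace = TRUE)
  b <- suppressWarnings(formBulks(phen, 8, 12))
  expect_length(b$high, 8L)
  expect_length(b$low, 12L)
  expect_length(intersect(b$high, b$low), 0L)
  # all-equal scores: first nHigh / last nLow by index, with a tie warning
  expect_warning(expect_warning(b2 <- formBulks(rep(2, 20), 8, 12), "tie"),
                 "tie")   # one warning per bulk boundary
  expect_equal(sort(b2$high), 1:8)
  expect_equal(sort(b2$low), 9:20)
  expect_error(formBulks(rep(1:3, 5), 8, 12), "exceed")
  expect_error(formBulks(rep(1, 30), 8, 12, rule = "class"), "identical")
  bc <- formBulks(c(1, 3, 2, 3, 1, 1), rule = "class")
  expect_equal(bc$high, c(2L, 4L))
  expect_equal(bc$low, c(1L, 5L, 6L))
})

test_that("SNP tables have consistent depths and respect fixed frequencies", {
  cfg <- bsaSimConfig(chromLengths = c(chrA = 2e6), markerSpacing = 1e4,
                      popType = "RIL", generation = 9, nIndividuals = 30,
                      qtls = data.frame(), epistasis = "none",
                      depthMean = 20, seed = 105)
  pop <- simulatePopulation(cfg)
  bulks <- list(high = 1:8, low = 9:20)
  rec <- sampleSnpTable(pop, bulks, cfg)
  mc <- S4Vectors::mcols(rec)
  expect_true(all(mc$highRef >= 0 & mc$highAlt >= 0 &
                  mc$lowRef >= 0 & mc$lowAlt >= 0))
  expect_true(all(mc$highRef + mc$highAlt >= 1))   # truncated depth
  expect_true(all(mc$lowRef + mc$lowAlt >= 1))
  # f = 0 in a bulk forces zero donor reads there
  fHigh <- colMeans(genotypeDoses(pop)[bulks$high, ]) / 2
  expect_true(all(mc$highAlt[fHigh == 0] == 0L))
  expect_error(sampleSnpTable(pop, list(high = integer(0), low = 1:3), cfg),
               "empty")
})

test_that("perfectly partitioned fixed-line bulks give delta near 1", {
  cfg <- bsaSimConfig(chromLengths = c(chrA = 1e5),
                      markerPositions = list(chrA = 50000),
                      popType = "RIL", generation = 9, nIndividuals = 60,
                      qtls = data.frame(), epistasis = "none",
                      depthMean = 500, seed = 106)
  pop <- simulatePopulation(cfg)
  d <- genotypeDoses(pop)[, 1L]
  bulks <- list(high = which(d == 2L)[1:8], low = which(d == 0L)[1:12])
  rec <- computeIndices(sampleSnpTable(pop, bulks, cfg))
  expect_gt(rec$snpIndexHigh, 0.99)
  expect_lt(rec$snpIndexLow, 0.01)
  expect_gt(rec$delta, 0.98)
})

test_that("the generated dataset is identical under a fixed seed", {
  cfg <- bsaSimConfig(chromLengths = c(chrA = 5e6), markerSpacing = 5e4,
                      popType = "RIL", generation = 9, nIndividuals = 20,
                      qtls = data.frame(), epistasis = "none", seed = 107)
  s1 <- suppressWarnings(simulateBsa(cfg, nHigh = 4, nLow = 6))
  s2 <- suppressWarnings(simulateBsa(cfg, nHigh = 4, nLow = 6))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("null loci have mean delta near zero over replicate populations", {
  # within one genome the delta-SNP index is correlated along chromosomes
  # through bulk composition (few independent blocks), so the zero expectation
  # is checked by pooling replicate populations rather than one large genome
  ms <- vapply(1:50, function(s) {
    cfg <- bsaSimConfig(chromLengths = c(chrA = 5e7), markerSpacing = 2.5e5,
                        popType = "RIL", generation = 9, nIndividuals = 49,
                        qtls = data.frame(), epistasis = "none",
                        depthMean = 30, seed = 3000 + s)
    sim <- suppressWarnings(simulateBsa(cfg))
    mean(computeIndices(sim$records)$delta)
  }, numeric(1))
  expect_lt(abs(mean(ms)), 0.04)   # se ~ 0.013 from composition noise
})

test_that("off-chromosome QTLs and bad configs are rejected", {
  expect_error(bsaSimConfig(qtls = data.frame(chrom = "chr1", pos = 9e9,
                                              a = 1, d = 0)),
               "off-chromosome")
  expect_error(bsaSimConfig(qtls = data.frame(chrom = "chrX", pos = 100,
                                              a = 1, d = 0)),
               "declared chromosome")
  expect_error(bsaSimConfig(nIndividuals = 1), "nIndividuals")
  expect_error(bsaSimConfig(depthMean = 0), "depthMean")
})
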