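# Shared fixtures, memoized across test files (helpers are sourced once per
# test run).  All randomness is seeded.

# study-design null: RIL(9), bulks 8/12, default depth grid
sharedNull <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateNull("RIL", 8, 12, generation = 9,
                             nReps = 5000, seed = 7)
    cache
  }
})

# a small GRanges SNP table with given per-bulk counts
grCounts <- function(pos, highRef, highAlt, lowRef, lowAlt, chrom = "chr1") {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos, width = 1L),
    REF = rep("A", length(pos)), ALT = rep("T", length(pos)),
    highRef = as.integer(highRef), highAlt = as.integer(highAlt),
    lowRef = as.integer(lowRef), lowAlt = as.integer(lowAlt))
}

# records drawn from the RIL(9) 8/12 null model itself, independently per SNP
# (the matched null for p-value calibration checks)
independentNullRecords <- function(n, depthMean = 30, seed = 1) {
  set.seed(seed)
  h <- 2^-8
  pg <- c((1 - h) / 2, h, (1 - h) / 2)
  fH <- rowSums(matrix(sample(0:2, n * 8, TRUE, pg), n, 8)) / 16
  fL <- rowSums(matrix(sample(0:2, n * 12, TRUE, pg), n, 12)) / 24
  dH <- qpois(runif(n, ppois(0, depthMean), 1), depthMean)
  dL <- qpois(runif(n, ppois(0, depthMean), 1), depthMean)
  aH <- rbinom(n, dH, fH); aL <- rbinom(n, dL, fL)
  grCounts(seq_len(n) * 10L, dH - aH, aH, dL - aL, aL)
}

# hand-built population: haplotype matrices over given loci
makePop <- function(h1, h2, chrom, pos, popType = "RIL", generation = 9) {
  loci <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  new("BsaPopulation", h1 = h1, h2 = h2, loci = loci,
      popType = popType, generation = generation)
}

# small F2 linkage fixture: markers on one chromosome, one additive QTL
f2Sim <- function(seed, n = 204, nMarkers = 17, spanBp = 6.65e6,
                  qtlBp = 3.4e6, a = 1.63, d = 0.60, noiseSd = 1.5,
                  startBp = 5e5) {
  mpos <- as.integer(round(seq(startBp, startBp + spanBp,
                               length.out = nMarkers)))
  qtlBp <- as.integer(qtlBp)
  cfg <- bsaSimConfig(
    chromLengths = c(chr1 = 43270923),
    markerPositions = list(chr1 = sort(unique(c(mpos, qtlBp)))),
    popType = "F2", nIndividuals = n,
    qtls = data.frame(chrom = "chr1", pos = qtlBp, a = a, d = d),
    epistasis = "none", noiseSd = noiseSd, phenotypeScale = c(1, 9),
    seed = seed)
  pop <- simulatePopulation(cfg)
  phen <- assignPhenotypes(pop, cfg)
  geno <- genotypeCodes(pop)
  markerNames <- paste0("chr1_", mpos)
  list(geno = geno[, markerNames, drop = FALSE],
       phen = phen,
       markerPos = data.frame(name = markerNames, chrom = "chr1",
                              posBp = mpos),
       qtlDose = genotypeDoses(pop)[, match(paste0("chr1_", qtlBp),
                                            colnames(geno))])
}
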