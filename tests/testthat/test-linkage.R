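# independent two-locus F2 class probabilities (doses i, j in 0..2), built
# by direct convolution of gamete haplotype frequencies -- the oracle used
# against the package's EM estimator
f2ClassProbs <- function(r) {
  hap <- matrix(0, 2, 2)
  hap[1, 1] <- hap[2, 2] <- (1 - r) / 2
  hap[1, 2] <- hap[2, 1] <- r / 2
  p <- matrix(0, 3, 3)
  for (x1 in 0:1) for (y1 in 0:1) for (x2 in 0:1) for (y2 in 0:1)
    p[x1 + x2 + 1, y1 + y2 + 1] <- p[x1 + x2 + 1, y1 + y2 + 1] +
      hap[x1 + 1, y1 + 1] * hap[x2 + 1, y2 + 1]
  p
}

sampleTwoLocus <- function(n, r, seed) {
  set.seed(seed)
  p <- as.vector(f2ClassProbs(r))      # column-major: class = (j, i)
  cls <- sample(0:8, n, replace = TRUE, prob = p)
  list(gi = cls %% 3, gj = cls %/% 3)
}

test_that("recombination fractions recover linkage and independence", {
  g <- rep(c(0, 1, 2), times = c(50, 100, 50))
  expect_equal(estimateRF(g, g), 0)
  u <- sampleTwoLocus(2000, 0.5, seed = 31)
  expect_lt(abs(estimateRF(u$gi, u$gj) - 0.5), 0.03)
  expect_error(estimateRF(c(0, 1, NA), c(0, 1, 1)), "non-missing")
})

test_that("EM estimates agree with a grid-search likelihood oracle", {
  d <- sampleTwoLocus(200, 0.1, seed = 32)
  counts <- table(factor(d$gi, 0:2), factor(d$gj, 0:2))
  grid <- seq(0, 0.5, by = 1e-4)
  ll <- vapply(grid, function(r) {
    p <- f2ClassProbs(r)
    sum(counts * log(pmax(p, 1e-300)))
  }, numeric(1))
  oracle <- grid[which.max(ll)]
  expect_lt(abs(estimateRF(d$gi, d$gj) - oracle), 1e-3)
})

test_that("the Kosambi map function matches its closed form and inverse", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3))
  r <- seq(0.01, 0.45, by = 0.04)
  expect_equal(kosambiInv(kosambi(r)), r, tolerance = 1e-12)
  expect_warning(out <- kosambi(0.5), "capped")
  expect_true(is.finite(out))
})

test_that("map construction accumulates adjacent distances from zero", {
  fx <- f2Sim(seed = 41, n = 1000, nMarkers = 3, spanBp = 5e6,
              a = 0, d = 0)
  map <- buildMap(fx$geno, fx$markerPos)
  tab <- mapTable(map)
  expect_equal(tab$cm[1L], 0)
  expect_false(is.unsorted(tab$cm))
  # adjacent spacing 10 cM (Haldane r = 0.0906); Kosambi compresses slightly
  expect_lt(abs(tab$cm[3L] - 2 * kosambi(0.0906)), 2.5)
  # single marker -> zero-length map
  m1 <- buildMap(fx$geno[, 1L, drop = FALSE], fx$markerPos[1L, ])
  expect_equal(mapTable(m1)$cm, 0)
})

test_that("the study-scale marker set yields a map near its simulated length", {
  fx <- f2Sim(seed = 42)   # 17 markers spanning 26.6 cM, n = 204
  map <- buildMap(fx$geno, fx$markerPos)
  expect_lt(abs(max(mapTable(map)$cm) - 26.6), 5)
})

oneMarkerScan <- function(geno, phen) {
  mp <- data.frame(name = colnames(geno), chrom = "chr1", posBp = 100)
  map <- buildMap(geno, mp)
  hkScan(geno, map, phen)
}

test_that("single-marker LOD equals the direct least-squares oracle", {
  geno <- matrix(c("A", "A", "H", "H", "B", "B"), ncol = 1,
                 dimnames = list(NULL, "m1"))
  y <- c(1, 2, 5, 5, 9, 8)
  sc <- scanTable(oneMarkerScan(geno, y))
  x <- c(-1, -1, 0, 0, 1, 1); z <- c(0, 0, 1, 1, 0, 0)
  fit <- lm(y ~ x + z)
  rss1 <- sum(residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(sc$lod, 3 * log10(rss0 / rss1))
  expect_equal(sc$pve, 100 * (1 - rss1 / rss0))
  expect_equal(sc$add, unname(coef(fit)["x"]))
  expect_equal(sc$dom, unname(coef(fit)["z"]))
})

test_that("a perfect fit hits the documented LOD ceiling", {
  geno <- matrix(c("A", "A", "H", "H", "B", "B"), ncol = 1,
                 dimnames = list(NULL, "m1"))
  y <- c(1, 1, 5, 5, 9, 9)    # exactly additive + dominance
  sc <- scanTable(oneMarkerScan(geno, y))
  expect_equal(sc$lod, (6 / 2) * log10(1 / 1e-8))
  expect_lt(sc$pve, 100)
})

test_that("scan values at marker positions equal per-marker regression", {
  fx <- f2Sim(seed = 43, nMarkers = 9)
  map <- buildMap(fx$geno, fx$markerPos)
  sc <- scanTable(hkScan(fx$geno, map, fx$phen))
  dose <- matrix(match(fx$geno, c("A", "H", "B")) - 2L, nrow = nrow(fx$geno))
  for (k in c(1L, 4L, 9L)) {
    cmK <- mapTable(map)$cm[k]
    row <- sc[abs(sc$cm - cmK) < 1e-9, ]
    x <- dose[, k]; z <- as.integer(x == 0L)
    fit <- lm(fx$phen ~ x + z)
    rss1 <- sum(residuals(fit)^2)
    rss0 <- sum((fx$phen - mean(fx$phen))^2)
    expect_equal(row$lod, (nrow(dose) / 2) * log10(rss0 / rss1),
                 tolerance = 1e-8)
    expect_equal(row$add, unname(coef(fit)["x"]), tolerance = 1e-8)
  }
})

test_that("LOD is invariant under affine phenotype transforms", {
  fx <- f2Sim(seed = 44, nMarkers = 7)
  map <- buildMap(fx$geno, fx$markerPos)
  l1 <- scanTable(hkScan(fx$geno, map, fx$phen))$lod
  l2 <- scanTable(hkScan(fx$geno, map, 2.5 * fx$phen - 7))$lod
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("zero phenotypic variance gives LOD 0 everywhere", {
  fx <- f2Sim(seed = 45, nMarkers = 5)
  map <- buildMap(fx$geno, fx$markerPos)
  expect_true(all(scanTable(hkScan(fx$geno, map, rep(5, 204)))$lod == 0))
})

test_that("ICIM without selected cofactors reduces to the base scan", {
  fx <- f2Sim(seed = 46, nMarkers = 7, a = 0, d = 0)   # null trait
  map <- buildMap(fx$geno, fx$markerPos)
  ic <- icimScan(fx$geno, map, fx$phen, linkageConfig(pin = 1e-12))
  expect_length(ic@cofactors, 0L)
  expect_equal(scanTable(ic)$lod, scanTable(hkScan(fx$geno, map, fx$phen))$lod)
})

twoQtlF2 <- function(seed, n = 204, a = c(1.63, 1.04), d = c(0.6, 1.25)) {
  m1 <- as.integer(round(seq(5e5, 7e6, length.out = 8)))
  m6 <- as.integer(round(seq(2.2e7, 2.8e7, length.out = 8)))
  cfg <- bsaSimConfig(
    markerPositions = list(chr1 = sort(c(m1, 3.4e6)),
                           chr6 = sort(c(m6, 2.715e7))),
    popType = "F2", nIndividuals = n,
    qtls = data.frame(chrom = c("chr1", "chr6"), pos = c(3.4e6, 2.715e7),
                      a = a, d = d),
    epistasis = "none", noiseSd = 1.5, phenotypeScale = c(1, 9), seed = seed)
  pop <- simulatePopulation(cfg)
  geno <- genotypeCodes(pop)
  mNames <- paste0(rep(c("chr1_", "chr6_"), each = 8), c(m1, m6))
  list(geno = geno[, mNames],
       phen = assignPhenotypes(pop, cfg),
       markerPos = data.frame(name = mNames,
                              chrom = rep(c("chr1", "chr6"), each = 8),
                              posBp = c(m1, m6)))
}

test_that("cofactor adjustment tends to sharpen unlinked QTL peaks", {
  wins <- 0L
  for (s in 1:10) {
    fx <- twoQtlF2(seed = 500 + s)
    map <- buildMap(fx$geno, fx$markerPos)
    hk <- scanTable(hkScan(fx$geno, map, fx$phen))
    ic <- scanTable(icimScan(fx$geno, map, fx$phen))
    better <- vapply(c("chr1", "chr6"), function(ch)
      max(ic$lod[ic$chrom == ch]) >= max(hk$lod[hk$chrom == ch]) - 1e-9,
      logical(1))
    wins <- wins + all(better)
  }
  expect_gte(wins, 6L)
})

test_that("peak effect estimates recover the induced additive and dominance", {
  # induced-scale truth: regression of the ordinal score on the true QTL
  # dose in a large population under the same generative model; the QTL sits
  # exactly on a marker so the flanking-probability attenuation of
  # Haley-Knott regression does not enter
  # closed-form truth: the ordinal score is 1 + #{cuts below the latent
  # value}, so the induced genotype-group means are sums of normal tail
  # probabilities
  a <- 1.63; d <- 0.60; sdn <- 1.5
  cuts <- qnorm(seq(0.8, 0.99, length.out = 8), 0, sdn)
  ey <- function(mu) 1 + sum(pnorm((mu - cuts) / sdn))
  truthA <- (ey(2 * a) - ey(0)) / 2
  truthD <- ey(a + d) - (ey(0) + ey(2 * a)) / 2
  qtlAtMarker <- 3409375
  nRep <- 60
  est <- t(vapply(seq_len(nRep), function(s) {
    fx <- f2Sim(seed = 600 + s, qtlBp = qtlAtMarker)
    map <- buildMap(fx$geno, fx$markerPos)
    sc <- scanTable(hkScan(fx$geno, map, fx$phen))
    pk <- sc[which.max(sc$lod), ]
    c(pk$add, pk$dom)
  }, numeric(2)))
  seA <- sd(est[, 1L]) / sqrt(nRep)
  seD <- sd(est[, 2L]) / sqrt(nRep)
  # the 0.1 allowance covers flanking-probability attenuation when the
  # LOD peak lands a step or two off the QTL marker
  expect_lt(abs(mean(est[, 1L]) - truthA), 2 * seA + 0.1)
  expect_lt(abs(mean(est[, 2L]) - truthD), 2 * seD + 0.1)
})

test_that("permutation thresholds are deterministic and degenerate correctly", {
  fx <- f2Sim(seed = 47, nMarkers = 5)
  map <- buildMap(fx$geno, fx$markerPos)
  cfgL <- linkageConfig(nPerm = 200, seed = 99)
  t1 <- permutationThreshold(fx$geno, map, fx$phen, cfgL)
  t2 <- permutationThreshold(fx$geno, map, fx$phen, cfgL)
  expect_identical(t1, t2)
  t0 <- permutationThreshold(fx$geno, map, rep(3, 204), cfgL)
  expect_equal(as.numeric(t0), 0)
  expect_error(permutationThreshold(fx$geno, map, fx$phen,
                                    linkageConfig(nPerm = 50)), "100")
})

test_that("the permutation threshold holds its genome-wide type-I error", {
  fx <- f2Sim(seed = 48, a = 0, d = 0)   # fixed genotypes, null trait
  map <- buildMap(fx$geno, fx$markerPos)
  set.seed(77)
  hits <- vapply(1:400, function(k) {
    y <- rnorm(204)
    thr <- permutationThreshold(fx$geno, map, y,
                                linkageConfig(nPerm = 200, seed = 1000 + k))
    max(scanTable(hkScan(fx$geno, map, y))$lod) > thr
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("QTL summaries report peaks above threshold with flanking markers", {
  fx <- twoQtlF2(seed = 70)
  map <- buildMap(fx$geno, fx$markerPos)
  sc <- hkScan(fx$geno, map, fx$phen)
  qtl <- summarizeQtl(sc, threshold = 3)
  expect_setequal(qtl$chrom, c("chr1", "chr6"))
  expect_true(all(qtl$lod >= 3))
  expect_true(all(qtl$leftMarker %in% fx$markerPos$name))
  expect_equal(nrow(summarizeQtl(sc, threshold = 1e6)), 0L)
})
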