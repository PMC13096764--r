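#' Simulated segregating population
#'
#' Haplotype-resolved genotypes of a simulated biparental population.  Alleles
#' are coded 0 (recurrent parent) and 1 (donor parent); the genotype dose at a
#' locus is the number of donor alleles (0, 1 or 2).
#'
#' @slot h1,h2 integer matrices (individuals x loci) holding the two
#'   haplotypes.
#' @slot loci `GRanges` of simulated SNP positions (width 1), sorted.
#' @slot popType,generation population model the individuals were drawn from.
#'
#' @seealso [simulatePopulation()], [genotypeDoses()], [genotypeCodes()]
#' @exportClass BsaPopulation
setClass("BsaPopulation", representation(
  h1         = "matrix",
  h2         = "matrix",
  loci       = "GRanges",
  popType    = "character",
  generation = "numeric"
))

setValidity("BsaPopulation", function(object) {
  msg <- character()
  if (!identical(dim(object@h1), dim(object@h2)))
    msg <- c(msg, "haplotype matrices must have identical dimensions")
  if (ncol(object@h1) != length(object@loci))
    msg <- c(msg, "one locus column per GRanges position required")
  if (length(object@h1) && !all(object@h1 %in% 0:1 & object@h2 %in% 0:1))
    msg <- c(msg, "haplotype alleles must be 0 or 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BsaPopulation", function(object) {
  cat("BsaPopulation:", nrow(object@h1), object@popType,
      if (object@popType != "F2")
        sprintf("(generation %d)", as.integer(object@generation)),
      "individuals,", ncol(object@h1), "loci\n")
  het <- mean(object@h1 != object@h2)
  cat(sprintf("  mean heterozygosity: %.4f\n", het))
})

#' @rdname accessors
#' @export
genotypeDoses <- function(object) object@h1 + object@h2

#' @rdname accessors
#' @export
lociRanges <- function(object) object@loci

#' Donor-dose genotypes as A/H/B marker codes
#'
#' @param object a [BsaPopulation-class].
#' @return character matrix (individuals x loci) with codes `"A"` (recurrent
#'   homozygote), `"H"` (heterozygote), `"B"` (donor homozygote); columns named
#'   `<chrom>_<pos>`.
#' @export
genotypeCodes <- function(object) {
  m <- matrix(c("A", "H", "B")[genotypeDoses(object) + 1L],
              nrow = nrow(object@h1))
  colnames(m) <- paste(as.character(GenomeInfoDb::seqnames(object@loci)),
                       GenomicRanges::start(object@loci), sep = "_")
  m
}

#' Build a simulation configuration
#'
#' Returns a [BsaSimConfig-class].  The defaults encode the study design the
#' package emulates: two rice chromosomes (1 and 6, IRGSP-1.0 lengths), a
#' recombinant-inbred population of 49 lines at selfing generation 9, SNP sites
#' every 1 kb (the density of a filtered whole-genome bulk-sequencing variant
#' set), 50x mean bulk depth, and two trait loci acting by complementary epistasis
#' with additive/dominance effects 1.63/0.60 (chromosome 1) and 1.04/1.25
#' (chromosome 6) in latent phenotype units.  The QTL positions sit at the
#' midpoints of the fine-mapped intervals on each chromosome.
#'
#' @param chromLengths named numeric, chromosome lengths (bp).
#' @param markerSpacing mean SNP spacing (bp).
#' @param markerPositions optional named list chromosome -> bp positions,
#'   overriding the regular grid (used e.g. to place linkage markers).
#' @param popType `"RIL"`, `"F2"` or `"BC1F"`.
#' @param generation selfing generation for RIL/BC1F.
#' @param nIndividuals population size.
#' @param qtls data.frame with columns `chrom`, `pos`, `a`, `d`.
#' @param epistasis `"complementary"` (trait requires donor alleles at all
#'   declared loci) or `"none"` (additive across loci).
#' @param noiseSd residual standard deviation on the latent scale.
#' @param phenotypeScale ordinal bounds, e.g. `c(1, 3)` or `c(1, 9)`.
#' @param depthMean mean read depth per SNP per bulk.
#' @param cmPerMb genetic-to-physical rate for crossover simulation.
#' @param seed RNG seed used by [simulatePopulation()] (NA = do not touch RNG).
#' @return a validated [BsaSimConfig-class].
#' @examples
#' cfg <- bsaSimConfig(nIndividuals = 20, markerSpacing = 1e6)
#' cfg
#' @export
bsaSimConfig <- function(chromLengths = c(chr1 = 43270923, chr6 = 31248787),
                         markerSpacing = 1000,
                         markerPositions = list(),
                         popType = c("RIL", "F2", "BC1F"),
                         generation = 9,
                         nIndividuals = 49,
                         qtls = data.frame(
                           chrom = c("chr1", "chr6"),
                           pos   = c(3400000, 27150000),
                           a     = c(1.63, 1.04),
                           d     = c(0.60, 1.25)),
                         epistasis = c("complementary", "none"),
                         noiseSd = 1.5,
                         phenotypeScale = c(1, 3),
                         depthMean = 50,
                         cmPerMb = 4,
                         seed = NA_real_) {
  popType <- match.arg(popType)
  epistasis <- match.arg(epistasis)
  new("BsaSimConfig",
      chromLengths = chromLengths, markerSpacing = markerSpacing,
      markerPositions = markerPositions, popType = popType,
      generation = generation, nIndividuals = nIndividuals, qtls = qtls,
      epistasis = epistasis, noiseSd = noiseSd,
      phenotypeScale = phenotypeScale, depthMean = depthMean,
      cmPerMb = cmPerMb, seed = as.numeric(seed))
}

## locus positions per chromosome, bp and cM
.lociBp <- function(config) {
  lapply(seq_along(config@chromLengths), function(i) {
    ch <- names(config@chromLengths)[i]
    if (!is.null(config@markerPositions[[ch]]))
      sort(unique(round(config@markerPositions[[ch]])))
    else
      seq(config@markerSpacing, config@chromLengths[i],
          by = config@markerSpacing)
  })
}

## one meiosis: recombine two haplotype vectors; cm = genetic positions (cM).
## Crossovers are a Poisson process on the genetic scale (Haldane model).
.meiosis <- function(h1, h2, cm) {
  span <- (cm[length(cm)] - cm[1L]) / 100   # Morgans
  nco <- rpois(1L, span)
  start <- runif(1L) < 0.5
  if (nco == 0L) return(if (start) h1 else h2)
  xo <- sort(runif(nco, cm[1L], cm[length(cm)]))
  phase <- (findInterval(cm, xo) + start) %% 2L
  ifelse(phase == 1L, h1, h2)
}

#' Simulate a biparental segregating population
#'
#' Gamete simulation with crossovers as a Poisson process on the genetic scale
#' (Haldane model, no interference); bp positions are converted to cM at the
#' configured constant rate.  F2 individuals are formed from two independent
#' F1 gametes; RIL(g) populations are iterated-selfing descendants of F2
#' individuals down to generation g; BC1F(g) individuals start as F1 gamete x
#' recurrent gamete and are then selfed.
#'
#' @param config a [BsaSimConfig-class]; `config@seed`, when not NA, seeds the
#'   RNG before simulation so the population (and everything drawn after it in
#'   the same stream) is reproducible.
#' @return a [BsaPopulation-class].
#' @examples
#' cfg <- bsaSimConfig(popType = "F2", nIndividuals = 50,
#'                     markerSpacing = 2e6, qtls = data.frame(), seed = 1)
#' pop <- simulatePopulation(cfg)
#' table(genotypeDoses(pop)[, 1])
#' @export
simulatePopulation <- function(config) {
  stopifnot(is(config, "BsaSimConfig"))
  validObject(config)
  if (!is.na(config@seed)) set.seed(as.integer(config@seed))
  bp <- .lociBp(config)
  cm <- lapply(bp, function(p) p * config@cmPerMb / 1e6)
  n <- as.integer(config@nIndividuals)
  nLoc <- vapply(bp, length, integer(1))
  H1 <- matrix(0L, n, sum(nLoc))
  H2 <- matrix(0L, n, sum(nLoc))
  colIdx <- split(seq_len(sum(nLoc)), rep(seq_along(bp), nLoc))
  gens <- switch(config@popType,
                 F2 = 2L, RIL = as.integer(config@generation),
                 BC1F = as.integer(config@generation))
  for (ci in seq_along(bp)) {
    g <- cm[[ci]]
    rec <- integer(length(g))          # recurrent haplotype (all 0)
    don <- rep(1L, length(g))          # donor haplotype
    for (ind in seq_len(n)) {
      if (config@popType == "BC1F") {
        a <- .meiosis(rec, don, g)     # F1 gamete
        b <- rec                       # recurrent gamete
        selfings <- gens - 1L
      } else {
        a <- .meiosis(rec, don, g)     # two F1 gametes -> F2 individual
        b <- .meiosis(rec, don, g)
        selfings <- gens - 2L
      }
      if (selfings > 0L) for (s in seq_len(selfings)) {
        a2 <- .meiosis(a, b, g)
        b2 <- .meiosis(a, b, g)
        a <- a2; b <- b2
      }
      H1[ind, colIdx[[ci]]] <- a
      H2[ind, colIdx[[ci]]] <- b
    }
  }
  loci <- GenomicRanges::GRanges(
    seqnames = rep(names(config@chromLengths), nLoc),
    ranges = IRanges::IRanges(start = unlist(bp), width = 1L),
    seqlengths = setNames(config@chromLengths, names(config@chromLengths)))
  new("BsaPopulation", h1 = H1, h2 = H2, loci = loci,
      popType = config@popType,
      generation = if (config@popType == "F2") 2 else config@generation)
}

## nearest-locus column index for each QTL; warns when not exact
.qtlLocusIndex <- function(pop, qtls) {
  chs <- as.character(GenomeInfoDb::seqnames(pop@loci))
  pos <- GenomicRanges::start(pop@loci)
  idx <- integer(nrow(qtls))
  for (i in seq_len(nrow(qtls))) {
    on <- which(chs == qtls$chrom[i])
    if (!length(on)) stop("QTL chromosome ", qtls$chrom[i], " has no loci")
    j <- on[which.min(abs(pos[on] - qtls$pos[i]))]
    if (pos[j] != qtls$pos[i])
      warning(sprintf("QTL at %s:%d mapped to nearest simulated locus %s:%d",
                      qtls$chrom[i], as.integer(qtls$pos[i]),
                      chs[j], pos[j]), call. = FALSE)
    idx[i] <- j
  }
  idx
}

#' Assign ordinal phenotype scores
#'
#' The latent trait value is `sum_i(a_i * x_i + d_i * z_i) + e` with `x_i` the
#' donor-allele dose and `z_i` the heterozygosity indicator at QTL i and
#' `e ~ Normal(0, noiseSd)`.  Under complementary epistasis the genetic term is
#' zeroed unless donor alleles are present (dose >= 1) at every declared
#' locus.  Latent values are binned into the ordinal scale at fixed cut points
#' given by upper-tail quantiles of the null (no-genetics) latent distribution,
#' so that with small effects the bottom score class dominates; with
#' `noiseSd = 0` the cut points are spread evenly between 0 and the maximal
#' genetic value instead.
#'
#' @param pop a [BsaPopulation-class].
#' @param config the [BsaSimConfig-class] used to simulate it.
#' @return integer vector of ordinal scores within `config@phenotypeScale`.
#' @export
assignPhenotypes <- function(pop, config) {
  stopifnot(is(pop, "BsaPopulation"), is(config, "BsaSimConfig"))
  n <- nrow(pop@h1)
  lo <- config@phenotypeScale[1L]; hi <- config@phenotypeScale[2L]
  nBins <- as.integer(hi - lo + 1L)
  if (nrow(config@qtls) == 0L) {
    genetic <- numeric(n)
  } else {
    if (config@epistasis == "complementary" && nrow(config@qtls) < 2L)
      stop("complementary epistasis requires at least two declared QTLs")
    idx <- .qtlLocusIndex(pop, config@qtls)
    x <- (pop@h1 + pop@h2)[, idx, drop = FALSE]
    z <- (pop@h1 != pop@h2)[, idx, drop = FALSE] + 0L
    genetic <- drop(x %*% config@qtls$a + z %*% config@qtls$d)
    if (config@epistasis == "complementary") {
      gate <- rowSums(x >= 1L) == ncol(x)
      genetic <- genetic * gate
    }
  }
  latent <- genetic + rnorm(n, 0, config@noiseSd)
  if (config@noiseSd > 0) {
    cuts <- qnorm(seq(0.8, 0.99, length.out = nBins - 1L), 0, config@noiseSd)
  } else {
    gmax <- max(genetic)
    cuts <- if (gmax > 0) seq(0, gmax, length.out = nBins)[-1L]
            else rep(Inf, nBins - 1L)
  }
  as.integer(lo + findInterval(latent, cuts))
}

#' Assign individuals to high and low bulks
#'
#' With the default `"rank"` rule the high bulk is the top `nHigh` individuals
#' by score and the low bulk the bottom `nLow`; ties at a bulk boundary are
#' broken by individual index (ascending for the high bulk, descending for the
#' low bulk), which keeps the two bulks disjoint whenever
#' `nHigh + nLow <= n`.  The `"class"` rule instead takes everyone at the
#' maximal score vs everyone at the minimal score.
#'
#' @param phenotypes numeric/integer score vector.
#' @param nHigh,nLow requested bulk sizes (rank rule).
#' @param rule `"rank"` or `"class"`.
#' @return list with integer index vectors `high` and `low`.
#' @examples
#' formBulks(c(3, 1, 1, 3, 2, 1, 3, 1), nHigh = 2, nLow = 3)
#' @export
formBulks <- function(phenotypes, nHigh = 8L, nLow = 12L,
                      rule = c("rank", "class")) {
  rule <- match.arg(rule)
  n <- length(phenotypes)
  if (rule == "rank") {
    if (nHigh + nLow > n)
      stop("bulk sizes exceed population size (", nHigh, "+", nLow,
           " > ", n, ")")
    idx <- seq_len(n)
    ordHigh <- order(-phenotypes, idx)
    ordLow <- order(phenotypes, -idx)
    high <- ordHigh[seq_len(nHigh)]
    low <- ordLow[seq_len(nLow)]
    s <- sort(phenotypes, decreasing = TRUE)
    if (nHigh < n && s[nHigh] == s[nHigh + 1L])
      warning("ties at the high-bulk boundary broken by individual index",
              call. = FALSE)
    s2 <- sort(phenotypes)
    if (nLow < n && s2[nLow] == s2[nLow + 1L])
      warning("ties at the low-bulk boundary broken by individual index",
              call. = FALSE)
  } else {
    if (max(phenotypes) == min(phenotypes))
      stop("all scores identical; class rule cannot form bulks")
    high <- which(phenotypes == max(phenotypes))
    low <- which(phenotypes == min(phenotypes))
  }
  list(high = high, low = low)
}

## Poisson truncated at >= 1: zero-depth sites are unobservable in a SNP table
.rtpois <- function(n, mu) qpois(runif(n, ppois(0, mu), 1), mu)

#' Sample a two-bulk SNP allele-depth table
#'
#' For each simulated SNP and each bulk, the true donor-allele frequency is
#' the mean donor dose over bulk members divided by 2; the total read depth is
#' Poisson(`depthMean`) truncated at >= 1 and the donor-allele read count is
#' Binomial(depth, frequency).
#'
#' @param pop a [BsaPopulation-class].
#' @param bulks list with `high`/`low` index vectors, from [formBulks()].
#' @param config the [BsaSimConfig-class] (for `depthMean`).
#' @return a sorted `GRanges` with metadata columns `REF`, `ALT` (synthetic
#'   bases; `ALT` is the donor allele), `highRef`, `highAlt`, `lowRef`,
#'   `lowAlt`.
#' @export
sampleSnpTable <- function(pop, bulks, config) {
  stopifnot(is(pop, "BsaPopulation"))
  if (!length(bulks$high) || !length(bulks$low))
    stop("empty bulk")
  doses <- genotypeDoses(pop)
  fHigh <- colMeans(doses[bulks$high, , drop = FALSE]) / 2
  fLow <- colMeans(doses[bulks$low, , drop = FALSE]) / 2
  L <- length(fHigh)
  depthH <- .rtpois(L, config@depthMean)
  depthL <- .rtpois(L, config@depthMean)
  altH <- rbinom(L, depthH, fHigh)
  altL <- rbinom(L, depthL, fLow)
  refIdx <- sample.int(4L, L, replace = TRUE)
  altIdx <- (refIdx - 1L + sample.int(3L, L, replace = TRUE)) %% 4L + 1L
  bases <- c("A", "C", "G", "T")
  gr <- pop@loci
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    REF = bases[refIdx], ALT = bases[altIdx],
    highRef = depthH - altH, highAlt = altH,
    lowRef = depthL - altL, lowAlt = altL)
  sort(gr)
}

#' Run the full synthetic bulked-segregant generator
#'
#' Convenience wrapper: simulates the population, assigns phenotypes, forms
#' bulks and samples the SNP allele-depth table in one reproducible stream
#' (seeded by `config@seed`).
#'
#' @inheritParams assignPhenotypes
#' @inheritParams formBulks
#' @return list with elements `config`, `population`, `phenotypes`, `bulks`,
#'   `records`.
#' @examples
#' sim <- simulateBsa(bsaSimConfig(markerSpacing = 5e5, seed = 1))
#' head(sim$records)
#' @export
simulateBsa <- function(config, nHigh = 8L, nLow = 12L,
                        rule = c("rank", "class")) {
  pop <- simulatePopulation(config)
  phen <- assignPhenotypes(pop, config)
  bulks <- formBulks(phen, nHigh = nHigh, nLow = nLow, rule = match.arg(rule))
  records <- sampleSnpTable(pop, bulks, config)
  list(config = config, population = pop, phenotypes = phen, bulks = bulks,
       records = records)
}
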