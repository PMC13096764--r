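#' SNP-table filters
#'
#' @param minDepth minimum total read depth per bulk (applied to each bulk).
#' @param maxDepth maximum total depth per bulk (`Inf` = no cap).
#' @param dropMonomorphic drop sites monomorphic across both bulks (no
#'   alternate read in either bulk, or no reference read in either bulk).
#' @return list of class settings consumed by [computeIndices()].
#' @export
snpFilters <- function(minDepth = 10L, maxDepth = Inf, dropMonomorphic = TRUE) {
  if (minDepth < 1) stop("minDepth must be >= 1")
  if (maxDepth < minDepth) stop("maxDepth must be >= minDepth")
  list(minDepth = minDepth, maxDepth = maxDepth,
       dropMonomorphic = dropMonomorphic)
}

.requireCountCols <- function(gr) {
  need <- c("highRef", "highAlt", "lowRef", "lowAlt")
  miss <- setdiff(need, names(S4Vectors::mcols(gr)))
  if (length(miss))
    stop("missing count columns: ", paste(miss, collapse = ", "))
}

#' Compute per-bulk SNP indices and the delta-SNP index
#'
#' The SNP index of a bulk is the donor-allele read fraction
#' `alt / (ref + alt)`; the delta-SNP index is high-bulk index minus low-bulk
#' index.  Rows failing the filters are removed before index computation and
#' the output is sorted by (chromosome, position).
#'
#' @param records `GRanges` with count columns `highRef`, `highAlt`, `lowRef`,
#'   `lowAlt` (as produced by [sampleSnpTable()] or [readSnpTable()]).
#' @param filters a [snpFilters()] list.
#' @return the filtered, sorted `GRanges` with added columns `snpIndexHigh`,
#'   `snpIndexLow`, `delta`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'   highRef = c(10L, 0L), highAlt = c(10L, 20L),
#'   lowRef = c(10L, 20L), lowAlt = c(10L, 0L))
#' computeIndices(gr)
#' @export
computeIndices <- function(records, filters = snpFilters()) {
  stopifnot(is(records, "GRanges"))
  .requireCountCols(records)
  mc <- S4Vectors::mcols(records)
  cnt <- as.matrix(as.data.frame(
    mc[, c("highRef", "highAlt", "lowRef", "lowAlt")]))
  if (any(cnt < 0)) stop("negative counts")
  key <- paste(as.character(GenomeInfoDb::seqnames(records)),
               GenomicRanges::start(records))
  if (anyDuplicated(key)) stop("duplicate (chrom, pos) rows")
  records <- sort(records)
  mc <- S4Vectors::mcols(records)
  dH <- mc$highRef + mc$highAlt
  dL <- mc$lowRef + mc$lowAlt
  keep <- dH >= filters$minDepth & dL >= filters$minDepth &
          dH <= filters$maxDepth & dL <= filters$maxDepth
  if (filters$dropMonomorphic) {
    mono <- (mc$highAlt + mc$lowAlt == 0L) | (mc$highRef + mc$lowRef == 0L)
    keep <- keep & !mono
  }
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " of ", length(records), " sites removed by filters")
  records <- records[keep]
  mc <- S4Vectors::mcols(records)
  iH <- mc$highAlt / (mc$highRef + mc$highAlt)
  iL <- mc$lowAlt / (mc$lowRef + mc$lowAlt)
  S4Vectors::mcols(records)$snpIndexHigh <- iH
  S4Vectors::mcols(records)$snpIndexLow <- iL
  S4Vectors::mcols(records)$delta <- iH - iL
  records
}

## donor-dose genotype frequencies at a neutral locus
.genoFreq <- function(popModel, generation) {
  switch(popModel,
    F2 = c(0.25, 0.5, 0.25),
    RIL = {
      h <- 2^-(generation - 1)
      c((1 - h) / 2, h, (1 - h) / 2)
    },
    BC1F = {
      het <- 0.5^generation
      bb <- (0.5 - het) / 2
      c(1 - het - bb, het, bb)
    },
    stop("unknown pop_model: ", popModel))
}

#' Simulate the null distribution of the delta-SNP index
#'
#' For each requested depth, bulk members' genotypes are drawn at a neutral
#' locus from the population model's genotype frequencies (F2 1:2:1; RIL(g)
#' fixed classes plus residual heterozygosity `2^-(g-1)`; BC1F(g)
#' correspondingly), the bulk donor-allele frequency is formed, read counts
#' are drawn Binomial(depth, frequency) per bulk, and the delta-SNP index is
#' recorded.
#'
#' @param popModel `"RIL"`, `"F2"` or `"BC1F"`.
#' @param nHigh,nLow bulk sizes.
#' @param generation selfing generation (RIL/BC1F).
#' @param depths per-bulk depth grid to tabulate.
#' @param nReps replicates per depth (>= 1000).
#' @param seed RNG seed.
#' @return a [NullDistribution-class].
#' @examples
#' nd <- simulateNull("RIL", 8, 12, depths = c(20, 50), nReps = 1000, seed = 1)
#' nullQuantile(nd, 0.95, 20)
#' @export
simulateNull <- function(popModel = c("RIL", "F2", "BC1F"),
                         nHigh, nLow, generation = 9,
                         depths = seq(5, 100, by = 5),
                         nReps = 5000L, seed = 1L) {
  popModel <- match.arg(popModel)
  if (nReps < 1000L) stop("nReps must be >= 1000")
  if (any(depths < 1)) stop("depths must be >= 1")
  depths <- sort(depths)
  set.seed(as.integer(seed))
  pg <- .genoFreq(popModel, generation)
  samples <- lapply(depths, function(d) {
    gH <- matrix(sample(0:2, nReps * nHigh, replace = TRUE, prob = pg),
                 nReps, nHigh)
    gL <- matrix(sample(0:2, nReps * nLow, replace = TRUE, prob = pg),
                 nReps, nLow)
    fH <- rowSums(gH) / (2 * nHigh)
    fL <- rowSums(gL) / (2 * nLow)
    idxH <- rbinom(nReps, d, fH) / d
    idxL <- rbinom(nReps, d, fL) / d
    sort(idxH - idxL)
  })
  new("NullDistribution", popModel = popModel, generation = generation,
      nHigh = nHigh, nLow = nLow, depths = as.numeric(depths),
      samples = samples, nReps = as.numeric(nReps), seed = as.numeric(seed))
}

## map arbitrary depths onto the tabulated grid: index pairs + weights for
## linear interpolation; depths outside the grid fall back to the nearest
## tabulated depth (warning handled by callers)
.depthBracket <- function(null, depth) {
  d <- null@depths
  if (length(d) == 1L)
    return(list(lo = rep(1L, length(depth)), hi = rep(1L, length(depth)),
                w = rep(1, length(depth))))
  depth <- pmin(pmax(depth, d[1L]), d[length(d)])
  hi <- findInterval(depth, d, left.open = TRUE) + 1L
  hi <- pmin(pmax(hi, 2L), length(d))
  lo <- hi - 1L
  w <- (d[hi] - depth) / (d[hi] - d[lo])   # weight of the lower depth
  list(lo = lo, hi = hi, w = w)
}

#' Null quantile of the absolute delta-SNP index
#'
#' @param null a [NullDistribution-class].
#' @param prob quantile level (e.g. 0.95 or 0.99).
#' @param depth per-bulk read depth(s); interpolated linearly between
#'   tabulated depths, clamped to the tabulated range.
#' @return numeric vector of `|delta|` quantiles.
#' @export
nullQuantile <- function(null, prob, depth) {
  q <- vapply(null@samples,
              function(s) unname(quantile(abs(s), prob)), numeric(1))
  br <- .depthBracket(null, depth)
  br$w * q[br$lo] + (1 - br$w) * q[br$hi]
}

## empirical two-sided p for |delta| against one sorted null sample
.empiricalP <- function(absDelta, sortedAbsNull) {
  n <- length(sortedAbsNull)
  ge <- n - findInterval(absDelta - 1e-12, sortedAbsNull)
  (1 + ge) / (n + 1)
}

#' Assign empirical per-SNP p-values
#'
#' Two-sided empirical p-values on `|delta|`:
#' `p = (1 + #\{null |delta| >= |observed|\}) / (nReps + 1)`.  Each record is
#' matched to the null by the harmonic mean of its two bulk depths (the
#' single-depth null with the same read-sampling variance), with linear
#' interpolation between tabulated depths; depths outside the tabulated range
#' use the nearest tabulated depth with a warning.
#'
#' @param records `GRanges` from [computeIndices()] (must carry `delta`).
#' @param null a matching [NullDistribution-class].
#' @return `records` with an added `pValue` column in (0, 1].
#' @export
assignPvalues <- function(records, null) {
  stopifnot(is(records, "GRanges"), is(null, "NullDistribution"))
  mc <- S4Vectors::mcols(records)
  if (is.null(mc$delta)) stop("run computeIndices() first (no delta column)")
  dH <- mc$highRef + mc$highAlt
  dL <- mc$lowRef + mc$lowAlt
  depth <- 2 / (1 / dH + 1 / dL)
  if (any(depth < null@depths[1L]))
    warning(sum(depth < null@depths[1L]),
            " record(s) below the smallest simulated depth; ",
            "nearest-depth fallback used", call. = FALSE)
  if (any(depth > null@depths[length(null@depths)]))
    warning(sum(depth > null@depths[length(null@depths)]),
            " record(s) above the largest simulated depth; ",
            "nearest-depth fallback used", call. = FALSE)
  absNull <- lapply(null@samples, function(s) sort(abs(s)))
  br <- .depthBracket(null, depth)
  obs <- abs(mc$delta)
  p <- numeric(length(records))
  grp <- paste(br$lo, br$hi)
  for (g in unique(grp)) {
    sel <- grp == g
    lo <- br$lo[sel][1L]; hi <- br$hi[sel][1L]
    pLo <- .empiricalP(obs[sel], absNull[[lo]])
    pHi <- if (hi == lo) pLo else .empiricalP(obs[sel], absNull[[hi]])
    p[sel] <- br$w[sel] * pLo + (1 - br$w[sel]) * pHi
  }
  S4Vectors::mcols(records)$pValue <- p
  records
}
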