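#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats rpois rbinom runif rnorm qnorm quantile setNames lm
#'   lm.fit anova pf qpois ppois sd coef residuals
#' @importFrom utils head tail read.table write.table
NULL

#' Simulation configuration for synthetic bulked-segregant designs
#'
#' `BsaSimConfig` describes a segregating population, the trait architecture
#' and the bulk-sequencing design from which synthetic SNP allele-depth tables
#' are generated.  The defaults of [bsaSimConfig()] encode the study design the
#' package was built around: 49 recombinant inbred lines (selfing generation 9)
#' derived from a cross between a recurrent elite parent and a weedy donor,
#' bulked 8 (trait) vs 12 (non-trait), with two trait loci on chromosomes 1 and
#' 6 that act by complementary epistasis -- the trait appears only when donor
#' alleles are present at both loci.
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot markerSpacing mean spacing (bp) of simulated SNP sites.
#' @slot markerPositions optional named list (chromosome -> positions in bp)
#'   overriding the regular grid; empty list means use the grid.
#' @slot popType `"F2"`, `"RIL"` or `"BC1F"`.
#' @slot generation selfing generation for `"RIL"`/`"BC1F"` (ignored for F2).
#' @slot nIndividuals population size.
#' @slot qtls data.frame with columns `chrom`, `pos`, `a` (additive, latent
#'   units per donor allele) and `d` (dominance, latent units).
#' @slot epistasis `"none"` or `"complementary"`.
#' @slot noiseSd latent-scale residual standard deviation.
#' @slot phenotypeScale integer length-2, ordinal score bounds (e.g. `c(1, 9)`).
#' @slot depthMean mean sequencing depth per SNP per bulk.
#' @slot cmPerMb genetic-to-physical rate used for crossover simulation.
#' @slot seed RNG seed (NA to leave the RNG state untouched).
#'
#' @seealso [bsaSimConfig()], [simulatePopulation()], [simulateBsa()]
#' @exportClass BsaSimConfig
setClass("BsaSimConfig", representation(
  chromLengths    = "numeric",
  markerSpacing   = "numeric",
  markerPositions = "list",
  popType         = "character",
  generation      = "numeric",
  nIndividuals    = "numeric",
  qtls            = "data.frame",
  epistasis       = "character",
  noiseSd         = "numeric",
  phenotypeScale  = "numeric",
  depthMean       = "numeric",
  cmPerMb         = "numeric",
  seed            = "numeric"
))

setValidity("BsaSimConfig", function(object) {
  msg <- character()
  if (length(object@chromLengths) < 1L || is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be a named numeric vector")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be > 0")
  if (object@markerSpacing <= 0)
    msg <- c(msg, "markerSpacing must be > 0")
  if (!object@popType %in% c("F2", "RIL", "BC1F"))
    msg <- c(msg, "popType must be one of 'F2', 'RIL', 'BC1F'")
  if (object@popType != "F2" && (is.na(object@generation) || object@generation < 2))
    msg <- c(msg, "generation must be >= 2 for RIL/BC1F populations")
  if (object@nIndividuals < 2)
    msg <- c(msg, "nIndividuals must be >= 2")
  if (nrow(object@qtls) > 0) {
    if (!all(c("chrom", "pos", "a", "d") %in% names(object@qtls)))
      msg <- c(msg, "qtls needs columns chrom, pos, a, d")
    else {
      if (!all(object@qtls$chrom %in% names(object@chromLengths)))
        msg <- c(msg, "every QTL must lie on a declared chromosome")
      else if (any(object@qtls$pos < 1 |
                   object@qtls$pos > object@chromLengths[object@qtls$chrom]))
        msg <- c(msg, "QTL position off-chromosome")
      if (!all(is.finite(object@qtls$a)) || !all(is.finite(object@qtls$d)))
        msg <- c(msg, "QTL effects a, d must be finite")
    }
  }
  if (!object@epistasis %in% c("none", "complementary"))
    msg <- c(msg, "epistasis must be 'none' or 'complementary'")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@phenotypeScale) != 2L ||
      object@phenotypeScale[2L] <= object@phenotypeScale[1L])
    msg <- c(msg, "phenotypeScale must be c(low, high) with high > low")
  if (object@depthMean <= 0)
    msg <- c(msg, "depthMean must be > 0")
  if (object@cmPerMb <= 0)
    msg <- c(msg, "cmPerMb must be > 0")
  if (length(msg)) msg else TRUE
})

#' Empirical null distribution of the delta-SNP index
#'
#' Depth-indexed Monte-Carlo samples of the delta-SNP index under the no-QTL
#' model for a given population type and pair of bulk sizes.  Used to assign
#' per-SNP empirical p-values, per-SNP confidence bands and window-level
#' resampling p-values.
#'
#' @slot popModel population model id (`"F2"`, `"RIL"`, `"BC1F"`).
#' @slot generation selfing generation (RIL/BC1F).
#' @slot nHigh,nLow bulk sizes.
#' @slot depths numeric grid of per-bulk read depths at which the null was
#'   tabulated.
#' @slot samples list (one per depth) of sorted signed null delta values.
#' @slot nReps replicates per depth.
#' @slot seed seed used.
#'
#' @seealso [simulateNull()], [assignPvalues()], [nullQuantile()]
#' @exportClass NullDistribution
setClass("NullDistribution", representation(
  popModel   = "character",
  generation = "numeric",
  nHigh      = "numeric",
  nLow       = "numeric",
  depths     = "numeric",
  samples    = "list",
  nReps      = "numeric",
  seed       = "numeric"
))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@depths) != length(object@samples))
    msg <- c(msg, "one sample vector per tabulated depth required")
  if (is.unsorted(object@depths, strictly = TRUE))
    msg <- c(msg, "depths must be strictly increasing")
  if (any(vapply(object@samples, is.unsorted, logical(1))))
    msg <- c(msg, "each null sample must be sorted")
  if (any(vapply(object@samples, length, integer(1)) != object@nReps))
    msg <- c(msg, "each null sample must hold nReps values")
  if (length(msg)) msg else TRUE
})

#' Trace of the progressive window-refinement procedure
#'
#' Records, for every rung of a [refineLadder()], the window statistics over
#' the retained windows (those containing at least one significant SNP) and the
#' candidate interval extracted at that rung.
#'
#' @slot region the input region (a length-1 `GRanges`).
#' @slot ladder two-column matrix of (window, step) sizes in bp.
#' @slot rungs list of `GRanges` window-statistic tables, one per rung
#'   (possibly empty when a rung was skipped or retained nothing).
#' @slot candidates list of candidate intervals (`GRanges` of length 1 or 0).
#' @slot criteria list with elements `tau` and `gap` (see
#'   [candidateCriteria()]).
#'
#' @seealso [refineRegion()], [candidateInterval()], [rungStats()]
#' @exportClass RefinementTrace
setClass("RefinementTrace", representation(
  region     = "GRanges",
  ladder     = "matrix",
  rungs      = "list",
  candidates = "list",
  criteria   = "list"
))

setValidity("RefinementTrace", function(object) {
  msg <- character()
  if (length(object@region) != 1L)
    msg <- c(msg, "region must be a single interval")
  if (ncol(object@ladder) != 2L)
    msg <- c(msg, "ladder must have two columns (window, step)")
  if (length(object@rungs) != nrow(object@ladder) ||
      length(object@candidates) != nrow(object@ladder))
    msg <- c(msg, "one rung table and one candidate per ladder row required")
  if (length(msg)) msg else TRUE
})

#' Genetic map built from F2 marker genotypes
#'
#' Ordered markers per linkage group with cumulative genetic positions
#' obtained from adjacent-pair recombination fractions through a map function
#' (Kosambi by default).
#'
#' @slot markers data.frame with columns `name`, `chrom`, `posBp`, `cm`
#'   (cumulative position, first marker of each group at 0) and `capped`
#'   (logical: the rf to the previous marker hit the 0.5 cap).
#' @slot mapFunction `"kosambi"` or `"haldane"`.
#'
#' @seealso [buildMap()], [mapTable()]
#' @exportClass GeneticMap
setClass("GeneticMap", representation(
  markers     = "data.frame",
  mapFunction = "character"
))

setValidity("GeneticMap", function(object) {
  msg <- character()
  need <- c("name", "chrom", "posBp", "cm")
  if (!all(need %in% names(object@markers)))
    msg <- c(msg, "markers needs columns name, chrom, posBp, cm")
  else {
    byc <- split(object@markers$cm, object@markers$chrom)
    if (any(vapply(byc, function(x) is.unsorted(x) || x[1L] != 0, logical(1))))
      msg <- c(msg, "cm positions must be non-decreasing and start at 0 per group")
  }
  if (!object@mapFunction %in% c("kosambi", "haldane"))
    msg <- c(msg, "mapFunction must be 'kosambi' or 'haldane'")
  if (length(msg)) msg else TRUE
})

#' Result of an F2 genome scan
#'
#' Per-position LOD, percent variance explained and additive/dominance
#' estimates on a regular cM grid, plus the scan method and (optionally) a
#' permutation LOD threshold.
#'
#' @slot table data.frame with columns `chrom`, `cm`, `lod`, `pve`, `add`,
#'   `dom`, `leftMarker`, `rightMarker`.
#' @slot method `"hk"` or `"icim"`.
#' @slot nInd number of individuals scanned.
#' @slot threshold permutation LOD threshold (NA when not computed).
#' @slot cofactors character vector of marker variables selected as cofactors
#'   (ICIM only; empty otherwise).
#'
#' @seealso [hkScan()], [icimScan()], [permutationThreshold()],
#'   [summarizeQtl()]
#' @exportClass QtlScan
setClass("QtlScan", representation(
  table     = "data.frame",
  method    = "character",
  nInd      = "numeric",
  threshold = "numeric",
  cofactors = "character"
))

setValidity("QtlScan", function(object) {
  msg <- character()
  need <- c("chrom", "cm", "lod", "pve", "add", "dom")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table needs columns chrom, cm, lod, pve, add, dom")
  else {
    if (any(object@table$lod < 0, na.rm = TRUE))
      msg <- c(msg, "LOD must be >= 0")
    if (any(object@table$pve < 0 | object@table$pve >= 100, na.rm = TRUE))
      msg <- c(msg, "PVE must lie in [0, 100)")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "BsaSimConfig", function(object) {
  cat("BsaSimConfig:", object@popType,
      if (object@popType != "F2") sprintf("(generation %d)", as.integer(object@generation)),
      "with", object@nIndividuals, "individuals\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%.1f Mb)", names(object@chromLengths),
                    object@chromLengths / 1e6), collapse = ", "), "\n")
  cat("  SNP spacing:", object@markerSpacing, "bp;  depth:",
      object@depthMean, "x;  rate:", object@cmPerMb, "cM/Mb\n")
  if (nrow(object@qtls)) {
    cat("  QTLs (", object@epistasis, " epistasis):\n", sep = "")
    for (i in seq_len(nrow(object@qtls)))
      cat(sprintf("    %s:%d  a=%.2f d=%.2f\n", object@qtls$chrom[i],
                  as.integer(object@qtls$pos[i]), object@qtls$a[i],
                  object@qtls$d[i]))
  } else cat("  no QTLs (null model)\n")
  cat("  phenotype scale ", object@phenotypeScale[1L], "..",
      object@phenotypeScale[2L], ", noise sd ", object@noiseSd, "\n", sep = "")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", object@popModel,
      if (object@popModel != "F2") sprintf("(generation %d)", as.integer(object@generation)),
      sprintf("bulks %d/%d", as.integer(object@nHigh), as.integer(object@nLow)), "\n")
  cat("  depths:", paste(range(object@depths), collapse = "-"),
      sprintf("(%d points), %d replicates each\n",
              length(object@depths), as.integer(object@nReps)))
  d <- object@depths[which.min(abs(object@depths - 30))]
  cat(sprintf("  e.g. q95(|delta|) at depth %d: %.3f\n", as.integer(d),
              nullQuantile(object, 0.95, d)))
})

setMethod("show", "RefinementTrace", function(object) {
  r <- object@region
  cat(sprintf("RefinementTrace over %s:%d-%d\n",
              as.character(GenomeInfoDb::seqnames(r)),
              GenomicRanges::start(r), GenomicRanges::end(r)))
  for (i in seq_len(nrow(object@ladder))) {
    cand <- object@candidates[[i]]
    cat(sprintf("  rung %d: W=%s S=%s, %d retained window(s)%s\n", i,
                format(object@ladder[i, 1L], big.mark = ","),
                format(object@ladder[i, 2L], big.mark = ","),
                length(object@rungs[[i]]),
                if (!is.null(cand) && length(cand))
                  sprintf(", candidate %d-%d",
                          GenomicRanges::start(cand), GenomicRanges::end(cand))
                else ""))
  }
})

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap (", object@mapFunction, "):\n", sep = "")
  for (ch in unique(object@markers$chrom)) {
    m <- object@markers[object@markers$chrom == ch, ]
    cat(sprintf("  %s: %d markers spanning %.1f cM\n", ch, nrow(m), max(m$cm)))
  }
})

setMethod("show", "QtlScan", function(object) {
  cat("QtlScan (", object@method, "): ", nrow(object@table),
      " positions, n = ", object@nInd, "\n", sep = "")
  pk <- object@table[which.max(object@table$lod), ]
  cat(sprintf("  peak: %s @ %.1f cM, LOD %.2f, PVE %.1f%%, Add %.2f, Dom %.2f\n",
              pk$chrom, pk$cm, pk$lod, pk$pve, pk$add, pk$dom))
  if (!is.na(object@threshold))
    cat(sprintf("  permutation threshold: LOD %.4f\n", object@threshold))
  if (length(object@cofactors))
    cat("  cofactors:", paste(object@cofactors, collapse = ", "), "\n")
})

## ---- simple accessors ---------------------------------------------------

#' Accessors for bsaqtl S4 objects
#'
#' Small read-only accessors: `chromLengths()` returns the named chromosome
#' length vector of a [BsaSimConfig-class]; `qtlEffects()` its QTL effect
#' table; `nullDepths()` the tabulated depth grid of a
#' [NullDistribution-class]; `rungStats()` the retained-window table of one
#' refinement rung; `candidateInterval()` the candidate of the final (or a
#' given) rung; `mapTable()` the marker table of a [GeneticMap-class];
#' `scanTable()` the per-position table of a [QtlScan-class] and
#' `lodThreshold()` its permutation threshold.
#'
#' @param object an object of the documented class.
#' @param i rung index (defaults to the final rung).
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
chromLengths <- function(object) object@chromLengths

#' @rdname accessors
#' @export
qtlEffects <- function(object) object@qtls

#' @rdname accessors
#' @export
nullDepths <- function(object) object@depths

#' @rdname accessors
#' @export
rungStats <- function(object, i = length(object@rungs)) object@rungs[[i]]

#' @rdname accessors
#' @export
candidateInterval <- function(object, i = length(object@candidates))
  object@candidates[[i]]

#' @rdname accessors
#' @export
mapTable <- function(object) object@markers

#' @rdname accessors
#' @export
scanTable <- function(object) object@table

#' @rdname accessors
#' @export
lodThreshold <- function(object) object@threshold
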