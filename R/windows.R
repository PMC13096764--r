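#' Build a fixed sliding-window grid
#'
#' Windows start at position 1 and advance by `step`; a window is emitted for
#' every start not exceeding the chromosome length, and the final windows are
#' clipped to the chromosome end.
#'
#' @param chromLengths named numeric, chromosome lengths in bp.
#' @param window window size W in bp (default 2 Mb).
#' @param step step size S in bp (default 100 kb); must satisfy
#'   `1 <= step <= window` (a larger step would leave SNPs uncovered).
#' @return `GRanges` of windows with `metadata()` recording the spec.
#' @examples
#' makeWindows(c(chrA = 300000), window = 100000, step = 50000)
#' @export
makeWindows <- function(chromLengths, window = 2e6, step = 1e5) {
  if (any(chromLengths <= 0)) stop("chromosome lengths must be > 0")
  if (step < 1 || step > window)
    stop("step must satisfy 1 <= step <= window")
  starts <- lapply(chromLengths, function(len) seq(1, len, by = step))
  n <- vapply(starts, length, integer(1))
  st <- unlist(starts, use.names = FALSE)
  len <- rep(chromLengths, n)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(names(chromLengths), n),
    ranges = IRanges::IRanges(start = st, end = pmin(st + window - 1, len)),
    seqlengths = setNames(chromLengths, names(chromLengths)))
  S4Vectors::metadata(gr) <- list(window = window, step = step, anchor = 1)
  gr
}

## core per-chromosome aggregation: records at positions pos (sorted) with
## per-record statistics, windows [starts, ends]; a SNP contributes to every
## window whose range covers it.
.windowIndexRange <- function(pos, starts, ends) {
  i1 <- findInterval(starts - 1L, pos) + 1L
  i2 <- findInterval(ends, pos)
  list(i1 = i1, i2 = i2, n = pmax(i2 - i1 + 1L, 0L))
}

.windowMeans <- function(x, i1, i2, n) {
  cs <- c(0, cumsum(x))
  out <- (cs[i2 + 1L] - cs[i1]) / n
  out[n == 0L] <- NA_real_
  out
}

#' Aggregate SNP statistics over sliding windows
#'
#' Computes, per window: the number of member SNPs, the number significant at
#' `sigLevel`, the mean delta-SNP index and the mean per-bulk SNP indices.
#' When a [NullDistribution-class] is supplied two extras are added: the
#' window-averaged per-SNP null `|delta|` quantile at each `bandLevels` (the
#' confidence band the window mean is compared against), and an empirical
#' window p-value from matched null resampling -- each member SNP draws
#' `windowReps` null deltas at its depth, the resampled window means are
#' formed, and `windowP = (1 + #\{|mean*| >= |mean|\}) / (windowReps + 1)`.
#'
#' @param records sorted `GRanges` from [computeIndices()] (with `pValue` if
#'   significance counts or resampling p-values are wanted).
#' @param windows `GRanges` from [makeWindows()].
#' @param null optional [NullDistribution-class].
#' @param sigLevel per-SNP significance level used for `nSig` and the
#'   `significant` flag.
#' @param windowReps null resamples per window p-value.
#' @param bandLevels quantile levels of the averaged confidence band.
#' @param seed optional seed for the resampling draws.
#' @return the window `GRanges` with statistic columns; windows without SNPs
#'   carry NA means and are never flagged significant.
#' @export
aggregateWindows <- function(records, windows, null = NULL, sigLevel = 0.05,
                             windowReps = 499L, bandLevels = c(0.95, 0.99),
                             seed = NULL) {
  stopifnot(is(records, "GRanges"), is(windows, "GRanges"))
  mc <- S4Vectors::mcols(records)
  if (is.null(mc$delta)) stop("records need a delta column (computeIndices)")
  ord <- GenomicRanges::order(records)
  if (is.unsorted(ord)) stop("records must be sorted by (chrom, pos)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  chs <- as.character(GenomeInfoDb::seqnames(records))
  pos <- GenomicRanges::start(records)
  wch <- as.character(GenomeInfoDb::seqnames(windows))
  hasP <- !is.null(mc$pValue)
  if (!is.null(null)) {
    dH <- mc$highRef + mc$highAlt
    dL <- mc$lowRef + mc$lowAlt
    depth <- 2 / (1 / dH + 1 / dL)
    bandQ <- lapply(bandLevels, function(lv) nullQuantile(null, lv, depth))
    nearestDepth <- vapply(depth, function(d)
      which.min(abs(null@depths - d)), integer(1))
  }
  nWin <- length(windows)
  nSnps <- integer(nWin); nSig <- rep(NA_integer_, nWin)
  meanDelta <- meanIH <- meanIL <- rep(NA_real_, nWin)
  winP <- rep(NA_real_, nWin)
  bands <- replicate(length(bandLevels), rep(NA_real_, nWin),
                     simplify = FALSE)
  for (ch in unique(wch)) {
    wi <- which(wch == ch)
    ri <- which(chs == ch)
    ir <- .windowIndexRange(pos[ri],
                            GenomicRanges::start(windows)[wi],
                            GenomicRanges::end(windows)[wi])
    nSnps[wi] <- ir$n
    meanDelta[wi] <- .windowMeans(mc$delta[ri], ir$i1, ir$i2, ir$n)
    meanIH[wi] <- .windowMeans(mc$snpIndexHigh[ri], ir$i1, ir$i2, ir$n)
    meanIL[wi] <- .windowMeans(mc$snpIndexLow[ri], ir$i1, ir$i2, ir$n)
    if (hasP)
      nSig[wi] <- as.integer(round(.windowMeans(
        as.numeric(mc$pValue[ri] < sigLevel), ir$i1, ir$i2, ir$n) * ir$n))
    if (!is.null(null) && length(ri)) {
      for (b in seq_along(bandLevels))
        bands[[b]][wi] <- .windowMeans(bandQ[[b]][ri], ir$i1, ir$i2, ir$n)
      ## matched null resampling of window means via per-SNP draws + prefix
      ## sums down each resample column
      B <- as.integer(windowReps)
      D <- matrix(0, length(ri), B)
      nd <- nearestDepth[ri]
      for (k in unique(nd)) {
        sel <- which(nd == k)
        pool <- null@samples[[k]]
        D[sel, ] <- pool[sample.int(length(pool), length(sel) * B,
                                    replace = TRUE)]
      }
      cs <- rbind(0, apply(D, 2, cumsum))
      ok <- which(ir$n > 0L)
      if (length(ok)) {
        M <- (cs[ir$i2[ok] + 1L, , drop = FALSE] -
              cs[ir$i1[ok], , drop = FALSE]) / ir$n[ok]
        cnt <- rowSums(abs(M) >= abs(meanDelta[wi][ok]) - 1e-12)
        winP[wi[ok]] <- (1 + cnt) / (B + 1)
      }
    }
  }
  out <- windows
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    nSnps = nSnps, nSig = nSig, meanDelta = meanDelta,
    meanIndexHigh = meanIH, meanIndexLow = meanIL)
  for (b in seq_along(bandLevels))
    S4Vectors::mcols(out)[[sprintf("band%02d", round(bandLevels[b] * 100))]] <-
      bands[[b]]
  S4Vectors::mcols(out)$windowP <- winP
  bandCol <- sprintf("band%02d", round((1 - sigLevel) * 100))
  sig <- nSnps > 0L & !is.na(winP) & winP < sigLevel
  if (bandCol %in% names(S4Vectors::mcols(out)))
    sig <- sig & !is.na(meanDelta) &
      abs(meanDelta) >= S4Vectors::mcols(out)[[bandCol]]
  S4Vectors::mcols(out)$significant <- sig
  S4Vectors::metadata(out) <- S4Vectors::metadata(windows)
  out
}

#' Call QTL intervals from window statistics
#'
#' A window qualifies at `alpha` when its resampling p-value is below `alpha`
#' and (by default) its `|mean delta|` also exceeds the window-averaged
#' per-SNP null quantile band at level `1 - alpha` -- the "clearly above the
#' surrounding background" condition.  Qualifying windows of consistent delta
#' sign that sit on consecutive steps of the window grid are merged into one
#' interval (a single missing step splits); the interval runs from the first
#' qualifying window start to `last qualifying window start + step - 1`
#' (clipped at the chromosome end), so boundaries lie on the step grid and
#' intervals from distinct runs never overlap.
#'
#' @param windowStats `GRanges` from [aggregateWindows()] (with a null).
#' @param alpha interval-calling significance level (0.05 or 0.01 with the
#'   default band levels).
#' @param useBand require the averaged-band condition as well as the window
#'   p-value (recommended; `FALSE` uses the resampling p alone).
#' @return `GRanges` of intervals with columns `sizeMb`, `level`,
#'   `alleleEffect` (`"donor"` when the trait bulk is enriched for the donor
#'   allele), `peakStart`, `peakEnd`, `peakDelta`.  Empty when nothing
#'   qualifies.
#' @export
callIntervals <- function(windowStats, alpha = 0.05, useBand = TRUE) {
  stopifnot(is(windowStats, "GRanges"))
  mc <- S4Vectors::mcols(windowStats)
  if (is.null(mc$windowP))
    stop("windowStats lacks windowP; aggregate with a NullDistribution")
  spec <- S4Vectors::metadata(windowStats)
  step <- spec$step
  if (is.null(step)) stop("windowStats lacks window-spec metadata")
  bandCol <- sprintf("band%02d", round((1 - alpha) * 100))
  if (useBand && !bandCol %in% names(mc))
    stop("no ", bandCol, " column; re-aggregate with bandLevels including ",
         1 - alpha)
  elig <- mc$nSnps > 0L & !is.na(mc$windowP) & mc$windowP < alpha
  if (useBand)
    elig <- elig & !is.na(mc$meanDelta) &
      abs(mc$meanDelta) >= mc[[bandCol]]
  ## peak-window qualification at the stricter 0.01 level, when available
  elig01 <- mc$nSnps > 0L & !is.na(mc$windowP) & mc$windowP < 0.01
  if ("band99" %in% names(mc))
    elig01 <- elig01 & !is.na(mc$meanDelta) &
      abs(mc$meanDelta) >= mc$band99
  res <- GenomicRanges::GRanges(seqlengths = GenomeInfoDb::seqlengths(windowStats))
  S4Vectors::mcols(res) <- S4Vectors::DataFrame(
    sizeMb = numeric(0), level = character(0), alleleEffect = character(0),
    peakStart = integer(0), peakEnd = integer(0), peakDelta = numeric(0))
  if (!any(elig)) return(res)
  wch <- as.character(GenomeInfoDb::seqnames(windowStats))
  st <- GenomicRanges::start(windowStats)
  en <- GenomicRanges::end(windowStats)
  pieces <- list()
  for (ch in unique(wch[elig])) {
    sel <- which(elig & wch == ch)
    k <- (st[sel] - spec$anchor) / step
    sgn <- sign(mc$meanDelta[sel])
    runBreak <- c(TRUE, diff(k) > 1 | diff(sgn) != 0)
    runId <- cumsum(runBreak)
    for (r in unique(runId)) {
      ix <- sel[runId == r]
      peak <- ix[which.max(abs(mc$meanDelta[ix]))]
      lvl <- if (alpha <= 0.01 || isTRUE(elig01[peak])) "<0.01"
             else sprintf("<%.2g", alpha)
      ivStart <- max(1, min(st[ix]))
      chLen <- GenomeInfoDb::seqlengths(windowStats)[ch]
      ivEnd <- max(st[ix]) + step - 1
      if (!is.na(chLen)) ivEnd <- min(ivEnd, chLen)
      iv <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(start = ivStart, end = ivEnd),
        seqlengths = GenomeInfoDb::seqlengths(windowStats))
      S4Vectors::mcols(iv) <- S4Vectors::DataFrame(
        sizeMb = sizeInMb(ivStart, ivEnd),
        level = lvl,
        alleleEffect = if (mc$meanDelta[peak] > 0) "donor" else "recurrent",
        peakStart = st[peak], peakEnd = en[peak],
        peakDelta = mc$meanDelta[peak])
      pieces[[length(pieces) + 1L]] <- iv
    }
  }
  out <- sort(do.call(c, pieces))
  S4Vectors::metadata(out) <- spec
  out
}
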