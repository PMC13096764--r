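#' Ladder of progressively narrowing window sizes
#'
#' The default ladder starts at the coarse genome-scan parameters (2 Mb
#' windows, 100 kb steps) and ends at the high-resolution 10 kb window with
#' 5 kb step; the intermediate rungs form a roughly geometric descent.
#'
#' @param windows,steps parallel numeric vectors (bp); `windows` must be
#'   strictly decreasing and `steps[i] <= windows[i]`.
#' @return two-column matrix (`window`, `step`).
#' @examples
#' refineLadder()
#' @export
refineLadder <- function(windows = c(2e6, 5e5, 1e5, 5e4, 1e4),
                         steps   = c(1e5, 2.5e4, 1e4, 5e3, 5e3)) {
  if (length(windows) != length(steps))
    stop("windows and steps must have equal length")
  if (any(diff(windows) >= 0))
    stop("window sizes must be strictly decreasing")
  if (any(steps > windows) || any(steps < 1))
    stop("each step must satisfy 1 <= step <= window")
  matrix(c(windows, steps), ncol = 2L,
         dimnames = list(NULL, c("window", "step")))
}

#' Criteria for extracting a candidate interval
#'
#' @param tau strength quantile in (0, 1): windows whose mean delta-SNP index
#'   reaches the `tau`-quantile of all retained windows count as "strong".
#' @param gap tolerated gap (in grid steps) between strong windows within one
#'   run.
#' @return list with elements `tau` and `gap`.
#' @export
candidateCriteria <- function(tau = 0.95, gap = 1L) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (gap < 0) stop("gap must be >= 0")
  list(tau = tau, gap = as.integer(gap))
}

#' Filter SNPs by per-SNP significance
#'
#' Keeps records with `pValue < alpha` (order preserved); the refinement
#' procedure runs on this significance-filtered set to increase resolution
#' and suppress background noise.
#'
#' @param records `GRanges` with a `pValue` column ([assignPvalues()]).
#' @param alpha per-SNP threshold (default 0.01).
#' @return the filtered `GRanges` (possibly empty, with a warning).
#' @export
selectSignificant <- function(records, alpha = 0.01) {
  stopifnot(is(records, "GRanges"))
  p <- S4Vectors::mcols(records)$pValue
  if (is.null(p)) stop("records lack pValue; run assignPvalues() first")
  out <- records[p < alpha]
  if (!length(out))
    warning("no SNP passes p < ", alpha, call. = FALSE)
  out
}

## parse "chr:start-end" into a GRanges when needed
.asRegion <- function(region) {
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1L]]
    if (length(m) != 4L) stop("cannot parse region string: ", region)
    region <- GenomicRanges::GRanges(
      m[2L], IRanges::IRanges(as.numeric(gsub(",", "", m[3L])),
                              as.numeric(gsub(",", "", m[4L]))))
  }
  if (!is(region, "GRanges") || length(region) != 1L)
    stop("region must be a single interval")
  region
}

#' Progressive sliding-window refinement of a QTL region
#'
#' For each rung of the ladder, windows are built over the region (anchored
#' at the region start, clipped at the region end), the mean delta-SNP index
#' and SNP counts are aggregated as in the coarse scan, and windows containing
#' at least one significant SNP are retained.  A candidate interval is
#' extracted from every non-empty rung with [extractCandidate()]; rungs whose
#' window exceeds the region size are skipped with a warning.
#'
#' @param records `GRanges`, normally pre-filtered with [selectSignificant()]
#'   (if a `pValue` column is present, significance is re-counted at `alpha`;
#'   otherwise all member SNPs count as significant).
#' @param region a length-1 `GRanges` or a `"chr:start-end"` string, normally
#'   an interval from [callIntervals()].
#' @param ladder matrix from [refineLadder()].
#' @param criteria list from [candidateCriteria()].
#' @param alpha per-SNP significance level used for the retention count.
#' @return a [RefinementTrace-class].
#' @export
refineRegion <- function(records, region, ladder = refineLadder(),
                         criteria = candidateCriteria(), alpha = 0.01) {
  stopifnot(is(records, "GRanges"))
  region <- .asRegion(region)
  ch <- as.character(GenomeInfoDb::seqnames(region))
  rs <- GenomicRanges::start(region); re <- GenomicRanges::end(region)
  mc0 <- S4Vectors::mcols(records)
  if (is.null(mc0$delta)) stop("records need a delta column (computeIndices)")
  keep <- as.character(GenomeInfoDb::seqnames(records)) == ch &
    GenomicRanges::start(records) >= rs & GenomicRanges::start(records) <= re
  records <- records[keep]
  pos <- GenomicRanges::start(records)
  mc <- S4Vectors::mcols(records)
  sig <- if (!is.null(mc$pValue)) as.numeric(mc$pValue < alpha)
         else rep(1, length(records))
  rungs <- vector("list", nrow(ladder))
  candidates <- vector("list", nrow(ladder))
  for (i in seq_len(nrow(ladder))) {
    W <- ladder[i, "window"]; S <- ladder[i, "step"]
    if (W > re - rs + 1) {
      warning(sprintf("rung %d skipped: window %g bp exceeds region size", i, W),
              call. = FALSE)
      rungs[[i]] <- GenomicRanges::GRanges()
      next
    }
    starts <- seq(rs, re, by = S)
    ends <- pmin(starts + W - 1, re)
    ir <- .windowIndexRange(pos, starts, ends)
    nSig <- as.integer(round(.windowMeans(sig, ir$i1, ir$i2, ir$n) * ir$n))
    retained <- which(!is.na(nSig) & nSig >= 1L)
    gr <- GenomicRanges::GRanges(
      rep(ch, length(retained)),
      IRanges::IRanges(start = starts[retained], end = ends[retained]))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      nSnps = ir$n[retained], nSig = nSig[retained],
      meanDelta = .windowMeans(mc$delta, ir$i1, ir$i2, ir$n)[retained])
    S4Vectors::metadata(gr) <- list(window = W, step = S, anchor = rs)
    rungs[[i]] <- gr
    if (length(gr))
      candidates[[i]] <- extractCandidate(gr, criteria)
  }
  new("RefinementTrace", region = region, ladder = ladder, rungs = rungs,
      candidates = candidates, criteria = criteria)
}

#' Extract the candidate interval from one rung of retained windows
#'
#' "Strong" windows are those whose mean delta-SNP index reaches the
#' `tau`-quantile of the retained windows.  The candidate is the longest run
#' of strong windows on the step grid, tolerating gaps of at most `gap`
#' steps; ties go to the run with the higher mean of window means, then to
#' the leftmost run.  The interval spans from the first strong window start to
#' the last strong window end.
#'
#' @param rungStats retained-window `GRanges` from one rung of
#'   [refineRegion()] (needs the window-spec metadata).
#' @param criteria list from [candidateCriteria()].
#' @return a length-1 `GRanges` with columns `nWindows` and `meanDelta`.
#' @export
extractCandidate <- function(rungStats, criteria = candidateCriteria()) {
  stopifnot(is(rungStats, "GRanges"))
  if (!length(rungStats)) stop("empty retained window set")
  spec <- S4Vectors::metadata(rungStats)
  if (is.null(spec$step)) stop("rungStats lacks window-spec metadata")
  md <- S4Vectors::mcols(rungStats)$meanDelta
  thr <- quantile(md, criteria$tau, names = FALSE)
  strong <- which(md >= thr)
  k <- (GenomicRanges::start(rungStats)[strong] - spec$anchor) / spec$step
  runId <- cumsum(c(TRUE, diff(k) > criteria$gap + 1))
  best <- 0L; bestLen <- -1L; bestMean <- -Inf
  for (r in unique(runId)) {
    ix <- strong[runId == r]
    len <- length(ix); mn <- mean(md[ix])
    if (len > bestLen || (len == bestLen && mn > bestMean)) {
      best <- r; bestLen <- len; bestMean <- mn
    }
  }
  ix <- strong[runId == best]
  out <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(rungStats))[1L],
    IRanges::IRanges(start = GenomicRanges::start(rungStats)[ix[1L]],
                     end = GenomicRanges::end(rungStats)[ix[length(ix)]]))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    nWindows = bestLen, meanDelta = bestMean)
  out
}
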