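#' Per-chromosome SNP-index and delta-SNP-index tracks
#'
#' Plots, for each chromosome, the sliding-window mean SNP index of both
#' bulks and the mean delta-SNP index with its null confidence band (when the
#' windows were aggregated with a null distribution).
#'
#' @param windowStats `GRanges` from [aggregateWindows()].
#' @param band which band column to draw (`"band95"` or `"band99"`),
#'   ignored when absent.
#' @param intervals optional `GRanges` of called intervals to shade.
#' @return invisibly, `NULL`; called for its side effect.
#' @importFrom graphics abline legend lines par plot rect
#' @importFrom grDevices adjustcolor
#' @export
plotDeltaTrack <- function(windowStats, band = "band95", intervals = NULL) {
  mc <- S4Vectors::mcols(windowStats)
  chs <- as.character(GenomeInfoDb::seqnames(windowStats))
  mid <- (GenomicRanges::start(windowStats) +
          GenomicRanges::end(windowStats)) / 2
  chrs <- unique(chs)
  op <- par(mfrow = c(length(chrs), 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (ch in chrs) {
    i <- chs == ch & !is.na(mc$meanDelta)
    plot(mid[i] / 1e6, mc$meanDelta[i], type = "l", col = "red",
         ylim = c(-1, 1), xlab = sprintf("%s position (Mb)", ch),
         ylab = "index", main = ch)
    lines(mid[i] / 1e6, mc$meanIndexHigh[i], col = "blue")
    lines(mid[i] / 1e6, mc$meanIndexLow[i], col = "black")
    if (band %in% names(mc)) {
      lines(mid[i] / 1e6, mc[[band]][i], lty = 2, col = "grey40")
      lines(mid[i] / 1e6, -mc[[band]][i], lty = 2, col = "grey40")
    }
    abline(h = 0, col = "grey70")
    if (!is.null(intervals)) {
      ii <- as.character(GenomeInfoDb::seqnames(intervals)) == ch
      if (any(ii))
        rect(GenomicRanges::start(intervals)[ii] / 1e6, -1,
             GenomicRanges::end(intervals)[ii] / 1e6, 1,
             col = adjustcolor("red", 0.1), border = NA)
    }
    if (ch == chrs[1L])
      legend("topright", bty = "n", lty = c(1, 1, 1, 2),
             col = c("blue", "black", "red", "grey40"),
             legend = c("high bulk", "low bulk", "delta", "null band"))
  }
  invisible(NULL)
}

#' Panels of the window-refinement trace
#'
#' One panel per ladder rung: retained-window mean delta-SNP index along the
#' region, with the rung's candidate interval shaded.
#'
#' @param trace a [RefinementTrace-class].
#' @return invisibly, `NULL`; called for its side effect.
#' @export
plotRefinement <- function(trace) {
  stopifnot(is(trace, "RefinementTrace"))
  nR <- length(trace@rungs)
  op <- par(mfrow = c(nR, 1), mar = c(3, 4, 1.5, 1))
  on.exit(par(op))
  rs <- GenomicRanges::start(trace@region) / 1e6
  re <- GenomicRanges::end(trace@region) / 1e6
  for (i in seq_len(nR)) {
    gr <- trace@rungs[[i]]
    lab <- sprintf("W=%s, S=%s",
                   format(trace@ladder[i, 1L], big.mark = ","),
                   format(trace@ladder[i, 2L], big.mark = ","))
    if (!length(gr)) {
      plot(NA, xlim = c(rs, re), ylim = c(0, 1), xlab = "", ylab = "mean delta",
           main = paste(lab, "(no retained windows)"))
      next
    }
    mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2e6
    plot(mid, S4Vectors::mcols(gr)$meanDelta, pch = 16, cex = 0.4,
         xlim = c(rs, re), xlab = "", ylab = "mean delta", main = lab)
    cand <- trace@candidates[[i]]
    if (!is.null(cand) && length(cand))
      rect(GenomicRanges::start(cand) / 1e6, par("usr")[3L],
           GenomicRanges::end(cand) / 1e6, par("usr")[4L],
           col = adjustcolor("red", 0.15), border = NA)
  }
  invisible(NULL)
}
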