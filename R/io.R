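#' Interval size helpers
#'
#' `sizeInMb()` reports an interval's size in Mb as `(end - start + 1) / 1e6`
#' rounded to one decimal (the convention of QTL summary tables);
#' `sizeInKb()` reports `(end - start) / 1000` truncated to an integer (the
#' convention used when quoting marker-flanked spans in kb).
#'
#' @param start,end 1-based inclusive interval coordinates.
#' @return numeric size.
#' @examples
#' sizeInMb(1, 7700000)          # 7.7
#' sizeInKb(3184505, 3603180)    # 418
#' @export
sizeInMb <- function(start, end) round((end - start + 1) / 1e6, 1)

#' @rdname sizeInMb
#' @export
sizeInKb <- function(start, end) floor((end - start) / 1000)

.snpCols <- c("CHROM", "POS", "REF", "ALT",
              "HIGH_REF", "HIGH_ALT", "LOW_REF", "LOW_ALT")
.optCols <- c(SNP_INDEX1 = "snpIndexHigh", SNP_INDEX2 = "snpIndexLow",
              DELTA = "delta", PVAL = "pValue")

#' Read a two-bulk SNP allele-depth table
#'
#' The file is tab-separated with header columns `CHROM`, `POS` (1-based),
#' `REF`, `ALT` (the donor allele), `HIGH_REF`, `HIGH_ALT`, `LOW_REF`,
#' `LOW_ALT`, optionally followed by precomputed `SNP_INDEX1`, `SNP_INDEX2`,
#' `DELTA`, `PVAL` columns; lines starting with `#` are comments.  Positions
#' must be strictly increasing within a chromosome and counts non-negative
#' integers; malformed rows are rejected with their line numbers.
#'
#' @param path file path.
#' @return sorted `GRanges` with metadata columns `REF`, `ALT`, `highRef`,
#'   `highAlt`, `lowRef`, `lowAlt` (+ any optional columns present).
#' @seealso [writeSnpTable()]
#' @export
readSnpTable <- function(path) {
  raw <- readLines(path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lineNo <- which(keep)
  if (!length(lineNo)) stop("no data rows in ", path)
  df <- read.table(text = raw[keep], header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  lineNo <- lineNo[-1L]                      # data lines (header removed)
  miss <- setdiff(.snpCols, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  cntCols <- c("POS", "HIGH_REF", "HIGH_ALT", "LOW_REF", "LOW_ALT")
  for (cc in cntCols) {
    v <- df[[cc]]
    bad <- !is.finite(v) | v != round(v) | (cc != "POS" & v < 0) |
      (cc == "POS" & v < 1)
    if (any(bad))
      stop("non-integer or negative ", cc, " at line(s) ",
           paste(head(lineNo[bad], 5L), collapse = ", "))
  }
  for (ch in unique(df$CHROM)) {
    p <- df$POS[df$CHROM == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      bad <- which(df$CHROM == ch)[which(diff(p) <= 0) + 1L]
      stop("POS not strictly increasing within ", ch, " at line(s) ",
           paste(head(lineNo[bad], 5L), collapse = ", "))
    }
  }
  gr <- GenomicRanges::GRanges(df$CHROM,
                               IRanges::IRanges(df$POS, width = 1L))
  mc <- S4Vectors::DataFrame(
    REF = df$REF, ALT = df$ALT,
    highRef = as.integer(df$HIGH_REF), highAlt = as.integer(df$HIGH_ALT),
    lowRef = as.integer(df$LOW_REF), lowAlt = as.integer(df$LOW_ALT))
  for (oc in names(.optCols))
    if (oc %in% names(df)) mc[[.optCols[[oc]]]] <- df[[oc]]
  S4Vectors::mcols(gr) <- mc
  sort(gr)
}

#' Write a two-bulk SNP allele-depth table
#'
#' @param records `GRanges` in the layout produced by [readSnpTable()] /
#'   [sampleSnpTable()]; computed index/p-value columns, when present, are
#'   written as `SNP_INDEX1`, `SNP_INDEX2`, `DELTA`, `PVAL`.
#' @param path output path (tab-separated, 1-based positions).
#' @return `path`, invisibly.
#' @export
writeSnpTable <- function(records, path) {
  stopifnot(is(records, "GRanges"))
  mc <- S4Vectors::mcols(records)
  df <- data.frame(
    CHROM = as.character(GenomeInfoDb::seqnames(records)),
    POS = GenomicRanges::start(records),
    REF = mc$REF, ALT = mc$ALT,
    HIGH_REF = mc$highRef, HIGH_ALT = mc$highAlt,
    LOW_REF = mc$lowRef, LOW_ALT = mc$lowAlt,
    check.names = FALSE)
  for (oc in names(.optCols))
    if (!is.null(mc[[.optCols[[oc]]]])) df[[oc]] <- mc[[.optCols[[oc]]]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a pair of bulk VCFs as a SNP table
#'
#' Sites biallelic in both files and carrying allelic-depth (`AD`) genotype
#' annotations are intersected; counts are polarized so that `ALT` is the
#' donor allele, either via an explicit donor-allele table or under the
#' convention that the files are donor-vs-reference calls (ALT = donor).
#' Multi-allelic sites are dropped and counted.  Requires the
#' VariantAnnotation package.
#'
#' @param vcfHigh,vcfLow paths to the high-bulk and low-bulk VCF files.
#' @param donorAlleles optional data.frame (`chrom`, `pos`, `allele`) giving
#'   the donor base at each site; sites whose donor base matches neither REF
#'   nor ALT are dropped.
#' @return sorted `GRanges` in the [readSnpTable()] layout.
#' @export
importVcfPair <- function(vcfHigh, vcfLow, donorAlleles = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("importVcfPair requires the VariantAnnotation package")
  readOne <- function(path) {
    v <- VariantAnnotation::readVcf(path, genome = "unknown")
    if (!"AD" %in% rownames(VariantAnnotation::geno(
          VariantAnnotation::header(v))))
      stop("missing allelic-depth (AD) field in ", path)
    alt <- VariantAnnotation::alt(v)
    rr <- SummarizedExperiment::rowRanges(v)
    list(chrom = as.character(GenomeInfoDb::seqnames(rr)),
         pos = GenomicRanges::start(rr),
         ref = as.character(VariantAnnotation::ref(v)),
         alt1 = vapply(alt, function(a) as.character(a)[1L], character(1)),
         multi = S4Vectors::elementNROWS(alt) != 1L,
         ad = VariantAnnotation::geno(v)$AD)
  }
  hi <- readOne(vcfHigh); lo <- readOne(vcfLow)
  kH <- paste0(hi$chrom, ":", hi$pos)
  kL <- paste0(lo$chrom, ":", lo$pos)
  nMulti <- sum(hi$multi) + sum(lo$multi)
  if (nMulti)
    message(nMulti, " multi-allelic site(s) dropped")
  okH <- !hi$multi & kH %in% kL[!lo$multi]
  idxH <- which(okH)
  idxL <- match(kH[okH], kL)
  if (!length(idxH)) {
    warning("no shared biallelic sites between the two files", call. = FALSE)
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      REF = character(0), ALT = character(0),
      highRef = integer(0), highAlt = integer(0),
      lowRef = integer(0), lowAlt = integer(0))
    return(gr)
  }
  ref <- hi$ref[idxH]
  alt <- hi$alt1[idxH]
  adH <- do.call(rbind, hi$ad[idxH, 1L])
  adL <- do.call(rbind, lo$ad[idxL, 1L])
  chrom <- hi$chrom[idxH]
  pos <- hi$pos[idxH]
  highRef <- adH[, 1L]; highAlt <- adH[, 2L]
  lowRef <- adL[, 1L]; lowAlt <- adL[, 2L]
  keep <- rep(TRUE, length(idxH))
  if (!is.null(donorAlleles)) {
    dKey <- paste0(donorAlleles$chrom, ":", donorAlleles$pos)
    m <- match(paste0(chrom, ":", pos), dKey)
    donor <- donorAlleles$allele[m]
    isAlt <- !is.na(donor) & donor == alt
    isRef <- !is.na(donor) & donor == ref
    keep <- isAlt | isRef
    ## flip counts where the donor allele is the reference base
    flip <- which(isRef)
    if (length(flip)) {
      tmpH <- highRef[flip]; highRef[flip] <- highAlt[flip]; highAlt[flip] <- tmpH
      tmpL <- lowRef[flip]; lowRef[flip] <- lowAlt[flip]; lowAlt[flip] <- tmpL
      tmpB <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmpB
    }
    if (any(!keep))
      message(sum(!keep), " site(s) dropped: donor allele matches neither ",
              "REF nor ALT")
  }
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(pos[keep], width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    REF = ref[keep], ALT = alt[keep],
    highRef = as.integer(highRef[keep]), highAlt = as.integer(highAlt[keep]),
    lowRef = as.integer(lowRef[keep]), lowAlt = as.integer(lowAlt[keep]))
  sort(gr)
}

#' Write QTL intervals as TSV or BED
#'
#' The TSV report is 1-based inclusive with QTL-table-style columns
#' (`Chromosome`, `Start`, `End`, `SizeMb`, `pLevel`, `AlleleEffect`); BED
#' output is standard 0-based half-open.
#'
#' @param intervals `GRanges` from [callIntervals()] (columns `sizeMb`,
#'   `level`, `alleleEffect` used when present).
#' @param path output path.
#' @param format `"TSV"` or `"BED"`.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(intervals, path, format = c("TSV", "BED")) {
  format <- match.arg(format)
  stopifnot(is(intervals, "GRanges"))
  mc <- S4Vectors::mcols(intervals)
  ch <- as.character(GenomeInfoDb::seqnames(intervals))
  st <- GenomicRanges::start(intervals)
  en <- GenomicRanges::end(intervals)
  lvl <- if (!is.null(mc$level)) mc$level else rep(NA_character_, length(ch))
  eff <- if (!is.null(mc$alleleEffect)) mc$alleleEffect
         else rep(NA_character_, length(ch))
  if (format == "TSV") {
    df <- data.frame(Chromosome = ch, Start = st, End = en,
                     SizeMb = sizeInMb(st, en), pLevel = lvl,
                     AlleleEffect = eff, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    name <- paste0(ch, ":", st, "-", en,
                   ifelse(is.na(lvl), "", paste0("|", lvl)))
    df <- data.frame(chrom = ch, start = st - 1L, end = en, name = name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Converts 0-based half-open BED records to 1-based inclusive `GRanges`, the
#' inverse of `writeIntervals(..., format = "BED")`.
#'
#' @param path BED file path.
#' @return `GRanges`.
#' @export
readIntervalsBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df[[1L]],
                         IRanges::IRanges(df[[2L]] + 1L, df[[3L]]))
}

#' Read an F2 marker genotype matrix
#'
#' CSV with individuals in rows and markers in columns (first column =
#' individual id), entries coded `A`/`H`/`B` and `-` (or empty) for missing.
#'
#' @param path CSV path.
#' @return character matrix with individual row names and marker column
#'   names; missing entries are `NA`.
#' @export
readGenotypes <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = 1L)
  m <- toupper(as.matrix(df))
  m[!m %in% c("A", "H", "B")] <- NA_character_
  bad <- !is.na(as.matrix(df)) & as.matrix(df) != "" &
    !toupper(as.matrix(df)) %in% c("A", "H", "B", "-")
  if (any(bad))
    stop("invalid genotype code(s): ",
         paste(unique(as.matrix(df)[bad]), collapse = ", "))
  m
}

#' Read a phenotype score vector
#'
#' CSV with two columns: individual id and numeric score.
#'
#' @param path CSV path.
#' @return named numeric vector.
#' @export
readPhenotypes <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Read / write a run configuration
#'
#' A run configuration is a named list (population model, bulk sizes,
#' filters, window spec, refinement ladder, linkage settings, seeds, output
#' directory ...) serialized as YAML; the round trip is lossless for scalar
#' and vector fields.
#'
#' @param path YAML file path.
#' @param config named list.
#' @return `readRunConfig()` the list; `writeRunConfig()` the path,
#'   invisibly.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
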