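#' Linkage-scan configuration
#'
#' @param step scan grid spacing in cM.
#' @param pin entry/stay p-value for stepwise cofactor selection (ICIM).
#' @param nPerm permutations for the LOD threshold.
#' @param alpha genome-wide significance level of the threshold.
#' @param seed RNG seed for permutations.
#' @return a list of settings.
#' @export
linkageConfig <- function(step = 1, pin = 0.001, nPerm = 1000L,
                          alpha = 0.05, seed = 1L) {
  if (step <= 0) stop("step must be > 0")
  if (pin <= 0 || pin >= 1) stop("PIN must lie in (0, 1)")
  list(step = step, pin = pin, nPerm = as.integer(nPerm), alpha = alpha,
       seed = as.integer(seed))
}

## A/H/B(/missing) codes -> donor dose 0/1/2/NA
.codesToDose <- function(m) {
  d <- match(toupper(as.matrix(m)), c("A", "H", "B")) - 1L
  matrix(d, nrow = nrow(m), dimnames = dimnames(m))
}

## F2 genotype-dose transition matrix across a recombination fraction r
.f2Trans <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3L, 3L, byrow = TRUE)
}

#' EM estimate of the recombination fraction between two F2 markers
#'
#' Maximum-likelihood estimation over the standard phase-known (coupling)
#' two-locus F2 genotype-class likelihood.  Each individual is two independent
#' gametes; the EM E-step distributes the ambiguous double-heterozygote class
#' over its parental/recombinant gamete configurations, and the M-step sets r
#' to the expected recombinant-gamete fraction.
#'
#' @param gi,gj genotype vectors for the two markers, coded as donor doses
#'   0/1/2 or as characters A/H/B; missing entries (`NA` or `"-"`) are dropped
#'   pairwise.
#' @param tol,maxit EM convergence controls.
#' @return the estimated recombination fraction in `[0, 0.5]`.
#' @examples
#' estimateRF(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2))
#' @export
estimateRF <- function(gi, gj, tol = 1e-10, maxit = 200L) {
  if (is.character(gi)) gi <- .codesToDose(matrix(gi, ncol = 1))[, 1L]
  if (is.character(gj)) gj <- .codesToDose(matrix(gj, ncol = 1))[, 1L]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 10L) stop("fewer than 10 jointly non-missing individuals")
  cls <- gi[ok] * 3L + gj[ok]             # 0..8
  counts <- tabulate(cls + 1L, nbins = 9L)
  ## gamete haplotypes: (A,A), (B,B), (A,B), (B,A); rec = recombinant flag
  al1 <- c(0L, 1L, 0L, 1L); al2 <- c(0L, 1L, 1L, 0L)
  rec <- c(0L, 0L, 1L, 1L)
  u <- rep(1:4, each = 4L); v <- rep(1:4, times = 4L)
  comboCls <- (al1[u] + al1[v]) * 3L + (al2[u] + al2[v])
  comboRec <- rec[u] + rec[v]
  n <- sum(counts)
  r <- 0.25
  for (it in seq_len(maxit)) {
    pg <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
    w <- pg[u] * pg[v]
    num <- tapply(w * comboRec, comboCls, sum)
    den <- tapply(w, comboCls, sum)
    eRec <- num / den                     # expected rec gametes per class
    rNew <- sum(counts * eRec[as.character(0:8)], na.rm = TRUE) / (2 * n)
    if (abs(rNew - r) < tol) { r <- rNew; break }
    r <- rNew
  }
  min(max(r, 0), 0.5)
}

#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction to map distance,
#' `d = 25 ln((1 + 2r) / (1 - 2r))` cM, allowing moderate crossover
#' interference; `kosambiInv()` is the closed-form inverse
#' `r = tanh(d / 50) / 2`.  Fractions at or above 0.5 are capped at 0.4999
#' with a warning before transformation.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return distances in cM, or fractions.
#' @examples
#' kosambi(0.25)            # 25 * log(3)
#' kosambiInv(kosambi(0.1))
#' @export
kosambi <- function(r) {
  if (any(r < 0)) stop("r must be >= 0")
  if (any(r >= 0.5)) {
    warning("recombination fraction >= 0.5 capped at 0.4999", call. = FALSE)
    r <- pmin(r, 0.4999)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInv <- function(d) {
  if (any(d < 0)) stop("d must be >= 0")
  tanh(d / 50) / 2
}

.haldane <- function(r) {
  if (any(r >= 0.5)) {
    warning("recombination fraction >= 0.5 capped at 0.4999", call. = FALSE)
    r <- pmin(r, 0.4999)
  }
  -50 * log(1 - 2 * r)
}
.haldaneInv <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Build a genetic map from F2 marker genotypes
#'
#' Markers are kept in physical order within each chromosome (linkage group);
#' adjacent-pair recombination fractions are estimated with [estimateRF()] and
#' converted to cM through the map function, accumulating from 0.
#'
#' @param genotypes matrix (individuals x markers) of A/H/B/missing codes or
#'   donor doses; column names must match `markerPos$name`.
#' @param markerPos data.frame with columns `name`, `chrom`, `posBp`.
#' @param mapFunction `"kosambi"` (default) or `"haldane"`.
#' @return a [GeneticMap-class]; pairs whose rf hit the 0.5 cap are flagged
#'   in the `capped` column.
#' @export
buildMap <- function(genotypes, markerPos, mapFunction = c("kosambi", "haldane")) {
  mapFunction <- match.arg(mapFunction)
  stopifnot(all(c("name", "chrom", "posBp") %in% names(markerPos)))
  if (!all(markerPos$name %in% colnames(genotypes)))
    stop("markerPos names missing from genotype columns")
  mp <- markerPos[order(markerPos$chrom, markerPos$posBp), ]
  dose <- .codesToDose(genotypes[, mp$name, drop = FALSE])
  fun <- if (mapFunction == "kosambi") kosambi else .haldane
  cm <- numeric(nrow(mp)); capped <- logical(nrow(mp))
  for (ch in unique(mp$chrom)) {
    ix <- which(mp$chrom == ch)
    if (length(ix) > 1L) for (k in 2:length(ix)) {
      r <- estimateRF(dose[, ix[k - 1L]], dose[, ix[k]])
      capped[ix[k]] <- r >= 0.5
      cm[ix[k]] <- cm[ix[k - 1L]] +
        withCallingHandlers(fun(r), warning = function(w)
          invokeRestart("muffleWarning"))
    }
  }
  mp$cm <- cm; mp$capped <- capped
  rownames(mp) <- NULL
  if (any(capped))
    warning(sum(capped), " adjacent pair(s) at the rf cap (unlinked?)",
            call. = FALSE)
  new("GeneticMap", markers = mp, mapFunction = mapFunction)
}

## ---- scan machinery -----------------------------------------------------

## Precompute, per scan position, expected additive dosage (in [-1, 1]) and
## heterozygote probability for every individual, conditioning on the nearest
## non-missing flanking markers (Haldane within-interval), plus the QR of the
## regression design.  Shared by hkScan, icimScan and permutationThreshold.
.scanDesign <- function(dose, map, step = 1) {
  mk <- map@markers
  n <- nrow(dose)
  positions <- list(); designs <- list()
  for (ch in unique(mk$chrom)) {
    ix <- which(mk$chrom == ch)
    cms <- mk$cm[ix]
    grid <- sort(unique(c(seq(0, max(cms), by = step), cms)))
    for (p in grid) {
      li <- ix[cms <= p]; ri <- ix[cms >= p]
      xhat <- numeric(n); zhat <- numeric(n)
      for (j in seq_len(n)) {
        gl <- NA_integer_; rl <- NA_real_
        for (m in rev(seq_along(li))) if (!is.na(dose[j, li[m]])) {
          gl <- dose[j, li[m]]; rl <- .haldaneInv(p - mk$cm[li[m]]); break
        }
        gr <- NA_integer_; rr <- NA_real_
        for (m in seq_along(ri)) if (!is.na(dose[j, ri[m]])) {
          gr <- dose[j, ri[m]]; rr <- .haldaneInv(mk$cm[ri[m]] - p); break
        }
        pr <- if (!is.na(gl) && !is.na(gr))
          .f2Trans(rl)[gl + 1L, ] * .f2Trans(rr)[, gr + 1L]
        else if (!is.na(gl)) .f2Trans(rl)[gl + 1L, ]
        else if (!is.na(gr)) .f2Trans(rr)[gr + 1L, ]   # chain reversibility
        else c(0.25, 0.5, 0.25)
        pr <- pr / sum(pr)
        xhat[j] <- pr[3L] - pr[1L]
        zhat[j] <- pr[2L]
      }
      X <- cbind(1, xhat, zhat)
      qrX <- qr(X)
      lm1 <- which.max(cms[cms <= p]); rm1 <- which(cms >= p)[1L]
      positions[[length(positions) + 1L]] <- data.frame(
        chrom = ch, cm = p,
        leftMarker = if (length(lm1)) mk$name[ix[lm1]] else NA_character_,
        rightMarker = if (length(rm1) && !is.na(rm1)) mk$name[ix[rm1]]
                      else NA_character_)
      designs[[length(designs) + 1L]] <- list(
        Q = qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE], qr = qrX, X = X)
    }
  }
  list(positions = do.call(rbind, positions), designs = designs, n = n)
}

## LOD curves for one or many phenotype vectors (columns of Y); the RSS1 = 0
## degeneracy is guarded by flooring RSS1 at eps * RSS0 (documented ceiling
## LOD = n/2 * log10(1/eps)).
.lodMatrix <- function(design, Y, eps = 1e-8) {
  Y <- as.matrix(Y)
  n <- design$n
  rss0 <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  nPos <- length(design$designs)
  lod <- matrix(0, nPos, ncol(Y))
  if (all(rss0 == 0)) return(lod)
  tot <- colSums(Y^2)
  for (i in seq_len(nPos)) {
    QtY <- crossprod(design$designs[[i]]$Q, Y)
    rss1 <- pmax(tot - colSums(QtY^2), eps * rss0)
    l <- (n / 2) * log10(rss0 / rss1)
    l[rss0 == 0] <- 0
    lod[i, ] <- pmax(l, 0)
  }
  lod
}

## per-position fit details for a single phenotype
.fitPositions <- function(design, y, eps = 1e-8) {
  n <- design$n
  rss0 <- sum((y - mean(y))^2)
  out <- design$positions
  nPos <- nrow(out)
  lod <- pve <- add <- dom <- numeric(nPos)
  for (i in seq_len(nPos)) {
    d <- design$designs[[i]]
    cf <- qr.coef(d$qr, y)
    cf[is.na(cf)] <- 0
    rss1 <- sum((y - d$X %*% cf)^2)
    rss1g <- max(rss1, eps * rss0)
    lod[i] <- if (rss0 == 0) 0 else max((n / 2) * log10(rss0 / rss1g), 0)
    pve[i] <- if (rss0 == 0) 0 else min(100 * (1 - rss1g / rss0), 100 - 1e-12)
    add[i] <- cf[2L]; dom[i] <- cf[3L]
  }
  out$lod <- lod; out$pve <- pve; out$add <- add; out$dom <- dom
  out[, c("chrom", "cm", "lod", "pve", "add", "dom",
          "leftMarker", "rightMarker")]
}

#' Haley-Knott interval-mapping scan of an F2
#'
#' At every position of a regular cM grid, the expected additive dosage and
#' heterozygote probability are computed from flanking-marker genotype
#' probabilities and the phenotype is regressed on them
#' (`y ~ 1 + xhat + zhat`).  `LOD = (n/2) log10(RSS0 / RSS1)`;
#' `PVE = 100 (1 - RSS1 / RSS0)`; `Add`/`Dom` are the fitted coefficients.
#' Ordinal scores are treated as numeric responses.
#'
#' @param genotypes matrix (individuals x markers) of A/H/B/missing codes or
#'   donor doses, columns matching the map's marker names.
#' @param map a [GeneticMap-class].
#' @param phenotypes numeric vector, one value per individual.
#' @param config a [linkageConfig()] list.
#' @return a [QtlScan-class].
#' @export
hkScan <- function(genotypes, map, phenotypes, config = linkageConfig()) {
  dose <- .codesToDose(genotypes[, map@markers$name, drop = FALSE])
  stopifnot(length(phenotypes) == nrow(dose))
  design <- .scanDesign(dose, map, config$step)
  tab <- .fitPositions(design, as.numeric(phenotypes))
  new("QtlScan", table = tab, method = "hk", nInd = nrow(dose),
      threshold = NA_real_, cofactors = character(0))
}

## stepwise forward/backward selection of marker variables on y at entry/stay
## level pin; V has named columns, NA imputed by column means upstream
.stepwiseSelect <- function(V, y, pin) {
  selected <- character(0)
  repeat {
    added <- FALSE
    cand <- setdiff(colnames(V), selected)
    if (length(cand)) {
      base <- if (length(selected)) V[, selected, drop = FALSE] else NULL
      pvals <- vapply(cand, function(v) {
        X0 <- cbind(rep(1, length(y)), base); X1 <- cbind(X0, V[, v])
        f0 <- lm.fit(X0, y); f1 <- lm.fit(X1, y)
        if (f1$rank <= f0$rank) return(1)
        rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
        df2 <- length(y) - f1$rank
        if (df2 <= 0 || rss1 <= 0) return(1)
        pf((rss0 - rss1) / (rss1 / df2), 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (min(pvals) < pin) {
        selected <- c(selected, cand[which.min(pvals)])
        added <- TRUE
      }
    }
    ## backward: drop any selected variable whose stay p exceeds pin
    dropped <- FALSE
    if (length(selected) > 1L) {
      X1 <- cbind(1, V[, selected, drop = FALSE])
      f1 <- lm.fit(X1, y)
      rss1 <- sum(f1$residuals^2)
      df2 <- length(y) - f1$rank
      pvals <- vapply(selected, function(v) {
        X0 <- cbind(rep(1, length(y)), V[, setdiff(selected, v), drop = FALSE])
        f0 <- lm.fit(X0, y)
        rss0 <- sum(f0$residuals^2)
        if (df2 <= 0 || rss1 <= 0) return(0)
        pf((rss0 - rss1) / (rss1 / df2), 1, df2, lower.tail = FALSE)
      }, numeric(1))
      if (max(pvals) > pin) {
        selected <- setdiff(selected, selected[which.max(pvals)])
        dropped <- TRUE
      }
    }
    if (!added && !dropped) break
  }
  selected
}

#' Inclusive composite interval mapping (additive model)
#'
#' Stage 1 selects marker cofactors by stepwise regression of the phenotype on
#' marker additive/dominance variables at entry/stay level `PIN`.  Stage 2
#' scans each position with the Haley-Knott machinery after adjusting the
#' phenotype for all selected cofactors except the variables of the two
#' markers flanking the current interval, so background QTL variation is
#' absorbed without absorbing the local signal.
#'
#' @inheritParams hkScan
#' @return a [QtlScan-class] (with the selected cofactors recorded); when no
#'   marker passes `PIN` the result equals the plain [hkScan()].
#' @export
icimScan <- function(genotypes, map, phenotypes, config = linkageConfig()) {
  dose <- .codesToDose(genotypes[, map@markers$name, drop = FALSE])
  y <- as.numeric(phenotypes)
  stopifnot(length(y) == nrow(dose))
  ## marker variable matrix: additive (dose - 1) and dominance (het) terms
  Vx <- dose - 1L
  Vz <- (dose == 1L) + 0L
  colnames(Vx) <- paste0(colnames(dose), ".x")
  colnames(Vz) <- paste0(colnames(dose), ".z")
  V <- cbind(Vx, Vz)
  for (k in seq_len(ncol(V)))
    V[is.na(V[, k]), k] <- mean(V[, k], na.rm = TRUE)
  keep <- apply(V, 2L, sd) > 0
  V <- V[, keep, drop = FALSE]
  selected <- .stepwiseSelect(V, y, config$pin)
  design <- .scanDesign(dose, map, config$step)
  if (!length(selected)) {
    tab <- .fitPositions(design, y)
    return(new("QtlScan", table = tab, method = "icim", nInd = nrow(dose),
               threshold = NA_real_, cofactors = character(0)))
  }
  pos <- design$positions
  nPos <- nrow(pos)
  lod <- pve <- add <- dom <- numeric(nPos)
  for (i in seq_len(nPos)) {
    flank <- c(pos$leftMarker[i], pos$rightMarker[i])
    flankVars <- paste0(rep(flank[!is.na(flank)], each = 2L), c(".x", ".z"))
    cof <- setdiff(selected, flankVars)
    yAdj <- if (length(cof)) {
      f <- lm.fit(cbind(1, V[, cof, drop = FALSE]), y)
      f$residuals + mean(y)
    } else y
    d <- design$designs[[i]]
    cf <- qr.coef(d$qr, yAdj)
    cf[is.na(cf)] <- 0
    rss0 <- sum((yAdj - mean(yAdj))^2)
    rss1 <- max(sum((yAdj - d$X %*% cf)^2), 1e-8 * rss0)
    lod[i] <- if (rss0 == 0) 0 else max((nrow(dose) / 2) * log10(rss0 / rss1), 0)
    pve[i] <- if (rss0 == 0) 0 else min(100 * (1 - rss1 / rss0), 100 - 1e-12)
    add[i] <- cf[2L]; dom[i] <- cf[3L]
  }
  tab <- pos
  tab$lod <- lod; tab$pve <- pve; tab$add <- add; tab$dom <- dom
  tab <- tab[, c("chrom", "cm", "lod", "pve", "add", "dom",
                 "leftMarker", "rightMarker")]
  new("QtlScan", table = tab, method = "icim", nInd = nrow(dose),
      threshold = NA_real_, cofactors = selected)
}

#' Permutation LOD threshold
#'
#' The phenotype is shuffled `nPerm` times against the (fixed) genotypes, the
#' genome-wide maximal LOD of the Haley-Knott scan is recorded for each
#' shuffle, and the threshold is the `ceiling((nPerm + 1) * (1 - alpha))`-th
#' order statistic of the maxima -- the exact-test convention, under which
#' `max LOD > threshold` has genome-wide type-I error at most `alpha`
#' (a plain sample quantile is anticonservative at small `nPerm`).
#' Deterministic given `config$seed`.
#'
#' @inheritParams hkScan
#' @return the threshold LOD (numeric scalar) with the permutation maxima in
#'   attribute `"maxLods"`.
#' @export
permutationThreshold <- function(genotypes, map, phenotypes,
                                 config = linkageConfig()) {
  dose <- .codesToDose(genotypes[, map@markers$name, drop = FALSE])
  y <- as.numeric(phenotypes)
  stopifnot(length(y) == nrow(dose))
  if (config$nPerm < 100L) stop("nPerm must be >= 100")
  design <- .scanDesign(dose, map, config$step)
  set.seed(config$seed)
  Y <- vapply(seq_len(config$nPerm), function(i) sample(y), numeric(length(y)))
  maxLods <- apply(.lodMatrix(design, Y), 2L, max)
  k <- min(ceiling((config$nPerm + 1) * (1 - config$alpha)), config$nPerm)
  thr <- sort(maxLods)[k]
  attr(thr, "maxLods") <- maxLods
  thr
}

#' Summarize significant QTL peaks of a scan
#'
#' Splits the scan into runs of positions with LOD at or above the threshold
#' and reports the peak of each run with its flanking markers, in the style of
#' a QTL confirmation table.
#'
#' @param scan a [QtlScan-class].
#' @param threshold LOD threshold (e.g. from [permutationThreshold()]).
#' @return data.frame with one row per peak: `chrom`, `cm`, `leftMarker`,
#'   `rightMarker`, `lod`, `pve`, `add`, `dom`.
#' @export
summarizeQtl <- function(scan, threshold) {
  stopifnot(is(scan, "QtlScan"), is.finite(threshold))
  tab <- scanTable(scan)
  out <- list()
  for (ch in unique(tab$chrom)) {
    t1 <- tab[tab$chrom == ch, ]
    sig <- t1$lod >= threshold
    if (!any(sig)) next
    r <- rle(sig)
    grp <- rep(seq_along(r$lengths), r$lengths)
    for (g in unique(grp[sig])) {
      blk <- t1[grp == g, ]
      out[[length(out) + 1L]] <- blk[which.max(blk$lod), ]
    }
  }
  if (!length(out))
    return(tab[0, c("chrom", "cm", "leftMarker", "rightMarker",
                    "lod", "pve", "add", "dom")])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "cm", "leftMarker", "rightMarker",
          "lod", "pve", "add", "dom")]
}
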