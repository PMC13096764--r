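---
title: "QTL-seq bulked-segregant mapping with bsaqtl: models and methods"
author: "bsaqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant mapping with bsaqtl: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

# The problem

In QTL-seq bulked-segregant analysis, two pools of individuals with opposite
extreme phenotypes are drawn from a segregating population and sequenced as
bulks.  At every SNP that distinguishes the two parents, the *SNP index* of a
bulk is the fraction of reads carrying the donor-parent allele, and the
*delta-SNP index* is the high-bulk index minus the low-bulk index.  Away from
trait loci both bulks are random draws from the population and the delta-SNP
index fluctuates around zero; at a locus that contributed to the bulk
selection the trait bulk is enriched for the causal allele and the delta-SNP
index is pushed towards +1 (donor allele increases the trait) or -1.

`bsaqtl` implements this analysis for two-bulk designs: simulation-based
null distributions and per-SNP empirical p-values, fixed sliding-window
genome scans with interval calling, a progressive window-refinement
procedure for fine-mapping, and an F2 interval-mapping validation stage.  A
synthetic-data module generates populations, ordinal trait scores, bulks and
read-count tables with the statistical structure the analysis assumes, so
that every stage can be exercised and calibrated without external data.

The design the package is built around is a rice introgression-line study:
49 recombinant inbred lines (selfing generation 9) derived from an elite
recurrent parent crossed with a weedy donor, bulked 8 (trait) versus 12
(non-trait); a high-tillering phenotype that appears only when donor alleles
are present at two loci simultaneously (chromosome 1 and chromosome 6 -
complementary epistasis); and an F2 validation population of 204 plants
scored 1-9 and genotyped at 41 markers (17 on chromosome 1, 24 on
chromosome 6).

# The synthetic-data generator

`simulatePopulation()` performs gamete-level simulation.  Crossovers are a
Poisson process on the genetic scale (Haldane model, no interference);
physical positions are converted to genetic positions at a constant rate,
4 cM/Mb by default, because no genetic-to-physical calibration is available
for the cross.  F2 individuals are two independent F1 gametes; RIL(g)
individuals are obtained by iterated selfing down to generation g, which
leaves residual heterozygosity close to $2^{-(g-1)}$ per locus; BC1F(g)
populations are supported analogously.  The map-function mismatch is
deliberate and documented: simulation uses Haldane while map *estimation*
uses Kosambi, so the simulated data carry a small, testable bias of the kind
real data would.

`assignPhenotypes()` builds a latent trait value
$\sum_i (a_i x_i + d_i z_i) + \varepsilon$, with $x_i$ the donor dose (0-2),
$z_i$ the heterozygosity indicator, and
$\varepsilon \sim N(0, \sigma)$.  Under the default complementary-epistasis
rule the genetic term is zeroed unless donor alleles are present at *all*
declared trait loci, reproducing a trait that neither parent shows.  The
latent value is binned to the ordinal scale (1-3 for the RIL screen, 1-9 for
the F2) at fixed cut points placed at upper-tail quantiles (80th-99th
percentile) of the null latent distribution, so that with weak or gated-out
genetics the bottom score class dominates, as in a field score where most
lines look like the recurrent parent.  The score-generating process of the
real study is not defined quantitatively anywhere; this construction is the
package's own choice and is documented by its closed form (the induced
genotype-group means are sums of normal tail probabilities, which the test
suite uses as an exact oracle).

Default parameters and why:

* `chromLengths`: rice chromosomes 1 and 6 (IRGSP-1.0 lengths), the two
  chromosomes that carry the trait loci.
* `markerSpacing = 1000` bp: the density of a filtered whole-genome bulk
  variant set; bulk resequencing yields millions of raw variants, and the
  fine-mapping stage needs thousands of sites per candidate region to be
  meaningful.
* `depthMean = 50`: typical per-bulk whole-genome sequencing depth.  Total
  depth is Poisson, truncated at one read (zero-depth sites never appear in
  a SNP table); the donor-allele read count is Binomial(depth, bulk allele
  frequency).
* `qtls`: chromosome 1 at 3.40 Mb and chromosome 6 at 27.15 Mb - the
  midpoints of the fine-mapped intervals - with additive/dominance effects
  1.63/0.60 and 1.04/1.25 in latent units, the values reported by the F2
  validation scan.
* `noiseSd = 1.5` latent units: a moderately heritable ordinal score;
  chosen once as realistic for a visually scored architecture trait and not
  revisited.
* `nIndividuals = 49`, bulks 8/12 by phenotype rank (ties broken by
  individual index, ascending for the high bulk and descending for the low
  bulk, which keeps the bulks disjoint and the generator deterministic).

What the generator does *not* emulate: read-level artifacts (mapping bias,
base errors, duplicated reads), indels, segregation distortion, shared
ancestry between specific lines, and multi-parent designs.  Tests passing on
synthetic data therefore validate the statistical machinery, not robustness
to alignment artifacts.

# Per-SNP statistics and the simulated null

`computeIndices()` filters sites (default: at least 10 reads per bulk, sites
with no alternate or no reference read in either bulk dropped) and computes
the indices as exact read fractions.  `simulateNull()` tabulates the null
delta-SNP index for a population model and pair of bulk sizes on a grid of
read depths (5-100 by 5): bulk members' genotypes are drawn at a neutral
locus from the model's genotype frequencies, the bulk allele frequencies are
formed, and read counts are drawn binomially.  `assignPvalues()` gives each
SNP a two-sided empirical p-value on $|\Delta|$ with the add-one estimator
$(1 + \#\{|\Delta^\ast| \ge |\Delta|\})/(n_{reps}+1)$, which cannot return
zero.  A record with unequal bulk depths is matched to the single-depth null
through the *harmonic* mean of the two depths, which preserves the
read-sampling variance $f(1-f)(1/d_H + 1/d_L)$ exactly; p-values are
interpolated linearly between tabulated depths, and depths outside the grid
fall back to the nearest tabulated depth with a warning.

Because read counts are discrete, the null |delta| distribution has atoms
(multiples of 1/depth convolved with the bulk-composition lattice).  Two
consequences are worth knowing: sample quantiles of the null can jump by one
atom (0.05 at depth 20) between Monte-Carlo runs even when the distributions
agree, and the empirical p-value has a point mass at exactly 1, so p-values
are *super*-uniform rather than uniform under the null.  The test suite
checks distributional agreement on the probability scale and super-uniformity
directly, plus two-sided calibration at the 0.01/0.05 decision thresholds.

# The genome scan and interval calling

`makeWindows()` builds the fixed grid (2 Mb windows advanced by 100 kb,
anchored at position 1, final windows clipped); `aggregateWindows()` computes
per-window SNP counts, significant-SNP counts and mean indices, plus two
significance devices when a null distribution is supplied:

* the *averaged confidence band*: the window mean of the per-SNP null
  $|\Delta|$ quantile at the requested level - the sliding-window band that
  QTL-seq-style plots draw around zero; and
* a *resampling window p-value*: each member SNP draws null deltas at its
  depth, resampled window means are formed, and the p-value is the add-one
  tail fraction of $|\overline{\Delta}^\ast| \ge |\overline{\Delta}|$.

`callIntervals()` requires both conditions - window p below alpha *and*
mean delta beyond the band at level $1-\alpha$ - before a window qualifies.
The two conditions formalize the published rule that a QTL region must show
an average delta-SNP index significantly greater than the surrounding region
with an average p below 0.05.  The resampling p-value alone would be
anticonservative here: SNPs inside a window share the bulk composition of
the same individuals, so their deltas are strongly correlated, while the
resampled null draws them independently.  The band condition restores the
comparison against the full null (composition plus read noise).  Qualifying
windows of consistent sign on consecutive grid steps merge; the interval
runs from the first qualifying window start to the last qualifying start
plus one step, so boundaries sit on the 100 kb grid and intervals from
separate runs never overlap.  Lowering alpha can only shrink intervals.

## What the study design can and cannot detect

With bulks of 8 and 12 lines, the composition component of the null delta
has a standard deviation near 0.23, and it is correlated along the genome
over tens of centimorgans, so a two-chromosome genome contains only a
handful of independent composition blocks.  Two practical consequences,
both visible in the package's seeded simulations (the acceptance script
recomputes them):

* the genome-wide fraction of SNPs below any p threshold is calibrated in
  expectation but varies widely between replicate populations, because it is
  an average over few independent blocks; and
* at alpha = 0.05 roughly a third of *null* genomes show at least one
  composition excursion that crosses the 95% band and is called as an
  interval.  This is a property of the design, not of the implementation:
  the study itself called three intervals of which only two were confirmed
  by linkage mapping.  Interval calling at alpha = 0.01, or larger bulks,
  are the remedies.

Under the default two-QTL model the trait bulk is fixed for the donor allele
at both loci, the expected delta at a trait locus is about 0.67, and the
coarse scan calls an interval containing or adjacent to the true locus in
most replicates; failures occur when the low bulk happens to carry the donor
allele in many members (the realized delta then sits below the band) or when
fewer than eight doubly-donor lines exist to fill the trait bulk.

# Progressive window refinement

`selectSignificant()` keeps SNPs with p below 0.01.  `refineRegion()` then
re-runs the window aggregation over a called region with a ladder of window
sizes - 2 Mb/100 kb down to 10 kb/5 kb by default; only the first and last
rungs are fixed by the published procedure, the intermediate rungs are a
configurable geometric descent - anchoring windows at the region start and
retaining windows that contain at least one significant SNP.
`extractCandidate()` formalizes "consistently strong signal": windows at or
above the `tau = 0.95` quantile of retained-window mean delta are strong,
and the candidate is the longest run of strong windows tolerating single-step
gaps, ties broken by higher mean then leftmost, spanning first to last
strong window.

A caveat that users should expect from this class of procedure: because the
refinement operates on significance-*selected* SNPs, sparse background and
shoulder windows carry an upward selection bias (only their lucky SNPs
survive the p filter), while the plateau at the true locus - where
essentially every SNP is significant - is estimated without that bias.  The
strongest windows therefore often sit a few hundred kilobases to a megabase
away from the causal position, even at high SNP density.  The study's own
fine-mapping showed exactly this signature: its sliding-window candidate lay
1.0-1.6 Mb from its linkage-mapping interval.  The candidate should be read
as a high-signal subregion of the QTL, not as a point estimate of the causal
position; the trace keeps every rung so the stability of the signal across
resolutions can be inspected (`plotRefinement()`).

# F2 linkage validation

`estimateRF()` estimates recombination fractions by EM over the phase-known
two-locus F2 likelihood, treating each individual as two independent gametes
and distributing the ambiguous double-heterozygote class in the E-step.
`buildMap()` keeps markers in physical order (the study's markers were
designed from resequencing positions, so no order search is performed) and
accumulates adjacent distances through the Kosambi function
$d = 25\ln\{(1+2r)/(1-2r)\}$.

`hkScan()` is Haley-Knott regression on a 1 cM grid: expected additive
dosage and heterozygote probability are computed from the nearest
non-missing flanking markers (Haldane within-interval closed forms - the
common hybrid with Kosambi between-marker distances), and
$LOD = (n/2)\log_{10}(RSS_0/RSS_1)$,
$PVE = 100(1 - RSS_1/RSS_0)$, with the additive and dominance coefficients
reported per position.  A perfect fit is guarded by flooring $RSS_1$ at
$10^{-8} RSS_0$, capping LOD at $4n$.  Ordinal scores are treated as numeric
responses, as additive inclusive composite interval mapping does; a
proportional-odds variant is out of scope.

`icimScan()` adds the inclusive-composite step: stepwise selection of marker
additive/dominance variables at entry/stay level `PIN = 0.001`, then a scan
in which the phenotype is adjusted for all selected cofactors except the
variables of the two markers flanking the current interval.  Missing
genotypes are mean-imputed in the cofactor matrix and handled by
flanking-marker conditioning in the scan itself.  `permutationThreshold()`
shuffles the phenotype (1000 times by default) and returns the
$\lceil (n_{perm}+1)(1-\alpha) \rceil$-th order statistic of the genome-wide
LOD maxima - the exact-test convention; a plain sample quantile is
measurably anticonservative at 200 permutations.  Permutations use the
Haley-Knott scan with the design matrices precomputed once, so 1000
permutations cost about as much as two scans.

# Numerical and reproducibility notes

* All randomness flows through explicit seeds (`BsaSimConfig@seed`,
  `simulateNull(seed=)`, `aggregateWindows(seed=)`,
  `linkageConfig(seed=)`); a fixed seed reproduces every output
  byte-identically.
* Coordinates are 1-based inclusive everywhere except BED output (0-based
  half-open).  `sizeInMb()` rounds `(end - start + 1)/1e6` to one decimal;
  `sizeInKb()` truncates `(end - start)/1000`, matching the conventions of
  the QTL tables this package's reports imitate.
* Problem sizes used by the test suite and acceptance script - 10,000-SNP
  null genomes, 20 seeded replicates per recovery rate, 200-400 outer
  replicates for permutation calibration, $10^6$-replicate Monte-Carlo
  oracles - were chosen to keep Monte-Carlo error well below the asserted
  tolerances.

# Known limitations

* Two bulks only; multi-bulk and multi-parent designs are out of scope.
* The null distribution conditions on bulk sizes and depth but draws bulk
  members independently; the finite-population correction from drawing both
  bulks out of the same 49 lines widens the null by about one percent of its
  standard deviation and is ignored.
* The refinement candidate inherits the selection bias discussed above.
* LOD thresholds from permutation use the base Haley-Knott scan; permuting
  the full cofactor-selection pipeline is substantially slower and is not
  the default.
* Upstream of the SNP table (alignment, variant calling, annotation) is out
  of scope; `importVcfPair()` expects biallelic calls with allelic depths.
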