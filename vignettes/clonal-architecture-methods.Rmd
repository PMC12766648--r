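---
title: "Models and methods for mapping clonal architecture from somatic SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mapping clonal architecture from somatic SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mosaiclineage)
```

# The problem

A somatic single-nucleotide variant (sSNV) that arises in a progenitor
cell during development is inherited by every descendant of that cell.
The fraction of cells carrying the variant — its mosaic fraction (MF),
estimated as twice the alternate allele fraction (AAF) for a
heterozygous autosomal site — records how early the variant arose, and
its distribution across tissue regions and cell types records where the
clone's descendants ended up.  This package turns four kinds of readout
(deep bulk WGS, ultra-deep replicate amplicons, single-cell panel
sequencing of amplified genomes, and sparse single-nucleus UMI tallies)
into quantitative statements about clonal architecture.

# The synthetic ground truth

Because real data of this kind are controlled-access, the simulator is a
first-class module, and its defaults define the study conditions used
throughout the tests:

* one founder doubles synchronously each generation to a final
  population of `6e7` mutation-bearing cells (`final_population_size`);
  `ceiling(log2(6e7)) = 26` generations span a 16-week neurogenic
  window, so one generation is ~0.6 weeks;
* `mutations_per_generation = 7` new population-level mutations per
  generation, each placed on a uniformly chosen extant lineage under the
  neutral infinite-sites assumption, so a mutation of origin generation
  `g` has true MF exactly `2^-g`;
* three regions (BA17, BA18, BA9 by default) with clade-level
  restriction: at a region's restriction generation, uncommitted clades
  commit; clades older than the restriction time span regions
  (dispersion), younger clades are region-confined.  Defaults (BA9 at
  generation 4, the visual-border regions at 8) reflect early prefrontal
  commitment and later occipital segregation;
* grouped cell types (upper/other-layer GluN, CGE/MGE GABN, astrocyte,
  oligodendrocyte, microglia) with proportions 0.30/0.30/0.10/0.10/
  0.10/0.07/0.03, a realistic cortical mix at the granularity the
  readouts resolve; within dorsal clones GluN and GABN are co-generated
  at `dorsal_glun_gabn_ratio = 12`;
* readout layers at the depths the assays deliver: Poisson(210x) bulk
  WGS, amplicons of at least 10,000 reads with 1-3 replicate primers and
  a per-base flanking error rate of 5e-4, a single-cell panel with
  allelic dropout (default 0.2) and Beta-distributed amplification
  imbalance around 0.5 (shape 200), and Poisson(2) UMIs per site per
  nucleus.

Only `tracked_lineages` (default 8192, a power of two) lineages are
simulated explicitly; beyond that generation each tracked lineage is a
clone whose mass is scaled analytically — sixty million cells are not
materializable, and nothing downstream needs them individually.
Mutations arising after the tracked phase are retained as within-clone
subclonal fractions (`2^-(g - g_cap)`), so the Poisson accrual and the
`2^-g` MF law hold at every generation; at default settings their MFs
(below 0.012%) sit under every detection floor.

What the generator does *not* emulate: selection, regional differences
in death rates, migration trajectories, recurrent mutation, copy-number
changes, and realistic sequencing-context error structure.  Tests that
pass on this generator therefore validate the statistical machinery
under the stated model, not robustness to biology the model omits.

# Regional sSNV-count ratios

Discovery pipelines lose sensitivity at low AAFs, so raw per-region
variant counts are not comparable.  For each of seven AAF bins (1-2%
through 20-50%), a per-bin detection threshold is simulated as the
minimum of Binomial(250, AAF) draws over the bin's members; per region,
each variant's simulated read count must strictly exceed the threshold
to be retained (strict exceedance is what lets variants absent from a
region drop out when a bin's minimum is zero), and each retained
variant contributes the reciprocal of its sensitivity.  The ratio of
projected sums is formed per iteration; the point estimate is the
median over iterations (the originating description does not specify a
point estimator) with percentile CIs, at a configurable level because
the source describes both 99% and 95% intervals.  Iterations with a
zero denominator are excluded and counted.  Thresholds are recomputed
each iteration so that threshold noise propagates into the CI.

Variants are assigned to bins by their cross-region mean AAF — the
choice matters only at bin edges and is the same quantity the
uniform-mixing null simulates: under the null every variant's regional
AAFs are replaced by that mean, and an upper-tail empirical p compares
the observed point ratio with the null ratio distribution.

The packaged default sensitivity curve is a logistic in log-AAF
(half-sensitivity at 2% AAF, ~1 above 10%); it is a placeholder shape,
not a published calibration, and `sensitivity_curve()` accepts measured
(AAF, sensitivity) tables, smoothing them with a spline and enforcing
positivity and monotonicity.

# The PWM artifact filter

Platform-specific artifacts (such as a NovaSeq-associated excess of
low-AAF T>G/A>C calls at TTCC repeats) are recognized by sequence
context.  Per substitution class — purine-reference records are
reverse-complemented into the pyrimidine frame first — a 41-base
position weight matrix is built from the test callset and another from
a control callset, with pseudocount 0.5 and masked characters excluded
column-wise.  Each record is scored by the joint multinomial log
likelihood ratio over the 9 bases centred on the call, and its
empirical p is `(1 + #{control LR >= observed}) / (n_control + 1)`;
records with `p < 0.05` are removed.

One numerical choice matters for calibration: every record is scored
leave-one-out with respect to the PWM it helped build.  Without this,
each record inflates its own likelihood, and at small callset sizes the
removal rate on exchangeable data is several times alpha; with it the
empirical p values are super-uniform, and the correction vanishes as
callsets grow.

# Deep-amplicon mosaicism and the restriction null

MF estimates average AAFs over replicate primers (MF percent =
200 x mean AAF); background error is the mean allele fraction over 100
flanking positions.  A site is *inconclusive* below 10,000 reads,
*detected* when it reaches the depth, carries the expected allele and
has MF >= 0.1%, and *absent* otherwise.  With replicate primers the
site depth for the 10,000-read rule is the summed depth — the
single-primer case reduces exactly to the stated rule.  Mosaicism
categories close their boundaries on the lower band (ultra-low <= 2% <
low <= 10% < higher <= 90%), with an average AAF of 45% or more read as
germline.

The uniform-mixing null for the number of occupied regions draws, per
region and replicate, mutant reads ~ Binomial(10,000, MF/2) — reads
sample alleles, not cells — and error reads at the averaged background
rate, calling detection when mutant reads exceed error reads and clear
the 0.1% floor.  The printed floor is interpreted on the MF scale
(mutant fraction > 0.05% of reads, i.e. more than 5 of 10,000), with
`floor_scale = "aaf"` exposing the literal reading; error reads are
drawn independently per region.  Lower-tail Poisson probabilities at
the simulated expectation, adjusted by Benjamini-Hochberg within a
donor's variant family (one-sided, fewer-than-expected), flag
regionally restricted variants.  Outlier flags use type-7
(linear-interpolation) quartiles and strict fences at 1.5 and 3 IQRs.

# Single-cell genotyping

The genotype model is two binomials: a carrier cell yields alternate
reads at `p_mut` (ideally 0.5, shifted by amplification imbalance; fit
from heterozygous control SNPs), a non-carrier at the error rate (fit
from reference-homozygous controls).  The site prior is the pooled
mutant-read fraction across cells mapped to a carrier fraction
(`min(2 x pooled AAF, 1 - 1e-3)`, clamped away from 0 and 1 — the
source states only proportionality).  The stated model closes
analytically, so parameters are point estimates rather than posterior
samples from a generic MCMC engine; zero-depth cells return the prior,
flagged.  Consensus across batches multiplies per-batch likelihood
ratios under a prior equal to the variant's mosaic cell fraction, and
withholds calls when two batches disagree with both single-batch
posteriors beyond 0.99.

# Perfect phylogeny, lineage tree, coalescent times

Under infinite sites, carrier sets must be laminar (nested or
disjoint); observed matrices violate this through dropout and error.
Imputation minimizes total posterior-weighted flips
(`cost = |posterior - new value|`), optionally constrained so each
site's carrier fraction stays within a tolerance of its MF.  Panels up
to 12 sites are solved exactly by branch and bound over conflict
witness triples (any compatible matrix must change at least one of the
six entries of a witness triple, so branching over them with
inclusion/exclusion locking is complete).  Larger panels use
tree-guided assignment: a site tree is estimated from carrier-set
overlaps — each site's parent is the latest-ordered earlier site
containing at least half its carriers, which strings co-branch sites
into chains — and each cell receives the root-chain minimizing its
total posterior disagreement.  Chains of a site tree have laminar
carrier sets, so the result is compatible by construction and the
procedure is single-pass.  Per-conflicting-pair repair was rejected
because pairwise flips cannot see multi-site evidence (a dropout cell
needs one flip that several site pairs observe) and its iteration can
cycle or deadlock when many sites share a branch.

On a compatible matrix the rooted perfect phylogeny is unique up to
zero-length orderings and is built directly from carrier-set nesting;
its parsimony score equals the number of placed sites, sites carried by
all cells map to the root branch, and a generic parsimony search would
add nothing but tie-breaking noise.

The coalescent model is defined here in full (the analysis it
reimplements did not publish its likelihood): the population doubles
each generation from one founder to `N = 2^G` cells, so population size
at forward time `t` is `2^t` regardless of `N`, and `N` enters as the
tip time `G = log2 N`.  A branch from `t_u` to `t_v` carries
Poisson(`mu (2^-t_u - 2^-t_v)`) mutations — the exact continuum limit
of placing `mu` population-level mutations per generation uniformly on
`2^t` lineages — and node times follow a coalescent with pairwise
intensity `ln(2) 2^-t`, matching the sibling probability
`1/(2^g - 1) ~ 2^-g` of strict binary division (half the Wright-Fisher
value, because every parent leaves exactly two offspring).  Polytomies
contribute `(d - 1)` simultaneous merger factors.  Priors: `log2 N`
uniform on `[log2 1e6, log2 1e9]`; `mu` a Jeffreys-type scale prior
`1/mu` with an exponential tail of mean 10.  Sampling is
Metropolis-within-Gibbs with full log-posterior recomputation per
proposal (trees here have hundreds of nodes; simplicity beats delta
tricks), a log random walk for `mu`, and for `G` alternating a local
random walk with an independence draw from the prior — the `G`
posterior is nearly flat, and this is stated openly: the data inform
`N` only through terms of order `2^-G`, so the reported `N` interval is
prior-dominated.  Convergence is monitored by split-chain Rhat on `mu`
and `G` with threshold 1.01 (4 chains, 2000 kept draws after 1000
warmup by default).  A variant's time of origin is the posterior
midpoint of its branch; post-MRCA weeks interpolate `log2`(population)
against week in a growth table whose default runs from one cell to
`2^26` (about sixty million) over 16 weeks, so generation 13 maps to
week 8 exactly.

The regional restriction statistic of a clade is the mean cross-region
patristic distance over the mean within-region distance — a ratio of
mean distances, since a single pair is either within- or cross-region
and a pairwise ratio is undefined — oriented so that values above 1
mean same-region clade-mates are more closely related (the
interpretation stated in the source; the reciprocal is available via
`orientation`).  CIs bootstrap cells within the clade, excluding
self-pairs of duplicated resamples.  Dispersion modes are plain k-means
(k = 5, 25 restarts, fixed seed) on the variants-by-region MF matrix,
with the effective k reduced when fewer distinct profiles exist.

# Cell-type sharing, clones and composition

A cell supports a variant when it has at least one mutant UMI; zero-UMI
cells are non-informative throughout, never counted as non-carriers.
For each unordered cell-type pair, the shared count is the number of
sSNVs supported by at least two distinct cells of each type, normalized
by the number of cross-type cell pairs sharing any mutant allele (the
most direct reading of "pairs of cells that shared mutations overall";
self-pairs use within-type pairs).  The observed-versus-expected
difference test pools the per-sSNV normalized contributions of both
sources and bootstraps pairs of resamples from the pool for the null
difference distribution — a pooled null is what makes the test a
calibrated level-alpha procedure, which the looser original wording
does not guarantee — with an upper-tail empirical p.

The minMF of a cell-type pair is the minimum MF among their shared
sSNVs (at least three required), with 90% percentile CIs over bootstrap
resamples of the shared sSNV set (sSNVs only; cells are not resampled —
the sSNV set is the unit of inference for the last shared ancestor).
Clones are Louvain communities (resolution 1, fixed seed) on the
weighted graph whose edges count variants shared by cell pairs.

Clone composition uses empirical Bayes: for a focal type, the count
`X` of type cells in a clone of size `N` is beta-binomial, and a
beta-binomial regression of `(X, N - X)` on the number of variants
represented in the clone and `log10 N` yields per-clone prior means
`mu0` and a shared precision `sigma0`, treated as the prior weight
(`alpha0 = mu0 sigma0`, `beta0 = (1 - mu0) sigma0`; the source formula
is typographically ambiguous, and the precision reading makes the
posterior `(alpha0 + X)/(sigma0 + N)` a proper Beta update).  Clones
below 10 cells are excluded.  Aggregate proportions are size-weighted
means of per-clone posteriors; their Monte-Carlo intervals propagate
regression-parameter uncertainty into the prior, without which a
prior-dominated fit (large `sigma0` on nearly-binomial data) would
collapse to zero-width intervals.  Non-convergent covariate regressions
fall back to an intercept-only model, then to a direct ML fit, with
warnings.

# Problem sizes and numerical choices

The test suite runs everything at reduced scale chosen for tight
feedback loops: 64-512 tracked lineages, 40-500 sampled cells, panels
of 20-50 sites, 100-1,000 Monte-Carlo iterations, 20 replicates for the
coalescent parameter-recovery experiment (2 chains, 700 kept draws),
200 replicates for calibration checks.  Degenerate inputs are handled
explicitly: empty AAF bins are flagged and excluded; zero-depth primers
and cells are excluded or returned at the prior; all-zero k-means input
reduces the effective k; clades without cross-region pairs return an
undefined RRS with a message rather than a number.

# Known limitations

* `N` from the coalescent fit is prior-dominated; treat its interval as
  a statement of prior range, not inference.
* The exact imputation solver is exponential in the worst case and is
  capped at 12 sites; the tree-guided method above that size is a
  heuristic whose quality degrades if the site-tree estimate is wrong
  (very high noise or very small clades).
* The default sensitivity curve is a documented placeholder; ratio
  estimates against real discovery pipelines require a measured curve.
* Amplification imbalance is modeled as a symmetric Beta around 0.5;
  real MDA bias is heavier-tailed and locus-dependent.
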