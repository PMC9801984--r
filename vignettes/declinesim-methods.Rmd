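---
title: "Methods: simulating and detecting recent population declines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting recent population declines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`declinesim` is a benchmarking pipeline for the question every
conservation-genomics study design has to answer: *given a sampling scheme
(contemporary-only, two time points, or serial museum samples), a data type
(whole genomes or RAD-like reduced representation), and a sample size, how
reliably can genomic methods detect a population decline that began only
decades ago?*  The package contains the whole loop: a forward-time
individual-based simulator with known demographic truth, dataset builders,
two in-package estimator families (a folded-SFS composite-likelihood fitter
and two linkage-disequilibrium estimators), and the evaluation statistics
(power, MAPE, log-ratio bias) used to compare designs.

# The simulated world

## Demography

A single panmictic dioecious population is simulated forward in time for
220 years.  Population size is regulated by the number of offspring $N_O$
produced each year; every offspring draws one female and one male parent
uniformly *with replacement* from the breeding-age pool.  This gives
near-Poisson reproductive success (mean 2, variance about 2), so $N_O$
tracks the effective size $N_e$ and the "size" of a scenario can be read as
an effective size.

Two life histories are available:

* **G1** — annual semelparous: everyone breeds at age 1 and dies.
  Generation time is exactly one year.
* **G2** — overlapping generations: age at first breeding 1 year, maximum
  age 8 years.  The survival schedule is *solved at construction*, not
  hard-coded: with first-year survival $s_1$ and constant adult survival
  $s_a$, the stable-age-structure constraints
  $s_1\sum_{a=1}^{8}s_a^{a-1}=1$ (expected breeder count equals offspring
  count) and $\sum a\,s_a^{a-1}/\sum s_a^{a-1}=3$ (mean breeder age, hence
  generation time, of 3 years) determine $(s_1,s_a)\approx(0.294, 0.730)$.

Recent trajectories are exponential declines at a per-year rate $\lambda$
starting $T_{dec}$ years before present: size at $t$ ybp is
$N_H\lambda^{T_{dec}-t}$ for $t<T_{dec}$.  $\lambda$ is per *year*, so
under G2 the per-generation decline is $\lambda^3$.  The contemporary to
historic ratio is $\lambda^{T_{dec}}$; for $\lambda=0.99$ and
$T_{dec}=120/90/60/30$ this gives $0.30/0.40/0.55/0.74$, and $0.21$ for
$\lambda=0.95$ over 30 years.  (The source literature pairs these two lists
"respectively" in the opposite order, which contradicts the arithmetic; the
package follows the arithmetic.)  Optionally a 10-fold ancestral size
change (expansion or bottleneck) is placed 10,000 generations before
present; it is restricted to $N_H=10{,}000$, G1, and three recent
trajectories, giving the 18-scenario study grid and, with 5 replicates,
3 schemes, 3 data types and 3 sample sizes per type, 2430 dataset
specifications.

## Genetic transmission: pedigree first, coalescent second

The forward stage records the complete pedigree.  Genotypes are then
generated *conditionally on that pedigree*, which preserves exactly the
features the estimators read: the recent genealogy (SFS distortion) and
linked and unlinked coancestry (LD).  Rather than dropping whole genomes
forward through every individual, sampled haplotypes are traced *backward*
at a set of point loci:

* Each sampled haplotype starts one lineage per locus.  At its carrier's
  birth year the lineage jumps into one of the corresponding parent's two
  haplotypes; a single meiosis (Poisson($rL$) crossovers, uniform
  breakpoints, fair-coin start) is shared by all loci the gamete carries,
  so linkage through the pedigree is exact.  Two lineages of the same
  locus landing in the same haplotype coalesce.  This is an exact
  realisation of segment transmission restricted to the loci of interest;
  the forward counterpart (`simulate_chromosome`, full segment mosaics) is
  kept as a reference implementation and cross-checked at toy scale.
* Lineages that reach founder haplotypes are continued through a *linked
  backward Wright-Fisher extension*: a virtual random-mating population of
  size $N_H$ in which each haplotype draws a random parent per generation,
  with shared meioses, until 2000 generations before present (the horizon
  of the binned-LD estimator's trajectory).  Without this stage the
  long-range LD contributed by pre-pedigree coancestry is missing and the
  binned-LD method sees a spurious size inflation at older time points.
* The remaining lineages are finished per locus by a single-locus Kingman
  coalescent with diploid size $N_H$ back to the ancestral change point
  and $N_A$ earlier.  Marginally (per locus) this is identical to the
  linked process, so SFS-type summaries are unaffected by where the
  hand-off happens; only pre-horizon LD differs.  For SFS-only datasets
  the linked extension can therefore be skipped (`linked_gens = 0`) at no
  cost in correctness — the acceptance script does this.

Mutations are dropped on the completed forest under infinite sites: one
Bernoulli trial per meiosis per locus in the pedigree and virtual stages
(branch lengths are integer meiosis counts) and Poisson mutations on the
coalescent-stage branches, each at rate $\mu\ell$ per generation for locus
length $\ell$.  Sites monomorphic across all sampled haplotypes are not
emitted; the total site count $L$ is carried as a scalar for likelihood
normalisation.

**Point-locus resolution.**  Whole-genome sequence is represented as a
contiguous tiling of 5 kb windows (within-window recombination, about
$5\times10^{-5}$ Morgans, is ignored; between-window linkage is exact);
RAD data as the 150 bp windows themselves.  The only visible artefact is
shared trees for SNPs inside one window, i.e. excess LD confined to pairs
closer than one window — far inside the lowest recombination-fraction bin,
beyond the time horizon any read-out uses.

**Backward-time units.**  The coalescent stages measure time in
generations, scaled by the life history's expected generation time (3 y
for G2); the discrete age structure is not modelled backward.

# Estimators

## Folded-SFS composite likelihood

Per timepoint the folded SFS is computed from minor-allele counts.  Four
models are fitted: constant size (M1, 1 parameter), a recent exponential
size change between $T_{rc}$ and the present (M2: $N_{contemp}$,
$N_{historic}$, $T_{rc}$), an instantaneous ancient change at $T_{ac}$
(M3: base and ancient sizes plus $T_{ac}$), and both (M4, 5 parameters).
Bounds: sizes $[10, 5\times10^5]$, $T_{rc}\in[10,120]$ ybp,
$T_{ac}\in[10^3,10^5]$ ybp.

The likelihood is a *marginal composite likelihood*: each timepoint's
folded bins are independent Poisson observations of the expected folded
SFS of the model truncated at that sampling time, plus a Poisson term for
the monomorphic class ($L$ minus the expected segregating total).  This is
a deliberate simplification of a joint multi-time "leaf" construction on a
single-population branch: for one panmictic population, the per-epoch
marginal spectra carry the same first-order information, and the AIC
classification the evaluation uses is unchanged.  It is documented here as
the package's chosen design.

Expected spectra come from a numerically stable engine: with
$F_j=\int_0^\infty e^{-b_j\tau(t)}dt$, $b_j=j(j-1)/2$,
$\tau(t)=\int_0^t ds/2N(s)$ computed exactly per epoch on a log-spaced
piecewise-constant grid (512 epochs spanning $10^{-2}$ to $10^6$
generations), the expected unfolded SFS is $\mu L\,W F$ where the weight
matrix $W$ obeys a stable three-term recursion in $j$.  The classical
alternating-sum spectral coefficients overflow double precision for
samples beyond about 50 haplotypes; the recursion is stable for hundreds.
$W$ is verified in the tests against an independent lineage-count ODE
integrator (Crank-Nicolson in $\tau$) and against closed forms (constant
size: $E[\xi_i]=4N\mu L/i$ to $10^{-15}$; $n=2$: $4N\mu L$).

Optimisation is bounded quasi-Newton (`L-BFGS-B`) on $\log_{10}$
parameters with log-uniform multi-starts plus a deterministic centre
start.  Model selection is minimum AIC ($2k-2\ell$), ties broken toward
fewer parameters, non-converged fits excluded; AICc is available by flag.
A decline is called when a recent-change model (M2/M4) wins *and*
$\hat N_{e,C}<\hat N_{e,H}$ (sizes read at 0 and 120 ybp).

## Unlinked-pair LD estimator

The squared Burrows composite correlation of diploid dosages (`cor()^2`,
the observed-variance normalisation valid for unphased data) is averaged
over SNP pairs on *different* chromosomes (MAF cutoff 0.05).  The
random-mating sample-size expectation ($1/S+3.19/S^2$ for $S\ge30$;
$0.0018+0.907/S+4.44/S^2$ below — the published weighted-regression
variants for unknown phase) is subtracted and the drift expectation
inverted for $\hat N_e$; a non-positive corrected mean returns an
*infinite* estimate, which the evaluation layer never counts as a
detection.  The 95% CI is a delete-one-locus (SNP) jackknife on the mean
$r^2$, mapped through the same inversion (upper $r^2$ gives the lower size
bound).  Jackknifing SNPs rather than pairs is a desk-scale choice; pairs
sharing a deleted SNP are removed together, which is the point of the
delete-one-*locus* scheme.

## Binned-LD trajectory

Same-chromosome pairs are mapped to recombination fraction through a
uniform 1 cM/Mb map and Haldane's function $c=(1-e^{-2d})/2$, truncated at
$h_c=0.05$, and accumulated into 400 equal-width bins.  Per bin the
sample-corrected $r^2_c=\bar r^2 - 1/S$ (floored at $10^{-6}$; bins below
are dropped) is inverted through $E[r^2]\approx1/(3+4Nc)$ and assigned to
generation $t=1/(2c)$, so $h_c=0.05$ maps to $t=10$ generations — the
youngest resolvable age, matching the known limitation that this method
family only resolves declines at least ~10 generations old.  The
trajectory is smoothed with a running median (15 bins); contemporary size
is read at $t=10$ and historic size at $120/\text{gen time}$ generations.
CIs are 2.5/97.5 percentiles over 40 SNP-resampling replicates of 50,000
SNPs; when fewer SNPs are available the resample is drawn *with
replacement* so the replicates still vary.  This whole construction
replaces the published genetic-algorithm fitter with a transparent per-bin
inversion: the evaluation layer only consumes $\hat N_{e,C}$ and
$\hat N_{e,H}$ with CIs, and the inversion reproduces both flat
trajectories for stable populations and the decline signal (see the
acceptance tests).

**Why the trajectory estimator applies its own MAF cutoff.**  The Sved
relation describes a ratio of expectations; the per-pair mean of $\hat r^2$
over pairs involving rare alleles falls below it in a
distance-dependent way, which would masquerade as growth toward the past.
With a 0.05 cutoff the per-bin means match the drift expectation closely
(verified in the tests), so `bin_pairs` defaults to `maf = 0.05` even
though the unlinked-pair estimator keeps its own, separately specified,
0.05 cutoff.

# Evaluation layer

Detection rules: AIC pathway as above; CI pathway calls a decline when the
upper 95% CI of $\hat N_{e,C}$ lies strictly below the lower 95% CI of
$\hat N_{e,H}$ (a boundary tie is *not* a detection — the strict rule is
deliberately conservative), and calls a constant history correct when the
CIs overlap.  For the AIC pathway a constant history is correct when a
constant-recent-size model wins; the source text appends an inequality
clause to that rule which only makes sense for declines and is treated as
an editing error.  Power is the fraction of correct calls among replicates
sharing a truth; MAPE is $\frac{100}{n}\sum|inferred-simulated|/simulated$
computed on the aggregation subset (constant, fast-30, slow-120
scenarios, generation time 1, both initial sizes, WGS and 50k-RAD
separately), with unlinked-pair records at $n=50$ excluded (they return
many infinite estimates) and infinite estimates counted per cell.

# Synthetic data: what a green test establishes

The generator emulates: random mating with near-Poisson reproductive
success, 50/50 sex assignment, exponential recent declines in discrete
yearly steps, uniform recombination (1 cM/Mb) and mutation
($10^{-8}$/bp/generation), free recombination between chromosomes, and
museum-style temporal sampling of 200 recorded individuals per checkpoint.
It does **not** emulate: genotyping error (beyond the explicit singleton
injection), missing data, allelic dropout, variable recombination or
mutation rates, selection, population structure or migration, phasing
error, or uncertainty in the genetic map.  Power numbers from this world
are therefore upper bounds for real data with comparable information
content, and the distortion experiments (MAF filter, singleton injection)
probe exactly the gap between the clean world and practice.

# Numerical choices

* Expected-SFS grid: 512 log-spaced epochs over $[10^{-2},10^6]$
  generations; constant-size spectra are exact, discretisation error only
  affects the exponential-ramp segment (cross-checked to $10^{-4}$
  against the ODE integrator).
* The ODE oracle integrates the pure-death lineage chain with
  Crank-Nicolson steps bounded by $0.5/b_{max}$ and an absorbing tail in
  closed form.
* Population sizes round to integers with a floor of 2 (one breeder of
  each sex); crossover breakpoints are continuous uniforms floored to
  integer bp for VCF export, with collisions resampled.
* Seeds: every stage derives its seed from a master seed and a stable
  polynomial string hash of the stage labels, so grids enumerate
  order-stably and any dataset can be regenerated in isolation.
* Optimiser defaults (5 multi-starts, `maxit` 80) aim at robustness;
  the acceptance script uses a documented lean profile (2 starts,
  `maxit` 50) whose recovery accuracy is validated in the tests.

# Known limitations

* The linked ancestry horizon (2000 generations) leaves pre-horizon LD
  unmodelled; bins mapping to ages beyond it under-read LD.  No read-out
  used by the evaluation looks there.
* The composite likelihood ignores linkage between sites and between
  timepoints; AIC differences are therefore composite-likelihood
  differences, as in the method family this emulates.
* The unlinked-pair estimator's published small-sample corrections are
  regression approximations; at $S<30$ combined with few loci the CI
  coverage is approximate and infinite estimates are common (this is a
  property of the method, reported rather than hidden).
* G2 backward-time scaling uses the expected generation time (3 y); age
  structure is not represented in the coalescent stages.
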