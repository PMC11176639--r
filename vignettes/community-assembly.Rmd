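---
title: "Quantifying community assembly processes with ecoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes with ecoassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Soil microbial surveys routinely ask not just *how* communities differ
between sites but *why*: is turnover driven by deterministic
environmental filtering (selection), by dispersal, or by neutral drift?
`ecoassembly` implements the two-step phylogenetic null-model framework
that answers this per pair of samples, together with the surrounding
inference stack a typical restoration-ecology survey needs: depth
filtering, rarefaction, cumulative sum scaling, collinearity pruning of
soil covariates, Bray-Curtis/PCoA diversity, PERMANOVA, Mantel
distance-decay, Procrustes congruence, distance-based forward selection,
Moran's eigenvector map variance partitioning, and indicator-value
analysis. A metacommunity simulator generates data assembled under each
process so every inference can be validated against a known truth.

## The two-step null model

**Step 1 — selection.** For samples $j,k$ the between-community mean
nearest taxon distance is

$$\beta\mathrm{MNTD}(j,k) = \tfrac12\Big[\sum_{i \in j} f_{ij}\,
\min_{i' \in k} d(i,i') + \sum_{i \in k} f_{ik}\,
\min_{i' \in j} d(i,i')\Big],$$

with $f$ the within-sample relative abundance and $d$ patristic
distance. The null shuffles the phylogeny's tip labels uniformly across
all taxa in the aligned table; $\beta$NTI is the z-score of the observed
value against `n_null` shuffles (default 999; one shuffle per replicate
is shared by all pairs, which leaves each pair's marginal null unchanged
and is `n_pairs`-fold cheaper). $\beta\mathrm{NTI} < -2$ is classified
homogeneous selection, $> +2$ heterogeneous selection. The z-score uses
the sample standard deviation over replicates; pairs with a degenerate
null (sd below `1e-12`, e.g. on a symmetric star tree) are flagged
undefined and excluded from summary denominators.

**Step 2 — dispersal vs drift.** Pairs not resolved by selection are
classified by the Raup-Crick metric on Bray-Curtis dissimilarity.
Each null community draws the sample's observed richness of taxa
without replacement with probability proportional to occurrence
frequency across the pool, places one individual on each drawn taxon,
and distributes the remaining reads with probability proportional to
regional relative abundance (so the null community's realized richness
equals the observed richness — without the guaranteed individual the
null is systematically too dissimilar and the metric acquires a
negative bias). With ties counted half, within `1e-12`,

$$RC_\mathrm{Bray} = 2\,\frac{\#(\mathrm{null} < \mathrm{obs}) +
\tfrac12\,\#(\mathrm{null} = \mathrm{obs})}{n_\mathrm{null}} - 1 .$$

$RC > +0.95$ is dispersal limitation, $RC < -0.95$ homogenizing
dispersal, anything else undominated. All four thresholds are strict
inequalities; boundary values fall through to the non-significant
branch.

Choices the framework leaves open, and what this package does:

* $\beta$MNTD is abundance-weighted by default (`abundance_weighted`
  flag), the dominant convention of the lineage of null-model studies
  this implements; RCBray runs on rarefied integer counts because its
  null draws individuals.
* The regional pool is every taxon present in the analyzed table. The
  pipeline excludes grass (unplanted control) samples from the
  assembly analysis by default (`assembly_pool = "planted"`), since the
  question concerns communities under the planted trees; `"all"` is
  available.
* Weighted sampling without replacement uses exponential keys
  (Efraimidis-Spirakis), distributionally identical to successive
  weighted draws but an order of magnitude faster at thousands of taxa.

## Preprocessing rules

* `filter_low_depth()` removes samples with fewer than 1000 reads
  (strictly `<`), then drops emptied taxa.
* `rarefy()` subsamples without replacement (multivariate
  hypergeometric) to an even depth; each sample's seed is derived as
  `seed + sample index`, so sample order never changes results.
* `css_normalize()`: the scaling factor of sample $j$ is the sum of its
  $k$ smallest nonzero counts with $k = \max(1, \lfloor q\,n_{nz}
  \rfloor)$, $q = 0.5$ by default. This quantile-*index* convention is
  well defined under heavy ties (all-equal counts give $s = $ sum of
  the smallest half, not of all counts); the adaptive-quantile variant
  of CSS is out of scope.
* `prune_collinear()` greedily resolves every pair with $|r| > 0.65$ by
  dropping the member with the larger mean $|r|$ against the remaining
  variables (ties lexicographic), and reports each drop. The output
  provably contains no offending pair.

## Multivariate stack

PERMANOVA delegates to `vegan::adonis2` with sequential (Type-I) terms
in the order given — plot type before plot, so the nested factor absorbs
residual variance — and free permutations; nestedness is represented by
term order, not restricted permutation blocks. $R^2$ is reported as
SS/SS$_{total}$ throughout (a caption in the survey literature that
describes $R^2$ as a square root of a variance component is internally
inconsistent with that usage and is not followed). Mantel tests are
one-tailed (greater); `distance_decay()` reports the correlation on the
similarity scale ($1 - BC$, negative under decay) with the one-tailed p
in the decay direction and a least-squares slope for plotting.
DistLM-style forward selection and the variance partition compute
McArdle-Anderson sums of squares on the Gower-centered distance matrix
itself ($\mathrm{tr}(HGH)$), so negative-eigenvalue structure is
retained rather than truncated away; the partition applies the Ezekiel
adjustment and reports fractions `a` (environment), `b` (shared), `c`
(space), `d` (residual), which sum to 1 by construction and may be
slightly negative individually. dbMEM construction follows the
truncated-distance recipe (threshold = longest minimum-spanning-tree
edge, beyond-threshold entries set to four times it, positive-eigenvalue
eigenvectors kept); MEM selection is by marginal dbRDA pseudo-F with
Benjamini-Hochberg correction — the framework's description
("significantly correlated") names no test, and the marginal+BH choice
is both simple and conservative; forward selection over MEMs can be
substituted by passing a pre-selected basis. All permutation p-values
use the $(b+1)/(m+1)$ estimator, so $p = 0$ is impossible.

IndVal uses group-equalized specificity $A$ (Dufrêne-Legendre), raw-mean
optionally, permutes group labels for significance and applies BH across
features; it requires relative or CSS-scaled input because $A$ compares
mean abundances across samples.

## What the simulator emulates — and what it does not

`assemble_communities()` generates a 272 m × 30 m strip of 8 plots
(3 monoculture, 3 mixed, 2 grass), lognormal sequencing depths with a
configurable number of samples planted below 1000 reads, a lognormal
regional pool over a Yule phylogeny carrying a Brownian niche trait,
spatially autocorrelated soil chemistry with a planted block of 7
collinear variables among 16, and counts assembled under one of five
known processes:

* **Homogeneous selection**: one Gaussian trait optimum shared by all
  sites. The optimum sits in the trait *tail* (`env_contrast = 1.5`
  z-units) because under Brownian evolution extreme trait values are
  phylogenetically clustered while mid-range values occur in every
  clade — selection toward the tail is what produces the low observed
  phylogenetic turnover the method detects, exactly as environmental
  tolerances (pH extremes, salinity) are conserved on real phylogenies.
  Each site additionally experiences a colonization lottery
  (`p_col = 0.6`) and mild lognormal abundance jitter
  (`drift_jitter = 0.5`): selection fixes the candidate membership,
  local drift realizes it. Without this local stochasticity all sites
  would share one multinomial weight vector and pairwise turnover would
  collapse to sampling noise, leaving the null nothing to measure. A
  weak flat immigration floor (`imm_floor = 0.002`) keeps
  phylogenetically scattered taxa flickering through the observed pool
  at trace abundance, which is what makes the tip-shuffle null
  informative (an entirely selection-filtered pool would be shuffled
  onto itself).
* **Heterogeneous selection**: optima $\pm$`env_contrast` on the two
  halves of the strip. Note the honest consequence: within-half pairs
  genuinely experience homogeneous selection, so the intended process
  is modal (cross-half pairs are the slight majority), not unanimous.
* **Dispersal limitation**: every taxon gets a home coordinate and its
  weight decays as $\exp(-d/\lambda)$, $\lambda = 30$ m, with no trait
  selection. Within-plot pairs can legitimately classify as
  homogenizing dispersal (mass effects at short range).
* **Homogenizing dispersal**: a connected core of sites samples one
  shared realized pool draw (mass effects homogenize composition down
  to the identity of rare taxa), while `n_peripheral` sites carry
  independent realized draws. The peripheral sites are essential: a
  dataset in which *every* sample derives from the same pool draw
  yields occurrence and abundance weights that reproduce exactly that
  process, and the Raup-Crick null adapts to it ($RC \approx 0$
  everywhere). Detection of homogenization is only possible against
  regional heterogeneity, so the scenario provides some.
* **Drift**: sites are assembled by the two-step neutral lottery itself
  (richness and totals fixed by a pilot multinomial realization,
  membership by occurrence-weighted sampling, reads by regional
  abundance). This is deliberate: the undominated class is *defined* as
  turnover consistent with that stochastic process, so the drift
  scenario instantiates the definition. Plain independent multinomials
  are measurably *less* variable than the two-step lottery and would be
  (correctly) classified as homogenizing.

Scenario depths default to `log(20000)` (dispersal limitation, drift),
`log(5000)` (selection scenarios) and `log(2000)` (homogenizing
dispersal) mean log-reads: occupancy must be sporadic rather than
saturated for presence-based turnover to exist, which is the situation
in real amplicon surveys where most ASVs occur in a minority of
samples. The selection scenarios default to `n_taxa = 1000` because the
nearest-taxon null has contrast only when per-sample richness is small
relative to the phylogenetic pool (real surveys: thousands of ASVs,
hundreds per sample); the other scenarios default to 300 taxa, where
the signature is depth-driven and a smaller pool keeps the
individual-based null affordable.

What the simulator does **not** emulate: sequence-level error and
chimeras, taxonomy, copy-number variation, bacterial-vs-fungal
biological differences beyond parameter presets, temporal dynamics,
and real soil-chemistry covariance structure (the planted collinear
block is stylized). Passing the recovery tests therefore shows the
*inference machinery* is sound under its own assumptions, not that any
particular field dataset satisfies those assumptions.

## Numerical choices

* PCoA drops negative eigenvalues (no Lingoes/Cailliez correction) and
  logs their summed magnitude; variance proportions are over positive
  eigenvalues only.
* Null z-scores use the $n-1$ standard deviation; enumeration tests in
  the suite use the same convention in the independent oracle.
* Tie tolerance for Raup-Crick equality is `1e-12` on Bray-Curtis
  values; relative-abundance row sums are validated to `1e-9`.
* Because permutation p-values are floored at `1/(n_perm + 1)`,
  Benjamini-Hochberg selection across `m` candidates (e.g. MEMs) needs
  `n_perm` well above `m / alpha` to be able to retain anything; MEM
  selection therefore defaults to 999 permutations.
* Stage seeds in `run_pipeline()` derive deterministically from the
  global seed and the stage name, so toggling one stage never shifts
  another's random stream; reruns are byte-identical.
* Samples with missing chemistry are flagged at read time, never
  imputed; environmental analyses should exclude them.

## Problem sizes used by the validation suite

Scenario-recovery runs use 32 samples (about 21 planted after depth
filtering and grass exclusion), 999 null replicates and the scenario
defaults above; calibration checks use 1000 PERMANOVA replicates and 50
null IndVal tables of 20 features; the Raup-Crick self-consistency
check uses 200 generated pairs at 199 replicates each. These sizes give
the acceptance checks stable Monte-Carlo behavior while keeping a full
validation run in the minutes range on one core.

## Known limitations

* The heterogeneous-selection margin is structural (~52% of pairs cross
  the environmental boundary), so its recovery is modal, not dominant.
* $\beta$NTI power falls quickly as per-sample richness approaches the
  pool size; with saturated occupancy the statistic is near zero by
  construction. Diagnose with the richness/pool ratio before
  interpreting low $|\beta\mathrm{NTI}|$ as drift.
* RCBray inherits the compositional quirks of Bray-Curtis at very
  uneven depths; rarefy first.
* The classifier assigns one label per pair; it does not partition
  variance within a pair among processes.
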