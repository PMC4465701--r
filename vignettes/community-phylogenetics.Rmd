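---
title: "Phylogenetic structure and trait convergence in habitat-filtered metacommunities"
author: "commphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic structure and trait convergence in habitat-filtered metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commphy)
```

## The questions the package answers

Given a set of presence/absence communities sampled along an environmental
contrast (here: forest vs non-forest vegetation) and a spatial gradient
(latitude), together with a phylogeny and morphometric traits for the
species pool, the package asks three linked questions:

1. Is each community phylogenetically structured — clustered or
   overdispersed — relative to its *regional* species pool?
2. Does phylogenetic composition turn over among communities along habitat
   and latitude?
3. Are community trait averages convergent across habitat, and if so, is the
   convergence an imprint of phylogenetic niche conservatism (habitat
   filters selecting whole clades) or independent of phylogeny?

## Distances, NRI and NTI

Reference phylogenies for regional herpetofaunas are typically assembled
from literature topologies without usable branch lengths, so all distances
are **node counts**: the number of edges between two tips, equivalently the
patristic distance with every edge set to length 1. `node_count_distances()`
delegates the path computation to `ape` after forcing unit edge lengths.

For a community of richness $S$ with distance matrix $d$,

$$\mathrm{MPD} = \binom{S}{2}^{-1}\sum_{i<j} d_{ij}, \qquad
  \mathrm{MNTD} = \frac{1}{S}\sum_i \min_{j \ne i} d_{ij}.$$

The null model draws communities of the same richness uniformly from the
site's regional pool — for presence data this is identical to shuffling the
tip labels of the pool subtree. Indices are sign-flipped standardized
effects, so clustering is positive:

$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}
  {\mathrm{sd}(\mathrm{MPD}_{null})},$$

and NTI analogously from MNTD. Two conventions coexist deliberately: Monte
Carlo nulls use the sample ($n-1$) standard deviation, matching the common
implementations this was cross-checked against (`picante::ses.mpd`), while
the exhaustive enumeration available for small pools
(`structure_index(..., exhaustive = TRUE)`) is the full null population and
uses the population form; results record which was used. Significance is
flagged at $|z| > 1.96$ as is conventional for these indices, with the
randomization rank also reported. A community equal to its pool has a
degenerate null (sd 0) and its index is reported as `NA` rather than forced.
Defaults are 9,999 randomizations; calibration and power analyses in the
tests use 199–999 draws, which leaves the indices' operating
characteristics unchanged while keeping the suite fast.

## Fuzzy weighting and PCPS

Compositional analysis of phylogenetic structure works on the
phylogeny-weighted composition **matrix P**. Node-count distances are mapped
to similarities $s_{ij} = 1 - d_{ij}/\max(d)$ — node counts are bounded, so
this ranges them onto $[0,1]$ without further choices — and each species
distributes one unit of belonging over its relatives,
$q_{ij} = s_{ij} / \sum_k s_{kj}$. With site compositions standardized to
relative frequencies, $P = Q\,W_{rel}$: columns of $Q$ and of $P$ sum to 1
by construction (tested to 1e-12), and a star phylogeny — no shared
history — returns the relative composition unchanged, so any difference
between $P$ and $W_{rel}$ is injected phylogenetic signal.

PCPS axes are classical PCoA of Bray–Curtis dissimilarities among the
columns of $P$. No Lingoes/Cailliez correction is applied; axes with
non-positive eigenvalues are dropped and counted, and per-axis fractions are
relative to the positive-eigenvalue total. PCoA scores are only identified
up to rotation and sign, so output signs are fixed (first nonzero score
positive) for reproducible files, and tests compare inter-site distances and
eigenvalue spectra, never raw coordinates. Species scores for ordination
plots are P-weighted averages of site scores — a plotting convenience, not a
canonical projection, and flagged as such.

How many axes carry interpretable signal is decided by db-RDA
F-maximization: for the leading $k$ axes regressed jointly on the
predictors, sums of squares pool over axes,
$R^2 = SS_{exp}/SS_{tot}$ and $F = (R^2/q) / ((1-R^2)/(n-q-1))$, and the $k$
with the greatest $F$ (lowest residual variation per model size) is
retained, ties going to fewer axes. With one axis this is exactly the
ordinary regression $F$, which the tests exploit. Permutation p-values
shuffle whole site rows of the predictor matrix (999 by default).

## Matrix T and the convergence tests

Trait analyses run only on sites where every present species has trait
data, mirroring how real surveys lose sites to missing specimens.
`derive_robustness()` adds stoutness controlled for body size as the
residual of log(CAM) on log(SVL) — the allometric-residual definition; a
raw-circumference alternative is selectable. Traits are then **ranged** to
$[0,1]$ across species. Ranging (rather than z-scoring) is what the
trait-convergence framework this implements uses, and it is the natural way
to mix millimetre lengths with scale counts; constant traits are dropped
with a warning.

Matrix **T** is the community-weighted mean
$T = W_{rel} \hat B$. Convergence is the matrix correlation $\rho(TE)$
between Euclidean dissimilarities of T rows and the 0/1 habitat mismatch,
computed on lower triangles. Because trait structure mixes convergence and
divergence signals, the reported test uses the trait subset maximizing
$\rho(TE)$, found by exhaustive search over all non-empty subsets (511 for
9 candidates; ties resolve to the smallest, then lexicographically first,
subset).

The permutation unit is the **species**: trait rows are shuffled, T and
every dependent dissimilarity are rebuilt, and the statistic is recomputed —
this is the null of "traits unrelated to species identity" that the
framework tests. A site-level Mantel shuffle is exposed as an option but is
not the default. Tests are one-sided (convergence = high $\rho$) and use
the $+1$ correction, $p = (\#\{\rho^* \ge \rho\} + 1)/(n+1)$, so p is never
zero. A permuted trait matrix can collapse to identical community rows;
such draws carry no association and score 0 rather than aborting the test.

Niche conservatism is judged by d-separation on the causal chain
$E \to P \to T$: with $\rho(PT)$ the phylogenetic signal at community level
and

$$\rho(TE.P) = \frac{r_{TE} - r_{TP}\,r_{EP}}
  {\sqrt{(1-r_{TP}^2)(1-r_{EP}^2)}},$$

a significant $\rho(TE)$ that collapses under control for P supports
conservatism; one that survives indicates convergence independent of
phylogeny; a non-significant $\rho(TE)$ means no detectable convergence.
The partial test uses 999 permutations by default (the marginal tests
9,999). A constant $D_P$ carries no information, so its correlations are
taken as 0 and the partial statistic reduces to the plain $\rho(TE)$.
Whether the published $\rho(PT)$ was computed on matrix-P dissimilarities or
on some other phylogeny-weighted quantity is not stated in the source
analyses; matrix P is used here because it already exists in the pipeline,
and the choice is recorded in outputs.

## Regressions and variation partitioning

Structure indices and PCPS axes are regressed on a habitat dummy
(forest = 1) plus absolute southern latitude in decimal degrees —
degree-minute strings such as `24°32'S` parse exactly to minutes/60. With
12 sites and these 2 predictors the overall test has $F_{2,9}$ degrees of
freedom. Two-set variation partitioning reports, from the three fits
y ~ X1, y ~ X2 and y ~ X1+X2: unique fractions $a$ and $c$, shared $b$,
residual $d$. Raw-$R^2$ fractions sum to exactly 1; adjusted-$R^2$
fractions can be negative under suppression and are reported unclipped.
Both forms are always emitted because published fraction percentages do not
always state which form they used; outputs record which form any comparison
matched. The implementation is plain OLS via `stats::lm` and is
cross-checked against `vegan::varpart` in the tests.

## What the generator emulates — and what it does not

`simulate_dataset()` produces ground-truthed data with the study system's
shape (the `snakelike_params()` preset: 182 species, 12 sites, 6 forest / 6
non-forest interleaved along latitudes 3.1–29.7°S, richness 9–61, 8
morphometric traits):

* **Phylogeny** — a pure-birth topology; only its node counts matter.
* **Traits** — independent Brownian motion per trait (rate $\sigma^2 = 1$
  on unit-length edges), exponentiated onto realistic positive scales
  (SVL ≈ 800 mm, scale counts ≈ 60–180) with a log-scale dispersion of
  0.25. A Brownian liability thresholded at its median defines a
  phylogenetically conserved habitat affinity; the habitat effect $\beta$
  shifts the filtered traits (TL, CAM, VS — the trait set that tracks
  habitat use in limbless squamates) by $\pm\beta/2$ by affinity class,
  non-forest species stouter with more ventral scales, forest species
  longer-tailed.
* **Pools** — major clades (average-linkage groups on node-count
  distances, 3 by default) get latitudinal range centres displaced from the
  gradient midpoint by $\gamma \times$ half the span, plus individual
  scatter (span/8); a site's pool is every species whose fixed-width range
  (0.8 × span) covers it. $\gamma = 0$ makes every pool the whole tree.
* **Assembly** — richness is drawn uniformly from the target range (capped
  at the pool), and members are sampled without replacement with weight
  $e^{-\phi}$ for affinity-mismatched species. $\phi = 0$ is exactly
  neutral sampling, which is what the false-positive calibration uses
  (1,000 communities; the $|z|>1.96$ rate must sit in [0.03, 0.07]).

Ground truth (affinity, liability, latent trait values, range centres,
per-site sampling weights) is returned and serialized with every dataset,
so recovery tests assert against known parameters, never snapshots.

The generator deliberately omits several features of the real data:
observational error in presences, correlated trait evolution, non-Brownian
(e.g. OU) dynamics, aquatic-species curation, and pools built from
geographic buffers over ecoregion maps (pools arrive as species lists —
their GIS construction is upstream of this package). Passing tests
therefore demonstrate the statistical machinery's operating characteristics
under a clean assembly model, not the fidelity of any particular empirical
claim.

## Numerical and design choices

* Distances are integers (edge counts); no tolerance issues arise before
  the similarity map. Column-stochasticity of Q and P is exact to machine
  precision and asserted at 1e-12.
* Subset restriction of Q to the observed species renormalizes its columns,
  preserving stochasticity when a tree carries unobserved tips.
* Exhaustive subset search accepts a new optimum only when it improves
  $\rho$ by more than 1e-12, which implements the smallest-subset-first
  tie-break deterministically.
* Species names are matched case-sensitively after whitespace trimming,
  with spaces and underscores equivalent (newick convention).
* Latitude is stored as absolute decimal degrees south; regressions are
  sign-invariant but one convention must be fixed, and it is recorded in
  every output header.
* Singleton communities, degenerate nulls, constant traits, single-habitat
  site sets and constant dissimilarities are all reported (`NA`, warnings,
  or explicit errors naming the site/trait) rather than silently patched.
* Simulation sizes in the tests (reps per condition, randomization counts)
  are chosen to give stable pass/fail behaviour on a single CPU: 50
  replicates per $\beta$ level, 199 permutations inside power loops, 999
  null draws in the calibration run. The vignette states these as the
  package's own study sizes.

## Known limitations

* The published survey values shipped in `inst/extdata` are the per-site
  summary indices; the underlying composition matrix, topology and trait
  measurements exist only as PDF supplements to the original survey and are
  not redistributed, so metacommunity-level published statistics
  ($\rho(TE)=0.572$ and kin) can only be recomputed by users who transcribe
  those supplements into the documented CSV/newick formats.
* NRI/NTI indices are themselves Monte-Carlo estimates; regressions on
  published, rounded index values will differ in the second or third
  decimal from regressions on the original unrounded estimates.
* The d-separation verdict is a two-test decision rule at a fixed
  $\alpha$; it inherits both tests' error rates and should be read
  accordingly at small site counts.
* The pooled-SS db-RDA treats retained axes with equal weight within the
  pooled $R^2$; axes are not eigenvalue-weighted beyond their natural score
  variances.
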