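---
title: "Methods: null-model community phylogenetics with spatial and edaphic covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null-model community phylogenetics with spatial and edaphic covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caatphylo)
```

`caatphylo` implements a complete analysis chain for detecting edaphic and
climatic structuring of plant community phylogenetic pattern. This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## The dated pool phylogeny

All metrics are defined on patristic distances (summed branch lengths, in
units of time) over a regional species-pool tree. Supertree topologies
typically arrive with few reliable node ages, so `date_tree()` builds a
*pseudo-chronogram*: the root is fixed (default `root_age = 137` My, the
commonly used stem age of the eudicots), any internal node named in the
ages table keeps its age, tips sit at zero, and every remaining node is
placed so that consecutive node ages along the path from its nearest dated
ancestor to its nearest dated descendant-or-tip are evenly spaced by node
count. This minimizes branch-length variance subject to the constraints —
adequate for distance-based community metrics, but *not* a substitute for
molecular dating where rate information exists.

Numerical choices worth knowing:

* Nodes are assigned top-down (increasing node depth), each anchored on its
  already-dated parent; on unbranched chains this reproduces the even
  node-count spacing exactly (a chain below a root at 9 My with two free
  nodes gets 6 and 3 My).
* When an undated node has several equally near dated descendants, the
  **largest** age wins — the most constraining choice, fixed for
  determinism. How the original even-spacing tools break this tie is
  undocumented; this is our design decision, not an inherited one.
* A naive per-node interpolation can place a node *below* a deeper dated
  descendant when a short tip path competes with a longer dated path, which
  would create negative branch lengths. Each assigned age is therefore
  floored at the largest constrained age in its subtree. Zero-length
  branches (age ties) are permitted; negative ones are an error.
* Dating is idempotent: re-dating a dated tree under the same constraint
  set changes nothing (tested).

## NRI and NTI

For a site sample $S$ with $|S| \ge 2$ and patristic distances $d$:

$$\mathrm{MPD} = \binom{|S|}{2}^{-1}\sum_{i<j} d(i,j), \qquad
  \mathrm{MNTD} = \frac{1}{|S|}\sum_{i} \min_{j \ne i} d(i,j).$$

Both are *unweighted* (incidence) forms: the inputs are floristic presence
lists, so abundance weighting is deliberately out of scope. The null model
reshuffles taxa labels across the tips of the pool tree; for an incidence
sample this is equivalent to drawing a uniform random subset of equal
richness, which is how `ses_metric()` implements it. Then

$$\mathrm{SES} = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{sd}(\mathrm{null})},
  \qquad \mathrm{NRI} = -\mathrm{SES}(\mathrm{MPD}), \quad
  \mathrm{NTI} = -\mathrm{SES}(\mathrm{MNTD}),$$

with the $n-1$ sample SD (standard SES practice, stable at the default
1000 permutations). Indices beyond $\pm 1.96$ are flagged as significant
clustering/overdispersion under the normal approximation. When the sample
*is* the pool the null has zero spread; the result carries an explicit
degenerate status rather than a number.

The randomization pool defaults to the **full** supplied tree even when a
community matrix covers a subset (e.g. growth-form partitions), matching
the convention of standardizing every assemblage against the complete
regional pool; `restrict_pool = TRUE` switches to subset-only
randomization. Which convention the original growth-form tables used is
not recoverable from the publication; the full pool is the default because
it is the stated null ("all species sampled").

Reproducibility: every randomized stage takes one master seed and derives
per-unit streams by hashing the site id and metric name (`derive_seed()`),
so per-site results are independent of site order and of which other sites
are present.

## Phylogenetic signal in life forms

The trait is the five-state Raunkiaer life form. Harmonization follows the
bud-position logic: aerophytes/epiphytes/hemiparasites are phanerophytes;
cacti and succulents are phanerophytes or chamaephytes by adult size;
climbers are therophytes if they senesce in the dry season, otherwise
phanerophytes or chamaephytes by size; conflicting multi-survey reports
resolve to the form with the *least protected* buds
(phanerophyte > chamaephyte > hemicryptophyte > cryptophyte > therophyte).

The statistic is the minimum number of state changes on the fixed tree,
computed by Hartigan's dynamic program, which — unlike the binary Fitch
pass — is exact on multifurcating trees; megatree topologies are heavily
polytomous, so this matters. The null swaps tip states uniformly
(999 reshuffles by default) and

$$p = \frac{1 + \#\{\mathrm{null} \le \mathrm{obs}\}}{n_\mathrm{rand} + 1}.$$

The add-one inclusion of the observed value is the standard permutation
convention; whether the original ad-hoc implementation used $\le$ or $<$ is
unknowable, and with hundreds of tips the difference is immaterial. Note
the change count is integer-valued: on small trees ties make the test
conservative (observed rejection slightly under $\alpha$), which is why the
size calibration in the tests uses a 128-tip tree.

## Spatial statistics

Distances are great-circle (haversine, spherical radius 6371 km). The
correlogram uses **equal-count** distance classes: the $n(n-1)/2$ pair
distances are sorted and cut into $k$ consecutive groups of equal size
(remainder to the first classes; ties kept adjacent by stable sort). With
13 sites and $k = 6$ this gives exactly 13 pairs per class. Within a class,
binary weights $w_{ij} = 1$ define

$$I = \frac{n}{S_0}\,
  \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j - \bar x)}{\sum_i (x_i-\bar x)^2},$$

unstandardized, the classic equal-frequency correlogram form (a
row-standardized option exists but is not default — the original tooling's
choice is unstated). Class "centroids" are the mean member distance;
conventions differ here and printed centroids from other software need not
match ours, but the $I$ values are binning-convention stable (verified: the
13-site reproduction matches at every class). Permutation $p$ per class
shuffles values across sites and compares $|I - E[I]|$ with
$E[I] = -1/(n-1)$, two-sided with add-one smoothing — our choice, again in
the absence of a stated convention.

PCNM filters: the distance matrix is truncated at $t$ (default: the
largest minimum-spanning-tree edge, which keeps the neighbour graph
connected), entries beyond $t$ replaced by $4t$, then Gower double-centering
of $-D^2/2$ and symmetric eigen-decomposition. Filters are the
positive-eigenvalue eigenvectors, descending; each is centered and the set
is orthogonal (checked to $10^{-8}$, and eigenvalues agree with an
independent implementation to the same tolerance). Only the first,
broad-scale filter enters the ANCOVA by default (`n_filters` admits more).

## Regression stages

`vif_screen()` computes $\mathrm{VIF}_k = 1/(1-R^2_k)$ and drops the worst
predictor one at a time until all values are at or below the threshold
(default 10 — the conventional cut; the original analysis reports which
variables were excluded but not its threshold). Perfect collinearity is
reported as infinite VIF and dropped first.

`ancova()` fits index ~ intercept + climate terms + treatment-coded edaphic
dummies + the spatial filter, with *sedimentary* as reference (the
published coefficient tables list only crystalline and inselberg rows,
implying that baseline), and flags coefficients at $\alpha = 0.10$ by
default (the tables' stated level; the correlogram stage uses 0.05 — both
are parameters). P-values are per-coefficient with no multiplicity
correction, matching the original reporting.

`variance_partition()` uses the three-fit identity
$[b] = [a{+}b] + [b{+}c] - [a{+}b{+}c]$ with Ezekiel-adjusted $R^2$ by
default (raw $R^2$ available); adjusted fractions can legitimately be
slightly negative. The joint fit tolerates aliasing between the climate and
edaphic blocks (total-overlap designs are meaningful: everything lands in
the shared fraction), and the published "interaction" column is interpreted
as fraction $[b]$ — implied, though never stated, by the defining identity.

## The synthetic study system

The generators exist so that every stage is testable without any external
download, and so that the pipeline's *inferential* behaviour can be
checked against constructions with known truth:

* `simulate_yule_tree()`: ultrametric pure-birth pool trees.
* `evolve_discrete_trait()`: symmetric Markov life forms; low rates give
  the clade-structured regime the signal test should detect.
* `evolve_continuous_niche()`: Brownian niche optima driving filtering.
* `assemble_communities()`: neutral (uniform subsets), filtering (species
  within a niche tolerance of the site environment, nearest-optimum
  top-up), repulsion (greedy max–min patristic selection; exact max–min
  subset choice is combinatorial and only the induced sign of
  overdispersion matters for testing).
* `simulate_sites()`: coordinates uniform on an 800 km square centred on
  the Caatinga; covariates from a Gaussian process with exponential
  covariance (default range 200 km, the scale at which short-distance
  autocorrelation was observed), realistic means/SDs for semi-arid
  temperature and precipitation, two deliberately collinear precipitation
  summaries to exercise the VIF screen, and edaphic classes in spatially
  blocked regions (k-means on coordinates). Dense Cholesky with $10^{-8}$
  jitter — site counts are small.

What passing these tests shows: the pipeline recovers the *direction and
significance structure* of known assembly processes (filtering ⇒ positive
median NRI with most sites flagged; repulsion ⇒ negative; neutral ⇒
calibrated 5% false-flag rate), the signal test has power 1 against perfect
clade structure and holds its size under shuffling, and the model stage's
coverage and false-positive rates are nominal. What it does **not** show:
anything about real floristic sampling — uneven effort, taxonomic
uncertainty, spatially aggregated richness, non-ultrametric topology error
— none of which the generators emulate, by design.

## Problem sizes and defaults

The study-scale defaults mirror the published constants: 1000 SES
permutations, 999 signal reshuffles, 6 distance classes, root age 137 My,
clustering threshold 1.96, model $\alpha = 0.10$. The test-suite
calibrations use 1000 neutral sites at 200 permutations, 500 replicates
for the signal-size and model-calibration checks, and a 100–150 species
pool with richness 10–30 — sizes chosen so the full stochastic battery
completes in a couple of minutes while keeping Monte-Carlo error well
inside the asserted bands (binomial SE under 1 percentage point at 500–1000
replicates).

## Known limitations

* The pseudo-chronogram is only as good as its age constraints; with none,
  node ages are pure node-count interpolation.
* The label-shuffle null is the only null model: no independent-swap or
  richness-stratified matrix nulls.
* ANCOVA assumes independent Gaussian errors; the spatial filter absorbs
  broad-scale autocorrelation but the package deliberately stops short of
  SAR/CAR error models.
* Equal-count classes with few sites make the long-distance classes wide
  and their $I$ values dominated by a handful of extreme pairs — visible in
  the 13-site example.
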