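# caatphylo

Community phylogenetics of seasonally dry tropical plant assemblages.

Seasonally dry tropical formations (SDTFs) such as the Brazilian Caatinga
impose a severe shared environmental filter — months of drought — yet their
substrates (deep sedimentary soils, shallow crystalline soils, near-bare
inselberg outcrops) differ sharply in how much water they hold. If drought
strategies are phylogenetically conserved, assemblages under stronger
filtering should be phylogenetically *clustered* (co-occurring species more
related than chance), while weaker filtering or stronger biotic repulsion
should yield *overdispersion*. `caatphylo` is a tested, reusable R pipeline
for asking exactly that question from floristic site lists, a dated regional
phylogeny, Raunkiaer life forms, and site coordinates/covariates — for any
SDTF-style study system, synthetic or real.

## What it computes

For a site with species set *S* and patristic distances *d* on the pool
phylogeny:

- **MPD** = mean of *d(i, j)* over all pairs in *S*; **MNTD** = mean over
  *i* ∈ *S* of min<sub>j≠i</sub> *d(i, j)*.
- **SES** of either metric under tip-label randomization:
  SES = (obs − mean<sub>null</sub>) / sd<sub>null</sub>, with
  **NRI = −SES(MPD)** and **NTI = −SES(MNTD)**; |index| > 1.96 flags
  significant clustering (+) or overdispersion (−).
- **Phylogenetic signal** in the 5-state Raunkiaer life form: the minimum
  parsimony count of state changes on the tree (Hartigan's algorithm, exact
  on polytomies) against a null of uniformly reshuffled tip states.
- **Spatial structure**: Moran's I correlograms over equal-count
  great-circle distance classes with permutation tests, and PCNM spatial
  eigenvector filters from the truncated inter-site distance matrix.
- **Environmental models**: VIF screening of climate covariates, ANCOVA of
  each index on climate + edaphic class (treatment-coded) + the first
  spatial filter, and variance partitioning
  [b] = [a+b] + [b+c] − [a+b+c] into pure-climate, shared, pure-edaphic and
  unexplained fractions (Ezekiel-adjusted R² by default).

Supporting machinery includes newick I/O, BLADJ-style even-spacing node
dating against an ages table (root default 137 My, the eudicot stem age),
and generators for complete synthetic study systems (Yule pool trees,
conserved discrete and Brownian traits, neutral / filtering / repulsion
community assembly, Gaussian-process site covariates).

## Worked example

The package ships the published 13-site Caatinga tables (coordinates,
substrate classes, and per-site NRI/NTI for all, woody and herbaceous
species) as a fixture. Recomputing the spatial autocorrelation of the
all-species net relatedness index:

```r
library(caatphylo)
tab <- caatinga_tables()
cg <- correlogram(tab$nri_all, tab, k = 6, n_perm = 999, seed = 1)
round(cg[c("centroid_km", "n_pairs", "I", "p")], 2)
#>   centroid_km n_pairs     I    p
#> 1       79.27      13  0.92 0.00
#> 2      240.91      13  0.07 0.50
#> 3      373.53      13  0.01 0.57
#> 4      449.20      13  0.04 0.54
#> 5      561.01      13 -0.56 0.05
#> 6      721.10      13 -0.97 0.00
```

Sites within ~100 km have strongly similar phylogenetic structure
(I = 0.92, p ≤ 0.001) while the most distant site pairs are strongly
dissimilar (I = −0.97) — the signature of regionally blocked edaphic
environments. `analysis/` contains the full numbered workflow:

1. `01_simulate_study.R` — generate a synthetic filtering-mode study;
2. `02_run_pipeline.R` — run every stage (`run_all()`) on it;
3. `03_caatinga_correlogram.R` — the 13-site reproduction above, all six
   indices;
4. `04_assembly_contrast.R` — neutral vs filtering vs repulsion assembly
   recovered as mean NRI ≈ 0, > 0, < 0 respectively.

Each script prints what it found and writes its tables under `results/`.

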